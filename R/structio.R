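#' @import dplyr
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
#' @importFrom purrr map map_dbl map_int map_lgl map2
NULL

# ---- structure container -----------------------------------------------

STANDARD_AA <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

AA_THREE_TO_ONE <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)

AA_ONE <- unname(AA_THREE_TO_ONE)

SOLVENT_RES <- c("HOH", "WAT", "TIP3", "TIP", "SOL", "DOD")
ION_RES <- c(
  "NA", "CL", "K", "MG", "ZN", "MN", "FE", "CD", "HG", "NI", "CU",
  "CO", "BR", "IOD", "CS", "LI", "SO4", "PO4"
)

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
BACKBONE_H <- c("H", "HN", "HA", "H1", "H2", "H3", "HA2", "HA3", "HT1", "HT2", "HT3")

# Bondi-style van der Waals radii (angstrom), keyed by element symbol
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, B = 1.92
)

#' Van der Waals radius by element
#'
#' Looks up Bondi-style van der Waals radii for element symbols. Unknown
#' elements raise an error rather than receiving a silent default, so that
#' surface-area and contact computations never run on unparameterised atoms.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in angstrom.
#' @export
#' @examples
#' vdw_radius(c("C", "N", "O"))
vdw_radius <- function(element) {
  el <- toupper(element)
  unknown <- setdiff(unique(el), names(VDW_RADII))
  if (length(unknown) > 0) {
    abort(paste0(
      "No van der Waals radius for element(s): ",
      paste(unknown, collapse = ", ")
    ))
  }
  unname(VDW_RADII[el])
}

infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% c("CL", "BR", "SE", "FE", "ZN", "MG", "NA"), two, one)
}

#' Construct a structure table
#'
#' Builds the atom-level tibble used throughout the package: one row per
#' atom with chain, author residue number (`seq_id`, preserved verbatim from
#' the source and never renumbered), residue type, atom name, element and
#' coordinates in angstrom. Side-chain membership is every atom except the
#' backbone N, CA, C, O (plus OXT) and backbone hydrogens; glycine's
#' side-chain set is empty.
#'
#' @param atoms A data frame with at least columns `chain`, `seq_id`,
#'   `res_type`, `atom`, `x`, `y`, `z`. Optional: `serial`, `ins`,
#'   `element`, `occ`, `is_ligand`.
#' @param title Optional title string carried as an attribute.
#' @return A tibble of class `kin_structure`.
#' @export
new_structure <- function(atoms, title = "") {
  atoms <- as_tibble(atoms)
  req <- c("chain", "seq_id", "res_type", "atom", "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing structure columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"serial" %in% names(atoms)) atoms$serial <- seq_len(nrow(atoms))
  if (!"ins" %in% names(atoms)) atoms$ins <- ""
  atoms$ins[is.na(atoms$ins)] <- ""
  if (!"element" %in% names(atoms)) atoms$element <- infer_element(atoms$atom)
  if (!"occ" %in% names(atoms)) atoms$occ <- 1
  if (!"is_ligand" %in% names(atoms)) {
    atoms$is_ligand <- !(atoms$res_type %in% STANDARD_AA)
  }
  atoms$seq_id <- as.integer(atoms$seq_id)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("Non-finite coordinates in structure")
  }
  atoms$is_sidechain <- !atoms$is_ligand &
    !(atoms$atom %in% BACKBONE_ATOMS) & !(atoms$atom %in% BACKBONE_H)
  atoms <- atoms[, unique(c(
    "serial", "chain", "seq_id", "ins", "res_type", "atom", "element",
    "x", "y", "z", "occ", "is_ligand", "is_sidechain",
    setdiff(names(atoms), c(
      "serial", "chain", "seq_id", "ins", "res_type", "atom", "element",
      "x", "y", "z", "occ", "is_ligand", "is_sidechain"
    ))
  ))]
  key <- paste(atoms$chain, paste0(atoms$seq_id, atoms$ins), sep = ":")
  pair <- unique(paste(key, atoms$res_type, sep = "|"))
  if (anyDuplicated(sub("\\|.*", "", pair)) > 0) {
    abort("A (chain, seq_id) key maps to more than one residue type")
  }
  structure(
    atoms,
    class = c("kin_structure", class(as_tibble(atoms))),
    title = title
  )
}

#' @export
print.kin_structure <- function(x, ...) {
  cat(sprintf(
    "# kin_structure: %d atoms, %d residues (%d ligand)\n",
    nrow(x), length(unique(residue_keys(x))),
    length(unique(residue_keys(x)[x$is_ligand]))
  ))
  NextMethod()
}

#' Residue keys of a structure
#'
#' The universal join key used across all modules: `"chain:seq_id"` with any
#' insertion code appended to the residue number.
#'
#' @param x A `kin_structure` or an atom data frame with `chain`, `seq_id`
#'   (and optionally `ins`) columns.
#' @return Character vector, one key per atom row.
#' @export
residue_keys <- function(x) {
  ins <- if ("ins" %in% names(x)) x$ins else ""
  paste(x$chain, paste0(x$seq_id, ins), sep = ":")
}

#' Per-residue summary of a structure
#'
#' @param x A `kin_structure`.
#' @return Tibble with one row per residue: `key`, `chain`, `seq_id`, `ins`,
#'   `res_type`, `is_ligand`, `n_atoms`.
#' @export
residue_table <- function(x) {
  res_key_vec <- residue_keys(x)
  x |>
    as_tibble() |>
    mutate(key = res_key_vec) |>
    group_by(.data$key) |>
    summarise(
      chain = .data$chain[1], seq_id = .data$seq_id[1], ins = .data$ins[1],
      res_type = .data$res_type[1], is_ligand = .data$is_ligand[1],
      n_atoms = dplyr::n(), .groups = "drop"
    ) |>
    arrange(match(.data$key, unique(residue_keys(x))))
}

coords_matrix <- function(x) {
  m <- cbind(x$x, x$y, x$z)
  colnames(m) <- c("x", "y", "z")
  m
}

set_coords <- function(structure, m) {
  structure$x <- m[, 1]
  structure$y <- m[, 2]
  structure$z <- m[, 3]
  structure
}

# ---- ensemble container ------------------------------------------------

#' Construct a conformational ensemble
#'
#' An ensemble is a shared topology (a [new_structure()] table) plus an
#' ordered set of coordinate frames, stored as an `n_atoms x 3 x n_frames`
#' array. Every frame must supply exactly one coordinate per topology atom.
#'
#' @param topology A `kin_structure`.
#' @param coords Array `n_atoms x 3 x n_frames`, or a list of `n_atoms x 3`
#'   matrices.
#' @param frame_spacing Informational time spacing between frames.
#' @return An object of class `kin_ensemble`.
#' @export
new_ensemble <- function(topology, coords, frame_spacing = NA_real_) {
  if (is.list(coords)) {
    coords <- array(
      unlist(coords),
      dim = c(nrow(coords[[1]]), 3, length(coords))
    )
  }
  if (dim(coords)[1] != nrow(topology) || dim(coords)[2] != 3) {
    abort(sprintf(
      "Frame coordinates (%d x %d) do not match topology (%d atoms)",
      dim(coords)[1], dim(coords)[2], nrow(topology)
    ))
  }
  if (any(!is.finite(coords))) abort("Non-finite coordinates in ensemble")
  structure(
    list(topology = topology, coords = coords, frame_spacing = frame_spacing),
    class = "kin_ensemble"
  )
}

#' @export
print.kin_ensemble <- function(x, ...) {
  cat(sprintf(
    "# kin_ensemble: %d frames x %d atoms (%d residues)\n",
    n_frames(x), nrow(x$topology), length(unique(residue_keys(x$topology)))
  ))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param ensemble A `kin_ensemble`.
#' @return Integer frame count.
#' @export
n_frames <- function(ensemble) dim(ensemble$coords)[3]

frame_structure <- function(ensemble, i) {
  set_coords(ensemble$topology, ensemble$coords[, , i])
}

as_ensemble <- function(x) {
  if (inherits(x, "kin_ensemble")) return(x)
  new_ensemble(x, array(coords_matrix(x), dim = c(nrow(x), 3, 1)))
}

#' Tidy an ensemble into a long coordinate table
#'
#' @param x A `kin_ensemble`.
#' @param ... Unused.
#' @return Tibble with one row per atom per frame.
#' @export
tidy.kin_ensemble <- function(x, ...) {
  nf <- n_frames(x)
  base <- as_tibble(x$topology)[, c("serial", "chain", "seq_id", "res_type", "atom")]
  purrr::map_dfr(seq_len(nf), function(i) {
    out <- base
    out$frame <- i
    out$x <- x$coords[, 1, i]
    out$y <- x$coords[, 2, i]
    out$z <- x$coords[, 3, i]
    out
  })
}

# ---- PDB I/O -----------------------------------------------------------

#' Read a PDB file
#'
#' Parses ATOM/HETATM records via bio3d, preserving author chain and residue
#' numbering verbatim. Multi-model files yield a [new_ensemble()]; altloc
#' duplicates are resolved to the highest occupancy (ties: first
#' encountered); crystallographic waters and simple ions are dropped unless
#' `keep_solvent = TRUE`.
#'
#' @param path Path to a PDB file.
#' @param model `"all"` (default) or a 1-based model number. Single-model
#'   files return a `kin_structure` either way.
#' @param keep_solvent Retain waters and monoatomic ions.
#' @return A `kin_structure`, or a `kin_ensemble` for multi-model files when
#'   `model = "all"`.
#' @export
read_pdb <- function(path, model = "all", keep_solvent = FALSE) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  atom_idx <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(atom_idx) == 0) abort(paste0("No ATOM/HETATM records in ", path))
  bad <- atom_idx[is.na(suppressWarnings(as.numeric(substr(lines[atom_idx], 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines[atom_idx], 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines[atom_idx], 47, 54))))]
  if (length(bad) > 0) {
    abort(sprintf("Malformed coordinate record at line %d of %s", bad[1], path))
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  multi <- length(model_starts) > 1
  if (multi) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(model_starts)) {
      abort("Unbalanced MODEL/ENDMDL records")
    }
    counts <- purrr::map2_int(model_starts, ends, function(s, e) {
      sum(rec[s:e] %in% c("ATOM  ", "HETATM"))
    })
    if (length(unique(counts)) > 1) {
      abort(sprintf(
        "MODEL sections differ in atom count (%s)",
        paste(unique(counts), collapse = ", ")
      ))
    }
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  n_models <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1
  if (!identical(model, "all")) {
    if (!is.numeric(model) || model < 1 || model > n_models) {
      abort(sprintf("Requested model %s but file has %d model(s)", model, n_models))
    }
  }
  atoms <- tibble(
    serial = at$eleno,
    chain = ifelse(is.na(at$chain), "A", at$chain),
    seq_id = at$resno,
    ins = ifelse(is.na(at$insert), "", at$insert),
    res_type = at$resid,
    atom = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "", infer_element(at$elety), at$elesy),
    occ = ifelse(is.na(at$o), 1, at$o),
    alt = ifelse(is.na(at$alt), "", at$alt),
    is_ligand = !(at$resid %in% STANDARD_AA)
  )
  # altloc: keep highest occupancy, tie -> first encountered
  atoms$row <- seq_len(nrow(atoms))
  keep <- atoms |>
    group_by(.data$chain, .data$seq_id, .data$ins, .data$atom) |>
    slice(which.max(.data$occ)) |>
    ungroup() |>
    pull(.data$row) |>
    sort()
  if (!keep_solvent) {
    sel <- atoms$res_type[keep] %in% SOLVENT_RES |
      (atoms$res_type[keep] %in% ION_RES)
    keep <- keep[!sel]
  }
  atoms <- atoms[keep, setdiff(names(atoms), c("alt", "row"))]
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz else matrix(pdb$xyz, nrow = 1)
  get_frame <- function(i) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)[keep, , drop = FALSE]
    m
  }
  build <- function(i) {
    m <- get_frame(i)
    new_structure(
      mutate(atoms, x = m[, 1], y = m[, 2], z = m[, 3]),
      title = basename(path)
    )
  }
  if (n_models == 1 || !identical(model, "all")) {
    return(build(if (identical(model, "all")) 1 else model))
  }
  topo <- build(1)
  coords <- array(0, dim = c(nrow(topo), 3, n_models))
  for (i in seq_len(n_models)) coords[, , i] <- get_frame(i)
  new_ensemble(topo, coords)
}

#' Write a structure or ensemble to PDB
#'
#' Fixed-width ATOM/HETATM records; ensembles become MODEL/ENDMDL blocks.
#' Coordinates are stored at the PDB's three-decimal precision, so a
#' read/write round trip reproduces them to 1e-3 angstrom.
#'
#' @param x A `kin_structure` or `kin_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt_atom <- function(s) {
    rec <- ifelse(s$is_ligand, "HETATM", "ATOM  ")
    nm <- ifelse(
      nchar(s$atom) >= 4, substr(s$atom, 1, 4),
      paste0(" ", formatC(s$atom, width = -3))
    )
    sprintf(
      "%s%5d %-4s %-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, s$serial %% 100000, nm, substr(s$res_type, 1, 3),
      substr(s$chain, 1, 1), s$seq_id, ifelse(s$ins == "", " ", s$ins),
      s$x, s$y, s$z, s$occ, 0, toupper(s$element)
    )
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (inherits(x, "kin_ensemble")) {
    for (i in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(fmt_atom(frame_structure(x, i)), con)
      writeLines("ENDMDL", con)
    }
  } else {
    writeLines(fmt_atom(x), con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- labelled matrix I/O -----------------------------------------------

#' Write a labelled square matrix as TSV
#'
#' @param m Square numeric matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  if (nrow(m) != ncol(m)) abort("Matrix must be square")
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  df <- as.data.frame(m)
  names(df) <- labels
  df <- cbind(key = labels, df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' @param path Path written by [write_matrix_tsv()].
#' @param correlation Validate as a correlation matrix (symmetric, unit
#'   diagonal, entries in `[-1, 1]`).
#' @return Numeric matrix with row/column labels.
#' @export
read_matrix_tsv <- function(path, correlation = FALSE) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1) {
    abort(sprintf(
      "Ragged matrix TSV: line %d has %d fields, expected %d",
      which(nf != nf[1])[1], nf[which(nf != nf[1])[1]], nf[1]
    ))
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    abort(sprintf("Matrix in %s is not square (%d x %d)", path, nrow(m), ncol(m)))
  }
  dimnames(m) <- list(labels, colnames(df)[-1])
  storage.mode(m) <- "double"
  if (correlation) validate_correlation(m)
  m
}

#' Validate a residue cross-correlation matrix
#'
#' Checks the container invariants: square, symmetric within 1e-12, exact
#' unit diagonal, entries in `[-1, 1]`.
#'
#' @param m Labelled square matrix.
#' @return `m`, invisibly, or an error.
#' @export
validate_correlation <- function(m) {
  if (nrow(m) != ncol(m)) abort("Correlation matrix must be square")
  if (max(abs(m - t(m))) > 1e-12) abort("Correlation matrix must be symmetric")
  if (any(abs(diag(m) - 1) > 1e-12)) abort("Correlation diagonal must be 1")
  if (any(m < -1 - 1e-12 | m > 1 + 1e-12)) abort("Correlations must lie in [-1, 1]")
  invisible(m)
}
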