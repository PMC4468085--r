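# Contact counting and classification (LPC-style 8 atom classes),
# Shrake-Rupley solvent-accessible surface area, relative accessibility.

ATOM_CLASSES <- c(
  "hydrophilic", "hydrophobic", "aromatic", "acceptor", "donor",
  "neutral", "neutral-donor", "neutral-acceptor"
)

the_cache <- new.env(parent = emptyenv())

load_tsv_resource <- function(name) {
  if (is.null(the_cache[[name]])) {
    path <- system.file("extdata", name, package = "kinnet")
    if (path == "") path <- file.path("inst", "extdata", name)
    the_cache[[name]] <- readr::read_tsv(path, show_col_types = FALSE)
  }
  the_cache[[name]]
}

#' The shipped atom classification table
#'
#' Eight LPC-style interaction classes (hydrophilic, hydrophobic, aromatic,
#' acceptor, donor, neutral, neutral-donor, neutral-acceptor) keyed by
#' residue type and atom name. The table reconstructs the published LPC
#' classification scheme; `res_type = "*"` rows are backbone/pseudo-atom
#' fallbacks. Users may supply their own table of the same shape.
#'
#' @param path Optional path to a replacement TSV with columns `res_type`,
#'   `atom`, `class`.
#' @return Tibble with columns `res_type`, `atom`, `class`.
#' @export
atom_class_table <- function(path = NULL) {
  if (!is.null(path)) {
    tbl <- readr::read_tsv(path, show_col_types = FALSE)
  } else {
    tbl <- load_tsv_resource("atom_classes.tsv")
  }
  bad <- setdiff(unique(tbl$class), ATOM_CLASSES)
  if (length(bad) > 0) {
    abort(paste0("Unknown atom class(es) in table: ", paste(bad, collapse = ", ")))
  }
  tbl
}

#' Classify atoms into the 8 LPC-style interaction classes
#'
#' Looks up each atom by (residue type, atom name), falling back to the
#' wildcard backbone rows, then to an element-based default for ligand/HET
#' atoms (C hydrophobic, N donor, O acceptor, otherwise neutral). Atoms with
#' no assignment are classed `"neutral"` with a warning.
#'
#' @param structure A `kin_structure`.
#' @param table Classification table from [atom_class_table()].
#' @return The structure tibble with an added `class` column.
#' @export
classify_atoms <- function(structure, table = atom_class_table()) {
  specific <- match(
    paste(structure$res_type, structure$atom),
    paste(table$res_type, table$atom)
  )
  wildcard <- match(
    paste("*", structure$atom),
    paste(table$res_type, table$atom)
  )
  cls <- table$class[ifelse(is.na(specific), wildcard, specific)]
  el <- toupper(structure$element)
  fallback <- dplyr::case_when(
    el == "C" ~ "hydrophobic",
    el == "N" ~ "donor",
    el == "O" ~ "acceptor",
    TRUE ~ "neutral"
  )
  use_fallback <- is.na(cls) & structure$is_ligand
  cls[use_fallback] <- fallback[use_fallback]
  if (any(is.na(cls) & toupper(structure$element) != "H")) {
    warn(sprintf(
      "%d heavy atom(s) missing from the class table; classed 'neutral'",
      sum(is.na(cls) & toupper(structure$element) != "H")
    ))
  }
  cls[is.na(cls)] <- "neutral"
  out <- structure
  out$class <- cls
  out
}

residue_contact_atoms <- function(structure, atoms = c("sidechain", "heavy", "all")) {
  atoms <- match.arg(atoms)
  heavy <- toupper(structure$element) != "H"
  if (atoms == "all") return(rep(TRUE, nrow(structure)))
  if (atoms == "heavy") return(heavy)
  # side-chain heavy atoms; glycine contributes its CA so that it can form
  # network edges at all (logged once per call via attribute)
  sel <- heavy & (structure$is_sidechain | structure$is_ligand)
  gly <- structure$res_type == "GLY" & structure$atom == "CA"
  sel | gly
}

pair_dist2 <- function(a, b) {
  pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b), 0)
}

#' Count inter-residue atom-pair contacts
#'
#' Number of distinct atom pairs between two residues within the cutoff
#' (comparison is `<=`, so a pair exactly at the cutoff counts). The default
#' atom set is side-chain heavy atoms; glycine contributes its CA.
#'
#' @param structure A `kin_structure`.
#' @param key_i,key_j Residue keys (see [residue_keys()]).
#' @param cutoff Distance cutoff in angstrom (default 4.5).
#' @param atoms `"sidechain"` (default), `"heavy"`, or `"all"`.
#' @return Integer contact count; symmetric in its arguments.
#' @export
count_contacts <- function(structure, key_i, key_j, cutoff = 4.5,
                           atoms = "sidechain") {
  sel <- residue_contact_atoms(structure, atoms)
  keys <- residue_keys(structure)
  ai <- coords_matrix(structure[sel & keys == key_i, ])
  aj <- coords_matrix(structure[sel & keys == key_j, ])
  if (nrow(ai) == 0 || nrow(aj) == 0) return(0L)
  sum(pair_dist2(ai, aj) <= cutoff^2)
}

#' All residue-pair contact counts of a structure
#'
#' Vectorised enumeration of every atom pair within the cutoff, tallied per
#' residue pair. Used both for interaction-strength networks and for
#' normalization-factor estimation.
#'
#' @inheritParams count_contacts
#' @return Tibble with `key_i`, `key_j` (ordered by first occurrence,
#'   `key_i` before `key_j`), and `n_pairs`.
#' @export
contact_map <- function(structure, cutoff = 4.5, atoms = "sidechain") {
  sel <- which(residue_contact_atoms(structure, atoms))
  keys_all <- residue_keys(structure)
  keys <- keys_all[sel]
  xyz <- coords_matrix(structure[sel, ])
  d2 <- pair_dist2(xyz, xyz)
  hit <- which(upper.tri(d2) & d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(key_i = character(), key_j = character(), n_pairs = integer()))
  }
  ki <- keys[hit[, 1]]
  kj <- keys[hit[, 2]]
  same <- ki == kj
  ki <- ki[!same]
  kj <- kj[!same]
  ord <- match(ki, unique(keys_all)) > match(kj, unique(keys_all))
  tmp <- ki[ord]
  ki[ord] <- kj[ord]
  kj[ord] <- tmp
  tibble(key_i = ki, key_j = kj) |>
    count(.data$key_i, .data$key_j, name = "n_pairs") |>
    arrange(
      match(.data$key_i, unique(keys_all)),
      match(.data$key_j, unique(keys_all))
    )
}

#' Ensemble-averaged ligand contacts per residue
#'
#' For each frame, counts heavy-atom pairs within the cutoff between ligand
#' atoms and each protein residue, with each contacting pair tallied under
#' the LPC-style class of its protein atom; reports the per-residue mean
#' count and mean class tallies over frames.
#'
#' @param ensemble A `kin_ensemble` (or `kin_structure`, treated as one
#'   frame) whose topology contains a ligand residue.
#' @param cutoff Contact cutoff in angstrom (default 4.5).
#' @param table Atom class table.
#' @return Tibble: `key`, `res_type`, `mean_contacts`, one `mean_<class>`
#'   column per interaction class.
#' @export
ensemble_ligand_contacts <- function(ensemble, cutoff = 4.5,
                                     table = atom_class_table()) {
  ensemble <- as_ensemble(ensemble)
  topo <- classify_atoms(ensemble$topology, table)
  if (!any(topo$is_ligand)) abort("No ligand residue in topology")
  heavy <- toupper(topo$element) != "H"
  lig <- which(topo$is_ligand & heavy)
  prot <- which(!topo$is_ligand & heavy)
  keys <- residue_keys(topo)
  nf <- n_frames(ensemble)
  per_frame <- purrr::map(seq_len(nf), function(t) {
    xyz <- ensemble$coords[, , t]
    d2 <- pair_dist2(xyz[prot, , drop = FALSE], xyz[lig, , drop = FALSE])
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    tibble(
      key = keys[prot][hit[, 1]],
      class = topo$class[prot][hit[, 1]]
    )
  })
  counts <- purrr::imap_dfr(per_frame, function(df, t) mutate(df, frame = t)) |>
    count(.data$frame, .data$key, .data$class)
  prot_res <- residue_table(topo[!topo$is_ligand, ])
  if (nrow(counts) == 0) {
    out <- prot_res[, c("key", "res_type")]
    out$mean_contacts <- 0
    for (cl in ATOM_CLASSES) out[[paste0("mean_", cl)]] <- 0
    return(out)
  }
  wide <- counts |>
    group_by(.data$key, .data$class) |>
    summarise(mean_n = sum(.data$n) / nf, .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "class", values_from = "mean_n",
      values_fill = 0, names_prefix = "mean_"
    )
  out <- prot_res[, c("key", "res_type")] |>
    left_join(wide, by = "key")
  for (cl in paste0("mean_", ATOM_CLASSES)) {
    if (!cl %in% names(out)) out[[cl]] <- 0
  }
  out[is.na(out)] <- 0
  out$mean_contacts <- rowSums(out[paste0("mean_", ATOM_CLASSES)])
  out[, c("key", "res_type", "mean_contacts", paste0("mean_", ATOM_CLASSES))]
}

sphere_points <- function(n) {
  # deterministic golden-section spiral on the unit sphere
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere over every heavy atom using a deterministic
#' golden-spiral quadrature: the per-atom area is the exposed fraction of
#' its solvent-excluded sphere times `4 pi (r + probe)^2`.
#'
#' @param structure A `kin_structure` with known elements (radii come from
#'   [vdw_radius()]).
#' @param probe Probe radius in angstrom (default 1.4, water).
#' @param n_points Quadrature points per sphere (default 960; the isolated
#'   sphere is then exact to well under 1 percent).
#' @return A `kin_sasa` list: `atoms` (per-atom `key`, `atom`, `area`) and
#'   `residues` (per-residue `key`, `res_type`, `area`), areas in angstrom
#'   squared.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960) {
  heavy <- which(toupper(structure$element) != "H")
  s <- structure[heavy, ]
  xyz <- coords_matrix(s)
  if (anyDuplicated(round(xyz, 6)) > 0) {
    abort("Overlapping identical atom coordinates; SASA undefined")
  }
  r <- vdw_radius(s$element) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  d2 <- pair_dist2(xyz, xyz)
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (r[i] + r)^2 & seq_len(n) != i)
    if (length(nb) > 0) {
      p <- sweep(pts * r[i], 2, xyz[i, ], "+")
      pd <- pair_dist2(p, xyz[nb, , drop = FALSE])
      covered <- rowSums(sweep(pd, 2, r[nb]^2, "<")) > 0
      frac <- sum(!covered) / n_points
    } else {
      frac <- 1
    }
    area[i] <- frac * 4 * pi * r[i]^2
  }
  atoms <- tibble(
    key = residue_keys(s), res_type = s$res_type, atom = s$atom, area = area
  )
  residues <- atoms |>
    group_by(.data$key) |>
    summarise(
      res_type = .data$res_type[1], area = sum(.data$area), .groups = "drop"
    ) |>
    arrange(match(.data$key, unique(residue_keys(s))))
  out <- list(atoms = atoms, residues = residues, probe = probe, n_points = n_points)
  class(out) <- "kin_sasa"
  out
}

#' @export
print.kin_sasa <- function(x, ...) {
  cat(sprintf(
    "# kin_sasa: %d atoms, %d residues, total %.1f A^2 (probe %.1f, %d points)\n",
    nrow(x$atoms), nrow(x$residues), sum(x$atoms$area), x$probe, x$n_points
  ))
  invisible(x)
}

#' Reference maximum solvent accessibilities
#'
#' Theoretical tripeptide-based maximum per-residue areas used as the
#' unfolded-state reference for relative solvent accessibility.
#'
#' @param path Optional replacement TSV with columns `res_type`, `max_sasa`.
#' @return Tibble with `res_type` and `max_sasa` (angstrom squared).
#' @export
max_sasa_table <- function(path = NULL) {
  if (!is.null(path)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    load_tsv_resource("max_sasa.tsv")
  }
}

#' Relative solvent accessibility
#'
#' RSA is the observed residue area divided by its unfolded-state reference
#' area; values can slightly exceed 1 for very exposed residues.
#'
#' @param sasa_profile A `kin_sasa` from [sasa()].
#' @param reference Reference table from [max_sasa_table()].
#' @return Tibble with `key`, `res_type`, `area`, `rsa`.
#' @export
rsa <- function(sasa_profile, reference = max_sasa_table()) {
  res <- sasa_profile$residues
  missing_types <- setdiff(
    res$res_type[res$res_type %in% STANDARD_AA | !res$res_type %in% "LIG"],
    reference$res_type
  )
  if (length(missing_types) > 0) {
    abort(paste0(
      "No reference area for residue type(s): ",
      paste(unique(missing_types), collapse = ", ")
    ))
  }
  res |>
    left_join(reference, by = "res_type") |>
    mutate(rsa = .data$area / .data$max_sasa) |>
    select("key", "res_type", "area", "rsa")
}
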