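# Seed-controlled generators of toy structures, ensembles, alignments and
# ligand-bridged complexes. All generators are pure functions of their
# arguments + seed; R's global RNG state is saved and restored.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("seed must be a single integer")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)
cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

# Natural-extension reference frame: place D bonded to C with bond length
# `bond`, bond angle B-C-D `theta` and torsion A-B-C-D `tau` (radians).
place_atom <- function(a, b, c, bond, theta, tau) {
  bc <- unitv(c - b)
  n <- unitv(cross3(b - a, bc))
  m <- cross3(n, bc)
  c + bond * (-cos(theta) * bc + sin(theta) * (cos(tau) * m + sin(tau) * n))
}

IDEAL_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
  ang_n_ca_c = 111.2 * pi / 180,
  ang_ca_c_n = 116.2 * pi / 180,
  ang_c_n_ca = 121.7 * pi / 180
)

TOY_RES_CYCLE <- c(
  "LEU", "SER", "VAL", "LYS", "PHE", "ASP", "GLY", "THR", "ILE", "GLU",
  "ALA", "ARG"
)

# Ideal-geometry N/CA/C backbone for given phi/psi (degrees), via NeRF.
build_backbone <- function(n_residues, phi, psi) {
  g <- IDEAL_GEOM
  coords <- matrix(0, nrow = 3 * n_residues, ncol = 3)
  coords[1, ] <- c(0, 0, 0)                              # N1
  coords[2, ] <- c(g$n_ca, 0, 0)                         # CA1
  coords[3, ] <- coords[2, ] + g$ca_c *
    c(cos(pi - g$ang_n_ca_c), sin(pi - g$ang_n_ca_c), 0) # C1
  phi <- phi * pi / 180
  psi <- psi * pi / 180
  omega <- pi
  for (i in seq_len(n_residues - 1)) {
    nI <- coords[3 * i - 2, ]
    caI <- coords[3 * i - 1, ]
    cI <- coords[3 * i, ]
    nN <- place_atom(nI, caI, cI, g$c_n, g$ang_ca_c_n, psi)
    caN <- place_atom(caI, cI, nN, g$n_ca, g$ang_c_n_ca, omega)
    cN <- place_atom(cI, nN, caN, g$ca_c, g$ang_n_ca_c, phi)
    coords[3 * i + 1, ] <- nN
    coords[3 * i + 2, ] <- caN
    coords[3 * i + 3, ] <- cN
  }
  coords
}

toy_atoms_from_backbone <- function(bb, res_types, side_chains, chain = "A",
                                    seq_start = 1L, sc_dirs = NULL) {
  n <- length(res_types)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    nI <- bb[3 * i - 2, ]
    caI <- bb[3 * i - 1, ]
    cI <- bb[3 * i, ]
    at <- tibble(
      chain = chain, seq_id = seq_start + i - 1L, res_type = res_types[i],
      atom = c("N", "CA", "C"), element = c("N", "C", "C"),
      x = c(nI[1], caI[1], cI[1]),
      y = c(nI[2], caI[2], cI[2]),
      z = c(nI[3], caI[3], cI[3])
    )
    if (res_types[i] != "GLY") {
      dir <- if (is.null(sc_dirs)) unitv(caI - (nI + cI) / 2) else sc_dirs[i, ]
      cb <- caI + 2.4 * dir
      sc <- tibble(
        chain = chain, seq_id = seq_start + i - 1L, res_type = res_types[i],
        atom = "CB2", element = "C", x = cb[1], y = cb[2], z = cb[3]
      )
      if (side_chains == "multi" && !res_types[i] %in% c("ALA", "SER")) {
        cg <- caI + 3.9 * dir
        sc <- bind_rows(sc, tibble(
          chain = chain, seq_id = seq_start + i - 1L, res_type = res_types[i],
          atom = "CG2", element = "C", x = cg[1], y = cg[2], z = cg[3]
        ))
      }
      at <- bind_rows(at, sc)
    }
    rows[[i]] <- at
  }
  bind_rows(rows)
}

#' Generate a deterministic toy structure
#'
#' Builds a small protein with ideal-geometry N/CA/C backbone and one
#' pseudo side-chain atom (`CB2`) per non-glycine residue, so that contact
#' counts downstream are small, hand-checkable integers. `fold = "helix"`
#' uses alpha-helical torsions (consecutive CA-CA close to 3.8 angstrom),
#' `"hairpin"` two antiparallel extended strands 4.8 angstrom apart, and
#' `"globule"` a compact jittered lattice that maximises side-chain contact
#' density (a pseudo-fold for contact statistics, not a stereochemically
#' ideal chain).
#'
#' @param n_residues Number of residues (at least 4).
#' @param fold One of `"helix"`, `"hairpin"`, `"globule"`.
#' @param seed Integer seed; the same seed always yields the identical
#'   structure.
#' @param side_chains `"single"` (one CB2 pseudo-atom) or `"multi"` (adds a
#'   CG2 atom on larger residues, for SASA realism).
#' @return A `kin_structure`.
#' @export
#' @examples
#' s <- gen_toy_structure(10, "helix", seed = 1)
#' residue_table(s)
gen_toy_structure <- function(n_residues, fold = c("helix", "hairpin", "globule"),
                              seed = 1, side_chains = c("single", "multi")) {
  fold <- match.arg(fold)
  side_chains <- match.arg(side_chains)
  if (n_residues < 4) abort("n_residues must be at least 4")
  res_types <- rep_len(TOY_RES_CYCLE, n_residues)
  with_seed(seed, {
    if (fold == "helix") {
      bb <- build_backbone(n_residues, phi = -57, psi = -47)
      atoms <- toy_atoms_from_backbone(bb, res_types, side_chains)
    } else if (fold == "hairpin") {
      n1 <- ceiling(n_residues / 2)
      n2 <- n_residues - n1
      bb1 <- build_backbone(n1, phi = -139, psi = 135)
      bb2 <- build_backbone(n2, phi = -139, psi = 135)
      # rotate strand 2 by 180 degrees about z (proper rotation) and offset
      bb2 <- cbind(-bb2[, 1], -bb2[, 2], bb2[, 3])
      bb2[, 1] <- bb2[, 1] + max(bb1[, 1])
      bb2[, 2] <- bb2[, 2] + 4.8
      atoms <- bind_rows(
        toy_atoms_from_backbone(bb1, res_types[seq_len(n1)], side_chains),
        toy_atoms_from_backbone(bb2, res_types[n1 + seq_len(n2)], side_chains,
          seq_start = n1 + 1L
        )
      )
    } else {
      side <- ceiling(n_residues^(1 / 3))
      grid <- expand.grid(ix = seq_len(side), iy = seq_len(side), iz = seq_len(side))
      grid <- grid[seq_len(n_residues), ]
      ca <- as.matrix(grid) * 4.5 + matrix(stats::runif(3 * n_residues, -0.25, 0.25),
        ncol = 3
      )
      bb <- matrix(0, nrow = 3 * n_residues, ncol = 3)
      dirs <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      dirs <- dirs / sqrt(rowSums(dirs^2))
      sc_dirs <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
      sc_dirs <- sc_dirs / sqrt(rowSums(sc_dirs^2))
      for (i in seq_len(n_residues)) {
        perp <- unitv(cross3(dirs[i, ], c(0, 0, 1) + 1e-3))
        bb[3 * i - 2, ] <- ca[i, ] - 1.458 * dirs[i, ]          # N
        bb[3 * i - 1, ] <- ca[i, ]                              # CA
        bb[3 * i, ] <- ca[i, ] + 1.525 * (0.3 * dirs[i, ] + 0.954 * perp) # C
      }
      atoms <- toy_atoms_from_backbone(bb, res_types, side_chains,
        sc_dirs = sc_dirs
      )
      # pull pseudo side chains closer for lattice contact density
      is_sc <- atoms$atom %in% c("CB2", "CG2")
      ca_m <- ca[atoms$seq_id[is_sc], , drop = FALSE]
      scale <- ifelse(atoms$atom[is_sc] == "CB2", 1.5 / 2.4, 2.6 / 3.9)
      atoms$x[is_sc] <- ca_m[, 1] + (atoms$x[is_sc] - ca_m[, 1]) * scale
      atoms$y[is_sc] <- ca_m[, 2] + (atoms$y[is_sc] - ca_m[, 2]) * scale
      atoms$z[is_sc] <- ca_m[, 3] + (atoms$z[is_sc] - ca_m[, 3]) * scale
    }
    out <- new_structure(atoms, title = sprintf("toy %s n=%d seed=%d", fold, n_residues, seed))
    attr(out, "spec") <- list(
      generator = "gen_toy_structure", n_residues = n_residues, fold = fold,
      seed = seed, side_chains = side_chains
    )
    out
  })
}

#' Generate a conformational ensemble along elastic-network modes
#'
#' Frames are the reference structure plus Gaussian-amplitude displacements
#' along selected anisotropic-network-model (ANM) modes, optionally plus
#' independent per-residue Gaussian noise. Mode displacements are defined on
#' CA atoms and applied rigidly to every atom of the residue. This stands in
#' for molecular-dynamics sampling at desk scale: the target variance of the
#' projection onto mode `k` is `(amplitude_k * temperature_scale)^2`.
#'
#' @param structure A `kin_structure` with at least 4 residues.
#' @param n_frames Number of frames (at least 2).
#' @param mode_spectrum Named list/data frame with columns `mode` (index into
#'   the ascending-eigenvalue ANM mode list; the first 6 are rigid-body and
#'   are rejected) and `amplitude` (angstrom).
#' @param noise_sd Standard deviation (angstrom, per axis) of independent
#'   per-residue displacement noise.
#' @param temperature_scale Global multiplier on all displacement amplitudes.
#' @param seed Integer seed.
#' @param cutoff,gamma ANM parameters passed to [anm_modes()].
#' @return A `kin_ensemble`.
#' @export
gen_ensemble <- function(structure, n_frames, mode_spectrum = NULL,
                         noise_sd = 0, temperature_scale = 1, seed = 1,
                         cutoff = 15, gamma = 1) {
  if (n_frames < 2) abort("n_frames must be at least 2")
  res_keys <- unique(residue_keys(structure))
  n_res <- length(res_keys)
  if (n_res < 4) abort("structure must have at least 4 residues")
  prot_keys <- residue_keys(structure)
  modes <- NULL
  if (!is.null(mode_spectrum)) {
    ms <- as_tibble(as.data.frame(mode_spectrum))
    if (!all(c("mode", "amplitude") %in% names(ms))) {
      abort("mode_spectrum needs columns `mode` and `amplitude`")
    }
    dyn <- anm_modes(structure, cutoff = cutoff, gamma = gamma)
    if (any(ms$mode <= dyn$n_rigid)) {
      abort(sprintf(
        "mode_spectrum selects a rigid-body (zero-frequency) mode (first %d are rigid)",
        dyn$n_rigid
      ))
    }
    modes <- dyn$modes[, ms$mode, drop = FALSE]
    amps <- ms$amplitude
    mode_res_keys <- dyn$labels
  }
  ref <- coords_matrix(structure)
  n_atoms <- nrow(ref)
  res_of_atom <- match(prot_keys, res_keys)
  with_seed(seed, {
    coords <- array(0, dim = c(n_atoms, 3, n_frames))
    for (t in seq_len(n_frames)) {
      disp_res <- matrix(0, nrow = n_res, ncol = 3)
      if (!is.null(modes)) {
        z <- stats::rnorm(ncol(modes))
        d <- as.vector(modes %*% (z * amps * temperature_scale))
        dm <- matrix(d, ncol = 3, byrow = TRUE)
        ix <- match(res_keys, mode_res_keys)
        dm_full <- matrix(0, nrow = n_res, ncol = 3)
        dm_full[!is.na(ix), ] <- dm[ix[!is.na(ix)], , drop = FALSE]
        disp_res <- disp_res + dm_full
      }
      if (noise_sd > 0) {
        disp_res <- disp_res + matrix(
          stats::rnorm(3 * n_res, sd = noise_sd * temperature_scale),
          ncol = 3
        )
      }
      coords[, , t] <- ref + disp_res[res_of_atom, , drop = FALSE]
    }
    ens <- new_ensemble(structure, coords)
    attr(ens, "spec") <- list(
      generator = "gen_ensemble", n_frames = n_frames,
      mode_spectrum = mode_spectrum, noise_sd = noise_sd,
      temperature_scale = temperature_scale, seed = seed
    )
    ens
  })
}

#' Specification for a synthetic multiple sequence alignment
#'
#' @param n_sequences,n_columns Alignment dimensions.
#' @param background 20-vector of amino-acid frequencies (named by one-letter
#'   code or in standard order), summing to 1 within 1e-9. Default uniform.
#' @param conserved_columns List of `list(col =, res =, p =)` entries: column
#'   `col` emits one-letter residue `res` with probability `p`, otherwise a
#'   background draw.
#' @param coevolving_pairs List of `list(col_a =, col_b =, coupling =)`:
#'   with probability `coupling` the two columns are drawn jointly from a
#'   two-state paired alphabet (so a fully coupled pair has mutual
#'   information exactly `ln 2` in the infinite-sample limit), otherwise
#'   independently from the background.
#' @param seed Integer seed.
#' @return An `msa_spec` list, validated.
#' @export
msa_spec <- function(n_sequences, n_columns, background = NULL,
                     conserved_columns = list(), coevolving_pairs = list(),
                     seed = 1) {
  if (is.null(background)) background <- rep(1 / 20, 20)
  if (is.null(names(background))) names(background) <- AA_ONE
  background <- background[AA_ONE]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-9) {
    abort("background must cover the 20 amino acids and sum to 1 within 1e-9")
  }
  cons_cols <- map_int(conserved_columns, ~ as.integer(.x$col))
  pair_cols <- unlist(map(coevolving_pairs, ~ c(.x$col_a, .x$col_b)))
  all_cols <- c(cons_cols, pair_cols)
  if (length(all_cols) > 0 && (max(all_cols) > n_columns || min(all_cols) < 1)) {
    abort("Planted column index outside alignment")
  }
  if (anyDuplicated(all_cols) > 0) {
    abort("Planted (conserved/coevolving) columns overlap")
  }
  for (p in coevolving_pairs) {
    if (p$coupling < 0 || p$coupling > 1) abort("coupling must lie in [0, 1]")
  }
  for (cc in conserved_columns) {
    if (cc$p < 0 || cc$p > 1) abort("conservation probability must lie in [0, 1]")
  }
  structure(
    list(
      n_sequences = n_sequences, n_columns = n_columns, background = background,
      conserved_columns = conserved_columns, coevolving_pairs = coevolving_pairs,
      seed = seed
    ),
    class = "msa_spec"
  )
}

#' Generate an alignment with planted conservation and coevolution
#'
#' Unplanted columns are i.i.d. draws from the background distribution; see
#' [msa_spec()] for the planted-column models.
#'
#' @param spec An [msa_spec()].
#' @return A `kin_msa` (see [new_msa()]).
#' @export
gen_msa <- function(spec) {
  stopifnot(inherits(spec, "msa_spec"))
  n <- spec$n_sequences
  L <- spec$n_columns
  bg <- spec$background
  with_seed(spec$seed, {
    m <- matrix(
      sample(AA_ONE, n * L, replace = TRUE, prob = bg),
      nrow = n, ncol = L
    )
    for (cc in spec$conserved_columns) {
      hit <- stats::runif(n) < cc$p
      m[hit, cc$col] <- cc$res
    }
    for (p in spec$coevolving_pairs) {
      letters_a <- sample(AA_ONE, 2)
      letters_b <- sample(AA_ONE, 2)
      coupled <- stats::runif(n) < p$coupling
      state <- sample(1:2, n, replace = TRUE)
      m[coupled, p$col_a] <- letters_a[state[coupled]]
      m[coupled, p$col_b] <- letters_b[state[coupled]]
    }
    msa <- new_msa(m, ids = sprintf("seq%04d", seq_len(n)))
    attr(msa, "spec") <- spec
    msa
  })
}

#' Specification for a synthetic ligand-bridged complex
#'
#' @param n_residues Protein size; residues `1..floor(n/2)` form lobe A and
#'   the rest lobe B of a two-lobe (dumbbell) fold whose lobes touch through
#'   a single bottleneck contact.
#' @param pocket_residues Residue indices lining the inter-lobe cleft; the
#'   ligand is placed so every pocket residue has at least one ligand heavy
#'   atom within 4.5 angstrom and no other residue has any.
#' @param ligand_atoms Number of ligand heavy atoms (at least 1).
#' @param bridge_strength Contact multiplier: roughly the number of ligand
#'   atoms packed against each pocket residue; `0` parks the ligand more than
#'   20 angstrom away (non-interacting control).
#' @param seed Integer seed.
#' @return A `complex_spec` list, validated.
#' @export
complex_spec <- function(n_residues, pocket_residues, ligand_atoms = 4,
                         bridge_strength = 1, seed = 1) {
  if (ligand_atoms < 1) abort("ligand_atoms must be at least 1")
  if (n_residues < 8) abort("n_residues must be at least 8")
  if (any(pocket_residues < 1 | pocket_residues > n_residues)) {
    abort("pocket_residues outside 1..n_residues")
  }
  structure(
    list(
      n_residues = n_residues, pocket_residues = sort(unique(pocket_residues)),
      ligand_atoms = ligand_atoms, bridge_strength = bridge_strength, seed = seed
    ),
    class = "complex_spec"
  )
}

#' Generate an apo/holo pair with a pocket-bridging ligand
#'
#' The apo protein is a two-lobe dumbbell: each lobe is a compact lattice of
#' residues with pseudo side chains, the lobes are separated by a 12
#' angstrom cleft, and exactly one cross-cleft side-chain contact (the
#' bottleneck) connects them. Pocket residues are placed on the cleft faces.
#' The holo structure is the identical protein plus one ligand residue
#' (`is_ligand` = TRUE) whose atoms touch every pocket residue within 4.5
#' angstrom and no other residue, so that the ligand bridges otherwise
#' weakly connected parts of the interaction network.
#'
#' @param spec A [complex_spec()].
#' @return List with elements `apo` and `holo` (both `kin_structure`).
#' @export
gen_complex <- function(spec) {
  stopifnot(inherits(spec, "complex_spec"))
  n <- spec$n_residues
  nA <- floor(n / 2)
  gap <- 12
  with_seed(spec$seed, {
    # two spherical lobes with inward-pointing pseudo side chains, joined by
    # a single bottleneck contact above the inter-lobe cleft
    R <- 5
    D <- 24
    mid_x <- D / 2
    centres <- list(A = c(0, 0, 0), B = c(D, 0, 0))
    pocket <- spec$pocket_residues
    pocketA <- pocket[pocket <= nA]
    pocketB <- pocket[pocket > nA]
    lobes <- list(A = seq_len(nA), B = (nA + 1):n)
    if (nA - length(pocketA) < 2 || (n - nA) - length(pocketB) < 2) {
      abort("Each lobe needs at least 2 non-pocket residues (pole and bottleneck)")
    }
    # role assignment: the bottleneck residue of each lobe sits off-sphere
    # above the cleft; the pole residue anchors it to its lobe
    bn <- c(
      A = max(setdiff(lobes$A, pocketA)),
      B = max(setdiff(lobes$B, pocketB))
    )
    pole <- c(
      A = min(setdiff(lobes$A, c(pocketA, bn))),
      B = min(setdiff(lobes$B, c(pocketB, bn)))
    )
    fib_dirs <- function(k) {
      i <- seq_len(k) - 0.5
      phi <- acos(1 - 2 * i / k)
      th <- pi * (1 + sqrt(5)) * i
      cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
    }
    ca <- matrix(NA_real_, n, 3)
    sgn <- c(A = 1, B = -1)
    for (lb in c("A", "B")) {
      members <- setdiff(lobes[[lb]], bn[lb])
      dirs <- fib_dirs(length(members))
      dirs[, 1] <- dirs[, 1] * sgn[lb] # cleft face is +x for A, -x for B
      pk <- if (lb == "A") pocketA else pocketB
      remaining <- seq_len(nrow(dirs))
      assign_dir <- integer(length(members))
      # pocket residues face the cleft: largest cleft-ward x
      if (length(pk) > 0) {
        ord <- remaining[order(dirs[remaining, 1] * sgn[lb], decreasing = TRUE)]
        assign_dir[match(pk, members)] <- ord[seq_along(pk)]
        remaining <- setdiff(remaining, ord[seq_along(pk)])
      }
      # pole residue faces up toward the bottleneck
      u_pole <- c(0.55 * sgn[lb], 0, 0.835)
      scores <- dirs[remaining, , drop = FALSE] %*% u_pole
      pole_dir <- remaining[which.max(scores)]
      assign_dir[match(pole[lb], members)] <- pole_dir
      remaining <- setdiff(remaining, pole_dir)
      assign_dir[assign_dir == 0] <- remaining
      ca[members, ] <- sweep(
        R * dirs[assign_dir, , drop = FALSE], 2, centres[[lb]], "+"
      ) + matrix(stats::runif(3 * length(members), -0.12, 0.12), ncol = 3)
      ca[bn[lb], ] <- c(mid_x - sgn[lb] * 2.25, 0, 9) +
        stats::runif(3, -0.08, 0.08)
    }
    res_types <- rep_len(setdiff(TOY_RES_CYCLE, "GLY"), n)
    inward <- t(vapply(seq_len(n), function(i) {
      cen <- if (i <= nA) centres$A else centres$B
      unitv(cen - ca[i, ] + stats::rnorm(3, sd = 0.01))
    }, numeric(3)))
    bb <- matrix(0, nrow = 3 * n, ncol = 3)
    for (i in seq_len(n)) {
      bb[3 * i - 2, ] <- ca[i, ] + c(-1.2, -0.6, 0.5)
      bb[3 * i - 1, ] <- ca[i, ]
      bb[3 * i, ] <- ca[i, ] + c(1.2, -0.6, -0.5)
    }
    atoms <- toy_atoms_from_backbone(bb, res_types, "single", sc_dirs = inward)
    # two-atom pseudo side chains along the inward radial (CB2 1.6, CG2
    # 3.0 angstrom) give neighbouring sphere residues several atom pairs,
    # clearing the interaction-strength admission threshold
    is_cb <- atoms$atom == "CB2"
    ca_m <- ca[atoms$seq_id[is_cb], , drop = FALSE]
    for (d in 1:3) {
      col <- c("x", "y", "z")[d]
      atoms[[col]][is_cb] <- ca_m[, d] + (atoms[[col]][is_cb] - ca_m[, d]) * (1.6 / 2.4)
    }
    extra_atoms <- list(
      purrr::map_dfr(seq_len(n), function(i) {
        pos <- ca[i, ] + 3.0 * inward[i, ]
        tibble(
          chain = "A", seq_id = i, res_type = res_types[i],
          atom = "CG2", element = "C", x = pos[1], y = pos[2], z = pos[3]
        )
      })
    )
    add_atom <- function(i, name, pos) {
      extra_atoms[[length(extra_atoms) + 1]] <<- tibble(
        chain = "A", seq_id = i, res_type = res_types[i],
        atom = name, element = "C", x = pos[1], y = pos[2], z = pos[3]
      )
    }
    # pocket residues: one cleft-facing atom the ligand binds
    for (p in pocketA) add_atom(p, "CD2", ca[p, ] + 2.4 * c(1, 0, 0))
    for (p in pocketB) add_atom(p, "CD2", ca[p, ] + 2.4 * c(-1, 0, 0))
    for (lb in c("A", "B")) {
      # pole <-> bottleneck contact (4 atom pairs at ~3.4 angstrom)
      u <- unitv(ca[bn[lb], ] - ca[pole[lb], ])
      cd_pole <- ca[pole[lb], ] + 2.4 * u
      add_atom(pole[lb], "CD2", cd_pole)
      add_atom(pole[lb], "CE2", cd_pole + c(0, 1.2, 0))
      dist <- vnorm(ca[bn[lb], ] - ca[pole[lb], ])
      g_len <- max(dist - 2.4 - 3.4, 0.8)
      cg_bn <- ca[bn[lb], ] - g_len * u
      add_atom(bn[lb], "CH2", cg_bn + c(0, 1.2, 0))
      # replace the generic inward CG2 of the bottleneck by the pole-facing one
      extra_atoms[[1]][extra_atoms[[1]]$seq_id == bn[lb], c("x", "y", "z")] <-
        as.list(cg_bn)
      # bottleneck <-> bottleneck facing atoms
      cd_bn <- ca[bn[lb], ] + sgn[lb] * c(0.75, 0, 0)
      add_atom(bn[lb], "CD2", cd_bn)
      add_atom(bn[lb], "CE2", cd_bn + c(0, 0, 1.2))
    }
    atoms <- bind_rows(atoms, bind_rows(extra_atoms)) |> arrange(.data$seq_id)
    apo <- new_structure(atoms, title = sprintf("synthetic apo n=%d seed=%d", n, spec$seed))

    # ligand placement in the cleft
    bs <- spec$bridge_strength
    per_pocket <- max(1L, round(bs))
    anchors <- list()
    cb_of <- function(r) {
      idx <- which(apo$seq_id == r & apo$atom == "CD2")
      c(apo$x[idx], apo$y[idx], apo$z[idx])
    }
    for (p in pocket) {
      cb <- cb_of(p)
      s <- if (p <= nA) 1 else -1
      for (k in seq_len(per_pocket)) {
        anchors[[length(anchors) + 1]] <- cb + (3.4 + 1.0 * (k - 1)) * c(s, 0, 0)
      }
    }
    n_anchor <- length(anchors)
    lig <- do.call(rbind, anchors)
    extra <- spec$ligand_atoms - n_anchor
    if (extra > 0) {
      # remaining atoms form a chain spanning the cleft between the
      # innermost anchors (or around the cleft centre if one-sided)
      xs <- lig[, 1]
      left <- lig[which(xs <= mid_x), , drop = FALSE]
      right <- lig[which(xs > mid_x), , drop = FALSE]
      if (nrow(left) > 0 && nrow(right) > 0) {
        a <- left[which.max(left[, 1]), ]
        b <- right[which.min(right[, 1]), ]
      } else {
        a <- c(mid_x - 1.5, 0, mean(lig[, 3]))
        b <- c(mid_x + 1.5, 0, mean(lig[, 3]))
      }
      fr <- seq_len(extra) / (extra + 1)
      fill <- t(vapply(fr, function(f) a + f * (b - a), numeric(3)))
      lig <- rbind(lig, fill)
    } else if (extra < 0) {
      lig <- lig[seq_len(spec$ligand_atoms), , drop = FALSE]
    }
    if (bs == 0) lig[, 3] <- lig[, 3] + 60  # park the ligand far away
    lig_tbl <- tibble(
      chain = "X", seq_id = 1L, res_type = "LIG",
      atom = sprintf("L%d", seq_len(nrow(lig))), element = "C",
      x = lig[, 1], y = lig[, 2], z = lig[, 3], is_ligand = TRUE
    )
    holo <- new_structure(bind_rows(as_tibble(apo)[names(lig_tbl)], lig_tbl),
      title = sprintf("synthetic holo n=%d seed=%d", n, spec$seed)
    )
    # contact contract: pocket residues touch the ligand, no others do
    if (bs > 0) {
      prot <- holo[!holo$is_ligand, ]
      lm <- lig
      dmin <- vapply(seq_len(n), function(r) {
        pm <- coords_matrix(prot[prot$seq_id == r, ])
        min(sqrt(pmax(outer(rowSums(pm^2), rowSums(lm^2), "+") - 2 * pm %*% t(lm), 0)))
      }, numeric(1))
      if (any(dmin[pocket] > 4.5)) {
        abort("pocket residues not mutually placeable within the 4.5 angstrom contact shell")
      }
      offenders <- setdiff(which(dmin <= 4.5), pocket)
      if (length(offenders) > 0) {
        abort(paste0(
          "non-pocket residue(s) fall inside the ligand contact shell: ",
          paste(offenders, collapse = ", ")
        ))
      }
    }
    out <- list(apo = apo, holo = holo)
    attr(out, "spec") <- spec
    out
  })
}

#' Export a synthetic object with a provenance sidecar
#'
#' Writes structures/ensembles as PDB and alignments as FASTA, plus a
#' `<path>.json` sidecar recording the generator specification and seed.
#'
#' @param x Object produced by a `gen_*` function.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_synthetic <- function(x, path) {
  if (inherits(x, "kin_msa")) {
    write_msa_fasta(x, path)
  } else {
    write_pdb(x, path)
  }
  spec <- attr(x, "spec")
  if (!is.null(spec)) {
    jsonlite::write_json(
      spec[setdiff(names(spec), NULL)],
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
  }
  invisible(path)
}
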