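# MM-GBSA free-energy combination over a minimal molecular-mechanics +
# GB/SA backend, and the computational alanine-scanning protocol. The
# parameter set is a documented toy force field: the combination equations
# are exact, force-field fidelity is not the goal.

KE_COULOMB <- 332.06 # kcal angstrom / (mol e^2)

ELEMENT_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, CL = 35.45, BR = 79.904, I = 126.904, SE = 78.971
)

#' Toy energy-model parameters
#'
#' Minimal parameter set backing the MM-GBSA equations on synthetic
#' systems: per-element Lennard-Jones well depths and minimum radii,
#' partial charges keyed by (residue type, atom name) with an all-zero
#' default, interior/solvent dielectrics, HCT-style generalized-Born
#' parameters, and the nonpolar surface coefficient
#' `sigma_np = 0.0072 kcal/(mol angstrom^2)`.
#'
#' @param charges Optional tibble `res_type`, `atom`, `q` (elementary
#'   charges) overriding the zero default; `res_type = "*"` matches any.
#' @param sigma_np Nonpolar solvation coefficient.
#' @param dielectric_in,dielectric_out Interior and solvent dielectrics.
#' @return An `kin_params` list.
#' @export
toy_params <- function(charges = NULL, sigma_np = 0.0072,
                       dielectric_in = 1, dielectric_out = 78.5) {
  if (sigma_np <= 0) abort("sigma_np must be positive")
  if (dielectric_in < 1 || dielectric_out < 1) abort("dielectrics must be >= 1")
  lj <- tibble(
    element = c("H", "C", "N", "O", "S", "P"),
    eps = c(0.030, 0.100, 0.170, 0.160, 0.300, 0.280),
    rmin_half = c(0.60, 1.90, 1.75, 1.70, 2.00, 2.05)
  )
  out <- list(
    lj = lj,
    charges = if (is.null(charges)) {
      tibble(res_type = character(), atom = character(), q = numeric())
    } else {
      as_tibble(charges)
    },
    dielectric_in = dielectric_in,
    dielectric_out = dielectric_out,
    sigma_np = sigma_np,
    gb = list(offset = 0.09, scale = 0.8),
    bond_k = 300 # kcal/(mol angstrom^2)
  )
  class(out) <- "kin_params"
  out
}

param_atoms <- function(structure, params) {
  el <- toupper(structure$element)
  idx <- match(el, params$lj$element)
  if (any(is.na(idx))) {
    abort(paste0(
      "Unparameterized element(s): ",
      paste(unique(el[is.na(idx)]), collapse = ", ")
    ))
  }
  q <- numeric(nrow(structure))
  if (nrow(params$charges) > 0) {
    ch <- params$charges
    spec <- match(
      paste(structure$res_type, structure$atom),
      paste(ch$res_type, ch$atom)
    )
    wild <- match(paste("*", structure$atom), paste(ch$res_type, ch$atom))
    hit <- ifelse(is.na(spec), wild, spec)
    q[!is.na(hit)] <- ch$q[hit[!is.na(hit)]]
  }
  list(
    eps = params$lj$eps[idx],
    rmin_half = params$lj$rmin_half[idx],
    q = q,
    mass = unname(ELEMENT_MASS[el])
  )
}

# minimal bonded topology: covalent bonds by distance (< 2.0 angstrom
# between heavy atoms, < 1.3 to hydrogen) plus named pseudo side-chain
# bonds; equilibrium lengths are the topology-structure distances, so the
# input geometry is the bonded-term minimum.
toy_bonds <- function(structure) {
  xyz <- coords_matrix(structure)
  el <- toupper(structure$element)
  d2 <- pair_dist2(xyz, xyz)
  lim <- outer(el == "H", el == "H", "|") * 0 + 2.0
  lim[el == "H", ] <- 1.3
  lim[, el == "H"] <- 1.3
  cand <- which(upper.tri(d2) & d2 <= lim^2 & d2 > 0.25, arr.ind = TRUE)
  keys <- residue_keys(structure)
  named <- which(
    structure$atom %in% c("CB2", "CG2")
  )
  extra <- purrr::map_dfr(named, function(i) {
    partner_name <- if (structure$atom[i] == "CB2") "CA" else "CB2"
    j <- which(keys == keys[i] & structure$atom == partner_name)
    if (length(j) == 1) tibble(row = min(i, j), col = max(i, j)) else NULL
  })
  b <- unique(rbind(
    tibble(row = cand[, 1], col = cand[, 2]),
    extra
  ))
  b$r0 <- sqrt(d2[cbind(b$row, b$col)])
  b
}

hct_born_radii <- function(xyz, rvdw, gb) {
  rho <- pmax(rvdw - gb$offset, 0.6)
  s <- gb$scale
  n <- nrow(xyz)
  d <- sqrt(pair_dist2(xyz, xyz))
  inv <- 1 / rho
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      r <- d[i, j]
      sr <- s * rho[j]
      if (rho[i] >= r + sr) next
      L <- max(r - sr, rho[i])
      U <- r + sr
      acc <- acc + 0.5 * (
        1 / L - 1 / U + (r / 4) * (1 / U^2 - 1 / L^2) +
          (1 / (2 * r)) * log(L / U) +
          (sr^2 / (4 * r)) * (1 / L^2 - 1 / U^2)
      )
    }
    inv[i] <- 1 / rho[i] - acc
  }
  1 / pmax(inv, 1e-3)
}

gb_energy <- function(xyz, q, rvdw, params) {
  if (all(q == 0)) return(0)
  R <- hct_born_radii(xyz, rvdw, params$gb)
  pref <- -0.5 * KE_COULOMB * (1 / params$dielectric_in - 1 / params$dielectric_out)
  d2 <- pair_dist2(xyz, xyz)
  RR <- outer(R, R)
  fgb <- sqrt(d2 + RR * exp(-d2 / (4 * RR)))
  qq <- outer(q, q)
  pref * sum(qq / fgb)
}

#' Energy decomposition of a structure
#'
#' Computes the toy molecular-mechanics terms: harmonic bond energy over
#' the minimal topology, 12-6 Lennard-Jones (`E = eps[(rmin/r)^12 -
#' 2(rmin/r)^6]`, Lorentz-Berthelot combination), Coulomb electrostatics
#' (`332.06 q_i q_j / (eps_in r)`), pairwise-descreening generalized-Born
#' polar solvation, and the nonpolar term `sigma_np * SASA`. Nonbonded
#' pairs exclude atoms of the same residue and directly bonded pairs. No
#' distance cutoff is applied (exact sums at toy scale).
#'
#' @param structure A `kin_structure` (or a frame of one).
#' @param params [toy_params()].
#' @param selection `"complex"` (all atoms), `"protein"`, or `"ligand"`.
#' @param sasa_points Quadrature points for the nonpolar term.
#' @return A `kin_energy` list with `e_bond`, `e_vdw`, `e_elec`, `g_np`,
#'   `g_gb` (kcal/mol) and their `total`.
#' @export
energy_terms <- function(structure, params = toy_params(),
                         selection = c("complex", "protein", "ligand"),
                         sasa_points = 240) {
  selection <- match.arg(selection)
  s <- switch(selection,
    complex = structure,
    protein = structure[!structure$is_ligand, ],
    ligand = structure[structure$is_ligand, ]
  )
  if (nrow(s) == 0) abort(paste0("Empty selection: ", selection))
  p <- param_atoms(s, params)
  xyz <- coords_matrix(s)
  n <- nrow(xyz)
  bonds <- toy_bonds(s)
  e_bond <- if (nrow(bonds) > 0) {
    r <- sqrt(rowSums((xyz[bonds$row, , drop = FALSE] -
      xyz[bonds$col, , drop = FALSE])^2))
    sum(params$bond_k * (r - bonds$r0)^2)
  } else {
    0
  }
  keys <- residue_keys(s)
  d2 <- pair_dist2(xyz, xyz)
  excl <- outer(keys, keys, "==")
  if (nrow(bonds) > 0) {
    excl[cbind(bonds$row, bonds$col)] <- TRUE
    excl[cbind(bonds$col, bonds$row)] <- TRUE
  }
  use <- upper.tri(d2) & !excl
  r <- sqrt(d2[use])
  epsij <- sqrt(outer(p$eps, p$eps))[use]
  rminij <- outer(p$rmin_half, p$rmin_half, "+")[use]
  sr6 <- (rminij / r)^6
  e_vdw <- sum(epsij * (sr6^2 - 2 * sr6))
  qq <- outer(p$q, p$q)[use]
  e_elec <- KE_COULOMB * sum(qq / r) / params$dielectric_in
  rvdw <- vdw_radius(s$element)
  g_gb <- gb_energy(xyz, p$q, rvdw, params)
  g_np <- params$sigma_np * sum(sasa(s, n_points = sasa_points)$atoms$area)
  out <- list(
    e_bond = e_bond, e_vdw = e_vdw, e_elec = e_elec,
    g_np = g_np, g_gb = g_gb,
    total = e_bond + e_vdw + e_elec + g_np + g_gb,
    selection = selection, n_atoms = n
  )
  class(out) <- "kin_energy"
  out
}

#' @export
print.kin_energy <- function(x, ...) {
  cat(sprintf(
    "# kin_energy (%s, %d atoms): bond %.3f vdw %.3f elec %.3f np %.3f gb %.3f kcal/mol\n",
    x$selection, x$n_atoms, x$e_bond, x$e_vdw, x$e_elec, x$g_np, x$g_gb
  ))
  invisible(x)
}

# analytic gradient of the gas-phase terms (bond + LJ + Coulomb); used by
# the minimizer and the vibrational Hessian
mm_gradient <- function(xyz, p, bonds, excl_use, params) {
  n <- nrow(xyz)
  g <- matrix(0, n, 3)
  if (nrow(bonds) > 0) {
    dv <- xyz[bonds$row, , drop = FALSE] - xyz[bonds$col, , drop = FALSE]
    r <- sqrt(rowSums(dv^2))
    f <- 2 * params$bond_k * (r - bonds$r0) / r
    gv <- dv * f
    for (k in seq_len(nrow(bonds))) {
      g[bonds$row[k], ] <- g[bonds$row[k], ] + gv[k, ]
      g[bonds$col[k], ] <- g[bonds$col[k], ] - gv[k, ]
    }
  }
  idx <- which(excl_use, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    dv <- xyz[idx[, 1], , drop = FALSE] - xyz[idx[, 2], , drop = FALSE]
    r2 <- rowSums(dv^2)
    r <- sqrt(r2)
    epsij <- sqrt(p$eps[idx[, 1]] * p$eps[idx[, 2]])
    rminij <- p$rmin_half[idx[, 1]] + p$rmin_half[idx[, 2]]
    sr6 <- (rminij^2 / r2)^3
    dE_dr <- epsij * 12 * (sr6 - sr6^2) / r +
      -KE_COULOMB * p$q[idx[, 1]] * p$q[idx[, 2]] / (params$dielectric_in * r2)
    gv <- dv * (dE_dr / r)
    for (k in seq_len(nrow(idx))) {
      g[idx[k, 1], ] <- g[idx[k, 1], ] + gv[k, ]
      g[idx[k, 2], ] <- g[idx[k, 2], ] - gv[k, ]
    }
  }
  g
}

mm_energy_gas <- function(xyz, p, bonds, excl_use, params) {
  e <- 0
  if (nrow(bonds) > 0) {
    r <- sqrt(rowSums((xyz[bonds$row, , drop = FALSE] -
      xyz[bonds$col, , drop = FALSE])^2))
    e <- e + sum(params$bond_k * (r - bonds$r0)^2)
  }
  idx <- which(excl_use, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    dv <- xyz[idx[, 1], , drop = FALSE] - xyz[idx[, 2], , drop = FALSE]
    r2 <- rowSums(dv^2)
    r <- sqrt(r2)
    epsij <- sqrt(p$eps[idx[, 1]] * p$eps[idx[, 2]])
    rminij <- p$rmin_half[idx[, 1]] + p$rmin_half[idx[, 2]]
    sr6 <- (rminij^2 / r2)^3
    e <- e + sum(epsij * (sr6^2 - 2 * sr6)) +
      KE_COULOMB * sum(p$q[idx[, 1]] * p$q[idx[, 2]] / r) / params$dielectric_in
  }
  e
}

nonbonded_mask <- function(structure, bonds) {
  keys <- residue_keys(structure)
  n <- nrow(structure)
  excl <- outer(keys, keys, "==")
  if (nrow(bonds) > 0) {
    excl[cbind(bonds$row, bonds$col)] <- TRUE
    excl[cbind(bonds$col, bonds$row)] <- TRUE
  }
  upper.tri(matrix(0, n, n)) & !excl
}

#' Steepest-descent minimization
#'
#' Adaptive-step steepest descent on the gas-phase terms (bonds + LJ +
#' Coulomb), stopping after `max_steps` steps or when the maximum gradient
#' component falls below `gtol`.
#'
#' @param structure A `kin_structure`.
#' @param params [toy_params()].
#' @param movable Logical/integer atom selection allowed to move (default
#'   all).
#' @param max_steps Step budget (default 1000).
#' @param gtol Gradient tolerance, kcal/(mol angstrom) (default 0.01).
#' @return The minimized `kin_structure`.
#' @export
minimize_sd <- function(structure, params = toy_params(), movable = NULL,
                        max_steps = 1000, gtol = 0.01) {
  p <- param_atoms(structure, params)
  bonds <- toy_bonds(structure)
  use <- nonbonded_mask(structure, bonds)
  xyz <- coords_matrix(structure)
  mov <- if (is.null(movable)) rep(TRUE, nrow(xyz)) else movable
  if (!any(mov)) return(structure)
  step <- 1e-3
  e <- mm_energy_gas(xyz, p, bonds, use, params)
  for (it in seq_len(max_steps)) {
    g <- mm_gradient(xyz, p, bonds, use, params)
    g[!mov, ] <- 0
    if (max(abs(g)) < gtol) break
    trial <- xyz - step * g
    e_try <- mm_energy_gas(trial, p, bonds, use, params)
    if (e_try < e) {
      xyz <- trial
      e <- e_try
      step <- step * 1.2
    } else {
      step <- step * 0.5
      if (step < 1e-10) break
    }
  }
  set_coords(structure, xyz)
}

#' Translational, rotational and vibrational entropy
#'
#' Closed-form ideal-gas translational (Sackur-Tetrode) and rigid-rotor
#' rotational entropies at the given temperature and 1 atm, plus the
#' harmonic-oscillator vibrational entropy from the mass-weighted Hessian
#' of the gas-phase terms (finite differences of the analytic gradient) on
#' a minimized structure. More than 6 near-zero Hessian eigenvalues means
#' the structure is not at a minimum and is an error.
#'
#' @param structure A minimized `kin_structure`.
#' @param params [toy_params()].
#' @param temperature Kelvin (default 300).
#' @return List with `s_trans`, `s_rot`, `s_vib` (kcal/(mol K)) and
#'   `frequencies` (cm^-1).
#' @export
entropy_terms <- function(structure, params = toy_params(), temperature = 300) {
  kB <- 1.380649e-23
  h <- 6.62607015e-34
  NA_ <- 6.02214076e23
  R_kcal <- 1.98720425864083e-3 # kcal/(mol K)
  p <- param_atoms(structure, params)
  m_amu <- p$mass
  m_tot <- sum(m_amu) * 1.66053906660e-27
  P <- 101325
  T <- temperature
  s_trans <- R_kcal * (log((2 * pi * m_tot * kB * T / h^2)^1.5 * kB * T / P) + 2.5)
  xyz <- coords_matrix(structure)
  n <- nrow(xyz)
  s_rot <- 0
  if (n > 1) {
    mk <- m_amu * 1.66053906660e-27
    com <- colSums(xyz * mk) / sum(mk)
    rc <- sweep(xyz, 2, com) * 1e-10
    I <- matrix(0, 3, 3)
    for (i in seq_len(n)) {
      ri <- rc[i, ]
      I <- I + mk[i] * (sum(ri^2) * diag(3) - outer(ri, ri))
    }
    ev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
    if (ev[1] / max(ev) < 1e-10) { # linear molecule
      Ib <- ev[3]
      s_rot <- R_kcal * (log(8 * pi^2 * Ib * kB * T / h^2) + 1)
    } else {
      q_rot <- sqrt(pi * prod(ev)) / 1 * (8 * pi^2 * kB * T / h^2)^1.5
      s_rot <- R_kcal * (log(q_rot) + 1.5)
    }
  }
  # mass-weighted Hessian by central differences of the analytic gradient
  s_vib <- 0
  freqs <- numeric(0)
  if (n > 1) {
    bonds <- toy_bonds(structure)
    use <- nonbonded_mask(structure, bonds)
    dx <- 1e-4
    H <- matrix(0, 3 * n, 3 * n)
    for (i in seq_len(n)) {
      for (d in 1:3) {
        xp <- xyz
        xp[i, d] <- xp[i, d] + dx
        gp <- mm_gradient(xp, p, bonds, use, params)
        xm <- xyz
        xm[i, d] <- xm[i, d] - dx
        gm <- mm_gradient(xm, p, bonds, use, params)
        H[, 3 * (i - 1) + d] <- as.vector(t((gp - gm) / (2 * dx)))
      }
    }
    H <- (H + t(H)) / 2
    mw <- rep(sqrt(m_amu), each = 3)
    Hm <- H / outer(mw, mw)
    ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
    ev <- sort(ev)
    scale_zero <- max(abs(ev))
    n_zero <- sum(abs(ev) < 1e-6 * max(scale_zero, 1))
    expected_zero <- if (n == 1) 3 else 6
    if (n_zero > expected_zero) {
      abort(sprintf(
        "%d near-zero Hessian eigenvalues (expected at most %d): structure not minimized",
        n_zero, expected_zero
      ))
    }
    pos <- ev[seq_along(ev) > n_zero & ev > 0]
    # sqrt(kcal/mol/A^2/amu) -> rad/s
    omega <- sqrt(pos) * 2.045483e13
    x <- h * omega / (2 * pi * kB * T)
    s_vib <- R_kcal * sum(x / (exp(x) - 1) - log(1 - exp(-x)))
    freqs <- omega / (2 * pi * 2.99792458e10)
  }
  list(s_trans = s_trans, s_rot = s_rot, s_vib = s_vib, frequencies = freqs)
}

frame_split <- function(structure) {
  list(
    complex = structure,
    protein = structure[!structure$is_ligand, ],
    ligand = structure[structure$is_ligand, ]
  )
}

solv_terms <- function(s, params, sasa_points) {
  p <- param_atoms(s, params)
  xyz <- coords_matrix(s)
  list(
    g_gb = gb_energy(xyz, p$q, vdw_radius(s$element), params),
    g_np = params$sigma_np * sum(sasa(s, n_points = sasa_points)$atoms$area)
  )
}

interaction_terms <- function(structure, params) {
  # exact intermolecular (complex - protein - ligand) vdW and Coulomb terms
  p <- param_atoms(structure, params)
  xyz <- coords_matrix(structure)
  il <- which(structure$is_ligand)
  ip <- which(!structure$is_ligand)
  d2 <- pair_dist2(xyz[ip, , drop = FALSE], xyz[il, , drop = FALSE])
  r <- sqrt(d2)
  epsij <- sqrt(outer(p$eps[ip], p$eps[il]))
  rminij <- outer(p$rmin_half[ip], p$rmin_half[il], "+")
  sr6 <- (rminij / r)^6
  qq <- outer(p$q[ip], p$q[il])
  list(
    e_vdw = sum(epsij * (sr6^2 - 2 * sr6)),
    e_elec = KE_COULOMB * sum(qq / r) / params$dielectric_in
  )
}

#' MM-GBSA binding free energy over an ensemble
#'
#' Single-trajectory protocol: for every frame the gas-phase interaction
#' terms are the exact intermolecular van der Waals and electrostatic sums
#' (complex minus isolated protein and ligand at identical coordinates, so
#' the internal-energy difference is zero by construction); the solvation
#' difference `dG_solv = G_solv(complex) - G_solv(protein) -
#' G_solv(ligand)` uses isolated species optionally minimized first. The
#' entropy term, when requested, combines closed-form translational and
#' rotational contributions with harmonic vibrational entropy on minimized
#' ensemble-average structures. `dG_bind = <dG_MM> + <dG_solv> - T<dS>`
#' holds to machine bookkeeping.
#'
#' @param ensemble A `kin_ensemble` containing one ligand residue.
#' @param params [toy_params()].
#' @param entropy `"none"` or `"harmonic"`.
#' @param subsample Use at most this many evenly spaced frames (default
#'   all).
#' @param minimize_isolated Minimize isolated species before the solvation
#'   terms (`min_steps` steepest-descent steps).
#' @param min_steps Minimization step budget per species per frame.
#' @param temperature Kelvin, for the entropy term.
#' @param sasa_points SASA quadrature points.
#' @return A `kin_mmgbsa` list: `dG_bind`, `dG_MM`, `dG_solv`, `TdS` (with
#'   components), and the per-frame term series.
#' @export
mmgbsa <- function(ensemble, params = toy_params(),
                   entropy = c("none", "harmonic"), subsample = NULL,
                   minimize_isolated = TRUE, min_steps = 50,
                   temperature = 300, sasa_points = 240) {
  entropy <- match.arg(entropy)
  ensemble <- as_ensemble(ensemble)
  if (!any(ensemble$topology$is_ligand)) abort("Ensemble has no ligand residue")
  nf <- n_frames(ensemble)
  frames <- if (!is.null(subsample) && subsample < nf) {
    unique(round(seq(1, nf, length.out = subsample)))
  } else {
    seq_len(nf)
  }
  per_frame <- purrr::map_dfr(frames, function(t) {
    fr <- frame_structure(ensemble, t)
    inter <- interaction_terms(fr, params)
    parts <- frame_split(fr)
    if (minimize_isolated) {
      parts$protein <- minimize_sd(parts$protein, params, max_steps = min_steps)
      parts$ligand <- minimize_sd(parts$ligand, params, max_steps = min_steps)
    }
    sv <- purrr::map(parts, solv_terms, params = params, sasa_points = sasa_points)
    tibble(
      frame = t,
      e_vdw = inter$e_vdw, e_elec = inter$e_elec,
      dg_np = sv$complex$g_np - sv$protein$g_np - sv$ligand$g_np,
      dg_gb = sv$complex$g_gb - sv$protein$g_gb - sv$ligand$g_gb
    )
  })
  per_frame$dg_frame <- per_frame$e_vdw + per_frame$e_elec +
    per_frame$dg_np + per_frame$dg_gb
  dG_MM <- mean(per_frame$e_vdw) + mean(per_frame$e_elec)
  dG_solv <- mean(per_frame$dg_np) + mean(per_frame$dg_gb)
  TdS <- 0
  S_parts <- NULL
  if (entropy == "harmonic") {
    avg <- set_coords(ensemble$topology, apply(
      ensemble$coords[, , frames, drop = FALSE],
      c(1, 2), mean
    ))
    parts <- frame_split(avg)
    parts <- purrr::map(parts, minimize_sd,
      params = params,
      max_steps = 1000, gtol = 0.01
    )
    ent <- purrr::map(parts, entropy_terms,
      params = params,
      temperature = temperature
    )
    tot <- function(e) e$s_trans + e$s_rot + e$s_vib
    dS <- tot(ent$complex) - tot(ent$protein) - tot(ent$ligand)
    TdS <- temperature * dS
    S_parts <- purrr::map(ent, function(e) {
      tibble(s_trans = e$s_trans, s_rot = e$s_rot, s_vib = e$s_vib)
    })
  }
  out <- list(
    dG_MM = dG_MM, dG_solv = dG_solv, TdS = TdS,
    dG_bind = dG_MM + dG_solv - TdS,
    per_frame = per_frame, n_frames = length(frames),
    entropy = entropy, entropy_components = S_parts
  )
  class(out) <- "kin_mmgbsa"
  out
}

#' @export
print.kin_mmgbsa <- function(x, ...) {
  cat(sprintf(
    "# kin_mmgbsa over %d frames: dG_bind %.3f = dG_MM %.3f + dG_solv %.3f - TdS %.3f kcal/mol\n",
    x$n_frames, x$dG_bind, x$dG_MM, x$dG_solv, x$TdS
  ))
  invisible(x)
}

#' Tidy the per-frame MM-GBSA series
#'
#' @param x A `kin_mmgbsa`.
#' @param ... Unused.
#' @return The per-frame tibble of energy terms.
#' @export
tidy.kin_mmgbsa <- function(x, ...) x$per_frame

#' Glance at an MM-GBSA result
#'
#' @param x A `kin_mmgbsa`.
#' @param ... Unused.
#' @return One-row tibble with the combined totals.
#' @export
glance.kin_mmgbsa <- function(x, ...) {
  tibble(
    dG_bind = x$dG_bind, dG_MM = x$dG_MM, dG_solv = x$dG_solv,
    TdS = x$TdS, n_frames = x$n_frames
  )
}

truncate_to_ala <- function(structure, key) {
  keys <- residue_keys(structure)
  mine <- keys == key
  sc <- mine & structure$is_sidechain
  keep_cb <- sc & structure$atom == "CB"
  drop <- sc & !keep_cb
  has_cb <- any(keep_cb)
  cg <- which(mine & structure$atom %in% c("CG", "CG1", "CG2") &
    structure$atom != "CB2")
  out <- structure[!drop, ]
  added <- NULL
  if (has_cb && length(cg) > 0) {
    # replace the (removed) C-gamma by a hydrogen at 1.09 angstrom along
    # the CB -> CG vector
    cb_i <- which(mine & structure$atom == "CB")
    v <- unitv(c(
      structure$x[cg[1]] - structure$x[cb_i],
      structure$y[cg[1]] - structure$y[cb_i],
      structure$z[cg[1]] - structure$z[cb_i]
    ))
    hpos <- c(structure$x[cb_i], structure$y[cb_i], structure$z[cb_i]) + 1.09 * v
    add <- as_tibble(structure[cb_i, ])
    add$atom <- "HB"
    add$element <- "H"
    add$x <- hpos[1]
    add$y <- hpos[2]
    add$z <- hpos[3]
    out <- bind_rows(as_tibble(out), add)
    added <- "HB"
  }
  res <- new_structure(as_tibble(out), title = attr(structure, "title"))
  res$res_type[residue_keys(res) == key] <- "ALA"
  attr(res, "added_atom") <- added
  res
}

#' Computational alanine scanning
#'
#' For each requested residue the side chain is truncated on every
#' wild-type frame (atoms beyond C-beta removed; a C-gamma, when present,
#' is replaced by a hydrogen at 1.09 angstrom along the C-beta to C-gamma
#' vector; the unified pseudo side chain `CB2` of toy structures is removed
#' entirely), the mutated side chain is minimized with the rest of the
#' system fixed, the binding terms are recomputed, and
#' `ddG_bind = dG_bind(mutant) - dG_bind(wild type)` is averaged over
#' frames with the entropy term omitted. Glycine and proline are skipped
#' with a reason; scanning an alanine is the identity mutation and reports
#' exactly 0.
#'
#' @param ensemble Wild-type holo `kin_ensemble`.
#' @param params [toy_params()].
#' @param residues Residue keys (or integer `seq_id`s on the first protein
#'   chain) to scan.
#' @param subsample Use at most this many evenly spaced frames.
#' @param min_steps Steepest-descent budget for the mutated side chain
#'   (default 1000 per the scanning protocol).
#' @param sasa_points SASA quadrature points.
#' @return A `kin_alascan` tibble: `key`, `res_type`, `ddG`, term-wise
#'   breakdown (`ddG_vdw`, `ddG_elec`, `ddG_np`, `ddG_gb`), and `skipped`
#'   reasons.
#' @export
alanine_scan <- function(ensemble, params = toy_params(), residues = NULL,
                         subsample = NULL, min_steps = 1000,
                         sasa_points = 240) {
  ensemble <- as_ensemble(ensemble)
  topo <- ensemble$topology
  if (!any(topo$is_ligand)) abort("Ensemble has no ligand residue")
  rt <- residue_table(topo[!topo$is_ligand, ])
  if (is.null(residues)) {
    residues <- rt$key
  } else if (is.numeric(residues)) {
    ch <- rt$chain[1]
    residues <- rt$key[match(residues, rt$seq_id)]
  }
  bad <- setdiff(residues, rt$key)
  if (length(bad) > 0) {
    abort(paste0("Unknown residue key(s): ", paste(bad, collapse = ", ")))
  }
  nf <- n_frames(ensemble)
  frames <- if (!is.null(subsample) && subsample < nf) {
    unique(round(seq(1, nf, length.out = subsample)))
  } else {
    seq_len(nf)
  }
  binding_terms <- function(fr, params) {
    inter <- interaction_terms(fr, params)
    parts <- frame_split(fr)
    sv <- purrr::map(parts, solv_terms, params = params, sasa_points = sasa_points)
    c(
      vdw = inter$e_vdw, elec = inter$e_elec,
      np = sv$complex$g_np - sv$protein$g_np - sv$ligand$g_np,
      gb = sv$complex$g_gb - sv$protein$g_gb - sv$ligand$g_gb
    )
  }
  wt_terms <- purrr::map(frames, function(t) {
    binding_terms(frame_structure(ensemble, t), params)
  })
  out <- purrr::map_dfr(residues, function(k) {
    info <- rt[rt$key == k, ]
    base <- tibble(
      key = k, res_type = info$res_type,
      ddG = NA_real_, ddG_vdw = NA_real_, ddG_elec = NA_real_,
      ddG_np = NA_real_, ddG_gb = NA_real_, skipped = NA_character_
    )
    if (info$res_type %in% c("GLY", "PRO")) {
      base$skipped <- paste0(info$res_type, ": no canonical C-beta truncation")
      return(base)
    }
    if (info$res_type == "ALA") {
      base[, c("ddG", "ddG_vdw", "ddG_elec", "ddG_np", "ddG_gb")] <- 0
      base$skipped <- "identity mutation"
      return(base)
    }
    d <- purrr::map(seq_along(frames), function(fi) {
      t <- frames[fi]
      fr <- frame_structure(ensemble, t)
      mut <- truncate_to_ala(fr, k)
      movable_atom <- attr(mut, "added_atom")
      if (!is.null(movable_atom) && min_steps > 0) {
        mov <- residue_keys(mut) == k & mut$atom == movable_atom
        mut <- minimize_sd(mut, params, movable = mov, max_steps = min_steps)
      }
      binding_terms(mut, params) - wt_terms[[fi]]
    })
    dm <- colMeans(do.call(rbind, d))
    base$ddG_vdw <- dm[["vdw"]]
    base$ddG_elec <- dm[["elec"]]
    base$ddG_np <- dm[["np"]]
    base$ddG_gb <- dm[["gb"]]
    base$ddG <- sum(dm)
    base
  })
  class(out) <- c("kin_alascan", class(as_tibble(out)))
  out
}
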