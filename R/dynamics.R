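# Ensemble statistics: rigid-body superposition, B-factors, essential
# dynamics (PCA), residue cross-correlations and anisotropic network model
# (ANM) normal modes.

select_atoms <- function(structure, selection = c("CA", "backbone", "heavy", "all")) {
  selection <- match.arg(selection)
  prot <- !structure$is_ligand
  switch(selection,
    CA = which(prot & structure$atom == "CA"),
    backbone = which(prot & structure$atom %in% c("N", "CA", "CB", "CB2", "C", "O")),
    heavy = which(toupper(structure$element) != "H"),
    all = seq_len(nrow(structure))
  )
}

# Kabsch optimal rotation (proper, det = +1) mapping P onto Q.
kabsch_rotation <- function(P, Q) {
  # right-multiplication convention: P %*% R approximates Q (rows = atoms)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superpose ensemble frames onto a reference
#'
#' Least-squares rigid-body fit (Kabsch singular value decomposition with a
#' proper-rotation determinant correction) of every frame onto the reference
#' over the selected atoms. The fitted transform is applied to all atoms.
#'
#' @param ensemble A `kin_ensemble`.
#' @param reference Frame index to fit onto, or `"mean"` for the ensemble
#'   average structure.
#' @param selection Atom selection used for the fit: `"CA"` or `"backbone"`.
#' @return A superposed `kin_ensemble`.
#' @export
superpose <- function(ensemble, reference = 1, selection = c("CA", "backbone")) {
  selection <- match.arg(selection)
  sel <- select_atoms(ensemble$topology, selection)
  if (length(sel) < 3) abort("Superposition needs at least 3 selected atoms")
  nf <- n_frames(ensemble)
  if (nf < 2) abort("Superposition needs at least 2 frames")
  ref <- if (identical(reference, "mean")) {
    apply(ensemble$coords, c(1, 2), mean)
  } else {
    ensemble$coords[, , reference]
  }
  ref_sel <- ref[sel, , drop = FALSE]
  ref_cen <- colMeans(ref_sel)
  out <- ensemble$coords
  for (t in seq_len(nf)) {
    fr <- ensemble$coords[, , t]
    cen <- colMeans(fr[sel, , drop = FALSE])
    R <- kabsch_rotation(
      sweep(fr[sel, , drop = FALSE], 2, cen),
      sweep(ref_sel, 2, ref_cen)
    )
    out[, , t] <- sweep(sweep(fr, 2, cen) %*% R, 2, ref_cen, "+")
  }
  new_ensemble(ensemble$topology, out, ensemble$frame_spacing)
}

#' Per-residue B-factors from an aligned ensemble
#'
#' Computes `B_i = (8 pi^2 / 3) * <dr_i^2>`, the crystallographic
#' Debye-Waller factor from the mean-square fluctuation about the ensemble
#' mean position, averaged over the selected atoms of each residue.
#'
#' @param ensemble A superposed `kin_ensemble`.
#' @param selection `"backbone"` (default) or `"CA"`.
#' @return Tibble with `key`, `chain`, `seq_id`, `res_type`, `bfactor`
#'   (angstrom squared).
#' @export
compute_bfactors <- function(ensemble, selection = c("backbone", "CA")) {
  selection <- match.arg(selection)
  if (n_frames(ensemble) < 2) abort("B-factors need at least 2 frames")
  sel <- select_atoms(ensemble$topology, selection)
  co <- ensemble$coords[sel, , , drop = FALSE]
  mean_pos <- apply(co, c(1, 2), mean)
  msf <- rowMeans(apply(co, 3, function(fr) rowSums((fr - mean_pos)^2)))
  topo <- ensemble$topology[sel, ]
  tibble(
    key = residue_keys(topo),
    chain = topo$chain, seq_id = topo$seq_id, res_type = topo$res_type,
    msf = msf
  ) |>
    group_by(.data$key) |>
    summarise(
      chain = .data$chain[1], seq_id = .data$seq_id[1],
      res_type = .data$res_type[1],
      bfactor = (8 * pi^2 / 3) * mean(.data$msf), .groups = "drop"
    ) |>
    arrange(.data$chain, .data$seq_id)
}

#' Residue cross-correlation matrix from an aligned ensemble
#'
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)` over the fluctuation
#' vectors of the selected atom of each residue (CA by default). Residues
#' with zero variance cannot be normalised; their off-diagonal entries are
#' set to 0 with a warning and the diagonal stays 1.
#'
#' @param ensemble A superposed `kin_ensemble` with at least 2 frames.
#' @param selection `"CA"` (default) or `"backbone"` (per-residue mean of
#'   backbone-atom fluctuations).
#' @return Labelled correlation matrix (residue keys), symmetric with unit
#'   diagonal, entries in `[-1, 1]`.
#' @export
cross_correlation <- function(ensemble, selection = c("CA", "backbone")) {
  selection <- match.arg(selection)
  nf <- n_frames(ensemble)
  if (nf < 2) abort("Cross-correlation needs at least 2 frames")
  sel <- select_atoms(ensemble$topology, selection)
  topo <- ensemble$topology[sel, ]
  keys <- unique(residue_keys(topo))
  n <- length(keys)
  res_idx <- match(residue_keys(topo), keys)
  # per-residue fluctuation vectors, averaged over the selection atoms
  fluc <- array(0, dim = c(n, 3, nf))
  mean_pos <- apply(ensemble$coords[sel, , , drop = FALSE], c(1, 2), mean)
  for (t in seq_len(nf)) {
    d <- ensemble$coords[sel, , t] - mean_pos
    fluc[, , t] <- rowsum(d, res_idx) / as.vector(table(res_idx))
  }
  inner <- matrix(0, n, n)
  for (t in seq_len(nf)) inner <- inner + fluc[, , t] %*% t(fluc[, , t])
  inner <- inner / nf
  v <- diag(inner)
  zero <- v <= 0 | !is.finite(v)
  if (any(zero)) {
    warn(sprintf(
      "%d residue(s) have zero fluctuation variance; their correlations are set to 0",
      sum(zero)
    ))
    v[zero] <- 1
  }
  C <- inner / sqrt(outer(v, v))
  if (any(zero)) {
    C[zero, ] <- 0
    C[, zero] <- 0
  }
  diag(C) <- 1
  C <- (C + t(C)) / 2
  C[C > 1] <- 1
  C[C < -1] <- -1
  dimnames(C) <- list(keys, keys)
  validate_correlation(C)
  C
}

new_dynamics <- function(type, modes, eigenvalues, labels, mobility, n_rigid = 0L) {
  structure(
    list(
      type = type, modes = modes, eigenvalues = eigenvalues,
      labels = labels, mobility = mobility, n_rigid = n_rigid
    ),
    class = "kin_dynamics"
  )
}

#' @export
print.kin_dynamics <- function(x, ...) {
  cat(sprintf(
    "# kin_dynamics (%s): %d modes over %d residues (%d rigid-body)\n",
    x$type, ncol(x$modes), length(x$labels), x$n_rigid
  ))
  invisible(x)
}

#' Tidy a dynamics result
#'
#' @param x A `kin_dynamics` from [pca_modes()] or [anm_modes()].
#' @param ... Unused.
#' @return Tibble with per-residue `key` and `mobility` (the root-mean-square
#'   displacement magnitude over the three lowest-frequency modes).
#' @export
tidy.kin_dynamics <- function(x, ...) x$mobility

#' Glance at a dynamics result
#'
#' @param x A `kin_dynamics`.
#' @param ... Unused.
#' @return One-row tibble with mode counts and variance summaries.
#' @export
glance.kin_dynamics <- function(x, ...) {
  tibble(
    type = x$type, n_modes = ncol(x$modes), n_rigid = x$n_rigid,
    total_variance = sum(x$eigenvalues),
    leading_fraction = if (x$type == "pca") {
      x$eigenvalues[1] / sum(x$eigenvalues)
    } else {
      NA_real_
    }
  )
}

#' Principal component analysis of an ensemble
#'
#' Eigen-decomposition of the positional covariance over the selected atoms
#' (essential dynamics). Following the standard essential-dynamics
#' convention, the "lowest frequency" modes are the largest-variance
#' principal components; the per-residue mobility profile is the
#' root-mean-square displacement magnitude over the three largest-variance
#' modes.
#'
#' @param ensemble A superposed `kin_ensemble` with more frames than the
#'   modes requested.
#' @param selection `"CA"` or `"backbone"` heavy atoms (N, CA, CB, C, O;
#'   the toy pseudo side-chain CB2 counts as CB).
#' @param n_modes Number of components to retain (default: all with
#'   positive variance).
#' @return A `kin_dynamics` with non-increasing eigenvalues (variance,
#'   angstrom squared), mutually orthonormal modes and a mobility tibble.
#' @export
pca_modes <- function(ensemble, selection = c("CA", "backbone"), n_modes = NULL) {
  selection <- match.arg(selection)
  nf <- n_frames(ensemble)
  sel <- select_atoms(ensemble$topology, selection)
  m <- length(sel)
  # frame rows, columns atom-major (x1, y1, z1, x2, ...)
  X <- t(vapply(
    seq_len(nf),
    function(t) as.vector(t(ensemble$coords[sel, , t])),
    numeric(3 * m)
  ))
  Xc <- scale(X, center = TRUE, scale = FALSE)
  total_var <- sum(Xc^2) / (nf - 1)
  if (total_var <= 0) abort("Degenerate (static) ensemble: zero total variance")
  eig <- eigen(stats::cov(X), symmetric = TRUE)
  pos <- which(eig$values > max(eig$values) * 1e-12)
  if (is.null(n_modes)) n_modes <- length(pos)
  if (nf <= n_modes) abort("Need more frames than requested modes")
  keep <- seq_len(min(n_modes, length(pos)))
  modes <- eig$vectors[, keep, drop = FALSE]
  vals <- eig$values[keep]
  topo <- ensemble$topology[sel, ]
  keys <- residue_keys(topo)
  k3 <- seq_len(min(3, length(vals)))
  atom_msf <- rowSums(vapply(k3, function(k) {
    vals[k] * rowSums(matrix(modes[, k], ncol = 3, byrow = TRUE)^2)
  }, numeric(m)))
  mobility <- tibble(key = keys, atom_msf = atom_msf) |>
    group_by(.data$key) |>
    summarise(mobility = sqrt(mean(.data$atom_msf)), .groups = "drop") |>
    arrange(match(.data$key, unique(keys)))
  out <- new_dynamics("pca", modes, vals, unique(keys), mobility)
  out$selection <- selection
  out$total_variance <- total_var
  out
}

#' Anisotropic network model modes
#'
#' Builds the standard ANM Hessian from CA-CA contacts within `cutoff` and
#' diagonalises it. A connected three-dimensional structure has exactly six
#' near-zero (rigid-body) eigenvalues; a disconnected contact graph is an
#' error naming the components.
#'
#' @param structure A `kin_structure` (protein residues; CA atoms used).
#' @param cutoff Contact cutoff in angstrom (default 15).
#' @param gamma Uniform spring force constant (default 1).
#' @return A `kin_dynamics` with modes in ascending eigenvalue order,
#'   `n_rigid` counting near-zero modes, and a mobility profile from the
#'   three lowest-frequency internal modes (amplitude proportional to
#'   `1/sqrt(eigenvalue)`).
#' @export
anm_modes <- function(structure, cutoff = 15, gamma = 1) {
  sel <- select_atoms(structure, "CA")
  topo <- structure[sel, ]
  keys <- residue_keys(topo)
  n <- length(sel)
  if (n < 2) abort("ANM needs at least 2 CA atoms")
  xyz <- coords_matrix(topo)
  d2 <- as.matrix(stats::dist(xyz))^2
  contact <- d2 <= cutoff^2 & d2 > 0
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(contact, mode = "undirected")
  )
  if (comp$no > 1) {
    abort(sprintf(
      "CA contact graph is disconnected at cutoff %.1f: %d components (sizes %s)",
      cutoff, comp$no, paste(comp$csize, collapse = ", ")
    ))
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (!contact[i, j]) next
      dv <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * outer(dv, dv) / sum(dv^2)
      ii <- (3 * i - 2):(3 * i)
      jj <- (3 * j - 2):(3 * j)
      H[ii, jj] <- blk
      H[jj, ii] <- blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  vals <- eig$values[ord]
  modes <- eig$vectors[, ord, drop = FALSE]
  n_rigid <- sum(vals < 1e-8 * max(vals))
  internal <- which(seq_along(vals) > n_rigid)
  k3 <- internal[seq_len(min(3, length(internal)))]
  atom_msf <- rowSums(vapply(k3, function(k) {
    rowSums(matrix(modes[, k], ncol = 3, byrow = TRUE)^2) / vals[k]
  }, numeric(n)))
  mobility <- tibble(key = keys, mobility = sqrt(atom_msf))
  out <- new_dynamics("anm", modes, vals, keys, mobility, n_rigid = n_rigid)
  out$hessian <- H
  out$cutoff <- cutoff
  out$gamma <- gamma
  out
}
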