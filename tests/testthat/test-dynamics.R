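rot_z <- function(th) {
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

test_that("superposition removes exact rigid transforms and is idempotent", {
  s <- gen_toy_structure(8, "helix", seed = 1)
  ref <- cbind(s$x, s$y, s$z)
  moved <- ref %*% rot_z(0.7) + matrix(c(3, -2, 5), nrow(ref), 3, byrow = TRUE)
  ens <- new_ensemble(s, list(ref, moved))
  fit <- superpose(ens, selection = "CA")
  expect_lt(sqrt(mean((fit$coords[, , 2] - ref)^2)), 1e-9)
  again <- superpose(fit, selection = "CA")
  expect_lt(max(abs(again$coords - fit$coords)), 1e-9)
})

test_that("mirror-image frames are fitted with a proper rotation only", {
  # 4-atom chiral toy; reflection cannot be removed by a proper rotation
  p <- matrix(c(
    0, 0, 0,
    1.5, 0, 0,
    1.5, 1.5, 0,
    1.5, 1.5, 1.5
  ), ncol = 3, byrow = TRUE)
  mirror <- p %*% diag(c(1, 1, -1))
  s <- new_structure(atom_row(1:4, rep("CA", 4), p[, 1], p[, 2], p[, 3]))
  ens <- new_ensemble(s, list(p, mirror))
  fit <- superpose(ens, selection = "CA")
  rmsd_fit <- sqrt(mean((fit$coords[, , 2] - p)^2))
  expect_gt(rmsd_fit, 0.1)
  # oracle: coarse search over proper rotations never beats the Kabsch fit
  center <- function(m) sweep(m, 2, colMeans(m))
  pc <- center(p)
  mc <- center(mirror)
  best <- Inf
  for (a in seq(0, 2 * pi, length.out = 13)) {
    for (b in seq(0, pi, length.out = 7)) {
      for (c in seq(0, 2 * pi, length.out = 13)) {
        Rz <- rot_z(a)
        Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
        R <- Rz %*% Ry %*% rot_z(c)
        best <- min(best, sqrt(mean((mc %*% R - pc)^2)))
      }
    }
  }
  expect_lte(rmsd_fit, best + 1e-6)
})

test_that("B-factors follow (8 pi^2 / 3) times the mean-square fluctuation", {
  s <- gen_toy_structure(6, "helix", seed = 1)
  ref <- cbind(s$x, s$y, s$z)
  ens_static <- new_ensemble(s, list(ref, ref, ref))
  expect_true(all(compute_bfactors(ens_static)$bfactor == 0))

  # one residue's atoms displaced +/- d along x: MSF = d^2 exactly
  d <- sqrt(0.3)
  up <- ref
  dn <- ref
  sel <- which(s$seq_id == 3)
  up[sel, 1] <- up[sel, 1] + d
  dn[sel, 1] <- dn[sel, 1] - d
  ens <- new_ensemble(s, list(up, dn))
  bf <- compute_bfactors(ens, selection = "backbone")
  expect_equal(bf$bfactor[bf$seq_id == 3], (8 * pi^2 / 3) * 0.3, tolerance = 1e-12)

  ens2 <- new_ensemble(s, list(
    {
      m <- ref
      m[sel, 1] <- m[sel, 1] + 2 * d
      m
    },
    {
      m <- ref
      m[sel, 1] <- m[sel, 1] - 2 * d
      m
    }
  ))
  bf2 <- compute_bfactors(ens2)
  expect_equal(bf2$bfactor[bf2$seq_id == 3], 4 * bf$bfactor[bf$seq_id == 3],
    tolerance = 1e-12
  )
  expect_error(compute_bfactors(new_ensemble(s, list(ref))), "2 frames")
})

test_that("B-factors match a naive two-pass oracle", {
  s <- gen_toy_structure(7, "helix", seed = 2)
  ens <- gen_ensemble(s, 40, noise_sd = 0.25, seed = 5)
  fit <- superpose(ens)
  bf <- compute_bfactors(fit, selection = "CA")
  ca <- which(s$atom == "CA")
  for (r in seq_along(ca)) {
    xs <- t(fit$coords[ca[r], , ])
    mu <- colMeans(xs)
    msf <- mean(rowSums(sweep(xs, 2, mu)^2))
    expect_equal(bf$bfactor[r], (8 * pi^2 / 3) * msf, tolerance = 1e-10)
  }
})

test_that("cross-correlations hit the perfect, mirrored and null limits", {
  s <- gen_toy_structure(6, "helix", seed = 1)
  ref <- cbind(s$x, s$y, s$z)
  i <- which(s$seq_id == 2)
  j <- which(s$seq_id == 5)
  frames <- lapply(c(-1, 1, -2, 2), function(a) {
    m <- ref
    m[i, 1] <- m[i, 1] + a * 0.3
    m[j, 1] <- m[j, 1] + a * 0.3
    m
  })
  cc <- suppressWarnings(cross_correlation(new_ensemble(s, frames)))
  expect_equal(cc["A:2", "A:5"], 1, tolerance = 1e-12)
  frames_m <- lapply(c(-1, 1, -2, 2), function(a) {
    m <- ref
    m[i, 1] <- m[i, 1] + a * 0.3
    m[j, 1] <- m[j, 1] - a * 0.3
    m
  })
  cc_m <- suppressWarnings(cross_correlation(new_ensemble(s, frames_m)))
  expect_equal(cc_m["A:2", "A:5"], -1, tolerance = 1e-12)
})

test_that("zero-variance residues are reported and zeroed", {
  s <- gen_toy_structure(5, "helix", seed = 1)
  ref <- cbind(s$x, s$y, s$z)
  mv <- which(s$seq_id == 2)
  frames <- lapply(c(-0.4, 0.4), function(a) {
    m <- ref
    m[mv, 2] <- m[mv, 2] + a
    m
  })
  expect_warning(cc <- cross_correlation(new_ensemble(s, frames)), "zero fluctuation")
  expect_equal(diag(cc), rep(1, 5), ignore_attr = TRUE)
  expect_true(all(cc["A:1", colnames(cc) != "A:1"] == 0))
})

test_that("cross-correlation is invariant to a global rotation of all frames", {
  s <- gen_toy_structure(6, "helix", seed = 3)
  ens <- gen_ensemble(s, 60, noise_sd = 0.2, seed = 6)
  fit <- superpose(ens)
  cc1 <- cross_correlation(fit)
  R <- rot_z(1.1)
  rot <- fit
  for (t in seq_len(n_frames(fit))) rot$coords[, , t] <- fit$coords[, , t] %*% R
  cc2 <- cross_correlation(rot)
  expect_equal(cc1, cc2, tolerance = 1e-10)
})

test_that("PCA conserves variance and recovers planted directions", {
  s <- gen_toy_structure(6, "helix", seed = 1)
  ref <- cbind(s$x, s$y, s$z)
  # variance along exactly one direction
  sel <- which(s$atom == "CA")
  frames <- lapply(c(-1, -0.5, 0.5, 1), function(a) {
    m <- ref
    m[sel, 1] <- m[sel, 1] + a
    m
  })
  pc <- pca_modes(new_ensemble(s, frames), selection = "CA")
  expect_equal(pc$eigenvalues[1] / sum(pc$eigenvalues), 1, tolerance = 1e-10)
  # total variance equals the covariance trace
  ens <- gen_ensemble(s, 50, noise_sd = 0.2, seed = 8)
  fit <- superpose(ens)
  pc2 <- pca_modes(fit, selection = "CA")
  expect_equal(sum(pc2$eigenvalues), pc2$total_variance, tolerance = 1e-8)
  # modes orthonormal
  gram <- t(pc2$modes) %*% pc2$modes
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
  expect_error(pca_modes(new_ensemble(s, list(ref, ref))), "static|Degenerate")
})

test_that("PCA recovers the ANM mode that generated the ensemble", {
  s <- gen_toy_structure(10, "helix", seed = 2)
  dyn <- anm_modes(s)
  ens <- gen_ensemble(s, 300, mode_spectrum = list(mode = 7, amplitude = 0.5), seed = 10)
  fit <- superpose(ens)
  pc <- pca_modes(fit, selection = "CA")
  cosine <- abs(sum(pc$modes[, 1] * dyn$modes[, 7]))
  expect_gt(cosine, 0.99)
})

test_that("ANM yields six rigid-body modes on connected structures", {
  s <- gen_toy_structure(9, "globule", seed = 4)
  dyn <- anm_modes(s, cutoff = 15)
  expect_identical(dyn$n_rigid, 6L)
  expect_true(all(diff(dyn$eigenvalues) > -1e-10))
  gram <- t(dyn$modes) %*% dyn$modes
  expect_lt(max(abs(gram - diag(ncol(gram)))), 1e-8)
})

test_that("a disconnected CA network is an error naming the components", {
  a <- atom_row(1:4, rep("CA", 4), c(0, 4, 0, 4), c(0, 0, 4, 4), 0)
  b <- atom_row(5:8, rep("CA", 4), c(50, 54, 50, 54), c(0, 0, 4, 4), 0)
  s <- new_structure(rbind(a, b))
  expect_error(anm_modes(s, cutoff = 10), "2 components")
})

test_that("the ANM Hessian matches hand assembly on a collinear 3-bead toy", {
  s <- new_structure(atom_row(1:3, rep("CA", 3), c(0, 2, 4), 0, 0))
  dyn <- anm_modes(s, cutoff = 2.5, gamma = 2)
  # only neighbours 1-2 and 2-3 touch; spring along x with gamma = 2
  blk <- matrix(0, 3, 3)
  blk[1, 1] <- -2
  H <- matrix(0, 9, 9)
  for (p in list(c(1, 2), c(2, 3))) {
    i <- p[1]
    j <- p[2]
    ii <- (3 * i - 2):(3 * i)
    jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  expect_equal(dyn$hessian, H, ignore_attr = TRUE)
})
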