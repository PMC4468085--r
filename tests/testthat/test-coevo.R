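toy_msa <- function(rows, ids = NULL) {
  new_msa(do.call(rbind, strsplit(rows, "")), ids = ids)
}

test_that("alignments read from FASTA and Stockholm with unified gaps", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">s1", "AR-D", ">s2", "ar.d", ">s3", "ARCD", ">s4", "AKCD"
  ), fa)
  msa <- read_msa(fa)
  expect_identical(nrow(msa$matrix), 4L)
  expect_identical(msa$matrix[1, 3], "-")
  expect_identical(msa$matrix[2, ], c("A", "R", "-", "D"))

  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(
    "# STOCKHOLM 1.0",
    "s1 AR.D",
    "s2 ARCD",
    "//"
  ), sto)
  msa2 <- read_msa(sto)
  expect_identical(nrow(msa2$matrix), 2L)
  expect_identical(msa2$matrix[1, 3], "-")

  ragged <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ARND", ">oops", "ARN"), ragged)
  expect_error(read_msa(ragged), "oops")
})

test_that("sequence weights are inverse single-linkage cluster sizes", {
  same <- toy_msa(rep("ARNDCQ", 4))
  expect_equal(sequence_weights(same), rep(1 / 4, 4))
  distinct <- toy_msa(c("AAAAAA", "RRRRRR", "NNNNNN"))
  expect_equal(sequence_weights(distinct), rep(1, 3))
  mixed <- toy_msa(c("ARNDCQ", "ARNDCQ", "WYWYWY"))
  expect_equal(sequence_weights(mixed), c(0.5, 0.5, 1))
  expect_error(sequence_weights(toy_msa("ARND")), "2 sequences")
})

test_that("mutual information reproduces the two-state hand example", {
  msa <- toy_msa(c("AR", "AR", "CD", "CD"))
  mi <- mi_matrix(msa)
  expect_equal(mi[1, 2], log(2), tolerance = 1e-12)
  expect_equal(mi[2, 1], mi[1, 2])
  expect_equal(diag(mi), c(0, 0), ignore_attr = TRUE)
  # identical constant columns carry no information
  const <- toy_msa(c("AA", "AA", "AA"))
  expect_equal(mi_matrix(const)[1, 2], 0, tolerance = 1e-12)
  expect_error(mi_matrix(toy_msa(c("A-", "A-"))), "gaps")
  # naive oracle agreement on weighted-free random alignments
  set.seed(3)
  for (rep in 1:5) {
    m <- matrix(sample(c("A", "C", "D", "E", "-"), 60, replace = TRUE), 30, 2)
    msa_r <- new_msa(m)
    expect_equal(mi_matrix(msa_r)[1, 2], naive_mi(m[, 1], m[, 2]),
      tolerance = 1e-12
    )
  }
})

test_that("MI respects the entropy bound and column/row order invariance", {
  set.seed(11)
  for (rep in 1:50) {
    m <- matrix(sample(kinnet:::AA_ONE[1:6], 40 * 4, replace = TRUE), 40, 4)
    msa <- new_msa(m)
    mi <- mi_matrix(msa)
    h <- column_entropy(msa)
    for (i in 1:3) {
      for (j in (i + 1):4) {
        expect_lte(mi[i, j], min(h[i], h[j]) + 1e-12)
        expect_gte(mi[i, j], -1e-12)
      }
    }
    perm <- sample(nrow(m))
    expect_equal(mi_matrix(new_msa(m[perm, ])), mi, tolerance = 1e-12)
    cperm <- c(3, 1, 4, 2)
    expect_equal(
      mi_matrix(new_msa(m[, cperm]))[1, 2],
      mi[cperm[1], cperm[2]],
      tolerance = 1e-12
    )
  }
})

test_that("sequence weighting feeds the joint frequencies", {
  # duplicating a sequence and halving its weight leaves MI unchanged
  base <- c("AR", "AR", "CD", "CD")
  msa1 <- toy_msa(base)
  msa2 <- toy_msa(c(base, "CD"))
  w <- c(1, 1, 1, 0.5, 0.5)
  expect_equal(
    mi_matrix(msa2, weights = w)[1, 2],
    mi_matrix(msa1)[1, 2],
    tolerance = 1e-12
  )
})

test_that("KL conservation hits its closed forms and stays non-negative", {
  q <- background_frequencies(uniform = TRUE)
  # column distribution equal to the background -> 0
  m <- matrix(rep(kinnet:::AA_ONE, 3), ncol = 3)
  kl <- kl_conservation(new_msa(m), background = q)
  expect_equal(kl$kl, rep(0, 3), tolerance = 1e-12)
  # fully conserved column under uniform background -> ln 20
  cons <- new_msa(matrix("W", nrow = 50, ncol = 2))
  expect_equal(kl_conservation(cons, background = q)$kl,
    rep(log(20), 2),
    tolerance = 1e-9
  )
  set.seed(5)
  rand <- new_msa(matrix(sample(kinnet:::AA_ONE, 1000 * 2, replace = TRUE), 1000, 2))
  expect_true(all(kl_conservation(rand)$kl >= -1e-12))
  expect_true(all(kl_conservation(rand, form = "printed")$kl |> is.finite()))
  expect_error(kl_conservation(new_msa(matrix("-", 4, 1))), "gaps")
})

test_that("cMI sums supra-threshold partners only", {
  mi <- matrix(0, 4, 4)
  mi[1, 2] <- mi[2, 1] <- 7
  mi[1, 3] <- mi[3, 1] <- 8
  mi[1, 4] <- mi[4, 1] <- 3
  cm <- cmi(mi, t = 6.5, scale = "raw")
  expect_equal(cm$cmi[1], 15.0, tolerance = 1e-12)
  expect_equal(cmi(mi * 0, t = 6.5, scale = "raw")$cmi, rep(0, 4))
  expect_equal(cmi(mi, t = -Inf, scale = "raw")$cmi, rowSums(mi))
  expect_error(cmi(mi, t = 6.5, scale = "z"), "mi_z")
})

test_that("permutation z-scores are deterministic and flag planted pairs", {
  msa <- gen_msa(msa_spec(400, 10,
    coevolving_pairs = list(list(col_a = 2, col_b = 7, coupling = 1)),
    seed = 3
  ))
  mi <- mi_matrix(msa)
  z1 <- mi_zscore(mi, msa, n_permutations = 30, seed = 4)
  z2 <- mi_zscore(mi, msa, n_permutations = 30, seed = 4)
  expect_identical(z1, z2)
  # per-pair null moments give each pair its own calibration
  zp <- suppressWarnings(
    mi_zscore(mi, msa, n_permutations = 30, seed = 4, pooled = FALSE)
  )
  expect_gt(zp[2, 7], 6.5)
  planted <- matrix(FALSE, 10, 10)
  planted[2, 7] <- planted[7, 2] <- TRUE
  expect_lte(mean(zp[upper.tri(zp) & !planted] > 6.5), 0.05)
  expect_error(mi_zscore(mi, msa, n_permutations = 5), "20 permutations")
})

test_that("alignment columns map onto structure residues with bookkeeping", {
  s <- gen_toy_structure(12, "helix", seed = 1)
  seq1 <- unname(kinnet:::AA_THREE_TO_ONE[residue_table(s)$res_type])
  rows <- c(paste(seq1, collapse = ""), paste(rev(seq1), collapse = ""))
  msa <- toy_msa(rows, ids = c("ref", "other"))
  mp <- map_msa_to_structure(msa, s, reference_id = "ref")
  expect_equal(mp$column, 1:12)
  expect_identical(mp$key, residue_table(s)$key)
  expect_true(all(mp$match))
  # leading gap columns shift the mapping
  msa2 <- toy_msa(c(paste0("--", paste(seq1, collapse = "")), paste0("AA", paste(seq1, collapse = ""))),
    ids = c("ref", "other")
  )
  mp2 <- map_msa_to_structure(msa2, s, reference_id = "ref")
  expect_equal(mp2$column, 3:14)
  expect_identical(mp2$key[1], residue_table(s)$key[1])
  # a single mismatch is reported, not fatal
  seq_mut <- seq1
  seq_mut[2] <- if (seq1[2] == "W") "Y" else "W"
  msa3 <- toy_msa(c(paste(seq_mut, collapse = ""), rows[2]), ids = c("ref", "o"))
  mp3 <- map_msa_to_structure(msa3, s, reference_id = "ref")
  expect_false(mp3$match[2])
  expect_true(all(mp3$match[-2]))
  # wholesale disagreement fails
  msa4 <- toy_msa(c(strrep("W", 12), rows[2]), ids = c("ref", "o"))
  expect_error(map_msa_to_structure(msa4, s, reference_id = "ref"), "90")
})

test_that("pMI averages cMI over physical neighbours", {
  s <- new_structure(rbind(
    atom_row(1, "CB2", 0, 0, 0),
    atom_row(2, "CB2", 3, 0, 0),
    atom_row(3, "CB2", -3, 0, 0),
    atom_row(4, "CB2", 100, 0, 0)
  ))
  mapping <- tibble::tibble(
    column = 1:4, key = paste0("A:", 1:4),
    aa_msa = "L", aa_structure = "L", match = TRUE
  )
  cm <- tibble::tibble(column = 1:4, cmi = c(9, 2, 4, 7))
  pm <- suppressWarnings(pmi(cm, s, mapping, distance = 5))
  expect_equal(pm$pmi[pm$key == "A:1"], 3.0, tolerance = 1e-12) # mean(2, 4)
  expect_true(is.na(pm$pmi[pm$key == "A:4"])) # isolated residue flagged
  # infinite threshold -> mean of all other residues
  pm_inf <- pmi(cm, s, mapping, distance = Inf)
  expect_equal(pm_inf$pmi[pm_inf$key == "A:1"], mean(c(2, 4, 7)), tolerance = 1e-12)
  # constant field identity
  cmc <- tibble::tibble(column = 1:4, cmi = rep(5, 4))
  pmc <- suppressWarnings(pmi(cmc, s, mapping, distance = 5))
  expect_true(all(pmc$pmi[!is.na(pmc$pmi)] == 5))
})

test_that("circular export emits ring records and deduplicated edges", {
  s <- gen_toy_structure(5, "helix", seed = 2)
  seq1 <- unname(kinnet:::AA_THREE_TO_ONE[residue_table(s)$res_type])
  msa <- gen_msa(msa_spec(1000, 5,
    coevolving_pairs = list(list(col_a = 1, col_b = 4, coupling = 1)),
    seed = 9
  ))
  msa$matrix[1, ] <- seq1
  msa$ids[1] <- "ref"
  mi <- mi_matrix(msa)
  z <- mi_zscore(mi, msa, n_permutations = 25, seed = 2)
  kl <- kl_conservation(msa)
  cm <- cmi(mi, z, t = 6.5)
  mapping <- map_msa_to_structure(msa, s, reference_id = "ref")
  pm <- suppressWarnings(pmi(cm, s, mapping))
  out <- export_circular(mi, z, kl, cm, pm, mapping, t = 6.5)
  expect_identical(nrow(out$ring), nrow(mapping))
  expect_true(all(out$edges$pos_a < out$edges$pos_b))
  expect_true(any(out$edges$pos_a == 1 & out$edges$pos_b == 4))
  stem <- withr::local_tempfile()
  export_circular(mi, z, kl, cm, pm, mapping, t = 6.5, path = stem)
  expect_true(file.exists(paste0(stem, "_ring.tsv")))
  expect_true(file.exists(paste0(stem, "_edges.json")))
})
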