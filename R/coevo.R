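# MSA-based coevolution: mutual information (nats), permutation z-scores,
# KL conservation, cumulative MI (cMI) and structure-local proximity MI
# (pMI), plus circular-network export.

#' Construct an alignment object
#'
#' @param m Character matrix (sequences x columns) of upper-case one-letter
#'   codes; `"."` and `"-"` are both accepted as gaps and unified to `"-"`.
#' @param ids Sequence identifiers.
#' @param reference_id Identifier of the sequence used for structure
#'   mapping, if any.
#' @return A `kin_msa` object.
#' @export
new_msa <- function(m, ids = NULL, reference_id = NULL) {
  if (!is.matrix(m)) abort("m must be a character matrix")
  m <- toupper(m)
  m[m == "."] <- "-"
  bad <- setdiff(unique(as.vector(m)), c(AA_ONE, "-", "X", "B", "Z", "U", "O"))
  if (length(bad) > 0) {
    warn(paste0(
      "Non-standard alignment symbol(s) treated as gaps: ",
      paste(bad, collapse = ", ")
    ))
    m[m %in% bad] <- "-"
  }
  if (is.null(ids)) ids <- sprintf("seq%04d", seq_len(nrow(m)))
  out <- list(matrix = m, ids = ids, reference_id = reference_id)
  class(out) <- "kin_msa"
  out
}

#' @export
print.kin_msa <- function(x, ...) {
  cat(sprintf(
    "# kin_msa: %d sequences x %d columns\n", nrow(x$matrix), ncol(x$matrix)
  ))
  invisible(x)
}

#' Read a multiple sequence alignment
#'
#' FASTA or Stockholm input; records are case-normalised and `.`/`-` gaps
#' unified. Ragged FASTA alignments raise an error naming the offending
#' record.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fasta"`, or `"stockholm"`.
#' @param reference_id Optional reference sequence id (see
#'   [map_msa_to_structure()]).
#' @return A `kin_msa`.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm"),
                     reference_id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(sto|stk|stockholm)$", path)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    seqs <- Biostrings::readBStringSet(path)
    w <- Biostrings::width(seqs)
    if (length(unique(w)) > 1) {
      off <- names(seqs)[which(w != w[1])[1]]
      abort(sprintf("Ragged alignment: record '%s' has width %d, expected %d",
        off, w[which(w != w[1])[1]], w[1]
      ))
    }
    m <- do.call(rbind, strsplit(unname(as.character(seqs)), ""))
    ids <- names(seqs)
  } else {
    aln <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
    m <- as.matrix(Biostrings::unmasked(aln))
    ids <- rownames(m)
    dimnames(m) <- NULL
  }
  new_msa(m, ids = ids, reference_id = reference_id)
}

#' Write an alignment as FASTA
#'
#' @param msa A `kin_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(msa, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (s in seq_len(nrow(msa$matrix))) {
    writeLines(paste0(">", msa$ids[s]), con)
    writeLines(paste(msa$matrix[s, ], collapse = ""), con)
  }
  invisible(path)
}

#' Shipped background amino-acid frequencies
#'
#' Database-wide frequencies (UniProt-style composition), renormalised to
#' sum exactly to 1. `uniform = TRUE` returns the flat 1/20 distribution
#' used in closed-form tests.
#'
#' @param path Optional replacement TSV with columns `aa`, `freq`.
#' @param uniform Return the uniform distribution instead.
#' @return Named 20-vector summing to 1.
#' @export
background_frequencies <- function(path = NULL, uniform = FALSE) {
  if (uniform) {
    return(stats::setNames(rep(1 / 20, 20), AA_ONE))
  }
  tbl <- if (!is.null(path)) {
    readr::read_tsv(path, show_col_types = FALSE)
  } else {
    load_tsv_resource("aa_background.tsv")
  }
  q <- stats::setNames(tbl$freq, tbl$aa)[AA_ONE]
  if (any(is.na(q) | q <= 0)) abort("Background must be positive for all 20 amino acids")
  q / sum(q)
}

encode_msa <- function(msa) {
  m <- matrix(match(msa$matrix, AA_ONE), nrow = nrow(msa$matrix))
  m[is.na(m)] <- 0L # gap
  m
}

#' Sequence weights by identity clustering
#'
#' Single-linkage clusters at the given fractional identity (pairwise
#' identity is the fraction of equal alignment positions); each sequence is
#' weighted `1 / cluster size`, so weights sum to the number of clusters.
#'
#' @param msa A `kin_msa` with at least 2 sequences.
#' @param threshold Fractional identity joining two sequences (default 0.62).
#' @return Numeric weight per sequence.
#' @export
sequence_weights <- function(msa, threshold = 0.62) {
  m <- encode_msa(msa)
  n <- nrow(m)
  if (n < 2) abort("Need at least 2 sequences")
  L <- ncol(m)
  ident <- matrix(0, n, n)
  for (sym in sort(unique(as.vector(m)))) {
    ind <- (m == sym) * 1
    ident <- ident + tcrossprod(ind)
  }
  ident <- ident / L
  g <- igraph::graph_from_adjacency_matrix(ident >= threshold, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership
  sz <- table(comp)
  1 / as.vector(sz[as.character(comp)])
}

mi_pair <- function(ci, cj, w, gap_as_symbol = FALSE) {
  if (!gap_as_symbol) {
    ok <- ci > 0L & cj > 0L
    ci <- ci[ok]
    cj <- cj[ok]
    w <- w[ok]
  } else {
    ci <- ci + 1L
    cj <- cj + 1L
  }
  if (length(ci) == 0) return(0)
  code <- ci * 32L + cj
  cnt <- rowsum(w, code)
  p <- cnt / sum(cnt)
  codes <- as.integer(rownames(cnt))
  a <- codes %/% 32L
  b <- codes %% 32L
  pa <- rowsum(p, a)
  pb <- rowsum(p, b)
  pai <- pa[match(a, as.integer(rownames(pa)))]
  pbj <- pb[match(b, as.integer(rownames(pb)))]
  sum(p * log(p / (pai * pbj)))
}

# fast path: unit weights, pairwise-complete gaps
mi_pair_fast <- function(ci, cj) {
  ok <- ci > 0L & cj > 0L
  ci <- ci[ok]
  cj <- cj[ok]
  if (length(ci) == 0) return(0)
  cnt <- tabulate(ci * 21L + cj, nbins = 21L * 21L + 20L)
  nz <- which(cnt > 0L)
  p <- cnt[nz] / length(ci)
  a <- nz %/% 21L
  b <- nz %% 21L
  pa <- tabulate(ci, nbins = 20L) / length(ci)
  pb <- tabulate(cj, nbins = 20L) / length(ci)
  sum(p * log(p / (pa[a] * pb[b])))
}

#' Mutual information matrix of an alignment
#'
#' Plug-in mutual information (nats) between every pair of columns,
#' `MI(i,j) = sum_ab P(a,b) ln[P(a,b) / (P(a) P(b))]`, with optionally
#' weighted sequence counts. Under the default gap policy, sequences gapped
#' at either column are dropped from that pair's joint counts; the
#' alternative treats the gap as a 21st symbol. The diagonal is 0 by
#' convention.
#'
#' @param msa A `kin_msa` with at least 2 columns.
#' @param weights Per-sequence weights (default: unweighted).
#' @param gap_policy `"pairwise"` (drop gapped pairs, default) or
#'   `"symbol"` (gap as 21st symbol).
#' @return Symmetric matrix (nats), labelled by column index.
#' @export
mi_matrix <- function(msa, weights = NULL, gap_policy = c("pairwise", "symbol")) {
  gap_policy <- match.arg(gap_policy)
  m <- encode_msa(msa)
  L <- ncol(m)
  if (L < 2) abort("Need at least 2 columns")
  all_gap <- which(colSums(m > 0L) == 0L)
  if (length(all_gap) > 0) {
    abort(paste0("Column(s) entirely gaps: ", paste(all_gap, collapse = ", ")))
  }
  mi <- matrix(0, L, L, dimnames = list(seq_len(L), seq_len(L)))
  fast <- is.null(weights) && gap_policy == "pairwise"
  w <- if (is.null(weights)) rep(1, nrow(m)) else weights
  for (i in seq_len(L - 1)) {
    ci <- m[, i]
    for (j in (i + 1):L) {
      v <- if (fast) {
        mi_pair_fast(ci, m[, j])
      } else {
        mi_pair(ci, m[, j], w, gap_as_symbol = gap_policy == "symbol")
      }
      mi[i, j] <- v
      mi[j, i] <- v
    }
  }
  mi
}

#' Per-column Shannon entropy
#'
#' @param msa A `kin_msa`.
#' @param weights Optional per-sequence weights.
#' @return Numeric entropy (nats) per column, gaps excluded.
#' @export
column_entropy <- function(msa, weights = NULL) {
  m <- encode_msa(msa)
  w <- if (is.null(weights)) rep(1, nrow(m)) else weights
  vapply(seq_len(ncol(m)), function(i) {
    ok <- m[, i] > 0L
    if (!any(ok)) return(NA_real_)
    cnt <- rowsum(w[ok], m[ok, i])
    p <- cnt / sum(cnt)
    -sum(p * log(p))
  }, numeric(1))
}

#' Permutation z-scores for mutual information
#'
#' Builds a null by independently shuffling each column's non-gap entries
#' (preserving both the column composition and the gap mask) and recomputing
#' the MI matrix. By default the null is pooled over all column pairs
#' (stable at modest permutation counts); `pooled = FALSE` gives per-pair
#' null moments.
#'
#' @param mi Observed MI matrix from [mi_matrix()].
#' @param msa The alignment it came from.
#' @param n_permutations At least 20 (default 100).
#' @param seed Integer seed.
#' @param weights,gap_policy As in [mi_matrix()].
#' @param pooled Pool null moments across pairs.
#' @return Matrix of z-scores; entries with zero null variance are `NA`
#'   with a warning.
#' @export
mi_zscore <- function(mi, msa, n_permutations = 100, seed = 1, weights = NULL,
                      gap_policy = c("pairwise", "symbol"), pooled = TRUE) {
  gap_policy <- match.arg(gap_policy)
  if (n_permutations < 20) abort("Need at least 20 permutations")
  m <- encode_msa(msa)
  L <- ncol(m)
  ut <- upper.tri(mi)
  with_seed(seed, {
    null_vals <- if (pooled) numeric(0) else NULL
    null_sum <- matrix(0, L, L)
    null_sq <- matrix(0, L, L)
    for (p in seq_len(n_permutations)) {
      mp <- m
      for (i in seq_len(L)) {
        ok <- which(mp[, i] > 0L)
        mp[ok, i] <- mp[sample(ok), i]
      }
      msa_p <- list(matrix = matrix(AA_ONE[ifelse(mp == 0L, NA, mp)], nrow = nrow(mp)))
      msa_p$matrix[is.na(msa_p$matrix)] <- "-"
      class(msa_p) <- "kin_msa"
      mi_p <- mi_matrix(msa_p, weights = weights, gap_policy = gap_policy)
      if (pooled) {
        null_vals <- c(null_vals, mi_p[ut])
      } else {
        null_sum <- null_sum + mi_p
        null_sq <- null_sq + mi_p^2
      }
    }
    if (pooled) {
      mu <- mean(null_vals)
      sdv <- stats::sd(null_vals)
      if (sdv == 0) {
        warn("Zero null variance; z-scores undefined")
        z <- matrix(NA_real_, L, L)
      } else {
        z <- (mi - mu) / sdv
      }
    } else {
      mu <- null_sum / n_permutations
      sdv <- sqrt(pmax(null_sq / n_permutations - mu^2, 0) *
        n_permutations / (n_permutations - 1))
      z <- (mi - mu) / sdv
      if (any(sdv == 0)) {
        warn("Zero null variance for some pairs; their z-scores are NA")
        z[sdv == 0] <- NA_real_
      }
    }
    diag(z) <- 0
    dimnames(z) <- dimnames(mi)
    z
  })
}

#' Kullback-Leibler conservation per column
#'
#' `KL_i = sum_a P(a) ln[P(a) / Q(a)]` over the residues observed in the
#' column (gaps excluded, frequencies renormalised). The `"printed"` form
#' drops the `P(a)` weight and sums `ln[P(a)/Q(a)]` over observed residues
#' only.
#'
#' @param msa A `kin_msa`.
#' @param weights Optional sequence weights.
#' @param background Named 20-vector from [background_frequencies()];
#'   default is the shipped database composition.
#' @param form `"weighted"` (standard KL, default) or `"printed"`.
#' @return Tibble with `column` and `kl` (nats).
#' @export
kl_conservation <- function(msa, weights = NULL,
                            background = background_frequencies(),
                            form = c("weighted", "printed")) {
  form <- match.arg(form)
  if (any(background <= 0)) abort("Background frequencies must be positive")
  background <- background / sum(background)
  m <- encode_msa(msa)
  w <- if (is.null(weights)) rep(1, nrow(m)) else weights
  kl <- vapply(seq_len(ncol(m)), function(i) {
    ok <- m[, i] > 0L
    if (!any(ok)) abort(paste0("Column ", i, " is entirely gaps"))
    cnt <- rowsum(w[ok], m[ok, i])
    p <- as.vector(cnt) / sum(cnt)
    q <- background[as.integer(rownames(cnt))]
    if (form == "weighted") sum(p * log(p / q)) else sum(log(p / q))
  }, numeric(1))
  tibble(column = seq_len(ncol(m)), kl = kl)
}

#' Cumulative mutual information per column
#'
#' `cMI_x = sum over y of MI(x, y)` restricted to pairs whose score exceeds
#' the threshold. The threshold is applied on the permutation z-score scale
#' by default (`scale = "z"`, requiring `mi_z`), because raw plug-in MI over
#' a 20-letter alphabet is bounded by `ln 20` and can never reach the
#' conventional 6.5 cutoff; `scale = "raw"` thresholds the MI values
#' themselves.
#'
#' @param mi MI matrix.
#' @param mi_z z-score matrix (needed for `scale = "z"`).
#' @param t Threshold (default 6.5).
#' @param scale `"z"` or `"raw"`.
#' @return Tibble with `column` and `cmi`.
#' @export
cmi <- function(mi, mi_z = NULL, t = 6.5, scale = c("z", "raw")) {
  scale <- match.arg(scale)
  score <- if (scale == "z") {
    if (is.null(mi_z)) abort("scale = 'z' needs the mi_z matrix")
    mi_z
  } else {
    mi
  }
  sel <- score > t
  sel[is.na(sel)] <- FALSE
  diag(sel) <- FALSE
  tibble(column = seq_len(nrow(mi)), cmi = rowSums(mi * sel))
}

#' Map alignment columns onto structure residues
#'
#' The reference row's non-gap columns are matched in order to the protein
#' residues of the structure; identity below 90 percent is an error,
#' individual mismatches are reported in the `match` column.
#'
#' @param msa A `kin_msa`.
#' @param structure A `kin_structure`.
#' @param reference_id Id of the alignment row to map through (default the
#'   alignment's `reference_id`).
#' @return Tibble with `column`, `key`, `aa_msa`, `aa_structure`, `match`.
#' @export
map_msa_to_structure <- function(msa, structure, reference_id = NULL) {
  if (is.null(reference_id)) reference_id <- msa$reference_id
  if (is.null(reference_id)) abort("No reference sequence id given")
  row <- match(reference_id, msa$ids)
  if (is.na(row)) abort(paste0("Reference id not in alignment: ", reference_id))
  ref <- msa$matrix[row, ]
  cols <- which(ref != "-")
  rt <- residue_table(structure[!structure$is_ligand, ])
  seq_struct <- unname(AA_THREE_TO_ONE[rt$res_type])
  if (length(cols) != nrow(rt)) {
    abort(sprintf(
      "Reference row has %d residues but the structure has %d",
      length(cols), nrow(rt)
    ))
  }
  aa_msa <- ref[cols]
  ok <- aa_msa == seq_struct
  if (mean(ok) < 0.9) {
    abort(sprintf(
      "Reference/structure identity %.0f%% is below 90%%", 100 * mean(ok)
    ))
  }
  tibble(
    column = cols, key = rt$key, aa_msa = aa_msa,
    aa_structure = seq_struct, match = ok
  )
}

#' Proximity mutual information
#'
#' For each mapped residue, the mean cMI of all other mapped residues whose
#' minimal heavy-atom distance is within the threshold. Residues with no
#' neighbour are reported with `NA`.
#'
#' @param cmi_tbl Tibble from [cmi()].
#' @param structure A `kin_structure`.
#' @param mapping Tibble from [map_msa_to_structure()].
#' @param distance Neighbourhood threshold in angstrom (default 5).
#' @return Tibble with `key`, `column`, `pmi`, `n_neighbors`.
#' @export
pmi <- function(cmi_tbl, structure, mapping, distance = 5) {
  prot <- structure[!structure$is_ligand &
    toupper(structure$element) != "H", ]
  keys <- residue_keys(prot)
  use <- mapping$key
  cvals <- stats::setNames(cmi_tbl$cmi[match(mapping$column, cmi_tbl$column)], use)
  xyz <- coords_matrix(prot)
  d2 <- pair_dist2(xyz, xyz)
  out <- purrr::map_dfr(seq_along(use), function(ix) {
    kx <- use[ix]
    mine <- keys == kx
    dmin <- vapply(use, function(ky) {
      if (ky == kx) return(Inf)
      sqrt(min(d2[mine, keys == ky]))
    }, numeric(1))
    nb <- setdiff(names(dmin)[dmin <= distance], kx)
    tibble(
      key = kx, column = mapping$column[ix],
      pmi = if (length(nb) > 0) mean(cvals[nb]) else NA_real_,
      n_neighbors = length(nb)
    )
  })
  if (any(is.na(out$pmi))) {
    warn(sprintf("%d residue(s) have no neighbour within %.1f angstrom", sum(is.na(out$pmi)), distance))
  }
  out
}

#' Circular-network export of coevolution scores
#'
#' Per-position ring records (position, reference residue, KL, cMI, pMI)
#' plus the deduplicated edge list of pairs above the threshold, for
#' circular-network rendering.
#'
#' @param mi,mi_z Score matrices.
#' @param kl_tbl,cmi_tbl,pmi_tbl Per-column/residue score tables.
#' @param mapping Tibble from [map_msa_to_structure()].
#' @param t Edge threshold (default 6.5 on the z scale).
#' @param scale `"z"` or `"raw"` (which matrix `t` is applied to).
#' @param path Optional output stem; writes `<path>_ring.tsv`,
#'   `<path>_edges.tsv` and `<path>_edges.json`.
#' @return List with `ring` and `edges` tibbles.
#' @export
export_circular <- function(mi, mi_z = NULL, kl_tbl, cmi_tbl, pmi_tbl,
                            mapping, t = 6.5, scale = c("z", "raw"),
                            path = NULL) {
  scale <- match.arg(scale)
  score <- if (scale == "z") mi_z else mi
  if (is.null(score)) abort("scale = 'z' needs mi_z")
  ring <- mapping |>
    left_join(kl_tbl, by = "column") |>
    left_join(cmi_tbl, by = "column") |>
    left_join(pmi_tbl |> select("column", "pmi"), by = "column") |>
    select(position = "column", residue = "aa_msa", "kl", "cmi", "pmi")
  hit <- which(upper.tri(score) & score > t, arr.ind = TRUE)
  edges <- tibble(
    pos_a = hit[, 1], pos_b = hit[, 2],
    mi = mi[hit], score = score[hit]
  ) |>
    filter(.data$pos_a %in% mapping$column, .data$pos_b %in% mapping$column)
  if (!is.null(path)) {
    readr::write_tsv(ring, paste0(path, "_ring.tsv"))
    readr::write_tsv(edges, paste0(path, "_edges.tsv"))
    jsonlite::write_json(edges, paste0(path, "_edges.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
  }
  list(ring = ring, edges = edges)
}
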