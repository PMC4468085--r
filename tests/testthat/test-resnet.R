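test_that("interaction strength follows the normalized contact formula", {
  expect_equal(interaction_strength(0, 50, 80), 0)
  expect_equal(interaction_strength(4, 100, 100), 4.0, tolerance = 1e-12)
  expect_equal(
    interaction_strength(4, 100, 100),
    interaction_strength(4, 100, 100)
  )
  expect_equal(interaction_strength(6, 30, 120), 6 / sqrt(3600) * 100)
  expect_equal(interaction_strength(4, 100, 100, form = "product"), 0.04)
  expect_error(interaction_strength(1, 0, 10), "> 0")
  expect_error(interaction_strength(-1, 10, 10), "non-negative")
})

test_that("the I_min admission rule keeps exactly the supra-threshold edges", {
  edges <- tibble::tibble(
    key_i = c("A:1", "A:1", "A:2"),
    key_j = c("A:2", "A:3", "A:3"),
    I = c(4.0, 2.0, 5.0)
  )
  g <- residue_graph(edges, i_min = 3.0)
  expect_identical(nrow(g$edges), 2L)
  expect_setequal(paste(g$edges$key_i, g$edges$key_j), c("A:1 A:2", "A:2 A:3"))
})

test_that("normalization factors take the dataset maximum and tables win", {
  # two residues of one type with controlled heavy-atom surroundings
  s1 <- new_structure(rbind(
    atom_row(1, "CB2", 0, 0, 0, res_type = "LEU"),
    atom_row(3, "CB2", 3, 0, 0, res_type = "SER"),
    atom_row(5, "CB2", 3, 4, 0, res_type = "SER")
  ))
  nf <- normalization_factors(s1)
  # LEU: 1 pair (to A:3); SER A:3: pairs to A:1 and A:5 -> 2
  expect_equal(nf$N[nf$res_type == "LEU"], 1)
  expect_equal(nf$N[nf$res_type == "SER"], 2)
  tab <- tibble::tibble(res_type = c("LEU", "SER"), N = c(10, 20))
  nf2 <- normalization_factors(s1, table = tab)
  expect_equal(nf2$N[nf2$res_type == "LEU"], 10)
  expect_error(normalization_factors(), "structure")
  expect_error(
    normalization_factors(mode = "table", table = tibble::tibble(res_type = "A", N = -1)),
    "positive"
  )
})

test_that("edge weights follow -log|C| with clamping at both ends", {
  edges <- tibble::tibble(key_i = "A:1", key_j = "A:2", I = 10)
  s <- new_structure(rbind(
    atom_row(1, "CB2", 0, 0, 0),
    atom_row(2, "CB2", 100, 0, 0) # no real contact; we inject edges below
  ))
  corr <- diag(2)
  dimnames(corr) <- list(c("A:1", "A:2"), c("A:1", "A:2"))
  corr[1, 2] <- corr[2, 1] <- 1 - 1e-6
  # strongly coupled -> near-zero distance
  w <- -log(pmin(pmax(abs(corr[1, 2]), 1e-6), 1 - 1e-6))
  expect_equal(w, -log(1 - 1e-6))
  corr0 <- corr
  corr0[1, 2] <- corr0[2, 1] <- 0
  w0 <- -log(pmin(pmax(abs(corr0[1, 2]), 1e-6), 1 - 1e-6))
  expect_equal(w0, -log(1e-6)) # finite even at zero correlation
})

test_that("build_graph wires correlation weights and the ligand node", {
  cx <- gen_complex(complex_spec(16, c(3, 14), ligand_atoms = 5, seed = 1))
  ens <- gen_ensemble(cx$holo, 30, noise_sd = 0.15, seed = 2)
  corr <- cross_correlation(ens)
  g <- build_graph(cx$holo, correlation = corr, weighting = "correlation")
  expect_true(all(g$edges$weight >= -log(1 - 1e-6) - 1e-12))
  expect_true(all(is.finite(g$edges$weight)))
  lig_edges <- g$edges[g$edges$key_j == "X:1" | g$edges$key_i == "X:1", ]
  expect_setequal(
    setdiff(c(lig_edges$key_i, lig_edges$key_j), "X:1"),
    c("A:3", "A:14")
  )
  expect_equal(
    unique(lig_edges$weight),
    stats::median(g$edges$weight[g$edges$key_j != "X:1" & g$edges$key_i != "X:1"])
  )
  # missing correlation entry errors
  expect_error(
    build_graph(cx$holo, correlation = corr[-1, -1], weighting = "correlation"),
    "missing residue"
  )
  expect_error(build_graph(cx$holo, i_min = -1, weighting = "uniform"), "non-negative")
  # bridge_strength 0 leaves the protein subgraph identical to apo
  cx0 <- gen_complex(complex_spec(16, c(3, 14), ligand_atoms = 5, bridge_strength = 0, seed = 1))
  ga <- build_graph(cx0$apo, weighting = "uniform")
  gh <- build_graph(cx0$holo, weighting = "uniform")
  prot_edges <- function(g) {
    g$edges[g$edges$key_i != "X:1" & g$edges$key_j != "X:1", ]
  }
  expect_identical(
    as.data.frame(prot_edges(gh)),
    as.data.frame(prot_edges(ga))
  )
})

test_that("Floyd-Warshall distances and path counts match hand enumeration", {
  p3 <- residue_graph(tibble::tibble(
    key_i = c("A", "B"), key_j = c("B", "C"), I = 100, weight = 1
  ), i_min = 0)
  sp <- shortest_path_counts(p3)
  expect_equal(sp$dist["A", "C"], 2)
  expect_equal(sp$counts["A", "C"], 1)
  # 4-cycle: opposite corners have two co-optimal paths
  c4 <- residue_graph(tibble::tibble(
    key_i = c("A", "B", "C", "D"), key_j = c("B", "C", "D", "A"),
    I = 100, weight = 1
  ), i_min = 0)
  sp4 <- shortest_path_counts(c4)
  expect_equal(sp4$dist["A", "C"], 2)
  expect_equal(sp4$counts["A", "C"], 2)
  expect_equal(sp4$counts["B", "D"], 2)
})

test_that("distances agree with an independent igraph oracle on random graphs", {
  for (seed in 1:50) {
    edges <- random_edge_graph(sample(4:8, 1), seed = seed)
    g <- residue_graph(edges, i_min = 0)
    sp <- shortest_path_counts(g)
    ig <- igraph::graph_from_data_frame(
      edges[, c("key_i", "key_j", "weight")],
      directed = FALSE,
      vertices = data.frame(name = g$nodes$key)
    )
    dm <- igraph::distances(ig, weights = igraph::E(ig)$weight)
    expect_equal(sp$dist, dm[rownames(sp$dist), colnames(sp$dist)],
      tolerance = 1e-12
    )
  }
})

test_that("normalized betweenness matches enumeration on canonical toys", {
  p3 <- residue_graph(tibble::tibble(
    key_i = c("A", "B"), key_j = c("B", "C"), I = 100, weight = 1
  ), i_min = 0)
  cb <- betweenness_centrality(p3)
  expect_equal(cb$betweenness[cb$key == "B"], 1.0, tolerance = 1e-12)
  expect_equal(cb$betweenness[cb$key != "B"], c(0, 0), tolerance = 1e-12)

  star <- residue_graph(tibble::tibble(
    key_i = rep("hub", 4), key_j = paste0("leaf", 1:4), I = 100, weight = 1
  ), i_min = 0)
  cbs <- betweenness_centrality(star)
  expect_equal(cbs$betweenness[cbs$key == "hub"], 1.0, tolerance = 1e-12)
  expect_true(all(cbs$betweenness[cbs$key != "hub"] == 0))

  c4 <- residue_graph(tibble::tibble(
    key_i = c("A", "B", "C", "D"), key_j = c("B", "C", "D", "A"),
    I = 100, weight = 1
  ), i_min = 0)
  cb4 <- betweenness_centrality(c4)
  expect_equal(cb4$betweenness, rep(1 / 6, 4), tolerance = 1e-12)

  # components of size < 3 score zero
  pair <- residue_graph(tibble::tibble(
    key_i = "A", key_j = "B", I = 100, weight = 1
  ), i_min = 0)
  expect_true(all(betweenness_centrality(pair)$betweenness == 0))
})

test_that("uniform-weight betweenness equals the topological variant", {
  for (seed in 1:10) {
    edges <- random_edge_graph(7, seed = seed)
    edges$weight <- 1
    g <- residue_graph(edges, i_min = 0)
    expect_equal(
      betweenness_centrality(g, weighted = TRUE)$betweenness,
      betweenness_centrality(g, weighted = FALSE)$betweenness,
      tolerance = 1e-12
    )
  }
})

test_that("delta centrality reports ligand-induced gains on bridged termini", {
  # path graph A-B-C-D-E; ligand bridges the termini A and E
  path_edges <- tibble::tibble(
    key_i = c("A", "B", "C", "D"), key_j = c("B", "C", "D", "E"),
    I = 100, weight = 1
  )
  apo <- betweenness_centrality(residue_graph(path_edges, i_min = 0))
  holo_edges <- rbind(
    path_edges,
    tibble::tibble(key_i = c("A", "E"), key_j = "LIG", I = 100, weight = 1)
  )
  holo <- betweenness_centrality(residue_graph(holo_edges, i_min = 0))
  dc <- delta_centrality(apo, holo)
  expect_gt(dc$delta[dc$key == "A"], 0)
  expect_gt(dc$delta[dc$key == "E"], 0)
  expect_lt(dc$delta[dc$key == "C"], 0) # old middle loses
  expect_false("LIG" %in% dc$key)
  # identical profiles -> all zero
  dc0 <- delta_centrality(apo, apo)
  expect_true(all(dc0$delta == 0))
  expect_error(
    delta_centrality(
      apo,
      betweenness_centrality(residue_graph(tibble::tibble(
        key_i = "x", key_j = "y", I = 100, weight = 1
      ), i_min = 0))
    ),
    "shared"
  )
})

test_that("betweenness equals exhaustive path enumeration on random graphs", {
  for (seed in 1:40) {
    n <- sample(4:7, 1)
    edges <- random_edge_graph(n, seed = 1000 + seed)
    g <- residue_graph(edges, i_min = 0)
    cb <- betweenness_centrality(g)
    oracle <- brute_betweenness(g$nodes$key, edges)
    expect_equal(cb$betweenness, unname(oracle[cb$key]), tolerance = 1e-12)
  }
})

test_that("adding a bridging node never hurts pair connectivity (monotone)", {
  for (seed in 1:10) {
    edges <- random_edge_graph(6, seed = 2000 + seed, p = 0.3)
    g <- residue_graph(edges, i_min = 0)
    sp <- shortest_path_counts(g)
    a <- g$nodes$key[1]
    b <- g$nodes$key[nrow(g$nodes)]
    bridged <- rbind(
      edges,
      tibble::tibble(key_i = c(a, b), key_j = "LIG", I = 100, weight = 1)
    )
    sp2 <- shortest_path_counts(residue_graph(bridged, i_min = 0))
    expect_lte(sp2$dist[a, b], sp$dist[a, b] + 1e-12)
  }
})

test_that("removing the top-betweenness node damages the network most", {
  mean_path <- function(g) {
    d <- shortest_path_counts(g)$dist
    v <- d[upper.tri(d)]
    mean(v[is.finite(v)])
  }
  worse <- 0L
  n_seeds <- 10L
  for (seed in seq_len(n_seeds)) {
    cx <- gen_complex(complex_spec(16, c(3, 14), ligand_atoms = 5, seed = seed))
    g <- build_graph(cx$holo, weighting = "uniform")
    cb <- betweenness_centrality(g)
    top <- cb$key[which.max(cb$betweenness)]
    set.seed(seed)
    rnd <- sample(setdiff(cb$key, top), 1)
    drop_node <- function(g, key) {
      residue_graph(
        g$edges[g$edges$key_i != key & g$edges$key_j != key, ],
        i_min = 0,
        nodes = g$nodes[g$nodes$key != key, ]
      )
    }
    worse <- worse + (mean_path(drop_node(g, top)) >=
      mean_path(drop_node(g, rnd)) - 1e-12)
  }
  expect_gte(worse, ceiling(0.7 * n_seeds))
})

test_that("joint profiles pass values through and warn on missing keys", {
  cb <- betweenness_centrality(residue_graph(tibble::tibble(
    key_i = c("A:1", "A:2"), key_j = c("A:2", "A:3"), I = 100, weight = 1
  ), i_min = 0))
  bf <- tibble::tibble(key = c("A:1", "A:2", "A:3"), bfactor = c(1, 2, 3))
  rs <- tibble::tibble(key = c("A:1", "A:2", "A:3"), rsa = c(0.1, 0.5, 0.9))
  jp <- joint_profiles(cb, bf, rs)
  expect_identical(nrow(jp), 3L)
  expect_equal(jp$bfactor, c(1, 2, 3))
  expect_warning(
    jp2 <- joint_profiles(cb, bf, rs[-2, ]),
    "Dropped"
  )
  expect_identical(nrow(jp2), 2L)
})

test_that("graph exports round-trip the edge list", {
  g <- residue_graph(tibble::tibble(
    key_i = c("A:1", "A:2"), key_j = c("A:2", "A:3"), I = c(5, 7), weight = c(1, 2)
  ), i_min = 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_graph_file(g, tsv)
  back <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(back$weight, g$edges$weight)
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graph_file(g, gml)
  ig <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(ig), 3)
  expect_equal(igraph::gsize(ig), 2)
})
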