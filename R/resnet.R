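# Residue interaction networks: normalized side-chain interaction
# strengths, correlation-weighted edges, Floyd-Warshall shortest paths with
# multiplicity counting, and normalized betweenness centrality.

#' Residue-type normalization factors
#'
#' In `dataset` mode, the factor `N_i` for residue type `i` is the maximum,
#' over all residues of that type in the supplied structures, of its total
#' heavy-atom pair count (main chain and side chain) to all surrounding
#' residues within the contact cutoff. In `table` mode a user table with
#' columns `res_type`, `N` is loaded verbatim; when both are given the
#' table wins. The dataset-derived defaults are a documented reconstruction
#' of the published normalization scheme.
#'
#' @param structures A `kin_structure` or list of them (dataset mode).
#' @param mode `"dataset"` or `"table"`.
#' @param table Tibble/data frame with columns `res_type`, `N`, or a path
#'   to such a TSV.
#' @param cutoff Contact cutoff in angstrom (default 4.5).
#' @return Tibble with `res_type` and strictly positive `N`.
#' @export
normalization_factors <- function(structures = NULL,
                                  mode = c("dataset", "table"),
                                  table = NULL, cutoff = 4.5) {
  mode <- match.arg(mode)
  tab <- NULL
  if (!is.null(table)) {
    tab <- if (is.character(table)) {
      readr::read_tsv(table, show_col_types = FALSE)
    } else {
      as_tibble(table)
    }
    if (!all(c("res_type", "N") %in% names(tab))) {
      abort("Normalization table needs columns res_type, N")
    }
    if (any(tab$N <= 0)) abort("Normalization factors must be strictly positive")
  }
  if (mode == "table" || (is.null(structures) && !is.null(tab))) {
    if (is.null(tab)) abort("mode = 'table' needs a table")
    return(tab[, c("res_type", "N")])
  }
  if (is.null(structures)) abort("dataset mode needs at least one structure")
  if (inherits(structures, "kin_structure")) structures <- list(structures)
  per_res <- purrr::map_dfr(structures, function(s) {
    s <- s[!s$is_ligand, ]
    cm <- contact_map(s, cutoff = cutoff, atoms = "heavy")
    rt <- residue_table(s)
    totals <- bind_rows(
      cm |> select(key = "key_i", n = "n_pairs"),
      cm |> select(key = "key_j", n = "n_pairs")
    ) |>
      group_by(.data$key) |>
      summarise(n = sum(.data$n), .groups = "drop")
    rt |>
      left_join(totals, by = "key") |>
      mutate(n = ifelse(is.na(.data$n), 0L, .data$n)) |>
      select("res_type", "n")
  })
  ds <- per_res |>
    group_by(.data$res_type) |>
    summarise(N = max(.data$n), .groups = "drop") |>
    filter(.data$N > 0)
  if (!is.null(tab)) {
    ds <- bind_rows(tab[, c("res_type", "N")], anti_join(ds, tab, by = "res_type"))
  }
  ds
}

#' Interaction strength between two residues
#'
#' `I_ij = n_ij / sqrt(N_i * N_j) * 100` (percent), following the
#' normalized side-chain contact scheme; `form = "product"` switches to
#' `n_ij / (N_i * N_j) * 100` for sensitivity checks.
#'
#' @param n_ij Atom-pair contact count (non-negative).
#' @param N_i,N_j Normalization factors (strictly positive).
#' @param form `"sqrt"` (default) or `"product"`.
#' @return Interaction strength in percent; symmetric in `i`, `j`.
#' @export
interaction_strength <- function(n_ij, N_i, N_j, form = c("sqrt", "product")) {
  form <- match.arg(form)
  if (any(N_i <= 0) || any(N_j <= 0)) abort("Normalization factors must be > 0")
  if (any(n_ij < 0)) abort("Contact counts must be non-negative")
  if (form == "sqrt") {
    n_ij / sqrt(N_i * N_j) * 100
  } else {
    n_ij / (N_i * N_j) * 100
  }
}

#' Per-pair interaction strengths of a structure
#'
#' Side-chain heavy-atom contact counts at the cutoff converted to percent
#' interaction strengths. Residue pairs adjacent in sequence
#' (`|delta seq_id| <= 1` on the same chain) are covalent neighbours, not
#' interactions, and are excluded by default.
#'
#' @param structure A `kin_structure` (ligand residues are skipped here;
#'   ligand edges are handled by [build_graph()]).
#' @param norm Normalization table from [normalization_factors()]; default
#'   derives dataset-mode factors from `structure` itself.
#' @param cutoff Contact cutoff in angstrom.
#' @param exclude_adjacent Drop sequence-adjacent pairs.
#' @param form Passed to [interaction_strength()].
#' @return Tibble with `key_i`, `key_j`, `n_pairs`, `I` (percent).
#' @export
interaction_strengths <- function(structure, norm = NULL, cutoff = 4.5,
                                  exclude_adjacent = TRUE,
                                  form = c("sqrt", "product")) {
  form <- match.arg(form)
  prot <- structure[!structure$is_ligand, ]
  if (is.null(norm)) norm <- normalization_factors(prot, cutoff = cutoff)
  rt <- residue_table(prot)
  missing_types <- setdiff(unique(rt$res_type), norm$res_type)
  if (length(missing_types) > 0) {
    abort(paste0(
      "No normalization factor for residue type(s): ",
      paste(missing_types, collapse = ", ")
    ))
  }
  cm <- contact_map(prot, cutoff = cutoff, atoms = "sidechain")
  if (exclude_adjacent && nrow(cm) > 0) {
    info <- rt[, c("key", "chain", "seq_id")]
    cm <- cm |>
      left_join(info, by = c(key_i = "key")) |>
      left_join(info, by = c(key_j = "key"), suffix = c("_i", "_j")) |>
      filter(.data$chain_i != .data$chain_j |
        abs(.data$seq_id_i - .data$seq_id_j) > 1) |>
      select("key_i", "key_j", "n_pairs")
  }
  nmap <- stats::setNames(norm$N, norm$res_type)
  tmap <- stats::setNames(rt$res_type, rt$key)
  cm |>
    mutate(I = interaction_strength(
      .data$n_pairs,
      nmap[tmap[.data$key_i]], nmap[tmap[.data$key_j]],
      form = form
    ))
}

#' Build the residue interaction graph
#'
#' Protein nodes are residues; an edge is present iff the interaction
#' strength exceeds `i_min` (percent). Under correlation weighting the edge
#' weight is `w_ij = -log(clamp(|C_ij|, eps, 1 - eps))`, so strongly
#' coupled residues are separated by near-zero network distance; under
#' uniform weighting every edge has weight 1. A bound ligand becomes a
#' single extra node with an edge to every residue having a mean ensemble
#' contact count of at least 1, weighted by the median protein edge weight.
#'
#' @param structure A `kin_structure`; a ligand residue (if any) is added as
#'   a node when `include_ligand` is `TRUE`.
#' @param correlation Labelled correlation matrix covering all protein
#'   residues (required for `weighting = "correlation"`).
#' @param norm Normalization table; defaults to dataset mode on `structure`.
#' @param i_min Edge admission threshold in percent (default 3.0; edges need
#'   `I > i_min`).
#' @param include_ligand Add the ligand node and its contact edges.
#' @param weighting `"correlation"` or `"uniform"`.
#' @param ligand_contacts Optional tibble from [ensemble_ligand_contacts()]
#'   (for ensemble-averaged ligand edges); defaults to single-frame contacts
#'   of `structure`.
#' @param eps Clamp bound for `|C_ij|` before the log.
#' @param cutoff,exclude_adjacent,form Passed to [interaction_strengths()].
#' @return A `kin_graph`: list with `nodes`, `edges`, `i_min`, `weighting`.
#' @export
build_graph <- function(structure, correlation = NULL, norm = NULL,
                        i_min = 3.0, include_ligand = TRUE,
                        weighting = c("correlation", "uniform"),
                        ligand_contacts = NULL, eps = 1e-6, cutoff = 4.5,
                        exclude_adjacent = TRUE, form = c("sqrt", "product")) {
  weighting <- match.arg(weighting)
  form <- match.arg(form)
  if (i_min < 0) abort("i_min must be non-negative")
  if (weighting == "correlation" && is.null(correlation)) {
    abort("weighting = 'correlation' needs a correlation matrix")
  }
  strengths <- interaction_strengths(structure,
    norm = norm, cutoff = cutoff,
    exclude_adjacent = exclude_adjacent, form = form
  )
  edges <- strengths |> filter(.data$I > i_min)
  prot_nodes <- residue_table(structure[!structure$is_ligand, ]) |>
    select("key", "res_type", "is_ligand")
  if (weighting == "correlation") {
    lab <- rownames(correlation)
    miss <- setdiff(prot_nodes$key, lab)
    if (length(miss) > 0) {
      abort(paste0(
        "Correlation matrix missing residue(s): ",
        paste(utils::head(miss, 5), collapse = ", ")
      ))
    }
    cvals <- abs(correlation[cbind(
      match(edges$key_i, lab),
      match(edges$key_j, lab)
    )])
    edges$weight <- -log(pmin(pmax(cvals, eps), 1 - eps))
  } else {
    edges$weight <- rep(1, nrow(edges))
  }
  nodes <- prot_nodes
  lig_res <- residue_table(structure[structure$is_ligand, ])
  if (include_ligand && nrow(lig_res) > 0) {
    if (is.null(ligand_contacts)) {
      ligand_contacts <- ensemble_ligand_contacts(structure, cutoff = cutoff)
    }
    lig_key <- lig_res$key[1]
    touched <- ligand_contacts |> filter(.data$mean_contacts >= 1)
    w_lig <- if (nrow(edges) > 0) stats::median(edges$weight) else 1
    if (nrow(touched) > 0) {
      edges <- bind_rows(edges, tibble(
        key_i = touched$key, key_j = lig_key,
        n_pairs = NA_integer_, I = NA_real_,
        weight = w_lig
      ))
    }
    nodes <- bind_rows(nodes, lig_res[1, c("key", "res_type", "is_ligand")])
  }
  out <- list(
    nodes = nodes, edges = edges, i_min = i_min, weighting = weighting
  )
  class(out) <- "kin_graph"
  out
}

#' Assemble a residue graph directly from an edge table
#'
#' Entry point for hand-built or externally derived interaction strengths:
#' applies the `I > i_min` admission rule and the chosen weighting exactly
#' as [build_graph()] does.
#'
#' @param edges Tibble with `key_i`, `key_j`, `I` (percent) and optionally
#'   `weight` (used as-is when present and `weighting` applies none).
#' @param i_min Admission threshold in percent.
#' @param nodes Optional tibble with `key` (defaults to keys seen in edges).
#' @param weight Uniform edge weight applied when the table has none.
#' @return A `kin_graph`.
#' @export
residue_graph <- function(edges, i_min = 3.0, nodes = NULL, weight = 1) {
  edges <- as_tibble(edges)
  if (!all(c("key_i", "key_j") %in% names(edges))) {
    abort("edges need key_i, key_j")
  }
  if ("I" %in% names(edges)) edges <- edges |> filter(.data$I > i_min)
  if (!"I" %in% names(edges)) edges$I <- NA_real_
  if (!"weight" %in% names(edges)) edges$weight <- weight
  if (!"n_pairs" %in% names(edges)) edges$n_pairs <- NA_integer_
  if (any(edges$weight < 0 | !is.finite(edges$weight))) {
    abort("Edge weights must be non-negative and finite")
  }
  if (is.null(nodes)) {
    nodes <- tibble(
      key = unique(c(edges$key_i, edges$key_j)),
      res_type = NA_character_, is_ligand = FALSE
    )
  } else {
    nodes <- as_tibble(nodes)
    if (!"res_type" %in% names(nodes)) nodes$res_type <- NA_character_
    if (!"is_ligand" %in% names(nodes)) nodes$is_ligand <- FALSE
  }
  out <- list(
    nodes = nodes,
    edges = edges[, c("key_i", "key_j", "n_pairs", "I", "weight")],
    i_min = i_min, weighting = "uniform"
  )
  class(out) <- "kin_graph"
  out
}

#' @export
print.kin_graph <- function(x, ...) {
  cat(sprintf(
    "# kin_graph: %d nodes, %d edges (I_min %.1f%%, %s weighting)\n",
    nrow(x$nodes), nrow(x$edges), x$i_min, x$weighting
  ))
  invisible(x)
}

#' Tidy a residue graph into its edge table
#'
#' @param x A `kin_graph`.
#' @param ... Unused.
#' @return The edge tibble (`key_i`, `key_j`, `n_pairs`, `I`, `weight`).
#' @export
tidy.kin_graph <- function(x, ...) x$edges

#' Glance at a residue graph
#'
#' @param x A `kin_graph`.
#' @param ... Unused.
#' @return One-row tibble: node/edge counts, threshold, component count.
#' @export
glance.kin_graph <- function(x, ...) {
  sp <- shortest_path_counts(x)
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    i_min = x$i_min, weighting = x$weighting,
    n_components = length(unique(sp$component))
  )
}

graph_weight_matrix <- function(graph, weighted = TRUE) {
  keys <- graph$nodes$key
  n <- length(keys)
  W <- matrix(Inf, n, n, dimnames = list(keys, keys))
  diag(W) <- 0
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$key_i, keys)
    j <- match(graph$edges$key_j, keys)
    w <- if (weighted) graph$edges$weight else rep(1, nrow(graph$edges))
    if (any(w < 0)) abort("Negative edge weight")
    W[cbind(i, j)] <- pmin(W[cbind(i, j)], w)
    W[cbind(j, i)] <- W[cbind(i, j)]
  }
  W
}

path_tol <- function(d) 1e-9 * pmax(abs(d), 1)

#' All-pairs shortest paths with multiplicity counts
#'
#' Floyd-Warshall all-pairs distances on the non-negative edge weights,
#' followed by exact counting of co-optimal path multiplicities (paths whose
#' length is within a relative 1e-9 of the minimum count as shortest).
#' Unreachable pairs have infinite distance and zero count.
#'
#' @param graph A `kin_graph`.
#' @param weighted Use edge weights (`TRUE`, default) or topological
#'   unit-length edges.
#' @return List with `dist` (matrix), `counts` (matrix `g_jk`), and
#'   `component` (integer id per node).
#' @export
shortest_path_counts <- function(graph, weighted = TRUE) {
  W <- graph_weight_matrix(graph, weighted)
  n <- nrow(W)
  D <- W
  for (k in seq_len(n)) {
    Dk <- outer(D[, k], D[k, ], "+")
    D <- pmin(D, Dk)
  }
  # count co-optimal paths from each source by increasing distance
  G <- matrix(0, n, n, dimnames = dimnames(W))
  adj <- is.finite(W) & W > 0 | (W == 0 & row(W) != col(W))
  for (s in seq_len(n)) {
    d <- D[s, ]
    ord <- order(d)
    g <- numeric(n)
    g[s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(d[v])) next
      pred <- which(adj[, v] & abs(d + W[, v] - d[v]) <= path_tol(d[v]))
      g[v] <- sum(g[pred])
    }
    G[s, ] <- g
  }
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      comp[is.finite(D[v, ])] <- cid
    }
  }
  list(dist = D, counts = G, component = stats::setNames(comp, rownames(W)))
}

#' Normalized betweenness centrality
#'
#' For each node `i`, sums over unordered pairs `j < k` (both distinct from
#' `i`, in `i`'s connected component) the fraction of co-optimal shortest
#' paths between `j` and `k` that pass through `i`, then divides by
#' `(N - 1)(N - 2) / 2` where `N` is the size of `i`'s component. Values
#' lie in `[0, 1]`; nodes in components of fewer than 3 nodes score 0.
#'
#' @param graph A `kin_graph`.
#' @param weighted Use edge weights (default) or topological paths.
#' @return A `kin_centrality` tibble: `key`, `res_type`, `is_ligand`,
#'   `component`, `betweenness`.
#' @export
betweenness_centrality <- function(graph, weighted = TRUE) {
  sp <- shortest_path_counts(graph, weighted)
  D <- sp$dist
  G <- sp$counts
  comp <- sp$component
  n <- nrow(D)
  cb <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(comp == comp[i])
    N <- length(members)
    if (N < 3) next
    jk <- members[members != i]
    through <- outer(D[jk, i], D[i, jk], "+")
    direct <- D[jk, jk, drop = FALSE]
    on_path <- abs(through - direct) <= path_tol(direct)
    frac <- (outer(G[jk, i], G[i, jk]) / direct_counts(G, jk)) * on_path
    frac[!is.finite(frac)] <- 0
    cb[i] <- sum(frac[upper.tri(frac)]) / ((N - 1) * (N - 2) / 2)
  }
  out <- graph$nodes
  out$component <- unname(comp[match(out$key, names(comp))])
  out$betweenness <- cb
  class(out) <- c("kin_centrality", class(as_tibble(out)))
  out
}

direct_counts <- function(G, jk) {
  g <- G[jk, jk, drop = FALSE]
  g[g == 0] <- Inf # unreachable or self pairs contribute 0 via division
  g
}

#' Ligand-induced centrality change
#'
#' `delta = C_b(holo) - C_b(apo)` on the shared residue keys; the ligand
#' node is excluded from the report.
#'
#' @param apo,holo `kin_centrality` profiles of the same protein without
#'   and with the bound ligand.
#' @return Tibble with `key`, `res_type`, `betweenness_apo`,
#'   `betweenness_holo`, `delta`.
#' @export
delta_centrality <- function(apo, holo) {
  a <- as_tibble(apo) |> filter(!.data$is_ligand)
  h <- as_tibble(holo) |> filter(!.data$is_ligand)
  shared <- intersect(a$key, h$key)
  if (length(shared) == 0) abort("No shared residue keys between profiles")
  inner_join(
    a |> select("key", "res_type", betweenness_apo = "betweenness"),
    h |> select("key", betweenness_holo = "betweenness"),
    by = "key"
  ) |>
    mutate(delta = .data$betweenness_holo - .data$betweenness_apo)
}

#' Joint centrality / B-factor / RSA table
#'
#' One row per residue with its betweenness, computed B-factor and relative
#' solvent accessibility, for centrality-versus-flexibility and
#' centrality-versus-burial scatter analyses. No binning is applied.
#'
#' @param centrality A `kin_centrality`.
#' @param bfactors Tibble from [compute_bfactors()].
#' @param rsa_profile Tibble from [rsa()].
#' @return Tibble with `key`, `res_type`, `betweenness`, `bfactor`, `rsa`;
#'   residues missing from any input are dropped with a warning.
#' @export
joint_profiles <- function(centrality, bfactors, rsa_profile) {
  base <- as_tibble(centrality) |>
    filter(!.data$is_ligand) |>
    select("key", "res_type", "betweenness")
  out <- base |>
    inner_join(bfactors |> select("key", "bfactor"), by = "key") |>
    inner_join(rsa_profile |> select("key", "rsa"), by = "key")
  dropped <- setdiff(base$key, out$key)
  if (length(dropped) > 0) {
    warn(paste0(
      "Dropped residue(s) missing from B-factor/RSA input: ",
      paste(utils::head(dropped, 5), collapse = ", ")
    ))
  }
  out
}

#' Convert a residue graph to igraph
#'
#' @param graph A `kin_graph`.
#' @return An igraph object with `weight` and `I` edge attributes.
#' @export
as_igraph <- function(graph) {
  g <- igraph::graph_from_data_frame(
    graph$edges |> select(from = "key_i", to = "key_j", "weight", "I"),
    directed = FALSE,
    vertices = graph$nodes |> select(name = "key", "res_type", "is_ligand")
  )
  g
}

#' Export a residue graph
#'
#' @param graph A `kin_graph`.
#' @param path Output path; format chosen by extension (`.graphml` or
#'   `.tsv` edge list).
#' @return `path`, invisibly.
#' @export
write_graph_file <- function(graph, path) {
  if (grepl("\\.graphml$", path)) {
    g <- as_igraph(graph)
    igraph::E(g)$I <- ifelse(is.na(igraph::E(g)$I), -1, igraph::E(g)$I)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    readr::write_tsv(graph$edges, path)
  }
  invisible(path)
}
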