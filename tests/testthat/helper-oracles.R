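# Independent oracles used across the suite. These deliberately take the
# slow, obviously-correct route (exhaustive enumeration, two-pass loops,
# direct formula evaluation) so they share no code with the implementation.

# enumerate all simple paths between two nodes of a small weighted graph
# given as an edge tibble; returns the minimal weight and the list of
# minimal-weight paths
enumerate_shortest <- function(nodes, edges, from, to, tol = 1e-9) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    rbind(
      edges[edges$key_i == v, c("key_j", "weight")] |>
        stats::setNames(c("to", "w")),
      edges[edges$key_j == v, c("key_i", "weight")] |>
        stats::setNames(c("to", "w"))
    )
  })
  best <- Inf
  paths <- list()
  walk <- function(v, seen, w, path) {
    if (v == to) {
      if (w < best - tol) {
        best <<- w
        paths <<- list(path)
      } else if (abs(w - best) <= tol * max(1, best)) {
        paths[[length(paths) + 1]] <<- path
      }
      return()
    }
    nb <- adj[[v]]
    for (k in seq_len(nrow(nb))) {
      u <- nb$to[k]
      if (u %in% seen) next
      if (w + nb$w[k] > best + tol * max(1, best)) next
      walk(u, c(seen, u), w + nb$w[k], c(path, u))
    }
  }
  walk(from, from, 0, from)
  # drop paths that ended above the final minimum
  keep <- vapply(paths, function(p) {
    w <- path_weight(edges, p)
    abs(w - best) <= tol * max(1, best)
  }, logical(1))
  list(dist = best, paths = paths[keep])
}

path_weight <- function(edges, path) {
  if (length(path) < 2) return(0)
  sum(vapply(seq_len(length(path) - 1), function(k) {
    a <- path[k]
    b <- path[k + 1]
    hit <- (edges$key_i == a & edges$key_j == b) |
      (edges$key_i == b & edges$key_j == a)
    min(edges$weight[hit])
  }, numeric(1)))
}

# exhaustive normalized betweenness on a small graph (<= 8 nodes)
brute_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  raw <- stats::setNames(numeric(n), nodes)
  reach <- stats::setNames(rep(list(character()), n), nodes)
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      res <- enumerate_shortest(nodes, edges, nodes[a], nodes[b])
      if (!is.finite(res$dist)) next
      reach[[nodes[a]]] <- union(reach[[nodes[a]]], nodes[b])
      reach[[nodes[b]]] <- union(reach[[nodes[b]]], nodes[a])
      g <- length(res$paths)
      for (v in nodes) {
        if (v == nodes[a] || v == nodes[b]) next
        thru <- sum(vapply(res$paths, function(p) v %in% p, logical(1)))
        raw[v] <- raw[v] + thru / g
      }
    }
  }
  vapply(nodes, function(v) {
    N <- length(reach[[v]]) + 1
    if (N < 3) return(0)
    raw[v] / ((N - 1) * (N - 2) / 2)
  }, numeric(1))
}

random_edge_graph <- function(n, seed, p = 0.5, weights = c(0.5, 1, 1.5, 2, 3)) {
  set.seed(seed)
  keys <- paste0("n", seq_len(n))
  pairs <- utils::combn(keys, 2)
  sel <- stats::runif(ncol(pairs)) < p
  if (!any(sel)) sel[1] <- TRUE
  tibble::tibble(
    key_i = pairs[1, sel], key_j = pairs[2, sel],
    I = 100, weight = sample(weights, sum(sel), replace = TRUE)
  )
}

# direct double-loop contact count
brute_contacts <- function(ai, aj, cutoff) {
  cnt <- 0L
  for (p in seq_len(nrow(ai))) {
    for (q in seq_len(nrow(aj))) {
      if (sqrt(sum((ai[p, ] - aj[q, ])^2)) <= cutoff) cnt <- cnt + 1L
    }
  }
  cnt
}

# naive plug-in MI for a two-column alignment (nats)
naive_mi <- function(a, b) {
  ok <- a != "-" & b != "-"
  a <- a[ok]
  b <- b[ok]
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  s <- 0
  for (i in rownames(tab)) {
    for (j in colnames(tab)) {
      p <- tab[i, j]
      if (p > 0) s <- s + p * log(p / (pa[[i]] * pb[[j]]))
    }
  }
  s
}

# small structure builders
atom_row <- function(seq_id, atom, x, y, z, res_type = "LEU", chain = "A",
                     element = NULL, is_ligand = FALSE) {
  tibble::tibble(
    chain = chain, seq_id = as.integer(seq_id), res_type = res_type,
    atom = atom,
    element = if (is.null(element)) substr(atom, 1, 1) else element,
    x = x, y = y, z = z, is_ligand = is_ligand
  )
}
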