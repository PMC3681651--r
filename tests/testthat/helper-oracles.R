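# Brute-force graph oracles, independent of igraph's statistics. They work
# on a plain adjacency matrix and use only base R, so they can arbitrate
# the package's (igraph-backed) implementations.

adj_of <- function(g) {
  if (is(g, "FunctionalGraph")) g <- asIgraph(g)
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# mean local clustering; degree < 2 contributes 0
oracle_clustering <- function(A) {
  n <- nrow(A)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(A[nb, nb]) / (k * (k - 1))
  }, numeric(1)))
}

# all-pairs BFS distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (s in seq_len(n)) {
    frontier <- s; d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] > 0))))
      nxt <- nxt[D[s, nxt] == Inf & nxt != s]
      if (!length(nxt)) break
      D[s, nxt] <- d
      frontier <- nxt
    }
  }
  D
}

# mean shortest path over reachable ordered pairs
oracle_charpath <- function(A) {
  D <- oracle_distances(A)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# betweenness by exhaustive shortest-path enumeration (fractional credit),
# each unordered pair counted once
oracle_betweenness <- function(A) {
  n <- nrow(A)
  D <- oracle_distances(A)
  bt <- numeric(n)
  all_paths <- function(s, t) {
    # enumerate shortest s-t paths by DFS along distance-decreasing edges
    res <- list()
    walk <- function(v, acc) {
      if (v == t) { res[[length(res) + 1L]] <<- acc; return(invisible()) }
      for (w in which(A[v, ] > 0))
        if (is.finite(D[w, t]) && D[w, t] == D[v, t] - 1) walk(w, c(acc, w))
    }
    walk(s, s)
    res
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(D[s, t]) || D[s, t] < 2) next
    paths <- all_paths(s, t)
    for (p in paths) {
      inner <- p[-c(1, length(p))]
      bt[inner] <- bt[inner] + 1 / length(paths)
    }
  }
  bt
}

# modularity of an explicit partition, direct formula
oracle_modularity <- function(A, membership) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  deg <- rowSums(A)
  q <- 0
  for (com in unique(membership)) {
    idx <- membership == com
    ec <- sum(A[idx, idx]) / 2
    dc <- sum(deg[idx])
    q <- q + ec / m - (dc / (2 * m))^2
  }
  q
}

# seeded random test graph (connected-ish, n <= 20 for the oracle battery)
random_test_graph <- function(n, p = 0.25, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  g
}
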