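.as_graph <- function(g) {
  if (is(g, "FunctionalGraph")) return(asIgraph(g))
  if (igraph::is_igraph(g)) return(g)
  stop("expected a FunctionalGraph or an igraph object")
}

#' Mean clustering coefficient
#'
#' Mean over nodes of the binary undirected local clustering coefficient
#' (fraction of closed neighbor pairs); nodes with degree < 2 contribute 0.
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object
#' @return clustering coefficient in [0, 1]
#' @export
clusteringCoefficient <- function(g) {
  g <- .as_graph(g)
  if (igraph::vcount(g) == 0) stop("empty graph")
  lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(lc)
}

#' Characteristic path length
#'
#' Mean shortest-path length over reachable ordered node pairs; unreachable
#' pairs are excluded and their count attached as attribute
#' \code{"unreachablePairs"}.
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object with >= 2 nodes
#' @return mean shortest-path length (>= 1 when any edge exists)
#' @export
characteristicPathLength <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  if (n < 2) stop("need at least 2 nodes")
  d <- igraph::distances(g)
  off <- d[row(d) != col(d)]
  reach <- off[is.finite(off)]
  if (!length(reach)) stop("no reachable node pair")
  structure(mean(reach), unreachablePairs = sum(!is.finite(off)) / 2)
}

#' Degree-preserving randomization
#'
#' Connected double-edge swaps: repeatedly exchanges the endpoints of two
#' random edges, rejecting self-loops and multi-edges, so the degree
#' sequence is exactly preserved while all other structure is destroyed.
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object with >= 2 edges
#' @param iterationsPerEdge swap attempts per edge
#' @param seed RNG seed (the output is reproducible for a fixed seed)
#' @return randomized igraph with identical degree sequence
#' @export
degreePreservingRandomize <- function(g, iterationsPerEdge = 10, seed = 1L) {
  g <- .as_graph(g)
  e <- igraph::ecount(g)
  if (e < 2 || .swaps_impossible(g)) {
    warning("no degree-preserving swap is possible; returning the input")
    return(g)
  }
  withr_seed(seed, igraph::rewire(
    g, igraph::keeping_degseq(niter = ceiling(iterationsPerEdge * e))))
}

# star-like graphs admit no double-edge swap: every edge shares a vertex
.swaps_impossible <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) < 2) return(TRUE)
  common <- intersect(el[1, ], el[2, ])
  for (v in common) if (all(el[, 1] == v | el[, 2] == v)) return(TRUE)
  FALSE
}

#' Degree-preserving latticization
#'
#' Double-edge swaps accepted only when they do not increase the total ring
#' distance of the rewired edges (nodes on a ring in index order, distance
#' min(|i-j|, n-|i-j|)), driving the graph toward a banded ring-lattice
#' ordering while preserving the degree sequence exactly.
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object with >= 2 edges
#' @param iterationsPerEdge swap attempts per edge
#' @param seed RNG seed
#' @return latticized igraph with identical degree sequence
#' @export
latticize <- function(g, iterationsPerEdge = 10, seed = 1L) {
  g0 <- .as_graph(g)
  ne <- igraph::ecount(g0)
  if (ne < 2 || .swaps_impossible(g0)) {
    warning("no degree-preserving swap is possible; returning the input")
    return(g0)
  }
  n <- igraph::vcount(g0)
  el <- igraph::as_edgelist(g0, names = FALSE)
  adj <- matrix(FALSE, n, n)
  adj[el] <- TRUE; adj[el[, 2:1, drop = FALSE]] <- TRUE
  ringd <- function(i, j) { k <- abs(i - j); pmin(k, n - k) }
  withr_seed(seed, {
    for (it in seq_len(ceiling(iterationsPerEdge * ne))) {
      pick <- sample.int(ne, 2)
      a <- el[pick[1], 1]; b <- el[pick[1], 2]
      c_ <- el[pick[2], 1]; d <- el[pick[2], 2]
      if (length(unique(c(a, b, c_, d))) < 4) next
      # candidate rewiring (a-d, c-b); flip one edge orientation half the time
      if (runif(1) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
      if (adj[a, d] || adj[c_, b]) next
      # Pareto acceptance: neither rewired edge may get longer and at least
      # one must get strictly shorter. A plain total-cost rule would trade
      # a big shortening of one edge against lengthening an already-short
      # edge, eroding the band structure it is meant to build.
      dab <- ringd(a, b); dcd <- ringd(c_, d)
      dad <- ringd(a, d); dcb <- ringd(c_, b)
      if (dad <= dab && dcb <= dcd && (dad < dab || dcb < dcd)) {
        adj[a, b] <- adj[b, a] <- FALSE
        adj[c_, d] <- adj[d, c_] <- FALSE
        adj[a, d] <- adj[d, a] <- TRUE
        adj[c_, b] <- adj[b, c_] <- TRUE
        el[pick[1], ] <- c(a, d)
        el[pick[2], ] <- c(c_, b)
      }
    }
  })
  out <- igraph::graph_from_edgelist(el, directed = FALSE)
  if (igraph::vcount(out) < n) out <- igraph::add_vertices(out, n - igraph::vcount(out))
  for (at in igraph::vertex_attr_names(g0))
    out <- igraph::set_vertex_attr(out, at, value = igraph::vertex_attr(g0, at))
  out
}

#' Small-worldness report
#'
#' Computes C and L for the graph, their means over \code{nNull}
#' degree-preserving randomized nulls (C_rand, L_rand) and latticized nulls
#' (C_latt), and the two small-worldness indices
#' \deqn{S = (C/C_{rand}) / (L/L_{rand})}{S = (C/C_rand)/(L/L_rand)}
#' \deqn{\omega = L_{rand}/L - C/C_{latt}}{omega = L_rand/L - C/C_latt}
#' S well above 1 indicates small-world structure; omega near 0 is
#' small-world, near -1 lattice-like, near +1 random-like.
#'
#' Bit-reproducible for a fixed seed.
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object
#' @param nNull number of null realizations per null type
#' @param iterationsPerEdge swap attempts per edge in the null generators
#' @param seed RNG seed
#' @return a \linkS4class{SmallWorldReport}
#' @export
smallWorldness <- function(g, nNull = 10L, iterationsPerEdge = 10, seed = 1L) {
  gg <- .as_graph(g)
  C <- clusteringCoefficient(gg)
  L <- as.numeric(characteristicPathLength(gg))
  crand <- lrand <- clatt <- numeric(nNull)
  for (i in seq_len(nNull)) {
    gr <- suppressWarnings(
      degreePreservingRandomize(gg, iterationsPerEdge, seed = seed + i))
    gl <- suppressWarnings(latticize(gg, iterationsPerEdge, seed = seed + i))
    crand[i] <- clusteringCoefficient(gr)
    lrand[i] <- as.numeric(characteristicPathLength(gr))
    clatt[i] <- clusteringCoefficient(gl)
  }
  Crand <- mean(crand); Lrand <- mean(lrand); Clatt <- mean(clatt)
  S <- (C / Crand) / (L / Lrand)
  omega <- Lrand / L - C / Clatt
  new(Class = "SmallWorldReport", nodes = as.integer(igraph::vcount(gg)),
      edges = as.integer(igraph::ecount(gg)), C = C, L = L, Crand = Crand,
      Lrand = Lrand, Clatt = Clatt, S = S, omega = omega,
      nNull = as.integer(nNull), seed = as.integer(seed))
}

#' Betweenness centrality
#'
#' Shortest-path betweenness with fractional credit for equal-length paths;
#' unnormalized pair counts (each unordered pair counted once).
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object
#' @return named numeric vector, one value per node
#' @export
betweennessCentrality <- function(g) {
  g <- .as_graph(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  if (is.null(names(b)) && !is.null(igraph::V(g)$name)) names(b) <- igraph::V(g)$name
  b
}

#' Community structure by greedy modularity maximization
#'
#' Fast-greedy agglomeration; returns the partition and its modularity Q.
#' An edgeless graph yields the singleton partition with Q = 0.
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object
#' @return list with \code{membership} (integer community per node) and
#'   \code{Q} (modularity of the returned partition)
#' @export
detectCommunities <- function(g) {
  g <- .as_graph(g)
  n <- igraph::vcount(g)
  if (igraph::ecount(g) == 0)
    return(list(membership = setNames(seq_len(n), igraph::V(g)$name), Q = 0))
  cm <- igraph::cluster_fast_greedy(igraph::simplify(g))
  list(membership = igraph::membership(cm),
       Q = igraph::modularity(g, igraph::membership(cm)))
}

#' Modularity of an explicit partition
#'
#' @param g a \linkS4class{FunctionalGraph} or igraph object
#' @param membership community id per node
#' @return modularity Q
#' @export
partitionModularity <- function(g, membership) {
  igraph::modularity(.as_graph(g), membership)
}
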