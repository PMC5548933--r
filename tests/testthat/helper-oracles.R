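# Independent oracles and shared toy networks for the test suite.

# Exact chromatic number by backtracking; feasible for n <= 8.
oracle_chromatic <- function(adj) {
  n <- nrow(adj)
  if (n == 0) return(0L)
  if (!any(adj)) return(1L)
  feasible <- function(k) {
    color <- integer(n)
    assign_node <- function(v) {
      if (v > n) return(TRUE)
      for (c in seq_len(k)) {
        ok <- TRUE
        for (u in seq_len(v - 1)) {
          if (adj[u, v] && color[u] == c) { ok <- FALSE; break }
        }
        if (ok) {
          color[v] <<- c
          if (assign_node(v + 1)) return(TRUE)
          color[v] <<- 0L
        }
      }
      FALSE
    }
    assign_node(1)
  }
  for (k in 1:n) if (feasible(k)) return(k)
  n
}

# Floyd-Warshall all-pairs shortest paths from a weighted igraph.
oracle_floyd_warshall <- function(net, p = 1) {
  n <- igraph::vcount(net)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight^p
  for (e in seq_len(nrow(el))) {
    i <- el[e, 1]; j <- el[e, 2]
    D[i, j] <- min(D[i, j], w[e])
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# Population Pearson moment skewness of a numeric vector.
oracle_skewness <- function(x) {
  mu <- mean(x)
  mean((x - mu)^3) / mean((x - mu)^2)^1.5
}

weighted_graph <- function(edges) {
  # edges: matrix/data.frame with columns from, to, weight (integer node ids)
  edges <- as.data.frame(edges)
  names(edges) <- c("from", "to", "weight")
  n <- max(edges$from, edges$to)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  igraph::E(g)$weight <- edges$weight
  igraph::V(g)$name <- as.character(seq_len(n))
  g
}

# Small connected weighted toys (<= 8 nodes) for exhaustive-coloring checks.
toy_networks <- function() {
  set.seed(404)
  toys <- list(
    path4 = weighted_graph(cbind(1:3, 2:4, c(0.5, 0.25, 1))),
    cycle5 = weighted_graph(cbind(1:5, c(2:5, 1), c(1, 1, 2, 0.5, 0.75))),
    star6 = weighted_graph(cbind(rep(1, 5), 2:6, c(1, 1, 0.5, 2, 1))),
    k4 = weighted_graph(cbind(c(1, 1, 1, 2, 2, 3), c(2, 3, 4, 3, 4, 4),
                              c(1, 2, 1, 1, 3, 1))),
    two_triangles = weighted_graph(cbind(c(1, 2, 1, 4, 5, 4, 3),
                                         c(2, 3, 3, 5, 6, 6, 4),
                                         c(1, 1, 1, 0.5, 0.5, 0.5, 2)))
  )
  g <- igraph::sample_gnp(8, 0.5)
  while (!igraph::is_connected(g)) g <- igraph::sample_gnp(8, 0.5)
  igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g), 0.2, 2), 2)
  igraph::V(g)$name <- as.character(1:8)
  toys$random8 <- g
  toys
}

sierpinski_truth <- log(3) / log(2) # b = 3, s = 1/2
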