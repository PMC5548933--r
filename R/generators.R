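#' Weighted Sierpinski fractal network
#'
#' Deterministic generator for the weighted Sierpinski family: the
#' genealogy network of a self-similar iterated function system with copy
#' factor `b` and contraction `s`. Construction level 1 is a ring of `b`
#' unit-weight edges over `b` nodes (a single edge when `b = 2`); at each
#' later level j every level-(j-1) node spawns `b` children, each attached
#' to its parent by one edge of weight s^(j-1). Generation k therefore has
#' b + b^2 + ... + b^k = b (b^k - 1)/(b - 1) nodes, the multiset of edge
#' weights is exactly \{s^0, ..., s^(k-1)\} with level counts growing
#' geometrically with ratio `b`, and the metric is hierarchically
#' self-similar: the subnetwork hanging off any level-j node is an s-scaled
#' image of the one hanging off a level-(j-1) node. The family's
#' theoretical fractal dimension is ln(b) / ln(1/s).
#'
#' The deeper the level, the more numerous and the lighter the edges, so
#' the link-weight distribution becomes strongly right-skewed as `s`
#' decreases or `b` grows — the regime where growth rules that ignore the
#' weight distribution mis-estimate the dimension.
#'
#' @param b copy factor, integer >= 2.
#' @param s scaling factor in (0, 1).
#' @param k generation, integer >= 1.
#' @param seed ignored; present for generator API uniformity (the
#'   construction is deterministic).
#' @return a weighted \code{igraph} network with `b (b^k - 1)/(b - 1)` nodes.
#' @examples
#' g3 <- sierpinski_network(b = 3, s = 1/2, k = 3)
#' igraph::vcount(g3)  # 39
#' @export
sierpinski_network <- function(b, s, k, seed = NULL) {
  if (length(b) != 1 || b < 2 || b != round(b)) {
    stop("`b` must be an integer >= 2")
  }
  if (length(s) != 1 || !is.finite(s) || s <= 0 || s >= 1) {
    stop("`s` must lie in (0, 1)")
  }
  if (length(k) != 1 || k < 1 || k != round(k)) {
    stop("`k` must be an integer >= 1")
  }
  b <- as.integer(b)
  k <- as.integer(k)
  # level 1: ring of b nodes, unit weights (single edge when b = 2)
  if (b == 2) {
    from <- 1L; to <- 2L
  } else {
    from <- seq_len(b)
    to <- c(seq_len(b)[-1], 1L)
  }
  w <- rep(1, length(from))
  n <- b
  level_nodes <- seq_len(b)
  if (k > 1) {
    for (lev in 2:k) {
      children <- n + seq_len(b * length(level_nodes))
      parents <- rep(level_nodes, each = b)
      from <- c(from, parents)
      to <- c(to, children)
      w <- c(w, rep(s^(lev - 1), length(children)))
      n <- n + length(children)
      level_nodes <- children
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to))
  igraph::E(g)$weight <- w
  igraph::V(g)$name <- as.character(seq_len(n))
  g$name <- sprintf("sierpinski(b=%d, s=%g, k=%d)", b, s, k)
  g
}

#' (u,v)-flower fractal network
#'
#' Generation 1 is a cycle of u + v nodes. Each later generation replaces
#' every edge (a, b) by two parallel paths of u and v edges between a and
#' b. All weights are 1. The edge count is (u+v)^g; the fractal dimension
#' ln(u+v)/ln(u) exists only for u > 1 (u = 1 gives a small-world family).
#'
#' @param u integer >= 1.
#' @param v integer >= u.
#' @param generation integer >= 1.
#' @return a weighted \code{igraph} network with unit weights.
#' @export
flower_network <- function(u, v, generation = 1) {
  if (length(u) != 1 || u < 1 || u != round(u)) stop("`u` must be an integer >= 1")
  if (length(v) != 1 || v < u || v != round(v)) stop("`v` must be an integer >= u")
  if (length(generation) != 1 || generation < 1 || generation != round(generation)) {
    stop("`generation` must be an integer >= 1")
  }
  u <- as.integer(u); v <- as.integer(v)
  n <- u + v
  from <- seq_len(n)
  to <- c(seq_len(n)[-1], 1L)
  for (gen in seq_len(generation - 1)) {
    nf <- integer(0)
    nt <- integer(0)
    for (e in seq_along(from)) {
      a <- from[e]; z <- to[e]
      # path of u edges
      if (u == 1) {
        nf <- c(nf, a); nt <- c(nt, z)
      } else {
        mid <- n + seq_len(u - 1)
        n <- n + u - 1L
        chain <- c(a, mid, z)
        nf <- c(nf, chain[-length(chain)])
        nt <- c(nt, chain[-1])
      }
      # path of v edges
      mid <- n + seq_len(v - 1)
      n <- n + v - 1L
      chain <- c(a, mid, z)
      nf <- c(nf, chain[-length(chain)])
      nt <- c(nt, chain[-1])
    }
    from <- nf; to <- nt
  }
  key <- paste(pmin(from, to), pmax(from, to))
  keep <- !duplicated(key)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(from[keep], to[keep]))
  igraph::E(g)$weight <- 1
  igraph::V(g)$name <- as.character(seq_len(n))
  g$name <- sprintf("flower(u=%d, v=%d, gen=%d)", u, v, generation)
  g
}

#' Theoretical fractal dimension of a generator family
#'
#' For the weighted Sierpinski family the dimension is ln(b)/ln(1/s); for
#' the (u,v)-flower it is ln(u+v)/ln(u). Supply either `(b, s)` or
#' `(u, v)`. A (1,v)-flower is small-world and has no finite fractal
#' dimension, so `u = 1` is a domain error.
#'
#' @param b,s Sierpinski copy and scaling factors.
#' @param u,v flower path lengths.
#' @return the theoretical dimension, a positive real.
#' @examples
#' theoretical_dimension(b = 3, s = 1/2)  # 1.585
#' theoretical_dimension(u = 3, v = 3)    # 1.631
#' @export
theoretical_dimension <- function(b = NULL, s = NULL, u = NULL, v = NULL) {
  if (!is.null(b) && !is.null(s)) {
    if (b < 2 || b != round(b)) stop("`b` must be an integer >= 2")
    if (s <= 0 || s >= 1) stop("`s` must lie in (0, 1)")
    return(log(b) / log(1 / s))
  }
  if (!is.null(u) && !is.null(v)) {
    if (u < 1 || u != round(u)) stop("`u` must be an integer >= 1")
    if (v < u || v != round(v)) stop("`v` must be an integer >= u")
    if (u == 1) {
      stop("a (1,v)-flower is small-world: no finite fractal dimension")
    }
    return(log(u + v) / log(u))
  }
  stop("supply either (b, s) for Sierpinski or (u, v) for a flower")
}
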