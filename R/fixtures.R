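#' Deterministic synthetic test fixtures
#'
#' Seeded generators for the structures used throughout the test suite,
#' each annotated with its ground truth:
#'
#' \describe{
#'   \item{`staircase_series`}{the linear relation y = 50 - 0.4 x sampled
#'     at x = 1..30, with runs of stagnant y observations inserted at
#'     configurable positions; truth: slope -0.4, staircase positions.}
#'   \item{`two_regime_series`}{a noise-free piecewise log-log series with
#'     slope -1.6 over the first 8 points and slope 0 over the next 6;
#'     truth: breakpoint index.}
#'   \item{`planted_two_env`}{two Sierpinski generation-3 blocks built with
#'     different scaling factors, joined by a single unit-weight edge;
#'     truth: block membership per node.}
#'   \item{`toy_bipartite`}{a random paper-author incidence (20 papers, 10
#'     authors) for the co-authorship weight rule.}
#' }
#'
#' @param name fixture name.
#' @param seed RNG seed.
#' @param stair_positions for `staircase_series`: x positions after which
#'   stagnant runs are inserted.
#' @param stair_width number of stagnant observations per staircase.
#' @return a list with the fixture data and its ground-truth annotations.
#' @export
make_fixture <- function(name = c("staircase_series", "two_regime_series",
                                  "planted_two_env", "toy_bipartite"),
                         seed = 1L, stair_positions = c(8, 20),
                         stair_width = 3L) {
  name <- match.arg(name)
  set.seed(as.integer(seed %% .Machine$integer.max))
  switch(name,
    staircase_series = {
      x <- 1:30
      y <- 50 - 0.4 * x
      for (pos in sort(stair_positions, decreasing = TRUE)) {
        i <- which(x == pos)
        if (length(i) != 1) next
        gap <- (x[i + 1] - x[i]) / (stair_width + 1)
        x_new <- x[i] + gap * seq_len(stair_width)
        x <- append(x, x_new, after = i)
        y <- append(y, rep(y[i], stair_width), after = i)
      }
      list(x = x, y = y, true_slope = -0.4, true_intercept = 50,
           stair_positions = stair_positions, stair_width = stair_width)
    },
    two_regime_series = {
      log_l <- seq(-3, 0.5, length.out = 14)
      log_M <- c(-1.6 * log_l[1:8] + 2, rep(-1.6 * log_l[8] + 2, 6))
      list(log_l = log_l, log_M = log_M, breakpoint = 8L,
           true_slopes = c(-1.6, 0))
    },
    planted_two_env = {
      g1 <- sierpinski_network(b = 3, s = 0.5, k = 3)
      g2 <- sierpinski_network(b = 3, s = 0.9, k = 3)
      n1 <- igraph::vcount(g1)
      igraph::V(g1)$name <- paste0("a", seq_len(n1))
      igraph::V(g2)$name <- paste0("b", seq_len(igraph::vcount(g2)))
      g <- igraph::disjoint_union(g1, g2)
      g <- igraph::add_edges(g, c(1, n1 + 1), attr = list(weight = 1))
      truth <- c(rep(1L, n1), rep(2L, igraph::vcount(g2)))
      list(network = as_weighted_network(g), labels = truth)
    },
    toy_bipartite = {
      n_papers <- 20L
      authors <- paste0("A", 1:10)
      memberships <- lapply(seq_len(n_papers), function(k) {
        sample(authors, sample(2:4, 1))
      })
      list(memberships = memberships, authors = authors)
    }
  )
}
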