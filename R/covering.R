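#' Dual graph of a network at a scale
#'
#' The dual graph at scale l connects every pair of nodes at distance
#' >= l; a proper coloring of the dual is exactly a partition into boxes
#' whose members are pairwise closer than l. Box-covering therefore
#' reduces to (NP-hard) minimum coloring of the dual, approximated here
#' greedily.
#'
#' @param D distance matrix.
#' @param l box scale (> 0).
#' @param tol distance comparison tolerance.
#' @return logical adjacency matrix of the dual graph.
#' @export
dual_graph <- function(D, l, tol = 1e-9) {
  if (l <= 0) stop("`l` must be > 0")
  A <- D >= l - tol
  diag(A) <- FALSE
  A
}

#' Box-covering by greedy coloring of the dual graph
#'
#' Runs `trials` greedy colorings of the dual graph at scale `l`:
#' Welsh-Powell orders (descending dual degree, ties broken by a seeded
#' shuffle) alternating with fully random node orders. Returns the
#' covering with the fewest boxes; per-trial box counts are retained so
#' callers can average instead of taking the minimum.
#'
#' @param D distance matrix.
#' @param l box scale.
#' @param trials number of coloring trials (>= 1).
#' @param seed RNG seed for order randomization.
#' @param tol distance comparison tolerance.
#' @return an object of class `box_covering`: scale, node-to-box
#'   assignment, box masses, measures mu_i = M_i / M_0, best box count and
#'   the per-trial counts.
#' @export
box_cover <- function(D, l, trials = 100, seed = 1L, tol = 1e-9) {
  if (trials < 1) stop("`trials` must be >= 1")
  n <- nrow(D)
  if (l > max(D) + tol) {
    assignment <- rep(1L, n)
    res <- list(counts = rep(1L, trials), assignment = assignment, n_boxes = 1L)
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    deg <- rowSums(D >= l - tol) # dual degrees (diagonal is 0 < l)
    orders <- matrix(0L, n, trials)
    for (t in seq_len(trials)) {
      if (t %% 2 == 1) {
        orders[, t] <- order(-deg, sample.int(n)) # Welsh-Powell, shuffled ties
      } else {
        orders[, t] <- sample.int(n)
      }
    }
    res <- greedy_box_cover(D, l, orders, tol)
  }
  masses <- as.integer(tabulate(res$assignment, nbins = res$n_boxes))
  structure(list(
    l = l,
    assignment = res$assignment,
    masses = masses,
    total_mass = n,
    measures = masses / n,
    n_boxes = res$n_boxes,
    trial_counts = as.integer(res$counts)
  ), class = "box_covering")
}

#' @export
print.box_covering <- function(x, ...) {
  cat(sprintf("Box covering at scale l = %g: %d boxes over %d nodes (mean over %d trials: %.2f)\n",
              x$l, x$n_boxes, x$total_mass, length(x$trial_counts),
              mean(x$trial_counts)))
  invisible(x)
}

#' Partition function of a box covering
#'
#' Sum over non-empty boxes of mu_i^q, whose scaling with (l/L) defines
#' the mass exponent tau(q). At q = 0 it is the number of boxes; at q = 1
#' it is 1 by normalization.
#'
#' @param cov a `box_covering`.
#' @param q distortion exponent.
#' @return the partition function value.
#' @export
partition_function <- function(cov, q) {
  stopifnot(inherits(cov, "box_covering"))
  sum(cov$measures^q)
}

#' Sandbox count around a center
#'
#' Counts the nodes other than the center whose distance to the center is
#' at most l (Heaviside convention H(0) = 1, so a node exactly at distance
#' l is inside). The measure is count / M_0, with the center excluded from
#' the count.
#'
#' @param D distance matrix.
#' @param center node index (1-based).
#' @param l sandbox radius.
#' @param tol comparison tolerance.
#' @param include_center count the center itself (used by the localized
#'   scaling features where log-counts must stay finite).
#' @return list with `center`, `l`, `count`, `measure`.
#' @export
sandbox_count <- function(D, center, l, tol = 1e-9, include_center = FALSE) {
  n <- nrow(D)
  if (center < 1 || center > n) stop("`center` out of range")
  cnt <- sum(D[, center] <= l + tol) - 1L # self-distance 0 always counted
  if (include_center) cnt <- cnt + 1L
  list(center = center, l = l, count = as.integer(cnt), measure = cnt / n)
}

#' Sandbox moment over a set of centers
#'
#' Mean over centers of (M_i(l) / M_0)^(q - 1): the randomized-center
#' estimate whose scaling with (l/L) gives tau(q). Centers with zero
#' count are excluded when q < 1 (their contribution would be infinite);
#' if every center has zero count the moment is undefined.
#'
#' @param D distance matrix.
#' @param l sandbox radius.
#' @param q distortion exponent.
#' @param centers node indices (caller supplies the seeded random sample).
#' @param tol comparison tolerance.
#' @return the moment estimate.
#' @export
sandbox_moment <- function(D, l, q, centers, tol = 1e-9) {
  n <- nrow(D)
  cnt <- vapply(centers, function(i) sum(D[, i] <= l + tol) - 1L, numeric(1))
  if (q < 1) {
    nz <- cnt > 0
    if (!any(nz)) {
      stop(sprintf("sandbox moment undefined at l = %g: all centers have zero count", l))
    }
    if (!all(nz)) {
      warning(sprintf("excluding %d zero-count sandbox(es) at l = %g (q < 1)",
                      sum(!nz), l))
    }
    cnt <- cnt[nz]
  }
  mean((cnt / n)^(q - 1))
}

#' Distribution of box measures across scales
#'
#' Diagnostic view of how the probability measure over the boxes shifts
#' from near-uniform at small scales to peaked at large scales, the
#' signature of structural heterogeneity behind multi-fractal scaling.
#'
#' @param net a weighted network.
#' @param scales scales at which to cover; defaults to the resampled
#'   unique-distance support.
#' @param trials,seed covering parameters.
#' @param max_scales cap on the default scale set.
#' @return a list (one entry per scale) of sorted measure vectors with
#'   attributes `n_boxes` and `max_measure`.
#' @export
measure_distribution <- function(net, scales = NULL, trials = 50, seed = 1L,
                                 max_scales = 30L) {
  D <- network_distances(net)
  if (is.null(scales)) {
    scales <- resample_scales(unique_distance_scales(D), max_scales)
  }
  out <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    cov <- box_cover(D, scales[i], trials = trials, seed = seed + i)
    mu <- sort(cov$measures)
    attr(mu, "n_boxes") <- cov$n_boxes
    attr(mu, "max_measure") <- max(mu)
    out[[i]] <- mu
  }
  names(out) <- signif(scales, 6)
  out
}
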