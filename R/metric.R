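#' All-pairs shortest-path distances
#'
#' Computes the full distance matrix d_ij = min over paths of the sum of
#' w^p along the path (p = 1 gives plain weighted shortest paths). igraph
#' chooses Dijkstra from every source for sparse non-negative graphs,
#' which is the recommended regime for desk-scale networks. Disconnected
#' inputs are rejected: every downstream scaling quantity assumes a
#' connected support.
#'
#' @param net a weighted network.
#' @param p exponent applied to each weight before summation (> 0).
#' @return a symmetric numeric matrix with zero diagonal.
#' @export
network_distances <- function(net, p = 1) {
  if (length(p) != 1 || !is.finite(p) || p <= 0) stop("`p` must be > 0")
  net <- as_weighted_network(net, require_connected = TRUE)
  D <- igraph::distances(net, weights = igraph::E(net)$weight^p)
  unname(D)
}

#' Diameter of a distance matrix
#' @param D a distance matrix.
#' @return the largest finite entry.
#' @export
network_diameter <- function(D) {
  max(D[is.finite(D)])
}

#' Unique shortest-path distances (the network's scale support)
#'
#' The strictly ordered unique distance sequence is the discrete support
#' of the shortest-path distribution, i.e. the only scales at which any
#' covering measure can change: the network has finite resolution. It is
#' the tentative growth rule of the corrected estimators. Values closer
#' than `tol` are merged to absorb floating-point path-sum noise.
#'
#' @param D a distance matrix.
#' @param tol absolute deduplication tolerance.
#' @return a strictly increasing numeric vector ending at the diameter,
#'   with attribute `provenance = "unique-distance"`.
#' @export
unique_distance_scales <- function(D, tol = 1e-9) {
  v <- D[upper.tri(D)]
  if (any(!is.finite(v))) stop("distance matrix contains non-finite entries")
  v <- sort(v[v > 0])
  if (length(v) == 0) stop("no positive distances")
  keep <- c(TRUE, diff(v) > tol)
  out <- v[keep]
  attr(out, "provenance") <- "unique-distance"
  out
}

#' Thin a scale sequence to a manageable size
#'
#' When the unique-distance support is large, downstream covering cost is
#' capped by linear index resampling: elements at uniformly spaced index
#' positions, always retaining the first and last scale.
#'
#' @param scales strictly increasing scale sequence.
#' @param max_count maximum number of scales to keep (>= 2).
#' @return a subset of `scales`, still strictly increasing.
#' @export
resample_scales <- function(scales, max_count) {
  if (max_count < 2) stop("`max_count` must be >= 2")
  n <- length(scales)
  if (n <= max_count) return(scales)
  idx <- unique(round(seq(1, n, length.out = max_count)))
  out <- scales[idx]
  attr(out, "provenance") <- attr(scales, "provenance")
  out
}

#' Linear box-size growth rule
#'
#' Arithmetic scale sequence l_min, l_min + step, ... This rule is
#' generally incompatible with a weighted network's discrete distance
#' support and is provided to demonstrate the staircase effect it causes.
#'
#' @param l_min,l_max range endpoints (l_min < l_max).
#' @param step positive increment.
#' @return increasing numeric vector tagged `provenance = "linear"`.
#' @export
linear_scales <- function(l_min, l_max, step) {
  if (step <= 0) stop("`step` must be > 0")
  if (l_min >= l_max) stop("`l_min` must be < `l_max`")
  out <- seq(l_min, l_max, by = step)
  attr(out, "provenance") <- "linear"
  out
}

#' Weight-accumulation growth rule
#'
#' Prefix sums of the ascending-sorted edge weights: the scale rule used
#' by the uncorrected baselines (BCANw / SBw). Optionally truncated at the
#' first prefix sum at or beyond `l_max` (typically the network diameter),
#' past which every covering is a single box.
#'
#' @param net a weighted network.
#' @param l_max optional truncation point.
#' @param tol deduplication tolerance.
#' @return increasing numeric vector tagged `provenance = "weight-accumulation"`.
#' @export
weight_accumulation_scales <- function(net, l_max = NULL, tol = 1e-9) {
  net <- as_weighted_network(net)
  w <- sort(igraph::E(net)$weight)
  if (length(w) == 0) stop("network has no edges")
  cs <- cumsum(w)
  keep <- c(TRUE, diff(cs) > tol)
  cs <- cs[keep]
  if (!is.null(l_max)) {
    stop_at <- which(cs >= l_max - tol)
    if (length(stop_at) > 0) cs <- cs[seq_len(stop_at[1])]
  }
  attr(cs, "provenance") <- "weight-accumulation"
  cs
}

#' Pearson moment skewness of the link-weight distribution
#'
#' gamma = E[(X - mu)^3] / E[(X - mu)^2]^(3/2) over the multiset of edge
#' weights, using population (biased) moments. The skewness of the weight
#' distribution governs how wide the staircases of an incompatible growth
#' rule become, hence how badly uncorrected estimators underestimate.
#'
#' @param net a weighted network.
#' @return the skewness coefficient.
#' @export
weight_skewness <- function(net) {
  net <- as_weighted_network(net)
  w <- igraph::E(net)$weight
  if (length(w) < 2) stop("need at least 2 edges")
  mu <- mean(w)
  m2 <- mean((w - mu)^2)
  if (m2 <= 0) stop("skewness undefined: all weights identical")
  mean((w - mu)^3) / m2^1.5
}
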