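#' Localized scaling feature vectors
#'
#' For every node, the sandbox count around it is evaluated on a shared
#' geometric grid of radii spanning the smallest positive distance up to
#' the network diameter; the feature vector is the log count at each grid
#' point, paired with the common log normalized radius log(l/L). Nodes in
#' the same automorphism orbit get identical features, since the vector
#' depends only on the node's distance profile. The center is included in
#' the count so the log is finite at every grid scale.
#'
#' @param net a connected weighted network.
#' @param grid_size number of grid radii (>= 4).
#' @param p path metric exponent.
#' @return an object of class `node_scaling_features`: `log_counts`
#'   (nodes x grid matrix), `log_scale` (shared log(l/L) coordinates),
#'   `scales`, `diameter`.
#' @export
node_scaling_features <- function(net, grid_size = 24L, p = 1) {
  if (grid_size < 4) stop("`grid_size` must be >= 4")
  net <- as_weighted_network(net, require_connected = TRUE)
  D <- network_distances(net, p = p)
  L <- network_diameter(D)
  dmin <- min(D[D > 0])
  scales <- exp(seq(log(dmin), log(L), length.out = grid_size))
  counts <- sandbox_counts_all(D, scales, 1e-9) + 1L # center included
  structure(list(
    log_counts = log(counts),
    log_scale = log(scales / L),
    scales = scales,
    diameter = L,
    nodes = node_label(net, seq_len(nrow(D)))
  ), class = "node_scaling_features")
}

#' @export
print.node_scaling_features <- function(x, ...) {
  cat(sprintf("Localized scaling features: %d nodes x %d grid scales (diameter %.4g)\n",
              nrow(x$log_counts), ncol(x$log_counts), x$diameter))
  invisible(x)
}

#' Label-free community detection from scaling features
#'
#' Clusters the localized scaling feature space with k-means, choosing the
#' number of communities by the elbow of the within-cluster dispersion
#' curve (largest second forward difference, ties to the smaller k).
#' Nodes with similar scaling environments are grouped together even when
#' they are not topological neighbours. Features are standardized per
#' coordinate before clustering.
#'
#' @param features a `node_scaling_features` object (or a plain numeric
#'   matrix of node features).
#' @param k_max largest candidate community count (>= 2).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart restarts per candidate k.
#' @return an object of class `community_result`: `labels` (1-based,
#'   named by node), `k`, `dispersion` (total within-cluster sum of
#'   squares per candidate k).
#' @export
detect_communities <- function(features, k_max = 8L, seed = 1L, nstart = 10L) {
  X <- if (inherits(features, "node_scaling_features")) {
    features$log_counts
  } else {
    as.matrix(features)
  }
  nodes <- if (inherits(features, "node_scaling_features")) {
    features$nodes
  } else {
    rownames(X)
  }
  n <- nrow(X)
  if (k_max < 2) stop("`k_max` must be >= 2")
  if (n < k_max + 1) stop("need at least `k_max` + 1 nodes")

  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("all nodes have identical features; returning a single community")
    labels <- rep(1L, n)
    names(labels) <- nodes
    return(structure(list(labels = labels, k = 1L,
                          dispersion = rep(0, k_max)),
                     class = "community_result"))
  }
  Z <- scale(X[, keep, drop = FALSE])

  set.seed(as.integer(seed %% .Machine$integer.max))
  k_eff <- min(k_max, nrow(unique(Z))) # k-means needs distinct centers
  wss <- numeric(k_eff)
  fits <- vector("list", k_eff)
  for (k in seq_len(k_eff)) {
    km <- suppressWarnings(
      stats::kmeans(Z, centers = k, nstart = nstart, iter.max = 50)
    )
    wss[k] <- km$tot.withinss
    fits[[k]] <- km
  }
  # elbow: largest second forward difference of the dispersion curve
  if (k_eff >= 3) {
    d2 <- wss[1:(k_eff - 2)] - 2 * wss[2:(k_eff - 1)] + wss[3:k_eff]
    k_best <- which.max(d2) + 1L
  } else {
    k_best <- k_eff
  }
  labels <- fits[[k_best]]$cluster
  names(labels) <- nodes
  structure(list(labels = labels, k = k_best, dispersion = wss),
            class = "community_result")
}

#' @export
print.community_result <- function(x, ...) {
  cat(sprintf("Scaling-feature communities: k = %d over %d nodes\n",
              x$k, length(x$labels)))
  print(table(community = x$labels))
  invisible(x)
}
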