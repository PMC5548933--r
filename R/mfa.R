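#' Multi-fractal spectrum of a weighted network
#'
#' Fits the generalized dimension D(q) of a weighted, connected,
#' undirected network by one of four estimators:
#'
#' \describe{
#'   \item{`"fbcw"`}{finite box-covering: boxes grown over the network's
#'     unique shortest-path distances, stagnant observations removed by the
#'     critical-scale filter, and the log-log regression restricted to the
#'     detected scaling range.}
#'   \item{`"fsbw"`}{finite sandbox: randomized sandbox centers on the same
#'     unique-distance growth rule, with the same filtering and range
#'     localization; saturated scales (every sampled sandbox already holds
#'     all other nodes) are dropped before fitting.}
#'   \item{`"bcanw"`}{box-covering baseline: weight-accumulation growth
#'     rule (prefix sums of ascending edge weights, truncated at the
#'     diameter), no filtering, full-range fit. Biased toward
#'     underestimation by the staircase effect.}
#'   \item{`"sbw"`}{sandbox baseline with the same incompatible growth rule
#'     and full-range fit.}
#' }
#'
#' For each q the accumulated measure is the box partition function
#' sum_i mu_i^q (box methods) or the randomized sandbox moment
#' mean[(M_i(l)/M_0)^(q-1)] (sandbox methods); its log-log slope against
#' l/L is the mass exponent tau(q) and D(q) = tau(q)/(q - 1). The q = 1
#' information dimension is estimated from the entropy series
#' sum_i mu_i log mu_i (box) or mean[log(M_i(l)/M_0)] (sandbox).
#'
#' @param net a weighted network (\code{igraph}).
#' @param method one of `"fbcw"`, `"fsbw"`, `"bcanw"`, `"sbw"`.
#' @param q distortion exponent grid (any real values; 1 is handled by the
#'   information-dimension limit).
#' @param trials covering trials per scale (box methods).
#' @param center_fraction fraction of nodes sampled as sandbox centers per
#'   repeat (sandbox methods), in (0, 1].
#' @param repeats number of center resamples (sandbox methods).
#' @param seed integer seed; results are reproducible given
#'   (seed, trials, centers).
#' @param max_scales cap on the number of scales (linear index resampling).
#' @param W sliding-window width for the critical-scale filter; default
#'   `max(3, ceiling(N/50))` where N is the series length.
#' @param min_points minimum window length for scaling-range detection.
#' @param p exponent of the path metric (distances minimize the sum of
#'   w^p along paths).
#' @param tol distance comparison tolerance.
#' @return an object of class `mfa` with components `q`, `tau`, `D`,
#'   `alpha`, `f_alpha`, per-q `fits`, the scale sequence and diagnostics.
#' @examples
#' \donttest{
#' g <- sierpinski_network(b = 3, s = 1/2, k = 4)
#' fit <- mfa(g, method = "fbcw", q = 0, trials = 50, seed = 1)
#' coef(fit)             # D(0), close to log(3)/log(2) = 1.585
#' }
#' @export
mfa <- function(net, method = c("fbcw", "fsbw", "bcanw", "sbw"),
                q = seq(-10, 10, by = 0.1), trials = 100,
                center_fraction = 0.5, repeats = 20, seed = 1L,
                max_scales = 100L, W = NULL, min_points = 5L, p = 1,
                tol = 1e-9) {
  method <- match.arg(method)
  net <- as_weighted_network(net, require_connected = TRUE)
  q <- round(as.numeric(q), 10)
  if (any(duplicated(q))) stop("duplicate values in `q`")

  D <- network_distances(net, p = p)
  L <- network_diameter(D)
  n <- nrow(D)

  corrected <- method %in% c("fbcw", "fsbw")
  scales <- if (corrected) {
    resample_scales(unique_distance_scales(D, tol), max_scales)
  } else {
    resample_scales(
      weight_accumulation_scales(net, l_max = L, tol = tol)^p,
      max_scales
    )
  }
  if (length(scales) < 3) stop("fewer than 3 usable scales")

  if (method %in% c("fbcw", "bcanw")) {
    series <- box_measure_series(D, scales, q, trials, seed, tol,
                                 corrected = corrected)
  } else {
    series <- sandbox_measure_series(D, scales, q, center_fraction, repeats,
                                     seed, tol,
                                     drop_saturated = corrected)
  }
  scales <- series$scales

  fits <- vector("list", length(q))
  tau <- numeric(length(q))
  Dq <- numeric(length(q))
  crit <- vector("list", length(q))
  for (j in seq_along(q)) {
    qj <- q[j]
    is_q1 <- abs(qj - 1) < 1e-8
    vals <- series$values[, j]
    ok <- is.finite(vals)
    res <- fit_measure_series(scales[ok], vals[ok], L = L,
                              filtered = corrected, W = W,
                              min_points = min_points,
                              log_y = !is_q1)
    fits[[j]] <- res$fit
    crit[[j]] <- res$critical
    if (is_q1) {
      Dq[j] <- res$fit$slope
      tau[j] <- 0
    } else {
      tau[j] <- res$fit$slope
      Dq[j] <- tau[j] / (qj - 1)
    }
  }

  out <- structure(list(
    call = match.call(),
    method = method,
    n_nodes = n,
    diameter = L,
    q = q,
    tau = tau,
    D = Dq,
    alpha = rep(NA_real_, length(q)),
    f_alpha = rep(NA_real_, length(q)),
    fits = fits,
    critical = crit,
    scales = scales,
    series = series$values,
    trial_counts = series$trial_counts,
    seed = seed
  ), class = "mfa")
  if (length(q) >= 3) out <- legendre_spectrum(out)
  out
}

# Accumulated box measures at every (scale, q). One covering per scale.
# For the corrected estimator two finite-resolution refinements apply:
# (i) since a valid covering at scale l is valid at every l' > l, the best
# covering found so far is carried forward along increasing l, enforcing
# the monotonicity of the minimal box count and suppressing greedy noise;
# (ii) scales whose best covering is all singletons are dropped — a
# trivial covering aggregates no mass and its partition function is
# scale-independent. The uncorrected baseline (BCANw) uses the raw
# per-scale best-of-trials coverings over its full scale range.
box_measure_series <- function(D, scales, q, trials, seed, tol,
                               corrected = TRUE) {
  n <- nrow(D)
  set.seed(as.integer(seed %% .Machine$integer.max))
  scale_seeds <- sample.int(.Machine$integer.max - 1, length(scales))
  covers <- vector("list", length(scales))
  for (i in seq_along(scales)) {
    cv <- box_cover(D, scales[i], trials = trials, seed = scale_seeds[i],
                    tol = tol)
    if (corrected && i > 1 && covers[[i - 1]]$n_boxes < cv$n_boxes) {
      prev <- covers[[i - 1]]
      cv <- structure(list(l = scales[i], assignment = prev$assignment,
                           masses = prev$masses, total_mass = prev$total_mass,
                           measures = prev$measures, n_boxes = prev$n_boxes,
                           trial_counts = cv$trial_counts),
                      class = "box_covering")
    }
    covers[[i]] <- cv
  }
  if (corrected) {
    counts <- vapply(covers, `[[`, integer(1), "n_boxes")
    usable <- counts < n
    if (sum(usable) < 3) usable <- rep(TRUE, length(scales))
    covers <- covers[usable]
    scales <- scales[usable]
  }
  values <- matrix(NA_real_, length(scales), length(q))
  for (j in seq_along(q)) {
    if (abs(q[j] - 1) < 1e-8) {
      values[, j] <- vapply(covers, function(cv) {
        sum(cv$measures * log(cv$measures))
      }, numeric(1))
    } else {
      values[, j] <- vapply(covers, partition_function, numeric(1), q = q[j])
    }
  }
  list(values = values, scales = scales,
       trial_counts = t(vapply(covers, `[[`, integer(trials), "trial_counts")))
}

# Randomized sandbox moments at every (scale, q); centers resampled
# without replacement per repeat and pooled. Two classes of degenerate
# scale are masked before fitting (corrected methods only): scales where
# some sampled sandbox is empty (the q < 1 moment is then defined only
# after excluding those centers, which biases it) and scales where some
# sampled sandbox already holds every other node (boundary saturation: the
# ball has run out of network, so its growth no longer reflects scaling).
sandbox_measure_series <- function(D, scales, q, center_fraction, repeats,
                                   seed, tol, drop_saturated = TRUE) {
  if (center_fraction <= 0 || center_fraction > 1) {
    stop("`center_fraction` must lie in (0, 1]")
  }
  if (repeats < 1) stop("`repeats` must be >= 1")
  n <- nrow(D)
  counts <- sandbox_counts_all(D, as.numeric(scales), tol)
  set.seed(as.integer(seed %% .Machine$integer.max))
  m <- max(1L, round(center_fraction * n))
  centers <- unlist(lapply(seq_len(repeats), function(r) sample.int(n, m)))
  C <- counts[centers, , drop = FALSE]

  min_count <- apply(C, 2, min)
  max_count <- apply(C, 2, max)
  if (drop_saturated) {
    keep <- max_count < n - 1L
    if (sum(keep) < 3) keep <- max_count > 0 # tiny networks: keep what exists
    C <- C[, keep, drop = FALSE]
    scales <- scales[keep]
    min_count <- min_count[keep]
  }

  values <- matrix(NA_real_, length(scales), length(q))
  warned <- FALSE
  for (j in seq_along(q)) {
    qj <- q[j]
    if (abs(qj - 1) < 1e-8) {
      values[, j] <- apply(C, 2, function(col) {
        nz <- col > 0
        if (!any(nz) || (drop_saturated && !all(nz))) return(NA_real_)
        mean(log(col[nz] / n))
      })
    } else if (qj < 1) {
      for (s in seq_len(ncol(C))) {
        col <- C[, s]
        nz <- col > 0
        if (!any(nz)) next # left as NA
        if (drop_saturated && !all(nz)) next # masked: exclusion-biased moment
        if (!all(nz) && !warned) {
          warning("zero-count sandboxes excluded from moments with q < 1")
          warned <- TRUE
        }
        values[s, j] <- mean((col[nz] / n)^(qj - 1))
      }
    } else {
      values[, j] <- colMeans((C / n)^(qj - 1))
    }
  }
  list(values = values, scales = scales, trial_counts = NULL)
}

# Shared per-q fitting pipeline: optional critical-scale filtering and
# scaling-range detection, then OLS on log(l/L).
fit_measure_series <- function(scales, values, L, filtered, W, min_points,
                               log_y) {
  n <- length(scales)
  if (n < 3) stop("fewer than 3 usable scales")
  cs <- NULL
  idx <- seq_len(n)
  if (filtered) {
    cs <- critical_scales(scales, values, W = W, log_measures = log_y)
    idx <- cs$indices
    if (length(idx) < 3) {
      warning("fewer than 3 critical scales; fitting all usable scales")
      idx <- seq_len(n)
    }
  }
  if (filtered && length(idx) >= max(min_points, 4)) {
    x <- log(scales[idx] / L)
    y <- if (log_y) log(values[idx]) else values[idx]
    rng <- detect_scaling_range(x, y, min_points = min_points)
    idx <- idx[rng[1]:rng[2]]
  }
  if (length(idx) < 3) stop("fewer than 3 usable scales after filtering")
  fit <- fit_loglog(scales[idx], values[idx], L = L, log_y = log_y)
  fit$range <- as.integer(c(idx[1], idx[length(idx)]))
  fit$indices <- idx
  list(fit = fit, critical = cs)
}

#' Legendre transform of the mass exponent
#'
#' Fills the Holder exponent alpha(q) = d tau / d q (central finite
#' differences on the q grid, one-sided at the ends) and the singularity
#' spectrum f(alpha) = q alpha - tau. A monofractal has constant alpha
#' and f(alpha) equal to the single dimension; fit noise can make alpha
#' non-monotone, which is flagged with a warning.
#'
#' @param object an `mfa` fit (or any list with `q` and `tau`).
#' @return the object with `alpha` and `f_alpha` filled.
#' @export
legendre_spectrum <- function(object) {
  q <- object$q
  tau <- object$tau
  m <- length(q)
  if (m < 3) stop("need tau on a grid of at least 3 q values")
  ord <- order(q)
  q <- q[ord]; tau <- tau[ord]
  alpha <- numeric(m)
  alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  alpha[m] <- (tau[m] - tau[m - 1]) / (q[m] - q[m - 1])
  if (m > 2) {
    for (i in 2:(m - 1)) {
      alpha[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
    }
  }
  f <- q * alpha - tau
  if (any(diff(alpha) > 1e-8)) {
    warning("alpha(q) is not non-increasing; spectrum returned unsorted")
    object$alpha_monotone <- FALSE
  } else {
    object$alpha_monotone <- TRUE
  }
  object$alpha[ord] <- alpha
  object$f_alpha[ord] <- f
  object
}

#' Normalized estimation error
#'
#' |estimate - truth| / |truth|, the relative error of a dimension
#' estimate against a theoretical ground truth.
#'
#' @param estimate estimated value.
#' @param truth reference value (non-zero).
#' @return the normalized error.
#' @export
normalized_error <- function(estimate, truth) {
  if (any(truth == 0)) stop("`truth` must be non-zero")
  abs(estimate - truth) / abs(truth)
}

#' Dominant (q = 0) fractal dimension of a fit
#' @param object an `mfa` fit whose grid contains q = 0.
#' @return D(0).
#' @export
dominant_dimension <- function(object) {
  stopifnot(inherits(object, "mfa"))
  j <- which(abs(object$q) < 1e-8)
  if (length(j) == 0) stop("q = 0 is not on the fitted grid")
  object$D[j]
}

#' @export
print.mfa <- function(x, ...) {
  cat(sprintf("Multi-fractal spectrum fit (%s)\n", toupper(x$method)))
  cat(sprintf("  network: %d nodes, diameter %.4g, %d scales\n",
              x$n_nodes, x$diameter, length(x$scales)))
  cat(sprintf("  q grid: %d values in [%g, %g]\n",
              length(x$q), min(x$q), max(x$q)))
  j0 <- which(abs(x$q) < 1e-8)
  if (length(j0) == 1) {
    cat(sprintf("  D(0) = %.4f (R^2 = %.4f, %d scales in range)\n",
                x$D[j0], x$fits[[j0]]$r_squared, x$fits[[j0]]$n_points))
  }
  invisible(x)
}

#' @export
summary.mfa <- function(object, ...) {
  tab <- data.frame(
    q = object$q,
    tau = object$tau,
    D = object$D,
    alpha = object$alpha,
    f_alpha = object$f_alpha,
    r_squared = vapply(object$fits, `[[`, numeric(1), "r_squared"),
    n_scales = vapply(object$fits, `[[`, numeric(1), "n_points")
  )
  out <- list(method = object$method, n_nodes = object$n_nodes,
              diameter = object$diameter, table = tab,
              width = if (all(is.finite(object$alpha))) {
                diff(range(object$alpha))
              } else NA_real_)
  class(out) <- "summary.mfa"
  out
}

#' @export
print.summary.mfa <- function(x, ...) {
  cat(sprintf("Multi-fractal spectrum (%s), %d nodes, diameter %.4g\n",
              toupper(x$method), x$n_nodes, x$diameter))
  if (is.finite(x$width)) {
    cat(sprintf("  spectrum width max(alpha) - min(alpha) = %.4f\n", x$width))
  }
  print(utils::head(x$table, 12), row.names = FALSE, digits = 4)
  if (nrow(x$table) > 12) cat(sprintf("  ... %d more q values\n", nrow(x$table) - 12))
  invisible(x)
}

#' @export
coef.mfa <- function(object, ...) {
  stats::setNames(object$D, paste0("D(", object$q, ")"))
}

#' Plot a multi-fractal spectrum fit
#'
#' Two panels: the generalized dimension D(q) against q, and the
#' singularity spectrum f(alpha) against alpha (when available).
#'
#' @param x an `mfa` fit.
#' @param ... passed to `plot`.
#' @export
plot.mfa <- function(x, ...) {
  has_spectrum <- any(is.finite(x$alpha))
  if (has_spectrum) {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  graphics::plot(x$q, x$D, type = "b", pch = 16, cex = 0.6,
                 xlab = "q", ylab = "D(q)",
                 main = sprintf("Generalized dimension (%s)", toupper(x$method)),
                 ...)
  if (has_spectrum) {
    graphics::plot(x$alpha, x$f_alpha, type = "b", pch = 16, cex = 0.6,
                   xlab = expression(alpha), ylab = expression(f(alpha)),
                   main = "Singularity spectrum")
  }
  invisible(x)
}
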