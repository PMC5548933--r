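#' Sliding-window variance filter
#'
#' For each window start t, the response is the within-window sum of
#' squared deviations from the window mean, sigma_t = sum_i (xbar - x_i)^2
#' over x_t..x_{t+W-1}. Stagnant stretches of a measure series respond
#' with zero; changes respond with peaks.
#'
#' @param values numeric observation sequence.
#' @param W window width (2 <= W <= length(values)).
#' @return numeric vector of length `length(values) - W + 1`.
#' @export
sliding_variance_filter <- function(values, W) {
  n <- length(values)
  if (W < 2) stop("`W` must be >= 2")
  if (W > n) stop("`W` must not exceed the series length")
  vapply(seq_len(n - W + 1), function(t) {
    x <- values[t:(t + W - 1)]
    sum((mean(x) - x)^2)
  }, numeric(1))
}

#' Critical scales of an accumulated-measure series
#'
#' Identifies the scales at which the accumulated measure genuinely
#' changes, discarding the stagnant observations (staircases) an
#' incompatible growth rule produces. Each retained index is the first
#' scale at which a new measure value holds (the scale where the change
#' lands); the first scale is always retained as the regression's left
#' anchor.
#'
#' For integer-valued series (q = 0 box counts) the selection is the exact
#' epsilon change-point filter: indices i with |M(d_i) - M(d_{i-1})| >
#' eps, eps defaulting to 0. For real-valued series (general-q partition
#' functions, sandbox moments) genuine plateaus carry small numerical
#' drift, so a fixed epsilon is unreliable; there the selection uses the
#' sliding-variance response sigma on the log measures: each peak of sigma
#' (strict local maximum with plateaus collapsed, boundary windows
#' compared against a zero response — conservative since sigma is
#' non-negative) marks a window containing a significant change, and the
#' retained scale is the landing point of the largest jump inside that
#' window. For W = 2 the two selections coincide.
#'
#' @param scales strictly increasing scale sequence.
#' @param measures accumulated measure at each scale.
#' @param W sliding-window width; default `max(3, ceiling(N / 50))`.
#' @param eps stagnation threshold for the integer branch (default 0).
#' @param rel_height significance threshold for the real-valued branch:
#'   sigma peaks below `rel_height * max(sigma)` are treated as plateau
#'   drift, not as critical changes.
#' @param log_measures apply the filter to `log(measures)` when all
#'   measures are positive.
#' @return an object of class `critical_scales`: `indices` (selected scale
#'   indices, anchored at 1), `changes` (change-point indices, integer
#'   branch), `sigma`, `peaks` (peak window starts), `W`, `eps`.
#' @export
critical_scales <- function(scales, measures, W = NULL, eps = NULL,
                            rel_height = 0.01, log_measures = TRUE) {
  n <- length(measures)
  if (length(scales) != n) stop("`scales` and `measures` lengths differ")
  if (is.null(W)) W <- max(3L, ceiling(n / 50))
  W <- as.integer(W)
  if (n < W + 2) stop("series too short for window width W (need >= W + 2 points)")

  integer_series <- all(abs(measures - round(measures)) < 1e-9)

  x <- measures
  if (log_measures && all(measures > 0)) x <- log(measures)
  sigma <- sliding_variance_filter(x, W)

  # peaks of sigma: strict local maxima with plateau collapse, boundary
  # windows compared against zero response
  r <- rle(sigma)
  starts <- cumsum(r$lengths) - r$lengths + 1
  m <- length(r$values)
  left <- c(0, r$values[-m])
  right <- c(r$values[-1], 0)
  peaks <- starts[r$values > left & r$values > right & r$values > 0]

  sig_peaks <- peaks
  if (max(sigma) > 0) {
    sig_peaks <- peaks[sigma[peaks] > rel_height * max(sigma)]
  }

  changes <- integer(0)
  if (integer_series) {
    if (is.null(eps)) eps <- 0
    changes <- which(abs(diff(measures)) > eps) + 1L
    selected <- changes
    if (length(selected) == 0 && stats::sd(measures) > 0) {
      warning("no measure changes above eps; retaining all scales")
      selected <- seq_len(n)
    }
  } else {
    # landing point of the dominant jump inside each peak window
    selected <- vapply(sig_peaks, function(t) {
      hi <- min(t + W - 2L, n - 1L)
      jumps <- abs(diff(x))[t:hi]
      as.integer(t + which.max(jumps))
    }, integer(1))
    if (length(selected) == 0) {
      warning("no sigma peaks found; falling back to change-point filter")
      e <- if (is.null(eps)) 1e-9 * max(abs(measures)) else eps
      selected <- which(abs(diff(measures)) > e) + 1L
    }
  }
  indices <- sort(unique(c(1L, selected)))

  structure(list(indices = indices, changes = changes, sigma = sigma,
                 peaks = peaks, W = W, eps = eps,
                 scales = scales[indices]),
            class = "critical_scales")
}

#' @export
print.critical_scales <- function(x, ...) {
  cat(sprintf("Critical scales: %d of %d retained (W = %d, eps = %g)\n",
              length(x$indices), length(x$sigma) + x$W - 1, x$W, x$eps))
  invisible(x)
}

#' Locate the scaling range of a log-log series
#'
#' Scans every contiguous index window of at least `min_points` points and
#' returns the one maximizing the R-squared of an ordinary least-squares
#' line, breaking ties (within `tol`) toward the longer window and then
#' toward the smaller start index. Real networks often obey a power law
#' only over a finite range of scales; forcing the full range reproduces
#' the global-fit behavior of the uncorrected baselines.
#'
#' Windows whose R-squared comes within `tol` of the best are treated as
#' ties and resolved toward the longer window: trimming the range is only
#' warranted when the fit clearly breaks, not to chase marginal gains on
#' data with mild log-periodic modulation.
#'
#' @param log_l,log_M coordinate vectors of equal length.
#' @param min_points minimum window length (>= 4).
#' @param tol R-squared tie tolerance.
#' @return integer vector `c(lo, hi)` of the selected window.
#' @export
detect_scaling_range <- function(log_l, log_M, min_points = 5L, tol = 5e-3) {
  n <- length(log_l)
  if (length(log_M) != n) stop("coordinate lengths differ")
  if (min_points < 4) stop("`min_points` must be >= 4")
  if (n < min_points) stop("fewer points than `min_points`")

  cx <- cumsum(log_l); cy <- cumsum(log_M)
  cxx <- cumsum(log_l^2); cyy <- cumsum(log_M^2); cxy <- cumsum(log_l * log_M)
  seg <- function(cs, lo, hi) cs[hi] - if (lo > 1) cs[lo - 1] else 0

  best_r2 <- -Inf; best_len <- 0L; best <- c(1L, n)
  for (lo in 1:(n - min_points + 1)) {
    for (hi in (lo + min_points - 1):n) {
      m <- hi - lo + 1
      sx <- seg(cx, lo, hi); sy <- seg(cy, lo, hi)
      sxx <- seg(cxx, lo, hi); syy <- seg(cyy, lo, hi); sxy <- seg(cxy, lo, hi)
      vx <- sxx - sx^2 / m
      vy <- syy - sy^2 / m
      if (vx <= 1e-12 * max(1, sxx)) next # degenerate x: no slope defined
      r2 <- if (vy <= 0) 0 else (sxy - sx * sy / m)^2 / (vx * vy)
      if (r2 > best_r2 + tol ||
          (abs(r2 - best_r2) <= tol &&
           (m > best_len || (m == best_len && lo < best[1])))) {
        best_r2 <- r2; best_len <- m; best <- c(lo, hi)
      }
    }
  }
  if (!is.finite(best_r2)) stop("no usable window: x values are degenerate")
  as.integer(best)
}

#' Log-log regression for a scaling exponent
#'
#' Ordinary least squares of log measure against log normalized scale
#' log(l / L). The slope is the exponent estimate; normalization by L
#' only shifts the intercept.
#'
#' @param l scales.
#' @param M measures (must be positive unless `log_y = FALSE`).
#' @param L normalization scale (defaults to `max(l)`).
#' @param range optional `c(lo, hi)` index window; default all points.
#' @param log_y take `log(M)` (set to `FALSE` for series that are already
#'   on log scale or signed, e.g. entropy sums).
#' @return an object of class `scaling_fit`: slope, intercept, r_squared,
#'   se_slope, n_points, range.
#' @export
fit_loglog <- function(l, M, L = NULL, range = NULL, log_y = TRUE) {
  if (is.null(L)) L <- max(l)
  if (is.null(range)) range <- c(1L, length(l))
  idx <- range[1]:range[2]
  if (length(idx) < 3) stop("need at least 3 points to fit")
  x <- log(l[idx] / L)
  y <- if (log_y) log(M[idx]) else M[idx]
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite values in fit")
  if (stats::sd(x) == 0) stop("degenerate fit: zero variance in log scales")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # noiseless data: perfect-fit warning
  r2 <- if (stats::sd(y) == 0) 1 else sm$r.squared
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = r2,
    se_slope = unname(sm$coefficients[2, 2]),
    n_points = length(idx),
    range = as.integer(range)
  ), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("slope = %.4f (se %.4f), intercept = %.4f, R^2 = %.4f over %d points [%d, %d]\n",
              x$slope, x$se_slope, x$intercept, x$r_squared, x$n_points,
              x$range[1], x$range[2]))
  invisible(x)
}

#' Exponential versus power-law model selection
#'
#' Fits N = a exp(b l) by OLS on (l, log N) and N = a l^b by OLS on
#' (log l, log N), and prefers the model with the higher R-squared on the
#' same point count. Box-count series of small-world networks follow the
#' exponential law; fractal networks follow the power law.
#'
#' @param l scales.
#' @param N positive counts/measures.
#' @param criterion `"r2"` or `"aic"`.
#' @return a list: `a`, `b` (exponential-law parameters), `power_exponent`,
#'   `r2_exponential`, `r2_power`, `preferred_model`.
#' @export
fit_exponential <- function(l, N, criterion = c("r2", "aic")) {
  criterion <- match.arg(criterion)
  if (length(l) < 4) stop("need at least 4 points")
  if (any(N <= 0)) stop("`N` must be positive")
  if (any(l <= 0)) stop("`l` must be positive for the power-law comparison")
  y <- log(N)
  fe <- stats::lm(y ~ l)
  fp <- stats::lm(y ~ log(l))
  r2 <- function(f) suppressWarnings(summary(f))$r.squared
  better_exp <- if (criterion == "r2") {
    r2(fe) >= r2(fp)
  } else {
    stats::AIC(fe) <= stats::AIC(fp)
  }
  list(
    a = exp(unname(stats::coef(fe)[1])),
    b = unname(stats::coef(fe)[2]),
    power_exponent = unname(stats::coef(fp)[2]),
    r2_exponential = r2(fe),
    r2_power = r2(fp),
    preferred_model = if (better_exp) "exponential" else "power"
  )
}
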