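# Median (L1) regression of distances on time with a bootstrap p-value.
#
# The L1 line minimizing the sum of absolute residuals always passes
# through at least two data points (when x is non-degenerate), so for
# moderate n the exact optimum is found by exhaustive search over all
# point-pair lines; above that an IRLS approximation is used.

# Exact/approximate L1 line fit. Returns c(intercept, slope).
fit_l1_line <- function(x, y, exact_max = 200) {
  n <- length(x)
  stopifnot(n >= 2, length(y) == n)
  if (length(unique(x)) < 2) stop("degenerate x: a single day", call. = FALSE)
  if (n <= exact_max) {
    pr <- utils::combn(n, 2)
    dx <- x[pr[2, ]] - x[pr[1, ]]
    ok <- dx != 0
    b <- (y[pr[2, ok]] - y[pr[1, ok]]) / dx[ok]
    a <- y[pr[1, ok]] - b * x[pr[1, ok]]
    # objective for every candidate line, vectorized over lines
    pred <- outer(x, b) + matrix(a, nrow = n, ncol = length(a), byrow = TRUE)
    obj <- colSums(abs(y - pred))
    k <- which.min(obj)
    c(a[k], b[k])
  } else {
    # iteratively reweighted least squares for the L1 objective
    fit <- stats::lm.fit(cbind(1, x), y)
    coefs <- fit$coefficients
    for (it in 1:60) {
      r <- y - coefs[1] - coefs[2] * x
      w <- 1 / pmax(abs(r), 1e-8)
      fit <- stats::lm.wfit(cbind(1, x), y, w)
      if (max(abs(fit$coefficients - coefs)) < 1e-10) break
      coefs <- fit$coefficients
    }
    unname(coefs)
  }
}

#' Median-regression trend test for a distance time series
#'
#' Fits `distance = a + b * day` by L1 (median) regression and assesses the
#' slope with a case-resampling bootstrap: `p = 2 * min(frac(b* <= 0),
#' frac(b* >= 0))` with a `+1/(n_boot+1)` continuity correction. The slope
#' is also reported rescaled to the full day span divided by the observed
#' distance range (`rc_range`) and by the distance standard deviation
#' (`rc_sd`).
#'
#' @param series tibble with columns `day` and `distance` (e.g. from
#'   [inter_subject_distance_series()])
#' @param n_boot number of bootstrap resamples (>= 100)
#' @param seed integer seed for the bootstrap
#' @param exact_max exhaustive pairwise-line search is used up to this n
#' @return object of class `mb_trend`
#' @export
median_regression_trend <- function(series, n_boot = 1999, seed = 1,
                                    exact_max = 200) {
  assert_cols(series, c("day", "distance"), "trend series")
  x <- series$day; y <- series$distance
  if (length(x) < 10) stop("need at least 10 (day, distance) pairs", call. = FALSE)
  if (n_boot < 100) stop("n_boot must be >= 100", call. = FALSE)
  coefs <- fit_l1_line(x, y, exact_max)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n <- length(x)
  bstar <- numeric(n_boot)
  for (k in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    bstar[k] <- tryCatch(fit_l1_line(x[idx], y[idx], exact_max)[2],
                         error = function(e) NA_real_)
  }
  bstar <- bstar[!is.na(bstar)]
  nb <- length(bstar)
  p <- min(1, 2 * min((sum(bstar <= 0) + 1) / (nb + 1),
                      (sum(bstar >= 0) + 1) / (nb + 1)))
  day_span <- diff(range(x))
  dist_range <- diff(range(y))
  structure(list(
    intercept = coefs[1], slope = coefs[2],
    rc_range = if (dist_range > 0) coefs[2] * day_span / dist_range else NA_real_,
    rc_sd = if (sd(y) > 0) coefs[2] * day_span / sd(y) else NA_real_,
    p_value = p, n_boot = nb, n = n,
    day_span = day_span, dist_range = dist_range, dist_sd = sd(y),
    boot_slopes = bstar, data = tibble::tibble(day = x, distance = y)
  ), class = "mb_trend")
}

#' @export
print.mb_trend <- function(x, ...) {
  cat(sprintf("<mb_trend> L1 slope %.3g per day (n = %d)\n", x$slope, x$n))
  cat(sprintf("  rc_range %.4g, rc_sd %.4g, bootstrap p = %.3g (%d resamples)\n",
              x$rc_range, x$rc_sd, x$p_value, x$n_boot))
  invisible(x)
}

#' @export
tidy.mb_trend <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "day"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.mb_trend <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept,
                 rc_range = x$rc_range, rc_sd = x$rc_sd,
                 p_value = x$p_value, n = x$n, n_boot = x$n_boot)
}

#' @export
autoplot.mb_trend <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$day, y = .data$distance)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         color = "#b2182b") +
    ggplot2::labs(title = sprintf("Median-regression trend: slope %.3g/day, p = %.2g",
                                  object$slope, object$p_value),
                  x = "day", y = "distance") +
    ggplot2::theme_minimal(base_size = 9)
}
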