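#' Unity crossing of a binned pair-correlation signal
#'
#' The separation `delta*` at which the binned signal first crosses `F = 1`,
#' linearly interpolated between bin centres `(j + 1/2) Delta - 1/2`. A
#' signal starting above 1 crosses downward and `delta*` estimates the
#' typical aggregate (cluster) size; a signal starting below 1 crosses
#' upward and `delta*` estimates the object/segregation scale instead, and
#' is flagged as such.
#'
#' @param pc a binned `"pair_correlation"` with at least two bins.
#' @param pixel_size optional micrometres per pixel; defaults to nothing, in
#'   which case only the pixel value is reported.
#' @return A `"cluster_estimate"`: list with `crossing_pixels`,
#'   `crossing_physical` (micron value or `NA`), `direction`
#'   (`"aggregation"` or `"segregation"`), `bandwidth`, `X`.
#' @export
unity_crossing <- function(pc, pixel_size = NULL) {
  stopifnot(inherits(pc, "pair_correlation"))
  if (length(pc$values) < 2L) {
    stop("need at least two bins to locate a crossing", call. = FALSE)
  }
  g <- pc$values - 1
  cent <- pc$centers
  if (g[1L] == 0) {
    stop("signal does not cross unity (starts exactly at 1)", call. = FALSE)
  }
  from_above <- g[1L] > 0
  hit <- if (from_above) which(g <= 0) else which(g >= 0)
  if (length(hit) == 0L) {
    stop("signal does not cross unity", call. = FALSE)
  }
  m <- hit[1L]
  delta_star <- cent[m - 1L] +
    (cent[m] - cent[m - 1L]) * g[m - 1L] / (g[m - 1L] - g[m])
  phys <- if (!is.null(pixel_size)) delta_star * pixel_size else NA_real_
  structure(
    list(crossing_pixels = delta_star, crossing_physical = phys,
         direction = if (from_above) "aggregation" else "segregation",
         bandwidth = pc$bandwidth, X = pc$X),
    class = "cluster_estimate"
  )
}

#' @export
print.cluster_estimate <- function(x, ...) {
  cat("Unity crossing (", x$direction, " scale): delta* = ",
      format(x$crossing_pixels, digits = 4), " pixels",
      if (!is.na(x$crossing_physical))
        paste0(" = ", format(x$crossing_physical, digits = 4), " um"),
      "  [bandwidth ", x$bandwidth, "]\n", sep = "")
  invisible(x)
}

#' Convert a pixel length to micrometres
#'
#' @param length_pixels length(s) in pixels.
#' @param pixel_size physical length of one pixel in micrometres (e.g. 0.44
#'   or 1.19 depending on the microscope).
#' @return Length(s) in micrometres.
#' @examples
#' to_physical(25, 0.44)  # 11
#' @export
to_physical <- function(length_pixels, pixel_size) {
  if (missing(pixel_size) || is.null(pixel_size)) {
    stop("'pixel_size' is required for physical conversion", call. = FALSE)
  }
  if (length(pixel_size) != 1L || !is.finite(pixel_size) || pixel_size <= 0) {
    stop("'pixel_size' must be a single positive number", call. = FALSE)
  }
  length_pixels * pixel_size
}

#' Fit an exponential growth curve to cell counts
#'
#' Nonlinear least squares of `n(t) = n0 exp(alpha t)` to per-time mean
#' counts, initialised from the log-linear regression. The coefficient of
#' determination is computed on the untransformed counts.
#'
#' @param times observation times in minutes (>= 3 values).
#' @param counts mean object counts per image at each time (positive).
#' @param stderr optional standard errors of the mean counts (reporting
#'   only; the fit is unweighted).
#' @return A `"growth_fit"`: fields `n0`, `alpha` (per minute),
#'   `r_squared`, `times`, `counts`, `stderr`, and the underlying `fit`.
#'   Supports [coef()], [predict()], [residuals()], `print`, `summary`,
#'   `plot`.
#' @examples
#' t <- 0:5
#' g <- fit_growth(t, 10 * exp(0.05 * t))
#' coef(g)
#' @export
fit_growth <- function(times, counts, stderr = NULL) {
  if (length(times) != length(counts) || length(times) < 3L) {
    stop("need >= 3 matched times and counts", call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    stop("counts must be positive", call. = FALSE)
  }
  init <- lm(log(counts) ~ times)
  start <- list(n0 = exp(coef(init)[[1L]]), alpha = coef(init)[[2L]])
  init_resid <- counts - start$n0 * exp(start$alpha * times)
  if (max(abs(init_resid)) <= 1e-10 * max(counts)) {
    # the log-linear initializer already fits exactly; the least-squares
    # refinement is degenerate (zero-residual Jacobian) and unnecessary
    fit <- NULL
    est <- c(n0 = start$n0, alpha = start$alpha)
  } else {
    fit <- tryCatch(
      minpack.lm::nlsLM(counts ~ n0 * exp(alpha * times),
                        start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        stop("growth fit did not converge (", conditionMessage(e),
             "); log-linear start was n0 = ", format(start$n0, digits = 4),
             ", alpha = ", format(start$alpha, digits = 4), call. = FALSE)
      })
    est <- coef(fit)
  }
  res <- counts - est[["n0"]] * exp(est[["alpha"]] * times)
  ss_res <- sum(res^2)
  ss_tot <- sum((counts - mean(counts))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res == 0) 1 else NA_real_
  } else {
    1 - ss_res / ss_tot
  }
  structure(
    list(n0 = est[["n0"]], alpha = est[["alpha"]], r_squared = r2,
         times = times, counts = counts, stderr = stderr, fit = fit),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("Exponential growth fit n(t) = n0 * exp(alpha * t)\n",
      "  n0 = ", format(x$n0, digits = 6),
      ", alpha = ", format(x$alpha, digits = 4), " per minute",
      ", R^2 = ", format(x$r_squared, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  c(n0 = object$n0, alpha = object$alpha)
}

#' @export
predict.growth_fit <- function(object, times = object$times, ...) {
  object$n0 * exp(object$alpha * times)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$counts - predict(object)
}

#' @export
summary.growth_fit <- function(object, ...) {
  print(object)
  cat("  doubling time:", format(log(2) / object$alpha, digits = 4),
      "minutes\n")
  invisible(object)
}

#' @export
plot.growth_fit <- function(x, xlab = "time (minutes)", ylab = "mean count",
                            ...) {
  plot(x$times, x$counts, pch = 16, xlab = xlab, ylab = ylab, ...)
  if (!is.null(x$stderr)) {
    arrows(x$times, x$counts - x$stderr, x$times, x$counts + x$stderr,
           angle = 90, code = 3, length = 0.02)
  }
  tt <- seq(min(x$times), max(x$times), length.out = 200L)
  lines(tt, predict(x, tt), col = 2)
  invisible(x)
}

#' Time-series report of clustering during growth
#'
#' For a series of sample sets observed at increasing times, bins each
#' time point's average pair-correlation at a fixed bandwidth, reads off
#' mean counts (with standard errors) and the unity crossing, and — when at
#' least three time points are available — fits the exponential growth
#' curve to the mean counts. Tracks how the typical cluster size evolves as
#' a population grows to confluence.
#'
#' @param sample_sets list of [sample_set()] objects, one per time point.
#' @param times observation times in minutes, same length.
#' @param bandwidth integer box-kernel bandwidth applied to every time point.
#' @param pixel_size optional micrometres per pixel for physical crossings.
#' @return A `"pcf_timeseries"`: data frame `per_time` (columns `time`,
#'   `n_mean`, `n_stderr`, `crossing`, `direction`), list `pcfs` of binned
#'   signals, and `growth` (a [fit_growth()] result, or `NULL` with fewer
#'   than 3 time points).
#' @export
timeseries_report <- function(sample_sets, times, bandwidth,
                              pixel_size = NULL) {
  if (!is.list(sample_sets) || length(sample_sets) != length(times)) {
    stop("'sample_sets' and 'times' must have equal length", call. = FALSE)
  }
  if (is.unsorted(times)) {
    stop("'times' must be nondecreasing", call. = FALSE)
  }
  pcfs <- vector("list", length(times))
  n_mean <- n_se <- crossing <- numeric(length(times))
  direction <- character(length(times))
  for (i in seq_along(times)) {
    ss <- sample_sets[[i]]
    stopifnot(inherits(ss, "sample_set"))
    counts <- vapply(ss$samples, npoints, integer(1))
    n_mean[i] <- mean(counts)
    n_se[i] <- if (ss$N > 1L) sd(counts) / sqrt(ss$N) else 0
    pcfs[[i]] <- bin_pcf(average_pcf(ss), bandwidth)
    cr <- tryCatch(unity_crossing(pcfs[[i]], pixel_size = pixel_size),
                   error = function(e) NULL)
    crossing[i] <- if (is.null(cr)) NA_real_ else cr$crossing_pixels
    direction[i] <- if (is.null(cr)) NA_character_ else cr$direction
  }
  growth <- if (length(times) >= 3L) {
    fit_growth(times, n_mean, stderr = n_se)
  } else {
    NULL
  }
  structure(
    list(per_time = data.frame(time = times, n_mean = n_mean,
                               n_stderr = n_se, crossing = crossing,
                               direction = direction),
         pcfs = pcfs, growth = growth, bandwidth = as.integer(bandwidth)),
    class = "pcf_timeseries"
  )
}

#' @export
print.pcf_timeseries <- function(x, ...) {
  cat("Pair-correlation time series (bandwidth ", x$bandwidth, ")\n",
      sep = "")
  print(format(x$per_time, digits = 4), row.names = FALSE)
  if (!is.null(x$growth)) print(x$growth)
  invisible(x)
}
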