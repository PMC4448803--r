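#' Periodic pair-distance on a ring of length X
#'
#' The wrap-around separation of two 1-based lattice coordinates,
#' `min(|x1 - x2|, X - |x1 - x2|)`, which lies in `0:(X/2)`. The periodic
#' form is appropriate when the image window is cut from a much larger
#' domain, so its edges are not physical boundaries.
#'
#' @param x1,x2 coordinates in `1:X` (vectorised).
#' @param X lattice side length (even).
#' @return Integer distances in `0:(X/2)`.
#' @examples
#' periodic_distance(1, 99, 100)  # wraps to 2
#' @export
periodic_distance <- function(x1, x2, X) {
  X <- check_lattice_side(X)
  if (any(x1 < 1 | x1 > X | x2 < 1 | x2 > X)) {
    stop("coordinates must lie in [1, ", X, "]", call. = FALSE)
  }
  d <- abs(x1 - x2)
  as.integer(pmin(d, X - d))
}

#' Pair-distance counts along one axis
#'
#' Counts, over all unordered pairs of distinct objects, the periodic
#' pair-distance of their x (or y) coordinates. Self-pairs are never counted;
#' the counts over the support `0:(X/2)` always sum to `n(n-1)/2`.
#'
#' Implemented via the per-coordinate occupancy histogram rather than an
#' explicit double loop, which is exact and O(X^2).
#'
#' @param pattern a [point_pattern()] with at least two objects.
#' @param axis `"x"` or `"y"`.
#' @return Integer vector `c(delta)` indexed by `delta = 0:(X/2)`.
#' @export
pair_distance_counts <- function(pattern, axis = c("x", "y")) {
  stopifnot(inherits(pattern, "point_pattern"))
  axis <- match.arg(axis)
  n <- npoints(pattern)
  if (n < 2L) {
    stop("pair-correlation undefined for fewer than 2 objects",
         call. = FALSE)
  }
  X <- pattern$X
  tab <- tabulate(pattern[[axis]], nbins = X)
  half <- X %/% 2L
  counts <- numeric(half + 1L)
  counts[1L] <- sum(tab * (tab - 1)) / 2
  idx <- seq_len(X) - 1L
  for (d in seq_len(half)) {
    s <- sum(tab * tab[((idx + d) %% X) + 1L])
    counts[d + 1L] <- if (d == half) s / 2 else s
  }
  counts
}

# Expected-count denominator: d(delta) = 2 at the support endpoints
# {0, X/2}, where the periodic distance map is 1-to-1 rather than 2-to-1.
# At delta = 0 the asymptotic factor 2 leaves a residual (X-1)/X bias under
# uniform sampling of distinct lattice sites (a pair at the same x must
# occupy different rows); the extra X/(X-1) makes the expectation exactly 1
# at every distance, verified by exact enumeration over ordered pairs of
# distinct sites.
distance_multiplicity <- function(X) {
  half <- X %/% 2L
  d <- rep(1, half + 1L)
  d[1L] <- 2 * X / (X - 1)
  d[half + 1L] <- 2
  d
}

#' Directional periodic pair-correlation function
#'
#' Scales the pair-distance counts along one Cartesian axis by the counts
#' expected for objects placed uniformly at random on the lattice:
#' `P(delta) = c(delta) d(delta) (X^2 - 1) / (X n (n - 1))`, with
#' `d(delta) = 2` at `delta` in `{0, X/2}` and 1 otherwise. Under complete
#' spatial randomness `P` fluctuates about 1; values above 1 indicate
#' aggregation at that separation, below 1 segregation.
#'
#' @inheritParams pair_distance_counts
#' @return Numeric vector `P(delta)`, `delta = 0:(X/2)`.
#' @export
directional_pcf <- function(pattern, axis = c("x", "y")) {
  axis <- match.arg(axis)
  counts <- pair_distance_counts(pattern, axis)
  n <- npoints(pattern)
  X <- as.numeric(pattern$X)
  counts * distance_multiplicity(pattern$X) * (X^2 - 1) / (X * n * (n - 1))
}

#' Isotropic periodic pair-correlation of one sample
#'
#' For patterns with no directional bias, the mean of the x- and y-direction
#' signals: `f(delta) = (P_x(delta) + P_y(delta)) / 2`.
#'
#' @param pattern a [point_pattern()] with at least two objects.
#' @return Numeric vector `f(delta)`, `delta = 0:(X/2)`.
#' @export
isotropic_pcf <- function(pattern) {
  (directional_pcf(pattern, "x") + directional_pcf(pattern, "y")) / 2
}

new_pair_correlation <- function(X, bandwidth, values, stderr, N, per_sample,
                                 label = NULL) {
  nb <- length(values)
  j <- seq_len(nb) - 1L
  structure(
    list(X = X, bandwidth = as.integer(bandwidth), bin = j,
         centers = (j + 0.5) * bandwidth - 0.5,
         values = as.numeric(values), stderr = as.numeric(stderr),
         N = as.integer(N), per_sample = per_sample,
         total_error = mean(stderr), label = label),
    class = "pair_correlation"
  )
}

#' Average isotropic pair-correlation over replicate samples
#'
#' Computes the per-sample isotropic signals `f_i(delta)`, their mean across
#' the `N` samples, and the standard error of the mean,
#' `sigma(delta) = sqrt( sum_i (f_i - fbar)^2 / (N (N - 1)) )`,
#' zero by convention when `N = 1`. The per-sample signals are retained in
#' the result so that [bin_pcf()] can compute binned standard errors.
#'
#' @param samples a [sample_set()]; every sample needs at least 2 objects.
#' @return A `"pair_correlation"` object with bandwidth 1: fields `X`,
#'   `bandwidth`, `bin`, `centers` (here equal to `delta = 0:(X/2)`),
#'   `values`, `stderr`, `N`, `per_sample` (N-row matrix), `total_error`.
#' @seealso [bin_pcf()], [pcf_spectral()]
#' @export
average_pcf <- function(samples) {
  stopifnot(inherits(samples, "sample_set"))
  small <- which(vapply(samples$samples, npoints, integer(1)) < 2L)
  if (length(small)) {
    lab <- samples$samples[[small[1L]]]$label
    stop("sample ", small[1L],
         if (!is.null(lab)) paste0(" ('", lab, "')"),
         " has fewer than 2 objects", call. = FALSE)
  }
  per_sample <- t(vapply(samples$samples, isotropic_pcf,
                         numeric(samples$X / 2 + 1)))
  summarize_replicates(samples$X, 1L, per_sample, label = samples$label)
}

summarize_replicates <- function(X, bandwidth, per_sample, label = NULL) {
  N <- nrow(per_sample)
  values <- colMeans(per_sample)
  stderr <- if (N == 1L) {
    numeric(ncol(per_sample))
  } else {
    sqrt(colSums(sweep(per_sample, 2L, values)^2) / (N * (N - 1)))
  }
  new_pair_correlation(X, bandwidth, values, stderr, N, per_sample, label)
}

#' Box-kernel binned pair-correlation
#'
#' Smooths the unbinned signal with a box kernel of integer bandwidth
#' `Delta`: per sample, `F_i(j)` is the mean of `f_i(delta)` over
#' `delta = j Delta, ..., (j+1) Delta - 1`, for
#' `j = 0, ..., floor(X / (2 Delta) + 1 / Delta) - 1`; trailing distances
#' that do not fill a complete bin are dropped. The replicate mean and
#' standard error are then formed exactly as for the unbinned signal, so
#' `Delta = 1` reproduces the input.
#'
#' @param pc an unbinned (`bandwidth = 1`) `"pair_correlation"` from
#'   [average_pcf()], with per-sample signals present.
#' @param bandwidth integer `Delta >= 1`.
#' @return A `"pair_correlation"` object at the requested bandwidth; bin
#'   `j` is centred at `(j + 1/2) Delta - 1/2` on the distance axis.
#' @export
bin_pcf <- function(pc, bandwidth) {
  stopifnot(inherits(pc, "pair_correlation"))
  if (pc$bandwidth != 1L) {
    stop("'pc' must be an unbinned (bandwidth 1) pair-correlation",
         call. = FALSE)
  }
  if (length(bandwidth) != 1L || bandwidth < 1 || bandwidth != round(bandwidth)) {
    stop("'bandwidth' must be a single integer >= 1", call. = FALSE)
  }
  bandwidth <- as.integer(bandwidth)
  len <- pc$X %/% 2L + 1L
  if (bandwidth > len) {
    stop("bandwidth exceeds signal support (", len, " distances)",
         call. = FALSE)
  }
  if (bandwidth == 1L) return(pc)
  nb <- len %/% bandwidth
  binned <- vapply(seq_len(nb), function(j) {
    cols <- ((j - 1L) * bandwidth + 1L):(j * bandwidth)
    rowMeans(pc$per_sample[, cols, drop = FALSE])
  }, numeric(pc$N))
  if (pc$N == 1L) binned <- matrix(binned, nrow = 1L)
  summarize_replicates(pc$X, bandwidth, binned, label = pc$label)
}

#' Total error of a replicate-averaged signal
#'
#' The arithmetic mean of the per-distance (or per-bin) standard errors: a
#' single scalar summarising how noisy the averaged pair-correlation signal
#' is. It decays as the number of replicate samples grows.
#'
#' @param x a `"pair_correlation"` object, or a numeric vector of standard
#'   errors.
#' @return An `"error_summary"`: list with `total_error`, `N`, `bandwidth`.
#' @export
total_error <- function(x) {
  if (inherits(x, "pair_correlation")) {
    se <- x$stderr; N <- x$N; bw <- x$bandwidth
  } else {
    se <- as.numeric(x); N <- NA_integer_; bw <- NA_integer_
  }
  if (length(se) == 0L) stop("empty standard-error vector", call. = FALSE)
  structure(list(total_error = mean(se), N = N, bandwidth = bw),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat("Total error E =", format(x$total_error, digits = 4),
      if (!is.na(x$N)) paste0("(N = ", x$N, ", bandwidth = ", x$bandwidth, ")"),
      "\n")
  invisible(x)
}

#' @export
print.pair_correlation <- function(x, ...) {
  cat("Periodic pair-correlation",
      if (!is.null(x$label)) paste0(" '", x$label, "'"), "\n",
      "  X = ", x$X, ", N = ", x$N, " samples, bandwidth = ", x$bandwidth,
      "\n  ", length(x$values), " ",
      if (x$bandwidth == 1L) "distances" else "bins",
      ", total error = ", format(x$total_error, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pair_correlation <- function(x, se = TRUE,
                                  xlab = "distance (pixels)",
                                  ylab = if (x$bandwidth == 1L) "f" else "F",
                                  ...) {
  plot(x$centers, x$values, type = "o", pch = 16, cex = 0.5,
       xlab = xlab, ylab = ylab, ...)
  if (se && any(x$stderr > 0)) {
    arrows(x$centers, x$values - x$stderr, x$centers, x$values + x$stderr,
           angle = 90, code = 3, length = 0.02, col = grey(0.5))
  }
  abline(h = 1, lty = 2)
  invisible(x)
}

#' Export a pair-correlation signal as a data frame
#'
#' @param x a `"pair_correlation"` object.
#' @param ... unused.
#' @return A data frame with columns `delta_or_bin`, `center`, `value`,
#'   `stderr`.
#' @export
as.data.frame.pair_correlation <- function(x, ...) {
  data.frame(delta_or_bin = x$bin, center = x$centers,
             value = x$values, stderr = x$stderr)
}
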