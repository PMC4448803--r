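#' Symmetrize an unbinned pair-correlation signal
#'
#' Reflects `f(delta)`, `delta = 0:(X/2)`, into an even, 2*pi-periodic signal
#' on the grid `delta_l = -pi + 2*pi*l/X`, `l = 0:(X-1)`: position `l`
#' carries `f(|l - X/2|)`, so `l = X/2` holds `f(0)` and `l = 0` holds
#' `f(X/2)`. Evenness about `l = X/2` makes every Fourier coefficient real.
#'
#' @param pc an unbinned `"pair_correlation"`, or a numeric vector of length
#'   `X/2 + 1`.
#' @param X lattice side; required when `pc` is a bare vector.
#' @return Numeric vector of length `X`.
#' @export
symmetrize_pcf <- function(pc, X = NULL) {
  if (inherits(pc, "pair_correlation")) {
    if (pc$bandwidth != 1L) {
      stop("symmetrization requires the unbinned (bandwidth 1) signal",
           call. = FALSE)
    }
    X <- pc$X
    f <- pc$values
  } else {
    f <- as.numeric(pc)
    if (is.null(X)) X <- 2L * (length(f) - 1L)
  }
  if (length(f) != X / 2 + 1) {
    stop("signal length must be X/2 + 1 = ", X / 2 + 1, ", got ", length(f),
         call. = FALSE)
  }
  f[abs(seq.int(0L, X - 1L) - X %/% 2L) + 1L]
}

#' Discrete Fourier transform of the symmetrized signal
#'
#' Computes `fhat_k = (1 / (X c_k)) * sum_l ftilde(delta_l) exp(-i k delta_l)`
#' over the grid `delta_l = -pi + 2*pi*l/X`, with `c_k = 2` at `k = X/2` and
#' 1 otherwise, retaining `k = 0:(X/2)` (negative wavenumbers follow by
#' symmetry). For an even input the coefficients are real; `fhat_0` is the
#' signal mean. Internally the sum is evaluated with [stats::fft()] and
#' rescaled (the grid offset `-pi` contributes a factor `(-1)^k`).
#'
#' @param x a symmetric numeric signal of length `X` (from
#'   [symmetrize_pcf()]) or an unbinned `"pair_correlation"`, which is
#'   symmetrized first.
#' @return A `"pcf_spectrum"` object: fields `X`, `k` (`0:(X/2)`),
#'   `coefficients` (real `fhat_k`), `power` (`fhat_k^2`).
#' @seealso [dominant_wavenumbers()], [filtered_signal()]
#' @export
pcf_dft <- function(x) {
  if (inherits(x, "pair_correlation")) x <- symmetrize_pcf(x)
  ftilde <- as.numeric(x)
  X <- length(ftilde)
  if (X < 2L || X %% 2L != 0L) {
    stop("symmetrized signal must have even length X", call. = FALSE)
  }
  k <- seq.int(0L, X %/% 2L)
  ck <- ifelse(k == X %/% 2L, 2, 1)
  raw <- fft(ftilde)[k + 1L] * (-1)^k / (X * ck)
  if (max(abs(Im(raw))) > 1e-8 * max(1, max(abs(Re(raw))))) {
    warning("input not symmetric: imaginary parts of the spectrum are not negligible",
            call. = FALSE)
  }
  coef <- Re(raw)
  structure(list(X = as.integer(X), k = k, coefficients = coef,
                 power = coef^2),
            class = "pcf_spectrum")
}

#' Dominant wavenumbers of a power spectrum
#'
#' Identifies the spectral peaks that carry an oscillatory length scale:
#' strict interior local maxima of the power `|fhat_k|^2` over
#' `k = 1:(X/2)`, ranked by topographic prominence (the peak's height above
#' the higher of the saddles separating it from stronger peaks) and returned
#' strongest first, up to `max_modes` of them.
#'
#' `k = 0` (the signal mean) is always excluded. Ranking by prominence
#' rather than raw power matters because any net excess or deficit of pairs
#' at short range — the aggregation or segregation blip every structured
#' pattern has — contributes a smooth low-`k` envelope that decays from
#' `k = 1` and carries no oscillatory length scale. Sampling noise riding on
#' that shoulder produces local maxima whose raw power can rival a genuine
#' oscillation peak, but their prominence is only the noise height, whereas
#' an isolated peak rising from a quiet part of the spectrum keeps its full
#' height. Ties break toward smaller `k` (longer wavelength). A spectrum
#' with no interior peak yields an empty result with a warning.
#'
#' @param spec a `"pcf_spectrum"`.
#' @param max_modes maximum number of wavenumbers to return (default 2).
#' @return Integer vector of wavenumbers, possibly empty.
#' @export
dominant_wavenumbers <- function(spec, max_modes = 2L) {
  stopifnot(inherits(spec, "pcf_spectrum"))
  if (max_modes < 1L) stop("'max_modes' must be >= 1", call. = FALSE)
  p <- spec$power[spec$k >= 1L]
  m <- length(p)
  cand <- if (m < 3L) {
    integer(0)
  } else {
    which(p[2:(m - 1L)] > p[1:(m - 2L)] & p[2:(m - 1L)] > p[3:m]) + 1L
  }
  # ignore peaks at the level of floating-point jitter
  floor_p <- (1e-9 * max(abs(spec$coefficients)))^2
  cand <- cand[p[cand] > floor_p]
  if (length(cand) == 0L) {
    warning("no interior peak in the power spectrum: no dominant wavenumber",
            call. = FALSE)
    return(integer(0))
  }
  prominence <- vapply(cand, function(k) {
    higher_l <- which(p[seq_len(k - 1L)] > p[k])
    higher_r <- which(p[(k + 1L):m] > p[k]) + k
    saddle_l <- if (length(higher_l)) min(p[max(higher_l):k]) else min(p[1:k])
    saddle_r <- if (length(higher_r)) min(p[k:min(higher_r)]) else min(p[k:m])
    p[k] - max(saddle_l, saddle_r)
  }, numeric(1))
  cand <- cand[order(-prominence, cand)]
  as.integer(head(cand, max_modes))
}

#' Filtered pair-correlation signal
#'
#' Inverse transform restricted to the wavenumber set `{0, -k1, +k1}`. By
#' evenness of the symmetrized signal this reduces to the closed form
#' `f_K(d) = fhat_0 + 2 fhat_k1 cos(2 pi k1 d / X)`, a cosine of wavelength
#' `X / k1` about the signal mean, evaluated at arbitrary real distances.
#'
#' @param spec a `"pcf_spectrum"`.
#' @param k1 the retained wavenumber, `1 <= k1 <= X/2`.
#' @param delta numeric distances at which to evaluate (typically in
#'   `[0, X/2]`).
#' @return Numeric vector of filtered values.
#' @export
filtered_signal <- function(spec, k1, delta) {
  stopifnot(inherits(spec, "pcf_spectrum"))
  if (length(k1) != 1L || k1 < 1L || k1 > spec$X / 2 || k1 != round(k1)) {
    stop("'k1' must be an integer in [1, X/2]", call. = FALSE)
  }
  spec$coefficients[1L] +
    2 * spec$coefficients[k1 + 1L] * cos(2 * pi * k1 * delta / spec$X)
}

#' Wavelength of a wavenumber
#'
#' The length scale, in pixels, of spectral mode `k` on a window of side
#' `X`: `lambda = X / k`.
#'
#' @param k wavenumber(s), `k >= 1`.
#' @param X lattice side length.
#' @return Numeric wavelength(s).
#' @examples
#' wavelength(17, 100)  # 5.88
#' @export
wavelength <- function(k, X) {
  if (any(k == 0)) stop("no finite wavelength for k = 0", call. = FALSE)
  if (any(k < 0 | k != round(k))) {
    stop("'k' must be a positive integer", call. = FALSE)
  }
  X / k
}

#' Bandwidth from a dominant wavelength
#'
#' The box-kernel bandwidth is the dominant wavelength rounded to the
#' nearest integer (halves round up), so that one bin spans one period of
#' the strongest fluctuation in the unbinned signal.
#'
#' @param lambda wavelength in pixels, `lambda >= 0.5`.
#' @return Integer bandwidth `Delta >= 1`.
#' @examples
#' select_bandwidth(5.88)  # 6
#' select_bandwidth(7.5)   # 8
#' @export
select_bandwidth <- function(lambda) {
  if (any(!is.finite(lambda) | lambda <= 0)) {
    stop("'lambda' must be positive", call. = FALSE)
  }
  if (any(lambda < 0.5)) {
    stop("wavelength below 0.5 pixel would give bandwidth 0", call. = FALSE)
  }
  as.integer(floor(lambda + 0.5))
}

#' Spectral bandwidth-selection pipeline
#'
#' The full estimator: averages the isotropic periodic pair-correlation over
#' the replicate samples, symmetrizes it, takes the discrete Fourier
#' transform, finds the dominant wavenumbers of the power spectrum, converts
#' each to a wavelength `lambda = X/k` and a candidate bandwidth
#' `Delta = [lambda]`, and re-bins the signal at the chosen bandwidth.
#' When several modes are comparably strong all candidates are reported;
#' by default the strongest mode's bandwidth is adopted, and `bandwidth`
#' overrides that choice (e.g. using prior knowledge of the object size to
#' pick among candidates).
#'
#' @param samples a [sample_set()].
#' @param max_modes how many dominant modes to report (default 2).
#' @param bandwidth optional integer bandwidth overriding the selected one.
#' @return A `"pcf_analysis"` object: fields `pcf` (unbinned signal),
#'   `spectrum`, `candidates` (data frame `k`, `lambda`, `bandwidth`),
#'   `bandwidth` (the adopted value, or `NA` for a flat spectrum), `binned`
#'   (signal at the adopted bandwidth, or `NULL`), `X`, `N`.
#' @examples
#' cfg <- simulation_config(X = 40, s = 3, rho0 = 0.3, N = 4, seed = 1)
#' fit <- pcf_spectral(simulate_ensemble(cfg))
#' fit$candidates
#' @export
pcf_spectral <- function(samples, max_modes = 2L, bandwidth = NULL) {
  pc <- average_pcf(samples)
  spec <- pcf_dft(symmetrize_pcf(pc))
  dom <- dominant_wavenumbers(spec, max_modes)
  if (length(dom)) {
    lam <- wavelength(dom, pc$X)
    candidates <- data.frame(k = dom, lambda = lam,
                             bandwidth = select_bandwidth(lam))
  } else {
    candidates <- data.frame(k = integer(0), lambda = numeric(0),
                             bandwidth = integer(0))
  }
  chosen <- if (!is.null(bandwidth)) {
    as.integer(bandwidth)
  } else if (nrow(candidates)) {
    candidates$bandwidth[1L]
  } else {
    NA_integer_
  }
  binned <- if (!is.na(chosen) && chosen <= pc$X / 2 + 1) {
    bin_pcf(pc, chosen)
  } else {
    NULL
  }
  structure(
    list(pcf = pc, spectrum = spec, candidates = candidates,
         bandwidth = chosen, binned = binned, X = pc$X, N = pc$N),
    class = "pcf_analysis"
  )
}

#' @export
print.pcf_spectrum <- function(x, ...) {
  cat("Pair-correlation power spectrum (X = ", x$X, ", k = 0..", x$X / 2,
      ")\n", sep = "")
  dom <- suppressWarnings(dominant_wavenumbers(x, 2L))
  if (length(dom)) {
    cat("  dominant wavenumbers:",
        paste(sprintf("k=%d (lambda=%.2f)", dom, x$X / dom), collapse = ", "),
        "\n")
  } else {
    cat("  flat spectrum (no dominant wavenumber)\n")
  }
  invisible(x)
}

#' @export
plot.pcf_spectrum <- function(x, ...) {
  keep <- x$k >= 1L
  plot(x$k[keep], x$power[keep], type = "h",
       xlab = "wavenumber k", ylab = "power", ...)
  invisible(x)
}

#' @export
print.pcf_analysis <- function(x, ...) {
  cat("Spectral pair-correlation analysis\n",
      "  X = ", x$X, ", N = ", x$N, " samples\n", sep = "")
  if (nrow(x$candidates)) {
    cat("  candidate bandwidths:\n")
    print(format(x$candidates, digits = 4), row.names = FALSE)
    cat("  adopted bandwidth:", x$bandwidth, "\n")
  } else {
    cat("  flat spectrum: no bandwidth selected\n")
  }
  invisible(x)
}

#' @export
summary.pcf_analysis <- function(object, ...) {
  cross <- if (is.null(object$binned)) NULL else
    tryCatch(unity_crossing(object$binned), error = function(e) NULL)
  out <- list(X = object$X, N = object$N,
              candidates = object$candidates, bandwidth = object$bandwidth,
              total_error_unbinned = object$pcf$total_error,
              total_error_binned = if (!is.null(object$binned))
                object$binned$total_error else NA_real_,
              crossing = cross)
  class(out) <- "summary.pcf_analysis"
  out
}

#' @export
print.summary.pcf_analysis <- function(x, ...) {
  cat("Spectral pair-correlation analysis: X =", x$X, ", N =", x$N, "\n")
  if (nrow(x$candidates)) {
    cat("Candidate bandwidths (strongest mode first):\n")
    print(format(x$candidates, digits = 4), row.names = FALSE)
  }
  cat("Adopted bandwidth:", x$bandwidth, "\n")
  cat("Total error: unbinned", format(x$total_error_unbinned, digits = 4),
      "| binned", format(x$total_error_binned, digits = 4), "\n")
  if (!is.null(x$crossing)) {
    cat("Unity crossing at delta* =",
        format(x$crossing$crossing_pixels, digits = 4),
        "pixels (", x$crossing$direction, ")\n")
  }
  invisible(x)
}

#' @export
plot.pcf_analysis <- function(x, which = c("binned", "unbinned", "spectrum"),
                              ...) {
  which <- match.arg(which)
  if (which == "spectrum") {
    plot(x$spectrum, ...)
  } else if (which == "unbinned" || is.null(x$binned)) {
    plot(x$pcf, ...)
    if (nrow(x$candidates)) {
      d <- seq(0, x$X / 2, length.out = 200L)
      lines(d, filtered_signal(x$spectrum, x$candidates$k[1L], d), col = 2)
    }
  } else {
    plot(x$binned, ...)
  }
  invisible(x)
}
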