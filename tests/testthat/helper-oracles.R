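# Independent oracles used across the suite: brute-force double loops and
# direct-summation transforms, deliberately naive.

# pair-distance counts over all unordered pairs, explicit double loop
brute_counts <- function(pattern, axis) {
  v <- pattern[[axis]]
  X <- pattern$X
  n <- length(v)
  counts <- numeric(X / 2 + 1)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- abs(v[i] - v[j])
        d <- min(d, X - d)
        counts[d + 1] <- counts[d + 1] + 1
      }
    }
  }
  counts
}

brute_directional_pcf <- function(pattern, axis) {
  X <- pattern$X
  n <- length(pattern$x)
  d <- rep(1, X / 2 + 1)
  d[1] <- 2 * X / (X - 1)
  d[X / 2 + 1] <- 2
  brute_counts(pattern, axis) * d * (X^2 - 1) / (X * n * (n - 1))
}

# direct summation of the rescaled DFT, including the c_k convention
brute_dft <- function(ftilde) {
  X <- length(ftilde)
  l <- 0:(X - 1)
  grid <- -pi + 2 * pi * l / X
  vapply(0:(X / 2), function(k) {
    ck <- if (k == X / 2) 2 else 1
    Re(sum(ftilde * exp(-1i * k * grid))) / (X * ck)
  }, numeric(1))
}

# uniform random pattern on distinct lattice sites (CSR reference)
csr_pattern <- function(X, n) {
  sites <- sample.int(X * X, n)
  point_pattern((sites - 1) %% X + 1, (sites - 1) %/% X + 1, X = X)
}

# drop degenerate (n < 2) realizations from a simulated ensemble
prune_sparse <- function(ss) {
  keep <- vapply(ss$samples, npoints, integer(1)) >= 2L
  sample_set(ss$samples[keep], label = ss$label)
}
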