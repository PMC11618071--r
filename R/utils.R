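# shared internals: deterministic seed splitting and smooth random fields

#' Derive a stage-specific seed from a master seed
#'
#' All randomness in the package flows from one integer master seed; each
#' stage (or ensemble member, bootstrap replicate, ...) re-seeds from a
#' deterministic hash of the master seed and a stage label, so any stage can
#' be regenerated independently of the others. Results stay inside the
#' 32-bit signed integer range R requires of `set.seed()`.
#'
#' @param seed master integer seed.
#' @param label stage label (character) or counter (integer).
#' @return a derived integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, label) {
  h <- if (is.character(label)) sum(utf8ToInt(label) * seq_along(utf8ToInt(label))) else as.numeric(label)
  m <- 2147483647 # 2^31 - 1
  s <- (as.numeric(seed) %% m) * 48271 %% m
  as.integer((s + h * 69621 + 1) %% m)
}

# Smooth Gaussian random field on an nr x nc lattice: white noise convolved
# with a separable Gaussian kernel (sd = range_cells), then z-scored.
# Uses the current RNG stream.
smoothField <- function(nr, nc, range_cells = 6) {
  z <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (range_cells > 0) {
    kr <- kernelMatrix(nr, range_cells)
    kc <- kernelMatrix(nc, range_cells)
    z <- kr %*% z %*% t(kc)
  }
  (z - mean(z)) / stats::sd(z)
}

# Row-normalized Gaussian smoothing matrix (n x n); edge rows renormalize so
# the field has no systematic edge trend.
kernelMatrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-((i - j)^2) / (2 * sigma^2)))
  K / rowSums(K)
}

# clamp a numeric vector into [lo, hi]
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)
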