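# shared internal helpers: conditions, z-normalization, small numerics

abort_cb <- function(message, class, ...) {
  abort(message, class = c(class, "cbmapr_error"), ...)
}

#' z-normalize a numeric trace
#'
#' Centers to mean 0 and scales to unit standard deviation (sample sd).
#' Barcodes are always z-normalized per molecule so that Pearson matching is
#' invariant to illumination level and camera gain.
#'
#' @param x numeric vector.
#' @return numeric vector with mean 0 and sd 1.
#' @details A (near-)constant input has no barcode information; it is
#'   rejected with a classed error (`cbmapr_degenerate_barcode`).
#' @export
z_normalize <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 2)
  s <- sd(x)
  if (!is.finite(s) || s <= max(1e-12 * mean(abs(x)), 1e-300)) {
    abort_cb("trace is (near) constant: degenerate barcode",
             class = "cbmapr_degenerate_barcode")
  }
  (x - mean(x)) / s
}

# Gaussian smoothing of a 1D trace with a truncated, renormalized kernel
# (same edge policy as the theory barcode rendering).
gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n <- length(x)
  r <- ceiling(6 * sigma)
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  xp <- c(rep(0, r), x, rep(0, r))
  mp <- c(rep(0, r), rep(1, n), rep(0, r))
  num <- convolve(xp, k, type = "filter")
  den <- convolve(mp, k, type = "filter")
  num / den
}

# run `expr` under a fixed RNG seed, restoring RNG state afterwards
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed) %% .Machine$integer.max, expr)
}

# derive a reproducible child seed (kept below 2^31)
child_seed <- function(seed, i) {
  (as.double(seed) * 48271 + i * 16807) %% 2147483647
}
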