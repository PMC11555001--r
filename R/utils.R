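# Shared numeric helpers: seed splitting, FFT-based causal convolution on a
# uniform time grid, and separable Gaussian smoothing.

#' Derive a reproducible sub-seed
#'
#' All randomness in the package flows from one integer seed; sub-streams
#' (volume, slice, parameter map, noise realisation, ...) get their own seed
#' through this polynomial mixing function, so fixtures are stable across
#' runs and independent of evaluation order.
#'
#' @param seed Base integer seed.
#' @param ... Further integers identifying the sub-stream.
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.numeric(seed), as.numeric(unlist(list(...))))
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (p in parts) {
    # multiplier small enough that h * mult stays exact in doubles
    h <- (h * 69069 + (p %% m) + 12345) %% m
    h <- (h * 69069 + 1) %% m
  }
  as.integer(h)
}

# zero-padded FFT length for linear convolution of two length-n sequences
.conv_pad <- function(n) stats::nextn(2L * n - 1L, 2L)

#' Causal discrete convolution of row time courses with a kernel
#'
#' Computes `out[j, i] = dt * sum_{l=1..i} x[j, i - l + 1] * k[l]` for every
#' row of `x` — the rectangle-rule discretisation of a causal convolution on
#' a uniform grid with step `dt`.
#'
#' @param x Matrix `J x n` (rows are time courses) or a length-`n` vector.
#' @param k Kernel sampled on the same grid, length `n`.
#' @param dt Grid step (carried so results are step-size-consistent).
#' @return Same shape as `x`.
#' @export
causal_conv <- function(x, k, dt) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  stopifnot(length(k) == n)
  np <- .conv_pad(n)
  fk <- stats::fft(c(k, numeric(np - n)))
  fx <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), np - n))))
  out <- Re(stats::mvfft(fx * fk, inverse = TRUE)) / np
  out <- t(out)[, seq_len(n), drop = FALSE] * dt
  if (vec) drop(out) else out
}

#' Causal cross-correlation of row time courses with a kernel
#'
#' Computes `out[j, v] = dt * sum_{l} x[j, v + l - 1] * k[l]` — the adjoint
#' of [causal_conv()] with respect to its first argument.
#'
#' @inheritParams causal_conv
#' @return Same shape as `x`.
#' @export
causal_corr <- function(x, k, dt) {
  vec <- !is.matrix(x)
  if (vec) x <- matrix(x, nrow = 1)
  n <- ncol(x)
  stopifnot(length(k) == n)
  np <- .conv_pad(n)
  fk <- stats::fft(c(k, numeric(np - n)))
  fx <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), np - n))))
  out <- Re(stats::mvfft(fx * Conj(fk), inverse = TRUE)) / np
  out <- t(out)[, seq_len(n), drop = FALSE] * dt
  if (vec) drop(out) else out
}

# sum over rows of the lag cross-correlation between X and Y:
# out[l] = dt * sum_j sum_i X[j, i - l + 1] * Y[j, i]
# (the gradient of <Y, causal_conv(X, k)> with respect to the kernel k).
pairsum_corr <- function(x, y, dt) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(y)) y <- matrix(y, nrow = 1)
  n <- ncol(x)
  stopifnot(ncol(y) == n, nrow(x) == nrow(y))
  np <- .conv_pad(n)
  fx <- stats::mvfft(t(cbind(x, matrix(0, nrow(x), np - n))))
  fy <- stats::mvfft(t(cbind(y, matrix(0, nrow(y), np - n))))
  s <- rowSums(Conj(fx) * fy)
  out <- Re(stats::fft(s, inverse = TRUE)) / np
  out[seq_len(n)] * dt
}

# 1D Gaussian kernel with given sigma (in samples), truncated at 4 sigma
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing of a 2D matrix, replicate-padded borders
gaussian_smooth2d <- function(img, sigma_vox) {
  if (sigma_vox <= 0) return(img)
  k <- .gauss_kernel(sigma_vox)
  r <- (length(k) - 1L) / 2L
  smooth_1d <- function(m) {
    # convolve each column with k, replicate padding
    n <- nrow(m)
    idx <- c(rep(1L, r), seq_len(n), rep(n, r))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * mp[j:(j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(img))))
}

# positivity floor used in Poisson ratios / logs
.EPS <- 1e-12
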