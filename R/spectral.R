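# Spectral-analysis kinetic model: tracer-specific exponential temporal
# bases (isotope decay folded in, zero before injection), global generating
# functions, and the dual-tracer forward model f_D = H_D B_D c_D evaluated
# on a fine grid and integrated to the frame schedule.

#' Build a tracer-specific exponential temporal basis
#'
#' Rates are the union of 0 and `n_basis - 1` logarithmically spaced values
#' in `[rate_min, rate_max]`. Column `n` is
#' `exp(-(rate_n + lambda_iso) (t - tau))` for `t >= tau` and 0 before the
#' tracer's injection time `tau`: the isotope physical decay is folded into
#' the basis, so the generating function convolved with it is decay-free.
#'
#' @param tracer A [tracer_spec()].
#' @param t_fine Fine time grid (minutes).
#' @param n_basis Total number of basis functions (default 25, including
#'   the zero-rate column).
#' @param rate_min,rate_max Bounds of the log-spaced rates (1/min).
#' @return Object of class `temporal_basis`: `values`
#'   (`length(t_fine) x n_basis`), `rates` (sorted ascending, first 0),
#'   `tracer`, `t_fine`, `dt`.
#' @export
build_basis <- function(tracer, t_fine, n_basis = 25L,
                        rate_min = 0.001, rate_max = 5) {
  stopifnot(inherits(tracer, "tracer_spec"), n_basis >= 2,
            rate_min > 0, rate_min < rate_max)
  rates <- c(0, exp(seq(log(rate_min), log(rate_max),
                        length.out = n_basis - 1L)))
  tau <- tracer$injection_time_min
  u <- t_fine - tau
  on <- u >= 0
  vals <- vapply(rates, function(r) {
    v <- numeric(length(t_fine))
    v[on] <- exp(-(r + tracer$decay_const_per_min) * u[on])
    v
  }, numeric(length(t_fine)))
  structure(list(values = vals, rates = rates, tracer = tracer,
                 t_fine = t_fine, dt = t_fine[2] - t_fine[1]),
            class = "temporal_basis")
}

#' @export
print.temporal_basis <- function(x, ...) {
  cat(sprintf("<temporal_basis %s, %d functions, rates 0-%.3g/min>\n",
              x$tracer$name, length(x$rates), max(x$rates)))
  invisible(x)
}

#' Initialise a generating function
#'
#' Generating functions are indexed by lag since their tracer's injection
#' (the injection delay itself is folded into the basis, whose columns are
#' zero before the injection time). Initialisation is a vector of ones on
#' the lag grid; the multiplicative updates preserve nonnegativity and keep
#' any zero samples at zero.
#'
#' @param t_fine Fine time grid (its length sets the lag grid).
#' @return Vector of ones of length `length(t_fine)`.
#' @export
init_generating_function <- function(t_fine) {
  rep(1, length(t_fine))
}

#' Injection-aligned decayed arterial input
#'
#' The generating function for which the spectral model reproduces a
#' two-tissue compartment TAC: `h(s) = e^{-lambda s} Cp(s + tau)` with `s`
#' the lag since injection — the plasma input re-referenced to the
#' injection time and attenuated by physical decay (which the basis folds
#' in on its side).
#'
#' @param aif Plasma input sampled on `t_fine` (scan time, non-decayed).
#' @param tracer A [tracer_spec()].
#' @param t_fine Fine time grid.
#' @return Lag-grid generating function, same length as `t_fine`.
#' @export
aligned_decayed_aif <- function(aif, tracer, t_fine) {
  stopifnot(length(aif) == length(t_fine))
  tau <- tracer$injection_time_min
  shifted <- stats::approx(t_fine, aif, xout = t_fine + tau,
                           rule = 2)$y
  lag <- t_fine - t_fine[1]
  shifted * exp(-tracer$decay_const_per_min * lag)
}

#' Convolve per-voxel time courses with a generating function
#'
#' Causal rectangle-rule convolution `(Hx)(t) = dt * sum_{s<=t} x(t-s) h(s)`
#' applied to every row, linear in both arguments.
#'
#' @param x `J x length(t_fine)` matrix (or vector) of fine-grid courses.
#' @param h Generating function on the same grid.
#' @param dt Fine-grid step.
#' @return Same shape as `x`.
#' @export
convolve_generating <- function(x, h, dt) {
  n <- if (is.matrix(x)) ncol(x) else length(x)
  if (length(h) != n) stop("generating function does not match the time grid")
  causal_conv(x, h, dt)
}

#' Frame-domain response matrix of a convolved basis
#'
#' Precomputes `M[t, n]`, the frame-integrated convolution of basis column
#' `n` with the generating function `h`. Since `h` and the frame schedule
#' are shared across voxels, the framed forward model for coefficient
#' matrix `C` (`J x n_basis`) is simply `C %*% t(M)`.
#'
#' @param basis A [build_basis()] result.
#' @param h Generating function on the basis fine grid.
#' @param Fmat Frame integration matrix from [frame_integration_matrix()].
#' @return `T x n_basis` matrix.
#' @export
basis_frame_matrix <- function(basis, h, Fmat) {
  conv <- causal_conv(t(basis$values), h, basis$dt)  # n_basis x fine_T
  # mathematically nonnegative for nonnegative basis and h; clamp the
  # ~1e-16 FFT roundoff so multiplicative updates stay nonnegative
  pmax(Fmat %*% t(conv), 0)                          # T x n_basis
}

#' Dual-tracer spectral forward model
#'
#' Evaluates the framed single-tracer models `H (B c)` for both tracers and
#' their sum, the dual-tracer model.
#'
#' @param c_pair Named list `list(FDG = , MET = )` of `J x n_basis`
#'   nonnegative coefficient matrices.
#' @param h_pair Named list of generating functions on the fine grid.
#' @param bases Named list of [build_basis()] results.
#' @param Fmat Frame integration matrix.
#' @return List with framed `J x T` matrices `FDG`, `MET`, `dual`, and the
#'   response matrices `M` used.
#' @export
model_forward_dual <- function(c_pair, h_pair, bases, Fmat) {
  nm <- names(bases)
  M <- lapply(nm, function(n) basis_frame_matrix(bases[[n]], h_pair[[n]], Fmat))
  names(M) <- nm
  single <- lapply(nm, function(n) {
    stopifnot(ncol(c_pair[[n]]) == ncol(M[[n]]))
    c_pair[[n]] %*% t(M[[n]])
  })
  names(single) <- nm
  c(single, list(dual = single[[1]] + single[[2]], M = M))
}

#' Nonnegative least-squares spectral fit of framed TACs
#'
#' Fits frame-domain TACs on the convolved basis by nonnegative least
#' squares (Lawson-Hanson), the classical spectral-analysis estimator when
#' the generating function is known.
#'
#' @param tac Frame-value vector (length `T`) or `J x T` matrix.
#' @param basis A [build_basis()] result.
#' @param h Generating function (e.g. a decayed AIF) on the fine grid.
#' @param Fmat Frame integration matrix.
#' @return List with `coef` (nonnegative coefficients), `fitted` framed
#'   values and `rel_resid` (relative L2 residual per TAC).
#' @export
spectral_nnls_fit <- function(tac, basis, h, Fmat) {
  M <- basis_frame_matrix(basis, h, Fmat)
  one <- !is.matrix(tac)
  if (one) tac <- matrix(tac, nrow = 1)
  coef <- matrix(0, nrow(tac), ncol(M))
  fitted <- matrix(0, nrow(tac), ncol(tac))
  for (j in seq_len(nrow(tac))) {
    fit <- pracma::lsqnonneg(M, as.numeric(tac[j, ]))
    coef[j, ] <- fit$x
    fitted[j, ] <- as.numeric(M %*% fit$x)
  }
  rel <- sqrt(rowSums((fitted - tac)^2) / pmax(rowSums(tac^2), .EPS))
  if (one) list(coef = drop(coef), fitted = drop(fitted), rel_resid = rel)
  else list(coef = coef, fitted = fitted, rel_resid = rel)
}
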