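# Voxel-wise compartment-model fitting baselines: bounded weighted least
# squares of the single-tracer (v-STCM) or summed dual-tracer (v-MTCM)
# two-tissue compartment model against measured framed TACs, parametric-map
# recovery of activity images, net-influx-rate maps and Gaussian
# post-smoothing.

#' Voxel-wise fit configuration
#'
#' Defaults follow the weighted-least-squares protocol: frame durations as
#' weights, all parameters initialised at 0.01, lower bound 1e-11,
#' upper bounds `VB` 1, `K1` 5, `k2`-`k4` 1 (with `k2 <= 2`), relative
#' tolerance 1e-8 and at most 1600 iterations.
#'
#' @param init Initial value for every kinetic parameter.
#' @param lower Lower bound for every parameter.
#' @param upper Named upper bounds for `VB`, `K1`, `k2`, `k3`, `k4`.
#' @param rel_tol Relative-change stopping tolerance.
#' @param max_iter Maximum optimizer iterations.
#' @return Object of class `fit_config`.
#' @export
fit_config <- function(init = 0.01, lower = 1e-11,
                       upper = c(VB = 1, K1 = 5, k2 = 2, k3 = 1, k4 = 1),
                       rel_tol = 1e-8, max_iter = 1600L) {
  stopifnot(lower >= 0, all(upper > lower), rel_tol > 0, max_iter >= 1)
  structure(list(init = init, lower = lower, upper = upper,
                 rel_tol = rel_tol, max_iter = as.integer(max_iter)),
            class = "fit_config")
}

# framed model TAC of one tracer for a parameter vector (VB,K1,k2,k3[,k4])
.model_frames <- function(theta, tracer, aif, t_fine, Fmat, fit_k4) {
  p <- list(VB = theta[1], K1 = theta[2], k2 = theta[3], k3 = theta[4],
            k4 = if (fit_k4) theta[5] else 0)
  tac <- tissue_tac(p, tracer, aif, aif, t_fine)
  drop(Fmat %*% tac)
}

#' Voxel-wise bounded weighted least-squares compartment fitting
#'
#' Fits, per voxel, the framed two-tissue compartment model (irreversible
#' for FDG, reversible for MET) to measured frame TACs by bounded
#' Levenberg-Marquardt, minimising `sum_t w_t (model_t - data_t)^2` with
#' the frame durations as weights. With one AIF this is the single-tracer
#' fit (v-STCM); with two AIFs the dual-tracer model (the sum of the two
#' single-tracer models, each carrying its own injection delay and physical
#' decay) is fitted jointly (v-MTCM), with a separate blood-volume fraction
#' per tracer.
#'
#' @param dyn A [dynamic_image()] (or `J x T` matrix) of measured frames.
#' @param aifs Named list of fine-grid plasma inputs, one per fitted tracer.
#' @param tracers Named list of [tracer_spec()]s matching `aifs`.
#' @param t_fine Fine time grid of the AIFs.
#' @param schedule The [frame_schedule()] of `dyn`.
#' @param config A [fit_config()].
#' @param voxels Optional subset of voxel indices to fit (default: voxels
#'   with any signal).
#' @return Named list (per tracer) of parameter matrices (`J x 5`, columns
#'   `VB`, `K1`, `k2`, `k3`, `k4`), plus `fitted` (`J x T` model frames),
#'   `converged` (logical per fitted voxel) and `voxels`.
#' @export
fit_compartment_voxelwise <- function(dyn, aifs, tracers, t_fine, schedule,
                                      config = fit_config(), voxels = NULL) {
  m <- if (inherits(dyn, "dynamic_image")) dyn$values else as.matrix(dyn)
  Fmat <- frame_integration_matrix(schedule, t_fine)
  nm <- names(tracers)
  stopifnot(length(nm) %in% c(1L, 2L), all(nm %in% names(aifs)))
  fit_k4 <- vapply(nm, function(n) tracers[[n]]$name != "FDG", logical(1))
  npar <- ifelse(fit_k4, 5L, 4L)
  if (is.null(voxels)) voxels <- which(rowSums(m) > 0)
  w <- schedule$duration_min
  sw <- sqrt(w)
  theta0 <- rep(config$init, sum(npar))
  lower <- rep(config$lower, sum(npar))
  upper <- unlist(lapply(seq_along(nm), function(i) {
    u <- config$upper[c("VB", "K1", "k2", "k3", "k4")]
    if (!fit_k4[i]) u <- u[1:4]
    u
  }))
  blocks <- split(seq_len(sum(npar)), rep(seq_along(nm), npar))
  pars <- lapply(nm, function(n) {
    p <- matrix(config$lower, nrow(m), 5,
                dimnames = list(NULL, c("VB", "K1", "k2", "k3", "k4")))
    if (tracers[[n]]$name == "FDG") p[, "k4"] <- 0
    p
  })
  names(pars) <- nm
  fitted <- matrix(0, nrow(m), ncol(m))
  conv <- logical(length(voxels))
  model_all <- function(theta) {
    out <- 0
    for (i in seq_along(nm)) {
      out <- out + .model_frames(theta[blocks[[i]]], tracers[[nm[i]]],
                                 aifs[[nm[i]]], t_fine, Fmat, fit_k4[i])
    }
    out
  }
  # central-difference Jacobian: the reversible model's k4 sensitivity is
  # too weak for forward differences, which stall the fit in flat valleys
  jac_of <- function(resid_fn) {
    function(theta) {
      Jm <- matrix(0, schedule$T, length(theta))
      for (k in seq_along(theta)) {
        d <- max(1e-6, 1e-4 * abs(theta[k]))
        tp <- theta; tn <- theta
        tp[k] <- min(theta[k] + d, upper[k])
        tn[k] <- max(theta[k] - d, lower[k])
        Jm[, k] <- (resid_fn(tp) - resid_fn(tn)) / (tp[k] - tn[k])
      }
      Jm
    }
  }
  for (vi in seq_along(voxels)) {
    v <- voxels[vi]
    y <- m[v, ]
    if (any(!is.finite(y))) {
      warning("voxel ", v, " has non-finite data; filled with initial values")
      next
    }
    resid_fn <- function(theta) sw * (model_all(theta) - y)
    fit <- minpack.lm::nls.lm(
      par = theta0, lower = lower, upper = upper,
      fn = resid_fn, jac = jac_of(resid_fn),
      control = minpack.lm::nls.lm.control(
        maxiter = min(config$max_iter, 1024L),
        ptol = config$rel_tol, ftol = config$rel_tol))
    conv[vi] <- fit$info %in% 1:4
    th <- fit$par
    for (i in seq_along(nm)) {
      b <- th[blocks[[i]]]
      pars[[nm[i]]][v, seq_len(npar[i])] <- b
    }
    fitted[v, ] <- model_all(th)
  }
  list(params = pars, fitted = fitted, converged = conv, voxels = voxels)
}

#' Recover single-tracer activity images from parameter maps
#'
#' Regenerates framed single-tracer activity through the same two-tissue
#' compartment forward model used for simulation.
#'
#' @param params `J x 5` parameter matrix (columns `VB`, `K1`, `k2`, `k3`,
#'   `k4`) or a `kinetic_params` object.
#' @param tracer A [tracer_spec()].
#' @param aif Fine-grid plasma input.
#' @param t_fine Fine time grid.
#' @param schedule Target [frame_schedule()].
#' @param voxels Optional subset of voxels to evaluate.
#' @return `J x T` matrix of framed activity (zero rows elsewhere).
#' @export
recover_activity <- function(params, tracer, aif, t_fine, schedule,
                             voxels = NULL) {
  Fmat <- frame_integration_matrix(schedule, t_fine)
  if (inherits(params, "kinetic_params")) {
    J <- length(params$K1)
    getp <- function(v) voxel_params(params, v)
  } else {
    params <- as.matrix(params)
    J <- nrow(params)
    getp <- function(v) params[v, c("VB", "K1", "k2", "k3", "k4")]
  }
  if (is.null(voxels)) voxels <- seq_len(J)
  out <- matrix(0, J, schedule$T)
  for (v in voxels) {
    p <- getp(v)
    if (sum(p) == 0) next
    tac <- tissue_tac(as.list(p), tracer, aif, aif, t_fine)
    out[v, ] <- drop(Fmat %*% tac)
  }
  pmax(out, 0)
}

#' Net influx rate map
#'
#' `Ki = K1 k3 / (k2 + k3)`, zero where `k2 + k3 = 0`.
#'
#' @param params `J x 5` parameter matrix or `kinetic_params` object.
#' @return Numeric vector of `Ki` per voxel.
#' @export
ki_map <- function(params) {
  if (inherits(params, "kinetic_params")) {
    K1 <- as.numeric(params$K1); k2 <- as.numeric(params$k2)
    k3 <- as.numeric(params$k3)
  } else {
    params <- as.matrix(params)
    K1 <- params[, "K1"]; k2 <- params[, "k2"]; k3 <- params[, "k3"]
  }
  den <- k2 + k3
  unname(ifelse(den > 0, K1 * k3 / den, 0))
}

#' Gaussian post-smoothing of a dynamic image
#'
#' Per-frame 2D Gaussian smoothing with kernel standard deviation
#' `fwhm / (2 sqrt(2 log 2))` converted to voxels.
#'
#' @param dyn A [dynamic_image()].
#' @param fwhm_mm Full width at half maximum in millimetres (0 = identity).
#' @return Smoothed [dynamic_image()].
#' @export
gaussian_postsmooth <- function(dyn, fwhm_mm = 3) {
  stopifnot(inherits(dyn, "dynamic_image"), fwhm_mm >= 0)
  if (fwhm_mm == 0) return(dyn)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / dyn$grid$voxel_size_mm
  vals <- dyn$values
  for (k in seq_len(ncol(vals))) {
    img <- matrix(vals[, k], dyn$grid$nx, dyn$grid$ny)
    vals[, k] <- as.numeric(gaussian_smooth2d(img, sigma_vox))
  }
  dynamic_image(pmax(vals, 0), dyn$grid, dyn$schedule)
}
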