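# Tracer kinetics: Feng plasma input functions, closed-form two-tissue
# compartment time-activity curves with blood fraction and physical decay,
# and generation of single- and dual-tracer dynamic images.

#' Tracer specification
#'
#' Bundles the isotope half-life, the derived decay constant and the
#' injection time of one tracer. Defaults cover the dual-injection protocol:
#' [18F]FDG at 0 min (half-life 109.8 min) and [11C]MET at 5 min
#' (half-life 20.4 min).
#'
#' @param name `"FDG"` or `"MET"`, or any label when the remaining fields
#'   are given explicitly.
#' @param isotope_half_life_min Physical half-life in minutes.
#' @param injection_time_min Injection time relative to scan start, minutes.
#' @return Object of class `tracer_spec` with `name`, `isotope_half_life_min`,
#'   `decay_const_per_min` (`log(2)/half_life`) and `injection_time_min`.
#' @export
tracer_spec <- function(name,
                        isotope_half_life_min = switch(name, FDG = 109.8, MET = 20.4,
                                                       stop("unknown tracer: ", name)),
                        injection_time_min = switch(name, FDG = 0, MET = 5, 0)) {
  stopifnot(isotope_half_life_min > 0, injection_time_min >= 0)
  structure(list(name = name,
                 isotope_half_life_min = isotope_half_life_min,
                 decay_const_per_min = log(2) / isotope_half_life_min,
                 injection_time_min = injection_time_min),
            class = "tracer_spec")
}

#' Feng plasma input-function parameters
#'
#' The Feng model describes arterial plasma concentration after a bolus as
#' `Cp(t) = (A1 (t - tau) - A2 - A3) e^{l1 (t - tau)} + A2 e^{l2 (t - tau)}
#' + A3 e^{l3 (t - tau)}` for `t > tau` and 0 before; continuity at the
#' injection time `tau` is automatic. Shipped defaults are the canonical
#' Feng bolus shape rescaled so the curve peaks at `peak_amplitude`
#' (activity units are arbitrary here: the acquisition model sets absolute
#' count levels separately).
#'
#' @param tracer A [tracer_spec()]; sets the delay `tau`.
#' @param peak_amplitude Peak plasma activity (default 100, nominal kBq/mL).
#' @param A Amplitudes `c(A1, A2, A3)` before rescaling.
#' @param lambda Rates `c(l1, l2, l3)` in 1/min (all negative).
#' @return Object of class `feng_params`.
#' @export
feng_params <- function(tracer, peak_amplitude = 100,
                        A = c(851.1225, 21.8798, 20.8113),
                        lambda = c(-4.1339, -0.1191, -0.0104)) {
  stopifnot(inherits(tracer, "tracer_spec"), length(A) == 3, length(lambda) == 3)
  p <- structure(list(A = A, lambda = lambda,
                      delay = tracer$injection_time_min, scale = 1),
                 class = "feng_params")
  tt <- seq(0, 10, by = 0.001) + p$delay
  pk <- max(feng_aif(p, tt))
  if (pk <= 0) stop("Feng parameters yield a non-positive curve")
  p$scale <- peak_amplitude / pk
  p
}

#' Evaluate a Feng arterial input function
#'
#' @param params A [feng_params()] object.
#' @param t Sorted nonnegative time grid (minutes).
#' @return `Cp(t)`, zero for `t <= delay`; an error if the parameters
#'   produce negative values anywhere on the grid.
#' @export
feng_aif <- function(params, t) {
  stopifnot(inherits(params, "feng_params"))
  if (is.unsorted(t) || any(t < 0)) stop("time grid must be sorted and nonnegative")
  u <- t - params$delay
  A <- params$A; l <- params$lambda
  v <- ifelse(u > 0,
              (A[1] * u - A[2] - A[3]) * exp(l[1] * u) +
                A[2] * exp(l[2] * u) + A[3] * exp(l[3] * u),
              0)
  v <- v * params$scale
  if (any(v < -1e-9 * max(abs(v)))) stop("Feng parameters yield a negative AIF")
  pmax(v, 0)
}

#' Convolve a decaying exponential with a sampled input curve
#'
#' Computes `y(t) = int_0^t e^{-rate (t - s)} f(s) ds` on a uniform grid by
#' the exact recursion for piecewise-linear `f` — the workhorse for
#' two-tissue compartment responses.
#'
#' @param rate Nonnegative exponential rate (1/min).
#' @param f Input sampled on the grid.
#' @param dt Grid step (min).
#' @return Vector of the same length as `f`.
#' @export
exp_conv <- function(rate, f, dt) {
  n <- length(f)
  if (n < 2) return(numeric(n))
  a <- rate
  if (a * dt < 1e-10) {
    # rate ~ 0: plain trapezoid accumulation
    incr <- dt * (f[-n] + f[-1]) / 2
    return(c(0, cumsum(incr)))
  }
  e <- exp(-a * dt)
  # integral over one step of e^{-a s} * (linear f), s from 0 (at t+dt) to dt
  c1 <- (1 - e) / a                      # weight on f(t+dt)
  c2 <- (1 - e * (1 + a * dt)) / a^2     # weight on slope
  m <- (f[-1] - f[-n]) / dt
  b <- f[-1] * c1 - m * c2
  c(0, as.numeric(stats::filter(b, e, method = "recursive")))
}

# two-tissue compartment impulse-response coefficients:
# IRF(t) = K1 * (B1 e^{-a1 t} + B2 e^{-a2 t})
.tc2_irf_coef <- function(K1, k2, k3, k4) {
  s <- k2 + k3 + k4
  if (k4 < 1e-12) {            # irreversible limit, avoids 0/0
    a1 <- 0; a2 <- k2 + k3
    if (a2 < 1e-12) return(list(a = c(0, 0), B = c(K1, 0)))
    return(list(a = c(a1, a2), B = K1 * c(k3 / a2, k2 / a2)))
  }
  d <- sqrt(s^2 - 4 * k2 * k4)
  a1 <- (s - d) / 2; a2 <- (s + d) / 2
  if (d < 1e-12) return(list(a = c(a1, a2), B = K1 * c(1, 0)))
  B1 <- (k3 + k4 - a1) / (a2 - a1)
  B2 <- (a2 - k3 - k4) / (a2 - a1)
  list(a = c(a1, a2), B = K1 * c(B1, B2))
}

#' Continuous tissue time-activity curve of one voxel
#'
#' Two-tissue compartment response to a plasma input, mixed with whole-blood
#' signal through the fractional blood volume and attenuated by physical
#' isotope decay referenced to the tracer's injection time:
#' `C(t) = [(1 - VB) C_tissue(t) + VB C_blood(t)] e^{-lambda (t - tau)}` for
#' `t >= tau`, 0 before. `C_tissue` is the closed-form bi-exponential
#' impulse response convolved with the (non-decayed) plasma input.
#'
#' @param p Named vector/list with `K1`, `k2`, `k3`, `k4`, `VB` (all >= 0,
#'   `VB <= 1`; irreversible model when `k4 = 0`).
#' @param tracer A [tracer_spec()].
#' @param aif Plasma input sampled on `t` (non-decayed).
#' @param blood Whole-blood curve sampled on `t`; defaults to the plasma
#'   input (no plasma-to-blood correction).
#' @param t Uniform fine time grid (minutes).
#' @return The decayed total activity curve on `t`.
#' @export
tissue_tac <- function(p, tracer, aif, blood = aif, t) {
  p <- as.list(p)
  vals <- unlist(p[c("K1", "k2", "k3", "k4", "VB")])
  if (any(vals < 0)) stop("kinetic parameters must be nonnegative")
  if (p$VB > 1) stop("VB must be <= 1")
  stopifnot(length(aif) == length(t), length(blood) == length(t))
  dt <- t[2] - t[1]
  co <- .tc2_irf_coef(p$K1, p$k2, p$k3, p$k4)
  ct <- co$B[1] * exp_conv(co$a[1], aif, dt) +
        co$B[2] * exp_conv(co$a[2], aif, dt)
  tot <- (1 - p$VB) * ct + p$VB * blood
  tau <- tracer$injection_time_min
  dec <- exp(-tracer$decay_const_per_min * (t - tau)) * (t >= tau)
  pmax(tot * dec, 0)
}

#' Simulate single- and dual-tracer dynamic images for one phantom slice
#'
#' Per-voxel continuous TACs are built with [tissue_tac()] (input shifted to
#' each tracer's injection time), frame-integrated to the schedule, and the
#' dual-tracer image is the elementwise sum of the two single-tracer images.
#' Feng parameters are perturbed per call (amplitudes and rates drawn with
#' the given coefficient of variation, absolute values taken) to emulate
#' population variation in the input functions.
#'
#' @param param_maps Named list `list(FDG = , MET = )` of `kinetic_params`
#'   from [sample_parameter_maps()].
#' @param tracers Named list of [tracer_spec()]s (default FDG + MET).
#' @param schedule A [frame_schedule()].
#' @param grid The [image_grid()] of the parameter maps.
#' @param seed Integer seed for the AIF perturbation.
#' @param dt Fine-grid step in minutes.
#' @param aif_cov Coefficient of variation of the Feng parameter
#'   perturbation (0 disables it).
#' @param peak_amplitude Nominal AIF peak passed to [feng_params()].
#' @return List with `dynamic_image`s `FDG`, `MET`, `dual`, the sampled
#'   `aifs` (list of fine-grid curves), `t_fine` and the `feng` parameter
#'   objects used.
#' @export
simulate_dynamic_images <- function(param_maps, tracers = list(FDG = tracer_spec("FDG"),
                                                               MET = tracer_spec("MET")),
                                    schedule = default_frame_schedule(),
                                    grid, seed = 1L, dt = 0.05,
                                    aif_cov = 0.1, peak_amplitude = 100) {
  stopifnot(inherits(grid, "image_grid"))
  t_fine <- fine_time_grid(schedule, dt)
  Fmat <- frame_integration_matrix(schedule, t_fine)
  set.seed(derive_seed(seed, 409L))
  out <- list()
  aifs <- list(); fengs <- list()
  for (nm in names(tracers)) {
    tr <- tracers[[nm]]
    fp <- feng_params(tr, peak_amplitude = peak_amplitude)
    if (aif_cov > 0) {
      fp$A <- abs(stats::rnorm(3, fp$A, aif_cov * abs(fp$A)))
      fp$lambda <- -abs(stats::rnorm(3, fp$lambda, aif_cov * abs(fp$lambda)))
    }
    aif <- feng_aif(fp, t_fine)
    pm <- param_maps[[nm]]
    if (is.null(pm)) stop("missing parameter maps for tracer ", nm)
    J <- grid$J
    vals <- matrix(0, J, schedule$T)
    act <- which(pm$K1 > 0 | pm$VB > 0)
    for (j in act) {
      tac <- tissue_tac(voxel_params(pm, j), tr, aif, aif, t_fine)
      vals[j, ] <- drop(Fmat %*% tac)
    }
    out[[nm]] <- dynamic_image(pmax(vals, 0), grid, schedule)
    aifs[[nm]] <- aif; fengs[[nm]] <- fp
  }
  dual <- dynamic_image(out[[1]]$values + out[[2]]$values, grid, schedule)
  c(out, list(dual = dual, aifs = aifs, t_fine = t_fine, feng = fengs))
}
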