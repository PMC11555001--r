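# Procedural 2D brain phantoms: elliptical head, folded grey-matter ribbon,
# white-matter interior and a single randomly placed circular tumour, plus
# Gaussian-sampled kinetic parameter maps with smooth within-region
# heterogeneity.

#' Tissue label codes used in phantom label maps
#'
#' Background 0, white matter 1, grey matter 2, tumour 3.
#'
#' @return Named integer vector.
#' @export
tissue_labels <- function() {
  c(background = 0L, WM = 1L, GM = 2L, TM = 3L)
}

#' Mean kinetic parameters per tissue region and tracer
#'
#' Literature-based regional means for the irreversible (FDG, `k4 = 0`) and
#' reversible (MET) two-tissue compartment models. Units: `K1` cc/min/g,
#' `k2`-`k4` 1/min, `VB` unitless.
#'
#' @return A data frame with columns `tracer`, `region`, `K1`, `k2`, `k3`,
#'   `k4`, `VB`.
#' @export
kinetic_means <- function() {
  data.frame(
    tracer = rep(c("FDG", "MET"), each = 3),
    region = rep(c("WM", "GM", "TM"), 2),
    K1 = c(0.05, 0.10, 0.11, 0.04, 0.08, 0.13),
    k2 = c(0.11, 0.14, 0.10, 0.06, 0.08, 0.03),
    k3 = c(0.05, 0.17, 0.15, 0.04, 0.10, 0.06),
    k4 = c(0, 0, 0, 0.028, 0.017, 0.012),
    VB = c(0.026, 0.103, 0.173, 0.026, 0.103, 0.173),
    stringsAsFactors = FALSE
  )
}

# head/cortex geometry knobs for one synthetic "volume"; slices within a
# volume share these and vary only the slice-dependent perturbations
.sample_volume_geometry <- function(seed) {
  set.seed(seed)
  list(
    ax = stats::runif(1, 0.36, 0.42),     # head semi-axes, fraction of FOV
    ay = stats::runif(1, 0.40, 0.46),
    gm_thick = stats::runif(1, 0.10, 0.16),  # GM ribbon thickness, fraction of radius
    n_folds = sample(5:8, 1),                # cortical fold count
    fold_amp = stats::runif(1, 0.25, 0.45)   # fold amplitude as fraction of thickness
  )
}

#' Generate a 2D brain phantom label map
#'
#' Builds an elliptical head containing a sinusoidally folded grey-matter
#' ribbon (emulating cortex), white matter inside it, and one circular
#' tumour whose diameter is drawn uniformly between 12 and 18 mm and whose
#' centre is drawn uniformly over positions where the whole tumour disk fits
#' inside the brain. The tumour overwrites underlying tissue labels.
#'
#' @param grid An [image_grid()]; must be large enough to contain an 18 mm
#'   tumour.
#' @param seed Integer seed; the map is deterministic given `(grid, seed)`.
#' @param geometry Optional volume-level geometry list (shared by slices of
#'   the same synthetic volume); drawn from `seed` when `NULL`.
#' @param slice_index Slice index within the volume, perturbing the ribbon
#'   phase and thickness so slices of one volume differ.
#' @return Object of class `phantom_slice`: fields `grid`, `labels`
#'   (`nx x ny` integer matrix with codes from [tissue_labels()]),
#'   `tumour_diameter_mm`, `tumour_center_vox`, `seed`.
#' @export
make_label_map <- function(grid = image_grid(), seed = 1L, geometry = NULL,
                           slice_index = 1L) {
  stopifnot(inherits(grid, "image_grid"))
  vox <- grid$voxel_size_mm
  fov <- c(grid$nx, grid$ny) * vox
  if (min(fov) < 2 * 18) {
    stop("grid too small to contain an 18 mm tumour inside the brain")
  }
  if (is.null(geometry)) geometry <- .sample_volume_geometry(derive_seed(seed, 101L))
  set.seed(derive_seed(seed, 211L, slice_index))

  # voxel-centre coordinates (mm), origin at grid centre
  xs <- (seq_len(grid$nx) - (grid$nx + 1) / 2) * vox
  ys <- (seq_len(grid$ny) - (grid$ny + 1) / 2) * vox
  X <- matrix(xs, grid$nx, grid$ny)
  Y <- matrix(ys, grid$nx, grid$ny, byrow = TRUE)

  ax <- geometry$ax * fov[1]; ay <- geometry$ay * fov[2]
  theta <- atan2(Y / ay, X / ax)
  rho <- sqrt((X / ax)^2 + (Y / ay)^2)   # normalised elliptical radius

  phase <- stats::runif(1, 0, 2 * pi)
  thick <- geometry$gm_thick * (1 + stats::runif(1, -0.2, 0.2))
  ribbon_in <- 1 - thick * (1 + geometry$fold_amp *
                              sin(geometry$n_folds * theta + phase))

  labels <- matrix(tissue_labels()[["background"]], grid$nx, grid$ny)
  labels[rho <= 1] <- tissue_labels()[["GM"]]
  labels[rho <= ribbon_in] <- tissue_labels()[["WM"]]

  # tumour: diameter U[12, 18] mm, centre uniform over voxels whose full
  # disk lies inside the brain mask
  diam <- stats::runif(1, 12, 18)
  rad <- diam / 2
  brain <- labels > 0
  margin <- rho <= (1 - rad / min(ax, ay))  # conservative inner margin
  cand <- which(margin & brain)
  if (length(cand) == 0) stop("no admissible tumour centre inside the brain")
  ctr <- cand[sample.int(length(cand), 1)]
  ci <- arrayInd(ctr, dim(labels))
  d2 <- (X - xs[ci[1]])^2 + (Y - ys[ci[2]])^2
  labels[d2 <= rad^2] <- tissue_labels()[["TM"]]

  structure(list(grid = grid, labels = labels,
                 tumour_diameter_mm = diam,
                 tumour_center_vox = as.integer(ci),
                 seed = as.integer(seed)),
            class = "phantom_slice")
}

#' @export
print.phantom_slice <- function(x, ...) {
  cat(sprintf("<phantom_slice %dx%d, tumour %.1f mm, seed %d>\n",
              x$grid$nx, x$grid$ny, x$tumour_diameter_mm, x$seed))
  invisible(x)
}

#' Draw regional parameter values around their configured means
#'
#' One draw per replicate: Gaussian with the given mean and standard
#' deviation `cov * mean`, with the absolute value taken after sampling.
#'
#' @param mean Regional mean value.
#' @param cov Coefficient of variation (default 0.1).
#' @param n Number of draws.
#' @return Numeric vector of `n` nonnegative draws.
#' @export
sample_regional_value <- function(mean, cov = 0.1, n = 1L) {
  abs(stats::rnorm(n, mean, cov * mean))
}

# smooth multiplicative heterogeneity field: Gaussian-smoothed white noise
# (sigma = 2 voxels) scaled to +-`amp` amplitude
.heterogeneity_field <- function(nx, ny, sigma_vox = 2, amp = 0.1) {
  z <- matrix(stats::rnorm(nx * ny), nx, ny)
  s <- gaussian_smooth2d(z, sigma_vox)
  m <- max(abs(s))
  if (m == 0) return(matrix(1, nx, ny))
  1 + amp * s / m
}

#' Sample kinetic parameter maps for one phantom slice and tracer
#'
#' Each region's parameters are drawn once per slice from a Gaussian around
#' the regional mean (sd = `cov * mean`, absolute value taken), then
#' multiplied by a smooth within-region heterogeneity field (Gaussian-
#' smoothed white noise, sigma 2 voxels, +-10% amplitude, independent per
#' parameter). FDG `k4` is identically zero (irreversible model); all
#' outputs are nonnegative; background voxels are zero.
#'
#' @param slice A `phantom_slice`.
#' @param tracer `"FDG"` or `"MET"`.
#' @param cov Coefficient of variation of the regional draws.
#' @param seed Integer seed.
#' @param means Optional override for [kinetic_means()].
#' @return Object of class `kinetic_params`: list of `nx x ny` matrices
#'   `K1`, `k2`, `k3`, `k4`, `VB`, plus `tracer` and `regional` (the drawn
#'   per-region values).
#' @export
sample_parameter_maps <- function(slice, tracer, cov = 0.1, seed = 1L,
                                  means = kinetic_means()) {
  stopifnot(inherits(slice, "phantom_slice"))
  if (!tracer %in% c("FDG", "MET")) stop("unknown tracer id: ", tracer)
  tab <- means[means$tracer == tracer, , drop = FALSE]
  rownames(tab) <- tab$region
  lbl <- tissue_labels()
  nx <- slice$grid$nx; ny <- slice$grid$ny
  pars <- c("K1", "k2", "k3", "k4", "VB")
  maps <- stats::setNames(lapply(pars, function(p) matrix(0, nx, ny)), pars)
  regional <- list()
  set.seed(derive_seed(seed, 307L, match(tracer, c("FDG", "MET"))))
  for (reg in c("WM", "GM", "TM")) {
    mask <- slice$labels == lbl[[reg]]
    vals <- vapply(pars, function(p) {
      mu <- tab[reg, p]
      if (mu == 0 || cov == 0) return(mu)  # exact mean when degenerate
      sample_regional_value(mu, cov, 1L)
    }, numeric(1))
    regional[[reg]] <- vals
    for (p in pars) {
      if (vals[[p]] == 0) next
      het <- .heterogeneity_field(nx, ny)
      maps[[p]][mask] <- abs(vals[[p]] * het[mask])
    }
  }
  if (tracer == "FDG") maps$k4[] <- 0
  maps$VB <- pmin(maps$VB, 1)
  structure(c(maps, list(tracer = tracer, regional = regional,
                         seed = as.integer(seed))),
            class = "kinetic_params")
}

#' Extract the kinetic parameters of one voxel
#'
#' @param params A `kinetic_params` object.
#' @param voxel Linear voxel index (column-major over the grid).
#' @return Named numeric vector `K1`, `k2`, `k3`, `k4`, `VB`.
#' @export
voxel_params <- function(params, voxel) {
  vapply(c("K1", "k2", "k3", "k4", "VB"),
         function(p) params[[p]][voxel], numeric(1))
}

#' Build a library of phantom slices
#'
#' Emulates a multi-subject dataset: `n_volumes` synthetic head geometries,
#' each sliced `slices_per_volume` times with slice-dependent cortical
#' perturbations and independently placed tumours.
#'
#' @param n_volumes Number of synthetic volumes (default 20).
#' @param slices_per_volume Slices per volume (default 5).
#' @param seed Integer seed.
#' @param grid Shared [image_grid()].
#' @return List of `n_volumes * slices_per_volume` `phantom_slice` objects;
#'   each carries `volume` and `slice_index` attributes.
#' @export
build_phantom_library <- function(n_volumes = 20L, slices_per_volume = 5L,
                                  seed = 1L, grid = image_grid()) {
  stopifnot(n_volumes >= 1, slices_per_volume >= 1)
  out <- vector("list", n_volumes * slices_per_volume)
  idx <- 1L
  for (v in seq_len(n_volumes)) {
    geom <- .sample_volume_geometry(derive_seed(seed, 101L, v))
    for (s in seq_len(slices_per_volume)) {
      sl <- make_label_map(grid, seed = derive_seed(seed, v, s),
                           geometry = geom, slice_index = s)
      attr(sl, "volume") <- v
      attr(sl, "slice_index") <- s
      out[[idx]] <- sl
      idx <- idx + 1L
    }
  }
  out
}

#' Brain mask of a phantom slice
#'
#' @param slice A `phantom_slice`.
#' @return Logical `nx x ny` matrix, `TRUE` inside the head.
#' @export
brain_mask <- function(slice) slice$labels > 0

#' Tumour mask of a phantom slice
#'
#' @param slice A `phantom_slice`.
#' @return Logical `nx x ny` matrix, `TRUE` in the tumour.
#' @export
tumour_mask <- function(slice) slice$labels == tissue_labels()[["TM"]]
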