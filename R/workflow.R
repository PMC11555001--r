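# End-to-end experiment orchestration: simulate phantoms, generate dynamic
# images, acquire and reconstruct noise realisations, separate with the
# requested methods, and tabulate bias / SD / NRMSE against the noise-free
# single-tracer MLEM references.

#' Experiment configuration
#'
#' The `desk` profile bounds every stage for interactive use and testing
#' (small grids, few realisations); the `full` profile mirrors the
#' 128 x 128, 20-realisation study design.
#'
#' @param profile `"desk"` or `"full"`.
#' @param n_phantoms Number of phantom slices to simulate.
#' @param n_realisations Noise realisations per phantom.
#' @param methods Character subset of `c("vSTCM", "vMTCM", "ISF4D")`.
#' @param seed Master seed.
#' @param grid_nx Grid side (desk default 32, full 128).
#' @param n_iter_mlem MLEM iterations per frame.
#' @param n_outer_isf4d IS-F4D outer cycles.
#' @param target_total_counts Expected counts per dual-tracer scan.
#' @param dt Fine-grid step (minutes).
#' @param schedule Frame schedule; the desk profile uses the condensed
#'   10-frame schedule ([desk_frame_schedule()]), the full profile the
#'   27-frame protocol.
#' @param out_dir Output directory (`NULL`: nothing written).
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(profile = c("desk", "full"),
                              n_phantoms = if (profile == "desk") 2L else 100L,
                              n_realisations = if (profile == "desk") 3L else 20L,
                              methods = c("vSTCM"),
                              seed = 1L,
                              grid_nx = if (profile == "desk") 32L else 128L,
                              n_iter_mlem = if (profile == "desk") 32L else 128L,
                              n_outer_isf4d = if (profile == "desk") 50L else 1600L,
                              target_total_counts = 5e6,
                              dt = if (profile == "desk") 0.25 else 0.05,
                              schedule = if (profile == "desk")
                                desk_frame_schedule() else default_frame_schedule(),
                              out_dir = NULL) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    stopifnot(grid_nx <= 64, n_realisations <= 5, schedule$T <= 27)
  }
  structure(list(profile = profile, n_phantoms = as.integer(n_phantoms),
                 n_realisations = as.integer(n_realisations),
                 methods = methods, seed = as.integer(seed),
                 grid_nx = as.integer(grid_nx),
                 n_iter_mlem = as.integer(n_iter_mlem),
                 n_outer_isf4d = as.integer(n_outer_isf4d),
                 target_total_counts = target_total_counts, dt = dt,
                 schedule = schedule,
                 out_dir = out_dir),
            class = "experiment_config")
}

#' Condensed 10-frame desk-profile schedule
#'
#' Covers the same 50-minute dual-injection window with fewer frames
#' (short frames after each injection at 0 and 5 minutes), trading temporal
#' resolution for speed in interactive runs and tests.
#'
#' @return A [frame_schedule()] with 10 frames totalling 50 minutes.
#' @export
desk_frame_schedule <- function() {
  frame_schedule(c(0.5, 1.5, 3, 0.5, 1.5, 3, 5, 10, 10, 15))
}

#' Stable hash of an experiment configuration
#'
#' @param cfg An [experiment_config()] (or any list).
#' @return Character hash; changes iff the configuration changes.
#' @export
config_hash <- function(cfg) {
  rlang::hash(jsonlite::toJSON(.strip_classes(cfg), digits = NA,
                               auto_unbox = TRUE, null = "null"))
}

# recursively drop S3 classes so configs serialise as plain JSON
.strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), .strip_classes) else unclass(x)
}

#' Simulate one complete example (phantom, images, reconstructions)
#'
#' Generates a phantom slice with parameter maps for both tracers, the
#' single- and dual-tracer dynamic images, and the MLEM reconstructions:
#' noise-free references plus `n_realisations` noisy realisations of the
#' dual and single-tracer acquisitions.
#'
#' @param cfg An [experiment_config()].
#' @param index Phantom index (drives the seed split).
#' @return List with `slice`, `maps`, `sim` (true images and AIFs),
#'   `system`, `ref` (noise-free single-tracer MLEM), and `noisy` (list of
#'   realisations: `dual`, `FDG`, `MET` reconstructions).
#' @export
simulate_example <- function(cfg, index = 1L) {
  grid <- image_grid(cfg$grid_nx, cfg$grid_nx,
                     voxel_size_mm = 2.602 * 128 / cfg$grid_nx)
  sl <- make_label_map(grid, seed = derive_seed(cfg$seed, 11L, index))
  maps <- list(
    FDG = sample_parameter_maps(sl, "FDG", seed = derive_seed(cfg$seed, 13L, index)),
    MET = sample_parameter_maps(sl, "MET", seed = derive_seed(cfg$seed, 17L, index)))
  sim <- simulate_dynamic_images(maps, schedule = cfg$schedule,
                                 grid = grid,
                                 seed = derive_seed(cfg$seed, 19L, index),
                                 dt = cfg$dt)
  n_ang <- max(16L, as.integer(round(cfg$grid_nx * 180 / 128)))
  n_rad <- as.integer(ceiling(sqrt(2) * cfg$grid_nx / 2) * 2 + 4L)
  system <- system_model(grid, n_angles = n_ang, n_radial_bins = n_rad,
                         mu_mask = brain_mask(sl))
  acq0 <- acquisition_config(cfg$target_total_counts, seed = 0L)
  ref <- list(
    FDG = simulate_acquisition(sim$FDG, system, acq0, cfg$n_iter_mlem,
                               noise = FALSE)$recon,
    MET = simulate_acquisition(sim$MET, system, acq0, cfg$n_iter_mlem,
                               noise = FALSE)$recon)
  noisy <- lapply(seq_len(cfg$n_realisations), function(r) {
    sd <- derive_seed(cfg$seed, 23L, index, r)
    list(
      dual = simulate_acquisition(sim$dual, system,
                                  acquisition_config(cfg$target_total_counts,
                                                     seed = sd),
                                  cfg$n_iter_mlem)$recon,
      FDG = simulate_acquisition(sim$FDG, system,
                                 acquisition_config(cfg$target_total_counts / 2,
                                                    seed = derive_seed(sd, 1L)),
                                 cfg$n_iter_mlem)$recon,
      MET = simulate_acquisition(sim$MET, system,
                                 acquisition_config(cfg$target_total_counts / 2,
                                                    seed = derive_seed(sd, 2L)),
                                 cfg$n_iter_mlem)$recon)
  })
  list(slice = sl, maps = maps, sim = sim, system = system, ref = ref,
       noisy = noisy)
}

# separate one noisy dual reconstruction with one method
.separate_with <- function(method, rec, ex, cfg) {
  schedule <- rec$schedule
  t_fine <- ex$sim$t_fine
  if (method == "vMTCM") {
    tracers <- list(FDG = tracer_spec("FDG"), MET = tracer_spec("MET"))
    fit <- fit_compartment_voxelwise(rec, ex$sim$aifs, tracers, t_fine,
                                     schedule)
    list(FDG = recover_activity(fit$params$FDG, tracers$FDG, ex$sim$aifs$FDG,
                                t_fine, schedule, fit$voxels),
         MET = recover_activity(fit$params$MET, tracers$MET, ex$sim$aifs$MET,
                                t_fine, schedule, fit$voxels))
  } else if (method == "ISF4D") {
    bases <- list(FDG = build_basis(tracer_spec("FDG"), t_fine),
                  MET = build_basis(tracer_spec("MET"), t_fine))
    res <- run_isf4d(rec, bases, schedule,
                     f4d_config(n_outer = cfg$n_outer_isf4d))
    res$images
  } else stop("unknown separation method: ", method)
}

#' Run a configured experiment end to end
#'
#' For every phantom: simulate, reconstruct, separate each noisy dual
#' realisation with each requested method (plus `vSTCM` applied to the
#' noisy single-tracer reconstructions as the single-tracer baseline), and
#' compute voxel-level and tumour-ROI metrics against the noise-free
#' single-tracer MLEM references.
#'
#' @param cfg An [experiment_config()].
#' @return List with `metrics` (data frame: phantom, method, tracer, bias,
#'   sd, nrmse, roi_nrmse) and `manifest` (seeds, config hash, versions).
#'   When `cfg$out_dir` is set, metrics CSV, manifest JSON and the
#'   reference images are written there.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  for (ix in seq_len(cfg$n_phantoms)) {
    ex <- simulate_example(cfg, ix)
    tm <- as.logical(tumour_mask(ex$slice))
    brain <- as.logical(brain_mask(ex$slice))
    schedule <- ex$ref$FDG$schedule
    t_fine <- ex$sim$t_fine
    for (method in unique(c("vSTCM", cfg$methods))) {
      for (tr in c("FDG", "MET")) {
        stacks <- vector("list", cfg$n_realisations)
        for (r in seq_len(cfg$n_realisations)) {
          if (method == "vSTCM") {
            tsp <- tracer_spec(tr)
            fit <- fit_compartment_voxelwise(
              ex$noisy[[r]][[tr]], ex$sim$aifs[tr],
              stats::setNames(list(tsp), tr), t_fine, schedule,
              voxels = which(brain))
            stacks[[r]] <- recover_activity(fit$params[[tr]], tsp,
                                            ex$sim$aifs[[tr]], t_fine,
                                            schedule, fit$voxels)
          } else {
            sep <- .separate_with(method, ex$noisy[[r]]$dual, ex, cfg)
            stacks[[r]] <- sep[[tr]]
          }
        }
        vox <- voxel_bias_sd_nrmse(stacks, ex$ref[[tr]]$values, mask = brain)
        roi <- roi_tac_nrmse(do.call(rbind, lapply(stacks, extract_roi_tac,
                                                   roi_mask = tm)),
                             extract_roi_tac(ex$ref[[tr]], tm))
        rows[[length(rows) + 1L]] <- data.frame(
          phantom = ix, method = method, tracer = tr,
          bias = vox$bias, sd = vox$sd, nrmse = vox$nrmse,
          roi_nrmse = roi$aggregate[["nrmse"]])
      }
    }
  }
  metrics <- do.call(rbind, rows)
  manifest <- list(config = .strip_classes(cfg), config_hash = config_hash(cfg),
                   package_version = tryCatch(
                     as.character(utils::packageVersion("mpetsep")),
                     error = function(e) "dev"),
                   r_version = R.version.string)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         digits = NA, auto_unbox = TRUE)
  }
  list(metrics = metrics, manifest = manifest)
}
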