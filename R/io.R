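# File interchange: dynamic images and maps as NIfTI with JSON sidecars,
# frame schedules as JSON, AIF curves and basis matrices as CSV.

#' Write a frame schedule to JSON
#'
#' @param schedule A [frame_schedule()].
#' @param path Output file.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(list(start_min = schedule$start_min,
                            duration_min = schedule$duration_min),
                       path, digits = NA)
  invisible(path)
}

#' Read a frame schedule from JSON
#'
#' @param path JSON file with `start_min` and `duration_min` arrays.
#' @return A [frame_schedule()].
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  frame_schedule(x$duration_min, x$start_min)
}

#' Write a dynamic image as 4D NIfTI plus schedule sidecar
#'
#' The 2D slice series is stored as `nx x ny x 1 x T`; the voxel size goes
#' into the NIfTI header and the schedule into `<path>.json`.
#'
#' @param dyn A [dynamic_image()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @export
write_dynamic_image <- function(dyn, path) {
  stopifnot(inherits(dyn, "dynamic_image"))
  arr <- array(dyn$values, c(dyn$grid$nx, dyn$grid$ny, 1, dyn$schedule$T))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(dyn$grid$voxel_size_mm, dyn$grid$voxel_size_mm, 1, 1)
  RNifti::writeNifti(img, path)
  write_schedule_json(dyn$schedule, paste0(path, ".json"))
  invisible(path)
}

#' Read a dynamic image written by [write_dynamic_image()]
#'
#' @param path The `.nii`/`.nii.gz` path (sidecar `<path>.json` required).
#' @return A [dynamic_image()].
#' @export
read_dynamic_image <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  schedule <- read_schedule_json(paste0(path, ".json"))
  grid <- image_grid(d[1], d[2], RNifti::pixdim(img)[1])
  dynamic_image(matrix(img, grid$J, schedule$T), grid, schedule)
}

#' Write phantom label and parameter maps as NIfTI with a JSON sidecar
#'
#' @param slice A `phantom_slice`.
#' @param param_maps Named list of `kinetic_params` (one per tracer).
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(slice, param_maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vox <- slice$grid$voxel_size_mm
  wr <- function(mat, name) {
    arr <- array(mat, c(slice$grid$nx, slice$grid$ny, 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vox, vox, 1)
    RNifti::writeNifti(img, file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(slice$labels, "labels")
  for (nm in names(param_maps)) {
    pm <- param_maps[[nm]]
    for (p in c("K1", "k2", "k3", "k4", "VB")) wr(pm[[p]], paste0(nm, "_", p))
  }
  jsonlite::write_json(
    list(seed = slice$seed, tumour_diameter_mm = slice$tumour_diameter_mm,
         voxel_size_mm = vox,
         regional = lapply(param_maps, function(p) p$regional),
         table_means = kinetic_means()),
    file.path(dir, "phantom.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' Write an AIF curve as two-column CSV
#'
#' @param t_min Time grid (minutes).
#' @param aif Activity values.
#' @param path Output CSV path.
#' @export
write_aif_csv <- function(t_min, aif, path) {
  utils::write.csv(data.frame(t_min = t_min, activity = aif), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an AIF curve from two-column CSV
#'
#' @param path CSV with columns `t_min`, `activity`.
#' @return List with `t_min` and `activity`.
#' @export
read_aif_csv <- function(path) {
  x <- utils::read.csv(path)
  list(t_min = x[[1]], activity = x[[2]])
}

#' Export a temporal basis as CSV
#'
#' First column is the fine time grid; remaining columns are the basis
#' functions, named by decay rate.
#'
#' @param basis A [build_basis()] result.
#' @param path Output CSV path.
#' @export
write_basis_csv <- function(basis, path) {
  df <- data.frame(t_min = basis$t_fine, basis$values)
  names(df)[-1] <- sprintf("rate_%.6g", basis$rates)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
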