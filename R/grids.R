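#' Image grid for 2D PET slices
#'
#' Defines the square-voxel sampling grid that phantoms, dynamic images and
#' the acquisition model share. The default matches a 128 x 128 brain slice
#' with 2.602 mm voxels.
#'
#' @param nx,ny Voxel counts along x and y (>= 8).
#' @param voxel_size_mm Edge length of the square voxels in millimetres.
#' @return An object of class `image_grid` with fields `nx`, `ny`,
#'   `voxel_size_mm` and the voxel count `J = nx * ny`.
#' @export
#' @examples
#' g <- image_grid(64, 64)
#' g$J
image_grid <- function(nx = 128L, ny = 128L, voxel_size_mm = 2.602) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  stopifnot(nx >= 8L, ny >= 8L, voxel_size_mm > 0)
  structure(list(nx = nx, ny = ny, voxel_size_mm = voxel_size_mm,
                 J = nx * ny),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid %d x %d, voxel %.3f mm>\n", x$nx, x$ny, x$voxel_size_mm))
  invisible(x)
}

#' Dynamic scan frame schedule
#'
#' A contiguous sequence of time frames, stored as start times and durations
#' in minutes. Frame values throughout the package are frame-length-corrected
#' (mean activity rate over the frame), so schedules carry the information
#' needed both for integration and for count scaling.
#'
#' @param duration_min Frame durations in minutes (all > 0).
#' @param start_min Optional frame start times; defaults to the cumulative
#'   sums of `duration_min` starting at 0. Frames must be contiguous.
#' @return Object of class `frame_schedule` with `start_min`, `duration_min`,
#'   `end_min`, `mid_min` and frame count `T`.
#' @export
frame_schedule <- function(duration_min, start_min = NULL) {
  duration_min <- as.numeric(duration_min)
  stopifnot(length(duration_min) >= 1, all(duration_min > 0))
  if (is.null(start_min)) {
    start_min <- cumsum(c(0, duration_min[-length(duration_min)]))
  }
  start_min <- as.numeric(start_min)
  stopifnot(length(start_min) == length(duration_min))
  if (length(start_min) > 1) {
    gaps <- abs(start_min[-1] - (start_min[-length(start_min)] +
                                   duration_min[-length(duration_min)]))
    if (any(gaps > 1e-9)) stop("frame schedule must be contiguous")
  }
  structure(list(start_min = start_min,
                 duration_min = duration_min,
                 end_min = start_min + duration_min,
                 mid_min = start_min + duration_min / 2,
                 T = length(duration_min)),
            class = "frame_schedule")
}

#' Default 27-frame, 50-minute dual-injection protocol
#'
#' Frames: 4 x 0.25, 2 x 0.5, 3 x 1, 4 x 0.25, 2 x 0.5, 3 x 1, 2 x 2,
#' 2 x 3, 4 x 5, 1 x 10 minutes. The second group of short frames starts at
#' 5 min, the injection time of the second tracer.
#'
#' @return A `frame_schedule` with 27 frames totalling 50 minutes.
#' @export
default_frame_schedule <- function() {
  frame_schedule(c(rep(0.25, 4), rep(0.5, 2), rep(1, 3),
                   rep(0.25, 4), rep(0.5, 2), rep(1, 3),
                   rep(2, 2), rep(3, 2), rep(5, 4), 10))
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule %d frames, %.4g-%.4g min>\n",
              x$T, x$start_min[1], x$end_min[x$T]))
  invisible(x)
}

#' Fine time grid covering a frame schedule
#'
#' @param schedule A `frame_schedule`.
#' @param dt Step in minutes (default 0.05, resolving the shortest default
#'   frame with 5 samples).
#' @return Numeric vector `seq(start, end, by = dt)`.
#' @export
fine_time_grid <- function(schedule, dt = 0.05) {
  stopifnot(inherits(schedule, "frame_schedule"), dt > 0)
  t0 <- schedule$start_min[1]
  t1 <- schedule$end_min[schedule$T]
  n <- round((t1 - t0) / dt)
  if (abs(n * dt - (t1 - t0)) > 1e-8)
    stop("dt must divide the scan duration")
  seq(t0, t1, length.out = n + 1L)
}

# Trapezoid quadrature weights for the integral of a piecewise-linear function
# sampled at `t` over the window [a, b]; a, b may fall between samples.
integration_weights <- function(t, a, b) {
  n <- length(t)
  w <- numeric(n)
  if (b <= t[1] || a >= t[n]) stop("integration window outside the time grid")
  if (a < t[1] - 1e-9 || b > t[n] + 1e-9) stop("integration window outside the time grid")
  a <- max(a, t[1]); b <- min(b, t[n])
  for (i in seq_len(n - 1)) {
    lo <- max(a, t[i]); hi <- min(b, t[i + 1])
    if (hi <= lo) next
    h <- t[i + 1] - t[i]
    # integral over [lo,hi] of linear interp = sum of endpoint weights
    u0 <- (lo - t[i]) / h; u1 <- (hi - t[i]) / h
    len <- hi - lo
    # weight on f(t[i]):   int (1-u) du * h ; on f(t[i+1]): int u du * h
    w[i]     <- w[i]     + len * (1 - (u0 + u1) / 2)
    w[i + 1] <- w[i + 1] + len * ((u0 + u1) / 2)
  }
  w
}

#' Frame integration matrix
#'
#' Builds the linear map from a fine-grid time course to frame-length-
#' corrected frame values: row `k` holds trapezoid weights over frame `k`
#' divided by its duration, so applying it yields the mean rate per frame.
#'
#' @param schedule A `frame_schedule`.
#' @param t_fine Fine time grid covering all frames.
#' @return A `T x length(t_fine)` dense matrix.
#' @export
frame_integration_matrix <- function(schedule, t_fine) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (schedule$start_min[1] < t_fine[1] - 1e-9 ||
      schedule$end_min[schedule$T] > t_fine[length(t_fine)] + 1e-9)
    stop("fine grid does not cover the frame schedule")
  Fmat <- matrix(0, schedule$T, length(t_fine))
  for (k in seq_len(schedule$T)) {
    Fmat[k, ] <- integration_weights(t_fine, schedule$start_min[k],
                                     schedule$end_min[k]) /
      schedule$duration_min[k]
  }
  Fmat
}

#' Integrate a continuous time course into frame values
#'
#' Frame value = (1/duration) * integral of the (piecewise-linear) time
#' course over the frame — the frame-length-corrected convention.
#'
#' @param x Numeric vector (one time course) or a `J x length(t_fine)`
#'   matrix of time courses in rows.
#' @param t_fine Fine time grid.
#' @param schedule A `frame_schedule` covered by `t_fine`.
#' @return Frame values: vector of length `T` or a `J x T` matrix.
#' @export
frame_integrate <- function(x, t_fine, schedule) {
  Fmat <- frame_integration_matrix(schedule, t_fine)
  if (is.matrix(x)) {
    stopifnot(ncol(x) == length(t_fine))
    x %*% t(Fmat)
  } else {
    stopifnot(length(x) == length(t_fine))
    drop(Fmat %*% x)
  }
}

#' Dynamic image container
#'
#' Voxel-by-frame activity (mean rate per frame) with its grid and schedule.
#'
#' @param values `J x T` matrix, nonnegative.
#' @param grid An `image_grid` with `J = nx * ny` voxels.
#' @param schedule A `frame_schedule` with `T` frames.
#' @return Object of class `dynamic_image`.
#' @export
dynamic_image <- function(values, grid, schedule) {
  stopifnot(inherits(grid, "image_grid"), inherits(schedule, "frame_schedule"))
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$J, ncol(values) == schedule$T)
  if (any(values < 0)) stop("dynamic image values must be nonnegative")
  structure(list(values = values, grid = grid, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  cat(sprintf("<dynamic_image %d voxels x %d frames (%d x %d grid)>\n",
              nrow(x$values), ncol(x$values), x$grid$nx, x$grid$ny))
  invisible(x)
}

#' Extract one frame of a dynamic image as a 2D matrix
#'
#' @param dyn A `dynamic_image`.
#' @param frame Frame index.
#' @return `nx x ny` matrix.
#' @export
frame_image <- function(dyn, frame) {
  stopifnot(inherits(dyn, "dynamic_image"))
  matrix(dyn$values[, frame], dyn$grid$nx, dyn$grid$ny)
}
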