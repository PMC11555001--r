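test_that("projection of a uniform disk matches the chord-length oracle", {
  grid <- image_grid(64, 64, voxel_size_mm = 2)
  sys <- system_model(grid, n_angles = 8L, n_radial_bins = 96L)
  xs <- (seq_len(64) - 32.5) * 2
  X <- matrix(xs, 64, 64); Y <- t(X)
  rad <- 40
  img <- (X^2 + Y^2 <= rad^2) * 1.5
  sino <- forward_project(img, sys)
  s <- (seq_len(96) - 48.5) * sys$bin_width_mm
  chord <- ifelse(abs(s) < rad, 2 * sqrt(pmax(rad^2 - s^2, 0)), 0) * 1.5
  prof <- matrix(sino, 96, 8)
  inside <- abs(s) < 0.8 * rad
  for (a in seq_len(8)) {
    rel_l2 <- sqrt(sum((prof[inside, a] - chord[inside])^2) /
                     sum(chord[inside]^2))
    expect_lt(rel_l2, 0.03)
    expect_lt(max(abs(prof[inside, a] - chord[inside])) / max(chord), 0.10)
  }
  # zero image projects to zero; attenuation only removes counts
  expect_equal(forward_project(img * 0, sys), numeric(length(sino)))
  sys_mu <- system_model(grid, 8L, 96L, mu_mask = img > 0)
  expect_true(all(forward_project(img, sys_mu) <= sino + 1e-12))
})

test_that("projector and backprojector are exact adjoints", {
  grid <- image_grid(32, 32, voxel_size_mm = 4)
  sys <- system_model(grid, n_angles = 12L, n_radial_bins = 52L,
                      mu_mask = matrix(TRUE, 32, 32))
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(grid$J)
    y <- rnorm(nrow(sys$A))
    lhs <- sum(forward_project(x, sys) * y)
    rhs <- sum(x * back_project(y, sys))
    expect_lt(abs(lhs - rhs) / max(abs(lhs), 1e-12), 1e-10)
  }
})

test_that("count scaling hits the target total with the configured background", {
  pr <- list(schedule = frame_schedule(c(1, 2, 2)))
  sinos <- list(rep(2, 50), rep(3, 50), rep(1, 50))
  cfg <- acquisition_config(1e5, background_fraction = 0.2, seed = 3L)
  out <- apply_counts_and_noise(sinos, pr$schedule, cfg)
  grand <- sum(vapply(out$mean, sum, numeric(1)))
  expect_equal(grand, 1e5)
  bg_total <- sum(out$background * 50)
  expect_equal(bg_total / grand, 0.2)
  out2 <- apply_counts_and_noise(sinos, pr$schedule, cfg)
  expect_identical(out$noisy, out2$noisy)  # deterministic given seed
  expect_error(apply_counts_and_noise(lapply(sinos, function(x) x * 0),
                                      pr$schedule, cfg), "zero total")
})

test_that("MLEM converges to the true image on an invertible toy system", {
  # two voxels, two rays with weights forming an invertible matrix
  grid <- image_grid(8, 8, 50)
  A <- Matrix::sparseMatrix(i = c(1, 1, 2, 2), j = c(1, 2, 1, 2),
                            x = c(1, 0.3, 0.25, 1), dims = c(2, grid$J))
  sys <- structure(list(A = A, att = rep(1, 2), grid = grid,
                        n_angles = 1L, n_radial_bins = 2L,
                        bin_width_mm = 1, mu_map = NULL),
                   class = "system_model")
  x_true <- numeric(grid$J); x_true[1:2] <- c(4, 7)
  y <- as.numeric(A %*% x_true)
  rec <- mlem_reconstruct(y, sys, n_iter = 10000L)
  expect_lt(sqrt(sum((rec$image[1:2] - x_true[1:2])^2) / sum(x_true^2)), 1e-6)
})

test_that("MLEM increases the Poisson likelihood and conserves counts", {
  grid <- image_grid(16, 16, 8)
  sys <- system_model(grid, n_angles = 12L, n_radial_bins = 28L)
  set.seed(8)
  img <- matrix(0, 16, 16); img[5:12, 5:12] <- runif(64, 1, 3)
  y <- rpois(nrow(sys$A), forward_project(img, sys))
  rec <- mlem_reconstruct(y, sys, n_iter = 60L, track_loglik = TRUE)
  expect_true(all(diff(rec$loglik) > -1e-8 * abs(rec$loglik[-1])))
  # count conservation: total modelled counts equal measured counts
  expect_equal(sum(forward_project(rec$image, sys)), sum(y),
               tolerance = 1e-8)
  expect_true(all(rec$image >= 0))
})

test_that("frame-by-frame reconstruction flags empty frames and restores rates", {
  grid <- image_grid(16, 16, voxel_size_mm = 2.602 * 8)
  sl <- make_label_map(grid, seed = 5L)
  maps <- list(FDG = sample_parameter_maps(sl, "FDG", seed = 1L),
               MET = sample_parameter_maps(sl, "MET", seed = 2L))
  sim <- simulate_dynamic_images(maps, grid = grid, seed = 1L, dt = 0.25,
                                 schedule = desk_frame_schedule())
  sys <- system_model(grid, n_angles = 16L, n_radial_bins = 28L,
                      mu_mask = brain_mask(sl))
  acq <- simulate_acquisition(sim$dual, sys, acquisition_config(2e5, seed = 1L),
                              n_iter = 30L)
  rec <- acq$recon
  expect_s3_class(rec, "dynamic_image")
  expect_true(all(rec$values >= 0))
  # reconstructed activity is on the same scale as the truth (brain mean)
  b <- as.logical(brain_mask(sl))
  ratio <- mean(rec$values[b, ]) / mean(sim$dual$values[b, ])
  expect_gt(ratio, 0.7); expect_lt(ratio, 1.3)
  # an all-zero frame yields a zero image and a warning
  sinos <- acq$sinos$noisy
  sinos[[2]] <- sinos[[2]] * 0L
  expect_warning(
    rec2 <- mlem_reconstruct_series(sinos, sys, sim$dual$schedule,
                                    acq$sinos$scale,
                                    background = acq$sinos$background,
                                    n_iter = 5L),
    "zero counts")
  expect_true(all(rec2$values[, 2] == 0))
})
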