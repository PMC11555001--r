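test_that("Feng input functions are causal, continuous and single-peaked", {
  pr <- fx_protocol()
  tr <- tracer_spec("MET")
  fp <- feng_params(tr)
  aif <- feng_aif(fp, pr$t_fine)
  expect_true(all(aif[pr$t_fine <= tr$injection_time_min] == 0))
  # continuity at injection: the curve tends to 0 as t -> tau+
  td <- seq(0, 50, by = 0.001)
  v <- feng_aif(fp, td)
  expect_lt(v[which(td > 5)[1]], 0.01 * max(v))
  tpk <- td[which.max(v)]
  expect_lt(tpk - tr$injection_time_min, 2)
  expect_gt(tpk, tr$injection_time_min)
  expect_true(all(v >= 0))
})

test_that("2TC tissue curves match a Runge-Kutta oracle", {
  skip_if_not_installed("deSolve")
  pr <- fx_protocol()
  trs <- fx_tracers()
  for (nm in c("FDG", "MET")) {
    tr <- trs$specs[[nm]]
    aif <- trs$aifs[[nm]]
    km <- kinetic_means()
    p <- km[km$tracer == nm & km$region == "GM", ]
    pars <- c(K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, VB = p$VB)
    tac <- tissue_tac(pars, tr, aif, aif, pr$t_fine)
    cpf <- stats::approxfun(pr$t_fine, aif, rule = 2)
    deriv <- function(t, y, parms) {
      list(c(pars[["K1"]] * cpf(t) - (pars[["k2"]] + pars[["k3"]]) * y[1] +
               pars[["k4"]] * y[2],
             pars[["k3"]] * y[1] - pars[["k4"]] * y[2]))
    }
    sol <- deSolve::ode(c(0, 0), pr$t_fine, deriv, NULL, method = "ode45",
                        atol = 1e-10, rtol = 1e-10)
    ct <- sol[, 2] + sol[, 3]
    dec <- ifelse(pr$t_fine >= tr$injection_time_min,
                  exp(-tr$decay_const_per_min *
                        (pr$t_fine - tr$injection_time_min)), 0)
    ref <- ((1 - pars[["VB"]]) * ct + pars[["VB"]] * aif) * dec
    expect_lt(sqrt(sum((tac - ref)^2) / sum(ref^2)), 1e-3)
  }
})

test_that("degenerate kinetic parameters give the expected limits", {
  pr <- fx_protocol()
  trs <- fx_tracers()
  tr <- trs$specs$FDG; aif <- trs$aifs$FDG
  zero <- tissue_tac(c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, VB = 0),
                     tr, aif, aif, pr$t_fine)
  expect_true(all(zero == 0))
  blood <- tissue_tac(c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, VB = 1),
                      tr, aif, aif, pr$t_fine)
  expect_equal(blood, aif * exp(-tr$decay_const_per_min * pr$t_fine))
  expect_error(tissue_tac(c(K1 = -1, k2 = 0, k3 = 0, k4 = 0, VB = 0),
                          tr, aif, aif, pr$t_fine), "nonnegative")
})

test_that("pure-blood voxels decay at the isotope rate between late frames", {
  pr <- fx_protocol()
  tr <- tracer_spec("MET")
  # constant unit blood pool: framed activity must follow e^{-lambda t}
  blood <- rep(1, length(pr$t_fine))
  tac <- tissue_tac(c(K1 = 0, k2 = 0, k3 = 0, k4 = 0, VB = 1),
                    tr, blood * 0, blood, pr$t_fine)
  fr <- frame_integrate(tac, pr$t_fine, pr$schedule)
  k1 <- 24; k2 <- 26
  dtmid <- pr$schedule$mid_min[k2] - pr$schedule$mid_min[k1]
  expect_equal(log(fr[k1] / fr[k2]) / dtmid, tr$decay_const_per_min,
               tolerance = 1e-3)
})

test_that("dual-tracer images satisfy additivity and the injection delay", {
  grid <- image_grid(16, 16, voxel_size_mm = 2.602 * 8)
  sl <- make_label_map(grid, seed = 2L)
  maps <- list(FDG = sample_parameter_maps(sl, "FDG", seed = 1L),
               MET = sample_parameter_maps(sl, "MET", seed = 2L))
  sim <- simulate_dynamic_images(maps, grid = grid, seed = 1L, dt = 0.25)
  expect_equal(sim$dual$values, sim$FDG$values + sim$MET$values)
  expect_true(all(sim$FDG$values >= 0) && all(sim$MET$values >= 0))
  # MET contributes nothing to frames ending before its 5-min injection
  sch <- sim$dual$schedule
  pre <- which(sch$end_min <= 5)
  expect_true(all(sim$MET$values[, pre] == 0))
  # deterministic in the seed
  sim2 <- simulate_dynamic_images(maps, grid = grid, seed = 1L, dt = 0.25)
  expect_identical(sim$dual$values, sim2$dual$values)
})

test_that("exponential convolution matches the analytic exponential kernel", {
  t <- seq(0, 10, by = 0.01)
  a <- 0.7; b <- 0.1
  y <- exp_conv(a, exp(-b * t), 0.01)
  analytic <- (exp(-b * t) - exp(-a * t)) / (a - b)
  expect_lt(max(abs(y - analytic)), 1e-4 * max(analytic))
  # zero-rate limit accumulates the trapezoid integral
  y0 <- exp_conv(0, t, 0.01)
  expect_equal(y0, t^2 / 2, tolerance = 1e-10)
})
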