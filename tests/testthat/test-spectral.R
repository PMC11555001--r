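test_that("temporal bases have the configured rates, decay and delays", {
  pr <- fx_protocol()
  bases <- fx_bases()
  for (nm in c("FDG", "MET")) {
    b <- bases[[nm]]
    expect_equal(ncol(b$values), 25L)
    expect_equal(b$rates[1], 0)
    expect_equal(length(b$rates), 25L)
    expect_equal(min(b$rates[-1]), 0.001)
    expect_equal(max(b$rates), 5)
    expect_true(all(diff(b$rates) > 0))
    expect_true(all(b$values >= 0))
  }
  # zero-rate FDG column decays at the pure isotope half-life
  bF <- build_basis(tracer_spec("FDG"), seq(0, 220, by = 0.05))
  i <- which.min(abs(seq(0, 220, by = 0.05) - 109.8))
  expect_equal(bF$values[i, 1], 0.5, tolerance = 1e-6)
  # MET columns are all zero before the 5-min injection
  bM <- bases$MET
  expect_true(all(bM$values[pr$t_fine < 5, ] == 0))
  expect_true(all(bM$values[pr$t_fine == 4.9 + 0.1, ][1] >= 0))
})

test_that("causal convolution behaves like a discrete convolution operator", {
  n <- 200; dt <- 0.05
  t <- (seq_len(n) - 1) * dt
  x <- matrix(exp(-0.5 * t), 1)
  # identity kernel: a unit impulse of height 1/dt at lag zero
  ident <- c(1 / dt, numeric(n - 1))
  expect_equal(convolve_generating(x, ident, dt), x, tolerance = 1e-12)
  # nonnegative inputs give nonnegative outputs
  set.seed(2)
  xr <- matrix(abs(rnorm(3 * n)), 3)
  hr <- abs(rnorm(n))
  expect_true(all(convolve_generating(xr, hr, dt) >= 0))
  # exponential x exponential against the closed form (rectangle rule is
  # first order, so the comparison runs on a finer grid)
  dt2 <- 0.005; t2 <- seq(0, 10, by = dt2)
  a <- 0.8; b <- 0.25
  got <- convolve_generating(matrix(exp(-a * t2), 1), exp(-b * t2), dt2)
  want <- (exp(-b * t2) - exp(-a * t2)) / (a - b)
  expect_lt(max(abs(got - want)) / max(want), 0.01)
  expect_error(convolve_generating(x, hr[-1], dt), "match")
})

test_that("adjoint identities of the convolution helpers hold", {
  set.seed(3)
  n <- 64; dt <- 0.2
  x <- matrix(rnorm(5 * n), 5)
  y <- matrix(rnorm(5 * n), 5)
  k <- rnorm(n)
  # <conv(x,k), y> == <x, corr(y,k)>
  expect_equal(sum(causal_conv(x, k, dt) * y),
               sum(x * causal_corr(y, k, dt)), tolerance = 1e-10)
  # <conv(x,k), y> == <k, pairsum_corr(x, y)>
  expect_equal(sum(causal_conv(x, k, dt) * y),
               sum(k * mpetsep:::pairsum_corr(x, y, dt)), tolerance = 1e-10)
})

test_that("the dual forward model is additive, linear and block-structured", {
  pr <- fx_protocol()
  bases <- fx_bases()
  trs <- fx_tracers()
  set.seed(4)
  J <- 6
  c_pair <- lapply(bases, function(b) matrix(abs(rnorm(J * 25, 0.1)), J))
  h_pair <- list(FDG = aligned_decayed_aif(trs$aifs$FDG, trs$specs$FDG, pr$t_fine),
                 MET = aligned_decayed_aif(trs$aifs$MET, trs$specs$MET, pr$t_fine))
  out <- model_forward_dual(c_pair, h_pair, bases, pr$Fmat)
  expect_equal(out$dual, out$FDG + out$MET)
  # zero MET coefficients: dual equals the FDG output
  c0 <- c_pair; c0$MET[] <- 0
  out0 <- model_forward_dual(c0, h_pair, bases, pr$Fmat)
  expect_equal(out0$dual, out0$FDG)
  expect_true(all(out0$MET == 0))
  # linearity in the coefficients
  c2 <- lapply(c_pair, function(x) 2 * x)
  out2 <- model_forward_dual(c2, h_pair, bases, pr$Fmat)
  expect_equal(out2$dual, 2 * out$dual, tolerance = 1e-12)
  # scale ambiguity: (c/a, a*h) leaves the output unchanged
  a <- 3.7
  ca <- lapply(c_pair, function(x) x / a)
  ha <- lapply(h_pair, function(h) a * h)
  outa <- model_forward_dual(ca, ha, bases, pr$Fmat)
  expect_equal(outa$dual, out$dual, tolerance = 1e-12)
})

test_that("one-voxel single-basis model reproduces frame-averaged basis values", {
  sch <- frame_schedule(c(0.5, 0.5, 1))
  t <- fine_time_grid(sch, 0.1)
  Fmat <- frame_integration_matrix(sch, t)
  tr <- tracer_spec("probe", isotope_half_life_min = 1e12,
                    injection_time_min = 0)
  b <- build_basis(tr, t, n_basis = 2)
  h <- c(1 / 0.1, numeric(length(t) - 1))  # impulse kernel
  M <- basis_frame_matrix(b, h, Fmat)
  expect_equal(M, Fmat %*% b$values, tolerance = 1e-10)
})

test_that("spectral NNLS represents compartmental TACs, up to the blood spike", {
  pr <- fx_protocol()
  trs <- fx_tracers()
  bases <- fx_bases()
  km <- kinetic_means()
  for (nm in c("FDG", "MET")) {
    tr <- trs$specs[[nm]]; aif <- trs$aifs[[nm]]
    h <- aligned_decayed_aif(aif, tr, pr$t_fine)
    for (reg in c("WM", "GM", "TM")) {
      p <- km[km$tracer == nm & km$region == reg, ]
      pars <- c(K1 = p$K1, k2 = p$k2, k3 = p$k3, k4 = p$k4, VB = p$VB)
      # tissue-only TAC (VB = 0) lies in the span of the convolved basis
      pars0 <- pars; pars0["VB"] <- 0
      tac0 <- frame_integrate(tissue_tac(pars0, tr, aif, aif, pr$t_fine),
                              pr$t_fine, pr$schedule)
      fit0 <- spectral_nnls_fit(tac0, bases[[nm]], h, pr$Fmat)
      expect_lt(fit0$rel_resid, 0.005)
      expect_true(all(fit0$coef >= 0))
      # the full TAC adds the vascular spike, which the <= 5/min rates can
      # only approximate; the residual stays bounded and is blood-driven
      tac <- frame_integrate(tissue_tac(pars, tr, aif, aif, pr$t_fine),
                             pr$t_fine, pr$schedule)
      fit <- spectral_nnls_fit(tac, bases[[nm]], h, pr$Fmat)
      expect_lt(fit$rel_resid, 0.12)
      expect_gt(fit$rel_resid, fit0$rel_resid)
    }
  }
})
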