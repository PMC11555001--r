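test_that("generalized KL divergence has its defining properties", {
  expect_equal(kl_divergence(c(2), c(1)), 2 * log(2) - 1, tolerance = 1e-12)
  m <- matrix(runif(20, 0, 5), 4)
  expect_equal(kl_divergence(m, m), 0, tolerance = 1e-9)
  set.seed(5)
  for (i in 1:1000) {
    a <- runif(3, 0, 10); b <- runif(3, 0.01, 10)
    expect_gte(kl_divergence(a, b), 0)
  }
  expect_error(kl_divergence(c(-1), c(1)), "nonnegative")
  # 0 log 0 convention
  expect_equal(kl_divergence(c(0), c(2)), 2)
})

test_that("coefficient update reproduces the hand-evaluated toy and fixed points", {
  toy <- fx_toy_system()
  # 1 voxel, 2 frames, 1 basis: B = (1,1)', identity kernel, c0 = 1,
  # m = (2,4): sensitivity 2, backprojected ratio 6, update 3
  M <- list(FDG = toy$Fmat %*% toy$B_step, MET = matrix(0.5, 2, 1))
  cp <- list(FDG = matrix(1), MET = matrix(0))
  m <- matrix(c(2, 4), 1)
  out <- c_update(cp, M, m)
  expect_equal(out$FDG[1, 1], 3, tolerance = 1e-12)
  expect_equal(out$MET[1, 1], 0)   # zeros stay zero
  # fixed point: m equal to the model leaves c unchanged
  cp2 <- list(FDG = matrix(2), MET = matrix(1))
  m2 <- cp2$FDG %*% t(M$FDG) + cp2$MET %*% t(M$MET)
  out2 <- c_update(cp2, M, m2)
  expect_equal(out2$FDG, cp2$FDG, tolerance = 1e-12)
  expect_equal(out2$MET, cp2$MET, tolerance = 1e-12)
})

test_that("generating-function update reproduces its toy and fixed point", {
  toy <- fx_toy_system()
  tr <- tracer_spec("probe", isotope_half_life_min = 1e12,
                    injection_time_min = 0)
  base <- structure(list(values = toy$B_impulse, rates = 0, tracer = tr,
                         t_fine = c(0, 1), dt = 1), class = "temporal_basis")
  bases <- list(FDG = base, MET = base)
  cp <- list(FDG = matrix(1), MET = matrix(0))
  hp <- list(FDG = c(1, 1), MET = c(1, 1))
  m <- matrix(c(3, 5), 1)
  out <- h_update(hp, cp, bases, m, toy$Fmat)
  expect_equal(out$FDG, c(3, 5), tolerance = 1e-12)
  # fixed point
  hp2 <- list(FDG = c(2, 3), MET = c(1, 1))
  M2 <- lapply(names(bases), function(n)
    basis_frame_matrix(bases[[n]], hp2[[n]], toy$Fmat))
  names(M2) <- names(bases)
  m2 <- cp$FDG %*% t(M2$FDG) + cp$MET %*% t(M2$MET)
  out2 <- h_update(hp2, cp, bases, m2, toy$Fmat)
  expect_equal(out2$FDG, hp2$FDG, tolerance = 1e-12)
  # zero samples of h persist under the multiplicative update
  hp3 <- list(FDG = c(2, 0), MET = c(1, 1))
  out3 <- h_update(hp3, cp, bases, m, toy$Fmat)
  expect_equal(out3$FDG[2], 0)
})

test_that("one coefficient MLEM update equals the proximal-gradient step", {
  set.seed(6)
  for (rep in 1:100) {
    J <- sample(2:5, 1); Tn <- sample(3:6, 1); nb <- sample(1:3, 1)
    M <- list(FDG = matrix(runif(Tn * nb, 0.1, 1), Tn),
              MET = matrix(runif(Tn * nb, 0.1, 1), Tn))
    cp <- list(FDG = matrix(runif(J * nb, 0.1, 2), J),
               MET = matrix(runif(J * nb, 0.1, 2), J))
    m <- matrix(runif(J * Tn, 0.5, 5), J)
    a <- c_update(cp, M, m)
    b <- c_update_gradient_form(cp, M, m)
    expect_lt(max(abs(a$FDG - b$FDG)), 1e-10)
    expect_lt(max(abs(a$MET - b$MET)), 1e-10)
  }
})

test_that("IS-F4D fits basis-generated noise-free dual data self-consistently", {
  sch <- desk_frame_schedule()
  t_fine <- fine_time_grid(sch, 0.25)
  bases <- list(FDG = build_basis(tracer_spec("FDG"), t_fine, 12),
                MET = build_basis(tracer_spec("MET"), t_fine, 12))
  Fmat <- frame_integration_matrix(sch, t_fine)
  set.seed(7)
  J <- 4
  c_true <- lapply(bases, function(b) {
    cm <- matrix(0, J, 12)
    cm[cbind(seq_len(J), sample(12, J, TRUE))] <- runif(J, 0.5, 2)
    cm
  })
  h_true <- list(
    FDG = exp_conv(0.8, exp(-0.3 * (t_fine - t_fine[1])), 0.25) * 5,
    MET = exp_conv(1.5, exp(-0.15 * (t_fine - t_fine[1])), 0.25) * 3)
  m <- model_forward_dual(c_true, h_true, bases, Fmat)$dual
  res <- run_isf4d(m, bases, sch, f4d_config(n_outer = 150L))
  # KL trace non-increasing within numerical tolerance
  expect_true(all(diff(res$kl_trace) <=
                    1e-9 * pmax(abs(res$kl_trace[-1]), 1)))
  # dual-model fit converges to the data
  rel <- sqrt(sum((res$dual - m)^2) / sum(m^2))
  expect_lt(rel, 0.01)
  # nonnegativity everywhere, and the separated images sum to the fit
  expect_true(all(res$images$FDG >= 0) && all(res$images$MET >= 0))
  expect_true(all(unlist(res$c_pair) >= 0) && all(unlist(res$h_pair) >= 0))
  expect_equal(res$images$FDG + res$images$MET, res$dual)
})

test_that("IS-F4D aborts with a diagnostic on non-finite input", {
  sch <- frame_schedule(c(1, 1))
  t_fine <- fine_time_grid(sch, 0.5)
  bases <- list(FDG = build_basis(tracer_spec("FDG"), t_fine, 3),
                MET = build_basis(tracer_spec("MET", 20.4, 0), t_fine, 3))
  expect_error(run_isf4d(matrix(-1, 2, 2), bases, sch), "negative|>= 0")
})
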