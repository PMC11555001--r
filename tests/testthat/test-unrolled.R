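# small shared geometry for the network tests
.net_fixture <- function() {
  fx("net_fixture", function() {
    grid <- image_grid(8, 8, 2.602)
    sch <- frame_schedule(c(0.5, 0.5, 1, 1, 2))
    t_fine <- fine_time_grid(sch, 0.25)
    bases <- list(FDG = build_basis(tracer_spec("FDG"), t_fine, 4),
                  MET = build_basis(tracer_spec("MET", 20.4, 1), t_fine, 4))
    Fmat <- frame_integration_matrix(sch, t_fine)
    set.seed(21)
    mk <- function() {
      cp <- lapply(bases, function(b) matrix(abs(rnorm(grid$J * 4, 0.5, 0.2)),
                                             grid$J))
      hp <- list(FDG = abs(rnorm(length(t_fine), 1, 0.2)),
                 MET = abs(rnorm(length(t_fine), 1, 0.2)))
      out <- model_forward_dual(cp, hp, bases, Fmat)
      list(m = out$dual,
           labels = list(FDG = out$FDG, MET = out$MET))
    }
    list(grid = grid, schedule = sch, t_fine = t_fine, bases = bases,
         Fmat = Fmat, batch = list(mk(), mk()))
  })
}

test_that("tape gradients match finite differences at a smooth point", {
  fxn <- .net_fixture()
  model <- unrolled_init(unrolled_config(2, 3, 2), fxn$bases, seed = 3)
  # positive biases keep the regulariser outputs away from the ReLU and
  # eps-floor kinks, where finite differences are meaningful
  for (k in 1:2) for (n in c("FDG", "MET")) {
    for (l in 1:2) model$blocks[[k]][[n]]$layers[[l]]$b[] <- 0.5
    model$blocks[[k]][[n]]$out$b[] <- 1.0
    model$blocks[[k]][[n]]$out$W <- model$blocks[[k]][[n]]$out$W * 0.1
  }
  fl <- mpetsep:::flatten_params(model)
  tape <- mpetsep:::tape_new()
  fw <- mpetsep:::unrolled_tape_forward(tape, model, fxn$batch, fxn$bases,
                                        fxn$Fmat, fxn$grid)
  grads <- mpetsep:::tape_backward(tape, fw$loss, as.list(fw$param_ids))
  loss_at <- function(vals) {
    m2 <- mpetsep:::assign_params(model, fl$paths, vals)
    tp <- mpetsep:::tape_new()
    mpetsep:::tp_val(tp, mpetsep:::unrolled_tape_forward(
      tp, m2, fxn$batch, fxn$bases, fxn$Fmat, fxn$grid)$loss)
  }
  set.seed(9)
  for (trial in 1:10) {
    k <- sample(length(fl$values), 1)
    i <- sample(length(fl$values[[k]]), 1)
    d <- 1e-6 * max(1, abs(fl$values[[k]][i]))
    vp <- fl$values; vp[[k]][i] <- vp[[k]][i] + d
    vm <- fl$values; vm[[k]][i] <- vm[[k]][i] - d
    fd <- (loss_at(vp) - loss_at(vm)) / (2 * d)
    an <- as.numeric(grads[[k]])[i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("CED tape gradients match finite differences", {
  fxn <- .net_fixture()
  model <- ced_init(ced_config(fxn$schedule$T, 4), seed = 2)
  fl <- mpetsep:::flatten_params(model)
  tape <- mpetsep:::tape_new()
  fw <- mpetsep:::ced_tape_forward(tape, model, fxn$batch, fxn$grid)
  grads <- mpetsep:::tape_backward(tape, fw$loss, as.list(fw$param_ids))
  loss_at <- function(vals) {
    m2 <- mpetsep:::assign_params(model, fl$paths, vals)
    tp <- mpetsep:::tape_new()
    mpetsep:::tp_val(tp, mpetsep:::ced_tape_forward(tp, m2, fxn$batch,
                                                    fxn$grid)$loss)
  }
  set.seed(10)
  for (trial in 1:10) {
    k <- sample(length(fl$values), 1)
    i <- sample(length(fl$values[[k]]), 1)
    d <- 1e-6 * max(1, abs(fl$values[[k]][i]))
    vp <- fl$values; vp[[k]][i] <- vp[[k]][i] + d
    vm <- fl$values; vm[[k]][i] <- vm[[k]][i] - d
    fd <- (loss_at(vp) - loss_at(vm)) / (2 * d)
    an <- as.numeric(grads[[k]])[i]
    expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("identity regularisers reduce the network to IS-F4D cycles exactly", {
  fxn <- .net_fixture()
  m <- fxn$batch[[1]]$m
  K <- 4L
  net <- unrolled_identity(unrolled_config(K, 2, 1), fxn$bases)
  sep_net <- unrolled_separate(m, net, fxn$bases, fxn$schedule, fxn$grid)
  ref <- run_isf4d(m, fxn$bases, fxn$schedule,
                   f4d_config(n_outer = K, n_init_c = 0L,
                              n_c_per_cycle = 1L, n_h_per_cycle = 1L))
  expect_lt(max(abs(sep_net$images$FDG - ref$images$FDG)), 1e-10)
  expect_lt(max(abs(sep_net$images$MET - ref$images$MET)), 1e-10)
  expect_lt(max(abs(sep_net$h_pair$FDG - ref$h_pair$FDG)), 1e-10)
})

test_that("untrained forward passes are nonnegative and seed-deterministic", {
  fxn <- .net_fixture()
  m <- fxn$batch[[1]]$m
  net1 <- unrolled_init(unrolled_config(2, 3, 2), fxn$bases, seed = 11)
  net2 <- unrolled_init(unrolled_config(2, 3, 2), fxn$bases, seed = 11)
  s1 <- unrolled_separate(m, net1, fxn$bases, fxn$schedule, fxn$grid)
  s2 <- unrolled_separate(m, net2, fxn$bases, fxn$schedule, fxn$grid)
  expect_identical(s1$images, s2$images)
  expect_true(all(s1$images$FDG >= 0) && all(s1$images$MET >= 0))
  # the separated pair reproduces the fitted dual model exactly
  out <- model_forward_dual(s1$c_pair, s1$h_pair, fxn$bases, fxn$Fmat)
  expect_equal(s1$images$FDG + s1$images$MET, out$dual, tolerance = 1e-12)
  # zero measurement collapses the identity-regulariser network to zero
  net0 <- unrolled_identity(unrolled_config(2, 2, 1), fxn$bases)
  s0 <- unrolled_separate(matrix(0, fxn$grid$J, fxn$schedule$T), net0,
                          fxn$bases, fxn$schedule, fxn$grid)
  expect_true(all(s0$images$FDG == 0) && all(s0$images$MET == 0))
})

test_that("parameter budgets are met by the default and matched models", {
  pr <- fx_protocol()
  bases <- fx_bases()
  full <- unrolled_init(unrolled_config(), bases, seed = 1)
  pc <- param_count(full)
  expect_gt(pc, 1.08e6); expect_lt(pc, 1.32e6)  # ~1.2 M budget
  ced <- build_ced_baseline(pc, n_frames = 27L, seed = 1)
  expect_lt(abs(param_count(ced) - pc), 0.1 * pc)
  expect_true(param_count(ced) == param_count(build_ced_baseline(pc, 27L, 2)))
  expect_error(build_ced_baseline(5e3, 27L), "1e4|target_param_count")
})

test_that("CED maps a dual series to two nonnegative single-tracer series", {
  fxn <- .net_fixture()
  model <- ced_init(ced_config(fxn$schedule$T, 4), seed = 5)
  sep <- ced_separate(fxn$batch[[1]]$m, model, fxn$grid, fxn$schedule)
  expect_equal(dim(sep$images$FDG), dim(fxn$batch[[1]]$m))
  expect_equal(dim(sep$images$MET), dim(fxn$batch[[1]]$m))
  expect_true(all(sep$images$FDG >= 0) && all(sep$images$MET >= 0))
})

test_that("a few Adam steps reduce the training loss at toy scale", {
  fxn <- .net_fixture()
  model <- unrolled_init(unrolled_config(1, 2, 1), fxn$bases, seed = 6)
  out <- train_network(model, fxn$batch, val_set = NULL,
                       cfg = train_config(learning_rate = 1e-2,
                                          batch_size = 2L, max_epochs = 8L,
                                          seed = 1L),
                       bases = fxn$bases, schedule = fxn$schedule,
                       grid = fxn$grid)
  expect_true(all(is.finite(out$train_loss)))
  expect_lt(min(out$train_loss), out$train_loss[1])
})
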