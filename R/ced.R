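# Parameter-matched convolutional encoder-decoder baseline: a generic
# purely data-driven separator mapping the dual-tracer dynamic image
# (T channels) to the two single-tracer dynamic images (2T channels).

#' CED configuration
#'
#' Encoder: two conv/pool stages (widths `width`, `2 width`); bottleneck
#' convolution; decoder: two upsample/conv stages; closing 1x1 convolution
#' to `2 T` output channels with a ReLU for nonnegativity. Every 3x3
#' convolution is followed by batch normalization and a PReLU.
#'
#' @param n_frames Number of input frames `T`.
#' @param width Base channel width.
#' @param eps Unused numerical floor, kept for interface symmetry.
#' @return Object of class `ced_config`.
#' @export
ced_config <- function(n_frames, width = 32L, eps = 1e-12) {
  stopifnot(n_frames >= 1, width >= 1)
  structure(list(n_frames = as.integer(n_frames), width = as.integer(width),
                 eps = eps),
            class = "ced_config")
}

.ced_stage <- function(kh, cin, cout) {
  list(W = xavier_conv(kh, kh, cin, cout), b = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout),
       run_mean = numeric(cout), run_var = rep(1, cout),
       a = rep(0.25, cout))
}

#' Initialise a CED model
#'
#' @param cfg A [ced_config()].
#' @param seed Integer seed (Xavier initialisation).
#' @return Object of class `ced_model`.
#' @export
ced_init <- function(cfg, seed = 1L) {
  set.seed(derive_seed(seed, 701L))
  Tn <- cfg$n_frames; W <- cfg$width
  stages <- list(
    enc1 = .ced_stage(3, Tn, W),
    enc2 = .ced_stage(3, W, 2L * W),
    mid = .ced_stage(3, 2L * W, 2L * W),
    dec1 = .ced_stage(3, 2L * W, W),
    dec2 = .ced_stage(3, W, W),
    out = list(W = xavier_conv(1, 1, W, 2L * Tn), b = numeric(2L * Tn)))
  structure(list(cfg = cfg, stages = stages), class = "ced_model")
}

#' Build a CED whose trainable count matches a target
#'
#' Scans base widths and returns the smallest model whose trainable
#' parameter count is within 10% of `target_param_count`.
#'
#' @param target_param_count Desired number of trainable parameters
#'   (>= 1e4).
#' @param n_frames Number of input frames.
#' @param seed Seed for the returned model's initialisation.
#' @return A `ced_model`.
#' @export
build_ced_baseline <- function(target_param_count, n_frames, seed = 1L) {
  stopifnot(target_param_count >= 1e4)
  for (w in seq(2L, 512L)) {
    m <- ced_init(ced_config(n_frames, w), seed = seed)
    pc <- param_count(m)
    if (abs(pc - target_param_count) <= 0.1 * target_param_count) return(m)
    if (pc > 1.1 * target_param_count) break
  }
  stop("no CED width matches the requested parameter budget within 10%")
}

.ced_stage_eval <- function(x, st) {
  x <- conv2d_f(x, st$W, st$b)
  x <- bn_f(x, st$gamma, st$beta, st$run_mean, st$run_var)
  prelu_f(x, st$a)
}

#' Separate a dual-tracer dynamic image with a CED model
#'
#' Evaluation-mode forward pass (running batch-norm statistics).
#'
#' @param m A [dynamic_image()] or `J x T` matrix.
#' @param model A `ced_model`.
#' @param grid The [image_grid()] of `m` (square, side divisible by 4).
#' @param schedule The [frame_schedule()] of `m`.
#' @return A `separation_result` with `images$FDG` and `images$MET`.
#' @export
ced_separate <- function(m, model, grid = NULL, schedule = NULL) {
  if (inherits(m, "dynamic_image")) {
    grid <- grid %||% m$grid; schedule <- schedule %||% m$schedule
    m <- m$values
  }
  Tn <- model$cfg$n_frames
  stopifnot(ncol(m) == Tn, grid$nx %% 4 == 0, grid$ny %% 4 == 0)
  x <- array(m, c(grid$nx, grid$ny, Tn, 1))
  st <- model$stages
  x <- .ced_stage_eval(x, st$enc1)
  x <- avgpool2_f(x)
  x <- .ced_stage_eval(x, st$enc2)
  x <- avgpool2_f(x)
  x <- .ced_stage_eval(x, st$mid)
  x <- upsample2_f(x)
  x <- .ced_stage_eval(x, st$dec1)
  x <- upsample2_f(x)
  x <- .ced_stage_eval(x, st$dec2)
  x <- conv2d_f(x, st$out$W, st$out$b)
  x <- x * (x > 0)
  images <- list(FDG = matrix(x[, , seq_len(Tn), 1], grid$J, Tn),
                 MET = matrix(x[, , Tn + seq_len(Tn), 1], grid$J, Tn))
  structure(list(images = images, dual = images$FDG + images$MET,
                 kl_trace = numeric(0), grid = grid, schedule = schedule,
                 config = model$cfg),
            class = "separation_result")
}

# training-mode tape forward over one mini-batch
ced_tape_forward <- function(tape, model, batch, grid) {
  Tn <- model$cfg$n_frames
  B <- length(batch)
  leaves <- .model_leaves(tape, model)
  st <- leaves$tree
  xin <- tp_stack(tape, vapply(batch, function(ex)
    tp_leaf(tape, array(ex$m, c(grid$nx, grid$ny, Tn))), integer(1)))
  bn_stats <- list()
  stage <- function(x, lv, key) {
    x <- tp_conv2d(tape, x, lv$W, lv$b)
    x <- tp_bn(tape, x, lv$gamma, lv$beta)
    bn_stats[[key]] <<- attr(tape$val[[x]], "batch_stats")
    tp_prelu(tape, x, lv$a)
  }
  x <- stage(xin, st$enc1, "enc1")
  x <- tp_avgpool2(tape, x)
  x <- stage(x, st$enc2, "enc2")
  x <- tp_avgpool2(tape, x)
  x <- stage(x, st$mid, "mid")
  x <- tp_upsample2(tape, x)
  x <- stage(x, st$dec1, "dec1")
  x <- tp_upsample2(tape, x)
  x <- stage(x, st$dec2, "dec2")
  x <- tp_conv2d(tape, x, st$out$W, st$out$b)
  x <- tp_relu(tape, x)
  loss <- tp_leaf(tape, 0)
  outputs <- list(FDG = vector("list", B), MET = vector("list", B))
  for (e in seq_len(B)) {
    sl <- tp_unstack(tape, x, e, c(grid$nx, grid$ny, 2L * Tn))
    fdg <- tp_reshape(tape, tp_node(tape, tp_val(tape, sl)[, , seq_len(Tn)], sl,
      local({ Tn2 <- Tn; d <- c(grid$nx, grid$ny, 2L * Tn)
        function(g) { out <- array(0, d); out[, , seq_len(Tn2)] <- g; list(out) } })),
      c(grid$J, Tn))
    met <- tp_reshape(tape, tp_node(tape, tp_val(tape, sl)[, , Tn + seq_len(Tn)], sl,
      local({ Tn2 <- Tn; d <- c(grid$nx, grid$ny, 2L * Tn)
        function(g) { out <- array(0, d); out[, , Tn2 + seq_len(Tn2)] <- g; list(out) } })),
      c(grid$J, Tn))
    outputs$FDG[[e]] <- fdg
    outputs$MET[[e]] <- met
    loss <- tp_add(tape, loss,
                   tp_scale(tape, tp_sse(tape, fdg, batch[[e]]$labels$FDG), 1 / B))
    loss <- tp_add(tape, loss,
                   tp_scale(tape, tp_sse(tape, met, batch[[e]]$labels$MET), 1 / B))
  }
  list(loss = loss, outputs = outputs, param_ids = leaves$ids,
       param_paths = leaves$paths, bn_stats = bn_stats)
}
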