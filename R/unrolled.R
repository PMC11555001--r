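# Kinetic model-informed unrolled separation network: K blocks, each
# performing one multiplicative MLEM update of the spectral coefficients,
# a trainable two-branch convolutional regulariser (one branch per tracer)
# replacing the proximal step, and one MLEM update of the generating
# functions. With identity regularisers the network is exactly K cycles of
# IS-F4D with one coefficient and one generating-function update per cycle.

#' Unrolled network configuration
#'
#' @param n_blocks Number of unrolled iteration blocks `K` (default 10).
#' @param width Channels of the hidden convolution layers; the default 50
#'   puts the total trainable count near 1.2 million at `K = 10` with
#'   25-function bases.
#' @param n_layers Number of 3x3 convolution layers per branch (default 3),
#'   each followed by batch normalization and a PReLU, before the closing
#'   1x1 convolution and the nonnegativity ReLU.
#' @param eps Positivity floor used inside the MLEM steps.
#' @return Object of class `unrolled_config`.
#' @export
unrolled_config <- function(n_blocks = 10L, width = 50L, n_layers = 3L,
                            eps = 1e-12) {
  stopifnot(n_blocks >= 1, width >= 1, n_layers >= 1)
  structure(list(n_blocks = as.integer(n_blocks), width = as.integer(width),
                 n_layers = as.integer(n_layers), eps = eps),
            class = "unrolled_config")
}

# one regulariser branch: n_layers x (conv3x3 + BN + PReLU), conv1x1, ReLU
.init_branch <- function(cfg, n_basis) {
  W <- cfg$width
  layers <- list()
  cin <- n_basis
  for (l in seq_len(cfg$n_layers)) {
    layers[[paste0("layer", l)]] <- list(
      W = xavier_conv(3, 3, cin, W), b = numeric(W),
      gamma = rep(1, W), beta = numeric(W),
      run_mean = numeric(W), run_var = rep(1, W),
      a = rep(0.25, W))
    cin <- W
  }
  list(layers = layers,
       out = list(W = xavier_conv(1, 1, W, n_basis), b = numeric(n_basis)))
}

#' Initialise an unrolled separation model
#'
#' Xavier-uniform convolution weights, unit batch-norm gains, PReLU slopes
#' 0.25; one two-branch regulariser per block.
#'
#' @param cfg An [unrolled_config()].
#' @param bases Named list (FDG, MET) of [build_basis()] results.
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `unrolled_model`.
#' @export
unrolled_init <- function(cfg, bases, seed = 1L) {
  set.seed(derive_seed(seed, 601L))
  blocks <- lapply(seq_len(cfg$n_blocks), function(k) {
    br <- lapply(bases, function(b) .init_branch(cfg, length(b$rates)))
    names(br) <- names(bases)
    br
  })
  names(blocks) <- paste0("block", seq_len(cfg$n_blocks))
  structure(list(cfg = cfg, blocks = blocks, tracers = names(bases),
                 identity_gamma = FALSE),
            class = "unrolled_model")
}

#' Identity-regulariser variant of the unrolled model
#'
#' Returns a model whose regularisers are the identity map, reducing the
#' network to `K` IS-F4D cycles with one coefficient and one generating-
#' function update each. Used to verify the model-based core of the
#' network.
#'
#' @param cfg An [unrolled_config()].
#' @param bases Named list of bases.
#' @return An `unrolled_model` with `identity_gamma = TRUE`.
#' @export
unrolled_identity <- function(cfg, bases) {
  m <- unrolled_init(cfg, bases, seed = 1L)
  m$identity_gamma <- TRUE
  m
}

#' Number of trainable parameters of a model
#'
#' @param model An `unrolled_model` or `ced_model`.
#' @return Integer count of trainable scalars (running statistics excluded).
#' @export
param_count <- function(model) {
  flat <- flatten_params(model)
  sum(vapply(flat$values, length, integer(1)))
}

# trainable parameter flattening (paths into the nested model list)
flatten_params <- function(model) {
  paths <- list(); values <- list()
  walk <- function(x, path) {
    if (is.list(x)) {
      for (nm in names(x)) {
        if (nm %in% c("run_mean", "run_var")) next
        walk(x[[nm]], c(path, nm))
      }
    } else if (is.numeric(x) &&
               path[length(path)] %in% c("W", "b", "gamma", "beta", "a")) {
      paths[[length(paths) + 1L]] <<- path
      values[[length(values) + 1L]] <<- x
    }
  }
  walk(model$blocks %||% model$stages, "blocks")
  paths <- lapply(paths, function(p) p[-1])
  list(paths = paths, values = values)
}

assign_params <- function(model, paths, values) {
  tree <- model$blocks %||% model$stages
  for (k in seq_along(paths)) {
    tree[[paths[[k]]]] <- array(values[[k]],
                                dim(tree[[paths[[k]]]]) %||%
                                  length(tree[[paths[[k]]]]))
  }
  if (!is.null(model$blocks)) model$blocks <- tree else model$stages <- tree
  model
}

# plain-evaluation regulariser branch (running BN statistics)
.branch_eval <- function(xa, branch) {
  for (ly in branch$layers) {
    xa <- conv2d_f(xa, ly$W, ly$b)
    xa <- bn_f(xa, ly$gamma, ly$beta, ly$run_mean, ly$run_var)
    xa <- prelu_f(xa, ly$a)
  }
  xa <- conv2d_f(xa, branch$out$W, branch$out$b)
  xa * (xa > 0)
}

#' Separate a dual-tracer dynamic image with an unrolled model
#'
#' Runs the `K` blocks from coefficients and generating functions
#' initialised to ones, then recovers the separated single-tracer framed
#' images through the single-tracer spectral model. The MLEM steps are the
#' exact [c_update()] and [h_update()] of the IS-F4D implementation; the
#' regularisers run in evaluation mode (running batch-norm statistics).
#'
#' @param m A [dynamic_image()] or `J x T` matrix of dual-tracer frames.
#' @param model An `unrolled_model` (trained or identity).
#' @param bases Named list of [build_basis()] results.
#' @param schedule The [frame_schedule()] of `m`.
#' @param grid The [image_grid()] (needed to reshape coefficient images for
#'   the convolutional branches; may be omitted for identity regularisers).
#' @return A `separation_result` (no KL trace).
#' @export
unrolled_separate <- function(m, model, bases, schedule, grid = NULL) {
  if (inherits(m, "dynamic_image")) { grid <- grid %||% m$grid; m <- m$values }
  stopifnot(is.matrix(m))
  nm <- names(bases)
  t_fine <- bases[[1]]$t_fine
  Fmat <- frame_integration_matrix(schedule, t_fine)
  eps <- model$cfg$eps
  J <- nrow(m)
  c_pair <- lapply(bases, function(b) matrix(1, J, length(b$rates)))
  h_pair <- lapply(bases, function(b) init_generating_function(t_fine))
  for (k in seq_len(model$cfg$n_blocks)) {
    M <- lapply(nm, function(n) basis_frame_matrix(bases[[n]], h_pair[[n]], Fmat))
    names(M) <- nm
    c_pair <- c_update(c_pair, M, m, eps)
    if (!model$identity_gamma) {
      stopifnot(!is.null(grid), grid$J == J)
      for (n in nm) {
        xa <- array(c_pair[[n]], c(grid$nx, grid$ny, ncol(c_pair[[n]]), 1))
        xa <- .branch_eval(xa, model$blocks[[k]][[n]])
        c_pair[[n]] <- matrix(xa, J, ncol(c_pair[[n]]))
      }
    }
    h_pair <- h_update(h_pair, c_pair, bases, m, Fmat, eps)
  }
  M <- lapply(nm, function(n) basis_frame_matrix(bases[[n]], h_pair[[n]], Fmat))
  names(M) <- nm
  images <- lapply(nm, function(n) c_pair[[n]] %*% t(M[[n]]))
  names(images) <- nm
  structure(list(images = images, c_pair = c_pair, h_pair = h_pair,
                 dual = images[[1]] + images[[2]], kl_trace = numeric(0),
                 grid = grid, schedule = schedule, config = model$cfg),
            class = "separation_result")
}

# tape regulariser branch on a stacked (nx, ny, C, B) node; returns the
# output node and the batch statistics of each BN layer
.branch_tape <- function(tape, x, branch_leaves) {
  stats <- list()
  for (li in seq_along(branch_leaves$layers)) {
    lv <- branch_leaves$layers[[li]]
    x <- tp_conv2d(tape, x, lv$W, lv$b)
    x <- tp_bn(tape, x, lv$gamma, lv$beta)
    stats[[li]] <- attr(tape$val[[x]], "batch_stats")
    x <- tp_prelu(tape, x, lv$a)
  }
  x <- tp_conv2d(tape, x, branch_leaves$out$W, branch_leaves$out$b)
  list(node = tp_relu(tape, x), stats = stats)
}

# build leaf nodes for every trainable parameter of the model; returns the
# nested structure of node ids plus flat bookkeeping for the backward pass
.model_leaves <- function(tape, model) {
  fl <- flatten_params(model)
  ids <- integer(length(fl$values))
  tree <- model$blocks %||% model$stages
  for (k in seq_along(fl$paths)) {
    ids[k] <- tp_leaf(tape, fl$values[[k]])
    tree[[fl$paths[[k]]]] <- ids[k]
  }
  list(tree = tree, ids = ids, paths = fl$paths)
}

# training-mode forward pass of the unrolled network over one mini-batch;
# returns the loss node and BN batch statistics per block/branch/layer
unrolled_tape_forward <- function(tape, model, batch, bases, Fmat, grid) {
  nm <- model$tracers
  eps <- model$cfg$eps
  B <- length(batch)
  J <- grid$J
  t_fine <- bases[[1]]$t_fine
  dt <- bases[[1]]$dt
  Bt <- lapply(bases, function(b) t(b$values))
  w_fine <- colSums(Fmat)
  leaves <- .model_leaves(tape, model)
  m_ids <- lapply(batch, function(ex) tp_leaf(tape, ex$m))
  Cn <- lapply(nm, function(n)
    lapply(seq_len(B), function(e) tp_leaf(tape, matrix(1, J, length(bases[[n]]$rates)))))
  names(Cn) <- nm
  hn <- lapply(nm, function(n)
    lapply(seq_len(B), function(e) tp_leaf(tape, init_generating_function(t_fine))))
  names(hn) <- nm
  bn_stats <- list()
  for (k in seq_len(model$cfg$n_blocks)) {
    Mn <- lapply(nm, function(n)
      lapply(seq_len(B), function(e)
        tp_frame_conv_basis(tape, hn[[n]][[e]], Bt[[n]], Fmat, dt)))
    names(Mn) <- nm
    # coefficient MLEM step per example
    Cbar <- lapply(nm, function(n) vector("list", B))
    names(Cbar) <- nm
    for (e in seq_len(B)) {
      q <- tp_add(tape,
                  tp_matmul(tape, Cn[[nm[1]]][[e]], Mn[[nm[1]]][[e]], tb = TRUE),
                  tp_matmul(tape, Cn[[nm[2]]][[e]], Mn[[nm[2]]][[e]], tb = TRUE))
      ratio <- tp_div(tape, m_ids[[e]], tp_pmax_const(tape, q, eps))
      for (n in nm) {
        sens <- tp_colsums(tape, Mn[[n]][[e]])
        bp <- tp_matmul(tape, ratio, Mn[[n]][[e]])
        upd <- tp_div(tape, bp, tp_bcast_row(tape, sens, J))
        Cbar[[n]][[e]] <- tp_mul(tape, Cn[[n]][[e]], upd)
      }
    }
    # batched two-branch regulariser
    if (!model$identity_gamma) {
      for (n in nm) {
        nb <- length(bases[[n]]$rates)
        stk <- tp_stack(tape, vapply(seq_len(B), function(e)
          tp_reshape(tape, Cbar[[n]][[e]], c(grid$nx, grid$ny, nb)), integer(1)))
        br <- .branch_tape(tape, stk, leaves$tree[[k]][[n]])
        bn_stats[[paste(k, n)]] <- br$stats
        for (e in seq_len(B)) {
          sl <- tp_unstack(tape, br$node, e, c(grid$nx, grid$ny, nb))
          Cn[[n]][[e]] <- tp_reshape(tape, sl, c(J, nb))
        }
      }
    } else {
      Cn <- Cbar
    }
    # generating-function MLEM step per example
    for (e in seq_len(B)) {
      q2 <- tp_add(tape,
                   tp_matmul(tape, Cn[[nm[1]]][[e]], Mn[[nm[1]]][[e]], tb = TRUE),
                   tp_matmul(tape, Cn[[nm[2]]][[e]], Mn[[nm[2]]][[e]], tb = TRUE))
      ratio2 <- tp_div(tape, m_ids[[e]], tp_pmax_const(tape, q2, eps))
      rfine <- tp_node(tape, tp_val(tape, ratio2) %*% Fmat, ratio2,
                       local({ Fm <- Fmat; function(g) list(g %*% t(Fm)) }))
      for (n in nm) {
        cs <- tp_colsums(tape, Cn[[n]][[e]])
        xbar <- tp_node(tape, tp_val(tape, cs) %*% Bt[[n]], cs,
                        local({ Bc <- Bt[[n]]; function(g) list(g %*% t(Bc)) }))
        sens_h <- tp_pairsum_corr(tape, xbar,
                                  tp_leaf(tape, matrix(w_fine, 1)), dt)
        adj_h <- tp_hadj(tape, Cn[[n]][[e]], rfine, Bt[[n]], dt)
        upd <- tp_div(tape, adj_h, tp_pmax_const(tape, sens_h, eps))
        hn[[n]][[e]] <- tp_mul(tape, hn[[n]][[e]], upd)
      }
    }
  }
  # final single-tracer outputs and MSE loss (Eq-style: mean over examples,
  # summed over tracers)
  loss <- tp_leaf(tape, 0)
  outputs <- lapply(nm, function(n) vector("list", B))
  names(outputs) <- nm
  for (e in seq_len(B)) {
    for (n in nm) {
      Mfin <- tp_frame_conv_basis(tape, hn[[n]][[e]], Bt[[n]], Fmat, dt)
      f <- tp_matmul(tape, Cn[[n]][[e]], Mfin, tb = TRUE)
      outputs[[n]][[e]] <- f
      loss <- tp_add(tape, loss,
                     tp_scale(tape, tp_sse(tape, f, batch[[e]]$labels[[n]]), 1 / B))
    }
  }
  list(loss = loss, outputs = outputs, param_ids = leaves$ids,
       param_paths = leaves$paths, bn_stats = bn_stats)
}
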