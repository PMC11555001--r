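# End-to-end network training: Adam on the summed per-tracer mean-squared
# error between separated and label dynamic images, with mini-batches,
# per-epoch validation and early stopping.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-4).
#' @param batch_size Mini-batch size (default 8).
#' @param max_epochs Maximum epochs (default 1200).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 20).
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param bn_momentum Running-statistics update rate for batch
#'   normalization.
#' @param seed Seed controlling shuffling (weight initialisation is seeded
#'   at model creation).
#' @param verbose Print the loss every `verbose` epochs (0 = silent).
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 8L,
                         max_epochs = 1200L, patience = 20L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         bn_momentum = 0.1, seed = 1L, verbose = 0L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 bn_momentum = bn_momentum, seed = as.integer(seed),
                 verbose = as.integer(verbose)),
            class = "train_config")
}

# update BN running statistics in the model tree from tape batch statistics
.update_bn <- function(model, bn_stats, momentum) {
  if (inherits(model, "unrolled_model")) {
    for (key in names(bn_stats)) {
      parts <- strsplit(key, " ")[[1]]
      k <- as.integer(parts[1]); n <- parts[2]
      for (li in seq_along(bn_stats[[key]])) {
        st <- bn_stats[[key]][[li]]
        ly <- model$blocks[[k]][[n]]$layers[[li]]
        ly$run_mean <- (1 - momentum) * ly$run_mean + momentum * st$mean
        ly$run_var <- (1 - momentum) * ly$run_var + momentum * st$var
        model$blocks[[k]][[n]]$layers[[li]] <- ly
      }
    }
  } else {
    for (key in names(bn_stats)) {
      st <- bn_stats[[key]]
      sg <- model$stages[[key]]
      sg$run_mean <- (1 - momentum) * sg$run_mean + momentum * st$mean
      sg$run_var <- (1 - momentum) * sg$run_var + momentum * st$var
      model$stages[[key]] <- sg
    }
  }
  model
}

# evaluation-mode loss over a set of examples
.eval_loss <- function(model, examples, bases, schedule, grid) {
  tot <- 0
  for (ex in examples) {
    sep <- if (inherits(model, "unrolled_model"))
      unrolled_separate(ex$m, model, bases, schedule, grid)
    else ced_separate(ex$m, model, grid, schedule)
    tot <- tot + sum((sep$images$FDG - ex$labels$FDG)^2) +
      sum((sep$images$MET - ex$labels$MET)^2)
  }
  tot / length(examples)
}

#' Train a separation network
#'
#' Minimises the sum over tracers of the mean squared error between the
#' separated and the label single-tracer dynamic images, end-to-end (the
#' MLEM steps of the unrolled model are differentiated through; nothing is
#' detached). Mini-batches are reshuffled every epoch; validation loss is
#' evaluated each epoch and the best weights are restored on early stop.
#'
#' @param model An `unrolled_model` or `ced_model`.
#' @param train_set,val_set Lists of examples: each
#'   `list(m = J x T dual matrix, labels = list(FDG =, MET =))`.
#' @param cfg A [train_config()].
#' @param bases Named list of [build_basis()] results (unrolled model).
#' @param schedule The [frame_schedule()] of the examples.
#' @param grid The [image_grid()] of the examples.
#' @return List with the trained `model`, `train_loss` and `val_loss`
#'   per-epoch vectors, and `best_epoch`.
#' @export
train_network <- function(model, train_set, val_set = NULL,
                          cfg = train_config(), bases = NULL,
                          schedule = NULL, grid = NULL) {
  stopifnot(length(train_set) >= 1)
  set.seed(derive_seed(cfg$seed, 801L))
  fl <- flatten_params(model)
  theta <- fl$values
  mom1 <- lapply(theta, function(v) v * 0)
  mom2 <- lapply(theta, function(v) v * 0)
  step <- 0L
  Fmat <- if (inherits(model, "unrolled_model"))
    frame_integration_matrix(schedule, bases[[1]]$t_fine) else NULL
  train_loss <- numeric(0); val_loss <- numeric(0)
  best <- Inf; best_model <- model; best_epoch <- 0L; wait <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(length(train_set))
    nb <- ceiling(length(train_set) / cfg$batch_size)
    ep_loss <- 0
    for (bi in seq_len(nb)) {
      idx <- ord[((bi - 1L) * cfg$batch_size + 1L):min(bi * cfg$batch_size,
                                                       length(train_set))]
      batch <- train_set[idx]
      tape <- tape_new()
      fw <- if (inherits(model, "unrolled_model"))
        unrolled_tape_forward(tape, model, batch, bases, Fmat, grid)
      else ced_tape_forward(tape, model, batch, grid)
      lv <- tp_val(tape, fw$loss)
      if (!is.finite(lv)) stop("non-finite training loss at epoch ", epoch)
      ep_loss <- ep_loss + lv * length(idx)
      grads <- tape_backward(tape, fw$loss, as.list(fw$param_ids))
      step <- step + 1L
      for (k in seq_along(theta)) {
        g <- as.numeric(grads[[k]])
        mom1[[k]] <- cfg$beta1 * mom1[[k]] + (1 - cfg$beta1) * g
        mom2[[k]] <- cfg$beta2 * mom2[[k]] + (1 - cfg$beta2) * g^2
        m_hat <- mom1[[k]] / (1 - cfg$beta1^step)
        v_hat <- mom2[[k]] / (1 - cfg$beta2^step)
        theta[[k]] <- as.numeric(theta[[k]]) -
          cfg$learning_rate * m_hat / (sqrt(v_hat) + cfg$adam_eps)
      }
      model <- assign_params(model, fl$paths, theta)
      model <- .update_bn(model, fw$bn_stats, cfg$bn_momentum)
    }
    train_loss <- c(train_loss, ep_loss / length(train_set))
    if (!is.null(val_set) && length(val_set) > 0) {
      vl <- .eval_loss(model, val_set, bases, schedule, grid)
      val_loss <- c(val_loss, vl)
      if (vl < best - 1e-12) {
        best <- vl; best_model <- model; best_epoch <- epoch; wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    } else {
      best_model <- model; best_epoch <- epoch
    }
    if (cfg$verbose > 0 && epoch %% cfg$verbose == 0)
      message(sprintf("epoch %d  train %.5g%s", epoch,
                      train_loss[epoch],
                      if (length(val_loss)) sprintf("  val %.5g", val_loss[epoch]) else ""))
  }
  list(model = best_model, train_loss = train_loss, val_loss = val_loss,
       best_epoch = best_epoch)
}
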