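# Minimal reverse-mode automatic differentiation tape.
#
# The unrolled separation network differentiates through multiplicative
# MLEM updates (matrix products, elementwise ratios, causal convolutions on
# the fine time grid) and through convolutional regularisers (conv2d, batch
# normalization, PReLU). No R deep-learning backend ships the causal-
# convolution operators the spectral model needs, so the package carries
# its own tape: each operation stores a value and a vector-Jacobian-product
# closure, and `tape_backward()` accumulates gradients in reverse order.
# Gradients are verified against central finite differences in the tests.

tape_new <- function() {
  env <- new.env(parent = emptyenv())
  env$val <- list()
  env$back <- list()    # per node: NULL (leaf) or list(parents=, vjp=)
  env$n <- 0L
  class(env) <- "ad_tape"
  env
}

tp_node <- function(tape, value, parents = NULL, vjp = NULL) {
  # force the promises first: evaluating `value`/`parents` may itself add
  # nodes to the tape, so the counter must only move afterwards
  force(value); force(parents); force(vjp)
  tape$n <- tape$n + 1L
  tape$val[[tape$n]] <- value
  tape$back[[tape$n]] <- if (is.null(parents)) NULL else
    list(parents = parents, vjp = vjp)
  tape$n
}

tp_leaf <- function(tape, value) tp_node(tape, value)

tp_val <- function(tape, id) {
  # force `id` before touching the list: its promise may append nodes
  force(id)
  tape$val[[id]]
}

# reverse sweep from the (scalar) node `loss`; returns gradients for `wrt`
tape_backward <- function(tape, loss, wrt) {
  g <- vector("list", tape$n)
  g[[loss]] <- 1
  for (id in seq(tape$n, 1L)) {
    bk <- tape$back[[id]]
    if (is.null(bk) || is.null(g[[id]])) next
    pg <- bk$vjp(g[[id]])
    for (k in seq_along(bk$parents)) {
      p <- bk$parents[k]
      if (is.null(pg[[k]])) next
      g[[p]] <- if (is.null(g[[p]])) pg[[k]] else g[[p]] + pg[[k]]
    }
  }
  lapply(wrt, function(id) {
    gr <- g[[id]]
    if (is.null(gr)) gr <- array(0, dim = dim(tape$val[[id]]) %||%
                                   length(tape$val[[id]]))
    gr
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- elementwise ops -------------------------------------------------

tp_add <- function(tape, a, b) {
  tp_node(tape, tp_val(tape, a) + tp_val(tape, b), c(a, b),
          function(g) list(g, g))
}

tp_sub <- function(tape, a, b) {
  tp_node(tape, tp_val(tape, a) - tp_val(tape, b), c(a, b),
          function(g) list(g, -g))
}

tp_mul <- function(tape, a, b) {
  va <- tp_val(tape, a); vb <- tp_val(tape, b)
  tp_node(tape, va * vb, c(a, b), function(g) list(g * vb, g * va))
}

tp_div <- function(tape, a, b) {
  va <- tp_val(tape, a); vb <- tp_val(tape, b)
  out <- va / vb
  tp_node(tape, out, c(a, b),
          function(g) list(g / vb, -g * out / vb))
}

tp_add_const <- function(tape, a, const) {
  tp_node(tape, tp_val(tape, a) + const, a, function(g) list(g))
}

tp_scale <- function(tape, a, s) {
  tp_node(tape, tp_val(tape, a) * s, a, function(g) list(g * s))
}

tp_pmax_const <- function(tape, a, floor) {
  va <- tp_val(tape, a)
  keep <- va > floor
  tp_node(tape, pmax(va, floor), a, function(g) list(g * keep))
}

tp_relu <- function(tape, a) {
  va <- tp_val(tape, a)
  pos <- va > 0
  tp_node(tape, va * pos, a, function(g) list(g * pos))
}

## ---- linear algebra --------------------------------------------------

# a %*% b, with optional transposes
tp_matmul <- function(tape, a, b, ta = FALSE, tb = FALSE) {
  va <- tp_val(tape, a); vb <- tp_val(tape, b)
  A <- if (ta) t(va) else va
  B <- if (tb) t(vb) else vb
  tp_node(tape, A %*% B, c(a, b), function(g) {
    ga <- g %*% t(B); if (ta) ga <- t(ga)
    gb <- t(A) %*% g; if (tb) gb <- t(gb)
    list(ga, gb)
  })
}

tp_colsums <- function(tape, a) {
  va <- tp_val(tape, a)
  J <- nrow(va)
  tp_node(tape, matrix(colSums(va), 1), a,
          function(g) list(matrix(rep(as.numeric(g), each = J), J)))
}

# broadcast a 1 x n row vector to J x n
tp_bcast_row <- function(tape, v, J) {
  vv <- tp_val(tape, v)
  tp_node(tape, matrix(rep(as.numeric(vv), each = J), J), v,
          function(g) list(matrix(colSums(g), 1)))
}

tp_reshape <- function(tape, a, dims) {
  va <- tp_val(tape, a)
  old <- dim(va) %||% length(va)
  tp_node(tape, array(va, dims), a,
          function(g) list(array(g, old)))
}

# stack a list of equal-shape arrays along a new last dimension
tp_stack <- function(tape, ids) {
  vals <- lapply(ids, function(i) tp_val(tape, i))
  d <- dim(vals[[1]]) %||% length(vals[[1]])
  out <- array(unlist(vals), c(d, length(ids)))
  tp_node(tape, out, as.integer(ids), function(g) {
    gm <- matrix(g, prod(d), length(ids))
    lapply(seq_along(ids), function(k) array(gm[, k], d))
  })
}

# extract slice k of the last dimension, reshaped to `dims`
tp_unstack <- function(tape, a, k, dims) {
  va <- tp_val(tape, a)
  d <- dim(va)
  nlast <- d[length(d)]
  per <- prod(d) / nlast
  vm <- matrix(va, per, nlast)
  tp_node(tape, array(vm[, k], dims), a, function(g) {
    om <- matrix(0, per, nlast)
    om[, k] <- as.numeric(g)
    list(array(om, d))
  })
}

## ---- temporal (causal convolution) ops -------------------------------

# frame-domain response matrix M = Fmat %*% t(causal_conv(t(B), h, dt))
tp_frame_conv_basis <- function(tape, h, Bt, Fmat, dt) {
  vh <- tp_val(tape, h)
  conv <- causal_conv(Bt, vh, dt)        # n_basis x fine_T
  tp_node(tape, Fmat %*% t(conv), h, function(g) {
    # dh[l] = dt * sum_{t,n} g[t,n] sum_i Fmat[t,i] Bt[n, i-l+1]
    list(pairsum_corr(Bt, t(g) %*% Fmat, dt))
  })
}

# fused h-step adjoint: out[l] = dt * sum_j sum_i (C B^T)[j, i-l+1] Y[j, i]
# with C (J x N) and Y (J x fine_T) nodes and the basis Bt (N x fine_T)
# constant. The voxel sum is folded into a crossproduct first, so the lag
# correlations only ever run over the N basis rows.
tp_hadj <- function(tape, C, Y, Bt, dt) {
  vC <- tp_val(tape, C); vY <- tp_val(tape, Y)
  tp_node(tape, pairsum_corr(Bt, crossprod(vC, vY), dt), c(C, Y),
          function(g) {
            CB <- causal_conv(Bt, as.numeric(g), dt)   # N x fine_T
            list(vY %*% t(CB), vC %*% CB)
          })
}

# out[l] = dt * sum_j sum_i x[j, i-l+1] y[j, i]; x, y both nodes
tp_pairsum_corr <- function(tape, x, y, dt) {
  vx <- tp_val(tape, x); vy <- tp_val(tape, y)
  tp_node(tape, pairsum_corr(vx, vy, dt), c(x, y), function(g) {
    gx <- causal_corr(vy, as.numeric(g), dt)
    gy <- causal_conv(vx, as.numeric(g), dt)
    if (!is.matrix(vx)) gx <- as.numeric(gx)
    if (!is.matrix(vy)) gy <- as.numeric(gy)
    list(gx, gy)
  })
}

## ---- loss ------------------------------------------------------------

# sum of squared differences to a constant target
tp_sse <- function(tape, a, target) {
  va <- tp_val(tape, a)
  diff <- va - target
  tp_node(tape, sum(diff^2), a, function(g) list(2 * g * diff))
}
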