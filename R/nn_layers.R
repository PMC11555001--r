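# Convolutional building blocks on batched image stacks laid out as
# (nx, ny, channels, batch) arrays. Each layer has a pure forward function
# (shared by the training tape and the plain evaluation path) and a tape
# wrapper with the corresponding vector-Jacobian products.

# Shift bookkeeping for row-matrix image stacks. Images are flattened to
# (nx*ny*B) x C matrices (pixel-and-batch rows, channel columns); a spatial
# shift is then a precomputed row-index lookup, with index np+1 pointing at
# an appended zero row. Indices are memoised per geometry.
.shift_cache <- new.env(parent = emptyenv())

.shift_indices <- function(nx, ny, B, kh, kw) {
  key <- paste(nx, ny, B, kh, kw)
  got <- .shift_cache[[key]]
  if (!is.null(got)) return(got)
  np <- nx * ny * B
  xi <- rep(seq_len(nx), times = ny * B)
  yi <- rep(rep(seq_len(ny), each = nx), times = B)
  base <- seq_len(np)
  r <- (kh - 1) / 2; s <- (kw - 1) / 2
  out <- list()
  for (u in seq_len(kh)) {
    for (v in seq_len(kw)) {
      di <- u - 1 - r; dj <- v - 1 - s
      sx <- xi - di; sy <- yi - dj
      ok <- sx >= 1 & sx <= nx & sy >= 1 & sy <= ny
      idx <- rep.int(np + 1L, np)
      idx[ok] <- base[ok] - di - dj * nx
      out[[length(out) + 1L]] <- idx
    }
  }
  .shift_cache[[key]] <- out
  out
}

.to_rows <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}

.from_rows <- function(m, d, C) {
  aperm(array(m, c(d[1], d[2], d[4], C)), c(1, 2, 4, 3))
}

# 3x3 (or 1x1) same-padding convolution; W is (kh, kw, Cin, Cout), b length Cout
conv2d_f <- function(x, W, b) {
  d <- dim(x)
  kh <- dim(W)[1]; kw <- dim(W)[2]
  Cin <- dim(W)[3]; Cout <- dim(W)[4]
  stopifnot(d[3] == Cin)
  np <- d[1] * d[2] * d[4]
  idx <- .shift_indices(d[1], d[2], d[4], kh, kw)
  xm <- rbind(.to_rows(x), 0)
  acc <- matrix(rep(b, each = np), np, Cout)
  for (k in seq_along(idx)) {
    u <- (k - 1) %/% kw + 1; v <- (k - 1) %% kw + 1
    acc <- acc + xm[idx[[k]], , drop = FALSE] %*% matrix(W[u, v, , ], Cin, Cout)
  }
  .from_rows(acc, d, Cout)
}

tp_conv2d <- function(tape, x, W, b) {
  vx <- tp_val(tape, x); vW <- tp_val(tape, W); vb <- tp_val(tape, b)
  d <- dim(vx)
  kh <- dim(vW)[1]; kw <- dim(vW)[2]
  Cin <- dim(vW)[3]; Cout <- dim(vW)[4]
  np <- d[1] * d[2] * d[4]
  idx <- .shift_indices(d[1], d[2], d[4], kh, kw)
  xm <- rbind(.to_rows(vx), 0)
  acc <- matrix(rep(vb, each = np), np, Cout)
  for (k in seq_along(idx)) {
    u <- (k - 1) %/% kw + 1; v <- (k - 1) %% kw + 1
    acc <- acc + xm[idx[[k]], , drop = FALSE] %*% matrix(vW[u, v, , ], Cin, Cout)
  }
  tp_node(tape, .from_rows(acc, d, Cout), c(x, W, b), function(g) {
    gm <- .to_rows(g)
    gb <- colSums(gm)
    gW <- array(0, dim(vW))
    gxm <- matrix(0, np + 1L, Cin)
    for (k in seq_along(idx)) {
      u <- (k - 1) %/% kw + 1; v <- (k - 1) %% kw + 1
      xs <- xm[idx[[k]], , drop = FALSE]
      gW[u, v, , ] <- crossprod(xs, gm)
      gpart <- gm %*% t(matrix(vW[u, v, , ], Cin, Cout))
      ii <- idx[[k]]
      gxm[ii, ] <- gxm[ii, , drop = FALSE] + gpart
    }
    list(.from_rows(gxm[seq_len(np), , drop = FALSE], d, Cin), gW, gb)
  })
}

# batch normalization over (pixels x batch) per channel
bn_f <- function(x, gamma, beta, mean_c, var_c, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  xn <- sweep(sweep(xm, 2, mean_c), 2, sqrt(var_c + eps), "/")
  out <- sweep(sweep(xn, 2, gamma, "*"), 2, beta, "+")
  aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_batch_stats <- function(x) {
  d <- dim(x)
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
  list(mean = colMeans(xm),
       var = colMeans(xm^2) - colMeans(xm)^2)
}

tp_bn <- function(tape, x, gamma, beta, eps = 1e-5) {
  vx <- tp_val(tape, x); vg <- tp_val(tape, gamma); vb <- tp_val(tape, beta)
  d <- dim(vx)
  n <- d[1] * d[2] * d[4]
  xm <- matrix(aperm(vx, c(1, 2, 4, 3)), n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xn <- sweep(xc, 2, istd, "*")
  out <- sweep(sweep(xn, 2, vg, "*"), 2, vb, "+")
  val <- aperm(array(out, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  node <- tp_node(tape, val, c(x, gamma, beta), function(g) {
    gm <- matrix(aperm(g, c(1, 2, 4, 3)), n, d[3])
    gbeta <- colSums(gm)
    ggamma <- colSums(gm * xn)
    gxn <- sweep(gm, 2, vg, "*")
    # standard batch-norm backward through mean and variance
    t1 <- sweep(gxn, 2, colMeans(gxn))
    t2 <- sweep(xn, 2, colMeans(gxn * xn), "*")
    gx <- sweep(t1 - t2, 2, istd, "*")
    list(aperm(array(gx, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3)),
         ggamma, gbeta)
  })
  attr(tape$val[[node]], "batch_stats") <- list(mean = mu, var = v)
  node
}

# PReLU with one learnable slope per channel
prelu_f <- function(x, a) {
  d <- dim(x)
  am <- rep(rep(a, each = d[1] * d[2]), times = d[4])
  pos <- x > 0
  x * pos + array(am, d) * x * !pos
}

tp_prelu <- function(tape, x, a) {
  vx <- tp_val(tape, x); va <- tp_val(tape, a)
  d <- dim(vx)
  am <- array(rep(rep(va, each = d[1] * d[2]), times = d[4]), d)
  pos <- vx > 0
  tp_node(tape, vx * pos + am * vx * !pos, c(x, a), function(g) {
    gx <- g * pos + g * am * !pos
    gneg <- g * vx * !pos
    ga <- vapply(seq_len(d[3]),
                 function(c) sum(gneg[, , c, ]), numeric(1))
    list(gx, ga)
  })
}

# 2x2 average pooling and nearest-neighbour upsampling (encoder-decoder)
avgpool2_f <- function(x) {
  d <- dim(x)
  i <- seq(1, d[1], by = 2); j <- seq(1, d[2], by = 2)
  (x[i, j, , , drop = FALSE] + x[i + 1, j, , , drop = FALSE] +
     x[i, j + 1, , , drop = FALSE] + x[i + 1, j + 1, , , drop = FALSE]) / 4
}

tp_avgpool2 <- function(tape, x) {
  vx <- tp_val(tape, x)
  d <- dim(vx)
  tp_node(tape, avgpool2_f(vx), x, function(g) {
    gx <- array(0, d)
    i <- seq(1, d[1], by = 2); j <- seq(1, d[2], by = 2)
    q <- g / 4
    gx[i, j, , ] <- q; gx[i + 1, j, , ] <- q
    gx[i, j + 1, , ] <- q; gx[i + 1, j + 1, , ] <- q
    list(gx)
  })
}

upsample2_f <- function(x) {
  d <- dim(x)
  out <- array(0, c(2 * d[1], 2 * d[2], d[3], d[4]))
  i <- seq(1, 2 * d[1], by = 2); j <- seq(1, 2 * d[2], by = 2)
  out[i, j, , ] <- x; out[i + 1, j, , ] <- x
  out[i, j + 1, , ] <- x; out[i + 1, j + 1, , ] <- x
  out
}

tp_upsample2 <- function(tape, x) {
  vx <- tp_val(tape, x)
  d <- dim(vx)
  tp_node(tape, upsample2_f(vx), x, function(g) {
    i <- seq(1, 2 * d[1], by = 2); j <- seq(1, 2 * d[2], by = 2)
    list(g[i, j, , , drop = FALSE] + g[i + 1, j, , , drop = FALSE] +
           g[i, j + 1, , , drop = FALSE] + g[i + 1, j + 1, , , drop = FALSE])
  })
}

# Xavier-uniform initial weights for a (kh, kw, Cin, Cout) kernel
xavier_conv <- function(kh, kw, cin, cout) {
  fan_in <- kh * kw * cin; fan_out <- kh * kw * cout
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(kh * kw * cin * cout, -lim, lim), c(kh, kw, cin, cout))
}
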