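# Minimal CPU neural-network primitives for the U-Net harness.
# Tensors are numeric arrays [height, width, channels]; 3x3 'same'
# convolutions are computed as im2col gathers followed by a BLAS gemm, and
# the input gradient reuses the same machinery as a convolution with the
# 180-degree-rotated, channel-transposed kernels (exact for zero padding).

.im2col_cache <- new.env(parent = emptyenv())

# Gather index for an im2col of shape (H, W, C): column j corresponds to the
# kernel offset (dy, dx, channel), dy fastest; row p to the output pixel
# (h, w), h fastest.  Cached per shape.
im2col_index <- function(H, W, C) {
  key <- sprintf("%d_%d_%d", H, W, C)
  idx <- .im2col_cache[[key]]
  if (!is.null(idx)) {
    return(idx)
  }
  hp <- H + 2L
  wp <- W + 2L
  base <- rep((seq_len(W) - 1L) * hp, each = H) + rep(seq_len(H), W) # (h, w) -> xp[h, w]
  offs <- integer(9L * C)
  j <- 0L
  for (cc in seq_len(C)) {
    for (dx in 0:2) {
      for (dy in 0:2) {
        j <- j + 1L
        offs[j] <- (cc - 1L) * hp * wp + dx * hp + dy
      }
    }
  }
  idx <- rep(offs, each = H * W) + rep(base, 9L * C)
  .im2col_cache[[key]] <- idx
  idx
}

im2col3 <- function(x) {
  d <- dim(x)
  H <- d[1]
  W <- d[2]
  C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  matrix(xp[im2col_index(H, W, C)], H * W, 9L * C)
}

# Kernel matrix is [9*Cin, Cout] with row index (dy, dx, cin), dy fastest —
# the same nesting as im2col3's column order.
rot_weights <- function(Wm, cin, cout) {
  Wa <- array(Wm, c(3L, 3L, cin, cout))
  Wr <- aperm(Wa[3:1, 3:1, , , drop = FALSE], c(1, 2, 4, 3))
  matrix(Wr, 9L * cout, cin)
}

conv_fw <- function(x, layer) {
  d <- dim(x)
  cols <- im2col3(x)
  out <- cols %*% layer$W
  out <- out + rep(layer$b, each = nrow(out))
  list(y = array(out, c(d[1], d[2], ncol(layer$W))), cols = cols, in_ch = d[3])
}

conv_bw <- function(dout, cache, layer) {
  d <- dim(dout)
  dmat <- matrix(dout, d[1] * d[2], d[3])
  dW <- crossprod(cache$cols, dmat)
  db <- colSums(dmat)
  dcols <- im2col3(dout)
  dx <- array(dcols %*% rot_weights(layer$W, cache$in_ch, d[3]), c(d[1], d[2], cache$in_ch))
  list(dW = dW, db = db, dx = dx)
}

# Instance normalization: per-sample, per-channel standardization with a
# learnable scale/shift.  Keeps pre-activations centered so the Dice loss
# cannot drive the logits into sigmoid saturation.
in_fw <- function(x, g, be, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  inv <- 1 / sqrt(colSums(xc^2) / n + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, g, `*`), 2L, be, `+`)
  list(y = array(y, d), xhat = xhat, inv = inv, dim = d)
}

in_bw <- function(dout, g, cache) {
  d <- cache$dim
  n <- d[1] * d[2]
  dy <- matrix(dout, n, d[3])
  dbe <- colSums(dy)
  dg <- colSums(dy * cache$xhat)
  dxhat <- sweep(dy, 2L, g, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dx <- sweep(
    sweep(dxhat, 2L, s1 / n) - sweep(cache$xhat, 2L, s2 / n, `*`),
    2L, cache$inv, `*`
  )
  list(dg = dg, dbe = dbe, dx = array(dx, d))
}

relu_fw <- function(x) {
  x[x < 0] <- 0
  x
}

relu_bw <- function(dout, y) {
  dout[y <= 0] <- 0
  dout
}

pool_fw <- function(x) {
  d <- dim(x)
  ro <- seq(1L, d[1], 2L)
  re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L)
  ce <- seq(2L, d[2], 2L)
  x11 <- x[ro, co, , drop = FALSE]
  x21 <- x[re, co, , drop = FALSE]
  x12 <- x[ro, ce, , drop = FALSE]
  x22 <- x[re, ce, , drop = FALSE]
  y <- pmax(x11, x21, x12, x22)
  a1 <- x11 == y
  a2 <- x21 == y & !a1
  a3 <- x12 == y & !(a1 | a2)
  a4 <- !(a1 | a2 | a3)
  list(y = y, masks = list(a1, a2, a3, a4), in_dim = d)
}

pool_bw <- function(dout, cache) {
  d <- cache$in_dim
  ro <- seq(1L, d[1], 2L)
  re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L)
  ce <- seq(2L, d[2], 2L)
  dx <- array(0, d)
  m <- cache$masks
  dx[ro, co, ] <- dout * m[[1]]
  dx[re, co, ] <- dout * m[[2]]
  dx[ro, ce, ] <- dout * m[[3]]
  dx[re, ce, ] <- dx[re, ce, ] + dout * m[[4]]
  dx
}

up_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

up_bw <- function(dout) {
  d <- dim(dout)
  ro <- seq(1L, d[1], 2L)
  re <- seq(2L, d[1], 2L)
  co <- seq(1L, d[2], 2L)
  ce <- seq(2L, d[2], 2L)
  dout[ro, co, , drop = FALSE] + dout[re, co, , drop = FALSE] +
    dout[ro, ce, , drop = FALSE] + dout[re, ce, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3]))
  out[, , seq_len(da[3])] <- a
  out[, , da[3] + seq_len(db[3])] <- b
  out
}
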