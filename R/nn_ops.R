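# Low-level neural-network primitives on (H, W, C) arrays.
#
# Convolutions are computed by the shift decomposition of same-padded
# convolution: a k x k conv is k^2 matrix products of the shifted input,
# reshaped to (H*W x Cin), with the (Cin x Cout) kernel slice, so all heavy
# lifting lands in the BLAS that R links. Batch size is one map per call;
# training-mode calls return caches for the hand-written backward passes.

.conv_init <- function(k, cin, cout) {
  # He initialization for ReLU nets
  list(w = array(stats::rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, cout)),
       b = numeric(cout))
}

.conv_forward <- function(x, p) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  kd <- dim(p$w); k <- kd[1]; cout <- kd[4]
  if (kd[3] != cin)
    stop(sprintf("conv channel mismatch: kernel expects %d, input has %d",
                 kd[3], cin))
  if (k == 1L) {
    xm <- x; dim(xm) <- c(H * W, cin)
    out <- xm %*% matrix(p$w, cin, cout)
  } else {
    pad <- (k - 1L) %/% 2L
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
    out <- matrix(0, H * W, cout)
    for (ky in seq_len(k)) for (kx in seq_len(k)) {
      xs <- xp[(ky - 1L) + seq_len(H), (kx - 1L) + seq_len(W), , drop = FALSE]
      dim(xs) <- c(H * W, cin)
      out <- out + xs %*% matrix(p$w[ky, kx, , ], cin, cout)
    }
  }
  out <- out + rep(p$b, each = H * W)
  dim(out) <- c(H, W, cout)
  out
}

.conv_backward <- function(x, p, dout) {
  d <- dim(x); H <- d[1]; W <- d[2]; cin <- d[3]
  kd <- dim(p$w); k <- kd[1]; cout <- kd[4]
  dmat <- dout; dim(dmat) <- c(H * W, cout)
  db <- colSums(dmat)
  dw <- array(0, kd)
  if (k == 1L) {
    xm <- x; dim(xm) <- c(H * W, cin)
    dw[1, 1, , ] <- crossprod(xm, dmat)
    dx <- dmat %*% t(matrix(p$w, cin, cout))
    dim(dx) <- c(H, W, cin)
  } else {
    pad <- (k - 1L) %/% 2L
    xp <- array(0, c(H + 2L * pad, W + 2L * pad, cin))
    xp[pad + seq_len(H), pad + seq_len(W), ] <- x
    dxp <- array(0, dim(xp))
    for (ky in seq_len(k)) for (kx in seq_len(k)) {
      ry <- (ky - 1L) + seq_len(H); rx <- (kx - 1L) + seq_len(W)
      xs <- xp[ry, rx, , drop = FALSE]
      dim(xs) <- c(H * W, cin)
      dw[ky, kx, , ] <- crossprod(xs, dmat)
      dxs <- dmat %*% t(matrix(p$w[ky, kx, , ], cin, cout))
      dim(dxs) <- c(H, W, cin)
      dxp[ry, rx, ] <- dxp[ry, rx, , drop = FALSE] + dxs
    }
    dx <- dxp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
  }
  list(dx = dx, dw = dw, db = db)
}

.bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       rmean = rep(0, c), rvar = rep(1, c))
}

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

# batch statistics over all spatial positions (batch of one map);
# training mode updates running statistics and returns the updated params
.bn_forward <- function(x, p, training, keep = FALSE) {
  d <- dim(x); N <- d[1] * d[2]; C <- d[3]
  xm <- x; dim(xm) <- c(N, C)
  if (training) {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm * xm) - mu * mu, 0)
    p$rmean <- (1 - .BN_MOMENTUM) * p$rmean + .BN_MOMENTUM * mu
    p$rvar <- (1 - .BN_MOMENTUM) * p$rvar + .BN_MOMENTUM * v
  } else {
    mu <- p$rmean
    v <- p$rvar
  }
  istd <- 1 / sqrt(v + .BN_EPS)
  xhat <- (xm - rep(mu, each = N)) * rep(istd, each = N)
  out <- xhat * rep(p$gamma, each = N) + rep(p$beta, each = N)
  dim(out) <- d
  list(out = out, p = p,
       cache = if (keep) list(xhat = xhat, istd = istd, dims = d) else NULL)
}

.bn_backward <- function(p, cache, dout) {
  d <- cache$dims; N <- d[1] * d[2]; C <- d[3]
  dmat <- dout; dim(dmat) <- c(N, C)
  dgamma <- colSums(dmat * cache$xhat)
  dbeta <- colSums(dmat)
  dxhat <- dmat * rep(p$gamma, each = N)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(m1, each = N) - cache$xhat * rep(m2, each = N)) *
    rep(cache$istd, each = N)
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# 2x2 max pooling, stride 2; spatial size must be even
.maxpool_forward <- function(x, keep = FALSE) {
  d <- dim(x); H <- d[1]; W <- d[2]
  if (H %% 2L != 0L || W %% 2L != 0L)
    stop("internal error: pooling a map whose size is not even")
  o <- seq(1L, H, 2L); e <- seq(2L, H, 2L)
  oc <- seq(1L, W, 2L); ec <- seq(2L, W, 2L)
  a <- x[o, oc, , drop = FALSE]; b <- x[e, oc, , drop = FALSE]
  cc <- x[o, ec, , drop = FALSE]; dd <- x[e, ec, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  cache <- NULL
  if (keep) {
    ma <- a == out
    mb <- (b == out) & !ma
    mc <- (cc == out) & !ma & !mb
    md <- !ma & !mb & !mc
    cache <- list(ma = ma, mb = mb, mc = mc, md = md, dims = d)
  }
  list(out = out, cache = cache)
}

.maxpool_backward <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  o <- seq(1L, d[1], 2L); e <- seq(2L, d[1], 2L)
  oc <- seq(1L, d[2], 2L); ec <- seq(2L, d[2], 2L)
  dx[o, oc, ] <- dout * cache$ma
  dx[e, oc, ] <- dout * cache$mb
  dx[o, ec, ] <- dout * cache$mc
  dx[e, ec, ] <- dout * cache$md
  dx
}

# nearest-neighbour 2x upsampling
.upsample_forward <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}

.upsample_backward <- function(dout) {
  d <- dim(dout)
  o <- seq(1L, d[1], 2L); e <- seq(2L, d[1], 2L)
  oc <- seq(1L, d[2], 2L); ec <- seq(2L, d[2], 2L)
  dout[o, oc, , drop = FALSE] + dout[e, oc, , drop = FALSE] +
    dout[o, ec, , drop = FALSE] + dout[e, ec, , drop = FALSE]
}

# channel concatenation (channel-last layout makes this a plain c())
.cat3 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- c(a, b)
  dim(out) <- c(da[1], da[2], da[3] + db[3])
  out
}

.slice_channels <- function(x, from, to) {
  x[, , from:to, drop = FALSE]
}
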