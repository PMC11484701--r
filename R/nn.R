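# Minimal convolutional-network engine: 3x3 convolutions via shifted-gather
# im2col + BLAS gemm, ReLU, 2x2 average pooling / nearest upsampling, exact
# reverse-mode gradients, and Adam. Activations are stored as (B*H*W) x C
# matrices in column-major pixel order; convolutions use zero padding.

.dwisure_cache <- new.env(parent = emptyenv())

# Gather indices for the nine 3x3 taps on a batched H x W grid. Out-of-image
# taps point at a trailing all-zero row. Tap k and tap 10-k are opposite
# offsets, which makes the gather self-adjoint up to that reindexing.
conv_grids <- function(H, W, B) {
  key <- paste0("c", H, "x", W, "x", B)
  g <- .dwisure_cache[[key]]
  if (!is.null(g)) return(g)
  n <- H * W
  r <- rep.int(seq_len(H), W)
  cc <- rep(seq_len(W), each = H)
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  zero_row <- n * B + 1L
  idx <- vector("list", 9L)
  for (k in 1:9) {
    sr <- r + offs$dy[k]; sc <- cc + offs$dx[k]
    ii <- (sc - 1L) * H + sr
    ii[sr < 1L | sr > H | sc < 1L | sc > W] <- NA_integer_
    if (B > 1L) ii <- rep(ii, B) + rep((0:(B - 1L)) * n, each = n)
    ii[is.na(ii)] <- zero_row
    idx[[k]] <- ii
  }
  g <- list(idx = idx, n = n * B)
  .dwisure_cache[[key]] <- g
  g
}

im2col <- function(X, g) {
  Cin <- ncol(X)
  Xz <- rbind(X, 0)
  out <- matrix(0, nrow(X), 9L * Cin)
  for (k in 1:9)
    out[, ((k - 1L) * Cin + 1L):(k * Cin)] <- Xz[g$idx[[k]], , drop = FALSE]
  out
}

conv_fwd <- function(X, layer, g) {
  Xc <- im2col(X, g)
  Z <- Xc %*% layer$W
  Z <- Z + matrix(layer$b, nrow(Z), length(layer$b), byrow = TRUE)
  list(Z = Z, Xc = Xc)
}

conv_bwd <- function(dZ, layer, cache, g, need_dx = TRUE) {
  Cin <- ncol(cache$Xc) %/% 9L
  gr <- list(W = crossprod(cache$Xc, dZ), b = colSums(dZ))
  dX <- NULL
  if (need_dx) {
    Tm <- tcrossprod(dZ, layer$W)  # n x 9Cin
    dX <- matrix(0, nrow(dZ), Cin)
    for (k in 1:9) {
      Tz <- rbind(Tm[, ((k - 1L) * Cin + 1L):(k * Cin), drop = FALSE], 0)
      dX <- dX + Tz[g$idx[[10L - k]], , drop = FALSE]
    }
  }
  list(grad = gr, dX = dX)
}

relu_fwd <- function(Z) {
  M <- Z > 0
  list(A = Z * M, M = M)
}

# 2x2 average-pool index sets; the four sets partition the fine grid.
pool_grids <- function(H, W, B) {
  key <- paste0("p", H, "x", W, "x", B)
  g <- .dwisure_cache[[key]]
  if (!is.null(g)) return(g)
  Hc <- H %/% 2L; Wc <- W %/% 2L
  rc <- rep.int(seq_len(Hc), Wc)
  cc <- rep(seq_len(Wc), each = Hc)
  idx <- vector("list", 4L); m <- 0L
  for (dj in 0:1) for (di in 0:1) {
    m <- m + 1L
    fr <- 2L * rc - 1L + di; fc <- 2L * cc - 1L + dj
    ii <- (fc - 1L) * H + fr
    if (B > 1L) ii <- rep(ii, B) + rep((0:(B - 1L)) * (H * W), each = Hc * Wc)
    idx[[m]] <- ii
  }
  g <- list(idx = idx, nf = H * W * B, nc = Hc * Wc * B)
  .dwisure_cache[[key]] <- g
  g
}

avgpool_fwd <- function(X, pg) {
  0.25 * (X[pg$idx[[1]], , drop = FALSE] + X[pg$idx[[2]], , drop = FALSE] +
          X[pg$idx[[3]], , drop = FALSE] + X[pg$idx[[4]], , drop = FALSE])
}

avgpool_bwd <- function(dXc, pg) {
  dX <- matrix(0, pg$nf, ncol(dXc))
  for (k in 1:4) dX[pg$idx[[k]], ] <- 0.25 * dXc
  dX
}

upsample_fwd <- function(Xc, pg) {
  X <- matrix(0, pg$nf, ncol(Xc))
  for (k in 1:4) X[pg$idx[[k]], ] <- Xc
  X
}

upsample_bwd <- function(dX, pg) {
  dX[pg$idx[[1]], , drop = FALSE] + dX[pg$idx[[2]], , drop = FALSE] +
    dX[pg$idx[[3]], , drop = FALSE] + dX[pg$idx[[4]], , drop = FALSE]
}

init_conv <- function(cin, cout, gain = 1) {
  sd <- gain * sqrt(2 / (9 * cin))
  list(W = matrix(stats::rnorm(9L * cin * cout, 0, sd), 9L * cin, cout),
       b = numeric(cout))
}

# ---- DnCNN ----------------------------------------------------------------

dncnn_init <- function(depth, width, in_channels) {
  p <- vector("list", depth)
  p[[1]] <- init_conv(in_channels, width)
  for (l in seq_len(depth - 2L) + 1L) p[[l]] <- init_conv(width, width)
  p[[depth]] <- init_conv(width, 1L, gain = 0.01)  # start near the identity
  p
}

dncnn_fwd <- function(params, X, g) {
  depth <- length(params)
  caches <- vector("list", depth)
  A <- X
  for (l in seq_len(depth - 1L)) {
    cf <- conv_fwd(A, params[[l]], g)
    rf <- relu_fwd(cf$Z)
    caches[[l]] <- list(Xc = cf$Xc, M = rf$M)
    A <- rf$A
  }
  cf <- conv_fwd(A, params[[depth]], g)
  caches[[depth]] <- list(Xc = cf$Xc)
  list(raw = cf$Z, caches = caches)
}

dncnn_bwd <- function(params, caches, dRaw, g) {
  depth <- length(params)
  grads <- vector("list", depth)
  bw <- conv_bwd(dRaw, params[[depth]], caches[[depth]], g,
                 need_dx = depth > 1L)
  grads[[depth]] <- bw$grad
  dA <- bw$dX
  for (l in rev(seq_len(depth - 1L))) {
    dZ <- dA * caches[[l]]$M
    bw <- conv_bwd(dZ, params[[l]], caches[[l]], g, need_dx = l > 1L)
    grads[[l]] <- bw$grad
    dA <- bw$dX
  }
  grads
}

# ---- U-Net ----------------------------------------------------------------

unet_init <- function(levels, width, in_channels) {
  w <- width * 2^(seq_len(levels) - 1L)
  enc <- vector("list", levels)
  dec <- vector("list", levels - 1L)
  prev <- in_channels
  for (l in seq_len(levels)) {
    enc[[l]] <- list(c1 = init_conv(prev, w[l]), c2 = init_conv(w[l], w[l]))
    prev <- w[l]
  }
  for (l in seq_len(levels - 1L))
    dec[[l]] <- list(c1 = init_conv(w[l + 1L] + w[l], w[l]),
                     c2 = init_conv(w[l], w[l]))
  list(enc = enc, dec = dec, final = init_conv(w[1L], 1L, gain = 0.01))
}

conv_relu_fwd <- function(A, layer, g) {
  cf <- conv_fwd(A, layer, g)
  rf <- relu_fwd(cf$Z)
  list(A = rf$A, cache = list(Xc = cf$Xc, M = rf$M))
}

conv_relu_bwd <- function(dA, layer, cache, g, need_dx = TRUE) {
  conv_bwd(dA * cache$M, layer, cache, g, need_dx)
}

unet_fwd <- function(params, X, H, W, B) {
  L <- length(params$enc)
  cg <- vector("list", L); pg <- vector("list", L - 1L)
  h <- H; w <- W
  for (l in seq_len(L)) {
    cg[[l]] <- conv_grids(h, w, B)
    if (l < L) { pg[[l]] <- pool_grids(h, w, B); h <- h %/% 2L; w <- w %/% 2L }
  }
  enc_cache <- vector("list", L)
  skips <- vector("list", L - 1L)
  A <- X
  for (l in seq_len(L)) {
    s1 <- conv_relu_fwd(A, params$enc[[l]]$c1, cg[[l]])
    s2 <- conv_relu_fwd(s1$A, params$enc[[l]]$c2, cg[[l]])
    enc_cache[[l]] <- list(c1 = s1$cache, c2 = s2$cache)
    A <- s2$A
    if (l < L) { skips[[l]] <- A; A <- avgpool_fwd(A, pg[[l]]) }
  }
  dec_cache <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    U <- upsample_fwd(A, pg[[l]])
    C <- cbind(U, skips[[l]])
    s1 <- conv_relu_fwd(C, params$dec[[l]]$c1, cg[[l]])
    s2 <- conv_relu_fwd(s1$A, params$dec[[l]]$c2, cg[[l]])
    dec_cache[[l]] <- list(c1 = s1$cache, c2 = s2$cache,
                           n_up = ncol(U))
    A <- s2$A
  }
  cf <- conv_fwd(A, params$final, cg[[1L]])
  list(raw = cf$Z,
       caches = list(enc = enc_cache, dec = dec_cache, final = list(Xc = cf$Xc),
                     cg = cg, pg = pg))
}

unet_bwd <- function(params, caches, dRaw) {
  L <- length(params$enc)
  cg <- caches$cg; pg <- caches$pg
  grads <- list(enc = vector("list", L), dec = vector("list", L - 1L))
  bw <- conv_bwd(dRaw, params$final, caches$final, cg[[1L]])
  grads$final <- bw$grad
  dA <- bw$dX
  dskip <- vector("list", L - 1L)
  for (l in seq_len(L - 1L)) {
    dc <- caches$dec[[l]]
    b2 <- conv_relu_bwd(dA, params$dec[[l]]$c2, dc$c2, cg[[l]])
    b1 <- conv_relu_bwd(b2$dX, params$dec[[l]]$c1, dc$c1, cg[[l]])
    grads$dec[[l]] <- list(c1 = b1$grad, c2 = b2$grad)
    dU <- b1$dX[, seq_len(dc$n_up), drop = FALSE]
    dskip[[l]] <- b1$dX[, -seq_len(dc$n_up), drop = FALSE]
    dA <- upsample_bwd(dU, pg[[l]])
  }
  for (l in rev(seq_len(L))) {
    if (l < L) dA <- avgpool_bwd(dA, pg[[l]]) + dskip[[l]]
    ec <- caches$enc[[l]]
    b2 <- conv_relu_bwd(dA, params$enc[[l]]$c2, ec$c2, cg[[l]])
    b1 <- conv_relu_bwd(b2$dX, params$enc[[l]]$c1, ec$c1, cg[[l]],
                        need_dx = l > 1L)
    grads$enc[[l]] <- list(c1 = b1$grad, c2 = b2$grad)
    dA <- b1$dX
  }
  grads
}

# ---- shared entry points --------------------------------------------------

# Forward pass of a denoiser net on a batched (B*H*W) x Cin activation
# matrix; channel 1 is the target. Returns the denoised target (n x 1) and
# the cache needed for gradients.
net_fwd <- function(net, X, H, W, B) {
  if (net$config$family == "dncnn") {
    g <- conv_grids(H, W, B)
    fw <- dncnn_fwd(net$params, X, g)
    fw$g <- g
  } else {
    fw <- unet_fwd(net$params, X, H, W, B)
  }
  out <- if (net$config$residual) X[, 1L, drop = FALSE] - fw$raw else fw$raw
  list(out = out, fw = fw)
}

# Gradients of a scalar loss with respect to all parameters, given dL/dout.
net_bwd <- function(net, state, dOut) {
  dRaw <- if (net$config$residual) -dOut else dOut
  if (net$config$family == "dncnn")
    dncnn_bwd(net$params, state$fw$caches, dRaw, state$fw$g)
  else
    unet_bwd(net$params, state$fw$caches, dRaw)
}

flatten_params <- function(p) unlist(p, use.names = FALSE)

unflatten_params <- function(flat, skel) {
  i <- 0L
  rec <- function(x) {
    if (is.list(x)) return(lapply(x, rec))
    n <- length(x)
    v <- flat[(i + 1L):(i + n)]
    i <<- i + n
    if (is.null(dim(x))) v else array(v, dim(x))
  }
  rec(skel)
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}
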