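# Internal neural-network engine.
#
# Feature maps are (B * nvox) x C numeric matrices: voxels in column-major
# (x fastest) order, samples stacked along rows.  Compiled kernels in
# src/kernels.cpp do the convolution/pooling/upsampling work; batch
# normalization, ReLU, softmax and Adam live here.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

xavier_mat <- function(nrow, ncol, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nrow * ncol, -lim, lim), nrow, ncol)
}

relu_fwd <- function(X) {
  mask <- X > 0
  X[!mask] <- 0
  list(y = X, mask = mask)
}

bn_fwd <- function(X, g, be, rm, rv, train) {
  C <- ncol(X)
  Y <- X
  if (train) {
    xhat <- X
    istd <- numeric(C)
    mu <- numeric(C)
    v <- numeric(C)
    n <- nrow(X)
    for (j in seq_len(C)) {
      xc <- X[, j]
      m <- sum(xc) / n
      xc <- xc - m
      vj <- sum(xc * xc) / n
      is <- 1 / sqrt(vj + BN_EPS)
      xhat[, j] <- xc * is
      Y[, j] <- g[j] * xhat[, j] + be[j]
      istd[j] <- is; mu[j] <- m; v[j] <- vj
    }
    rm_new <- (1 - BN_MOMENTUM) * rm + BN_MOMENTUM * mu
    rv_new <- (1 - BN_MOMENTUM) * rv + BN_MOMENTUM * v
    list(y = Y, xhat = xhat, istd = istd, rm = rm_new, rv = rv_new)
  } else {
    for (j in seq_len(C))
      Y[, j] <- g[j] * (X[, j] - rm[j]) / sqrt(rv[j] + BN_EPS) + be[j]
    list(y = Y)
  }
}

bn_bwd <- function(dY, cache, g) {
  C <- ncol(dY)
  dX <- dY
  dg <- numeric(C)
  dbe <- numeric(C)
  for (j in seq_len(C)) {
    dy <- dY[, j]
    xh <- cache$xhat[, j]
    dg[j] <- sum(dy * xh)
    dbe[j] <- sum(dy)
    dX[, j] <- g[j] * cache$istd[j] *
      (dy - mean(dy) - xh * mean(dy * xh))
  }
  list(dx = dX, dg = dg, dbe = dbe)
}

# one "node" = conv(3x3x3) -> ReLU -> BN; a block is two nodes
node_fwd <- function(params, state, pfx, X, d, B, train) {
  W <- params[[paste0(pfx, "_W")]]
  b <- params[[paste0(pfx, "_b")]]
  h <- conv3_fwd(X, d[1], d[2], d[3], B, W, b)
  r <- relu_fwd(h)
  bn <- bn_fwd(r$y, params[[paste0(pfx, "_g")]],
               params[[paste0(pfx, "_be")]],
               state[[paste0(pfx, "_rm")]],
               state[[paste0(pfx, "_rv")]], train)
  cache <- if (train) list(x = X, mask = r$mask, bn = bn) else NULL
  list(y = bn$y, cache = cache,
       rm = bn$rm, rv = bn$rv)
}

node_bwd <- function(params, pfx, dY, cache, d, B, grads) {
  g <- params[[paste0(pfx, "_g")]]
  bb <- bn_bwd(dY, cache$bn, g)
  grads[[paste0(pfx, "_g")]] <- bb$dg
  grads[[paste0(pfx, "_be")]] <- bb$dbe
  dh <- bb$dx
  dh[!cache$mask] <- 0
  cb <- conv3_bwd(cache$x, dh, d[1], d[2], d[3], B,
                  params[[paste0(pfx, "_W")]])
  grads[[paste0(pfx, "_W")]] <- cb$dw
  grads[[paste0(pfx, "_b")]] <- as.numeric(cb$db)
  list(dx = cb$dx, grads = grads)
}

softmax_rows <- function(S) {
  m <- S[, 1]
  for (j in seq_len(ncol(S))[-1]) m <- pmax(m, S[, j])
  P <- exp(S - m)
  P / rowSums(P)
}

# labels: 0-based integer class indices, length nrow(scores)
softmax_ce <- function(scores, labels) {
  P <- softmax_rows(scores)
  n <- nrow(P)
  ix <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(P[ix], 1e-12)))
  G <- P
  G[ix] <- G[ix] - 1
  list(loss = loss, grad = G / n)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * gr
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * gr * gr
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(params = params, st = st)
}

# Full U-Net forward.  X: (B*nvox) x in_channels; d: spatial dims.
# Returns scores plus (when train or want_cache) the cache needed by
# unet_backward, and refreshed BN running statistics.
unet_forward <- function(model, X, d, B, train = FALSE) {
  cfg <- model$cfg
  L <- cfg$levels
  params <- model$params
  state <- model$state
  cache <- list()
  skips <- list()
  dims <- list()
  h <- X
  dd <- d
  for (l in seq_len(L)) {
    for (j in 1:2) {
      pfx <- sprintf("enc%d_n%d", l, j)
      r <- node_fwd(params, state, pfx, h, dd, B, train)
      h <- r$y
      if (train) {
        cache[[pfx]] <- r$cache
        state[[paste0(pfx, "_rm")]] <- r$rm
        state[[paste0(pfx, "_rv")]] <- r$rv
      }
    }
    if (l < L) {
      skips[[l]] <- h
      dims[[l]] <- dd
      p <- pool3_fwd(h, dd[1], dd[2], dd[3], B)
      if (train) cache[[sprintf("pool%d", l)]] <-
        list(idx = p$idx, nrow_x = nrow(h))
      h <- p$y
      dd <- dd %/% 2L
    }
  }
  for (l in rev(seq_len(L - 1))) {
    pfx <- sprintf("up%d", l)
    hu <- upconv3_fwd(h, dd[1], dd[2], dd[3], B,
                      params[[paste0(pfx, "_W")]],
                      params[[paste0(pfx, "_b")]])
    if (train) cache[[pfx]] <- list(x = h, d = dd)
    dd <- dims[[l]]
    csk <- ncol(skips[[l]])
    h <- cbind(skips[[l]], hu)
    if (train) cache[[sprintf("cat%d", l)]] <- csk
    skips[[l]] <- NULL
    for (j in 1:2) {
      pfx <- sprintf("dec%d_n%d", l, j)
      r <- node_fwd(params, state, pfx, h, dd, B, train)
      h <- r$y
      if (train) {
        cache[[pfx]] <- r$cache
        state[[paste0(pfx, "_rm")]] <- r$rm
        state[[paste0(pfx, "_rv")]] <- r$rv
      }
    }
  }
  if (train) cache[["out"]] <- h
  scores <- h %*% params$out_W
  scores <- sweep(scores, 2L, params$out_b, `+`)
  list(scores = scores, cache = cache, state = state, dims_out = dd)
}

# dScores -> gradients for every parameter.  Mirrors unet_forward.
unet_backward <- function(model, cache, dScores, d, B) {
  cfg <- model$cfg
  L <- cfg$levels
  params <- model$params
  grads <- list()
  grads$out_W <- crossprod(cache$out, dScores)
  grads$out_b <- colSums(dScores)
  dh <- dScores %*% t(params$out_W)

  dskip <- list()
  dd <- d
  for (l in seq_len(L - 1)) {
    for (j in 2:1) {
      pfx <- sprintf("dec%d_n%d", l, j)
      r <- node_bwd(params, pfx, dh, cache[[pfx]], dd, B, grads)
      grads <- r$grads
      dh <- r$dx
    }
    csk <- cache[[sprintf("cat%d", l)]]
    dskip[[l]] <- dh[, seq_len(csk), drop = FALSE]
    dhu <- dh[, (csk + 1):ncol(dh), drop = FALSE]
    pfx <- sprintf("up%d", l)
    up <- cache[[pfx]]
    ub <- upconv3_bwd(up$x, dhu, up$d[1], up$d[2], up$d[3], B,
                      params[[paste0(pfx, "_W")]])
    grads[[paste0(pfx, "_W")]] <- ub$dw
    grads[[paste0(pfx, "_b")]] <- as.numeric(ub$db)
    dh <- ub$dx
    dd <- up$d
    # NB: we walk decoder levels from the deepest-resolution end upward,
    # which matches reverse order of the forward pass because the forward
    # decoder loop runs l = L-1 .. 1.
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      pc <- cache[[sprintf("pool%d", l)]]
      dh <- pool3_bwd(dh, pc$idx, pc$nrow_x)
      dh <- dh + dskip[[l]]
      dd <- dd * 2L
    }
    for (j in 2:1) {
      pfx <- sprintf("enc%d_n%d", l, j)
      r <- node_bwd(params, pfx, dh, cache[[pfx]], dd, B, grads)
      grads <- r$grads
      dh <- r$dx
    }
  }
  grads
}
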