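# Independent brute-force oracles used to validate the compiled metric and
# convolution paths.  These stay deliberately naive: explicit loops and
# full distance matrices.

oracle_confusion <- function(pred, truth) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i]; t <- truth[i]
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

oracle_surface <- function(mask) {
  d <- dim(mask)
  pts <- matrix(0L, nrow = 0, ncol = 3)
  nb <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
              c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (!mask[x, y, z]) next
    surf <- FALSE
    for (k in 1:6) {
      p <- c(x, y, z) + nb[k, ]
      if (any(p < 1) || any(p > d) || !mask[p[1], p[2], p[3]]) {
        surf <- TRUE
        break
      }
    }
    if (surf) pts <- rbind(pts, c(x, y, z) - 1L)
  }
  pts
}

oracle_hd95 <- function(pred, truth, spacing = c(1, 1, 1),
                        method = "max", percentile = 95) {
  A <- oracle_surface(pred)
  B <- oracle_surface(truth)
  if (nrow(A) == 0 || nrow(B) == 0) return(NA_real_)
  Am <- sweep(A, 2, spacing, `*`)
  Bm <- sweep(B, 2, spacing, `*`)
  D2 <- outer(rowSums(Am^2), rowSums(Bm^2), `+`) - 2 * Am %*% t(Bm)
  D2[D2 < 0] <- 0
  D <- sqrt(D2)
  dAB <- apply(D, 1, min)
  dBA <- apply(D, 2, min)
  q <- percentile / 100
  if (method == "max")
    max(quantile(dAB, q, names = FALSE), quantile(dBA, q, names = FALSE))
  else
    quantile(c(dAB, dBA), q, names = FALSE)
}

# naive direct 3x3x3 zero-padded convolution matching the packed weight
# layout: col = (ci-1)*27 + (kx+1) + 3*(ky+1) + 9*(kz+1) + 1
oracle_conv3 <- function(xarr, W, bias) {
  d <- dim(xarr)
  nx <- d[1]; ny <- d[2]; nz <- d[3]; cin <- d[4]
  cout <- ncol(W)
  out <- array(0, c(nx, ny, nz, cout))
  for (co in seq_len(cout))
    for (zo in seq_len(nz)) for (yo in seq_len(ny)) for (xo in seq_len(nx)) {
      acc <- bias[co]
      for (ci in seq_len(cin))
        for (kz in -1:1) for (ky in -1:1) for (kx in -1:1) {
          xi <- xo + kx; yi <- yo + ky; zi <- zo + kz
          if (xi < 1 || xi > nx || yi < 1 || yi > ny || zi < 1 || zi > nz)
            next
          col <- (ci - 1) * 27 + (kx + 1) + 3 * (ky + 1) + 9 * (kz + 1) + 1
          acc <- acc + xarr[xi, yi, zi, ci] * W[col, co]
        }
      out[xo, yo, zo, co] <- acc
    }
  out
}

# random nonempty mask: a fuzzy ball plus salt noise, so surfaces are a mix
# of coherent and isolated voxels
random_mask <- function(shape, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ctr <- runif(3, 0.3, 0.7) * shape
  r <- runif(1, 0.15, 0.4) * min(shape)
  g <- expand.grid(x = seq_len(shape[1]), y = seq_len(shape[2]),
                   z = seq_len(shape[3]))
  d <- sqrt((g$x - ctr[1])^2 + (g$y - ctr[2])^2 + (g$z - ctr[3])^2)
  m <- array(d < r, dim = shape)
  salt <- array(runif(prod(shape)) < 0.02, dim = shape)
  m <- m | salt
  if (!any(m)) m[1, 1, 1] <- TRUE
  m
}
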