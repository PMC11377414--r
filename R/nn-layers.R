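# Internal layer primitives on (H, W, C, N) arrays. Convolutions, transposed
# convolutions and pooling are C++ (im2col + BLAS gemm); the elementwise and
# normalization layers live here.

.dims4 <- function(x) {
  d <- dim(x)
  stopifnot(length(d) == 4L)
  d
}

# promote (H,W) or (H,W,C) to (H,W,C,N)
.as4d <- function(x) {
  d <- dim(x)
  if (is.null(d)) stop("expected an array")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(d) == 3L) dim(x) <- c(d, 1L)
  x
}

.concatC <- function(a, b) {
  da <- .dims4(a); db <- .dims4(b)
  if (!all(da[c(1, 2, 4)] == db[c(1, 2, 4)]))
    stop(sprintf("concat: spatial/batch mismatch %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  H <- da[1]; W <- da[2]; N <- da[4]
  out <- array(0, c(H, W, da[3] + db[3], N))
  # per-sample block copy keeps the channel axis contiguous
  am <- array(a, c(H * W * da[3], N)); bm <- array(b, c(H * W * db[3], N))
  om <- matrix(0, H * W * (da[3] + db[3]), N)
  om[seq_len(H * W * da[3]), ] <- am
  om[H * W * da[3] + seq_len(H * W * db[3]), ] <- bm
  array(om, c(H, W, da[3] + db[3], N))
}

.splitC <- function(x, c1) {
  d <- .dims4(x)
  P <- d[1] * d[2]
  xm <- array(x, c(P * d[3], d[4]))
  list(a = array(xm[seq_len(P * c1), , drop = FALSE], c(d[1], d[2], c1, d[4])),
       b = array(xm[P * c1 + seq_len(P * (d[3] - c1)), , drop = FALSE],
                 c(d[1], d[2], d[3] - c1, d[4])))
}

.lrelu_fwd <- function(x, slope) {
  pos <- x > 0
  list(y = x * (slope + (1 - slope) * pos), pos = pos)
}

.lrelu_bwd <- function(gy, pos, slope) gy * (slope + (1 - slope) * pos)

# Instance normalization: per (channel, sample) mean/variance over H*W,
# population variance, eps inside the square root.
.in_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- .dims4(x)
  P <- d[1] * d[2]; G <- d[3] * d[4]
  xm <- matrix(x, P, G)
  mu <- colMeans(xm)
  va <- colMeans(xm * xm) - mu^2
  std <- sqrt(pmax(va, 0) + eps)
  xhat <- (xm - rep(mu, each = P)) / rep(std, each = P)
  gcol <- rep(rep(gamma, d[4]), each = P)
  y <- xhat * gcol + rep(rep(beta, d[4]), each = P)
  dim(y) <- d
  list(y = y, xhat = xhat, std = std, d = d)
}

.in_bwd <- function(gy, cache, gamma) {
  d <- cache$d
  P <- d[1] * d[2]
  gym <- matrix(gy, P, d[3] * d[4])
  gcol <- rep(rep(gamma, d[4]), each = P)
  gxh <- gym * gcol
  m1 <- colMeans(gxh)
  m2 <- colMeans(gxh * cache$xhat)
  gx <- (gxh - rep(m1, each = P) - cache$xhat * rep(m2, each = P)) /
    rep(cache$std, each = P)
  dim(gx) <- d
  # reduce (c, n) columns to per-channel sums
  gg <- rowSums(matrix(colSums(gym * cache$xhat), d[3], d[4]))
  gb <- rowSums(matrix(colSums(gym), d[3], d[4]))
  list(gx = gx, ggamma = gg, gbeta = gb)
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

# nearest-neighbor 2x upsampling (alternative decoder head of the tconv)
.nn_up2 <- function(x) {
  d <- .dims4(x)
  idx <- rep(seq_len(d[1]), each = 2)
  jdx <- rep(seq_len(d[2]), each = 2)
  x[idx, jdx, , , drop = FALSE]
}

.nn_up2_bwd <- function(gy) {
  d <- .dims4(gy)
  H <- d[1] / 2; W <- d[2] / 2
  g <- gy[seq(1, d[1], 2), , , , drop = FALSE] +
    gy[seq(2, d[1], 2), , , , drop = FALSE]
  g[, seq(1, d[2], 2), , , drop = FALSE] +
    g[, seq(2, d[2], 2), , , drop = FALSE]
}
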