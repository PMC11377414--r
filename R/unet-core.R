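# Connected dual U-Net: weight bookkeeping, forward pass and hand-derived
# backward pass. Parameters live in a flat named list ("u1.enc1.c1.W", ...);
# the first U-Net ("u1") maps CT -> pseudo-PET, the second ("u2") maps
# concat(CT, pseudo-PET) -> tumor logits, receiving the first U-Net's
# decoder features e_k as cross-network skip inputs at encoder levels
# 1..depth-1.

.widths <- function(cfg) cfg@baseWidth * 2L^(seq_len(cfg@depth) - 1L)

# Shape inventory of a single U-Net. `extra` gives, per encoder level, the
# channels arriving over cross-network skips (0 where none).
.unetShapes <- function(cfg, inCh, extra, outCh) {
  w <- .widths(cfg)
  d <- cfg@depth
  sh <- list()
  for (k in seq_len(d)) {
    cin <- (if (k == 1L) inCh else w[k - 1L]) + extra[k]
    sh[[sprintf("enc%d.c1.W", k)]] <- c(3L, 3L, cin, w[k])
    sh[[sprintf("enc%d.c1.b", k)]] <- w[k]
    sh[[sprintf("enc%d.c2.W", k)]] <- c(3L, 3L, w[k], w[k])
    sh[[sprintf("enc%d.c2.b", k)]] <- w[k]
    if (cfg@normAffine) {
      sh[[sprintf("enc%d.n1.g", k)]] <- w[k]
      sh[[sprintf("enc%d.n1.be", k)]] <- w[k]
      sh[[sprintf("enc%d.n2.g", k)]] <- w[k]
      sh[[sprintf("enc%d.n2.be", k)]] <- w[k]
    }
  }
  for (k in seq_len(d - 1L)) {
    sh[[sprintf("dec%d.up.W", k)]] <- c(2L, 2L, w[k + 1L], w[k])
    sh[[sprintf("dec%d.up.b", k)]] <- w[k]
    sh[[sprintf("dec%d.c1.W", k)]] <- c(3L, 3L, 2L * w[k], w[k])
    sh[[sprintf("dec%d.c1.b", k)]] <- w[k]
    sh[[sprintf("dec%d.c2.W", k)]] <- c(3L, 3L, w[k], w[k])
    sh[[sprintf("dec%d.c2.b", k)]] <- w[k]
    if (cfg@normAffine) {
      sh[[sprintf("dec%d.n1.g", k)]] <- w[k]
      sh[[sprintf("dec%d.n1.be", k)]] <- w[k]
      sh[[sprintf("dec%d.n2.g", k)]] <- w[k]
      sh[[sprintf("dec%d.n2.be", k)]] <- w[k]
    }
  }
  sh[["head.W"]] <- c(1L, 1L, w[1L], outCh)
  sh[["head.b"]] <- outCh
  sh
}

.connectedShapes <- function(cfg) {
  w <- .widths(cfg)
  d <- cfg@depth
  noExtra <- integer(d)
  crossExtra <- c(w[seq_len(d - 1L)], 0L)
  s1 <- .unetShapes(cfg, cfg@inChannels, noExtra, cfg@petOutChannels)
  s2 <- .unetShapes(cfg, cfg@inChannels + cfg@petOutChannels, crossExtra,
                    cfg@segOutChannels)
  names(s1) <- paste0("u1.", names(s1))
  names(s2) <- paste0("u2.", names(s2))
  c(s1, s2)
}

#' Count trainable parameters of the connected dual U-Net
#'
#' Sums every trainable scalar — convolution and transposed-convolution
#' kernels, biases, and instance-norm affine terms — of the full dual
#' network described by a configuration. At the published configuration
#' (base width 48, depth 5, one input channel) the network holds about
#' 36.7 million parameters.
#'
#' @param x a [ModelConfig-class] or [ConnectedUNet-class].
#' @return Integer-valued count of trainable scalars.
#' @export
#' @examples
#' countTrainableParameters(modelConfig(baseWidth = 8, depth = 3))
countTrainableParameters <- function(x) {
  cfg <- if (methods::is(x, "ConnectedUNet")) x@config else x
  stopifnot(methods::is(cfg, "ModelConfig"))
  sum(vapply(.connectedShapes(cfg), prod, numeric(1)))
}

# He initialization scaled for leaky activations; biases zero, norm scale 1.
# The segmentation head bias starts at the foreground-prior log-odds
# (prior 0.01), the focal-loss convention for rare-foreground tasks: the
# network begins confidently negative on background instead of spending
# early steps suppressing it.
.initParams <- function(shapes, segPrior = 0.01) {
  out <- vector("list", length(shapes))
  names(out) <- names(shapes)
  for (nm in names(shapes)) {
    d <- shapes[[nm]]
    if (grepl("\\.W$", nm)) {
      fanIn <- prod(d[seq_len(length(d) - 1L)])
      out[[nm]] <- array(stats::rnorm(prod(d), sd = sqrt(2 / fanIn)), d)
    } else if (grepl("\\.g$", nm)) {
      out[[nm]] <- rep(1, d)
    } else {
      out[[nm]] <- rep(0, d)
    }
  }
  if (!is.null(out[["u2.head.b"]]))
    out[["u2.head.b"]] <- rep(stats::qlogis(segPrior),
                              length(out[["u2.head.b"]]))
  out
}

#' Build a connected dual U-Net with freshly initialized weights
#'
#' @param config a [ModelConfig-class].
#' @param seed integer seed for the weight initialization (He-style normal
#'   draws); the global RNG state is restored afterwards.
#' @return A [ConnectedUNet-class].
#' @export
#' @examples
#' net <- connectedUNet(modelConfig(baseWidth = 4, depth = 2), seed = 1)
#' net
connectedUNet <- function(config = modelConfig(), seed = 1L) {
  p <- .withSeed(seed, .initParams(.connectedShapes(config)))
  methods::new("ConnectedUNet", config = config, params = p)
}

# evaluate `expr` under a fixed seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# ---- conv block (two 3x3 convs with instance norm + LeakyReLU) ---------

.norm1 <- function(n) rep(1, n)

.blockFwd <- function(x, p, key, cfg, keep = FALSE) {
  slope <- cfg@leakySlope
  nc <- dim(p[[paste0(key, ".c1.W")]])[4]
  g1 <- if (cfg@normAffine) p[[paste0(key, ".n1.g")]] else .norm1(nc)
  b1 <- if (cfg@normAffine) p[[paste0(key, ".n1.be")]] else rep(0, nc)
  g2 <- if (cfg@normAffine) p[[paste0(key, ".n2.g")]] else .norm1(nc)
  b2 <- if (cfg@normAffine) p[[paste0(key, ".n2.be")]] else rep(0, nc)
  cache <- NULL
  if (cfg@convFirst) {
    a1 <- conv2d_fwd_cpp(x, p[[paste0(key, ".c1.W")]],
                         p[[paste0(key, ".c1.b")]], 1L)
    f1 <- in_lrelu_fwd_cpp(a1, g1, b1, slope, 1e-5)
    a2 <- conv2d_fwd_cpp(f1$y, p[[paste0(key, ".c2.W")]],
                         p[[paste0(key, ".c2.b")]], 1L)
    f2 <- in_lrelu_fwd_cpp(a2, g2, b2, slope, 1e-5)
    if (keep) cache <- list(x = x, h1 = f1$xhat, s1 = f1$std, z1 = f1$y,
                            h2 = f2$xhat, s2 = f2$std)
    return(list(y = f2$y, cache = cache))
  }
  # ablation ordering: InstanceNorm(Conv(LeakyReLU(x)))
  l0 <- .lrelu_fwd(x, slope)
  a1 <- conv2d_fwd_cpp(l0$y, p[[paste0(key, ".c1.W")]],
                       p[[paste0(key, ".c1.b")]], 1L)
  n1 <- .in_fwd(a1, g1, b1)
  l1 <- .lrelu_fwd(n1$y, slope)
  a2 <- conv2d_fwd_cpp(l1$y, p[[paste0(key, ".c2.W")]],
                       p[[paste0(key, ".c2.b")]], 1L)
  n2 <- .in_fwd(a2, g2, b2)
  if (keep) cache <- list(x = l0$y, p0 = l0$pos,
                          n1 = n1[c("xhat", "std", "d")],
                          p1 = l1$pos, z1 = l1$y,
                          n2 = n2[c("xhat", "std", "d")])
  list(y = n2$y, cache = cache)
}

.gadd <- function(G, nm, v) {
  cur <- G$g[[nm]]
  G$g[[nm]] <- if (is.null(cur)) v else cur + v
  invisible(NULL)
}

.blockBwd <- function(gy, p, key, cfg, cache, G) {
  slope <- cfg@leakySlope
  nc <- dim(p[[paste0(key, ".c1.W")]])[4]
  g1 <- if (cfg@normAffine) p[[paste0(key, ".n1.g")]] else .norm1(nc)
  b1v <- if (cfg@normAffine) p[[paste0(key, ".n1.be")]] else rep(0, nc)
  g2 <- if (cfg@normAffine) p[[paste0(key, ".n2.g")]] else .norm1(nc)
  b2v <- if (cfg@normAffine) p[[paste0(key, ".n2.be")]] else rep(0, nc)
  if (cfg@convFirst) {
    bn2 <- in_lrelu_bwd_cpp(gy, cache$h2, cache$s2, g2, b2v, slope)
    if (cfg@normAffine) {
      .gadd(G, paste0(key, ".n2.g"), bn2$ggamma)
      .gadd(G, paste0(key, ".n2.be"), bn2$gbeta)
    }
    bc2 <- conv2d_bwd_cpp(cache$z1, p[[paste0(key, ".c2.W")]], bn2$gx, 1L)
    .gadd(G, paste0(key, ".c2.W"), bc2$gw)
    .gadd(G, paste0(key, ".c2.b"), bc2$gb)
    bn1 <- in_lrelu_bwd_cpp(bc2$gx, cache$h1, cache$s1, g1, b1v, slope)
    if (cfg@normAffine) {
      .gadd(G, paste0(key, ".n1.g"), bn1$ggamma)
      .gadd(G, paste0(key, ".n1.be"), bn1$gbeta)
    }
    bc1 <- conv2d_bwd_cpp(cache$x, p[[paste0(key, ".c1.W")]], bn1$gx, 1L)
    .gadd(G, paste0(key, ".c1.W"), bc1$gw)
    .gadd(G, paste0(key, ".c1.b"), bc1$gb)
    return(bc1$gx)
  }
  bn2 <- .in_bwd(gy, cache$n2, g2)
  if (cfg@normAffine) {
    .gadd(G, paste0(key, ".n2.g"), bn2$ggamma)
    .gadd(G, paste0(key, ".n2.be"), bn2$gbeta)
  }
  bc2 <- conv2d_bwd_cpp(cache$z1, p[[paste0(key, ".c2.W")]], bn2$gx, 1L)
  .gadd(G, paste0(key, ".c2.W"), bc2$gw)
  .gadd(G, paste0(key, ".c2.b"), bc2$gb)
  gz1 <- .lrelu_bwd(bc2$gx, cache$p1, slope)
  bn1 <- .in_bwd(gz1, cache$n1, g1)
  if (cfg@normAffine) {
    .gadd(G, paste0(key, ".n1.g"), bn1$ggamma)
    .gadd(G, paste0(key, ".n1.be"), bn1$gbeta)
  }
  bc1 <- conv2d_bwd_cpp(cache$x, p[[paste0(key, ".c1.W")]], bn1$gx, 1L)
  .gadd(G, paste0(key, ".c1.W"), bc1$gw)
  .gadd(G, paste0(key, ".c1.b"), bc1$gb)
  .lrelu_bwd(bc1$gx, cache$p0, slope)
}

# ---- upsampling stage --------------------------------------------------

.upFwd <- function(x, p, key, cfg) {
  if (cfg@upsample == "tconv")
    return(tconv2d_fwd_cpp(x, p[[paste0(key, ".up.W")]],
                           p[[paste0(key, ".up.b")]]))
  up <- .nn_up2(x)
  conv2d_fwd_cpp(up, p[[paste0(key, ".up.W")]],
                 p[[paste0(key, ".up.b")]], 0L)
}

.upBwd <- function(x, gy, p, key, cfg, G) {
  if (cfg@upsample == "tconv") {
    b <- tconv2d_bwd_cpp(x, p[[paste0(key, ".up.W")]], gy)
    .gadd(G, paste0(key, ".up.W"), b$gw)
    .gadd(G, paste0(key, ".up.b"), b$gb)
    return(b$gx)
  }
  up <- .nn_up2(x)
  b <- conv2d_bwd_cpp(up, p[[paste0(key, ".up.W")]], gy, 0L)
  .gadd(G, paste0(key, ".up.W"), b$gw)
  .gadd(G, paste0(key, ".up.b"), b$gb)
  .nn_up2_bwd(b$gx)
}

# ---- full single-U-Net forward / backward ------------------------------

.checkDivisible <- function(x, cfg) {
  d <- .dims4(x)
  f <- 2L^(cfg@depth - 1L)
  if (d[1] %% f != 0L || d[2] %% f != 0L)
    stop(sprintf(
      "input %dx%d not divisible by 2^(depth-1) = %d; pad the input first",
      d[1], d[2], f))
  invisible(d)
}

.unetForward <- function(p, pre, x, cfg, extra = NULL, keep = FALSE) {
  d <- cfg@depth
  enc <- vector("list", d)
  skips <- vector("list", d)
  cur <- x
  for (k in seq_len(d)) {
    st <- list()
    if (k > 1L) {
      pr <- maxpool2_fwd_cpp(cur)
      st$poolIdx <- pr$idx
      st$poolDim <- dim(cur)
      cur <- pr$y
    }
    if (!is.null(extra) && k <= length(extra) && !is.null(extra[[k]])) {
      st$ownCh <- dim(cur)[3]
      cur <- .concatC(cur, extra[[k]])
    }
    bl <- .blockFwd(cur, p, sprintf("%s.enc%d", pre, k), cfg, keep)
    st$block <- bl$cache
    skips[[k]] <- bl$y
    enc[[k]] <- st
    cur <- bl$y
  }
  dec <- vector("list", d - 1L)
  e <- vector("list", d - 1L)
  deep <- skips[[d]]
  for (k in rev(seq_len(d - 1L))) {
    key <- sprintf("%s.dec%d", pre, k)
    up <- .upFwd(deep, p, key, cfg)
    if (!all(dim(up)[1:2] == dim(skips[[k]])[1:2]))
      stop("decoder/skip resolution mismatch")
    u <- .concatC(up, skips[[k]])
    bl <- .blockFwd(u, p, key, cfg, keep)
    dec[[k]] <- list(deepIn = if (keep) deep, upCh = dim(up)[3],
                     block = bl$cache)
    e[[k]] <- bl$y
    deep <- bl$y
  }
  headKey <- sprintf("%s.head", pre)
  out <- conv2d_fwd_cpp(deep, p[[paste0(headKey, ".W")]],
                        p[[paste0(headKey, ".b")]], 0L)
  list(out = out,
       e = e,
       cache = if (keep) list(enc = enc, dec = dec, headIn = deep))
}

# gOut: gradient w.r.t. the head output. gE: optional per-level gradients
# w.r.t. the decoder features e_k (back-flow from the second U-Net's
# cross-network skips). Returns parameter grads, gradient w.r.t. the net
# input, and gradients w.r.t. any `extra` encoder inputs.
.unetBackward <- function(p, pre, cfg, cache, gOut, gE = NULL) {
  d <- cfg@depth
  G <- new.env(parent = emptyenv())
  G$g <- list()
  headKey <- sprintf("%s.head", pre)
  hb <- conv2d_bwd_cpp(cache$headIn, p[[paste0(headKey, ".W")]], gOut, 0L)
  .gadd(G, paste0(headKey, ".W"), hb$gw)
  .gadd(G, paste0(headKey, ".b"), hb$gb)
  gcur <- hb$gx
  if (!is.null(gE) && length(gE) >= 1L && !is.null(gE[[1L]]))
    gcur <- gcur + gE[[1L]]

  gskip <- vector("list", d)
  for (k in seq_len(d - 1L)) {
    key <- sprintf("%s.dec%d", pre, k)
    gu <- .blockBwd(gcur, p, key, cfg, cache$dec[[k]]$block, G)
    sp <- .splitC(gu, cache$dec[[k]]$upCh)
    gskip[[k]] <- sp$b
    gdeep <- .upBwd(cache$dec[[k]]$deepIn, sp$a, p, key, cfg, G)
    if (k < d - 1L) {
      gcur <- gdeep
      if (!is.null(gE) && length(gE) >= k + 1L && !is.null(gE[[k + 1L]]))
        gcur <- gcur + gE[[k + 1L]]
    } else {
      gskip[[d]] <- gdeep
    }
  }
  gExtra <- vector("list", d)
  gpool <- NULL
  gInput <- NULL
  for (k in rev(seq_len(d))) {
    st <- cache$enc[[k]]
    g <- gskip[[k]]
    if (!is.null(gpool)) g <- g + gpool
    gin <- .blockBwd(g, p, sprintf("%s.enc%d", pre, k), cfg, st$block, G)
    if (!is.null(st$ownCh)) {
      sp <- .splitC(gin, st$ownCh)
      gExtra[[k]] <- sp$b
      gin <- sp$a
    }
    if (k > 1L) {
      gpool <- maxpool2_bwd_cpp(gin, st$poolIdx, st$poolDim)
    } else {
      gInput <- gin
    }
  }
  list(grads = G$g, gInput = gInput, gExtra = gExtra)
}

# ---- connected (dual) network ------------------------------------------

.connectedForward <- function(p, cfg, ct, keep = FALSE) {
  .checkDivisible(ct, cfg)
  f1 <- .unetForward(p, "u1", ct, cfg, keep = keep)
  x2 <- .concatC(ct, f1$out)
  d <- cfg@depth
  extra <- c(f1$e, list(NULL))   # e_k feeds encoder level k; none at level d
  f2 <- .unetForward(p, "u2", x2, cfg, extra = extra, keep = keep)
  list(pet = f1$out, logits = f2$out, prob = .sigmoid(f2$out),
       f1 = f1, f2 = f2, ct = if (keep) ct)
}

.connectedBackward <- function(p, cfg, fw, gPet = NULL, gLogits) {
  b2 <- .unetBackward(p, "u2", cfg, fw$f2$cache, gLogits)
  gx2 <- .splitC(b2$gInput, cfg@inChannels)
  gPetTotal <- gx2$b
  if (!is.null(gPet)) gPetTotal <- gPetTotal + gPet
  b1 <- .unetBackward(p, "u1", cfg, fw$f1$cache, gPetTotal, gE = b2$gExtra)
  list(grads = c(b1$grads, b2$grads))
}

# ---- exported stage-level and network-level operations -----------------

#' Run one encoder stage
#'
#' Applies the level's two-convolution block (3x3, padding 1, instance norm,
#' LeakyReLU) followed by 2x2 stride-2 max pooling. Exposed mainly for
#' inspection and testing; [forwardConnected()] runs the full network.
#'
#' @param model a [ConnectedUNet-class].
#' @param input array (H, W, C) or (H, W, C, N); `C` must match the level's
#'   expected input channels and H, W must be even.
#' @param level encoder level, 1-based.
#' @param unet `"u1"` or `"u2"`.
#' @return list with `skip` (pre-pooling features) and `pooled` arrays.
#' @export
encoderStage <- function(model, input, level, unet = "u1") {
  x <- .as4d(input)
  d <- .dims4(x)
  if (d[1] %% 2L != 0L || d[2] %% 2L != 0L)
    stop(sprintf("encoder stage needs even spatial dims, got %dx%d",
                 d[1], d[2]))
  key <- sprintf("%s.enc%d", unet, level)
  wdim <- dim(model@params[[paste0(key, ".c1.W")]])
  if (is.null(wdim)) stop("no such encoder level: ", level)
  if (wdim[3] != d[3])
    stop(sprintf("level %d expects %d input channels, got %d",
                 level, wdim[3], d[3]))
  bl <- .blockFwd(x, model@params, key, model@config)
  pooled <- maxpool2_fwd_cpp(bl$y)$y
  list(skip = bl$y, pooled = pooled)
}

#' Run one decoder stage
#'
#' Upsamples the deeper features (2x2 stride-2 transposed convolution by
#' default), concatenates the matching-resolution encoder skip, and applies
#' the stage's two-convolution block.
#'
#' @param model a [ConnectedUNet-class].
#' @param deep array of the deeper level's features (level + 1).
#' @param skip the encoder skip features at the stage's own level.
#' @param level decoder stage, 1-based (1 = highest resolution).
#' @param unet `"u1"` or `"u2"`.
#' @return Feature array with the skip's spatial size.
#' @export
decoderStage <- function(model, deep, skip, level, unet = "u1") {
  deep <- .as4d(deep); skip <- .as4d(skip)
  key <- sprintf("%s.dec%d", unet, level)
  if (is.null(model@params[[paste0(key, ".up.W")]]))
    stop("no such decoder stage: ", level)
  up <- .upFwd(deep, model@params, key, model@config)
  if (!all(dim(up)[1:2] == dim(skip)[1:2]))
    stop(sprintf("resolution mismatch: upsampled %dx%d vs skip %dx%d",
                 dim(up)[1], dim(up)[2], dim(skip)[1], dim(skip)[2]))
  .blockFwd(.concatC(up, skip), model@params, key, model@config)$y
}

#' Forward pass of the first (pseudo-PET) U-Net
#'
#' @param model a [ConnectedUNet-class].
#' @param ct array (H, W), (H, W, C) or (H, W, C, N); spatial dims must be
#'   divisible by `2^(depth-1)`.
#' @return list with `pet` (linear, unbounded pseudo-PET map, same spatial
#'   size as the input) and `decoderFeatures` (list of per-level decoder
#'   features e_k, highest resolution first), which carry the PET knowledge
#'   into the second U-Net.
#' @export
forwardFirstUNet <- function(model, ct) {
  x <- .as4d(ct)
  .checkDivisible(x, model@config)
  f <- .unetForward(model@params, "u1", x, model@config)
  list(pet = f$out, decoderFeatures = f$e)
}

#' Forward pass of the full connected network
#'
#' Runs the first U-Net (CT -> pseudo-PET), then the second U-Net on
#' concat(CT, pseudo-PET) with the first U-Net's decoder features injected
#' into the matching-resolution encoder levels. The segmentation head is a
#' sigmoid, so `segProb` lies in \[0,1\]; the PET head is linear.
#'
#' @inheritParams forwardFirstUNet
#' @return list with `pseudoPet` and `segProb` arrays, both of the input's
#'   spatial size.
#' @export
#' @examples
#' net <- connectedUNet(modelConfig(baseWidth = 2, depth = 2), seed = 1)
#' out <- forwardConnected(net, array(runif(16 * 16), c(16, 16)))
#' range(out$segProb)
forwardConnected <- function(model, ct) {
  x <- .as4d(ct)
  fw <- .connectedForward(model@params, model@config, x)
  list(pseudoPet = fw$pet, segProb = fw$prob)
}
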