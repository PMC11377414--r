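# Architecture-level contracts of the connected dual U-Net.

test_that("encoder stages honor the shape and width-doubling contract", {
  cfg <- modelConfig(baseWidth = 8, depth = 3)
  net <- connectedUNet(cfg, seed = 1)
  x <- array(rnorm(64 * 64), c(64, 64, 1, 1))
  s1 <- encoderStage(net, x, level = 1)
  expect_equal(dim(s1$skip), c(64, 64, 8, 1))
  expect_equal(dim(s1$pooled), c(32, 32, 8, 1))
  s2 <- encoderStage(net, s1$pooled, level = 2)
  expect_equal(dim(s2$skip), c(32, 32, 16, 1))
  expect_equal(dim(s2$pooled), c(16, 16, 16, 1))

  expect_error(encoderStage(net, array(0, c(15, 15, 1, 1)), level = 1),
               "even spatial dims")
  expect_error(encoderStage(net, array(0, c(16, 16, 3, 1)), level = 1),
               "input channels")
})

test_that("zero input flows through the bias-only path of a block", {
  net <- tinyNet(seed = 4)
  z <- array(0, c(8, 8, 1, 1))
  s <- encoderStage(net, z, level = 1)
  # freshly initialized biases and norm shifts are 0, so everything stays 0
  expect_true(all(s$skip == 0))
  expect_true(all(s$pooled == 0))
  # with a norm shift beta = 0.3 the block output is the constant
  # LeakyReLU(0.3) = 0.3 (normalized zero map + affine shift)
  net@params[["u1.enc1.n2.be"]][] <- 0.3
  s <- encoderStage(net, z, level = 1)
  expect_equal(unname(as.vector(s$skip)), rep(0.3, 8 * 8 * 2),
               tolerance = 1e-12)
  expect_equal(unname(as.vector(s$pooled)), rep(0.3, 4 * 4 * 2),
               tolerance = 1e-12)
})

test_that("decoder stage doubles resolution and matches the skip size", {
  cfg <- modelConfig(baseWidth = 8, depth = 3)
  net <- connectedUNet(cfg, seed = 1)
  deep <- array(rnorm(16 * 16 * 32), c(16, 16, 32, 1))
  skip <- array(rnorm(32 * 32 * 16), c(32, 32, 16, 1))
  out <- decoderStage(net, deep, skip, level = 2)
  expect_equal(dim(out), c(32, 32, 16, 1))
  badSkip <- array(0, c(64, 64, 16, 1))
  expect_error(decoderStage(net, deep, badSkip, level = 2),
               "resolution mismatch")
})

test_that("a depth-2 toy network preserves an 8x8 input end to end", {
  net <- tinyNet(seed = 2)
  x <- array(rnorm(64), c(8, 8, 1, 1))
  f <- forwardFirstUNet(net, x)
  expect_equal(dim(f$pet), c(8, 8, 1, 1))
  expect_length(f$decoderFeatures, 1L)
  expect_equal(dim(f$decoderFeatures[[1]]), c(8, 8, 2, 1))
  out <- forwardConnected(net, x)
  expect_equal(dim(out$pseudoPet), c(8, 8, 1, 1))
  expect_equal(dim(out$segProb), c(8, 8, 1, 1))
})

test_that("repeated encoding of a 288 input reaches an 18x18 bottleneck", {
  cfg <- modelConfig(baseWidth = 1, depth = 5)
  net <- connectedUNet(cfg, seed = 1)
  cur <- array(rnorm(288 * 288), c(288, 288, 1, 1))
  sizes <- integer(0)
  for (k in 1:5) {
    st <- encoderStage(net, cur, level = k)
    sizes <- c(sizes, dim(st$skip)[1])
    cur <- st$pooled
  }
  expect_equal(sizes, c(288, 144, 72, 36, 18))
})

test_that("indivisible input sizes are rejected with a shape error", {
  net <- connectedUNet(modelConfig(baseWidth = 2, depth = 4), seed = 1)
  expect_error(forwardFirstUNet(net, array(0, c(20, 20, 1, 1))),
               "divisible")
  expect_error(forwardConnected(net, array(0, c(20, 20, 1, 1))),
               "divisible")
})

test_that("inference is deterministic and segProb lies in [0,1]", {
  net <- connectedUNet(modelConfig(baseWidth = 4, depth = 3), seed = 9)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  o1 <- forwardConnected(net, x)
  o2 <- forwardConnected(net, x)
  expect_identical(o1$pseudoPet, o2$pseudoPet)
  expect_identical(o1$segProb, o2$segProb)
  expect_true(all(o1$segProb >= 0 & o1$segProb <= 1))
})

test_that("shape conservation holds over randomized valid input sizes", {
  set.seed(33)
  for (i in 1:5) {
    depth <- sample(2:4, 1)
    net <- connectedUNet(modelConfig(baseWidth = 2, depth = depth),
                         seed = i)
    mult <- 2^(depth - 1)
    hw <- mult * sample(2:4, 2, replace = TRUE)
    x <- array(rnorm(prod(hw)), c(hw, 1, 1))
    out <- forwardConnected(net, x)
    expect_equal(dim(out$pseudoPet)[1:2], hw)
    expect_equal(dim(out$segProb)[1:2], hw)
  }
})

test_that("cross-network connections are live (guidance ablation)", {
  net <- connectedUNet(modelConfig(baseWidth = 4, depth = 3), seed = 5)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  full <- forwardConnected(net, x)$segProb
  # zero every first-U-Net decoder weight so its decoder features collapse;
  # if the cross connections carry signal, the segmentation must change
  ablated <- net
  for (nm in grep("^u1\\.(dec|head)", names(net@params), value = TRUE))
    ablated@params[[nm]][] <- 0
  expect_gt(max(abs(forwardConnected(ablated, x)$segProb - full)), 1e-6)
})

test_that("segmentation loss gradients reach the first U-Net", {
  # finite-difference check that the cross-U-Net skips carry gradient
  cfg <- tinyConfig()
  net <- tinyNet(seed = 7)
  set.seed(1)
  x <- array(runif(64), c(8, 8, 1, 1))
  mask <- array(rbinom(64, 1, 0.3), c(8, 8, 1, 1))
  segLoss <- function(p) {
    fw <- cunet:::.connectedForward(p, cfg, x)
    focalLoss(fw$prob, mask) + diceLoss(fw$prob, mask)
  }
  fw <- cunet:::.connectedForward(net@params, cfg, x, keep = TRUE)
  gProb <- cunet:::.focalLossGrad(fw$prob, mask) +
    cunet:::.diceLossGrad(fw$prob, mask)
  gLogits <- gProb * fw$prob * (1 - fw$prob)
  bb <- cunet:::.connectedBackward(net@params, cfg, fw, gPet = NULL,
                                   gLogits = gLogits)
  nm <- "u1.enc1.c1.W"
  expect_gt(sum(abs(bb$grads[[nm]])), 0)
  for (i in c(1, 5)) {
    eps <- 1e-6
    pp <- net@params; pp[[nm]][i] <- pp[[nm]][i] + eps
    pm <- net@params; pm[[nm]][i] <- pm[[nm]][i] - eps
    num <- (segLoss(pp) - segLoss(pm)) / (2 * eps)
    expect_equal(bb$grads[[nm]][i], num, tolerance = 1e-4)
  }
})

test_that("parameter count matches a hand tally on a toy configuration", {
  # base width 1, depth 2, 1 input channel, tallied layer by layer:
  # U-Net 1: enc1 (9+1+9+1+4) + enc2 (18+2+36+2+8) + dec1 (8+1+18+1+9+1+4)
  #          + head (1+1) = 134
  # U-Net 2 input has 2 channels (CT + pseudo-PET) and 1 extra cross
  # channel at level 1: enc1 c1 = 3*3*3*1 = 27 -> 152 total
  expect_equal(countTrainableParameters(modelConfig(baseWidth = 1,
                                                    depth = 2)), 286)
})

test_that("parameter count is a pure function of the configuration", {
  cfg <- modelConfig(baseWidth = 8, depth = 3)
  net <- connectedUNet(cfg, seed = 3)
  expect_equal(countTrainableParameters(cfg),
               sum(vapply(net@params, length, numeric(1))))
  expect_equal(countTrainableParameters(cfg), countTrainableParameters(net))
})

test_that("doubling the base width roughly quadruples the count", {
  r <- countTrainableParameters(modelConfig(baseWidth = 16, depth = 4)) /
    countTrainableParameters(modelConfig(baseWidth = 8, depth = 4))
  expect_gt(r, 3.5)
  expect_lt(r, 4.1)
})

test_that("checkpoints round-trip through disk with a JSON sidecar", {
  net <- tinyNet(seed = 6)
  ck <- methods::new("Checkpoint", model = net,
                     teacherParams = net@params,
                     validationScore = 0.5, epoch = 3L)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(ck, path)
  expect_true(file.exists(paste0(path, ".json")))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$baseWidth, 2)
  ck2 <- loadCheckpoint(path)
  expect_identical(ck2@model@params, net@params)
  expect_equal(validationScore(ck2), 0.5)
  unlink(c(path, paste0(path, ".json")))
})
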