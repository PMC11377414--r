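# Augmentation, teacher views and the teacher-student optimization loop.

test_that("augmentation with trivial settings is the identity", {
  s <- list(ct = matrix(runif(64), 8, 8), mask = matrix(rbinom(64, 1, 0.3),
                                                        8, 8))
  spec <- augmentationSpec(rotationDegrees = 0, flipProb = 0)
  expect_identical(augmentSample(s, spec), s)
})

test_that("180-degree rotation is an involution and masks stay binary", {
  m <- matrix(runif(63), 7, 9)
  expect_identical(rotateSlice(rotateSlice(m, 180), 180), m)
  set.seed(8)
  s <- list(ct = matrix(runif(144), 12, 12),
            mask = matrix(rbinom(144, 1, 0.3), 12, 12))
  spec <- augmentationSpec(cropSize = c(8, 8))
  for (i in 1:100) {
    out <- augmentSample(s, spec)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_equal(dim(out$ct), c(8, 8))
    expect_identical(dim(out$ct), dim(out$mask))
  }
  expect_error(augmentSample(s, augmentationSpec(cropSize = c(20, 20))),
               "crop size")
})

test_that("teacher views rotate and map back exactly", {
  set.seed(5)
  x <- matrix(runif(81), 9, 9)
  for (i in 1:20) {
    v <- teacherView(x)
    expect_identical(undoRotation(v$rotated, v$rotation), x)
  }
  # a 90-degree view sends pixel (1,1) to a corner of the grid
  m <- matrix(0, 3, 3); m[1, 1] <- 1
  r <- rotateSlice(m, 90)
  expect_equal(which(r == 1), 7L)  # (row 1, col 3): clockwise quarter-turn
  expect_error(teacherView(matrix(0, 3, 4)), "square")
})

test_that("one training step updates the teacher as an exact EMA", {
  set.seed(21)
  cfg <- tinyConfig()
  net <- connectedUNet(cfg, seed = 3)
  state <- methods::new("TrainingState", step = 0L, epoch = 1L, alpha = 0,
                        w = 0.1, teacherParams = net@params,
                        opt = cunet:::.adamInit())
  mkA <- function() list(ct = matrix(runif(64), 8),
                         pet = matrix(runif(64), 8))
  mkB <- function() list(ct = matrix(runif(64), 8),
                         mask = matrix(rbinom(64, 1, 0.2), 8))
  teacherBefore <- state@teacherParams
  replay <- teacherBefore
  model <- net
  for (k in 1:3) {
    r <- trainStep(model, state, list(mkA()), list(mkB()), lr = 1e-3)
    # manual EMA replay with the published schedule must match bit for bit
    replay <- emaUpdate(replay, r$model@params, emaSchedule(k - 1))
    expect_identical(r$state@teacherParams, replay)
    # convexity: each teacher scalar lies between old teacher and student
    for (nm in c("u1.enc1.c1.W", "u2.head.W")) {
      lo <- pmin(state@teacherParams[[nm]], r$model@params[[nm]])
      hi <- pmax(state@teacherParams[[nm]], r$model@params[[nm]])
      expect_true(all(r$state@teacherParams[[nm]] >= lo - 1e-12 &
                        r$state@teacherParams[[nm]] <= hi + 1e-12))
    }
    model <- r$model
    state <- r$state
  }
  expect_equal(state@step, 3L)
  expect_equal(state@alpha, emaSchedule(2))
})

test_that("the loss breakdown satisfies total = w*C + H + F", {
  set.seed(22)
  net <- tinyNet(seed = 5)
  state <- methods::new("TrainingState", step = 0L, epoch = 1L, alpha = 0,
                        w = 0.07, teacherParams = net@params,
                        opt = cunet:::.adamInit())
  bA <- list(list(ct = matrix(runif(64), 8), pet = matrix(runif(64), 8)))
  bB <- list(list(ct = matrix(runif(64), 8),
                  mask = matrix(rbinom(64, 1, 0.2), 8)))
  r <- trainStep(net, state, bA, bB)
  l <- r$loss
  expect_equal(l$total, l$w * l$consistency + l$petMse + l$seg,
               tolerance = 1e-12)
  expect_equal(l$w, 0.07)
})

test_that("without A data and consistency, gradients come from F only", {
  set.seed(23)
  cfg <- tinyConfig()
  net <- tinyNet(seed = 2)
  bB <- list(list(ct = matrix(runif(64), 8),
                  mask = matrix(rbinom(64, 1, 0.2), 8)))
  ctB <- cunet:::.stackSlices(lapply(bB, `[[`, "ct"))
  maskB <- cunet:::.stackSlices(lapply(bB, `[[`, "mask"))
  fw <- cunet:::.connectedForward(net@params, cfg, ctB, keep = TRUE)
  gProb <- cunet:::.focalLossGrad(fw$prob, maskB) +
    cunet:::.diceLossGrad(fw$prob, maskB)
  bb <- cunet:::.connectedBackward(net@params, cfg, fw, gPet = NULL,
                                   gLogits = gProb * fw$prob *
                                     (1 - fw$prob))
  # F reaches both U-Nets (via the cross connections), and a second call
  # with zeroed segmentation gradient produces exactly zero gradients
  expect_gt(sum(abs(bb$grads[["u1.enc1.c1.W"]])), 0)
  zero <- cunet:::.connectedBackward(net@params, cfg, fw, gPet = NULL,
                                     gLogits = fw$prob * 0)
  expect_equal(sum(abs(unlist(zero$grads))), 0)
})

test_that("training is reproducible under a fixed seed", {
  sp <- ablationSplit()
  cfg <- modelConfig(baseWidth = 2, depth = 3)
  r1 <- trainConnectedUNet(cfg, sp$dataA[1], sp$dataB[1], sp$val,
                           epochs = 2, batchSize = 2, seed = 7)
  r2 <- trainConnectedUNet(cfg, sp$dataA[1], sp$dataB[1], sp$val,
                           epochs = 2, batchSize = 2, seed = 7)
  expect_identical(r1$checkpoint@model@params, r2$checkpoint@model@params)
  expect_identical(r1$log, r2$log)
})

test_that("the cosine schedule spans lrMax to lrMin", {
  expect_equal(cunet:::.cosineLr(1, 20), 1e-4)
  expect_equal(cunet:::.cosineLr(20, 20), 1e-5)
  mid <- cunet:::.cosineLr(10, 20)
  expect_true(mid < 1e-4 && mid > 1e-5)
})

test_that("checkpoint selection is an argmax over epochs", {
  r <- deskTraining()
  val <- r$log$valDsc[!is.na(r$log$valDsc)]
  expect_equal(validationScore(r$checkpoint), max(val))
  expect_gte(validationScore(r$checkpoint), val[1])
  # final-epoch learning rate sits at the cosine endpoint
  expect_equal(r$log$lr[nrow(r$log)], 1e-5)
})

test_that("slice-wise prediction respects geometry and thresholding", {
  r <- deskTraining()
  s <- deskSplit()$test[[1]]
  pr <- predictVolume(r$checkpoint, s$ct)
  p <- voxels(pr$prob)
  expect_true(all(p >= 0 & p <= 1))
  expect_identical(voxels(pr$mask), (p > 0.5) * 1)
  expect_equal(dim(p), dim(voxels(s$ct)))
  expect_equal(spacing(pr$mask), spacing(s$ct))
  # a trained model finds the tumor: non-empty prediction
  expect_gt(sum(voxels(pr$mask)), 0)
})
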