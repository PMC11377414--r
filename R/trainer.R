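# Teacher-student semi-supervised training loop. Data A supplies (CT, PET)
# pairs and drives the PET-synthesis MSE term H; Data B supplies (CT, mask)
# pairs and drives the segmentation term F (focal + dice) plus the
# rotation-consistency term C between the student's and the teacher's
# pseudo-PET. The student is optimized on w*C + H + F; the teacher is an
# EMA of the student.

# ---- Adam --------------------------------------------------------------

.adamInit <- function() list(m = list(), v = list(), t = 0L)

.adamStep <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- opt$m[[nm]]
    v <- opt$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, opt = opt)
}

.cosineLr <- function(epoch, epochs, lrMax = 1e-4, lrMin = 1e-5) {
  if (epochs <= 1) return(lrMax)
  lrMin + 0.5 * (lrMax - lrMin) * (1 + cos(pi * (epoch - 1) / (epochs - 1)))
}

.sumGrads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.null(a[[nm]])) b[[nm]] else a[[nm]] + b[[nm]]
  }
  a
}

.stackSlices <- function(slices) {
  d <- dim(slices[[1]])
  out <- array(0, c(d[1], d[2], 1L, length(slices)))
  for (i in seq_along(slices)) out[, , 1L, i] <- slices[[i]]
  out
}

# ---- augmentation ------------------------------------------------------

#' Describe the training augmentations
#'
#' @param rotationDegrees quarter-turn angles to draw from.
#' @param flipProb probability of a horizontal flip.
#' @param cropSize target (h, w) of the random crop, or `NULL` to skip
#'   cropping.
#' @return list used by [augmentSample()].
#' @export
augmentationSpec <- function(rotationDegrees = c(0, 90, 180, 270),
                             flipProb = 0.5, cropSize = NULL) {
  stopifnot(all(rotationDegrees %% 90 == 0))
  list(rotationDegrees = rotationDegrees, flipProb = flipProb,
       cropSize = cropSize)
}

#' Apply one random augmentation jointly to all grids of a sample
#'
#' The same rotation, flip and crop are applied to every grid in the sample
#' (CT + PET or CT + mask), so geometry stays aligned. Quarter-turn
#' rotations, flips and integer crops involve no resampling, so masks stay
#' exactly binary. Uses the global RNG.
#'
#' @param sample named list of matrices (e.g. `list(ct = ..., mask = ...)`);
#'   non-matrix entries pass through untouched.
#' @param spec an [augmentationSpec()].
#' @return the augmented sample.
#' @export
augmentSample <- function(sample, spec = augmentationSpec()) {
  grids <- vapply(sample, is.matrix, logical(1))
  d <- dim(sample[[which(grids)[1]]])
  if (!is.null(spec$cropSize) && any(spec$cropSize > d))
    stop("crop size exceeds the image size")
  deg <- spec$rotationDegrees[sample.int(length(spec$rotationDegrees), 1)]
  doFlip <- stats::runif(1) < spec$flipProb
  off <- c(0L, 0L)
  if (!is.null(spec$cropSize))
    off <- c(sample.int(d[1] - spec$cropSize[1] + 1L, 1) - 1L,
             sample.int(d[2] - spec$cropSize[2] + 1L, 1) - 1L)
  for (nm in names(sample)[grids]) {
    m <- sample[[nm]]
    m <- .rotateQuarter(m, deg)
    if (doFlip) m <- m[, ncol(m):1, drop = FALSE]
    if (!is.null(spec$cropSize))
      m <- m[off[1] + seq_len(spec$cropSize[1]),
             off[2] + seq_len(spec$cropSize[2]), drop = FALSE]
    sample[[nm]] <- m
  }
  sample
}

#' Random rotated view for the teacher network
#'
#' Draws a quarter-turn angle, rotates the CT slice, and returns the record
#' needed to map the teacher's output back into the student's frame with
#' [undoRotation()]. Uses the global RNG.
#'
#' @param ct square matrix.
#' @return list with `rotated` (matrix) and `rotation` (degrees).
#' @export
teacherView <- function(ct) {
  if (nrow(ct) != ncol(ct))
    stop("teacher view requires square slices (quarter-turn rotations)")
  deg <- c(0, 90, 180, 270)[sample.int(4L, 1)]
  list(rotated = .rotateQuarter(ct, deg), rotation = deg)
}

# ---- one optimization step ---------------------------------------------

#' Run one teacher-student optimization step
#'
#' Performs, in order: (i) student first-U-Net forward on batch A and the
#' PET MSE term H; (ii) student connected forward on batch B, the
#' segmentation term F (focal + dice) and — against the teacher's
#' pseudo-PET computed on a randomly rotated view of B's CT and rotated
#' back — the consistency term C; (iii) one Adam step on
#' `w*C + H + F` (student only); (iv) the EMA teacher update with
#' `alpha = emaSchedule(step)`.
#'
#' @param model a [ConnectedUNet-class] (student).
#' @param state a [TrainingState-class]; its `w` slot is the consistency
#'   weight used.
#' @param batchA list of samples `list(ct = matrix, pet = matrix)`; may be
#'   empty (H is then 0).
#' @param batchB non-empty list of samples `list(ct = matrix,
#'   mask = matrix)`.
#' @param lr Adam learning rate for this step.
#' @param gamma focal-loss exponent.
#' @param smooth dice smoothing constant.
#' @return list with the updated `model`, `state`, and `loss` (the
#'   [totalLoss()] breakdown).
#' @export
trainStep <- function(model, state, batchA, batchB, lr = 1e-4, gamma = 2,
                      smooth = 1e-6) {
  if (length(batchB) == 0L) stop("batch B must be non-empty")
  p <- model@params
  cfg <- model@config
  grads <- list()

  H <- 0
  if (length(batchA) > 0L) {
    ctA <- .stackSlices(lapply(batchA, `[[`, "ct"))
    petA <- .stackSlices(lapply(batchA, `[[`, "pet"))
    fwA <- .unetForward(p, "u1", ctA, cfg, keep = TRUE)
    H <- petMSE(fwA$out, petA)
    gH <- 2 * (fwA$out - petA) / length(petA)
    bA <- .unetBackward(p, "u1", cfg, fwA$cache, gH)
    grads <- .sumGrads(grads, bA$grads)
  }

  ctB <- .stackSlices(lapply(batchB, `[[`, "ct"))
  maskB <- .stackSlices(lapply(batchB, `[[`, "mask"))
  fwB <- .connectedForward(p, cfg, ctB, keep = TRUE)

  Floss <- focalLoss(fwB$prob, maskB, gamma = gamma) +
    diceLoss(fwB$prob, maskB, smooth = smooth)
  gProb <- .focalLossGrad(fwB$prob, maskB, gamma = gamma) +
    .diceLossGrad(fwB$prob, maskB, smooth = smooth)
  gLogits <- gProb * fwB$prob * (1 - fwB$prob)

  # teacher on rotated B, output rotated back into the student frame
  views <- lapply(batchB, function(s) teacherView(s$ct))
  ctT <- .stackSlices(lapply(views, `[[`, "rotated"))
  fwT <- .unetForward(state@teacherParams, "u1", ctT, cfg)
  tPet <- fwB$pet * 0
  for (i in seq_along(views))
    tPet[, , 1L, i] <- undoRotation(fwT$out[, , 1L, i], views[[i]]$rotation)
  C <- consistencyLoss(fwB$pet, tPet)
  gPet <- state@w * 2 * (fwB$pet - tPet) / length(tPet)

  bB <- .connectedBackward(p, cfg, fwB, gPet = gPet, gLogits = gLogits)
  grads <- .sumGrads(grads, bB$grads)

  loss <- totalLoss(C, H, Floss, state@w)

  st <- .adamStep(p, grads, state@opt, lr)
  model@params <- st$params
  alpha <- emaSchedule(state@step)
  state@teacherParams <- emaUpdate(state@teacherParams, st$params, alpha)
  state@opt <- st$opt
  state@alpha <- alpha
  state@step <- state@step + 1L
  list(model = model, state = state, loss = loss)
}

# flatten study list into per-slice samples
.slicesOf <- function(studies, field) {
  out <- list()
  for (s in studies) {
    ct <- voxels(s$ct)
    oth <- voxels(s[[field]])
    for (i in seq_len(dim(ct)[3])) {
      smp <- list(ct = ct[, , i], studyId = s$studyId)
      smp[[field]] <- oth[, , i]
      out[[length(out) + 1L]] <- smp
    }
  }
  out
}

.cycleIdx <- function(n, len) {
  if (n >= len) sample.int(n)[seq_len(len)] else
    rep(sample.int(n), length.out = len)
}

# ---- full training loop ------------------------------------------------

#' Train the connected U-Net with the teacher-student framework
#'
#' Flattens the studies into 2D slice samples, then runs `epochs` epochs of
#' [trainStep()] with Adam and a cosine learning-rate schedule (1e-4 down
#' to 1e-5). The consistency weight follows [consistencyWeight()] with the
#' epoch as the schedule step; the EMA coefficient follows [emaSchedule()]
#' per optimizer step. After every epoch the mean study-wise Dice on
#' `valB` is computed and the best-scoring weights are kept (no early
#' stopping).
#'
#' @param config a [ModelConfig-class].
#' @param dataA list of studies with `ct` and `pet` [Volume-class]s (may be
#'   empty for a CT-only ablation).
#' @param dataB,valB lists of studies with `ct` and `mask` volumes.
#' @param epochs number of epochs.
#' @param batchSize slices per batch for both A and B (default 8).
#' @param lrMax,lrMin cosine learning-rate endpoints.
#' @param rampLength consistency ramp extent in epochs.
#' @param valA optional list of (ct, pet) studies; when given, the
#'   held-out pseudo-PET MSE of the first U-Net is logged per epoch.
#' @param augment an [augmentationSpec()], or `NULL` to disable.
#' @param useConsistency set `FALSE` to drop the C term (teacher still
#'   tracked), for ablations.
#' @param seed integer seed controlling initialization, shuffling,
#'   augmentation and teacher views.
#' @param verbose print per-epoch progress.
#' @return list with `checkpoint` (a [Checkpoint-class], best validation
#'   epoch) and `log` (data.frame: step, epoch, H, C, F, w, alpha, total,
#'   lr, plus per-epoch validation rows).
#' @export
trainConnectedUNet <- function(config, dataA, dataB, valB, epochs = 20,
                               batchSize = 8, lrMax = 1e-4, lrMin = 1e-5,
                               rampLength = 80, valA = NULL,
                               augment = augmentationSpec(),
                               useConsistency = TRUE, seed = 1L,
                               verbose = FALSE) {
  if (length(dataB) == 0L) stop("data B (masked studies) must be non-empty")
  if (length(valB) == 0L) stop("validation set must be non-empty")
  .withSeed(seed, {
    model <- methods::new("ConnectedUNet", config = config,
                          params = .initParams(.connectedShapes(config)))
    state <- methods::new("TrainingState", step = 0L, epoch = 1L,
                          alpha = 0, w = consistencyWeight(0, rampLength),
                          teacherParams = model@params, opt = .adamInit())
    samplesA <- if (length(dataA)) .slicesOf(dataA, "pet") else list()
    samplesB <- .slicesOf(dataB, "mask")
    nA <- length(samplesA)
    nB <- length(samplesB)
    stepsPerEpoch <- max(ceiling(nA / batchSize), ceiling(nB / batchSize))

    log <- list()
    best <- NULL
    for (epoch in seq_len(epochs)) {
      lr <- .cosineLr(epoch, epochs, lrMax, lrMin)
      state@epoch <- as.integer(epoch)
      state@w <- if (useConsistency)
        consistencyWeight(epoch - 1, rampLength) else 0
      idxA <- if (nA) .cycleIdx(nA, stepsPerEpoch * batchSize)
      idxB <- .cycleIdx(nB, stepsPerEpoch * batchSize)
      for (s in seq_len(stepsPerEpoch)) {
        take <- function(samples, idx) {
          sel <- idx[(s - 1L) * batchSize + seq_len(batchSize)]
          lapply(samples[sel], function(x)
            if (is.null(augment)) x else augmentSample(x, augment))
        }
        bA <- if (nA) take(samplesA, idxA) else list()
        bB <- take(samplesB, idxB)
        r <- trainStep(model, state, bA, bB, lr = lr)
        model <- r$model
        state <- r$state
        log[[length(log) + 1L]] <- data.frame(
          step = state@step, epoch = epoch, H = r$loss$petMse,
          C = r$loss$consistency, F = r$loss$seg, w = r$loss$w,
          alpha = state@alpha, total = r$loss$total, lr = lr,
          valDsc = NA_real_, valPetMse = NA_real_)
      }
      val <- .meanStudyDice(model, valB)
      valMse <- if (is.null(valA)) NA_real_ else .meanPetMse(model, valA)
      log[[length(log) + 1L]] <- data.frame(
        step = state@step, epoch = epoch, H = NA, C = NA, F = NA, w = NA,
        alpha = NA, total = NA, lr = lr, valDsc = val, valPetMse = valMse)
      if (verbose)
        message(sprintf("epoch %d: lr %.2e, val DSC %.4f", epoch, lr, val))
      if (is.null(best) || val >= best@validationScore) {
        best <- methods::new("Checkpoint", model = model,
                             teacherParams = state@teacherParams,
                             validationScore = val,
                             epoch = as.integer(epoch))
      }
    }
    list(checkpoint = best, log = do.call(rbind, log), finalState = state)
  })
}

.meanPetMse <- function(model, studies) {
  errs <- vapply(studies, function(s) {
    vox <- voxels(s$ct)
    d <- dim(vox)
    x <- array(vox, c(d[1], d[2], 1L, d[3]))
    fw <- .unetForward(model@params, "u1", x, model@config)
    pv <- voxels(s$pet)
    mean((fw$out - array(pv, dim(fw$out)))^2)
  }, numeric(1))
  mean(errs)
}

.meanStudyDice <- function(model, studies, threshold = 0.5) {
  scores <- vapply(studies, function(s) {
    pr <- predictVolume(model, s$ct, threshold = threshold)
    diceCoefficient(voxels(pr$mask), voxels(s$mask))
  }, numeric(1))
  mean(scores)
}

#' Slice-wise inference on a volume
#'
#' Runs the connected network on every axial slice and assembles pseudo-PET,
#' tumor-probability and thresholded binary-mask volumes on the input grid.
#'
#' @param model a [ConnectedUNet-class] or [Checkpoint-class].
#' @param volume a CT [Volume-class] (or bare 3D array) whose in-plane size
#'   is divisible by `2^(depth-1)`.
#' @param threshold binarization threshold for the mask (default 0.5).
#' @param batchSlices slices processed per forward pass.
#' @return list of [Volume-class]s: `pet`, `prob`, `mask`.
#' @export
predictVolume <- function(model, volume, threshold = 0.5, batchSlices = 8L) {
  if (methods::is(model, "Checkpoint")) model <- model@model
  v <- if (methods::is(volume, "Volume")) volume else Volume(volume)
  vox <- voxels(v)
  d <- dim(vox)
  prob <- array(0, d)
  pet <- array(0, d)
  for (start in seq(1L, d[3], by = batchSlices)) {
    sel <- start:min(start + batchSlices - 1L, d[3])
    x <- array(vox[, , sel], c(d[1], d[2], 1L, length(sel)))
    fw <- .connectedForward(model@params, model@config, x)
    prob[, , sel] <- fw$prob[, , 1L, ]
    pet[, , sel] <- fw$pet[, , 1L, ]
  }
  list(pet = Volume(pet, spacing(v), "PET", v@origin),
       prob = Volume(prob, spacing(v), "prob", v@origin),
       mask = Volume((prob > threshold) * 1, spacing(v), "mask", v@origin))
}
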