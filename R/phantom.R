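# Synthetic thorax phantoms: CT with two dark lung fields in a brighter
# body disc, one bright ellipsoidal tumor coherent across slices, a PET
# channel built as a blurred tumor hot spot, a binary tumor mask, and an
# optional distractor blob (bright on CT, absent from PET and mask) that
# gives the tumor-area detector false positives to remove.

#' Create a phantom specification
#'
#' Defaults describe the study conditions used throughout the package: a
#' 288 x 288 in-plane grid with 48 slices (so the 21-slice window logic of
#' the area detector is exercised), tumor radii of 8-24 px, CT tumor
#' contrast 0.45 over the lung field, PET hot-spot multiplier 6 over a 0.1
#' background, 2 px PET blur, 2% Gaussian noise and a 20% distractor rate.
#' Desk-scale tests shrink `imageSize`/`nSlices` and the radius range
#' proportionally.
#'
#' @param imageSize slice (height, width) in px.
#' @param nSlices axial slices per study.
#' @param tumorRadiusRange in-plane tumor radius interval (px), min 2.
#' @param tumorIntensity CT contrast of tumor over lung tissue.
#' @param petContrast PET hot-spot multiplier over background.
#' @param petBlurSigma Gaussian sigma of the PET hot spot (px).
#' @param noiseSigma additive Gaussian noise s.d.
#' @param distractorProb probability of a distractor blob per study.
#' @param seed RNG seed.
#' @return A [PhantomSpec-class].
#' @export
#' @examples
#' phantomSpec(imageSize = c(64, 64), nSlices = 8, tumorRadiusRange = c(4, 9))
phantomSpec <- function(imageSize = c(288, 288), nSlices = 48,
                        tumorRadiusRange = c(8, 24), tumorIntensity = 0.45,
                        petContrast = 6, petBlurSigma = 2,
                        noiseSigma = 0.02, distractorProb = 0.2,
                        seed = 1L) {
  methods::new("PhantomSpec", imageSize = as.integer(imageSize),
               nSlices = as.integer(nSlices),
               tumorRadiusRange = as.numeric(tumorRadiusRange),
               tumorIntensity = tumorIntensity, petContrast = petContrast,
               petBlurSigma = petBlurSigma, noiseSigma = noiseSigma,
               distractorProb = distractorProb, seed = as.integer(seed))
}

# binary ellipse on an (H, W) grid, 1-based center
.ellipse <- function(H, W, cy, cx, ry, rx) {
  yy <- matrix(seq_len(H), H, W)
  xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  ((yy - cy) / ry)^2 + ((xx - cx) / rx)^2 <= 1
}

# ellipsoidal blob across slices; in-plane circular with radius r scaled by
# the slice's position along the z semi-axis rz
.blob3d <- function(H, W, nS, cy, cx, cz, r, rz) {
  out <- array(0, c(H, W, nS))
  for (k in seq_len(nS)) {
    f <- 1 - ((k - cz) / rz)^2
    if (f <= 0) next
    rk <- r * sqrt(f)
    if (rk < 1) next
    out[, , k] <- .ellipse(H, W, cy, cx, rk, rk) * 1
  }
  out
}

#' Generate one synthetic CT/PET/mask study
#'
#' CT is piecewise constant (background 0.02, body 0.5, lungs 0.12, tumor =
#' lung + `tumorIntensity`) plus Gaussian noise; PET is `bg +
#' (min(0.95, bg * petContrast) - bg) * blur(mask)` with background
#' `bg = 0.1`, plus noise; the mask is the exact tumor ellipsoid indicator.
#' A distractor blob (same CT contrast as the tumor, short axial run) is
#' placed in the opposite lung with probability `distractorProb`; it never
#' appears in the PET or the mask. All intensities are clipped to \[0,1\].
#' Generation is fully determined by `spec@seed` (same seed, bit-identical
#' study).
#'
#' @param spec a [PhantomSpec-class].
#' @param studyId identifier stored in the study.
#' @return A [PhantomStudy-class].
#' @export
#' @examples
#' ph <- generatePhantom(phantomSpec(imageSize = c(64, 64), nSlices = 8,
#'                                   tumorRadiusRange = c(4, 9), seed = 7))
#' ph
generatePhantom <- function(spec, studyId = sprintf("phantom-%06d",
                                                    spec@seed)) {
  H <- spec@imageSize[1]; W <- spec@imageSize[2]; nS <- spec@nSlices
  .withSeed(spec@seed, {
    body <- .ellipse(H, W, (H + 1) / 2, (W + 1) / 2, 0.44 * H, 0.46 * W)
    lungRy <- 0.28 * H; lungRx <- 0.16 * W
    lungCx <- c((W + 1) / 2 - 0.22 * W, (W + 1) / 2 + 0.22 * W)
    lungs <- list(
      .ellipse(H, W, (H + 1) / 2, lungCx[1], lungRy, lungRx),
      .ellipse(H, W, (H + 1) / 2, lungCx[2], lungRy, lungRx))

    r <- stats::runif(1, spec@tumorRadiusRange[1], spec@tumorRadiusRange[2])
    if (r >= min(lungRy, lungRx))
      stop("tumor radius exceeds the lung field")
    side <- sample.int(2L, 1)
    maxDy <- lungRy - r; maxDx <- lungRx - r
    cyT <- (H + 1) / 2 + stats::runif(1, -0.6, 0.6) * maxDy
    cxT <- lungCx[side] + stats::runif(1, -0.6, 0.6) * maxDx
    czT <- stats::runif(1, 0.4, 0.6) * nS
    rzT <- max(1.5, stats::runif(1, 0.25, 0.45) * nS)
    mask <- .blob3d(H, W, nS, cyT, cxT, czT, r, rzT)

    ctSlice <- matrix(0.02, H, W)
    ctSlice[body] <- 0.5
    ctSlice[lungs[[1]] | lungs[[2]]] <- 0.12
    ct <- array(ctSlice, c(H, W, nS))
    ct[mask == 1] <- 0.12 + spec@tumorIntensity

    if (stats::runif(1) < spec@distractorProb) {
      rd <- stats::runif(1, 0.6, 0.9) * r
      cyD <- (H + 1) / 2 + stats::runif(1, -0.6, 0.6) * (lungRy - rd)
      cxD <- lungCx[3L - side] + stats::runif(1, -0.6, 0.6) * (lungRx - rd)
      czD <- stats::runif(1, 0.3, 0.7) * nS
      rzD <- max(1, stats::runif(1, 0.08, 0.18) * nS)
      distractor <- .blob3d(H, W, nS, cyD, cxD, czD, rd, rzD)
      ct[distractor == 1] <- 0.12 + spec@tumorIntensity
    }

    bg <- 0.1
    peak <- min(0.95, bg * spec@petContrast)
    hot <- array(0, dim(mask))
    for (k in seq_len(nS)) {
      if (!any(mask[, , k] > 0) ) next
      hot[, , k] <- EBImage::gblur(mask[, , k], sigma = spec@petBlurSigma)
    }
    if (max(hot) > 0) hot <- hot / max(hot)
    pet <- bg + (peak - bg) * hot

    if (spec@noiseSigma > 0) {
      ct <- ct + stats::rnorm(length(ct), sd = spec@noiseSigma)
      pet <- pet + stats::rnorm(length(pet), sd = spec@noiseSigma)
    }
    ct <- pmin(pmax(ct, 0), 1)
    pet <- pmin(pmax(pet, 0), 1)

    methods::new("PhantomStudy",
                 ct = Volume(ct, modality = "CT"),
                 pet = Volume(pet, modality = "PET"),
                 mask = Volume(mask, modality = "mask"),
                 spec = spec, tumorCenter = c(cyT, cxT, czT),
                 tumorRadius = c(r, r, rzT), studyId = studyId)
  })
}

#' Generate a series of phantom studies
#'
#' @param n number of studies.
#' @param spec template [PhantomSpec-class]; each study uses
#'   `spec@seed + i` as its own seed.
#' @return list of [PhantomStudy-class].
#' @export
generatePhantomSeries <- function(n, spec = phantomSpec()) {
  lapply(seq_len(n), function(i) {
    si <- spec
    si@seed <- spec@seed + as.integer(i)
    generatePhantom(si, studyId = sprintf("phantom-%06d", si@seed))
  })
}

#' Split studies into Data A, Data B, validation and test sets
#'
#' Reproduces the supervision structure of the training corpus: Data A
#' studies keep only (CT, PET) — PET-paired studies carry no masks — and
#' Data B plus the evaluation splits keep only (CT, mask). With 126 studies
#' and fractions (0.8, 0.1, 0.1) this yields a 100/13/13 train/val/test
#' division.
#'
#' @param studies list of [PhantomStudy-class] (or any objects with `ct`,
#'   `pet`, `mask` slots and a `studyId`).
#' @param fractions length-3 (train, val, test), summing to 1.
#' @param aFraction fraction of the training studies assigned to Data A.
#' @param seed shuffle seed.
#' @return list with elements `dataA`, `dataB`, `val`, `test`; each entry is
#'   a list of `list(ct = , pet = /mask = , studyId = )`.
#' @export
makeABSplit <- function(studies, fractions = c(0.8, 0.1, 0.1),
                        aFraction = 0.5, seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  n <- length(studies)
  nTrain <- floor(fractions[1] * n)
  nVal <- round(fractions[2] * n)
  nTest <- n - nTrain - nVal
  if (nTrain < 2L || nVal < 1L || nTest < 1L)
    stop("too few studies for a non-empty split")
  .withSeed(seed, {
    ord <- sample.int(n)
    nA <- round(nTrain * aFraction)
    asA <- function(s) list(ct = s@ct, pet = s@pet, studyId = s@studyId)
    asB <- function(s) list(ct = s@ct, mask = s@mask, studyId = s@studyId)
    list(
      dataA = lapply(studies[ord[seq_len(nA)]], asA),
      dataB = lapply(studies[ord[nA + seq_len(nTrain - nA)]], asB),
      val = lapply(studies[ord[nTrain + seq_len(nVal)]], asB),
      test = lapply(studies[ord[nTrain + nVal + seq_len(nTest)]], asB))
  })
}
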