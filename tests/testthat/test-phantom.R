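# Phantom generator and the A/B supervision split.

smallSpec <- function(seed = 1, ...) {
  phantomSpec(imageSize = c(64, 64), nSlices = 8,
              tumorRadiusRange = c(4, 9), seed = seed, ...)
}

test_that("generation is bit-identical under a fixed seed", {
  a <- generatePhantom(smallSpec(seed = 5))
  b <- generatePhantom(smallSpec(seed = 5))
  expect_identical(voxels(a@ct), voxels(b@ct))
  expect_identical(voxels(a@pet), voxels(b@pet))
  expect_identical(voxels(a@mask), voxels(b@mask))
  c <- generatePhantom(smallSpec(seed = 6))
  expect_false(identical(voxels(a@ct), voxels(c@ct)))
})

test_that("noise-free phantoms are piecewise constant with exact masks", {
  ph <- generatePhantom(smallSpec(seed = 3, noiseSigma = 0,
                                  distractorProb = 0))
  vals <- unique(as.vector(voxels(ph@ct)))
  # background, body, lung, tumor only
  expect_true(all(vals %in% c(0.02, 0.5, 0.12, 0.12 + 0.45)))
  # mask is exactly the set of tumor-intensity voxels
  expect_identical(voxels(ph@mask),
                   (voxels(ph@ct) == 0.12 + 0.45) * 1)
  expect_true(all(voxels(ph@mask) %in% c(0, 1)))
  expect_gt(sum(voxels(ph@mask)), 0)
})

test_that("PET hot spot dominates the background by construction", {
  ratios <- vapply(1:20, function(i) {
    ph <- generatePhantom(smallSpec(seed = 200 + i))
    m <- voxels(ph@mask); p <- voxels(ph@pet)
    mean(p[m == 1]) / mean(p[m == 0])
  }, numeric(1))
  expect_true(all(ratios >= 6 / 2))   # >= petContrast / 2
})

test_that("distractor blobs never enter the mask or the PET channel", {
  ph <- generatePhantom(smallSpec(seed = 11, noiseSigma = 0,
                                  distractorProb = 1))
  ct <- voxels(ph@ct); m <- voxels(ph@mask); p <- voxels(ph@pet)
  bright <- ct == 0.12 + 0.45
  distractor <- bright & m == 0
  expect_gt(sum(distractor), 0)          # the blob exists on CT
  expect_lt(max(p[distractor]), 0.2)     # but stays cold on PET
})

test_that("the A/B split reproduces 100/13/13 on 126 studies", {
  # split bookkeeping only needs study stubs, not full image volumes
  studies <- generatePhantomSeries(
    126, phantomSpec(imageSize = c(16, 16), nSlices = 2,
                     tumorRadiusRange = c(2, 2.4), petBlurSigma = 1,
                     seed = 900))
  sp <- makeABSplit(studies, fractions = c(0.8, 0.1, 0.1), seed = 4)
  expect_equal(length(sp$dataA) + length(sp$dataB), 100L)
  expect_length(sp$val, 13L)
  expect_length(sp$test, 13L)
  # supervision structure: A exposes no mask, B/val/test expose no PET
  expect_named(sp$dataA[[1]], c("ct", "pet", "studyId"))
  expect_named(sp$dataB[[1]], c("ct", "mask", "studyId"))
  expect_named(sp$test[[1]], c("ct", "mask", "studyId"))
  # disjoint and covering
  ids <- c(vapply(sp$dataA, `[[`, "", "studyId"),
           vapply(sp$dataB, `[[`, "", "studyId"),
           vapply(sp$val, `[[`, "", "studyId"),
           vapply(sp$test, `[[`, "", "studyId"))
  expect_length(unique(ids), 126L)
  expect_setequal(ids, vapply(studies, function(s) s@studyId, ""))
  expect_error(makeABSplit(studies[1:3], c(0.8, 0.1, 0.1)), "too few")
  expect_error(makeABSplit(studies, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("an oversized tumor is rejected", {
  expect_error(
    generatePhantom(phantomSpec(imageSize = c(32, 32), nSlices = 4,
                                tumorRadiusRange = c(6, 6), seed = 1)),
    "exceeds the lung")
})
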