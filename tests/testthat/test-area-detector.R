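# Rotation expansion, window selection, farthest pairs, clustering, region
# masking and the full refinement pipeline.

test_that("rotation expansion quadruples the sequence with provenance", {
  set.seed(3)
  vol <- array(runif(3 * 8 * 8), c(8, 8, 3))
  sq <- expandWithRotations(vol)
  expect_length(sq@slices, 12L)
  expect_equal(sq@provenance$source, rep(1:3, each = 4))
  expect_equal(sq@provenance$rotation, rep(c(0, 90, 180, 270), 3))
  # entry 6 is source slice 2 rotated by 90 degrees
  expect_equal(sq@provenance[6, ],
               data.frame(source = 2, rotation = 90), ignore_attr = TRUE)
  # un-rotating every entry reproduces its source exactly
  for (i in seq_along(sq@slices)) {
    src <- sq@provenance$source[i]
    expect_identical(undoRotation(sq@slices[[i]],
                                  sq@provenance$rotation[i]),
                     vol[, , src])
  }
  expect_error(expandWithRotations(array(0, c(4, 6, 2))), "square")
})

test_that("the TSI window takes up to 21 slices around the middle slice", {
  pos <- rep(FALSE, 60); pos[11:50] <- TRUE      # 40-slice tumor run
  w <- selectTsiWindow(pos)
  expect_length(w, 21L)
  expect_equal(w, 20:40)                         # centered on slice 30
  pos5 <- rep(FALSE, 12); pos5[4:8] <- TRUE      # short run: clipped
  expect_equal(selectTsiWindow(pos5), 4:8)
  pos21 <- rep(FALSE, 30); pos21[1:21] <- TRUE   # run exactly 21 long
  expect_equal(selectTsiWindow(pos21), 1:21)
  # two runs: the longest wins
  pos2 <- rep(FALSE, 40); pos2[3:7] <- TRUE; pos2[20:35] <- TRUE
  expect_true(all(selectTsiWindow(pos2) %in% 20:35))
  expect_error(selectTsiWindow(rep(FALSE, 10)), "no tumor")
  # never exceeds 21 for any run length
  for (len in c(1, 10, 21, 22, 35)) {
    p <- rep(FALSE, 50); p[5 + seq_len(len)] <- TRUE
    expect_lte(length(selectTsiWindow(p)), 21L)
  }
})

test_that("farthestPair finds the diameter with deterministic ties", {
  m <- matrix(0, 6, 6)
  m[cbind(c(1, 5, 2), c(1, 5, 2))] <- 1  # (x,y): (0,0), (4,4), (1,1)
  q <- farthestPair(m)
  expect_equal(unlist(q[c("xl", "yl", "xr", "yr")]),
               c(xl = 0, yl = 0, xr = 4, yr = 4))
  expect_equal(q$distance, sqrt(32))
  # the documented 3-4-5 example
  m2 <- matrix(0, 6, 6)
  m2[1, 1] <- 1; m2[5, 4] <- 1; m2[2, 2] <- 1   # (0,0), (3,4), (1,1)
  q2 <- farthestPair(m2)
  expect_equal(q2$distance, 5)
  expect_equal(unlist(q2[c("xl", "yl", "xr", "yr")]),
               c(xl = 0, yl = 0, xr = 3, yr = 4))
  # two-pixel mask returns that pair
  m3 <- matrix(0, 4, 4); m3[2, 3] <- 1; m3[4, 1] <- 1
  q3 <- farthestPair(m3)
  expect_equal(unlist(q3[c("xl", "yl", "xr", "yr")]),
               c(xl = 0, yl = 3, xr = 2, yr = 1))
  expect_error(farthestPair(matrix(0, 3, 3)), "at least 2")
})

test_that("farthestPair agrees with the brute-force oracle", {
  set.seed(99)
  for (i in 1:50) {
    m <- randomMask(sample(8:24, 1), sample(8:24, 1), p = runif(1, 0.05, 0.5))
    got <- farthestPair(m)
    ref <- bruteFarthest(m)
    expect_equal(unname(unlist(got[c("xl", "yl", "xr", "yr")])), ref$q)
    expect_equal(got$distance, ref$d)
  }
  # also exercise the convex-hull path (> 400 positives)
  big <- matrix(0, 40, 40); big[5:35, 5:35] <- 1
  gb <- farthestPair(big)
  expect_equal(gb$distance, sqrt(2) * 30)
})

test_that("farthest pairs map to each other under 180-degree rotation", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(9:15, 1)
    m <- randomMask(n, n, p = 0.15)
    q <- farthestPair(m)
    qr <- farthestPair(rotateSlice(m, 180))
    # the diameter is invariant; the argmax pair maps into the tie set,
    # so its back-rotated endpoints must be positive pixels of the
    # original mask at exactly the same (maximal) separation
    expect_equal(qr$distance, q$distance)
    bx <- n - 1 - c(qr$xl, qr$xr); by <- n - 1 - c(qr$yl, qr$yr)
    expect_true(all(m[cbind(by + 1, bx + 1)] == 1))
    expect_equal(sqrt(diff(bx)^2 + diff(by)^2), q$distance)
  }
})

test_that("2-means recovers well-separated quadruple groups", {
  # two exact quadruples duplicated: centers equal the quadruples
  q <- data.frame(xl = c(10, 10, 90, 90), yl = c(5, 5, 80, 80),
                  xr = c(20, 20, 99, 99), yr = c(9, 9, 95, 95))
  cl <- clusterQuadruples(q, seed = 1)
  ctr <- cl$centers[order(cl$centers[, 1]), ]
  expect_equal(unname(ctr[1, ]), c(10, 5, 20, 9))
  expect_equal(unname(ctr[2, ]), c(90, 80, 99, 95))
  expect_equal(sum(cl$sizes), 4L)

  # Gaussian blobs 100 apart, sd 1: recovered within 2 px
  set.seed(12)
  mk <- function(mu, n) data.frame(xl = rnorm(n, mu, 1),
                                   yl = rnorm(n, mu, 1),
                                   xr = rnorm(n, mu + 10, 1),
                                   yr = rnorm(n, mu + 10, 1))
  qq <- rbind(mk(20, 10), mk(120, 10))
  cl2 <- clusterQuadruples(qq, seed = 3)
  ctr2 <- cl2$centers[order(cl2$centers[, 1]), ]
  expect_true(all(abs(ctr2[1, ] - c(20, 20, 30, 30)) < 2))
  expect_true(all(abs(ctr2[2, ] - c(120, 120, 130, 130)) < 2))

  # permutation invariance up to label swap
  perm <- sample(nrow(qq))
  cl3 <- clusterQuadruples(qq[perm, ], seed = 3)
  expect_equal(ctr2, cl3$centers[order(cl3$centers[, 1]), ],
               tolerance = 1e-9, ignore_attr = TRUE)

  # single-quadruple fallback
  one <- clusterQuadruples(q[1, ], seed = 1)
  expect_equal(nrow(one$centers), 1L)
})

test_that("the region rectangle follows the min/max +/- lambda rule", {
  q <- data.frame(xl = 100, yl = 100, xr = 120, yr = 110)
  cl <- clusterQuadruples(q, seed = 1)
  rm1 <- buildRegionMask(cl, q, imageShape = c(288, 288), lam = 50)
  on <- which(rm1@mask == 1, arr.ind = TRUE)
  expect_equal(range(on[, 2] - 1), c(50, 170))   # columns (x)
  expect_equal(range(on[, 1] - 1), c(50, 160))   # rows (y)
  expect_equal(sum(rm1@mask), 121 * 111)

  # degenerate: lam 0 with P0 = P0' marks a single pixel
  q2 <- data.frame(xl = 7, yl = 4, xr = 7, yr = 4)
  rm2 <- buildRegionMask(clusterQuadruples(q2), q2,
                         imageShape = c(16, 16), lam = 0)
  expect_equal(sum(rm2@mask), 1)
  expect_equal(which(rm2@mask == 1, arr.ind = TRUE)[1, ],
               c(row = 5, col = 8))

  # clipping at the border: mask sum equals the clipped area
  rm3 <- buildRegionMask(cl, q, imageShape = c(150, 150), lam = 50)
  expect_equal(sum(rm3@mask), (min(170, 149) - 50 + 1) *
                 (min(160, 149) - 50 + 1))
})

test_that("an all-covering region leaves the prediction unchanged", {
  # force confident positive output so the first pass is non-empty
  net <- connectedUNet(modelConfig(baseWidth = 2, depth = 2), seed = 10)
  net@params[["u2.head.b"]][] <- 3
  vol <- Volume(array(runif(16 * 16 * 6), c(16, 16, 6)))
  res <- refineVolume(net, vol, lam = 16)   # lam >= image: U is all ones
  expect_true(all(res$region@mask == 1))
  expect_identical(voxels(res$mask), voxels(res$firstPass))
  # and in general nothing survives outside the rectangle
  res2 <- refineVolume(net, vol, lam = 2)
  outside <- array(1 - res2$region@mask, dim(voxels(res2$mask)))
  expect_equal(sum(voxels(res2$mask) * outside), 0)
})

test_that("refinement is deterministic given model and seed", {
  net <- connectedUNet(modelConfig(baseWidth = 2, depth = 2), seed = 10)
  net@params[["u2.head.b"]][] <- 3
  vol <- Volume(array(runif(16 * 16 * 4), c(16, 16, 4)))
  r1 <- refineVolume(net, vol, lam = 3, seed = 2)
  r2 <- refineVolume(net, vol, lam = 3, seed = 2)
  expect_identical(voxels(r1$mask), voxels(r2$mask))
  expect_identical(r1$quadruples, r2$quadruples)
})
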