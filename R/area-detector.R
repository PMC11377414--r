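# Clustering-based tumor-area detection: rotation expansion of the slice
# sequence, farthest-pixel-pair quadruples over a 21-slice window around the
# middle tumor-positive slice, 2-means clustering of the quadruples,
# rectangular region masking, and re-prediction on the masked CT.

#' Expand a slice sequence with quarter-turn rotations
#'
#' Every slice C_i is followed by its 90, 180 and 270 degree rotations, so
#' the output holds 4N slices in the order (C_i, C_i^90, C_i^180, C_i^270,
#' C_{i+1}, ...). The provenance records each entry's source slice and
#' applied rotation so downstream predictions can be mapped back to the
#' source frame with [undoRotation()].
#'
#' @param x a [Volume-class], 3D array, or list of square matrices.
#' @return A [SliceSequence-class] of length 4N.
#' @export
#' @examples
#' sq <- expandWithRotations(array(runif(3 * 8 * 8), c(8, 8, 3)))
#' sq
expandWithRotations <- function(x) {
  slices <- .asSliceList(x)
  if (nrow(slices[[1]]) != ncol(slices[[1]]))
    stop("rotation expansion requires square slices")
  out <- vector("list", 4L * length(slices))
  src <- integer(length(out))
  rot <- numeric(length(out))
  j <- 0L
  for (i in seq_along(slices)) {
    for (deg in c(0, 90, 180, 270)) {
      j <- j + 1L
      out[[j]] <- .rotateQuarter(slices[[i]], deg)
      src[j] <- i
      rot[j] <- deg
    }
  }
  methods::new("SliceSequence", slices = out,
               provenance = data.frame(source = src, rotation = rot))
}

.asSliceList <- function(x) {
  if (methods::is(x, "SliceSequence")) return(x@slices)
  if (methods::is(x, "Volume")) x <- voxels(x)
  if (is.array(x) && length(dim(x)) == 3L)
    return(lapply(seq_len(dim(x)[3]), function(k) x[, , k]))
  if (is.list(x)) return(x)
  stop("expected a Volume, 3D array, list of matrices, or SliceSequence")
}

#' Select the quadruple-extraction window of tumor slices
#'
#' Finds the longest contiguous run of tumor-positive slices, takes its
#' middle slice S_N, and returns the run indices within 10 slices of S_N on
#' either side: at most 21 slices, exactly 21 whenever the run is long
#' enough.
#'
#' @param masks binary slice masks: a [SliceSequence-class], 3D array, list
#'   of matrices, or a logical vector of per-slice positivity.
#' @return integer vector of selected slice indices (1-based).
#' @export
#' @examples
#' pos <- rep(FALSE, 60); pos[11:50] <- TRUE  # 40 tumor slices
#' length(selectTsiWindow(pos))               # 21
selectTsiWindow <- function(masks) {
  positive <- if (is.logical(masks) || (is.atomic(masks) && is.null(dim(masks)))) {
    as.logical(masks)
  } else {
    vapply(.asSliceList(masks), function(m) any(m > 0), logical(1))
  }
  if (!any(positive)) stop("no tumor detected: all slices are empty")
  r <- rle(positive)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- which(r$values)
  best <- pos[which.max(r$lengths[pos])]   # longest run, first on ties
  lo <- starts[best]; hi <- ends[best]
  sn <- (lo + hi) %/% 2L
  seq(max(lo, sn - 10L), min(hi, sn + 10L))
}

#' Farthest pixel pair on a tumor slice
#'
#' Returns the pair of positive pixels at maximal Euclidean distance, as the
#' quadruple (x_l, y_l, x_r, y_r) with 0-based coordinates (x = column,
#' y = row), ordered so (x_l, y_l) <= (x_r, y_r) lexicographically. Ties are
#' broken deterministically by the lexicographically smallest quadruple.
#' For large masks the search is restricted to the convex hull of the
#' positive pixels (the diameter of a finite set is attained at hull
#' vertices).
#'
#' @param mask binary matrix with at least two positive pixels.
#' @return list with `xl`, `yl`, `xr`, `yr` and `distance` (px).
#' @export
#' @examples
#' m <- matrix(0, 5, 5); m[1, 1] <- 1; m[4, 5] <- 1; m[2, 2] <- 1
#' farthestPair(m)  # (0,0) to (4,3), distance 5
farthestPair <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) < 2L)
    stop("farthest pair needs at least 2 positive pixels")
  x <- idx[, 2] - 1L
  y <- idx[, 1] - 1L
  if (length(x) > 400L) {
    h <- grDevices::chull(x, y)
    x <- x[h]; y <- y[h]
  }
  # squared distances are exact integers, so ties are exact
  dx <- outer(x, x, "-")
  dy <- outer(y, y, "-")
  d2 <- dx * dx + dy * dy
  mx <- max(d2)
  at <- which(d2 == mx, arr.ind = TRUE)
  at <- at[at[, 1] < at[, 2], , drop = FALSE]
  quads <- t(apply(at, 1, function(ij) {
    a <- c(x[ij[1]], y[ij[1]]); b <- c(x[ij[2]], y[ij[2]])
    if (a[1] > b[1] || (a[1] == b[1] && a[2] > b[2])) c(b, a) else c(a, b)
  }))
  best <- quads[order(quads[, 1], quads[, 2], quads[, 3], quads[, 4])[1], ]
  list(xl = best[1], yl = best[2], xr = best[3], yr = best[4],
       distance = sqrt(mx))
}

#' Cluster quadruples into two groups
#'
#' Standard 2-means (10 restarts, 300-iteration cap, fixed seed) on the
#' 4-vectors (x_l, y_l, x_r, y_r). With fewer than two distinct quadruples
#' the function falls back to a single cluster containing everything.
#'
#' @param quads data.frame or matrix with columns xl, yl, xr, yr (one row
#'   per quadruple); extra columns (e.g. `slice`) are carried through.
#' @param seed k-means seed.
#' @return list with `centers` (one row per cluster), `assignment`,
#'   `sizes`, and `withinss`.
#' @export
clusterQuadruples <- function(quads, seed = 1L) {
  m <- as.matrix(as.data.frame(quads)[, c("xl", "yl", "xr", "yr")])
  if (nrow(m) < 2L || nrow(unique(m)) < 2L) {
    ctr <- matrix(colMeans(m), 1, 4,
                  dimnames = list(NULL, colnames(m)))
    return(list(centers = ctr, assignment = rep(1L, nrow(m)),
                sizes = nrow(m), withinss = 0))
  }
  km <- .withSeed(seed,
                  stats::kmeans(m, centers = 2L, nstart = 10L,
                                iter.max = 300L))
  list(centers = km$centers, assignment = km$cluster, sizes = km$size,
       withinss = km$withinss)
}

#' Build the rectangular region mask from the majority cluster
#'
#' Takes the cluster with more quadruples (ties: lower within-cluster
#' variance, then lower label), averages its left points into P0 and its
#' right points into P0', and sets to 1 the axis-aligned bounding rectangle
#' of {P0, P0'} expanded by `lam` pixels on every side, clipped to the
#' image.
#'
#' @param cluster result of [clusterQuadruples()].
#' @param quads the clustered quadruples (data.frame with xl, yl, xr, yr).
#' @param imageShape integer(2), (rows, cols) of the CT slices.
#' @param lam expansion margin in pixels (default 50).
#' @return A [RegionMask-class].
#' @export
buildRegionMask <- function(cluster, quads, imageShape, lam = 50) {
  quads <- as.data.frame(quads)
  if (nrow(quads) == 0L) stop("empty cluster: no quadruples")
  k <- if (length(cluster$sizes) == 1L) 1L
  else if (cluster$sizes[1] != cluster$sizes[2]) which.max(cluster$sizes)
  else which.min(cluster$withinss)[1]
  sel <- cluster$assignment == k
  p0 <- c(mean(quads$xl[sel]), mean(quads$yl[sel]))
  p0p <- c(mean(quads$xr[sel]), mean(quads$yr[sel]))
  H <- imageShape[1]; W <- imageShape[2]
  x0 <- max(0, floor(min(p0[1], p0p[1]) - lam))
  x1 <- min(W - 1, ceiling(max(p0[1], p0p[1]) + lam))
  y0 <- max(0, floor(min(p0[2], p0p[2]) - lam))
  y1 <- min(H - 1, ceiling(max(p0[2], p0p[2]) + lam))
  mask <- matrix(0, H, W)
  mask[(y0:y1) + 1L, (x0:x1) + 1L] <- 1
  methods::new("RegionMask", mask = mask, p0 = p0, p0prime = p0p,
               lam = as.numeric(lam))
}

#' Refine a segmentation by tumor-area detection
#'
#' Full three-stage pipeline: (1) expand the CT slices with quarter-turn
#' rotations, predict a tumor mask for every expanded slice and map each
#' prediction back to the source frame; (2) select up to 21 slices around
#' the middle tumor-positive slice, extract the farthest-pixel-pair
#' quadruple of each, and 2-means-cluster the quadruples; (3) build the
#' rectangular region mask from the majority cluster, zero the CT outside
#' it, and re-predict on the masked CT. The returned mask is intersected
#' with the rectangle, so no positive pixel survives outside the detected
#' region.
#'
#' @param model a [Checkpoint-class] or [ConnectedUNet-class].
#' @param ctVolume CT [Volume-class] with square slices.
#' @param lam rectangle expansion margin (px), default 50.
#' @param threshold binarization threshold.
#' @param seed k-means seed.
#' @return list with `mask` (refined binary [Volume-class]), `region`
#'   ([RegionMask-class]), `quadruples` (data.frame), `window` (selected
#'   expanded-slice indices) and `firstPass` (unrefined mask volume).
#' @export
refineVolume <- function(model, ctVolume, lam = 50, threshold = 0.5,
                         seed = 1L) {
  if (methods::is(model, "Checkpoint")) model <- model@model
  v <- if (methods::is(ctVolume, "Volume")) ctVolume else Volume(ctVolume)
  vox <- voxels(v)
  d <- dim(vox)
  if (d[1] != d[2]) stop("tumor-area detection requires square slices")

  firstPass <- predictVolume(model, v, threshold = threshold)

  expanded <- expandWithRotations(v)
  nE <- length(expanded@slices)
  masks <- vector("list", nE)
  for (start in seq(1L, nE, by = 8L)) {
    sel <- start:min(start + 7L, nE)
    x <- .stackSlices(expanded@slices[sel])
    fw <- .connectedForward(model@params, model@config, x)
    for (i in seq_along(sel)) {
      pm <- (fw$prob[, , 1L, i] > threshold) * 1
      masks[[sel[i]]] <-
        undoRotation(pm, expanded@provenance$rotation[sel[i]])
    }
  }

  win <- selectTsiWindow(masks)
  rows <- list()
  for (i in win) {
    if (sum(masks[[i]]) < 2) next
    q <- farthestPair(masks[[i]])
    rows[[length(rows) + 1L]] <- data.frame(
      xl = q$xl, yl = q$yl, xr = q$xr, yr = q$yr,
      distance = q$distance, slice = i)
  }
  if (length(rows) == 0L) stop("no tumor detected: no usable quadruples")
  quads <- do.call(rbind, rows)

  cl <- clusterQuadruples(quads, seed = seed)
  region <- buildRegionMask(cl, quads, imageShape = d[1:2], lam = lam)

  maskedCt <- vox * array(region@mask, d)
  refined <- predictVolume(model, Volume(maskedCt, spacing(v), "CT",
                                         v@origin),
                           threshold = threshold)
  refMask <- voxels(refined$mask) * array(region@mask, d)

  list(mask = Volume(refMask, spacing(v), "mask", v@origin),
       region = region, quadruples = quads, window = win,
       firstPass = firstPass$mask)
}
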