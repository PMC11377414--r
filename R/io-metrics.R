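# NIfTI I/O, preprocessing to the reference grid (1 mm in-plane, 512 x 512,
# then a 288 center crop), and the evaluation metrics: Dice, IoU and the
# 95th-percentile symmetric surface distance (HD95).

#' Load a volume from a NIfTI file
#'
#' Reads voxels, spacing and origin from a `.nii`/`.nii.gz` file; intensity
#' values are untouched. Modality is taken from `modality` if given,
#' otherwise inferred: a volume whose values are all 0/1 is a mask, anything
#' else is CT.
#'
#' @param path NIfTI file path. Directories (DICOM series) are not
#'   supported; convert such series to NIfTI first.
#' @param modality optional explicit modality tag.
#' @return A [Volume-class].
#' @export
loadVolume <- function(path, modality = NULL) {
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; ",
         "convert the series to NIfTI first")
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  vox <- array(as.vector(img), dim = dim(img))
  if (length(dim(vox)) == 2L) dim(vox) <- c(dim(vox), 1L)
  if (length(dim(vox)) != 3L)
    stop("expected a 3D NIfTI volume, got ", length(dim(vox)), " dims")
  sp <- attr(img, "pixdim")[1:3]
  if (is.null(modality))
    modality <- if (all(vox %in% c(0, 1))) "mask" else "CT"
  orig <- tryCatch(as.numeric(RNifti::origin(img)),
                   error = function(e) c(0, 0, 0))
  Volume(vox, spacing = sp, modality = modality, origin = orig)
}

#' Write a volume to a NIfTI file
#'
#' @param v a [Volume-class].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
writeVolume <- function(v, path) {
  img <- RNifti::asNifti(voxels(v))
  RNifti::pixdim(img) <- spacing(v)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Resample a volume to the reference in-plane grid
#'
#' Brings every slice to `spacingMm` (default 1 mm) pixel spacing on a
#' `planeSize` x `planeSize` grid (default 512), preserving the physical
#' extent: the slice is first resized by the spacing ratio (bilinear for
#' intensities, nearest-neighbor for masks, so masks stay binary) and then
#' center-cropped or zero-padded to the target size. The slice axis is
#' untouched. Already-conformant volumes are returned unchanged, making the
#' operation idempotent.
#'
#' @param v a [Volume-class].
#' @param spacingMm target in-plane spacing (mm).
#' @param planeSize target in-plane size (px).
#' @return resampled [Volume-class].
#' @export
resampleToReference <- function(v, spacingMm = 1, planeSize = 512) {
  d <- dim(voxels(v))
  sp <- spacing(v)
  if (all(abs(sp[1:2] - spacingMm) < 1e-9) &&
      d[1] == planeSize && d[2] == planeSize)
    return(v)
  newHW <- pmax(1L, as.integer(round(d[1:2] * sp[1:2] / spacingMm)))
  isMask <- modality(v) == "mask"
  vox <- voxels(v)
  out <- array(0, c(planeSize, planeSize, d[3]))
  for (k in seq_len(d[3])) {
    s <- vox[, , k]
    rs <- if (all(newHW == d[1:2])) s else
      EBImage::resize(s, w = newHW[1], h = newHW[2],
                      filter = if (isMask) "none" else "bilinear")
    out[, , k] <- .fitPlane(rs, planeSize)
  }
  if (isMask) out <- (out > 0.5) * 1
  Volume(out, spacing = c(spacingMm, spacingMm, sp[3]),
         modality = modality(v), origin = v@origin)
}

# center-crop or zero-pad a matrix to size x size
.fitPlane <- function(m, size) {
  d <- dim(m)
  out <- matrix(0, size, size)
  ro <- (d[1] - size) %/% 2L
  co <- (d[2] - size) %/% 2L
  rIn <- seq_len(min(d[1], size)) + max(ro, 0L)
  cIn <- seq_len(min(d[2], size)) + max(co, 0L)
  rOut <- seq_len(min(d[1], size)) + max(-ro, 0L)
  cOut <- seq_len(min(d[2], size)) + max(-co, 0L)
  out[rOut, cOut] <- m[rIn, cIn]
  out
}

#' Center crop of a volume
#'
#' Extracts the central `size` x `size` window of every slice. The crop
#' offset is `floor((dim - size) / 2)` in each in-plane axis and is also
#' recorded in the returned volume's origin, so predictions can be mapped
#' back with [unCrop()].
#'
#' @param v a [Volume-class] with in-plane size >= `size`.
#' @param size crop size (default 288).
#' @return cropped [Volume-class].
#' @export
centerCrop <- function(v, size = 288) {
  d <- dim(voxels(v))
  if (any(d[1:2] < size))
    stop(sprintf("plane %dx%d smaller than crop size %d", d[1], d[2], size))
  off <- (d[1:2] - size) %/% 2L
  vox <- voxels(v)[off[1] + seq_len(size), off[2] + seq_len(size), ,
                   drop = FALSE]
  Volume(vox, spacing = spacing(v), modality = modality(v),
         origin = v@origin + c(off * spacing(v)[1:2], 0))
}

#' Undo a center crop
#'
#' Places a cropped volume back onto the reference grid, zero-padding
#' outside the cropped window.
#'
#' @param v the cropped [Volume-class].
#' @param refDim integer(2) or (3): the pre-crop grid size.
#' @return zero-padded [Volume-class] of the reference size.
#' @export
unCrop <- function(v, refDim) {
  d <- dim(voxels(v))
  off <- (refDim[1:2] - d[1:2]) %/% 2L
  out <- array(0, c(refDim[1:2], d[3]))
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), ] <- voxels(v)
  Volume(out, spacing = spacing(v), modality = modality(v),
         origin = v@origin - c(off * spacing(v)[1:2], 0))
}

.binArr <- function(x) {
  if (methods::is(x, "Volume")) x <- voxels(x)
  if (!all(x %in% c(0, 1))) stop("mask must be binary")
  x
}

#' Overlap metrics between binary masks
#'
#' `diceCoefficient` returns `2|A∩B| / (|A| + |B|)` and `iou` returns
#' `|A∩B| / |A∪B|`; the two are related by `IoU = DSC / (2 - DSC)`. When
#' both masks are empty the metrics are defined as 1; when exactly one is
#' empty, as 0.
#'
#' @param a,b binary arrays or mask [Volume-class]s of equal shape.
#' @return scalar in \[0,1\].
#' @export
#' @examples
#' a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
#' b <- matrix(0, 4, 4); b[1:2, 2:3] <- 1
#' diceCoefficient(a, b)  # 0.5
#' iou(a, b)              # 1/3
diceCoefficient <- function(a, b) {
  a <- .binArr(a); b <- .binArr(b)
  .checkSameShape(a, b)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' @rdname diceCoefficient
#' @export
iou <- function(a, b) {
  a <- .binArr(a); b <- .binArr(b)
  .checkSameShape(a, b)
  u <- sum(pmin(a + b, 1))
  if (u == 0) return(1)
  sum(a * b) / u
}

# coordinates (mm) of surface voxels: positive voxels with a face-adjacent
# background voxel (array border counts as background)
.surfaceCoords <- function(x, spacing) {
  d <- dim(x)
  i1 <- 1L + seq_len(d[1]); i2 <- 1L + seq_len(d[2]); i3 <- 1L + seq_len(d[3])
  pad <- array(0, d + 2L)
  pad[i1, i2, i3] <- x
  nb <- pad[i1 - 1L, i2, i3, drop = FALSE] *
    pad[i1 + 1L, i2, i3, drop = FALSE] *
    pad[i1, i2 - 1L, i3, drop = FALSE] *
    pad[i1, i2 + 1L, i3, drop = FALSE]
  if (d[3] > 1L)
    nb <- nb * pad[i1, i2, i3 - 1L, drop = FALSE] *
      pad[i1, i2, i3 + 1L, drop = FALSE]
  surf <- which(x == 1 & nb == 0, arr.ind = TRUE)
  if (ncol(surf) == 2L) surf <- cbind(surf, 1L)
  sweep(surf - 1, 2, spacing, "*")
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Extracts the surface voxels of both masks, computes for each surface
#' point the distance (mm) to the nearest surface point of the other mask,
#' and returns the 95th percentile of the pooled directed distances. When
#' both masks are empty the distance is 0. When exactly one is empty the
#' distance is undefined; following the package's reporting convention it
#' returns the image diagonal in mm with attribute `undefined = TRUE`, so
#' aggregates stay finite.
#'
#' @param a,b binary arrays (2D or 3D) or mask [Volume-class]s.
#' @param spacing voxel spacing in mm (recycled to the array rank); taken
#'   from the volumes when omitted.
#' @return HD95 in mm.
#' @export
hd95 <- function(a, b, spacing = NULL) {
  if (is.null(spacing)) {
    spacing <- if (methods::is(a, "Volume")) spacing(a) else c(1, 1, 1)
  }
  a <- .binArr(a); b <- .binArr(b)
  .checkSameShape(a, b)
  if (is.matrix(a)) { dim(a) <- c(dim(a), 1L); dim(b) <- dim(a) }
  spacing <- rep_len(spacing, 3L)
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) return(0)
  if (sa == 0 || sb == 0) {
    diag <- sqrt(sum(((dim(a) - 1) * spacing)^2))
    attr(diag, "undefined") <- TRUE
    return(diag)
  }
  pa <- .surfaceCoords(a, spacing)
  pb <- .surfaceCoords(b, spacing)
  d <- c(min_pair_dists_cpp(pa, pb), min_pair_dists_cpp(pb, pa))
  unname(stats::quantile(d, 0.95, type = 7))
}

#' Evaluate predicted masks against ground truth
#'
#' Computes per-study DSC, IoU and HD95 plus the mean and population
#' standard deviation of each metric.
#'
#' @param pred,truth matched lists of binary mask volumes/arrays.
#' @param spacing voxel spacing for HD95 when the masks are bare arrays.
#' @return list with `perStudy` (data.frame: study, dsc, iou, hd95,
#'   hd95Undefined) and `aggregate` (data.frame: metric, mean, sd).
#' @export
evaluateMasks <- function(pred, truth, spacing = c(1, 1, 1)) {
  if (length(pred) != length(truth))
    stop("prediction and truth lists differ in length")
  rows <- lapply(seq_along(pred), function(i) {
    h <- hd95(pred[[i]], truth[[i]], spacing)
    data.frame(study = i, dsc = diceCoefficient(pred[[i]], truth[[i]]),
               iou = iou(pred[[i]], truth[[i]]), hd95 = as.numeric(h),
               hd95Undefined = isTRUE(attr(h, "undefined")))
  })
  per <- do.call(rbind, rows)
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- data.frame(
    metric = c("dsc", "iou", "hd95"),
    mean = c(mean(per$dsc), mean(per$iou), mean(per$hd95)),
    sd = c(popSd(per$dsc), popSd(per$iou), popSd(per$hd95)))
  list(perStudy = per, aggregate = agg)
}
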