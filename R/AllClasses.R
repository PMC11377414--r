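# S4 class definitions. Voxel arrays are stored (rows, cols, slices) so a
# single slice is a native R matrix; quadruple coordinates are 0-based with
# x = column, y = row.

#' Accessors for image volumes and model objects
#'
#' `voxels()` returns the raw voxel array of a [Volume-class] (rows, cols,
#' slices); `spacing()` its voxel spacing in mm; `modality()` its modality
#' tag (`"CT"`, `"PET"` or `"mask"`). `networkConfig()` extracts the
#' [ModelConfig-class] from a model or checkpoint, and `validationScore()`
#' the mean validation Dice of a [Checkpoint-class].
#'
#' @param x an object.
#' @return The slot value.
#' @name accessors
#' @aliases voxels spacing modality networkConfig validationScore
#' @examples
#' v <- Volume(array(0, c(4, 4, 2)), spacing = c(1, 1, 1), modality = "CT")
#' dim(voxels(v))
#' spacing(v)
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("networkConfig", function(x) standardGeneric("networkConfig"))

#' @rdname accessors
#' @export
setGeneric("validationScore", function(x) standardGeneric("validationScore"))


#' Image volume with spacing and modality
#'
#' A 3D scalar grid — the unit of all I/O in the package. CT and PET volumes
#' hold intensities (normalized to \[0,1\] by the phantom generator and the
#' training pipeline); mask volumes hold binary labels.
#'
#' @slot voxels numeric 3D array, dim (rows, cols, slices).
#' @slot spacing numeric(3), voxel spacing in mm as (row, col, slice).
#' @slot modality one of `"CT"`, `"PET"`, `"mask"`, or `"prob"` for
#'   probability maps produced by inference.
#' @slot origin numeric(3), world-space origin carried through NIfTI I/O.
#'
#' @seealso [Volume()], [loadVolume()], [writeVolume()]
#' @export
setClass("Volume",
  representation(voxels = "array", spacing = "numeric",
                 modality = "character", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), modality = "CT", origin = c(0, 0, 0))
)

setValidity("Volume", function(object) {
  if (length(dim(object@voxels)) != 3L)
    return("voxels must be a 3D array (rows, cols, slices)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be three positive numbers (mm)")
  if (!object@modality %in% c("CT", "PET", "mask", "prob"))
    return("modality must be one of 'CT', 'PET', 'mask', 'prob'")
  if (object@modality == "mask" && !all(object@voxels %in% c(0, 1)))
    return("mask volumes must be binary (0/1)")
  TRUE
})

#' Construct a Volume
#'
#' @param voxels 3D array (rows, cols, slices); a matrix is promoted to a
#'   single-slice volume.
#' @param spacing voxel spacing in mm, length 3.
#' @param modality `"CT"`, `"PET"` or `"mask"`.
#' @param origin world origin, length 3.
#' @return A [Volume-class] object.
#' @export
#' @examples
#' Volume(array(runif(32), c(4, 4, 2)))
Volume <- function(voxels, spacing = c(1, 1, 1), modality = "CT",
                   origin = c(0, 0, 0)) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  methods::new("Volume", voxels = voxels, spacing = as.numeric(spacing),
               modality = modality, origin = as.numeric(origin))
}

#' Connected U-Net hyperparameters
#'
#' Describes the dual (connected) U-Net: a first U-Net mapping CT to a
#' pseudo-PET image and a second U-Net mapping CT + pseudo-PET to a tumor
#' probability map, with cross-network skip connections from the first
#' U-Net's decoder into the second U-Net's encoder. Channel width doubles
#' at every resolution level: level k carries `baseWidth * 2^(k-1)`
#' channels. Each level applies two 3x3 convolutions, each followed by
#' instance normalization (with affine terms) and a LeakyReLU.
#'
#' @slot inChannels input channels of the first U-Net (CT), default 1.
#' @slot baseWidth channels at the highest resolution level. The published
#'   configuration uses 48; unit tests use 8 or less.
#' @slot depth number of resolution levels (default 5), so inputs must be
#'   divisible by `2^(depth-1)`.
#' @slot leakySlope negative slope of the LeakyReLU, in (0,1).
#' @slot petOutChannels,segOutChannels output channels of the two heads (1).
#' @slot normAffine logical; carry learnable scale/shift in instance norm.
#' @slot convFirst logical; `TRUE` applies Conv -> InstanceNorm -> LeakyReLU
#'   (the conventional ordering), `FALSE` swaps to LeakyReLU-before-Conv for
#'   ablation.
#' @slot upsample `"tconv"` (2x2 stride-2 transposed convolution, default)
#'   or `"nearest"` (nearest-neighbor upsampling followed by a 2x2
#'   convolution).
#'
#' @seealso [modelConfig()], [connectedUNet()], [countTrainableParameters()]
#' @export
setClass("ModelConfig",
  representation(inChannels = "integer", baseWidth = "integer",
                 depth = "integer", leakySlope = "numeric",
                 petOutChannels = "integer", segOutChannels = "integer",
                 normAffine = "logical", convFirst = "logical",
                 upsample = "character"),
  prototype(inChannels = 1L, baseWidth = 48L, depth = 5L, leakySlope = 0.01,
            petOutChannels = 1L, segOutChannels = 1L, normAffine = TRUE,
            convFirst = TRUE, upsample = "tconv")
)

setValidity("ModelConfig", function(object) {
  if (object@baseWidth < 1L) return("baseWidth must be >= 1")
  if (object@depth < 2L) return("depth must be >= 2")
  if (object@leakySlope <= 0 || object@leakySlope >= 1)
    return("leakySlope must lie in (0,1)")
  if (!object@upsample %in% c("tconv", "nearest"))
    return("upsample must be 'tconv' or 'nearest'")
  TRUE
})

#' Create a model configuration
#'
#' @param inChannels,baseWidth,depth,leakySlope,petOutChannels,segOutChannels
#'   see [ModelConfig-class].
#' @param normAffine,convFirst,upsample see [ModelConfig-class].
#' @return A [ModelConfig-class].
#' @export
#' @examples
#' modelConfig(baseWidth = 8, depth = 3)
modelConfig <- function(inChannels = 1, baseWidth = 48, depth = 5,
                        leakySlope = 0.01, petOutChannels = 1,
                        segOutChannels = 1, normAffine = TRUE,
                        convFirst = TRUE, upsample = "tconv") {
  methods::new("ModelConfig", inChannels = as.integer(inChannels),
               baseWidth = as.integer(baseWidth), depth = as.integer(depth),
               leakySlope = leakySlope,
               petOutChannels = as.integer(petOutChannels),
               segOutChannels = as.integer(segOutChannels),
               normAffine = normAffine, convFirst = convFirst,
               upsample = upsample)
}

#' The connected dual U-Net model
#'
#' Holds the configuration and a flat named list of weight arrays
#' (`u1.*` for the PET-synthesis U-Net, `u2.*` for the segmentation U-Net).
#' Create with [connectedUNet()].
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of numeric arrays (weights).
#' @export
setClass("ConnectedUNet",
  representation(config = "ModelConfig", params = "list"))

#' Synthetic phantom specification
#'
#' Parameters of the thorax phantom generator: an axial "body" disc with two
#' low-intensity lung fields, one bright ellipsoidal tumor inside a lung
#' (coherent across slices), an optional distractor blob in the opposite
#' lung (bright on CT, absent from PET and mask), and a PET channel built as
#' a Gaussian-blurred tumor hot spot over a cold background.
#'
#' @slot imageSize integer(2), slice height and width in pixels.
#' @slot nSlices number of axial slices.
#' @slot tumorRadiusRange numeric(2), in-plane tumor radius interval (px).
#' @slot tumorIntensity CT contrast of the tumor over the lung field.
#' @slot petContrast hot-spot multiplier of PET tumor signal over background.
#' @slot petBlurSigma Gaussian sigma (px) of the PET hot spot.
#' @slot noiseSigma additive Gaussian noise s.d. on CT and PET.
#' @slot distractorProb probability that a study contains a distractor blob.
#' @slot seed integer RNG seed.
#' @export
setClass("PhantomSpec",
  representation(imageSize = "integer", nSlices = "integer",
                 tumorRadiusRange = "numeric", tumorIntensity = "numeric",
                 petContrast = "numeric", petBlurSigma = "numeric",
                 noiseSigma = "numeric", distractorProb = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (any(object@tumorRadiusRange < 2))
    return("tumor radii must be >= 2 px")
  if (object@distractorProb < 0 || object@distractorProb > 1)
    return("distractorProb must lie in [0,1]")
  if (any(object@imageSize < 16)) return("imageSize must be >= 16 px")
  TRUE
})

#' Synthetic CT/PET/mask study
#'
#' @slot ct,pet,mask [Volume-class] triplet on a common grid.
#' @slot spec the generating [PhantomSpec-class].
#' @slot tumorCenter numeric(3) ground-truth center (row, col, slice;
#'   1-based).
#' @slot tumorRadius numeric(3) ground-truth semi-axes (row, col, slice px).
#' @slot studyId character identifier.
#' @export
setClass("PhantomStudy",
  representation(ct = "Volume", pet = "Volume", mask = "Volume",
                 spec = "PhantomSpec", tumorCenter = "numeric",
                 tumorRadius = "numeric", studyId = "character"))

#' Training checkpoint
#'
#' Snapshot of student and teacher weights with the validation score that
#' selected it. Serialize with [saveCheckpoint()] / [loadCheckpoint()];
#' the on-disk form is an RDS container plus a plain-JSON sidecar of the
#' model configuration, so checkpoints are self-describing.
#'
#' @slot model a [ConnectedUNet-class] (student weights).
#' @slot teacherParams named list, teacher weights (same structure).
#' @slot validationScore mean validation Dice in \[0,1\].
#' @slot epoch epoch at which the snapshot was taken.
#' @export
setClass("Checkpoint",
  representation(model = "ConnectedUNet", teacherParams = "list",
                 validationScore = "numeric", epoch = "integer"))

setValidity("Checkpoint", function(object) {
  if (object@validationScore < 0 || object@validationScore > 1)
    return("validationScore must lie in [0,1]")
  TRUE
})

#' Slice sequence with rotation provenance
#'
#' An ordered list of square 2D slices together with, for every entry, the
#' index of its source slice and the quarter-turn rotation applied to it.
#' Produced by [expandWithRotations()]; the provenance lets every rotated
#' prediction be mapped back to the source frame.
#'
#' @slot slices list of matrices.
#' @slot provenance data.frame with columns `source` (1-based index) and
#'   `rotation` (degrees, one of 0, 90, 180, 270).
#' @export
setClass("SliceSequence",
  representation(slices = "list", provenance = "data.frame"))

setValidity("SliceSequence", function(object) {
  if (nrow(object@provenance) != length(object@slices))
    return("provenance must have one row per slice")
  if (!all(object@provenance$rotation %in% c(0, 90, 180, 270)))
    return("rotations must be quarter-turns")
  TRUE
})

#' Rectangular region-of-interest mask
#'
#' Axis-aligned rectangle around the cluster-derived points P0 and P0',
#' expanded by `lam` pixels per side and clipped to the image bounds; 1
#' inside the rectangle, 0 outside.
#'
#' @slot mask binary matrix.
#' @slot p0,p0prime numeric(2) points (x, y), 0-based.
#' @slot lam expansion margin in pixels (default 50).
#' @export
setClass("RegionMask",
  representation(mask = "matrix", p0 = "numeric", p0prime = "numeric",
                 lam = "numeric"))

# ---- show methods -----------------------------------------------------

setMethod("show", "Volume", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("Volume [%s]: %d x %d x %d voxels, spacing %s mm\n",
              object@modality, d[1], d[2], d[3],
              paste(signif(object@spacing, 3), collapse = " x ")))
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf(
    "ModelConfig: baseWidth %d, depth %d (widths %s), in %d ch\n",
    object@baseWidth, object@depth,
    paste(object@baseWidth * 2^(seq_len(object@depth) - 1), collapse = "/"),
    object@inChannels))
})

setMethod("show", "ConnectedUNet", function(object) {
  cat("Connected dual U-Net\n")
  show(object@config)
  cat(sprintf("  %s trainable parameters in %d arrays\n",
              format(countTrainableParameters(object@config), big.mark = ","),
              length(object@params)))
})

setMethod("show", "PhantomStudy", function(object) {
  d <- dim(object@ct@voxels)
  cat(sprintf(
    "PhantomStudy %s: %d x %d x %d, tumor r = (%s) px at (%s)\n",
    object@studyId, d[1], d[2], d[3],
    paste(signif(object@tumorRadius, 3), collapse = ", "),
    paste(round(object@tumorCenter, 1), collapse = ", ")))
})

setMethod("show", "Checkpoint", function(object) {
  cat(sprintf("Checkpoint (epoch %d): validation DSC %.4f\n",
              object@epoch, object@validationScore))
  show(object@model@config)
})

setMethod("show", "SliceSequence", function(object) {
  cat(sprintf("SliceSequence: %d slices (%d source, rotations %s)\n",
              length(object@slices),
              length(unique(object@provenance$source)),
              paste(sort(unique(object@provenance$rotation)),
                    collapse = "/")))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf(
    "RegionMask: %d x %d, %d px inside; P0 (%s), P0' (%s), lambda %g\n",
    nrow(object@mask), ncol(object@mask), sum(object@mask),
    paste(round(object@p0, 1), collapse = ", "),
    paste(round(object@p0prime, 1), collapse = ", "), object@lam))
})

# ---- accessors --------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("voxels", "Volume", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("spacing", "Volume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("modality", "Volume", function(x) x@modality)

#' @rdname accessors
#' @export
setMethod("networkConfig", "ConnectedUNet", function(x) x@config)

#' @rdname accessors
#' @export
setMethod("networkConfig", "Checkpoint", function(x) x@model@config)

#' @rdname accessors
#' @export
setMethod("validationScore", "Checkpoint", function(x) x@validationScore)

#' Teacher-student training state
#'
#' Mutable state threaded through [trainStep()]: the global step counter,
#' the current epoch, the EMA coefficient and consistency weight in force,
#' the teacher weights, and the Adam optimizer moments.
#'
#' @slot step global optimizer step, 0-based.
#' @slot epoch current epoch, 1-based.
#' @slot alpha EMA coefficient used at the most recent teacher update.
#' @slot w consistency weight in force.
#' @slot teacherParams named list of teacher weights (same structure as the
#'   student's).
#' @slot opt Adam moment estimates (internal).
#' @export
setClass("TrainingState",
  representation(step = "integer", epoch = "integer", alpha = "numeric",
                 w = "numeric", teacherParams = "list", opt = "list"))
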