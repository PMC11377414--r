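# Exact quarter-turn rotations of matrices (no resampling, masks stay
# binary). Angles are degrees clockwise in the displayed image; 90 and 270
# require square inputs to preserve the grid shape.

.rotateQuarter <- function(m, deg) {
  deg <- deg %% 360
  if (deg == 0) return(m)
  if (deg %in% c(90, 270) && nrow(m) != ncol(m))
    stop("quarter-turn rotation of a non-square slice changes its shape")
  switch(as.character(deg),
    "90"  = t(m[nrow(m):1, , drop = FALSE]),
    "180" = m[nrow(m):1, ncol(m):1, drop = FALSE],
    "270" = t(m[, ncol(m):1, drop = FALSE]),
    stop("rotation must be a multiple of 90 degrees")
  )
}

#' Undo a recorded quarter-turn rotation
#'
#' Maps a slice produced under a rotated view back to the source frame:
#' `undoRotation(.rotateQuarter(x, a), a)` is `x` exactly for every
#' quarter-turn angle `a`.
#'
#' @param m matrix.
#' @param deg the rotation that was applied (0, 90, 180 or 270 degrees).
#' @return matrix in the original frame.
#' @export
undoRotation <- function(m, deg) .rotateQuarter(m, (360 - deg) %% 360)

#' Rotate a slice by a quarter-turn
#'
#' @param m matrix (square for 90 and 270 degrees).
#' @param deg 0, 90, 180 or 270 (degrees, clockwise).
#' @return the rotated matrix.
#' @export
#' @examples
#' rotateSlice(diag(3), 90)
rotateSlice <- function(m, deg) .rotateQuarter(m, deg)
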