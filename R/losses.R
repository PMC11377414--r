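# Loss terms of the multitask objective L = w*C + H + F, the EMA coefficient
# and consistency-weight schedules, and the teacher EMA update.

.checkSameShape <- function(a, b) {
  if (!identical(dim(a), dim(b)) && length(a) != length(b))
    stop("shape mismatch between prediction and target")
  if (!is.null(dim(a)) && !is.null(dim(b)) && !identical(dim(a), dim(b)))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(dim(a), collapse = "x"),
                 paste(dim(b), collapse = "x")))
  invisible(TRUE)
}

#' PET reconstruction loss (mean squared error)
#'
#' The H term of the training objective: mean of squared differences between
#' the synthesized pseudo-PET and the acquired PET, over all elements.
#'
#' @param pred,target numeric arrays of equal shape.
#' @return non-negative scalar.
#' @export
#' @examples
#' petMSE(c(0, 1), c(1, 1))  # 0.5
petMSE <- function(pred, target) {
  .checkSameShape(pred, target)
  mean((pred - target)^2)
}

#' Consistency loss between student and teacher pseudo-PET
#'
#' Mean squared difference between the student's and the (rotation-aligned)
#' teacher's pseudo-PET maps. Both maps must already be in the same frame;
#' aligning the teacher output back from its rotated view is the trainer's
#' job ([teacherView()]).
#'
#' @param studentPet,teacherPet numeric arrays of equal shape.
#' @return non-negative scalar.
#' @export
consistencyLoss <- function(studentPet, teacherPet) {
  .checkSameShape(studentPet, teacherPet)
  mean((studentPet - teacherPet)^2)
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(prob*mask) + smooth) / (sum(prob) + sum(mask) + smooth)`.
#'
#' @param prob probability map in \[0,1\].
#' @param mask binary ground-truth map of the same shape.
#' @param smooth smoothing constant added to numerator and denominator.
#' @return scalar in \[0,1\].
#' @export
#' @examples
#' diceLoss(matrix(0.5, 2, 2), matrix(1, 2, 2), smooth = 0)  # 1/3
diceLoss <- function(prob, mask, smooth = 1e-6) {
  .checkSameShape(prob, mask)
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  1 - (2 * sum(prob * mask) + smooth) / (sum(prob) + sum(mask) + smooth)
}

# gradient of diceLoss w.r.t. prob
.diceLossGrad <- function(prob, mask, smooth = 1e-6) {
  A <- 2 * sum(prob * mask) + smooth
  B <- sum(prob) + sum(mask) + smooth
  -(2 * mask * B - A) / B^2
}

#' Focal loss for binary segmentation
#'
#' Mean over pixels of `-(1 - p_t)^gamma * log(p_t)` where `p_t` is the
#' predicted probability of the true class (`prob` on positives, `1 - prob`
#' on negatives). With `gamma = 0` this reduces to binary cross-entropy.
#' Probabilities are clipped to `[eps, 1 - eps]` before the log.
#'
#' @param prob probability map in \[0,1\].
#' @param mask binary ground-truth map.
#' @param gamma focusing exponent (default 2).
#' @param eps clipping constant.
#' @return non-negative scalar.
#' @export
#' @examples
#' focalLoss(0.5, 1, gamma = 2)  # 0.25 * log(2)
focalLoss <- function(prob, mask, gamma = 2, eps = 1e-7) {
  .checkSameShape(prob, mask)
  p <- pmin(pmax(prob, eps), 1 - eps)
  pt <- mask * p + (1 - mask) * (1 - p)
  mean(-(1 - pt)^gamma * log(pt))
}

# gradient of focalLoss w.r.t. prob (clip treated as pass-through)
.focalLossGrad <- function(prob, mask, gamma = 2, eps = 1e-7) {
  p <- pmin(pmax(prob, eps), 1 - eps)
  pt <- mask * p + (1 - mask) * (1 - p)
  dpt <- if (gamma == 0) {
    -1 / pt
  } else {
    gamma * (1 - pt)^(gamma - 1) * log(pt) - (1 - pt)^gamma / pt
  }
  dpt * (2 * mask - 1) / length(p)
}

#' EMA decay schedule for the teacher update
#'
#' `alpha = min(1 - 1/(step + 1), 0.99)`: the teacher tracks the student
#' closely early in training and becomes a slow moving average once
#' `step >= 99`.
#'
#' @param step global optimizer step, 0-based.
#' @return scalar in \[0, 0.99\].
#' @export
#' @examples
#' emaSchedule(0)    # 0
#' emaSchedule(9)    # 0.9
#' emaSchedule(1e4)  # 0.99
emaSchedule <- function(step) {
  if (any(step < 0)) stop("step must be >= 0")
  pmin(1 - 1 / (step + 1), 0.99)
}

#' Consistency weight ramp
#'
#' `w = 0.1 * exp(-5 * (1 - T)^2)` with `T = 1 - step/rampLength`, `T`
#' clamped to \[0,1\]: the weight starts at 0.1 and decays towards
#' `0.1 * exp(-5)` at the end of the ramp, then stays there.
#'
#' @param step schedule step (epoch index in the trainer), 0-based.
#' @param rampLength ramp extent (default 80).
#' @return scalar in (0, 0.1].
#' @export
#' @examples
#' consistencyWeight(0)   # 0.1
#' consistencyWeight(80)  # 0.1 * exp(-5)
consistencyWeight <- function(step, rampLength = 80) {
  tt <- pmin(pmax(1 - step / rampLength, 0), 1)
  0.1 * exp(-5 * (1 - tt)^2)
}

#' Combine loss components
#'
#' @param c consistency term (C).
#' @param h PET mean-squared-error term (H).
#' @param f segmentation term (F = focal + dice).
#' @param w consistency weight.
#' @return list with the unweighted components, `w`, and
#'   `total = w*c + h + f`.
#' @export
totalLoss <- function(c, h, f, w) {
  vals <- c(c = c, h = h, f = f, w = w)
  if (any(!is.finite(vals)))
    stop("non-finite loss component: ",
         paste(names(vals)[!is.finite(vals)], collapse = ", "))
  list(consistency = c, petMse = h, seg = f, w = w, total = w * c + h + f)
}

#' Exponential moving average update of the teacher weights
#'
#' Every teacher scalar becomes `alpha * teacher + (1 - alpha) * student`;
#' the student is untouched. With `alpha = 0` the teacher copies the
#' student; with `alpha = 1` it is frozen.
#'
#' @param teacher,student named lists of numeric arrays with identical
#'   structure.
#' @param alpha decay coefficient in \[0,1\].
#' @return the updated teacher weight list.
#' @export
emaUpdate <- function(teacher, student, alpha) {
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0,1]")
  if (!identical(names(teacher), names(student)))
    stop("teacher/student weight structure mismatch")
  for (nm in names(teacher)) {
    if (length(teacher[[nm]]) != length(student[[nm]]))
      stop("teacher/student weight structure mismatch at ", nm)
    teacher[[nm]] <- alpha * teacher[[nm]] + (1 - alpha) * student[[nm]]
  }
  teacher
}
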