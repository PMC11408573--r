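#' @include AllClasses.R utils.R
NULL

#' Label a nodule from its radiologist malignancy scores
#'
#' A nodule needs at least three raters to be labelled at all; with fewer it
#' is `excluded` regardless of the scores. Otherwise the mean score decides:
#' benign when the average is at most 1.5, malignant when it is at least
#' 3.5, excluded in between. The threshold comparison is done in integer
#' arithmetic on the score sum (average <= 1.5 iff 2*sum <= 3*n, average >=
#' 3.5 iff 2*sum >= 7*n), so boundary averages are classified exactly with
#' no floating-point artifacts.
#'
#' @param scores integer vector of malignancy scores, each in 1..5
#' @return List with `value` (`"benign"`, `"malignant"` or `"excluded"`)
#'   and `averageScore` (numeric mean of the scores, NA for an empty input).
#' @examples
#' labelFromScores(c(1, 1, 1))      # benign, average 1
#' labelFromScores(c(5, 5, 4, 5))   # malignant, average 4.75
#' labelFromScores(c(2, 3, 2))      # excluded
#' labelFromScores(c(1, 1))         # excluded: only two raters
#' @export
labelFromScores <- function(scores) {
  scores <- as.integer(scores)
  if (length(scores) && any(scores < 1L | scores > 5L))
    specError("scores", "all scores must lie in 1..5")
  avg <- if (length(scores)) sum(scores) / length(scores) else NA_real_
  if (length(scores) < 3L)
    return(list(value = "excluded", averageScore = avg))
  s <- sum(scores); n <- length(scores)
  value <- if (2L * s <= 3L * n) "benign"
  else if (2L * s >= 7L * n) "malignant"
  else "excluded"
  list(value = value, averageScore = avg)
}

.rotateMatrix <- function(m, angle, fill) {
  r <- EBImage::rotate(EBImage::Image(m), angle, filter = "bilinear",
                       output.dim = dim(m), bg.col = fill)
  matrix(as.numeric(EBImage::imageData(r)), nrow(m), ncol(m))
}

#' Rotation augmentation of an annotated slice
#'
#' Returns the original plus one rotated copy per angle (default +-2 and
#' +-4 degrees, i.e. five outputs). Pixels are rotated about the image
#' center with bilinear interpolation; regions swept in from outside the
#' frame are filled with the slice's background mean (mean intensity
#' outside the nodule mask). The mask is rotated with the same transform
#' and re-binarized at 0.5. Rotated copies record their angle and the id of
#' the unaugmented source.
#'
#' @param image an [AnnotatedImage-class]
#' @param angles rotation angles in degrees
#' @return List of [AnnotatedImage-class]: the original first, then one per
#'   angle.
#' @export
augmentRotations <- function(image, angles = c(2, -2, 4, -4)) {
  stopifnot(is(image, "AnnotatedImage"))
  fill <- mean(image@pixels[image@mask == 0L])
  if (!is.finite(fill)) fill <- mean(image@pixels)
  out <- vector("list", 1L + length(angles))
  out[[1]] <- image
  for (i in seq_along(angles)) {
    a <- angles[i]
    px <- .rotateMatrix(image@pixels, a, fill)
    px <- round(pmin(pmax(px, 0), 1) * 255) / 255
    mk <- .rotateMatrix(image@mask * 1.0, a, 0)
    mk <- matrix(as.integer(mk >= 0.5), nrow(mk), ncol(mk))
    out[[i + 1]] <- new("AnnotatedImage",
      imageId = sprintf("%s_rot%+g", image@imageId, a),
      patientId = image@patientId, noduleId = image@noduleId,
      pixels = px, mask = mk, classLabel = image@classLabel,
      radiologistScores = image@radiologistScores,
      augmentationAngle = as.numeric(a),
      sourceImageId = image@imageId)
  }
  out
}

#' Rotation-augment every original slice of a cohort
#'
#' Applies [augmentRotations()] to each unaugmented slice of each patient
#' and appends the copies to that patient's slice list, so patient-wise
#' splitting automatically keeps augmented copies with their source.
#'
#' @param cohort a [PhantomCohort-class]
#' @param angles rotation angles in degrees
#' @return The augmented [PhantomCohort-class].
#' @export
augmentCohort <- function(cohort, angles = c(2, -2, 4, -4)) {
  stopifnot(is(cohort, "PhantomCohort"))
  cohort@patients <- lapply(cohort@patients, function(p) {
    orig <- Filter(function(s) s@augmentationAngle == 0, p@slices)
    p@slices <- unlist(lapply(orig, augmentRotations, angles = angles),
                       recursive = FALSE)
    p
  })
  cohort
}
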