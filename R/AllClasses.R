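#' PhantomSpec: parameters of a synthetic phantom-CT cohort
#'
#' Describes a cohort of synthetic patients, each carrying a multi-slice
#' "scan" of a simplified thorax with one nodule per slice. Benign and
#' malignant nodules are separable by construction (malignant radius range
#' lies at or above the benign range, and malignant nodules are spiculated).
#' Every patient additionally carries an identity signature: a low-amplitude
#' 2-D sinusoidal texture with patient-specific frequency and phase, added
#' across the whole slice. The signature is the leakage channel that makes
#' image-wise splitting overfit.
#'
#' @slot nBenign,nMalignant number of patients per class (>= 1)
#' @slot slicesPerPatient original (unaugmented) slices per patient (>= 1)
#' @slot imageSize side of the square image, pixels
#' @slot benignRadiusRange,malignantRadiusRange nodule radius low/high in
#'   pixels; `malignantRadiusRange[1] >= benignRadiusRange[2]`
#' @slot signatureStrength amplitude of the per-patient sinusoidal identity
#'   texture, as a fraction of the intensity scale, in `[0, 1]`
#' @slot noiseSd standard deviation of the additive Gaussian pixel noise
#' @slot seed integer seed; the cohort is a pure function of the spec
#' @export
setClass("PhantomSpec",
  representation(
    nBenign = "integer", nMalignant = "integer",
    slicesPerPatient = "integer", imageSize = "integer",
    benignRadiusRange = "numeric", malignantRadiusRange = "numeric",
    signatureStrength = "numeric", noiseSd = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  msgs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) msgs <<- c(msgs, msg)
  chk(length(object@nBenign) == 1L && object@nBenign >= 1L,
      "nBenign: must be a count >= 1")
  chk(length(object@nMalignant) == 1L && object@nMalignant >= 1L,
      "nMalignant: must be a count >= 1")
  chk(length(object@slicesPerPatient) == 1L && object@slicesPerPatient >= 1L,
      "slicesPerPatient: must be a count >= 1")
  chk(length(object@imageSize) == 1L && object@imageSize >= 32L,
      "imageSize: must be >= 32 pixels")
  chk(length(object@benignRadiusRange) == 2L &&
        all(object@benignRadiusRange > 0) &&
        diff(object@benignRadiusRange) >= 0,
      "benignRadiusRange: must be positive (low, high)")
  chk(length(object@malignantRadiusRange) == 2L &&
        all(object@malignantRadiusRange > 0) &&
        diff(object@malignantRadiusRange) >= 0,
      "malignantRadiusRange: must be positive (low, high)")
  if (length(object@benignRadiusRange) == 2L &&
      length(object@malignantRadiusRange) == 2L) {
    chk(object@malignantRadiusRange[1] >= object@benignRadiusRange[2],
        "malignantRadiusRange: low must be >= benignRadiusRange high")
    # spiculated boundary extends to 1.3 * R; it must fit inside the
    # smallest jittered lung-field semi-axis (0.92 * 0.20 * imageSize)
    # with a 2 px margin
    chk(max(object@malignantRadiusRange) * 1.3 + 2 <=
          0.92 * 0.20 * object@imageSize,
        "malignantRadiusRange: nodules must fit inside the lung field")
  }
  chk(length(object@signatureStrength) == 1L &&
        object@signatureStrength >= 0 && object@signatureStrength <= 1,
      "signatureStrength: must lie in [0, 1]")
  chk(length(object@noiseSd) == 1L && object@noiseSd >= 0,
      "noiseSd: must be >= 0")
  chk(length(object@seed) == 1L && !is.na(object@seed),
      "seed: must be a single integer")
  if (length(msgs)) msgs else TRUE
})

#' AnnotatedImage: one slice with mask and annotations
#'
#' @slot imageId,patientId,noduleId identifiers
#' @slot pixels numeric matrix in `[0, 1]`, row-major slice image
#' @slot mask integer matrix of the same shape with values in `{0, 1}`,
#'   nonzero exactly on the nodule
#' @slot classLabel `"benign"` or `"malignant"` (patient ground truth)
#' @slot radiologistScores integer malignancy scores, each in 1..5
#' @slot augmentationAngle rotation in degrees (0 for originals)
#' @slot sourceImageId id of the unaugmented source (self for originals)
#' @export
setClass("AnnotatedImage",
  representation(
    imageId = "character", patientId = "character", noduleId = "character",
    pixels = "matrix", mask = "matrix", classLabel = "character",
    radiologistScores = "integer", augmentationAngle = "numeric",
    sourceImageId = "character"))

setValidity("AnnotatedImage", function(object) {
  msgs <- character()
  if (!identical(dim(object@pixels), dim(object@mask)))
    msgs <- c(msgs, "pixels and mask must have identical shape")
  if (any(object@pixels < 0 | object@pixels > 1))
    msgs <- c(msgs, "pixels must lie in [0, 1]")
  if (!all(object@mask %in% c(0L, 1L)))
    msgs <- c(msgs, "mask values must be 0 or 1")
  if (!object@classLabel %in% c("benign", "malignant"))
    msgs <- c(msgs, "classLabel must be 'benign' or 'malignant'")
  if (length(object@radiologistScores) &&
      any(object@radiologistScores < 1L | object@radiologistScores > 5L))
    msgs <- c(msgs, "radiologistScores must lie in 1..5")
  if (length(msgs)) msgs else TRUE
})

#' PatientPhantom: one synthetic patient
#'
#' @slot patientId unique id within a cohort
#' @slot classLabel `"benign"` or `"malignant"`; all the patient's nodules
#'   share it
#' @slot signatureParams list with the patient's identity-texture parameters
#'   (`fx`, `fy` spatial frequencies in cycles/pixel, `phase`, `amplitude`)
#' @slot anatomyParams list describing the two lung-field ellipses
#' @slot slices list of [AnnotatedImage-class] objects
#' @export
setClass("PatientPhantom",
  representation(
    patientId = "character", classLabel = "character",
    signatureParams = "list", anatomyParams = "list", slices = "list"))

#' PhantomCohort: a list of patients plus the spec that generated them
#'
#' @slot patients list of [PatientPhantom-class]
#' @slot spec the generating [PhantomSpec-class]
#' @export
setClass("PhantomCohort",
  representation(patients = "list", spec = "PhantomSpec"))

setValidity("PhantomCohort", function(object) {
  ids <- vapply(object@patients, function(p) p@patientId, character(1))
  if (anyDuplicated(ids)) "patient ids must be unique within a cohort"
  else TRUE
})

#' SplitPlan: assignment of every image to exactly one partition
#'
#' @slot mode `"fair"` (patient-wise) or `"unfair"` (image-wise)
#' @slot assignment named character vector, image_id ->
#'   train/validation/test/challenge
#' @slot fractions numeric (train, validation, test) summing to 1 over the
#'   non-challenge pool
#' @slot seed integer seed the plan was drawn with
#' @export
setClass("SplitPlan",
  representation(mode = "character", assignment = "character",
                 fractions = "numeric", seed = "integer"))

setValidity("SplitPlan", function(object) {
  msgs <- character()
  if (!object@mode %in% c("fair", "unfair"))
    msgs <- c(msgs, "mode must be 'fair' or 'unfair'")
  if (is.null(names(object@assignment)) ||
      anyDuplicated(names(object@assignment)))
    msgs <- c(msgs, "assignment must be uniquely named by image_id")
  bad <- setdiff(unique(object@assignment),
                 c("train", "validation", "test", "challenge"))
  if (length(bad))
    msgs <- c(msgs, paste("unknown partition:", paste(bad, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' MccvSchedule: per-epoch patient-level train/validation assignments
#'
#' Monte Carlo cross-validation at patient level: the validation patient set
#' is re-drawn independently at the start of every epoch.
#'
#' @slot epochAssignments list (one per epoch) of named character vectors,
#'   patient_id -> `"train"` or `"validation"`
#' @slot valFraction fraction of patients held out per epoch
#' @slot seed integer seed
#' @export
setClass("MccvSchedule",
  representation(epochAssignments = "list", valFraction = "numeric",
                 seed = "integer"))

setValidity("MccvSchedule", function(object) {
  for (e in object@epochAssignments) {
    if (!all(e %in% c("train", "validation")))
      return("epoch assignments must map to 'train' or 'validation'")
    if (!any(e == "validation") || !any(e == "train"))
      return("each epoch needs at least one train and one validation patient")
  }
  TRUE
})

#' TrainingConfig: hyperparameters of the reference classifier
#'
#' @slot learningRate initial learning rate (default 1e-4)
#' @slot batchSize minibatch size (default 32)
#' @slot nEpochs number of epochs
#' @slot plateauFactor factor applied to the learning rate on a validation
#'   plateau (default 0.1, i.e. reduced to one-tenth)
#' @slot plateauPatience epochs without validation-accuracy improvement
#'   before the reduction fires (default 5)
#' @slot seed integer seed for weight init and shuffling
#' @slot mccv whether the validation patients are re-drawn every epoch
#' @export
setClass("TrainingConfig",
  representation(learningRate = "numeric", batchSize = "integer",
                 nEpochs = "integer", plateauFactor = "numeric",
                 plateauPatience = "integer", weightDecay = "numeric",
                 seed = "integer", mccv = "logical"))

setValidity("TrainingConfig", function(object) {
  msgs <- character()
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be > 0")
  if (object@plateauFactor <= 0 || object@plateauFactor >= 1)
    msgs <- c(msgs, "plateauFactor must lie in (0, 1)")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be >= 1")
  if (object@nEpochs < 1L) msgs <- c(msgs, "nEpochs must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' TrainedModel: the reference small CNN with its training history
#'
#' The parameter slot is opaque; the supported surface is the contract
#' triplet [predictProb()], [lastConvActivations()], [classScoreGradient()]
#' plus [trainingHistory()] and [evaluateAccuracy()].
#'
#' @slot params list of weight matrices/vectors
#' @slot classes character(2), class labels in index order (index 1 and 2)
#' @slot inputSize side of the square input the model was trained on
#' @slot history data.frame with epoch, train_acc, val_acc, lr
#' @slot config the [TrainingConfig-class] used
#' @export
setClass("TrainedModel",
  representation(params = "list", classes = "character",
                 inputSize = "integer", history = "data.frame",
                 config = "TrainingConfig"))

#' CamConfig: options for class-activation heat maps
#'
#' @slot channelCombination `"weighted_average"`, `"weighted_maximum"` or
#'   `"both"` — how weighted channel maps are reduced to one heat map
#' @slot rectifyNegative zero out negative evidence before normalization
#' @slot colormapName colormap used by [overlayHeatmap()]
#' @export
setClass("CamConfig",
  representation(channelCombination = "character",
                 rectifyNegative = "logical", colormapName = "character"))

setValidity("CamConfig", function(object) {
  if (!object@channelCombination %in%
      c("weighted_average", "weighted_maximum", "both"))
    "channelCombination must be weighted_average, weighted_maximum or both"
  else TRUE
})

#' HeatMap: a normalized class-activation map on the image grid
#'
#' @slot values numeric matrix at image resolution; min 0 and max 1 exactly
#'   unless degenerate, in which case all zeros
#' @slot degenerate TRUE when the pre-normalization map was constant
#' @slot nativeResolution dim of the conv-grid map before upsampling
#' @slot normalizationBounds (min, max) of the map before min-max scaling
#' @export
setClass("HeatMap",
  representation(values = "matrix", degenerate = "logical",
                 nativeResolution = "integer",
                 normalizationBounds = "numeric"))

setValidity("HeatMap", function(object) {
  v <- object@values
  if (object@degenerate) {
    if (any(v != 0)) return("degenerate heat map must be all zeros")
  } else {
    if (abs(min(v)) > 1e-12 || abs(max(v) - 1) > 1e-12)
      return("non-degenerate heat map must have min 0 and max 1")
  }
  TRUE
})
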