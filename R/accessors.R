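#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname accessors
#' @aliases pixels,AnnotatedImage-method
setMethod("pixels", "AnnotatedImage", function(object) object@pixels)

#' @rdname accessors
setMethod("mask", "AnnotatedImage", function(object) object@mask)

#' @rdname accessors
setMethod("imageId", "AnnotatedImage", function(object) object@imageId)

#' @rdname accessors
setMethod("patientId", "AnnotatedImage", function(object) object@patientId)

#' @rdname accessors
setMethod("patientId", "PatientPhantom", function(object) object@patientId)

#' @rdname accessors
setMethod("classLabel", "AnnotatedImage", function(object) object@classLabel)

#' @rdname accessors
setMethod("classLabel", "PatientPhantom", function(object) object@classLabel)

#' @rdname accessors
setMethod("radiologistScores", "AnnotatedImage",
          function(object) object@radiologistScores)

#' @rdname accessors
setMethod("patients", "PhantomCohort", function(object) object@patients)

#' @rdname accessors
setMethod("slices", "PatientPhantom", function(object) object@slices)

#' @rdname accessors
setMethod("assignment", "SplitPlan", function(object) object@assignment)

#' @rdname accessors
setMethod("splitMode", "SplitPlan", function(object) object@mode)

#' @rdname accessors
setMethod("epochAssignments", "MccvSchedule",
          function(object) object@epochAssignments)

#' @rdname accessors
setMethod("heatmapValues", "HeatMap", function(object) object@values)

#' @rdname accessors
setMethod("isDegenerate", "HeatMap", function(object) object@degenerate)

#' @rdname accessors
setMethod("trainingHistory", "TrainedModel", function(object) object@history)

#' @rdname accessors
setMethod("modelParameters", "TrainedModel", function(object) object@params)

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec:", object@nBenign, "benign +", object@nMalignant,
      "malignant patients,", object@slicesPerPatient, "slices each,",
      paste0(object@imageSize, "x", object@imageSize), "px\n")
  cat("  benign radius [", object@benignRadiusRange[1], ",",
      object@benignRadiusRange[2], "] px; malignant [",
      object@malignantRadiusRange[1], ",", object@malignantRadiusRange[2],
      "] px\n")
  cat("  signatureStrength", object@signatureStrength, " noiseSd",
      object@noiseSd, " seed", object@seed, "\n")
})

setMethod("show", "PhantomCohort", function(object) {
  cls <- vapply(object@patients, classLabel, character(1))
  nsl <- sum(vapply(object@patients, function(p) length(p@slices),
                    integer(1)))
  cat("PhantomCohort:", length(object@patients), "patients (",
      sum(cls == "benign"), "benign /", sum(cls == "malignant"),
      "malignant ),", nsl, "slices\n")
})

setMethod("show", "AnnotatedImage", function(object) {
  cat("AnnotatedImage", object@imageId, "patient", object@patientId,
      paste0("(", object@classLabel, ")"),
      paste0(nrow(object@pixels), "x", ncol(object@pixels)),
      "angle", object@augmentationAngle, "\n")
})

setMethod("show", "SplitPlan", function(object) {
  cat("SplitPlan mode =", object@mode, "seed =", object@seed, "\n")
  print(table(object@assignment))
})

setMethod("show", "MccvSchedule", function(object) {
  cat("MccvSchedule:", length(object@epochAssignments),
      "epochs, valFraction", object@valFraction, "\n")
})

setMethod("show", "TrainedModel", function(object) {
  h <- object@history
  cat("TrainedModel (small CNN,", paste0(object@inputSize, "x",
      object@inputSize), "input), classes:",
      paste(object@classes, collapse = "/"), "\n")
  if (nrow(h))
    cat("  ", nrow(h), "epochs; final train_acc",
        round(h$train_acc[nrow(h)], 3), "val_acc",
        round(h$val_acc[nrow(h)], 3), "lr", h$lr[nrow(h)], "\n")
})

setMethod("show", "HeatMap", function(object) {
  cat("HeatMap", paste0(nrow(object@values), "x", ncol(object@values)),
      "(native", paste0(object@nativeResolution[1], "x",
      object@nativeResolution[2]), ")",
      if (object@degenerate) "DEGENERATE" else "", "\n")
})
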