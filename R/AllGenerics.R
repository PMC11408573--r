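#' @include AllClasses.R
NULL

#' Accessors for phantom-cohort objects
#'
#' Small accessor generics for the S4 containers in this package, following
#' the usual accessor-not-slot convention.
#'
#' @param object an object of the documented class
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setGeneric("mask", function(object) standardGeneric("mask"))

#' @rdname accessors
#' @export
setGeneric("imageId", function(object) standardGeneric("imageId"))

#' @rdname accessors
#' @export
setGeneric("patientId", function(object) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setGeneric("classLabel", function(object) standardGeneric("classLabel"))

#' @rdname accessors
#' @export
setGeneric("radiologistScores",
           function(object) standardGeneric("radiologistScores"))

#' @rdname accessors
#' @export
setGeneric("patients", function(object) standardGeneric("patients"))

#' @rdname accessors
#' @export
setGeneric("slices", function(object) standardGeneric("slices"))

#' @rdname accessors
#' @export
setGeneric("assignment", function(object) standardGeneric("assignment"))

#' @rdname accessors
#' @export
setGeneric("splitMode", function(object) standardGeneric("splitMode"))

#' @rdname accessors
#' @export
setGeneric("epochAssignments",
           function(object) standardGeneric("epochAssignments"))

#' @rdname accessors
#' @export
setGeneric("heatmapValues", function(object) standardGeneric("heatmapValues"))

#' @rdname accessors
#' @export
setGeneric("isDegenerate", function(object) standardGeneric("isDegenerate"))

#' @rdname accessors
#' @export
setGeneric("trainingHistory",
           function(object) standardGeneric("trainingHistory"))

#' @rdname accessors
#' @export
setGeneric("modelParameters",
           function(object) standardGeneric("modelParameters"))

#' Classifier contract surface
#'
#' Any model usable with [computeCam()] implements these three generics:
#' class probabilities, last-convolutional-layer activations, and the
#' gradient of a class score (pre-softmax logit) with respect to those
#' activations.
#'
#' @param model a trained model object
#' @param x a single grayscale image (numeric matrix) or, for
#'   `predictProb`, an `H x W x N` array
#' @param class class index (1-based) or class label whose score is
#'   differentiated
#' @return `predictProb`: an `N x 2` matrix of class probabilities (rows sum
#'   to 1); `lastConvActivations`: an `h x w x C` array; `classScoreGradient`:
#'   an array of the same shape as the activations.
#' @name model-contract
NULL

#' @rdname model-contract
#' @export
setGeneric("predictProb", function(model, x) standardGeneric("predictProb"))

#' @rdname model-contract
#' @export
setGeneric("lastConvActivations",
           function(model, x) standardGeneric("lastConvActivations"))

#' @rdname model-contract
#' @export
setGeneric("classScoreGradient",
           function(model, x, class) standardGeneric("classScoreGradient"))
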