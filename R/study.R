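#' @include experiment.R
NULL

#' Canonical desk-scale leakage study conditions
#'
#' One fixed set of study conditions for the paired fair/unfair experiment,
#' used by the package's own validation: a balanced 40-patient cohort of
#' 64 x 64 slices with 5 slices per patient, well-separated nodule radius
#' ranges, a strong patient signature (amplitude 0.5, ten times the pixel
#' noise), a 5 + 5 patient challenge set and (0.5, 0.2, 0.3) split
#' fractions. Training runs Adam at 3e-3 for 50 epochs with plateau
#' patience 15.
#'
#' `leakageStudy()` runs the full paired experiment under these conditions
#' for one seed; `signatureStrength = 0` gives the ablation arm in which
#' the leakage channel is absent.
#'
#' @param seed integer seed driving the cohort, splits and training
#' @param signatureStrength identity-signature amplitude (0 ablates)
#' @return `leakageStudySpec`: a [PhantomSpec-class];
#'   `leakageStudyConfig`: a [TrainingConfig-class]; `leakageStudy`: an
#'   [ExperimentReport-class].
#' @export
leakageStudySpec <- function(seed = 1L, signatureStrength = 0.5) {
  phantomSpec(nBenign = 20L, nMalignant = 20L, slicesPerPatient = 5L,
              imageSize = 64L, benignRadiusRange = c(3.5, 5),
              malignantRadiusRange = c(6, 7.5),
              signatureStrength = signatureStrength, noiseSd = 0.05,
              seed = 1000L + as.integer(seed))
}

#' @rdname leakageStudySpec
#' @export
leakageStudyConfig <- function(seed = 1L) {
  trainingConfig(learningRate = 3e-3, batchSize = 32L, nEpochs = 50L,
                 plateauFactor = 0.1, plateauPatience = 15L,
                 seed = as.integer(seed))
}

#' @rdname leakageStudySpec
#' @export
leakageStudy <- function(seed = 1L, signatureStrength = 0.5) {
  runFairUnfairExperiment(
    leakageStudySpec(seed, signatureStrength),
    config = leakageStudyConfig(seed),
    fractions = c(0.5, 0.2, 0.3),
    challengeCounts = c(benign = 5L, malignant = 5L),
    seed = as.integer(seed))
}
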