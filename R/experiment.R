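#' @include AllClasses.R phantom.R annotation.R splitting.R classifier.R
#' @include heatmap.R scoring.R
NULL

#' ExperimentReport: results of a paired fair/unfair study
#'
#' @slot accuracyTable one row per model tag with test and challenge
#'   accuracy under both split regimes
#' @slot scores per-image interpretability scores for both arms
#' @slot sampleImages the shared test slices the heat maps were scored on
#' @slot fairModel,unfairModel the two trained classifiers
#' @slot provenance generating spec, config, seeds, fractions and leakage
#'   audits
#' @export
setClass("ExperimentReport",
  representation(accuracyTable = "data.frame", scores = "data.frame",
                 sampleImages = "list", fairModel = "TrainedModel",
                 unfairModel = "TrainedModel", provenance = "list"))

setMethod("show", "ExperimentReport", function(object) {
  cat("ExperimentReport (paired fair/unfair study)\n")
  print(object@accuracyTable, row.names = FALSE)
  cat(" ", nrow(object@scores), "interpretability score rows on",
      length(object@sampleImages), "sampled test images\n")
})

# drop slices whose radiologist-score label is 'excluded'; relabel the rest
# from the scores (ground truth and derived label coincide unless score
# jitter pushed a nodule across the exclusion band)
.labelCohort <- function(cohort) {
  cohort@patients <- lapply(cohort@patients, function(p) {
    keep <- list()
    for (s in p@slices) {
      lab <- labelFromScores(s@radiologistScores)
      if (lab$value == "excluded") next
      s@classLabel <- lab$value
      keep[[length(keep) + 1L]] <- s
    }
    p@slices <- keep
    p
  })
  cohort@patients <- Filter(function(p) length(p@slices) > 0,
                            cohort@patients)
  cohort
}

.imageArray <- function(images) {
  stopifnot(length(images) >= 1L)
  d <- dim(pixels(images[[1]]))
  x <- array(0, c(d, length(images)))
  for (i in seq_along(images)) x[, , i] <- pixels(images[[i]])
  x
}

#' Run the paired fair/unfair leakage experiment on a phantom cohort
#'
#' End-to-end study: generate the cohort, label nodules from radiologist
#' scores, rotation-augment, hold out a challenge set of whole patients,
#' then train two classifiers from identical initialization on the same
#' pool — one under a patient-wise ("fair") split with per-epoch MCCV
#' validation redraws, one under a static image-wise ("unfair") split.
#' Both arms are evaluated on their own test partition and on the shared
#' challenge set, and interpretability scores are computed for both models
#' on one shared sample of fair-test slices. The only factor varying
#' between the arms is the split mode.
#'
#' @param spec a [PhantomSpec-class]
#' @param config a [TrainingConfig-class] (applied to both arms)
#' @param fractions (train, validation, test) fractions over the
#'   non-challenge pool
#' @param challengeCounts named vector: benign/malignant challenge patients
#' @param seed integer seed for splitting and image sampling
#' @param angles augmentation rotation angles
#' @param nScoreImages number of test slices scored for interpretability
#' @param camCfg a [CamConfig-class]
#' @return An [ExperimentReport-class].
#' @export
runFairUnfairExperiment <- function(spec, config = trainingConfig(),
                                    fractions = c(0.7, 0.2, 0.1),
                                    challengeCounts = c(benign = 2L,
                                                        malignant = 2L),
                                    seed = 1L,
                                    angles = c(2, -2, 4, -4),
                                    nScoreImages = 8L,
                                    camCfg = camConfig()) {
  cohort <- generateCohort(spec)
  cohort <- .labelCohort(cohort)
  cohort <- augmentCohort(cohort, angles = angles)
  carve <- carveChallengeSet(cohort, challengeCounts[["benign"]],
                             challengeCounts[["malignant"]], seed = seed)
  manifest <- cohortManifest(cohort)

  fairPlan <- splitPatientwise(manifest, fractions, seed = seed,
                               challengePatients = carve$challenge)
  unfairPlan <- splitImagewise(manifest, fractions, seed = seed,
                               challengePatients = carve$challenge)

  images <- cohortImages(cohort)
  names(images) <- vapply(images, imageId, character(1))
  labels <- setNames(vapply(images, classLabel, character(1)),
                     names(images))
  pats <- setNames(vapply(images, patientId, character(1)), names(images))

  arr <- function(ids) .imageArray(images[ids])
  partIds <- function(plan, parts)
    names(assignment(plan))[assignment(plan) %in% parts]

  # fair arm: patient-wise pool with per-epoch MCCV validation redraws
  fairPoolIds <- partIds(fairPlan, c("train", "validation"))
  fairPoolPat <- unique(pats[fairPoolIds])
  valFrac <- fractions[2] / (fractions[1] + fractions[2])
  schedule <- mccvSchedule(fairPoolPat, valFraction = valFrac,
                           nEpochs = config@nEpochs, seed = seed)
  fairCfg <- config; fairCfg@mccv <- TRUE
  fairModel <- trainClassifier(arr(fairPoolIds), labels[fairPoolIds],
                               config = fairCfg, schedule = schedule,
                               patientIds = pats[fairPoolIds])

  # unfair arm: static image-wise split, identical config and init seed
  unfTrainIds <- partIds(unfairPlan, "train")
  unfValIds <- partIds(unfairPlan, "validation")
  unfairCfg <- config; unfairCfg@mccv <- FALSE
  unfairModel <- trainClassifier(arr(unfTrainIds), labels[unfTrainIds],
                                 config = unfairCfg,
                                 validation = list(x = arr(unfValIds),
                                                   y = labels[unfValIds]))

  challengeIds <- partIds(fairPlan, "challenge")
  fairTestIds <- partIds(fairPlan, "test")
  unfTestIds <- partIds(unfairPlan, "test")
  xCh <- arr(challengeIds)

  acc <- data.frame(
    model_tag = "small_cnn", n_epochs = config@nEpochs,
    fair_test = evaluateAccuracy(fairModel, arr(fairTestIds),
                                 labels[fairTestIds]),
    fair_challenge = evaluateAccuracy(fairModel, xCh,
                                      labels[challengeIds]),
    unfair_test = evaluateAccuracy(unfairModel, arr(unfTestIds),
                                   labels[unfTestIds]),
    unfair_challenge = evaluateAccuracy(unfairModel, xCh,
                                        labels[challengeIds]),
    stringsAsFactors = FALSE)

  sampleIds <- withSeed(seed + 1L, {
    sample(fairTestIds, min(nScoreImages, length(fairTestIds)))
  })
  sampleImages <- images[sampleIds]
  scores <- rbind(
    scoreTable(sampleImages, fairModel, camCfg, modelTag = "fair"),
    scoreTable(sampleImages, unfairModel, camCfg, modelTag = "unfair"))

  prov <- list(
    spec = list(nBenign = spec@nBenign, nMalignant = spec@nMalignant,
                slicesPerPatient = spec@slicesPerPatient,
                imageSize = spec@imageSize,
                benignRadiusRange = spec@benignRadiusRange,
                malignantRadiusRange = spec@malignantRadiusRange,
                signatureStrength = spec@signatureStrength,
                noiseSd = spec@noiseSd, seed = spec@seed),
    config = list(learningRate = config@learningRate,
                  batchSize = config@batchSize, nEpochs = config@nEpochs,
                  plateauFactor = config@plateauFactor,
                  plateauPatience = config@plateauPatience,
                  seed = config@seed),
    fractions = fractions, challengeCounts = as.list(challengeCounts),
    seed = seed, angles = angles, sampleImageIds = sampleIds,
    audits = list(
      fair = auditLeakage(fairPlan, manifest)$leakingPatients,
      unfair = auditLeakage(unfairPlan, manifest)$leakingPatients))

  new("ExperimentReport", accuracyTable = acc, scores = scores,
      sampleImages = sampleImages, fairModel = fairModel,
      unfairModel = unfairModel, provenance = prov)
}

.grayToRGB <- function(m) {
  out <- array(0, c(dim(m), 3L))
  for (ch in 1:3) out[, , ch] <- m
  out
}

#' Render an experiment report to files
#'
#' Writes `accuracy_table.csv`, `scores.csv`, `provenance.json` and an
#' overlay panel `panel.png` with one row per sampled test image and four
#' columns: nodule mask, original slice, fair-model CAM overlay,
#' unfair-model CAM overlay.
#'
#' @param report an [ExperimentReport-class]
#' @param dir output directory (created if absent)
#' @return Character vector of the files written, invisibly.
#' @export
renderReport <- function(report, dir) {
  stopifnot(is(report, "ExperimentReport"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  w(report@accuracyTable, "accuracy_table.csv")
  w(report@scores, "scores.csv")
  pj <- file.path(dir, "provenance.json")
  jsonlite::write_json(report@provenance, pj, auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, pj)

  if (!nrow(report@scores) || !length(report@sampleImages)) {
    warning("score table empty; overlay panel omitted")
    return(invisible(files))
  }
  cfg <- camConfig(channelCombination = "weighted_average")
  rows <- lapply(report@sampleImages, function(img) {
    px <- pixels(img)
    fcam <- computeCam(report@fairModel, px, "malignant", cfg)
    ucam <- computeCam(report@unfairModel, px, "malignant", cfg)
    cells <- list(.grayToRGB(mask(img)), .grayToRGB(px),
                  overlayHeatmap(px, fcam), overlayHeatmap(px, ucam))
    do.call(abind3, cells)
  })
  panel <- do.call(function(...) abind3(..., along = 1L), rows)
  pp <- file.path(dir, "panel.png")
  EBImage::writeImage(EBImage::Image(panel, colormode = "Color"), pp,
                      type = "png")
  invisible(c(files, pp))
}

# minimal abind for H x W x 3 arrays, along rows (1) or columns (2)
abind3 <- function(..., along = 2L) {
  xs <- list(...)
  if (along == 2L) {
    out <- array(0, c(dim(xs[[1]])[1],
                      sum(vapply(xs, function(x) dim(x)[2], numeric(1))),
                      3L))
    at <- 0L
    for (x in xs) {
      out[, at + seq_len(dim(x)[2]), ] <- x
      at <- at + dim(x)[2]
    }
  } else {
    out <- array(0, c(sum(vapply(xs, function(x) dim(x)[1], numeric(1))),
                      dim(xs[[1]])[2], 3L))
    at <- 0L
    for (x in xs) {
      out[at + seq_len(dim(x)[1]), , ] <- x
      at <- at + dim(x)[1]
    }
  }
  out
}
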