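# Shared fixtures: small cohort specs, synthetic manifests, and toy models
# implementing the CAM contract generics.

tinySpec <- function(nBenign = 2L, nMalignant = 2L, slicesPerPatient = 3L,
                     imageSize = 64L, signatureStrength = 0.25,
                     noiseSd = 0.05, seed = 7L) {
  phantomSpec(nBenign = nBenign, nMalignant = nMalignant,
              slicesPerPatient = slicesPerPatient, imageSize = imageSize,
              benignRadiusRange = c(4, 5.5),
              malignantRadiusRange = c(5.5, 7),
              signatureStrength = signatureStrength, noiseSd = noiseSd,
              seed = seed)
}

# bare manifest for split tests: no pixel data needed
makeManifest <- function(nPatients, slicesPer, classes = NULL) {
  if (is.null(classes))
    classes <- rep(c("benign", "malignant"), length.out = nPatients)
  do.call(rbind, lapply(seq_len(nPatients), function(i)
    data.frame(
      image_id = sprintf("p%03d_s%02d", i, seq_len(slicesPer)),
      patient_id = sprintf("p%03d", i),
      class = classes[i], stringsAsFactors = FALSE)))
}

# quickly build an AnnotatedImage from raw matrices
makeImage <- function(pixels, mask, id = "img1", patient = "p001",
                      class = "malignant", scores = c(5L, 5L, 5L)) {
  new("AnnotatedImage", imageId = id, patientId = patient,
      noduleId = paste0(patient, "_n01"), pixels = pixels,
      mask = mask, classLabel = class, radiologistScores = scores,
      augmentationAngle = 0, sourceImageId = id)
}

# valid HeatMap from arbitrary values (min-max normalized unless constant)
makeHeatMap <- function(values) {
  rg <- range(values)
  if (diff(rg) < 1e-12)
    new("HeatMap", values = values * 0, degenerate = TRUE,
        nativeResolution = dim(values), normalizationBounds = rg)
  else
    new("HeatMap", values = (values - rg[1]) / diff(rg),
        degenerate = FALSE, nativeResolution = dim(values),
        normalizationBounds = rg)
}

# Toy CAM-contract model: the last-conv "activations" are the image itself
# (single channel, optionally scaled), and the class score is the spatial
# mean of that channel, so the gradient is uniform 1/(h*w).
setClass("ToyMeanModel", representation(scale = "numeric"))

setMethod("lastConvActivations", "ToyMeanModel", function(model, x) {
  array(model@scale * x, c(dim(x), 1L))
})
setMethod("classScoreGradient", "ToyMeanModel", function(model, x, class) {
  array(model@scale / (nrow(x) * ncol(x)), c(dim(x), 1L))
})

# Toy coarse-grid contract model: fixed activations on a grid much smaller
# than the image, uniform gradients; used for upsampling-location checks.
setClass("ToyCoarseModel", representation(A = "array"))

setMethod("lastConvActivations", "ToyCoarseModel", function(model, x) model@A)
setMethod("classScoreGradient", "ToyCoarseModel", function(model, x, class) {
  array(1, dim(model@A))
})

# a deterministic small real CNN with near-zero training (random weights)
randomCnn <- function(imageSize = 64L, seed = 3L) {
  x <- array(stats::runif(imageSize * imageSize * 4), c(imageSize, imageSize, 4))
  y <- c("benign", "malignant", "benign", "malignant")
  trainClassifier(x, y, trainingConfig(learningRate = 1e-12, nEpochs = 1,
                                       batchSize = 4L, seed = seed))
}
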