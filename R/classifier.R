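#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a training configuration
#'
#' Defaults mirror the reference training recipe: Adam at learning rate
#' 1e-4, batches of 32, and a plateau rule that multiplies the learning
#' rate by 0.1 when the validation accuracy has not improved (by more than
#' 1e-4 over the best value seen) for `plateauPatience` epochs.
#'
#' @param learningRate initial learning rate
#' @param batchSize minibatch size
#' @param nEpochs training epochs
#' @param plateauFactor learning-rate multiplier on a validation plateau
#' @param plateauPatience epochs of no improvement before the multiplier
#'   fires
#' @param weightDecay decoupled (AdamW-style) weight decay per step,
#'   applied to the convolutional and dense weights but not the biases
#' @param seed integer seed (weight init and shuffling)
#' @param mccv redraw the patient-level validation set every epoch
#' @return A validated [TrainingConfig-class].
#' @export
trainingConfig <- function(learningRate = 1e-4, batchSize = 32L,
                           nEpochs = 50L, plateauFactor = 0.1,
                           plateauPatience = 5L, weightDecay = 0,
                           seed = 1L, mccv = FALSE) {
  new("TrainingConfig", learningRate = as.numeric(learningRate),
      batchSize = as.integer(batchSize), nEpochs = as.integer(nEpochs),
      plateauFactor = as.numeric(plateauFactor),
      plateauPatience = as.integer(plateauPatience),
      weightDecay = as.numeric(weightDecay),
      seed = as.integer(seed), mccv = as.logical(mccv))
}

# channel widths of the reference network
.ARCH <- c(C1 = 8L, C2 = 16L, C3 = 16L)

# spatial side of the last conv grid for a square input of side S:
# conv(3) -> pool(2) -> conv(3) -> pool(2) -> conv(3), all valid
.convGridSize <- function(S) {
  s <- S - 2L; s <- s %/% 2L; s <- s - 2L; s <- s %/% 2L; s - 2L
}

.initParams <- function() {
  he <- function(nout, nin) {
    matrix(stats::rnorm(nout * nin, 0, sqrt(2 / nin)), nout, nin)
  }
  list(W1 = he(.ARCH["C1"], 9L), b1 = rep(0, .ARCH["C1"]),
       W2 = he(.ARCH["C2"], 9L * .ARCH["C1"]), b2 = rep(0, .ARCH["C2"]),
       W3 = he(.ARCH["C3"], 9L * .ARCH["C2"]), b3 = rep(0, .ARCH["C3"]),
       Wfc = he(2L, .ARCH["C3"]), bfc = rep(0, 2))
}

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr, wd = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (k in names(params)) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    step <- lr * (state$m[[k]] / b1t) / (sqrt(state$v[[k]] / b2t) + eps)
    if (wd > 0 && startsWith(k, "W"))
      step <- step + lr * wd * params[[k]]
    params[[k]] <- params[[k]] - step
  }
  list(params = params, state = state)
}

# per-image mean centering: the network sees zero-mean slices, so global
# brightness (which scales with nodule area) is not available as a
# shortcut and class evidence must be spatially localized
.centerImages <- function(x) {
  if (is.matrix(x)) return(x - mean(x))
  mu <- apply(x, 3, mean)
  sweep(x, 3, mu)
}

.toClassIndex <- function(y, classes) {
  idx <- match(as.character(y), classes)
  if (anyNA(idx))
    specError("y", paste("labels must be one of:",
                         paste(classes, collapse = ", ")))
  idx - 1L
}

#' Train the reference small convolutional classifier
#'
#' A 3-block CNN (3x3 convs with ReLU, two 2x2 max-pools, global average
#' pooling, two-way softmax head) trained with Adam on weighted
#' cross-entropy; class weights are inverse-frequency so imbalanced pools
#' do not collapse to the majority class. Validation comes either from a
#' static held-out set, or — when `schedule` is given — from a per-epoch
#' Monte Carlo redraw of validation patients; in that mode `patientIds`
#' maps each training image to its patient. The learning rate is multiplied
#' by `plateauFactor` whenever validation accuracy has not improved for
#' `plateauPatience` consecutive epochs. Training is deterministic given
#' the config seed.
#'
#' The only preprocessing is per-image mean centering (applied identically
#' at prediction time): global slice brightness, which scales with nodule
#' area, is removed so class evidence has to be spatially localized.
#'
#' When a validation signal exists (static or MCCV) the returned model is
#' the best-validation-accuracy snapshot seen during training; the full
#' history still covers all epochs. Note what this means under the two
#' split regimes: with patient-wise MCCV the snapshot is selected on
#' held-out patients and so favours generalization, whereas a validation
#' set that shares patients with training selects for the memorizing
#' model — the selection signal is only as honest as the split behind it.
#'
#' @param x `H x W x N` array of grayscale images in `[0, 1]`
#' @param y character vector of length N, `"benign"`/`"malignant"`
#' @param config a [TrainingConfig-class]
#' @param validation optional list with elements `x` and `y`: a static
#'   validation set
#' @param schedule optional [MccvSchedule-class]; its epochs must cover
#'   `config@nEpochs`
#' @param patientIds patient id per image; required with `schedule`
#' @return A [TrainedModel-class] with the full per-epoch history
#'   (train_acc, val_acc, lr).
#' @export
trainClassifier <- function(x, y, config = trainingConfig(),
                            validation = NULL, schedule = NULL,
                            patientIds = NULL) {
  stopifnot(is(config, "TrainingConfig"))
  validObject(config)
  classes <- c("benign", "malignant")
  y <- as.character(y)
  N <- dim(x)[3]
  stopifnot(length(y) == N)
  if (length(unique(y)) < 2L && is.null(schedule))
    specError("y", "training set must contain both classes")
  useMccv <- !is.null(schedule)
  if (useMccv) {
    stopifnot(is(schedule, "MccvSchedule"))
    if (is.null(patientIds) || length(patientIds) != N)
      specError("patientIds", "required (one per image) when a schedule is given")
    if (length(epochAssignments(schedule)) < config@nEpochs)
      specError("schedule", "fewer epochs than config@nEpochs")
  }

  # inverse-frequency class weights over the full pool
  tab <- table(factor(y, levels = classes))
  wClass <- as.numeric(sum(tab) / (2 * pmax(tab, 1L)))
  yIdx <- .toClassIndex(y, classes)
  x <- .centerImages(x)
  if (!is.null(validation)) validation$x <- .centerImages(validation$x)

  withSeed(config@seed, {
    params <- .initParams()
    opt <- .adamInit(params)
    lr <- config@learningRate
    bestVal <- -Inf
    bestParams <- NULL
    stall <- 0L
    hist <- vector("list", config@nEpochs)

    for (ep in seq_len(config@nEpochs)) {
      if (useMccv) {
        ass <- epochAssignments(schedule)[[ep]]
        known <- patientIds %in% names(ass)
        if (!all(known))
          specError("schedule", "schedule does not cover every patient in x")
        trIdx <- which(ass[patientIds] == "train")
        vaIdx <- which(ass[patientIds] == "validation")
        if (!length(trIdx) || !length(vaIdx))
          specError("schedule", "empty train or validation set in an epoch")
        if (length(unique(yIdx[trIdx])) < 2L)
          specError("schedule", "single-class training set in an epoch")
      } else {
        trIdx <- seq_len(N)
        vaIdx <- integer()
      }
      ord <- sample(trIdx)
      nCorrect <- 0L
      nSeen <- 0L
      nBatch <- ceiling(length(ord) / config@batchSize)
      for (bi in seq_len(nBatch)) {
        b <- ord[(((bi - 1L) * config@batchSize) + 1L):
                   min(bi * config@batchSize, length(ord))]
        res <- .cpp_cnn_batch_grad(x[, , b, drop = FALSE], yIdx[b],
                                   wClass[yIdx[b] + 1L], params)
        upd <- .adamStep(params, res$grads, opt, lr, config@weightDecay)
        params <- upd$params
        opt <- upd$state
        nCorrect <- nCorrect + res$correct
        nSeen <- nSeen + length(b)
      }
      trainAcc <- nCorrect / nSeen

      valAcc <- NA_real_
      if (useMccv) {
        p <- .cpp_cnn_forward(x[, , vaIdx, drop = FALSE], params)
        valAcc <- mean((p[, 2] > p[, 1]) == (yIdx[vaIdx] == 1L))
      } else if (!is.null(validation)) {
        vi <- .toClassIndex(validation$y, classes)
        p <- .cpp_cnn_forward(validation$x, params)
        valAcc <- mean((p[, 2] > p[, 1]) == (vi == 1L))
      }
      hist[[ep]] <- data.frame(epoch = ep, train_acc = trainAcc,
                               val_acc = valAcc, lr = lr)

      if (!is.na(valAcc)) {
        # first-best checkpoint: the earliest epoch reaching the best
        # validation accuracy is kept, so once validation saturates the
        # snapshot stays at the epoch that first achieved it
        if (valAcc > bestVal + 1e-4) {
          bestVal <- valAcc
          bestParams <- params
          stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= config@plateauPatience) {
            lr <- lr * config@plateauFactor
            stall <- 0L
          }
        }
      }
    }
    # best-validation checkpointing: when a validation signal exists, the
    # returned model is the snapshot with the best validation accuracy
    # seen during training (without one, the final weights)
    if (!is.null(bestParams)) params <- bestParams
    new("TrainedModel", params = params, classes = classes,
        inputSize = as.integer(dim(x)[1]), history = do.call(rbind, hist),
        config = config)
  })
}

#' Classification accuracy of a model on labelled images
#'
#' Argmax-probability prediction compared against the labels; returns the
#' exact fraction correct.
#'
#' @param model a [TrainedModel-class]
#' @param x `H x W x N` image array
#' @param y character labels of length N
#' @return Fraction correct in `[0, 1]`.
#' @export
evaluateAccuracy <- function(model, x, y) {
  stopifnot(dim(x)[3] >= 1L)
  p <- predictProb(model, x)
  pred <- model@classes[max.col(p, ties.method = "first")]
  mean(pred == as.character(y))
}

#' @rdname model-contract
setMethod("predictProb", "TrainedModel", function(model, x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  .cpp_cnn_forward(.centerImages(x), model@params)
})

#' @rdname model-contract
setMethod("lastConvActivations", "TrainedModel", function(model, x) {
  stopifnot(is.matrix(x))
  .cpp_cnn_activations(.centerImages(x), model@params)
})

#' @rdname model-contract
setMethod("classScoreGradient", "TrainedModel", function(model, x, class) {
  stopifnot(is.matrix(x))
  ci <- if (is.character(class)) match(class, model@classes)
  else as.integer(class)
  if (is.na(ci) || ci < 1L || ci > 2L)
    specError("class", "must be a valid class label or index")
  s <- .convGridSize(nrow(x))
  C3 <- .ARCH[["C3"]]
  g <- array(0, c(s, s, C3))
  # logit_c = sum_k Wfc[c, k] * mean(A_k) + b_c, so the gradient is
  # constant per channel: Wfc[c, k] / (h * w)
  for (k in seq_len(C3)) g[, , k] <- model@params$Wfc[ci, k] / (s * s)
  g
})

#' Read a training configuration from a YAML or JSON file
#'
#' Keys mirror the [trainingConfig()] arguments (learningRate, batchSize,
#' nEpochs, plateauFactor, plateauPatience, weightDecay, seed, mccv);
#' missing keys fall back to the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return A validated [TrainingConfig-class].
#' @export
readTrainingConfig <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(trainingConfig))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    specError("config", paste("unknown keys:", paste(bad, collapse = ", ")))
  do.call(trainingConfig, vals)
}

#' Export a model's training history as CSV
#'
#' @param model a [TrainedModel-class]
#' @param path output CSV path (columns epoch, train_acc, val_acc, lr)
#' @return `path`, invisibly.
#' @export
exportTrainingHistory <- function(model, path) {
  utils::write.csv(trainingHistory(model), path, row.names = FALSE)
  invisible(path)
}

#' Save / load a trained model checkpoint
#'
#' The checkpoint is a plain-text JSON file holding the weights, class
#' order, input size and history.
#'
#' @param model a [TrainedModel-class]
#' @param path checkpoint path
#' @return `saveModel`: `path`, invisibly; `loadModel`: the restored
#'   [TrainedModel-class].
#' @export
saveModel <- function(model, path) {
  cfg <- model@config
  obj <- list(
    params = lapply(model@params, function(p)
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))),
    classes = model@classes, inputSize = model@inputSize,
    history = model@history,
    config = list(learningRate = cfg@learningRate,
                  batchSize = cfg@batchSize, nEpochs = cfg@nEpochs,
                  plateauFactor = cfg@plateauFactor,
                  plateauPatience = cfg@plateauPatience,
                  weightDecay = cfg@weightDecay, seed = cfg@seed,
                  mccv = cfg@mccv))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(obj$params, function(p) {
    if (!is.null(p$dim) && length(p$dim)) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  new("TrainedModel", params = params, classes = obj$classes,
      inputSize = as.integer(obj$inputSize),
      history = as.data.frame(obj$history),
      config = do.call(trainingConfig, as.list(obj$config)))
}
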