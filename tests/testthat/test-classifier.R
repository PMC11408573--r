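# Reference CNN: determinism, memorization sanity check, plateau rule, and
# the contract surface (probabilities, activations, gradients).

# trivially separable toy set: vertical gratings (benign) vs horizontal
# gratings (malignant); orientation survives the per-image mean centering
toySet <- function(n = 10L, size = 64L, seed = 1L) {
  withr::with_seed(seed, {
    x <- array(0, c(size, size, n))
    y <- rep(c("benign", "malignant"), length.out = n)
    rows <- matrix(seq_len(size), size, size)
    for (i in seq_len(n)) {
      g <- if (y[i] == "benign") 0.3 * sin(2 * pi * 0.2 * rows)
      else 0.3 * sin(2 * pi * 0.2 * t(rows))
      x[, , i] <- pmin(pmax(0.5 + g + matrix(rnorm(size^2, 0, 0.05),
                                             size, size), 0), 1)
    }
    list(x = x, y = y)
  })
}

test_that("the network memorizes a tiny separable set", {
  ts <- toySet()
  m <- trainClassifier(ts$x, ts$y,
                       trainingConfig(learningRate = 1e-2, nEpochs = 40L,
                                      batchSize = 10L, seed = 2L))
  expect_equal(evaluateAccuracy(m, ts$x, ts$y), 1.0)
  h <- trainingHistory(m)
  expect_equal(nrow(h), 40L)
  # loss proxy: training accuracy improves from the early epochs
  expect_gt(mean(h$train_acc[31:40]), mean(h$train_acc[1:5]))
})

test_that("training is deterministic given the config seed", {
  ts <- toySet(n = 6L)
  cfg <- trainingConfig(learningRate = 1e-3, nEpochs = 3L, seed = 11L)
  m1 <- trainClassifier(ts$x, ts$y, cfg)
  m2 <- trainClassifier(ts$x, ts$y, cfg)
  expect_identical(trainingHistory(m1), trainingHistory(m2))
  expect_identical(modelParameters(m1), modelParameters(m2))
})

test_that("a flat validation accuracy triggers the one-tenth plateau rule", {
  ts <- toySet(n = 8L)
  # two identical validation images with opposite labels: accuracy is 0.5
  # whatever the model does, so no improvement is ever possible
  vx <- array(rep(ts$x[, , 1], 2), c(dim(ts$x)[1:2], 2L))
  vy <- c("benign", "malignant")
  cfg <- trainingConfig(learningRate = 1e-3, nEpochs = 8L,
                        plateauPatience = 3L, seed = 4L)
  m <- trainClassifier(ts$x, ts$y, cfg, validation = list(x = vx, y = vy))
  h <- trainingHistory(m)
  expect_true(all(h$val_acc == 0.5))
  ratios <- h$lr[-1] / h$lr[-nrow(h)]
  expect_true(any(abs(ratios - 0.1) < 1e-12))
  # first reduction fires after exactly plateauPatience stalled epochs
  expect_equal(h$lr[5], 0.1 * h$lr[1])
})

test_that("probabilities are a proper distribution and gradients match activations",
{
  m <- randomCnn(imageSize = 48L)
  x <- array(runif(48 * 48 * 3), c(48, 48, 3))
  p <- predictProb(m, x)
  expect_equal(dim(p), c(3L, 2L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  A <- lastConvActivations(m, x[, , 1])
  G <- classScoreGradient(m, x[, , 1], "malignant")
  expect_identical(dim(A), dim(G))
  expect_error(classScoreGradient(m, x[, , 1], "weird"), "class")
})

test_that("accuracy is the exact fraction of argmax-correct predictions", {
  m <- randomCnn(imageSize = 48L)
  # zero weights force logits (0, 0): constant benign under first-argmax
  m@params <- lapply(m@params, function(p) p * 0)
  x <- array(runif(48 * 48 * 10), c(48, 48, 10))
  expect_equal(evaluateAccuracy(m, x, rep(c("benign", "malignant"), 5)),
               0.5)
  expect_equal(evaluateAccuracy(m, x, c(rep("benign", 7),
                                        rep("malignant", 3))), 0.7)
  expect_equal(evaluateAccuracy(m, x, rep("benign", 10)), 1.0)
})

test_that("single-class training sets are rejected", {
  ts <- toySet(n = 4L)
  expect_error(trainClassifier(ts$x, rep("benign", 4),
                               trainingConfig(nEpochs = 1L)), "classes")
})

test_that("model checkpoints and history export round-trip", {
  ts <- toySet(n = 4L)
  m <- trainClassifier(ts$x, ts$y,
                       trainingConfig(learningRate = 1e-3, nEpochs = 2L,
                                      seed = 1L))
  dir <- withr::local_tempdir()
  ck <- file.path(dir, "model.json")
  saveModel(m, ck)
  m2 <- loadModel(ck)
  expect_equal(modelParameters(m2), modelParameters(m), tolerance = 1e-12)
  x1 <- ts$x[, , 1]
  expect_equal(predictProb(m2, x1), predictProb(m, x1), tolerance = 1e-9)
  hp <- file.path(dir, "history.csv")
  exportTrainingHistory(m, hp)
  expect_equal(read.csv(hp)$train_acc, trainingHistory(m)$train_acc)
})

test_that("training configs round-trip through YAML and JSON files", {
  dir <- withr::local_tempdir()
  yp <- file.path(dir, "cfg.yaml")
  writeLines(c("learningRate: 0.003", "nEpochs: 7", "plateauPatience: 9",
               "mccv: yes"), yp)
  cfg <- readTrainingConfig(yp)
  expect_equal(cfg@learningRate, 0.003)
  expect_equal(cfg@nEpochs, 7L)
  expect_equal(cfg@plateauPatience, 9L)
  expect_true(cfg@mccv)
  expect_equal(cfg@batchSize, 32L) # default preserved
  jp <- file.path(dir, "cfg.json")
  jsonlite::write_json(list(learningRate = 1e-3, seed = 4), jp,
                       auto_unbox = TRUE)
  cfg2 <- readTrainingConfig(jp)
  expect_equal(cfg2@learningRate, 1e-3)
  expect_equal(cfg2@seed, 4L)
  writeLines("unknownKey: 1", yp)
  expect_error(readTrainingConfig(yp), "unknown keys")
})
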