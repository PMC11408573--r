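# Interpretability scores: locality, shape correlation against the
# definitional formulas, and the score-table assembly.

# definitional oracles, written independently of the implementation
oraclePearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
oracleMidrank <- function(v) {
  vapply(seq_along(v), function(i)
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2, numeric(1))
}
oracleSpearman <- function(x, y) {
  oraclePearson(oracleMidrank(x), oracleMidrank(y))
}

test_that("locality scores are the max and mean inside the mask", {
  v <- matrix(0, 4, 4)
  v[1, 1:4] <- c(0.2, 0.4, 0.6, 0.8)
  v[4, 4] <- 1 # pin max for a valid HeatMap
  hm <- new("HeatMap", values = v, degenerate = FALSE,
            nativeResolution = c(4L, 4L), normalizationBounds = c(0, 1))
  msk <- matrix(0L, 4, 4); msk[1, 1:4] <- 1L
  expect_equal(noduleLocality(hm, msk),
               c(nodule_max = 0.8, nodule_mean = 0.5))
  # heat map equal to the mask: perfect focus
  hm2 <- makeHeatMap(matrix(as.numeric(msk), 4, 4))
  expect_equal(noduleLocality(hm2, msk),
               c(nodule_max = 1, nodule_mean = 1))
  expect_error(noduleLocality(hm, matrix(0L, 4, 4)), "mask")
  expect_error(noduleLocality(hm, matrix(0L, 2, 2)), "mask")
})

test_that("locality ignores heat outside the mask", {
  withr::with_seed(1, {
    msk <- matrix(0L, 8, 8); msk[3:5, 3:5] <- 1L
    inside <- runif(9)
    v1 <- matrix(runif(64), 8, 8); v1[msk == 1L] <- inside
    v2 <- matrix(runif(64), 8, 8); v2[msk == 1L] <- inside
    v1[1, 1] <- 0; v1[8, 8] <- 1; v2[1, 1] <- 0; v2[8, 8] <- 1
    h1 <- new("HeatMap", values = v1, degenerate = FALSE,
              nativeResolution = c(8L, 8L), normalizationBounds = c(0, 1))
    h2 <- new("HeatMap", values = v2, degenerate = FALSE,
              nativeResolution = c(8L, 8L), normalizationBounds = c(0, 1))
    expect_equal(noduleLocality(h1, msk), noduleLocality(h2, msk))
  })
})

test_that("self- and anti-correlated maps hit the correlation extremes", {
  msk <- matrix(0L, 6, 6); msk[2:4, 2:4] <- 1L
  hmSelf <- makeHeatMap(matrix(as.numeric(msk), 6, 6))
  ccSelf <- shapeCorrelation(hmSelf, msk)
  expect_equal(ccSelf$pearson, 1)
  expect_equal(ccSelf$spearman, 1)
  hmAnti <- makeHeatMap(matrix(1 - as.numeric(msk), 6, 6))
  ccAnti <- shapeCorrelation(hmAnti, msk)
  expect_equal(ccAnti$pearson, -1)
  expect_equal(ccAnti$spearman, -1)
})

test_that("a constant heat map scores (0, 0) with the degenerate flag", {
  msk <- matrix(0L, 5, 5); msk[2, 2] <- 1L
  dg <- makeHeatMap(matrix(0.4, 5, 5))
  cc <- shapeCorrelation(dg, msk)
  expect_identical(cc, list(pearson = 0, spearman = 0, degenerate = TRUE))
  expect_equal(noduleLocality(dg, msk),
               c(nodule_max = 0, nodule_mean = 0))
})

test_that("all-constant masks are rejected for correlation", {
  hm <- makeHeatMap(matrix(runif(25), 5, 5))
  expect_error(shapeCorrelation(hm, matrix(1L, 5, 5)), "mask")
  expect_error(shapeCorrelation(hm, matrix(0L, 5, 5)), "mask")
})

test_that("correlations match the definitional formulas on random pairs", {
  withr::with_seed(42, {
    for (i in 1:100) {
      n <- sample(6:12, 1)
      v <- matrix(runif(n * n), n, n)
      # random heat maps with ties to exercise the midrank convention
      v <- round(v, sample(1:3, 1))
      msk <- matrix(rbinom(n * n, 1L, 0.3), n, n)
      if (all(msk == 0L)) msk[1, 1] <- 1L
      if (all(msk == 1L)) msk[1, 1] <- 0L
      hm <- makeHeatMap(v)
      if (isDegenerate(hm)) next
      cc <- shapeCorrelation(hm, msk)
      x <- as.numeric(heatmapValues(hm)); y <- as.numeric(msk)
      expect_lt(abs(cc$pearson - oraclePearson(x, y)), 1e-10)
      expect_lt(abs(cc$spearman - oracleSpearman(x, y)), 1e-10)
    }
  })
})

test_that("Spearman is invariant under strictly monotone transforms", {
  withr::with_seed(5, {
    v <- matrix(runif(100), 10, 10)
    msk <- matrix(rbinom(100, 1L, 0.25), 10, 10)
    msk[1, 1] <- 1L; msk[10, 10] <- 0L
    base <- shapeCorrelation(makeHeatMap(v), msk)$spearman
    for (f in list(function(x) x^3, exp, function(x) 5 * x + 2)) {
      tr <- shapeCorrelation(makeHeatMap(f(v)), msk)$spearman
      expect_equal(tr, base, tolerance = 1e-12)
    }
    # Pearson is invariant under positive affine maps
    baseP <- shapeCorrelation(makeHeatMap(v), msk)$pearson
    affP <- shapeCorrelation(makeHeatMap(3 * v + 1), msk)$pearson
    expect_equal(affP, baseP, tolerance = 1e-12)
  })
})

test_that("score tables carry one row per image per variant", {
  co <- generateCohort(tinySpec(seed = 21L))
  imgs <- cohortImages(co)[1:8]
  m <- randomCnn(imageSize = 64L, seed = 2L)
  st <- scoreTable(imgs, m, camConfig("both"), modelTag = "toy")
  expect_equal(nrow(st), 16L)
  expect_setequal(unique(st$cam_variant),
                  c("weighted_average", "weighted_maximum"))
  expect_true(all(st$nodule_mean <= st$nodule_max + 1e-12))
  expect_true(all(st$model_tag == "toy"))
  expect_true(all(st$pearson >= -1 & st$pearson <= 1))
  expect_true(all(st$spearman >= -1 & st$spearman <= 1))
  # degenerate rows carry all-zero scores
  dg <- st[st$degenerate, ]
  if (nrow(dg))
    expect_true(all(dg$nodule_max == 0 & dg$pearson == 0))
})
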