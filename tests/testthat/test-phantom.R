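# Phantom cohort generation: counts, determinism, signature behaviour,
# score assignment, and the on-disk round trip.

test_that("cohort has the requested shape and one nodule per slice", {
  spec <- phantomSpec(nBenign = 8L, nMalignant = 8L, slicesPerPatient = 10L,
                      imageSize = 64L, benignRadiusRange = c(4, 5.5),
                      malignantRadiusRange = c(5.5, 7), seed = 7L)
  co <- generateCohort(spec)
  expect_length(patients(co), 16L)
  imgs <- cohortImages(co)
  expect_length(imgs, 160L)
  expect_equal(sum(vapply(imgs, function(i) sum(mask(i)) > 0, logical(1))),
               160L)
  cls <- vapply(patients(co), classLabel, character(1))
  expect_equal(unname(table(cls)[c("benign", "malignant")]),
               c(8L, 8L), ignore_attr = TRUE)
  # every slice inherits its patient's class
  for (p in patients(co))
    expect_true(all(vapply(slices(p), classLabel, character(1)) ==
                      classLabel(p)))
})

test_that("identical spec yields a byte-identical cohort", {
  spec <- tinySpec(seed = 42L)
  expect_identical(generateCohort(spec), generateCohort(spec))
  expect_identical(cohortManifest(generateCohort(spec)),
                   cohortManifest(generateCohort(spec)))
})

test_that("pixels, masks and geometry satisfy the slice invariants", {
  co <- generateCohort(tinySpec(seed = 3L))
  for (p in patients(co)) {
    for (s in slices(p)) {
      expect_true(all(pixels(s) >= 0 & pixels(s) <= 1))
      expect_true(all(mask(s) %in% c(0L, 1L)))
      expect_identical(dim(pixels(s)), dim(mask(s)))
      # nodule lies inside one of the patient's lung-field ellipses
      idx <- which(mask(s) == 1L, arr.ind = TRUE) - 1L
      inside <- vapply(p@anatomyParams, function(e) {
        all(((idx[, 1] - e$cr) / e$ar)^2 +
              ((idx[, 2] - e$cc) / e$ac)^2 <= 1.05)
      }, logical(1))
      expect_true(any(inside))
    }
  }
})

test_that("slices of one patient share signature parameters across patients",
{
  co <- generateCohort(tinySpec(nBenign = 3L, nMalignant = 3L, seed = 9L))
  sigs <- lapply(patients(co), function(p) p@signatureParams)
  fx <- vapply(sigs, function(s) s$fx, numeric(1))
  expect_equal(anyDuplicated(fx), 0L) # continuous draws: all distinct
})

test_that("with zero signature, background statistics do not separate patients",
{
  # lung-interior background pixels (outside the nodule) of two patients are
  # drawn from the same noise distribution when signatureStrength = 0; a
  # two-sample t-test at alpha = 0.01 should fail to reject for >= 95% of
  # patient pairs
  spec <- phantomSpec(nBenign = 8L, nMalignant = 7L, slicesPerPatient = 1L,
                      imageSize = 64L, benignRadiusRange = c(4, 5.5),
                      malignantRadiusRange = c(5.5, 7),
                      signatureStrength = 0, noiseSd = 0.05, seed = 11L)
  co <- generateCohort(spec)
  lungBg <- function(p) {
    s <- slices(p)[[1]]
    g <- fairCAM:::.coordGrids(nrow(pixels(s)))
    keep <- matrix(FALSE, nrow(pixels(s)), ncol(pixels(s)))
    for (e in p@anatomyParams)
      keep <- keep | (((g$row - e$cr) / (0.9 * e$ar))^2 +
                        ((g$col - e$cc) / (0.9 * e$ac))^2 <= 1)
    pixels(s)[keep & mask(s) == 0L]
  }
  bg <- lapply(patients(co), lungBg)
  pairs <- utils::combn(length(bg), 2)
  pvals <- apply(pairs, 2, function(ij)
    stats::t.test(bg[[ij[1]]], bg[[ij[2]]])$p.value)
  expect_gte(length(pvals), 100L)
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("radiologist scores anchor at the class extremes with zero jitter",
{
  co <- generateCohort(tinySpec(seed = 5L))
  ben <- patients(co)[[1]]; mal <- patients(co)[[3]]
  expect_equal(classLabel(ben), "benign")
  expect_equal(classLabel(mal), "malignant")
  sb <- assignRadiologistScores(ben, nRaters = 4L, scoreJitter = 0,
                                seed = 1L)
  expect_true(all(vapply(sb, function(s) identical(s, rep(1L, 4L)),
                         logical(1))))
  sm <- assignRadiologistScores(mal, nRaters = 3L, scoreJitter = 0,
                                seed = 1L)
  expect_true(all(vapply(sm, function(s) identical(s, rep(5L, 3L)),
                         logical(1))))
  # jitter > 0: every score clamped to the 1..5 scale
  sj <- assignRadiologistScores(mal, nRaters = 50L, scoreJitter = 5,
                                seed = 2L)
  expect_true(all(unlist(sj) >= 1L & unlist(sj) <= 5L))
  expect_error(assignRadiologistScores(ben, nRaters = 0L),
               "nRaters")
})

test_that("invalid specs fail validation naming the offending field", {
  expect_error(phantomSpec(nBenign = 0L), "nBenign")
  expect_error(phantomSpec(slicesPerPatient = 0L), "slicesPerPatient")
  expect_error(phantomSpec(benignRadiusRange = c(8, 10),
                           malignantRadiusRange = c(6, 9)),
               "malignantRadiusRange")
})

test_that("write/read round trip reproduces the cohort exactly", {
  co <- generateCohort(tinySpec(seed = 13L))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  co2 <- readCohort(dir)
  expect_identical(lapply(cohortImages(co), pixels),
                   lapply(cohortImages(co2), pixels))
  expect_identical(lapply(cohortImages(co), mask),
                   lapply(cohortImages(co2), mask))
  expect_identical(cohortManifest(co), cohortManifest(co2))
  expect_equal(co@spec, co2@spec)
})

test_that("an empty cohort writes a header-only manifest", {
  co <- new("PhantomCohort", patients = list(), spec = tinySpec())
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  lines <- readLines(file.path(dir, "manifest.csv"))
  expect_length(lines, 1L)
  expect_match(lines, "image_id")
})

test_that("a manifest row pointing to a missing PNG fails naming the image",
{
  co <- generateCohort(tinySpec(seed = 17L))
  dir <- withr::local_tempdir()
  writeCohort(co, dir)
  victim <- imageId(cohortImages(co)[[2]])
  file.remove(file.path(dir, "masks", paste0(victim, ".png")))
  expect_error(readCohort(dir), victim)
})
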