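# Fair/unfair splits, the challenge carve-out, MCCV scheduling and the
# leakage audit.

test_that("challenge carve-out removes whole patients deterministically", {
  co <- generateCohort(tinySpec(nBenign = 8L, nMalignant = 8L,
                                slicesPerPatient = 1L, seed = 1L))
  cv <- carveChallengeSet(co, 2L, 2L, seed = 5L)
  expect_length(cv$challenge, 4L)
  expect_length(cv$pool, 12L)
  expect_length(intersect(cv$challenge, cv$pool), 0L)
  expect_identical(cv, carveChallengeSet(co, 2L, 2L, seed = 5L))
  expect_error(carveChallengeSet(co, 9L, 2L, seed = 1L), "benign")
})

test_that("image-wise split partitions by largest-remainder fractions", {
  man <- makeManifest(10L, 10L)  # 100 images, 50 per class
  plan <- splitImagewise(man, c(0.7, 0.2, 0.1), seed = 3L)
  expect_equal(splitMode(plan), "unfair")
  tab <- table(assignment(plan))
  expect_equal(unname(tab[c("train", "validation", "test")]),
               c(70L, 20L, 10L), ignore_attr = TRUE)
  # stratified: exactly half of each partition per class
  ap <- applySplit(man, plan)
  tab2 <- table(ap$split, ap$class)
  expect_equal(unname(tab2[c("train", "validation", "test"), "benign"]),
               c(35L, 10L, 5L), ignore_attr = TRUE)
  expect_equal(unname(tab2[c("train", "validation", "test"), "malignant"]),
               c(35L, 10L, 5L), ignore_attr = TRUE)
  # degenerate fractions: everything lands in train
  all_train <- splitImagewise(man, c(1, 0, 0), seed = 3L)
  expect_true(all(assignment(all_train) == "train"))
  expect_identical(assignment(plan),
                   assignment(splitImagewise(man, c(0.7, 0.2, 0.1),
                                             seed = 3L)))
})

test_that("patient-wise split keeps every patient in one partition", {
  man <- makeManifest(10L, 6L)
  plan <- splitPatientwise(man, c(0.6, 0.2, 0.2), seed = 2L)
  expect_equal(splitMode(plan), "fair")
  ap <- applySplit(man, plan)
  perPat <- tapply(ap$split, ap$patient_id, function(x) length(unique(x)))
  expect_true(all(perPat == 1L))
  patPart <- tapply(ap$split, ap$patient_id, function(x) x[1])
  expect_equal(unname(table(patPart)[c("train", "validation", "test")]),
               c(6L, 2L, 2L), ignore_attr = TRUE)
  expect_error(splitPatientwise(makeManifest(4L, 2L), c(0.6, 0.2, 0.2),
                                seed = 1L), "patients")
})

test_that("patient-wise plans audit leak-free over many seeds", {
  man <- makeManifest(12L, 5L)
  for (seed in 1:100) {
    plan <- splitPatientwise(man, c(0.6, 0.2, 0.2), seed = seed)
    expect_length(auditLeakage(plan, man)$leakingPatients, 0L)
  }
})

test_that("image-wise splits on a multi-slice cohort almost always leak", {
  man <- makeManifest(20L, 10L)
  leaks <- vapply(1:50, function(seed) {
    plan <- splitImagewise(man, c(0.7, 0.2, 0.1), seed = seed)
    length(auditLeakage(plan, man)$leakingPatients) > 0
  }, logical(1))
  expect_true(all(leaks))
})

test_that("audit conserves per-class image counts and validates coverage", {
  man <- makeManifest(8L, 4L)
  plan <- splitImagewise(man, c(0.5, 0.25, 0.25), seed = 9L)
  audit <- auditLeakage(plan, man)
  expect_equal(sum(audit$counts$Freq), nrow(man))
  byClass <- tapply(audit$counts$Freq, audit$counts$class, sum)
  expect_equal(unname(byClass), unname(table(man$class)),
               ignore_attr = TRUE)
  expect_error(auditLeakage(plan, man[-1, ]), "missing")
})

test_that("challenge patients stay out of both split modes", {
  man <- makeManifest(10L, 4L)
  ch <- c("p001", "p002")
  for (f in list(splitImagewise, splitPatientwise)) {
    plan <- f(man, c(0.6, 0.2, 0.2), seed = 4L, challengePatients = ch)
    ap <- applySplit(man, plan)
    expect_true(all(ap$split[ap$patient_id %in% ch] == "challenge"))
    expect_true(all(ap$split[!ap$patient_id %in% ch] != "challenge"))
  }
})

test_that("MCCV epochs are disjoint covers with the requested size", {
  pats <- sprintf("p%03d", 1:10)
  sch <- mccvSchedule(pats, valFraction = 0.2, nEpochs = 3L, seed = 1L)
  eps <- epochAssignments(sch)
  expect_length(eps, 3L)
  for (e in eps) {
    expect_setequal(names(e), pats)
    expect_equal(sum(e == "validation"), 2L)
    expect_equal(sum(e == "train"), 8L)
  }
  expect_length(epochAssignments(mccvSchedule(pats, 0.2, 1L, 2L)), 1L)
  expect_identical(mccvSchedule(pats, 0.2, 5L, 3L),
                   mccvSchedule(pats, 0.2, 5L, 3L))
})

test_that("MCCV re-draws validation patients across epochs", {
  pats <- sprintf("p%03d", 1:10)
  sch <- mccvSchedule(pats, valFraction = 0.2, nEpochs = 50L, seed = 7L)
  valSets <- vapply(epochAssignments(sch), function(e)
    paste(sort(names(e)[e == "validation"]), collapse = ","), character(1))
  expect_gte(length(unique(valSets)), 2L)
})

test_that("MCCV rejects degenerate validation fractions", {
  pats <- sprintf("p%03d", 1:10)
  expect_error(mccvSchedule(pats, valFraction = 0.04, nEpochs = 2L),
               "valFraction")
  expect_error(mccvSchedule(pats, valFraction = 0.99, nEpochs = 2L),
               "valFraction")
  expect_error(mccvSchedule(pats, valFraction = 0, nEpochs = 2L),
               "valFraction")
})
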