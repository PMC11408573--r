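#' @include AllClasses.R utils.R
NULL

#' Hold out a challenge set of whole patients
#'
#' Challenge patients are removed from the pool before any split is drawn,
#' in both fair and unfair modes, so they probe generalization to genuinely
#' new subjects.
#'
#' @param cohort a [PhantomCohort-class]
#' @param nBenignPatients,nMalignantPatients patients per class to hold out
#' @param seed integer seed
#' @return List with `challenge` and `pool`: character vectors of patient
#'   ids.
#' @export
carveChallengeSet <- function(cohort, nBenignPatients, nMalignantPatients,
                              seed = 1L) {
  stopifnot(is(cohort, "PhantomCohort"))
  ids <- vapply(cohort@patients, patientId, character(1))
  cls <- vapply(cohort@patients, classLabel, character(1))
  ben <- ids[cls == "benign"]; mal <- ids[cls == "malignant"]
  if (nBenignPatients > length(ben))
    specError("nBenignPatients",
              sprintf("requested %d benign challenge patients, only %d available",
                      nBenignPatients, length(ben)))
  if (nMalignantPatients > length(mal))
    specError("nMalignantPatients",
              sprintf("requested %d malignant challenge patients, only %d available",
                      nMalignantPatients, length(mal)))
  withSeed(seed, {
    ch <- c(sample(ben, nBenignPatients), sample(mal, nMalignantPatients))
    list(challenge = ch, pool = setdiff(ids, ch))
  })
}

.assignByFractions <- function(items, fractions) {
  parts <- c("train", "validation", "test")
  sizes <- largestRemainder(length(items), fractions)
  rep(parts, times = sizes)
}

.checkFractions <- function(fractions) {
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9)
    specError("fractions",
              "must be three nonnegative numbers (train, validation, test) summing to 1")
}

.planFromAssignment <- function(mode, assign, fractions, seed) {
  new("SplitPlan", mode = mode, assignment = assign,
      fractions = as.numeric(fractions), seed = as.integer(seed))
}

#' Image-wise ("unfair") split
#'
#' Shuffles individual images uniformly and partitions them by the given
#' fractions with largest-remainder rounding, stratified by class. Slices
#' (and augmented copies) of one patient may — and on multi-slice cohorts
#' almost surely do — span train, validation and test: this is the leakage
#' hazard the package audits.
#'
#' @param manifest data.frame with at least image_id, patient_id, class
#' @param fractions (train, validation, test) fractions summing to 1
#' @param seed integer seed
#' @param challengePatients patient ids already carved out; their images
#'   are assigned to the challenge partition
#' @return A [SplitPlan-class] with `mode = "unfair"`.
#' @export
splitImagewise <- function(manifest, fractions = c(0.7, 0.2, 0.1),
                           seed = 1L, challengePatients = character()) {
  .checkFractions(fractions)
  chRows <- manifest$patient_id %in% challengePatients
  pool <- manifest[!chRows, , drop = FALSE]
  assign <- setNames(rep("challenge", sum(chRows)),
                     manifest$image_id[chRows])
  withSeed(seed, {
    for (cl in unique(pool$class)) {
      ids <- sample(pool$image_id[pool$class == cl])
      assign[ids] <- .assignByFractions(ids, fractions)
    }
  })
  .planFromAssignment("unfair", assign[manifest$image_id], fractions, seed)
}

#' Patient-wise ("fair") split
#'
#' Shuffles and partitions whole patients, stratified by class; every image
#' follows its patient, so no patient's slices ever span partitions.
#'
#' @inheritParams splitImagewise
#' @return A [SplitPlan-class] with `mode = "fair"`.
#' @export
splitPatientwise <- function(manifest, fractions = c(0.7, 0.2, 0.1),
                             seed = 1L, challengePatients = character()) {
  .checkFractions(fractions)
  chRows <- manifest$patient_id %in% challengePatients
  pool <- manifest[!chRows, , drop = FALSE]
  patientClass <- tapply(pool$class, pool$patient_id,
                         function(x) x[1])
  nParts <- sum(fractions > 0)
  patAssign <- character()
  withSeed(seed, {
    for (cl in unique(patientClass)) {
      pids <- names(patientClass)[patientClass == cl]
      if (length(pids) < nParts)
        specError("manifest",
                  sprintf("class '%s' has %d patients but %d nonzero fractions",
                          cl, length(pids), nParts))
      pids <- sample(pids)
      patAssign[pids] <- .assignByFractions(pids, fractions)
    }
  })
  assign <- setNames(rep("challenge", nrow(manifest)), manifest$image_id)
  inPool <- !chRows
  assign[manifest$image_id[inPool]] <-
    patAssign[manifest$patient_id[inPool]]
  .planFromAssignment("fair", assign, fractions, seed)
}

#' Monte Carlo cross-validation schedule over patients
#'
#' Draws an independent patient-level train/validation assignment for every
#' epoch: the validation patients change each time a new epoch starts,
#' while train and validation stay disjoint and jointly cover the pool.
#'
#' @param patientIds character vector: the training-pool patients
#' @param valFraction fraction of patients held out per epoch (0, 1)
#' @param nEpochs number of epochs (>= 1)
#' @param seed integer seed
#' @return An [MccvSchedule-class].
#' @export
mccvSchedule <- function(patientIds, valFraction = 0.2, nEpochs = 50L,
                         seed = 1L) {
  if (valFraction <= 0 || valFraction >= 1)
    specError("valFraction", "must lie strictly between 0 and 1")
  if (nEpochs < 1L) specError("nEpochs", "must be >= 1")
  n <- length(patientIds)
  nVal <- round(valFraction * n)
  if (nVal < 1L)
    specError("valFraction",
              sprintf("%g of %d patients rounds to zero validation patients",
                      valFraction, n))
  if (nVal >= n)
    specError("valFraction", "leaves no training patients")
  withSeed(seed, {
    eps <- lapply(seq_len(nEpochs), function(e) {
      val <- sample(patientIds, nVal)
      setNames(ifelse(patientIds %in% val, "validation", "train"),
               patientIds)
    })
    new("MccvSchedule", epochAssignments = eps,
        valFraction = as.numeric(valFraction), seed = as.integer(seed))
  })
}

#' Audit a split plan for patient-identity leakage
#'
#' A patient "leaks" when their images appear in more than one partition.
#' Patient-wise plans audit clean by construction; image-wise plans on
#' multi-slice cohorts essentially always leak.
#'
#' @param plan a [SplitPlan-class]
#' @param manifest data.frame with image_id, patient_id, class covering the
#'   plan
#' @return List: `leakingPatients` (character, possibly empty),
#'   `partitionsPerPatient` (named list), and `counts` (data.frame of
#'   images per partition per class).
#' @export
auditLeakage <- function(plan, manifest) {
  stopifnot(is(plan, "SplitPlan"))
  miss <- setdiff(names(plan@assignment), manifest$image_id)
  if (length(miss))
    specError("manifest",
              paste("images in plan missing from manifest:",
                    paste(utils::head(miss, 5), collapse = ", ")))
  part <- plan@assignment[manifest$image_id]
  perPatient <- tapply(part, manifest$patient_id,
                       function(x) sort(unique(x)), simplify = FALSE)
  leaking <- names(perPatient)[vapply(perPatient, length, integer(1)) > 1L]
  counts <- as.data.frame(table(partition = part, class = manifest$class),
                          stringsAsFactors = FALSE)
  list(leakingPatients = leaking,
       partitionsPerPatient = perPatient,
       counts = counts)
}

#' Write a split back into a manifest
#'
#' @param manifest a cohort manifest data.frame
#' @param plan a [SplitPlan-class] covering it
#' @return The manifest with its `split` column filled from the plan.
#' @export
applySplit <- function(manifest, plan) {
  stopifnot(is(plan, "SplitPlan"))
  manifest$split <- unname(plan@assignment[manifest$image_id])
  if (anyNA(manifest$split))
    specError("plan", "plan does not cover every manifest image")
  manifest
}
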