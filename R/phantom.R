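#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a phantom-cohort specification
#'
#' The spec fully determines the cohort ([generateCohort()] is a pure
#' function of it). Defaults describe a balanced 20-patient cohort of
#' 128 x 128 slices with a moderate identity signature well above the pixel
#' noise.
#'
#' @param nBenign,nMalignant patients per class
#' @param slicesPerPatient original slices per patient
#' @param imageSize square image side in pixels
#' @param benignRadiusRange,malignantRadiusRange nodule radius (low, high)
#'   in pixels; the malignant low must be at or above the benign high so the
#'   classes are separable by size/shape by construction
#' @param signatureStrength amplitude of the per-patient sinusoidal identity
#'   texture (fraction of the intensity scale). This is the leakage channel:
#'   0 disables it
#' @param noiseSd sd of additive Gaussian pixel noise
#' @param seed integer seed
#' @return A validated [PhantomSpec-class].
#' @examples
#' spec <- phantomSpec(nBenign = 2, nMalignant = 2, slicesPerPatient = 3,
#'                     imageSize = 64, benignRadiusRange = c(4, 5.5),
#'                     malignantRadiusRange = c(5.5, 6.5), seed = 1)
#' cohort <- generateCohort(spec)
#' cohort
#' @export
phantomSpec <- function(nBenign = 10L, nMalignant = 10L,
                        slicesPerPatient = 8L, imageSize = 128L,
                        benignRadiusRange = c(6, 10),
                        malignantRadiusRange = c(10, 16),
                        signatureStrength = 0.2, noiseSd = 0.05,
                        seed = 1L) {
  new("PhantomSpec",
      nBenign = as.integer(nBenign), nMalignant = as.integer(nMalignant),
      slicesPerPatient = as.integer(slicesPerPatient),
      imageSize = as.integer(imageSize),
      benignRadiusRange = as.numeric(benignRadiusRange),
      malignantRadiusRange = as.numeric(malignantRadiusRange),
      signatureStrength = as.numeric(signatureStrength),
      noiseSd = as.numeric(noiseSd), seed = as.integer(seed))
}

# intensity palette of the phantom thorax (8-bit CT-like contrast)
.INTENSITY <- list(air = 0.05, body = 0.55, lung = 0.20, nodule = 0.80)

# pixel-center coordinate grids (0-based, row-major, origin top-left)
.coordGrids <- function(S) {
  list(row = matrix(0:(S - 1), S, S, byrow = FALSE),
       col = matrix(0:(S - 1), S, S, byrow = TRUE))
}

.insideEllipse <- function(g, e) {
  ((g$row - e$cr) / e$ar)^2 + ((g$col - e$cc) / e$ac)^2 <= 1
}

# draw per-patient lung-field geometry with mild anatomical jitter
.drawAnatomy <- function(S) {
  jit <- function(x, f = 0.02) x + stats::runif(1, -f * S, f * S)
  sc <- function() stats::runif(1, 0.92, 1.08)
  list(
    left = list(cr = jit(0.52 * S), cc = jit(0.28 * S),
                ar = 0.32 * S * sc(), ac = 0.20 * S * sc()),
    right = list(cr = jit(0.52 * S), cc = jit(0.72 * S),
                 ar = 0.32 * S * sc(), ac = 0.20 * S * sc()))
}

# nodule boundary radius as a function of polar angle; malignant nodules are
# spiculated (star-shaped boundary), benign nodules are smooth disks
.noduleRadiusFun <- function(class, R) {
  if (class == "benign") {
    function(theta) rep(R, length(theta))
  } else {
    nspikes <- sample(7:12, 1)
    theta0 <- stats::runif(1, 0, 2 * pi)
    function(theta) R * (1 + 0.3 * cos(nspikes * (theta - theta0)))
  }
}

# sample a nodule center such that the full spiculated extent fits inside
# the chosen lung ellipse
.placeNodule <- function(lung, Rmax) {
  for (i in 1:200) {
    u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
    if (u^2 + v^2 > 1) next
    cr <- lung$cr + u * lung$ar
    cc <- lung$cc + v * lung$ac
    margin <- ((cr - lung$cr) / (lung$ar - Rmax - 1))^2 +
      ((cc - lung$cc) / (lung$ac - Rmax - 1))^2
    if (lung$ar - Rmax - 1 > 0 && lung$ac - Rmax - 1 > 0 && margin <= 1)
      return(c(cr, cc))
  }
  c(lung$cr, lung$cc) # fallback: ellipse center always fits
}

.renderSlice <- function(spec, anatomy, sig, class, g) {
  S <- spec@imageSize
  base <- matrix(.INTENSITY$air, S, S)
  body <- list(cr = 0.5 * S, cc = 0.5 * S, ar = 0.42 * S, ac = 0.46 * S)
  base[.insideEllipse(g, body)] <- .INTENSITY$body
  base[.insideEllipse(g, anatomy$left)] <- .INTENSITY$lung
  base[.insideEllipse(g, anatomy$right)] <- .INTENSITY$lung

  rng <- if (class == "benign") spec@benignRadiusRange else
    spec@malignantRadiusRange
  R <- stats::runif(1, rng[1], rng[2])
  rfun <- .noduleRadiusFun(class, R)
  Rmax <- if (class == "benign") R else R * 1.3
  lung <- if (stats::runif(1) < 0.5) anatomy$left else anatomy$right
  ctr <- .placeNodule(lung, Rmax)

  dr <- g$row - ctr[1]; dc <- g$col - ctr[2]
  rr <- sqrt(dr^2 + dc^2)
  th <- atan2(dc, dr)
  msk <- matrix(as.integer(rr <= rfun(th)), S, S)

  px <- base
  px[msk == 1L] <- .INTENSITY$nodule
  if (spec@signatureStrength > 0) {
    # the signature covers the whole slice, nodule included: a model
    # attending to it gains no information about where the nodule is, so
    # signature reliance cannot masquerade as nodule focus (a texture
    # restricted to the background would leak the nodule position through
    # its complement once heat maps are rectified)
    tex <- sig$amplitude *
      sin(2 * pi * (sig$fx * g$row + sig$fy * g$col) + sig$phase)
    px <- px + tex
  }
  if (spec@noiseSd > 0)
    px <- px + matrix(stats::rnorm(S * S, 0, spec@noiseSd), S, S)
  px <- pmin(pmax(px, 0), 1)
  px <- round(px * 255) / 255   # snap to the 8-bit grid: PNG IO is lossless
  list(pixels = px, mask = msk)
}

.drawScores <- function(class, nRaters, jitter) {
  base <- if (class == "benign") 1 else 5
  s <- round(base + stats::rnorm(nRaters, 0, jitter))
  as.integer(pmin(pmax(s, 1), 5))
}

#' Generate a synthetic phantom-CT cohort
#'
#' Produces `nBenign + nMalignant` patients, each a multi-slice scan. Every
#' slice holds exactly one nodule of the patient's class (smooth disk for
#' benign, spiculated for malignant) inside one of two lung-field ellipses,
#' with the ground-truth mask. All of a patient's slices share that
#' patient's identity signature — a sinusoidal texture with patient-specific
#' spatial frequency and phase, added across the whole slice at amplitude
#' `signatureStrength`. Per-nodule radiologist malignancy scores
#' (1-5) are drawn around 1 (benign) or 5 (malignant) with sd `scoreJitter`.
#'
#' The output is byte-identical across calls with an identical spec.
#'
#' @param spec a [PhantomSpec-class]
#' @param nRaters radiologists scoring each nodule (default 4)
#' @param scoreJitter sd of the score draw around the class anchor
#' @return A [PhantomCohort-class].
#' @seealso [writeCohort()], [assignRadiologistScores()]
#' @export
generateCohort <- function(spec, nRaters = 4L, scoreJitter = 0.5) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  S <- spec@imageSize
  g <- .coordGrids(S)
  withSeed(spec@seed, {
    classes <- c(rep("benign", spec@nBenign),
                 rep("malignant", spec@nMalignant))
    pats <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      pid <- sprintf("p%03d", i)
      sig <- list(fx = stats::runif(1, 0.08, 0.42),
                  fy = stats::runif(1, 0.08, 0.42),
                  phase = stats::runif(1, 0, 2 * pi),
                  amplitude = spec@signatureStrength)
      anatomy <- .drawAnatomy(S)
      sl <- vector("list", spec@slicesPerPatient)
      for (k in seq_len(spec@slicesPerPatient)) {
        r <- .renderSlice(spec, anatomy, sig, classes[i], g)
        iid <- sprintf("%s_s%02d", pid, k)
        sl[[k]] <- new("AnnotatedImage",
          imageId = iid, patientId = pid,
          noduleId = sprintf("%s_n%02d", pid, k),
          pixels = r$pixels, mask = r$mask, classLabel = classes[i],
          radiologistScores = .drawScores(classes[i], nRaters, scoreJitter),
          augmentationAngle = 0, sourceImageId = iid)
      }
      pats[[i]] <- new("PatientPhantom", patientId = pid,
                       classLabel = classes[i], signatureParams = sig,
                       anatomyParams = anatomy, slices = sl)
    }
    new("PhantomCohort", patients = pats, spec = spec)
  })
}

#' Draw radiologist malignancy scores for a patient's nodules
#'
#' Scores are integers in 1..5 drawn around the class anchor (1 for benign,
#' 5 for malignant) with sd `scoreJitter`, then clamped to the scale. With
#' `scoreJitter = 0` a benign nodule averages exactly 1 and a malignant one
#' exactly 5.
#'
#' @param patient a [PatientPhantom-class]
#' @param nRaters number of radiologists (>= 1)
#' @param scoreJitter sd of the draw
#' @param seed integer seed
#' @return Named list, nodule id -> integer score vector of length
#'   `nRaters`.
#' @export
assignRadiologistScores <- function(patient, nRaters = 4L,
                                    scoreJitter = 0.5, seed = 1L) {
  stopifnot(is(patient, "PatientPhantom"))
  if (nRaters < 1L) specError("nRaters", "must be >= 1")
  withSeed(seed, {
    out <- lapply(patient@slices, function(s)
      .drawScores(patient@classLabel, nRaters, scoreJitter))
    names(out) <- vapply(patient@slices, function(s) s@noduleId,
                         character(1))
    out
  })
}

#' Manifest of a cohort
#'
#' One row per slice (including augmented copies) with the columns of the
#' on-disk `manifest.csv`: image_id, patient_id, nodule_id, class,
#' radiologist_scores (semicolon-joined), augmentation_angle,
#' source_image_id, split (empty until a plan is applied).
#'
#' @param cohort a [PhantomCohort-class]
#' @return A data.frame.
#' @export
cohortManifest <- function(cohort) {
  rows <- lapply(unlist(lapply(cohort@patients, slices),
                        recursive = FALSE), function(s)
    data.frame(image_id = s@imageId, patient_id = s@patientId,
               nodule_id = s@noduleId, class = s@classLabel,
               radiologist_scores = paste(s@radiologistScores,
                                          collapse = ";"),
               augmentation_angle = s@augmentationAngle,
               source_image_id = s@sourceImageId, split = "",
               stringsAsFactors = FALSE))
  if (!length(rows))
    return(data.frame(image_id = character(), patient_id = character(),
                      nodule_id = character(), class = character(),
                      radiologist_scores = character(),
                      augmentation_angle = numeric(),
                      source_image_id = character(), split = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Flat list of all slices in a cohort
#'
#' @param cohort a [PhantomCohort-class]
#' @return List of [AnnotatedImage-class] in patient, then slice, order.
#' @export
cohortImages <- function(cohort) {
  unlist(lapply(cohort@patients, slices), recursive = FALSE)
}

#' Write / read a cohort directory
#'
#' `writeCohort()` materialises a cohort as `images/<id>.png` (8-bit
#' grayscale), `masks/<id>.png` (values 0/255), `manifest.csv`, and a
#' `cohort.json` sidecar holding the spec and per-patient signature/anatomy
#' parameters. Because generated intensities live on the 8-bit grid, the
#' round trip `readCohort(writeCohort(x))` reproduces every pixel, mask and
#' manifest row exactly.
#'
#' @param cohort a [PhantomCohort-class]
#' @param dir target directory (created if absent)
#' @return `writeCohort`: the manifest path, invisibly. `readCohort`: a
#'   [PhantomCohort-class].
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "PhantomCohort"))
  dir.create(file.path(dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  for (s in cohortImages(cohort)) {
    EBImage::writeImage(EBImage::Image(s@pixels),
                        file.path(dir, "images", paste0(s@imageId, ".png")),
                        type = "png")
    EBImage::writeImage(EBImage::Image(s@mask * 1.0),
                        file.path(dir, "masks", paste0(s@imageId, ".png")),
                        type = "png")
  }
  man <- cohortManifest(cohort)
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  sp <- cohort@spec
  meta <- list(
    spec = list(nBenign = sp@nBenign, nMalignant = sp@nMalignant,
                slicesPerPatient = sp@slicesPerPatient,
                imageSize = sp@imageSize,
                benignRadiusRange = sp@benignRadiusRange,
                malignantRadiusRange = sp@malignantRadiusRange,
                signatureStrength = sp@signatureStrength,
                noiseSd = sp@noiseSd, seed = sp@seed),
    patients = lapply(cohort@patients, function(p)
      list(patientId = p@patientId, classLabel = p@classLabel,
           signatureParams = p@signatureParams,
           anatomyParams = p@anatomyParams,
           sliceIds = vapply(p@slices, imageId, character(1)))))
  jsonlite::write_json(meta, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manPath)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  manPath <- file.path(dir, "manifest.csv")
  if (!file.exists(manPath))
    specError("dir", paste("no manifest.csv under", dir))
  man <- utils::read.csv(manPath, stringsAsFactors = FALSE,
                         colClasses = "character")
  man$augmentation_angle <- as.numeric(man$augmentation_angle)
  meta <- jsonlite::read_json(file.path(dir, "cohort.json"),
                              simplifyVector = FALSE)
  spc <- do.call(phantomSpec, lapply(meta$spec, unlist))

  readGray <- function(path, iid, what) {
    if (!file.exists(path))
      stop(sprintf("missing %s file for manifest row with image_id '%s'",
                   what, iid), call. = FALSE)
    m <- EBImage::imageData(EBImage::readImage(path))
    matrix(as.numeric(m), nrow(m), ncol(m))
  }
  sliceById <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(man))) {
    iid <- man$image_id[i]
    px <- readGray(file.path(dir, "images", paste0(iid, ".png")), iid,
                   "image")
    mk <- readGray(file.path(dir, "masks", paste0(iid, ".png")), iid,
                   "mask")
    mk <- matrix(as.integer(mk >= 0.5), nrow(mk), ncol(mk))
    sc <- if (nzchar(man$radiologist_scores[i]))
      as.integer(strsplit(man$radiologist_scores[i], ";")[[1]])
    else integer()
    assign(iid, new("AnnotatedImage", imageId = iid,
                    patientId = man$patient_id[i],
                    noduleId = man$nodule_id[i], pixels = px, mask = mk,
                    classLabel = man$class[i], radiologistScores = sc,
                    augmentationAngle = man$augmentation_angle[i],
                    sourceImageId = man$source_image_id[i]),
           envir = sliceById)
  }
  pats <- lapply(meta$patients, function(p) {
    new("PatientPhantom", patientId = p$patientId,
        classLabel = p$classLabel,
        signatureParams = lapply(p$signatureParams, as.numeric),
        anatomyParams = lapply(p$anatomyParams,
                               function(e) lapply(e, as.numeric)),
        slices = lapply(unlist(p$sliceIds), function(id)
          get(id, envir = sliceById)))
  })
  new("PhantomCohort", patients = pats, spec = spc)
}
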