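#' @include AllClasses.R heatmap.R
NULL

#' Nodule-locality scores of a heat map
#'
#' Maximum and mean heat-map value inside the ground-truth nodule mask —
#' how much of the model's attention lands on the nodule itself. A
#' degenerate heat map scores (0, 0) by convention.
#'
#' @param heatmap a [HeatMap-class]
#' @param mask binary matrix of the same shape with at least one 1 pixel
#' @return Named numeric: `nodule_max`, `nodule_mean`.
#' @export
noduleLocality <- function(heatmap, mask) {
  stopifnot(is(heatmap, "HeatMap"))
  v <- heatmapValues(heatmap)
  if (!identical(dim(v), dim(mask)))
    specError("mask", "heat map and mask shapes differ")
  inside <- v[mask == 1]
  if (!length(inside))
    specError("mask", "empty mask: locality score undefined")
  c(nodule_max = max(inside), nodule_mean = mean(inside))
}

#' Heatmap-mask shape correlation
#'
#' Pearson (linear) and Spearman (rank, average ranks on ties) correlation
#' between the heat map and the binary nodule mask, both flattened over the
#' full image grid in the same pixel order. A zero-variance (degenerate)
#' heat map yields (0, 0) with `degenerate = TRUE` rather than NA, keeping
#' score tables total.
#'
#' @param heatmap a [HeatMap-class]
#' @param mask binary matrix of the same shape containing both 0s and 1s
#' @return List: `pearson`, `spearman`, `degenerate`.
#' @export
shapeCorrelation <- function(heatmap, mask) {
  stopifnot(is(heatmap, "HeatMap"))
  v <- as.numeric(heatmapValues(heatmap))
  m <- as.numeric(mask)
  if (!identical(dim(heatmapValues(heatmap)), dim(mask)))
    specError("mask", "heat map and mask shapes differ")
  if (all(m == 0) || all(m == 1))
    specError("mask",
              "mask must contain both 0 and 1 (correlation against a constant)")
  if (isDegenerate(heatmap) || stats::sd(v) == 0)
    return(list(pearson = 0, spearman = 0, degenerate = TRUE))
  list(pearson = stats::cor(v, m),
       spearman = stats::cor(rank(v, ties.method = "average"),
                             rank(m, ties.method = "average")),
       degenerate = FALSE)
}

#' Interpretability score table for a set of images
#'
#' One row per image per CAM variant: nodule locality (max, mean inside the
#' mask) and whole-grid shape correlations (Pearson, Spearman). The heat
#' map is computed for the malignant class on every image — the attention
#' map of the malignancy score — so the scores measure how much of the
#' model's malignancy evidence lands on the nodule, for benign and
#' malignant slices alike.
#'
#' @param images list of [AnnotatedImage-class] (each with a nonempty mask)
#' @param model a model honouring the CAM contract generics
#' @param config a [CamConfig-class]; with `"both"` two rows per image
#' @param modelTag label recorded in the `model_tag` column (e.g. "fair")
#' @return data.frame: image_id, patient_id, model_tag, cam_variant,
#'   nodule_max, nodule_mean, pearson, spearman, degenerate.
#' @export
scoreTable <- function(images, model, config = camConfig(),
                       modelTag = "model") {
  rows <- list()
  for (img in images) {
    hm <- computeCam(model, pixels(img), "malignant", config)
    if (is(hm, "HeatMap"))
      hm <- setNames(list(hm), config@channelCombination)
    for (variant in names(hm)) {
      h <- hm[[variant]]
      loc <- if (isDegenerate(h)) c(nodule_max = 0, nodule_mean = 0)
      else noduleLocality(h, mask(img))
      cc <- shapeCorrelation(h, mask(img))
      rows[[length(rows) + 1L]] <- data.frame(
        image_id = imageId(img), patient_id = patientId(img),
        model_tag = modelTag, cam_variant = variant,
        nodule_max = unname(loc["nodule_max"]),
        nodule_mean = unname(loc["nodule_mean"]),
        pearson = cc$pearson, spearman = cc$spearman,
        degenerate = cc$degenerate || isDegenerate(h),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
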