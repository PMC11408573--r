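#' @include AllClasses.R AllGenerics.R utils.R
NULL

#' Construct a CAM configuration
#'
#' @param channelCombination how the gradient-weighted channel maps are
#'   reduced across channels: `"weighted_average"`, `"weighted_maximum"`,
#'   or `"both"` to compute the two variants side by side
#' @param rectifyNegative zero out negative evidence before normalization
#'   (standard CAM practice; configurable)
#' @param colormapName colormap for overlays (`"jet"` or any
#'   [grDevices::hcl.colors()] palette name)
#' @return A validated [CamConfig-class].
#' @export
camConfig <- function(channelCombination = "both", rectifyNegative = TRUE,
                      colormapName = "jet") {
  new("CamConfig", channelCombination = channelCombination,
      rectifyNegative = as.logical(rectifyNegative),
      colormapName = colormapName)
}

# reduce gradient-weighted channel maps to a single native-resolution map
.camNative <- function(A, G, variant, rectify) {
  if (!identical(dim(A), dim(G)))
    stop("contract violation: activation and gradient shapes differ (",
         paste(dim(A), collapse = "x"), " vs ",
         paste(dim(G), collapse = "x"), ")", call. = FALSE)
  K <- dim(A)[3]
  w <- vapply(seq_len(K), function(k) mean(G[, , k]), numeric(1))
  maps <- lapply(seq_len(K), function(k) w[k] * A[, , k])
  M <- switch(variant,
    weighted_average = Reduce(`+`, maps) / K,
    weighted_maximum = Reduce(pmax, maps),
    stop("unknown CAM variant: ", variant, call. = FALSE))
  if (rectify) M <- pmax(M, 0)
  M
}

.upsampleBilinear <- function(m, outDim) {
  r <- EBImage::resize(EBImage::Image(m), w = outDim[1], h = outDim[2],
                       filter = "bilinear")
  matrix(as.numeric(EBImage::imageData(r)), outDim[1], outDim[2])
}

.heatmapFromNative <- function(M, outDim) {
  bounds <- range(M)
  native <- dim(M)
  if (diff(bounds) < 1e-12) {
    return(new("HeatMap", values = matrix(0, outDim[1], outDim[2]),
               degenerate = TRUE, nativeResolution = as.integer(native),
               normalizationBounds = bounds))
  }
  Mn <- (M - bounds[1]) / (bounds[2] - bounds[1])
  up <- .upsampleBilinear(Mn, outDim)
  # bilinear resampling can shift the extrema slightly off 0/1; re-pin the
  # min-max normalization on the image grid so the invariant holds exactly
  rg <- range(up)
  if (diff(rg) < 1e-12)
    return(new("HeatMap", values = matrix(0, outDim[1], outDim[2]),
               degenerate = TRUE, nativeResolution = as.integer(native),
               normalizationBounds = bounds))
  up <- (up - rg[1]) / (rg[2] - rg[1])
  new("HeatMap", values = up, degenerate = FALSE,
      nativeResolution = as.integer(native),
      normalizationBounds = bounds)
}

#' Compute a class-activation heat map
#'
#' Grad-CAM-style construction: (1) take the last-convolutional-layer
#' activations and the gradient of the target class's pre-softmax score
#' with respect to them; (2) average each channel's gradient spatially to
#' get a neuron weight; (3) combine the weighted channel maps by the
#' configured reduction (average, maximum, or both); (4) optionally rectify
#' negative values; (5) min-max normalize (a constant map is flagged
#' degenerate and set to all zeros); (6) bilinearly upsample to the image
#' grid.
#'
#' Works for any model implementing [lastConvActivations()] and
#' [classScoreGradient()].
#'
#' @param model a model honouring the contract generics
#' @param image grayscale image matrix the map should be computed for
#' @param targetClass class label or index whose evidence is mapped
#' @param config a [CamConfig-class]
#' @return A [HeatMap-class], or — when `channelCombination = "both"` — a
#'   named list of two (`weighted_average`, `weighted_maximum`).
#' @export
computeCam <- function(model, image, targetClass = "malignant",
                       config = camConfig()) {
  stopifnot(is(config, "CamConfig"))
  validObject(config)
  A <- lastConvActivations(model, image)
  G <- classScoreGradient(model, image, targetClass)
  outDim <- dim(image)
  one <- function(variant)
    .heatmapFromNative(.camNative(A, G, variant, config@rectifyNegative),
                       outDim)
  if (config@channelCombination == "both")
    list(weighted_average = one("weighted_average"),
         weighted_maximum = one("weighted_maximum"))
  else one(config@channelCombination)
}

.JET <- c("#00007F", "#0000FF", "#007FFF", "#00FFFF", "#7FFF7F",
          "#FFFF00", "#FF7F00", "#FF0000", "#7F0000")

.colormapFun <- function(name) {
  cols <- if (identical(name, "jet")) .JET
  else grDevices::hcl.colors(256, name)
  ramp <- grDevices::colorRamp(cols)
  function(v) ramp(v) / 255
}

#' Overlay a heat map on its source image
#'
#' The heat map is colour-mapped and alpha-blended onto the grayscale
#' image; `alpha = 0` reproduces the grayscale image in RGB, `alpha = 1`
#' gives the pure colormapped map. A degenerate (all-zero) map renders as
#' the colormap's lowest colour everywhere.
#'
#' @param image grayscale matrix in `[0, 1]`
#' @param heatmap a [HeatMap-class] of the same shape
#' @param colormapName colormap (see [camConfig()])
#' @param alpha blend weight of the heat map, in `[0, 1]`
#' @return `H x W x 3` RGB array in `[0, 1]`.
#' @export
overlayHeatmap <- function(image, heatmap, colormapName = "jet",
                           alpha = 0.5) {
  stopifnot(is(heatmap, "HeatMap"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    specError("alpha", "must be a single number in [0, 1]")
  v <- heatmapValues(heatmap)
  if (!identical(dim(image), dim(v)))
    specError("heatmap", "image and heat map shapes differ")
  cmap <- .colormapFun(colormapName)(as.numeric(v))
  out <- array(0, c(dim(image), 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * image +
      alpha * matrix(cmap[, ch], nrow(image), ncol(image))
  out
}
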