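# Dense-grid inference and suitability-map scaling: evaluate the model on a
# regular lattice of points, turn per-species scores into comparable [0, 1]
# maps, and render them as red overlays on a background image.

# Lattice over [lo, hi]: anchored at the lower bound, inclusive of the
# upper bound when the step divides the extent; a step larger than the
# extent degenerates to the single centered point.
.lattice <- function(lo, hi, step) {
  if (step >= hi - lo) return((lo + hi) / 2)
  seq(lo, hi + 1e-9, by = step)
}

#' Dense model inference over an area
#'
#' Evaluates a trained convolutional model on a regular lattice of points,
#' assembling the same per-point environmental tensor as for occurrences.
#' Points whose patch would cross a layer border are marked failed rather
#' than silently skipped. Deterministic for a frozen model.
#'
#' @param model a [ConvSDM-class].
#' @param layers named raster layers in the model's channel order.
#' @param area `c(xmin, xmax, ymin, ymax)`.
#' @param step lattice step (m); the reference fine-scale analysis uses a
#'   50 m step at full scale.
#' @param patchPx patch size in pixels.
#' @return list of class `InferenceGrid`: `points` (data.frame `x, y, ok`),
#'   `logits` and `probabilities` (points x species matrices, `NA` rows for
#'   failed points), `area`, `step`, `nx`, `ny`.
#' @export
denseInference <- function(model, layers, area, step, patchPx) {
  xs <- .lattice(area[1], area[2], step)
  ys <- .lattice(area[3], area[4], step)
  pts <- data.frame(x = rep(xs, times = length(ys)),
                    y = rep(rev(ys), each = length(xs)))  # row 1 = north
  ok <- rep(TRUE, nrow(pts))
  tensors <- vector("list", nrow(pts))
  for (i in seq_len(nrow(pts))) {
    res <- tryCatch(extractPatch(layers, c(pts$x[i], pts$y[i]), patchPx),
                    error = function(e) NULL)
    tensors[i] <- list(res)
    if (is.null(res)) ok[i] <- FALSE
  }
  S <- length(model@species)
  logits <- matrix(NA_real_, nrow(pts), S,
                   dimnames = list(NULL, model@species))
  probs <- logits
  if (any(ok)) {
    arr <- array(NA_real_, dim = c(patchPx, patchPx,
                                   length(layers), sum(ok)))
    for (j in seq_along(which(ok)))
      arr[, , , j] <- tensorValues(tensors[[which(ok)[j]]])
    attr(arr, "channelMeta") <- channelMeta(tensors[[which(ok)[1]]])
    pr <- predictConvSDM(model, arr)
    logits[ok, ] <- t(speciesLogits(pr$scores))
    probs[ok, ] <- t(speciesProbabilities(pr$scores))
  }
  structure(list(points = data.frame(pts, ok = ok), logits = logits,
                 probabilities = probs, area = area, step = step,
                 nx = length(xs), ny = length(ys)),
            class = "InferenceGrid")
}

#' Scale convolutional-model logits to a [0, 1] suitability surface
#'
#' Applies a unit-slope sigmoid centered on the area mean of the species'
#' logits, then min-max rescaling, so the area maximum maps to 1 and the
#' minimum to 0. Strictly order-preserving; rank statistics (hence AUC)
#' computed from the scaled values equal those from the raw logits.
#'
#' @param logits numeric vector of the species' logits over the area
#'   (`NA`s for failed points are carried through; the area mean uses
#'   successful points only).
#' @return scaled values in [0, 1].
#' @export
scaleCnnLogits <- function(logits) {
  v <- logits[!is.na(logits)]
  if (length(unique(v)) < 2)
    stop("degenerate map: constant logits cannot be min-max scaled")
  s <- stats::plogis(logits - mean(v))
  (s - min(s, na.rm = TRUE)) /
    (max(s, na.rm = TRUE) - min(s, na.rm = TRUE))
}

#' Min-max scale baseline probabilities to a suitability surface
#'
#' The baseline's outputs are already in [0, 1]; only min-max rescaling is
#' applied so the local maximum is 1 and the local minimum 0. Idempotent on
#' already-spanning input.
#'
#' @param probabilities numeric vector over the area.
#' @return scaled values in [0, 1].
#' @export
scaleBaselineProbabilities <- function(probabilities) {
  v <- probabilities[!is.na(probabilities)]
  if (length(unique(v)) < 2)
    stop("degenerate map: constant values cannot be min-max scaled")
  (probabilities - min(v)) / (max(v) - min(v))
}

#' Build a suitability map for one species from an inference grid
#'
#' @param grid an `InferenceGrid` from [denseInference()].
#' @param species species id.
#' @param method `"cnn"` (sigmoid + min-max on logits) or `"baseline"`
#'   (min-max on probabilities).
#' @return a [SuitabilityMap-class]; failed lattice points are `NA`.
#' @export
suitabilityMap <- function(grid, species, method = c("cnn", "baseline")) {
  method <- match.arg(method)
  species <- as.character(species)
  v <- if (method == "cnn") scaleCnnLogits(grid$logits[, species])
       else scaleBaselineProbabilities(grid$probabilities[, species])
  m <- matrix(v, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  layer <- rasterLayer(m, resolution = grid$step,
                       origin = c(grid$area[1] - grid$step / 2,
                                  grid$area[4] + grid$step / 2),
                       name = paste0("suitability_", species))
  new("SuitabilityMap", species = species, layer = layer,
      provenance = list(method = method, area = grid$area,
                        step = grid$step))
}

#' Render a suitability map over a background image
#'
#' Alpha-composites a transparent-to-bright-red overlay: suitability 0 is
#' fully transparent (background shows through), 1 is opaque pure red,
#' with linear alpha in between.
#'
#' @param map a [SuitabilityMap-class].
#' @param background H x W x 3 RGB array in [0, 1] covering the same grid.
#' @return H x W x 3 RGB array; write with [png::writePNG()] if needed.
#' @export
renderMap <- function(map, background) {
  g <- map@layer@grid
  if (!all(dim(background)[1:2] == dim(g)) ||
      length(dim(background)) != 3 || dim(background)[3] != 3)
    stop("background extent does not match the suitability map")
  alpha <- g
  alpha[is.na(alpha)] <- 0
  red <- c(1, 0, 0)
  out <- background
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * background[, , ch] + alpha * red[ch]
  out
}
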