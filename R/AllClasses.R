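#' @import methods
#' @importFrom stats prcomp rnorm runif quantile lm pf sd predict plogis
#'   setNames complete.cases pchisq
#' @importFrom utils read.csv write.csv head
#' @useDynLib convSDM, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' RasterLayer: a single-band georeferenced grid
#'
#' In-memory raster on a local planar coordinate system. Row 1 of the grid is
#' the northmost row; pixel (i, j) covers the half-open square
#' \eqn{[xmin + (j-1) r, xmin + j r) \times (ymax - i r, ymax - (i-1) r]}
#' with r the resolution in meters per pixel, so every point belongs to
#' exactly one pixel. Missing cells are `NA` in memory; the `nodata` slot is
#' the sentinel used on disk.
#'
#' @slot name layer name.
#' @slot grid numeric matrix of cell values (row 1 = north).
#' @slot resolution pixel size in meters.
#' @slot origin numeric length-2, (x, y) of the top-left corner.
#' @slot kind `"continuous"` or `"categorical"`.
#' @slot nodata numeric sentinel written to / read from disk.
#' @export
setClass("RasterLayer",
  representation(name = "character", grid = "matrix",
                 resolution = "numeric", origin = "numeric",
                 kind = "character", nodata = "numeric"),
  prototype(name = "layer", resolution = 1, origin = c(0, 0),
            kind = "continuous", nodata = -9999))

setValidity("RasterLayer", function(object) {
  msg <- character()
  if (length(object@resolution) != 1 || object@resolution <= 0)
    msg <- c(msg, "resolution must be a single positive number")
  if (length(object@origin) != 2)
    msg <- c(msg, "origin must be (x, y) of the top-left corner")
  if (!object@kind %in% c("continuous", "categorical"))
    msg <- c(msg, "kind must be 'continuous' or 'categorical'")
  if (object@kind == "categorical") {
    v <- object@grid[!is.na(object@grid)]
    if (length(v) && any(v != round(v)))
      msg <- c(msg, "categorical grid must hold integer class codes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RasterLayer
#'
#' @param grid numeric matrix, row 1 = northmost row.
#' @param resolution pixel size (m).
#' @param origin (x, y) of the top-left corner; defaults to (0, nrow * res)
#'   so the lower-left corner sits at the coordinate origin.
#' @param kind `"continuous"` or `"categorical"`.
#' @param name layer name.
#' @param nodata on-disk sentinel for missing cells.
#' @return a [RasterLayer-class] object.
#' @export
rasterLayer <- function(grid, resolution = 1, origin = NULL,
                        kind = "continuous", name = "layer",
                        nodata = -9999) {
  grid <- as.matrix(grid)
  storage.mode(grid) <- "double"
  if (is.null(origin)) origin <- c(0, nrow(grid) * resolution)
  new("RasterLayer", name = name, grid = grid,
      resolution = unname(as.numeric(resolution)),
      origin = unname(as.numeric(origin)), kind = kind,
      nodata = unname(as.numeric(nodata)))
}

#' EnvironmentalTensor: a multi-channel patch centered on an occurrence
#'
#' @slot values numeric array with dim (H, W, C); H = W = patch size, row 1
#'   is the northmost row of the patch.
#' @slot channelMeta data.frame with columns `name` and `kind`, one row per
#'   channel, in channel order.
#' @slot center (x, y) of the occurrence the patch is centered on.
#' @slot resolution pixel size (m) shared by all channels.
#' @export
setClass("EnvironmentalTensor",
  representation(values = "array", channelMeta = "data.frame",
                 center = "numeric", resolution = "numeric"))

setValidity("EnvironmentalTensor", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (length(d) != 3) msg <- c(msg, "values must be an (H, W, C) array")
  else {
    if (d[1] != d[2]) msg <- c(msg, "patch must be square (H = W)")
    if (d[3] != nrow(object@channelMeta))
      msg <- c(msg, "channelMeta rows must match channel count")
  }
  if (anyNA(object@values)) msg <- c(msg, "tensor must not contain nodata")
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a simulated landscape with known ground truth
#'
#' Holds the latent environmental fields, the derived raster channels
#' (pseudo-RGB, near-IR, categorical land cover, elevation), coarse
#' environment rasters, the species niche table, the sampled occurrences and
#' the per-occurrence ground truth.
#'
#' @slot extent width/height of the world in meters (square).
#' @slot resolution pixel size (m) of the fields and channels.
#' @slot fields named list of latent [RasterLayer-class] fields
#'   (temperature, moisture, elevation) plus the derived `roughness` field
#'   (local standard deviation of elevation) used by context species.
#' @slot layers named list of channel rasters in declared order
#'   r, g, b, nir, landcover, elevation.
#' @slot envRasters coarse environment rasters (point-value covariates for
#'   the baseline model), one per latent field.
#' @slot species data.frame of niche parameters (one row per species).
#' @slot occurrences data.frame `occ_id, species_id, x, y, split`.
#' @slot truth data.frame of latent-field values and true suitability at
#'   each occurrence.
#' @slot params list echoing the generating configuration (including seed).
#' @export
setClass("SyntheticWorld",
  representation(extent = "numeric", resolution = "numeric",
                 fields = "list", layers = "list", envRasters = "list",
                 species = "data.frame", occurrences = "data.frame",
                 truth = "data.frame", params = "list"))

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  lc <- object@layers[["landcover"]]
  if (!is.null(lc)) {
    k <- object@params$classCount
    if (!is.null(k) && !all(lc@grid %in% 0:(k - 1)))
      msg <- c(msg, "land-cover channel contains undeclared classes")
  }
  occ <- object@occurrences
  if (nrow(occ)) {
    m <- object@params$margin
    if (!is.null(m) &&
        (any(occ$x < m) || any(occ$x > object@extent - m) ||
         any(occ$y < m) || any(occ$y > object@extent - m)))
      msg <- c(msg, "occurrences violate the border margin")
  }
  if (length(msg)) msg else TRUE
})

#' ConvSDM: a trained convolutional species distribution model
#'
#' A small strided convolutional feature extractor phi ending in global
#' average pooling, composed with a linear species head psi, trained by
#' cross-entropy so that softmax(psi(phi(x))) estimates relative species
#' probabilities.
#'
#' @slot config model configuration (see [convSDMConfig()]).
#' @slot weights list of conv block weights and the linear head.
#' @slot channelStats per-model-channel standardization statistics computed
#'   on the training split.
#' @slot species character vector of species ids in head order.
#' @slot log data.frame of per-epoch training (and validation) loss.
#' @export
setClass("ConvSDM",
  representation(config = "list", weights = "list", channelStats = "list",
                 species = "character", log = "data.frame"))

#' SpeciesScores: per-occurrence species scores
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with species as rows and occurrences as columns. Assays: `probabilities`
#' (always; columns sum to 1) and, for convolutional models, `logits` (the
#' pre-softmax linear-head activations, used as the habitat-suitability
#' score for AUC).
#'
#' @export
setClass("SpeciesScores", contains = "SummarizedExperiment")

setValidity("SpeciesScores", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  msg <- character()
  if (!"probabilities" %in% a)
    msg <- c(msg, "a 'probabilities' assay is required")
  else {
    p <- SummarizedExperiment::assay(object, "probabilities")
    if (any(p < -1e-9)) msg <- c(msg, "probabilities must be non-negative")
    if (ncol(p) && any(abs(colSums(p) - 1) > 1e-6))
      msg <- c(msg, "probabilities must sum to 1 per occurrence")
  }
  if (length(msg)) msg else TRUE
})

#' SuitabilityMap: a per-species habitat suitability raster in [0, 1]
#'
#' @slot species species id the map refers to.
#' @slot layer [RasterLayer-class] of scaled suitability values (failed
#'   inference points are `NA`).
#' @slot provenance list describing the model, scaling method and area.
#' @export
setClass("SuitabilityMap",
  representation(species = "character", layer = "RasterLayer",
                 provenance = "list"))

setValidity("SuitabilityMap", function(object) {
  v <- object@layer@grid[!is.na(object@layer@grid)]
  if (length(v) && (min(v) < -1e-12 || max(v) > 1 + 1e-12))
    "suitability values must lie in [0, 1]" else TRUE
})
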