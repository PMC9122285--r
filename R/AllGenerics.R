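#' @name convSDM-accessors
#' @title Accessors for convSDM classes
#' @param x an object.
#' @param ... ignored.
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname convSDM-accessors
#' @export
setGeneric("rasterGrid", function(x, ...) standardGeneric("rasterGrid"))
#' @rdname convSDM-accessors
#' @export
setGeneric("rasterKind", function(x, ...) standardGeneric("rasterKind"))
#' @rdname convSDM-accessors
#' @export
setGeneric("rasterExtent", function(x, ...) standardGeneric("rasterExtent"))
#' @rdname convSDM-accessors
#' @export
setGeneric("tensorValues", function(x, ...) standardGeneric("tensorValues"))
#' @rdname convSDM-accessors
#' @export
setGeneric("channelMeta", function(x, ...) standardGeneric("channelMeta"))
#' @rdname convSDM-accessors
#' @export
setGeneric("occurrences", function(x, ...) standardGeneric("occurrences"))
#' @rdname convSDM-accessors
#' @export
setGeneric("speciesTable", function(x, ...) standardGeneric("speciesTable"))
#' @rdname convSDM-accessors
#' @export
setGeneric("speciesTraits", function(x, ...) standardGeneric("speciesTraits"))
#' @rdname convSDM-accessors
#' @export
setGeneric("groundTruth", function(x, ...) standardGeneric("groundTruth"))
#' @rdname convSDM-accessors
#' @export
setGeneric("worldLayers", function(x, ...) standardGeneric("worldLayers"))
#' @rdname convSDM-accessors
#' @export
setGeneric("envRasters", function(x, ...) standardGeneric("envRasters"))
#' @rdname convSDM-accessors
#' @export
setGeneric("latentFields", function(x, ...) standardGeneric("latentFields"))
#' @rdname convSDM-accessors
#' @export
setGeneric("trainingLog", function(x, ...) standardGeneric("trainingLog"))
#' @rdname convSDM-accessors
#' @export
setGeneric("modelConfig", function(x, ...) standardGeneric("modelConfig"))
#' @rdname convSDM-accessors
#' @export
setGeneric("speciesLogits", function(x, ...) standardGeneric("speciesLogits"))
#' @rdname convSDM-accessors
#' @export
setGeneric("speciesProbabilities",
           function(x, ...) standardGeneric("speciesProbabilities"))

setMethod("rasterGrid", "RasterLayer", function(x, ...) x@grid)
setMethod("rasterKind", "RasterLayer", function(x, ...) x@kind)
setMethod("rasterExtent", "RasterLayer", function(x, ...) {
  c(xmin = x@origin[1],
    xmax = x@origin[1] + ncol(x@grid) * x@resolution,
    ymin = x@origin[2] - nrow(x@grid) * x@resolution,
    ymax = x@origin[2])
})
setMethod("tensorValues", "EnvironmentalTensor", function(x, ...) x@values)
setMethod("channelMeta", "EnvironmentalTensor", function(x, ...) x@channelMeta)
setMethod("occurrences", "SyntheticWorld", function(x, ...) x@occurrences)
setMethod("speciesTable", "SyntheticWorld", function(x, ...) x@species)
setMethod("groundTruth", "SyntheticWorld", function(x, ...) x@truth)
setMethod("worldLayers", "SyntheticWorld", function(x, ...) x@layers)
setMethod("envRasters", "SyntheticWorld", function(x, ...) x@envRasters)
setMethod("latentFields", "SyntheticWorld", function(x, ...) x@fields)
setMethod("trainingLog", "ConvSDM", function(x, ...) x@log)
setMethod("modelConfig", "ConvSDM", function(x, ...) x@config)
setMethod("speciesLogits", "SpeciesScores", function(x, ...)
  SummarizedExperiment::assay(x, "logits"))
setMethod("speciesProbabilities", "SpeciesScores", function(x, ...)
  SummarizedExperiment::assay(x, "probabilities"))

setMethod("show", "RasterLayer", function(object) {
  d <- dim(object@grid)
  cat(sprintf("RasterLayer '%s' (%s): %d x %d px at %g m/px\n",
              object@name, object@kind, d[1], d[2], object@resolution))
  e <- rasterExtent(object)
  cat(sprintf("  extent: x [%g, %g), y (%g, %g]\n",
              e["xmin"], e["xmax"], e["ymin"], e["ymax"]))
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %g x %g m at %g m/px, %d species (%d context), %d occurrences\n",
    object@extent, object@extent, object@resolution,
    nrow(object@species), sum(object@species$context),
    nrow(object@occurrences)))
})

setMethod("show", "EnvironmentalTensor", function(object) {
  d <- dim(object@values)
  cat(sprintf("EnvironmentalTensor: %d x %d px, %d channels (%s), center (%g, %g)\n",
              d[1], d[2], d[3],
              paste(object@channelMeta$name, collapse = ", "),
              object@center[1], object@center[2]))
})

setMethod("show", "ConvSDM", function(object) {
  cfg <- object@config
  cat(sprintf(
    "ConvSDM: blocks [%s] -> %d features -> %d species; trained %d epochs\n",
    paste(cfg$blocks, collapse = ", "), cfg$featureDim,
    length(object@species), nrow(object@log)))
})

setMethod("show", "SuitabilityMap", function(object) {
  d <- dim(object@layer@grid)
  cat(sprintf("SuitabilityMap for species %s (%s): %d x %d points\n",
              object@species,
              object@provenance$method %||% "?", d[1], d[2]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
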