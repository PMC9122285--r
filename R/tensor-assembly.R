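# Tensor assembly: resampling heterogeneous rasters to a common resolution,
# extracting fixed-size patches centered on occurrences, and reading
# point-values of environment rasters.

#' Resample a raster layer to a target resolution
#'
#' Continuous layers are resampled by bilinear interpolation between input
#' pixel centers (clamped at the border, so output values never exceed the
#' input range); categorical layers use nearest-neighbor only, which keeps
#' the class set intact. The output preserves the layer's extent, so the
#' target resolution must tile it.
#'
#' @param layer a [RasterLayer-class].
#' @param targetResolution output pixel size (m).
#' @param method `"auto"` (from the layer kind), `"bilinear"` or
#'   `"nearest"`. Requesting bilinear for a categorical layer is an error.
#' @return a resampled [RasterLayer-class].
#' @export
resampleLayer <- function(layer, targetResolution,
                          method = c("auto", "bilinear", "nearest")) {
  stopifnot(is(layer, "RasterLayer"))
  if (!is.numeric(targetResolution) || targetResolution <= 0)
    stop("targetResolution must be positive")
  method <- match.arg(method)
  if (method == "auto")
    method <- if (layer@kind == "categorical") "nearest" else "bilinear"
  if (layer@kind == "categorical" && method == "bilinear")
    stop("bilinear resampling would corrupt the classes of a categorical layer")
  g <- layer@grid
  e <- rasterExtent(layer)
  width <- e["xmax"] - e["xmin"]; height <- e["ymax"] - e["ymin"]
  ncolOut <- round(width / targetResolution)
  nrowOut <- round(height / targetResolution)
  if (abs(ncolOut * targetResolution - width) > 1e-6 ||
      abs(nrowOut * targetResolution - height) > 1e-6)
    stop("targetResolution does not tile the layer extent")
  # continuous (row, col) positions of the output pixel centers on the
  # input pixel-center lattice
  xq <- e["xmin"] + (seq_len(ncolOut) - 0.5) * targetResolution
  yq <- e["ymax"] - (seq_len(nrowOut) - 0.5) * targetResolution
  colPos <- (xq - e["xmin"]) / layer@resolution + 0.5
  rowPos <- (e["ymax"] - yq) / layer@resolution + 0.5
  if (method == "nearest") {
    ri <- pmin(pmax(round(rowPos), 1), nrow(g))
    ci <- pmin(pmax(round(colPos), 1), ncol(g))
    out <- g[ri, ci, drop = FALSE]
  } else {
    rp <- pmin(pmax(rowPos, 1), nrow(g))
    cp <- pmin(pmax(colPos, 1), ncol(g))
    if (nrow(g) < 2 || ncol(g) < 2) {
      ri <- pmin(pmax(round(rp), 1), nrow(g))
      ci <- pmin(pmax(round(cp), 1), ncol(g))
      out <- g[ri, ci, drop = FALSE]
    } else {
      qx <- rep(cp, each = length(rp))
      qy <- rep(rp, times = length(cp))
      v <- pracma::interp2(x = seq_len(ncol(g)), y = seq_len(nrow(g)),
                           Z = g, xp = qx, yp = qy, method = "linear")
      # interpolation arithmetic can overshoot the node range by a few ulp;
      # the mathematical result cannot, so clamp
      v <- pmin(pmax(v, min(g, na.rm = TRUE)), max(g, na.rm = TRUE))
      out <- matrix(v, nrow = length(rp), ncol = length(cp))
    }
  }
  rasterLayer(out, resolution = targetResolution,
              origin = layer@origin, kind = layer@kind,
              name = layer@name, nodata = layer@nodata)
}

# 1-based row/col index windows for a patch of patchPx pixels whose
# occurrence pixel is the cell containing `center`. For even P the
# occurrence pixel sits at patch index (P/2, P/2) (0-based), i.e. the patch
# covers the half-open square [c - r P/2, c + r P/2) on each axis.
.patchWindow <- function(layer, center, patchPx) {
  idx <- .cellIndex(layer, center[1], center[2])
  if (anyNA(idx)) stop("patch center outside the layer extent")
  off <- floor(patchPx / 2)
  list(rows = idx[1, "row"] - off + seq_len(patchPx) - 1L,
       cols = idx[1, "col"] - off + seq_len(patchPx) - 1L)
}

#' Extract an environmental tensor centered on a point
#'
#' Stacks patches from a list of raster layers at a common resolution into
#' an (H, W, C) tensor, channels in the declared list order. The patch must
#' lie fully inside every layer (no implicit padding) and must not contain
#' nodata cells.
#'
#' @param layers named list of [RasterLayer-class] at one resolution.
#' @param center (x, y) of the occurrence.
#' @param patchPx patch size in pixels (H = W).
#' @return an [EnvironmentalTensor-class].
#' @export
extractPatch <- function(layers, center, patchPx) {
  stopifnot(length(layers) >= 1, patchPx >= 1)
  res <- vapply(layers, slot, numeric(1), "resolution")
  if (length(unique(res)) != 1)
    stop("all layers must share a common resolution")
  vals <- array(NA_real_, dim = c(patchPx, patchPx, length(layers)))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    w <- .patchWindow(l, center, patchPx)
    if (min(w$rows) < 1 || max(w$rows) > nrow(l@grid) ||
        min(w$cols) < 1 || max(w$cols) > ncol(l@grid))
      stop("patch crosses the boundary of layer '", l@name, "'")
    patch <- l@grid[w$rows, w$cols, drop = FALSE]
    if (anyNA(patch))
      stop("patch contains nodata cells in layer '", l@name, "'")
    vals[, , i] <- patch
  }
  meta <- data.frame(
    name = vapply(layers, slot, character(1), "name"),
    kind = vapply(layers, slot, character(1), "kind"),
    stringsAsFactors = FALSE)
  new("EnvironmentalTensor", values = vals, channelMeta = meta,
      center = as.numeric(center), resolution = res[1])
}

#' Assemble tensors for a table of occurrences
#'
#' Batch form of [extractPatch()]: returns an (H, W, C, N) array with the
#' channel metadata attached as the `"channelMeta"` attribute.
#'
#' @param layers named list of [RasterLayer-class] at one resolution.
#' @param occurrences data.frame with columns `x`, `y` (and `occ_id`).
#' @param patchPx patch size in pixels.
#' @return numeric array (H, W, C, N); dimnames on N are the occ ids.
#' @export
assembleTensors <- function(layers, occurrences, patchPx) {
  n <- nrow(occurrences)
  C <- length(layers)
  out <- array(NA_real_, dim = c(patchPx, patchPx, C, n))
  grids <- lapply(layers, slot, "grid")
  for (j in seq_len(n)) {
    center <- c(occurrences$x[j], occurrences$y[j])
    for (i in seq_len(C)) {
      l <- layers[[i]]
      w <- .patchWindow(l, center, patchPx)
      if (min(w$rows) < 1 || max(w$rows) > nrow(grids[[i]]) ||
          min(w$cols) < 1 || max(w$cols) > ncol(grids[[i]]))
        stop("patch for occurrence ", occurrences$occ_id[j] %||% j,
             " crosses the boundary of layer '", l@name, "'")
      out[, , i, j] <- grids[[i]][w$rows, w$cols]
    }
  }
  if (anyNA(out)) stop("assembled tensors contain nodata cells")
  attr(out, "channelMeta") <- data.frame(
    name = vapply(layers, slot, character(1), "name"),
    kind = vapply(layers, slot, character(1), "kind"),
    stringsAsFactors = FALSE)
  dimnames(out) <- list(NULL, NULL, names(layers),
                        as.character(occurrences$occ_id %||% seq_len(n)))
  out
}

#' Write / read an environmental tensor on disk
#'
#' One directory per occurrence: each channel as an ASCII grid
#' georeferenced at the patch location, plus `meta.json` with the channel
#' order, kinds, center and resolution.
#'
#' @param tensor an [EnvironmentalTensor-class].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly (write); the tensor (read).
#' @export
writeTensor <- function(tensor, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  v <- tensorValues(tensor)
  meta <- channelMeta(tensor)
  p <- dim(v)[1]
  r <- tensor@resolution
  off <- floor(p / 2)
  origin <- c(tensor@center[1] - off * r, tensor@center[2] + off * r)
  for (i in seq_len(nrow(meta))) {
    l <- rasterLayer(v[, , i], resolution = r, origin = origin,
                     kind = meta$kind[i], name = meta$name[i])
    writeAsciiGrid(l, file.path(dir, sprintf("band_%02d_%s", i,
                                             meta$name[i])))
  }
  jsonlite::write_json(list(channels = meta, center = tensor@center,
                            resolution = r, patchPx = p),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname writeTensor
#' @export
readTensor <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  p <- meta$patchPx
  vals <- array(NA_real_, dim = c(p, p, nrow(meta$channels)))
  for (i in seq_len(nrow(meta$channels))) {
    l <- readAsciiGrid(file.path(dir, sprintf("band_%02d_%s", i,
                                              meta$channels$name[i])))
    vals[, , i] <- rasterGrid(l)
  }
  new("EnvironmentalTensor", values = vals,
      channelMeta = as.data.frame(meta$channels),
      center = meta$center, resolution = meta$resolution)
}

#' Subset an assembled tensor batch along occurrences
#'
#' Plain `[` on a tensor array drops the channel metadata; this keeps it.
#'
#' @param tensors (H, W, C, N) array from [assembleTensors()].
#' @param idx occurrence index (logical or integer).
#' @return the subset array with `channelMeta` preserved.
#' @export
tensorSubset <- function(tensors, idx) {
  out <- tensors[, , , idx, drop = FALSE]
  attr(out, "channelMeta") <- attr(tensors, "channelMeta")
  out
}

#' Point values of environment rasters
#'
#' Looks up the value of each environment raster at the cell containing each
#' point (half-open containment). Cells flagged nodata yield `NA`; a point
#' outside the coverage of every raster is an error.
#'
#' @param envRasters named list of [RasterLayer-class].
#' @param points data.frame with columns `x`, `y`.
#' @return data.frame, one column per raster, one row per point.
#' @export
envVectorAt <- function(envRasters, points) {
  stopifnot(length(envRasters) >= 1)
  out <- lapply(envRasters, function(l) {
    idx <- .cellIndex(l, points$x, points$y)
    v <- rep(NA_real_, nrow(points))
    ok <- !is.na(idx[, "row"])
    v[ok] <- l@grid[cbind(idx[ok, "row"], idx[ok, "col"])]
    v
  })
  out <- as.data.frame(out)
  names(out) <- names(envRasters)
  covered <- Reduce(`|`, lapply(envRasters, function(l) {
    !is.na(.cellIndex(l, points$x, points$y)[, "row"])
  }))
  if (any(!covered))
    stop(sum(!covered), " point(s) outside the coverage of all rasters")
  out
}
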