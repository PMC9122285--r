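# Raster I/O: ESRI ASCII grid (.asc) with a JSON sidecar carrying the layer
# name and kind. The .asc format is plain text, north-up, square pixels.

#' Write a raster layer as an ESRI ASCII grid
#'
#' Writes `<path>.asc` plus `<path>.json` holding the layer name and kind.
#' `NA` cells are written as the layer's nodata sentinel.
#'
#' @param layer a [RasterLayer-class].
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path) {
  stopifnot(is(layer, "RasterLayer"))
  g <- layer@grid
  e <- rasterExtent(layer)
  hdr <- c(sprintf("ncols %d", ncol(g)),
           sprintf("nrows %d", nrow(g)),
           sprintf("xllcorner %.10g", e["xmin"]),
           sprintf("yllcorner %.10g", e["ymin"]),
           sprintf("cellsize %.10g", layer@resolution),
           sprintf("NODATA_value %.10g", layer@nodata))
  g[is.na(g)] <- layer@nodata
  rows <- apply(g, 1, function(r)
    paste(formatC(r, format = "g", digits = 15), collapse = " "))
  writeLines(c(hdr, rows), paste0(path, ".asc"))
  jsonlite::write_json(list(name = layer@name, kind = layer@kind),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a raster layer written by [writeAsciiGrid()]
#'
#' @param path file path without extension.
#' @return a [RasterLayer-class].
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(paste0(path, ".asc"))
  hdr <- strsplit(lines[1:6], " +")
  vals <- vapply(hdr, function(h) as.numeric(h[2]), numeric(1))
  names(vals) <- vapply(hdr, function(h) tolower(h[1]), character(1))
  g <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(trimws(l), " +")[[1]])))
  stopifnot(ncol(g) == vals["ncols"], nrow(g) == vals["nrows"])
  g[g == vals["nodata_value"]] <- NA_real_
  meta <- if (file.exists(paste0(path, ".json")))
    jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  else list(name = basename(path), kind = "continuous")
  rasterLayer(g, resolution = unname(vals["cellsize"]),
              origin = unname(c(vals["xllcorner"],
                                vals["yllcorner"] +
                                  vals["nrows"] * vals["cellsize"])),
              kind = meta$kind, name = meta$name,
              nodata = unname(vals["nodata_value"]))
}

# Row/col of the pixel containing (x, y) under the half-open convention
# (west/north edges inclusive). Returns NA for points outside the extent.
.cellIndex <- function(layer, x, y) {
  e <- rasterExtent(layer)
  r <- layer@resolution
  col <- floor((x - e["xmin"]) / r) + 1
  row <- floor((e["ymax"] - y) / r) + 1
  # the north edge y == ymax maps to row 1, the south edge is excluded;
  # mirror that on x so x == xmax is excluded
  bad <- col < 1 | col > ncol(layer@grid) | row < 1 | row > nrow(layer@grid)
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Coordinates of pixel centers for (row, col) matrices.
.cellCenter <- function(layer, row, col) {
  e <- rasterExtent(layer)
  r <- layer@resolution
  cbind(x = e["xmin"] + (col - 0.5) * r, y = e["ymax"] - (row - 0.5) * r)
}
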