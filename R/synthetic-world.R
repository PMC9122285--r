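# Synthetic landscapes with known ground truth: smooth latent environmental
# fields, derived raster channels, parameterized Gaussian niches and biased
# occurrence sampling. Every downstream stage of the pipeline is testable
# against the truth exported here.

# Periodic Gaussian smoothing of a matrix via 2-D FFT. sigmaPx is the
# kernel standard deviation in pixels. Output is standardized (mean 0,
# sd 1) so kernel width changes smoothness, not scale.
.gaussianSmooth <- function(m, sigmaPx) {
  n <- nrow(m); p <- ncol(m)
  di <- pmin(0:(n - 1), n - 0:(n - 1))
  dj <- pmin(0:(p - 1), p - 0:(p - 1))
  kern <- exp(-outer(di^2, dj^2, `+`) / (2 * sigmaPx^2))
  kern <- kern / sum(kern)
  out <- Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) / (n * p)
  (out - mean(out)) / stats::sd(out)
}

# Local standard deviation within a (2*radiusPx + 1)^2 window, windows
# clipped at the border. Exact, via integral images.
.localSD <- function(m, radiusPx) {
  n <- nrow(m); p <- ncol(m)
  boxSum <- function(x) {
    cs <- apply(apply(x, 2, cumsum), 1, cumsum)  # transposed cumulative sum
    cs <- t(cs)
    padded <- matrix(0, n + 1, p + 1)
    padded[-1, -1] <- cs
    r <- radiusPx
    i1 <- pmax(seq_len(n) - r, 1); i2 <- pmin(seq_len(n) + r, n)
    j1 <- pmax(seq_len(p) - r, 1); j2 <- pmin(seq_len(p) + r, p)
    padded[i2 + 1, j2 + 1, drop = FALSE] - padded[i1, j2 + 1, drop = FALSE] -
      padded[i2 + 1, j1, drop = FALSE] + padded[i1, j1, drop = FALSE]
  }
  cnt <- boxSum(matrix(1, n, p))
  mu <- boxSum(m) / cnt
  v <- boxSum(m^2) / cnt - mu^2
  sqrt(pmax(v, 0))
}

#' Generate latent environmental fields
#'
#' Produces three standardized latent fields on the world grid: a
#' `temperature` field with a strictly monotone west-east gradient (plus a
#' smooth north-south modulation), a `moisture` field (seeded white noise
#' convolved with a Gaussian kernel) and an `elevation` field built as a
#' very smooth base plus fine-scale relief whose local amplitude is
#' modulated by an independent smooth "ruggedness" field. The amplitude
#' modulation makes the local standard deviation of elevation (terrain
#' roughness) spatially structured while staying uncorrelated with the
#' point elevation value - the property context-dependent species probe.
#'
#' @param extent world width/height in meters.
#' @param resolution pixel size in meters.
#' @param seed RNG seed; the fields are deterministic given the seed.
#' @param moistureKernel Gaussian kernel sd (m) for the moisture field.
#' @param elevationBaseKernel kernel sd (m) of the smooth elevation base.
#' @param elevationFineKernel kernel sd (m) of the fine relief.
#' @param ruggednessKernel kernel sd (m) of the amplitude-modulation field.
#' @return named list of [RasterLayer-class] fields (`temperature`,
#'   `moisture`, `elevation`), each with a `"role"` attribute.
#' @export
generateFields <- function(extent, resolution, seed,
                           moistureKernel = 60,
                           elevationBaseKernel = 250,
                           elevationFineKernel = 8,
                           ruggednessKernel = 150) {
  if (!is.numeric(extent) || extent <= 0 || !is.numeric(resolution) ||
      resolution <= 0 || extent < 2 * resolution)
    stop("extent and resolution must be positive (extent >= 2 pixels)")
  n <- round(extent / resolution)
  set.seed(seed)
  xn <- matrix(rep((seq_len(n) - 0.5) / n, each = n), n, n)
  yn <- matrix(rep((seq_len(n) - 0.5) / n, times = n), n, n)
  temp <- 2 * (xn - 0.5) + 0.25 * sin(2 * pi * yn)
  temp <- (temp - mean(temp)) / stats::sd(temp)
  moist <- .gaussianSmooth(matrix(rnorm(n * n), n, n),
                           moistureKernel / resolution)
  base <- .gaussianSmooth(matrix(rnorm(n * n), n, n),
                          elevationBaseKernel / resolution)
  fine <- .gaussianSmooth(matrix(rnorm(n * n), n, n),
                          elevationFineKernel / resolution)
  rug <- .gaussianSmooth(matrix(rnorm(n * n), n, n),
                         ruggednessKernel / resolution)
  rug01 <- (rug - min(rug)) / (max(rug) - min(rug))
  elev <- base + rug01 * fine
  elev <- (elev - mean(elev)) / stats::sd(elev)
  mk <- function(g, nm, role) {
    l <- rasterLayer(g, resolution = resolution, origin = c(0, extent),
                     kind = "continuous", name = nm)
    attr(l, "role") <- role
    l
  }
  elevLayer <- mk(elev, "elevation", "elevation-like smooth field")
  # the smooth component alone: what a coarse terrain product resolves
  # (the fine relief only exists at imagery resolution)
  attr(elevLayer, "smoothBase") <- base
  list(temperature = mk(temp, "temperature", "temperature-like gradient"),
       moisture = mk(moist, "moisture", "moisture-like random field"),
       elevation = elevLayer)
}

# Fixed qualitative palette for land-cover classes (rows: R, G, B, and a
# near-IR base reflectance), recycled deterministically beyond 8 classes.
.classPalette <- function(k) {
  base <- rbind(
    c(0.15, 0.45, 0.10, 0.85),  # forest
    c(0.75, 0.70, 0.30, 0.55),  # cropland
    c(0.55, 0.55, 0.55, 0.25),  # urban
    c(0.20, 0.35, 0.65, 0.10),  # water-like
    c(0.80, 0.60, 0.45, 0.40),  # bare soil
    c(0.35, 0.60, 0.25, 0.70),  # shrubland
    c(0.90, 0.85, 0.75, 0.50),  # sand
    c(0.45, 0.30, 0.20, 0.35))  # wetland
  base[((seq_len(k) - 1) %% nrow(base)) + 1, , drop = FALSE]
}

#' Derive raster channels from latent fields
#'
#' Builds the six world channels: categorical land cover as equal-frequency
#' threshold bands of a temperature/moisture mixture, pseudo-RGB as
#' per-class base colors plus continuous field modulation plus seeded
#' noise, near-IR as an affine mix of moisture and the class base
#' reflectance, and the elevation channel as the elevation field itself.
#'
#' @param fields output of [generateFields()].
#' @param classCount number of land-cover classes (>= 2).
#' @param seed RNG seed for the pixel noise.
#' @param noiseAmp standard deviation of the additive pixel noise; 0 makes
#'   every channel a deterministic function of (class, field values).
#' @return named list of [RasterLayer-class]: `r, g, b, nir, landcover,
#'   elevation`.
#' @export
deriveChannels <- function(fields, classCount = 4, seed = 1,
                           noiseAmp = 0.05) {
  if (classCount < 2) stop("classCount must be at least 2")
  tg <- rasterGrid(fields$temperature)
  mg <- rasterGrid(fields$moisture)
  eg <- rasterGrid(fields$elevation)
  res <- fields$temperature@resolution
  origin <- fields$temperature@origin
  mix <- 0.6 * tg + 0.4 * mg
  br <- stats::quantile(mix, probs = seq_len(classCount - 1) / classCount)
  lc <- matrix(findInterval(mix, br), nrow(mix), ncol(mix))
  pal <- .classPalette(classCount)
  set.seed(seed)
  scl <- function(g) (g - min(g)) / (max(g) - min(g))
  noise <- function() if (noiseAmp > 0)
    matrix(rnorm(length(tg), sd = noiseAmp), nrow(tg)) else 0
  rch <- 0.55 * matrix(pal[lc + 1, 1], nrow(lc)) + 0.35 * scl(tg) + noise()
  gch <- 0.55 * matrix(pal[lc + 1, 2], nrow(lc)) + 0.35 * scl(mg) + noise()
  bch <- 0.55 * matrix(pal[lc + 1, 3], nrow(lc)) + 0.35 * scl(eg) + noise()
  nir <- 0.60 * scl(mg) + 0.40 * matrix(pal[lc + 1, 4], nrow(lc)) + noise()
  mk <- function(g, nm, kind = "continuous")
    rasterLayer(g, resolution = res, origin = origin, kind = kind, name = nm)
  list(r = mk(rch, "r"), g = mk(gch, "g"), b = mk(bch, "b"),
       nir = mk(nir, "nir"),
       landcover = mk(lc, "landcover", kind = "categorical"),
       elevation = mk(eg, "elevation"))
}

#' Build a synthetic species table
#'
#' Species are Gaussian niches over the latent fields. Non-context species
#' have a narrow optimum on temperature (the primary axis), a moderate one
#' on moisture and a wide one on elevation. Context species instead depend
#' on terrain roughness - the local standard deviation of elevation within
#' `contextRadius` - a neighborhood statistic invisible to point-value
#' models. Niche optima double as the species trait table.
#'
#' @param nSpecies total number of species.
#' @param nContext how many of them are context-dependent.
#' @param seed RNG seed.
#' @param prevalence per-species relative abundance (recycled); default equal.
#' @return data.frame with one row per species: `species_id`, `prevalence`,
#'   `context`, and `mu_` / `sd_` columns per niche axis (`temperature`,
#'   `moisture`, `elevation`, `roughness`). Unused axes have infinite `sd_`
#'   (no constraint) and `NA` optima.
#' @export
syntheticSpecies <- function(nSpecies = 20, nContext = 8, seed = 1,
                             prevalence = 1) {
  stopifnot(nSpecies >= 2, nContext >= 0, nContext <= nSpecies)
  set.seed(seed)
  ctx <- rep(c(FALSE, TRUE), c(nSpecies - nContext, nContext))
  sp <- data.frame(species_id = seq_len(nSpecies),
                   prevalence = rep_len(prevalence, nSpecies),
                   context = ctx)
  # standardized fields: optima spread over the central range
  nPlain <- nSpecies - nContext
  muT <- rep(NA_real_, nSpecies)
  if (nPlain > 0)  # evenly spread optima along the gradient, shuffled
    muT[!ctx] <- seq(-1.5, 1.5, length.out = nPlain)[sample(nPlain)]
  sp$mu_temperature <- muT
  sp$sd_temperature <- ifelse(ctx, Inf, 0.30)
  sp$mu_moisture <- ifelse(ctx, NA, runif(nSpecies, -1.2, 1.2))
  sp$sd_moisture <- ifelse(ctx, Inf, 0.60)
  sp$mu_elevation <- ifelse(ctx, NA, runif(nSpecies, -1, 1))
  sp$sd_elevation <- ifelse(ctx, Inf, 1.20)
  # roughness optima are filled against the realized roughness field when
  # the world is assembled; placeholders here keep the table complete
  sp$mu_roughness <- NA_real_
  sp$sd_roughness <- ifelse(ctx, 0.25, Inf)
  sp
}

#' Ground-truth habitat suitability of one species at given conditions
#'
#' Product over niche axes of Gaussian responses
#' \eqn{\exp(-(v - \mu)^2 / (2\sigma^2))}; axes with infinite breadth do not
#' constrain. Context species substitute the `roughness` neighborhood
#' statistic for the point elevation value.
#'
#' @param species one row of the species table.
#' @param values named list/vector of axis values (`temperature`,
#'   `moisture`, `elevation`, `roughness`); entries may be matrices.
#' @return suitability in (0, 1], same shape as the inputs.
#' @export
nicheSuitability <- function(species, values) {
  axes <- c("temperature", "moisture", "elevation", "roughness")
  out <- NULL
  for (a in axes) {
    mu <- species[[paste0("mu_", a)]]
    sdv <- species[[paste0("sd_", a)]]
    if (is.null(sdv) || !is.finite(sdv)) next
    if (is.na(mu)) next
    v <- values[[a]]
    if (is.null(v)) stop("axis '", a, "' required but not supplied")
    g <- exp(-(v - mu)^2 / (2 * sdv^2))
    out <- if (is.null(out)) g else out * g
  }
  if (is.null(out)) {
    v <- values[[1]]
    out <- array(1, dim = dim(v) %||% length(v))
  }
  out
}

#' Observation-effort field
#'
#' Uniform by default; `"roadside"` adds a high-effort vertical stripe
#' through the middle of the world, mimicking roadside bias in
#' citizen-science sampling.
#'
#' @param template a [RasterLayer-class] defining the grid.
#' @param type `"uniform"` or `"roadside"`.
#' @param roadWidth stripe width (m).
#' @param bias multiplicative effort on the stripe.
#' @return a [RasterLayer-class] of positive effort weights.
#' @export
effortField <- function(template, type = c("uniform", "roadside"),
                        roadWidth = 50, bias = 10) {
  type <- match.arg(type)
  g <- matrix(1, nrow(template@grid), ncol(template@grid))
  if (type == "roadside") {
    e <- rasterExtent(template)
    xc <- e["xmin"] + (seq_len(ncol(g)) - 0.5) * template@resolution
    mid <- (e["xmin"] + e["xmax"]) / 2
    g[, abs(xc - mid) <= roadWidth / 2] <- bias
  }
  rasterLayer(g, resolution = template@resolution, origin = template@origin,
              kind = "continuous", name = "effort")
}

#' Sample occurrences from a synthetic world
#'
#' Species-then-location sampling: each record first draws a species with
#' probability proportional to prevalence, then a pixel with probability
#' proportional to suitability times effort, restricted to the interior
#' margin so patches never cross the world border. Coordinates are snapped
#' to pixel centers. Species whose intensity is identically zero are
#' skipped with a warning.
#'
#' @param suitGrids list (per species) of suitability matrices.
#' @param species species table.
#' @param template [RasterLayer-class] defining the grid geometry.
#' @param nTotal number of occurrences to draw.
#' @param effort effort [RasterLayer-class] or `NULL` for uniform.
#' @param marginPx border margin in pixels excluded from sampling.
#' @param seed RNG seed.
#' @return data.frame `occ_id, species_id, x, y, split` (split = "train").
#' @export
sampleOccurrences <- function(suitGrids, species, template, nTotal,
                              effort = NULL, marginPx = 0, seed = 1) {
  set.seed(seed)
  if (nTotal == 0)
    return(data.frame(occ_id = integer(), species_id = integer(),
                      x = numeric(), y = numeric(), split = character()))
  n <- nrow(template@grid); p <- ncol(template@grid)
  eff <- if (is.null(effort)) matrix(1, n, p) else effort@grid
  mask <- matrix(0, n, p)
  ri <- (marginPx + 1):(n - marginPx); ci <- (marginPx + 1):(p - marginPx)
  mask[ri, ci] <- 1
  prev <- species$prevalence / sum(species$prevalence)
  counts <- as.vector(stats::rmultinom(1, nTotal, prev))
  recs <- vector("list", nrow(species))
  skipped <- 0L
  for (s in seq_len(nrow(species))) {
    if (counts[s] == 0) next
    w <- as.vector(suitGrids[[s]] * eff * mask)
    if (sum(w) <= 0) { skipped <- skipped + 1L; next }
    cells <- sample.int(length(w), counts[s], replace = TRUE, prob = w)
    row <- ((cells - 1) %% n) + 1
    col <- ((cells - 1) %/% n) + 1
    xy <- .cellCenter(template, row, col)
    recs[[s]] <- data.frame(species_id = species$species_id[s],
                            x = xy[, "x"], y = xy[, "y"])
  }
  if (skipped > 0)
    warning(skipped, " species skipped: all-zero sampling intensity")
  occ <- do.call(rbind, recs)
  occ <- occ[sample.int(nrow(occ)), , drop = FALSE]  # interleave species
  data.frame(occ_id = seq_len(nrow(occ)), species_id = occ$species_id,
             x = occ$x, y = occ$y, split = "train",
             row.names = NULL)
}

#' Generate a complete synthetic world
#'
#' Orchestrates [generateFields()], [deriveChannels()],
#' [syntheticSpecies()] and [sampleOccurrences()] into a
#' [SyntheticWorld-class] with exported ground truth. Defaults define the
#' package's reference study conditions: a 2 x 2 km landscape at 2 m/px,
#' 20 species of which 8 are context-dependent, 32 px patches and ~4,500
#' occurrences.
#'
#' @param extent world size (m).
#' @param resolution pixel size (m).
#' @param nSpecies,nContext species counts (see [syntheticSpecies()]).
#' @param classCount land-cover classes.
#' @param nOccurrences total occurrences sampled.
#' @param patchPx patch size; sampling keeps a margin of `patchPx/2` pixels.
#' @param contextRadius radius (m) of the roughness neighborhood statistic.
#' @param envResolution resolution (m) of the coarse environment rasters.
#' @param effortType `"uniform"` or `"roadside"` (see [effortField()]).
#' @param noiseAmp channel noise amplitude (see [deriveChannels()]).
#' @param seed RNG seed; the whole world is deterministic given the seed.
#' @return a [SyntheticWorld-class].
#' @export
syntheticWorld <- function(extent = 2000, resolution = 2, nSpecies = 20,
                           nContext = 8, classCount = 4,
                           nOccurrences = 4500, patchPx = 32,
                           contextRadius = 20, envResolution = 20,
                           effortType = "uniform", noiseAmp = 0.05,
                           seed = 1) {
  fields <- generateFields(extent, resolution, seed = seed)
  layers <- deriveChannels(fields, classCount = classCount,
                           seed = seed + 1L, noiseAmp = noiseAmp)
  rough <- .localSD(rasterGrid(fields$elevation),
                    radiusPx = max(1, round(contextRadius / resolution)))
  rough <- (rough - mean(rough)) / stats::sd(rough)
  fields$roughness <- rasterLayer(rough, resolution = resolution,
                                  origin = c(0, extent), name = "roughness")
  sp <- syntheticSpecies(nSpecies, nContext, seed = seed + 2L)
  # context optima spread over the realized roughness distribution
  set.seed(seed + 3L)
  if (nContext > 0) {
    qs <- (sample(seq_len(nContext)) - 0.5) / nContext
    sp$mu_roughness[sp$context] <- stats::quantile(rough, probs = qs)
  }
  gridVals <- list(temperature = rasterGrid(fields$temperature),
                   moisture = rasterGrid(fields$moisture),
                   elevation = rasterGrid(fields$elevation),
                   roughness = rough)
  suitGrids <- lapply(seq_len(nrow(sp)), function(s)
    nicheSuitability(sp[s, ], gridVals))
  eff <- if (effortType == "uniform") NULL else
    effortField(fields$temperature, type = effortType)
  occ <- sampleOccurrences(suitGrids, sp, fields$temperature, nOccurrences,
                           effort = eff, marginPx = ceiling(patchPx / 2),
                           seed = seed + 4L)
  idx <- .cellIndex(fields$temperature, occ$x, occ$y)
  truth <- data.frame(occ_id = occ$occ_id, species_id = occ$species_id)
  for (a in names(gridVals))
    truth[[a]] <- gridVals[[a]][cbind(idx[, "row"], idx[, "col"])]
  truth$suitability <- vapply(seq_len(nrow(occ)), function(j) {
    s <- match(occ$species_id[j], sp$species_id)
    nicheSuitability(sp[s, ], as.list(truth[j, c("temperature", "moisture",
                                                 "elevation", "roughness")]))
  }, numeric(1))
  # environment rasters emulate coarse climate/terrain products: they carry
  # the smooth elevation base only, so the fine relief (and hence the
  # roughness statistic) is visible to patch models but not to point values
  envSrc <- fields[c("temperature", "moisture", "elevation")]
  envSrc$elevation <- rasterLayer(attr(fields$elevation, "smoothBase"),
                                  resolution = resolution,
                                  origin = c(0, extent), name = "elevation")
  env <- lapply(envSrc, resampleLayer, targetResolution = envResolution)
  new("SyntheticWorld", extent = extent, resolution = resolution,
      fields = fields, layers = layers, envRasters = env,
      species = sp, occurrences = occ, truth = truth,
      params = list(seed = seed, classCount = classCount,
                    patchPx = patchPx, contextRadius = contextRadius,
                    margin = ceiling(patchPx / 2) * resolution,
                    envResolution = envResolution, noiseAmp = noiseAmp,
                    effortType = effortType))
}

#' Species trait table derived from niche optima
#'
#' The exported traits are the generating optima themselves (temperature,
#' moisture and elevation preference plus roughness preference for context
#' species), the synthetic analog of ordinal indicator values.
#'
#' @param world a [SyntheticWorld-class].
#' @return data.frame keyed by `species_id`.
#' @export
setMethod("speciesTraits", "SyntheticWorld", function(x, ...) {
  sp <- x@species
  data.frame(species_id = sp$species_id,
             trait_temperature = sp$mu_temperature,
             trait_moisture = sp$mu_moisture,
             trait_elevation = sp$mu_elevation,
             trait_roughness = sp$mu_roughness)
})

#' Write / read a synthetic world to a directory
#'
#' Channels and environment rasters go to ASCII grids, occurrences /
#' species / truth to CSV, the configuration echo to JSON.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return `dir` invisibly (write); a list with the re-read tables (read).
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(world@layers))
    writeAsciiGrid(world@layers[[nm]], file.path(dir, paste0("layer_", nm)))
  for (nm in names(world@envRasters))
    writeAsciiGrid(world@envRasters[[nm]], file.path(dir, paste0("env_", nm)))
  write.csv(world@occurrences, file.path(dir, "occurrences.csv"),
            row.names = FALSE)
  write.csv(world@species, file.path(dir, "species.csv"), row.names = FALSE)
  write.csv(world@truth, file.path(dir, "truth.csv"), row.names = FALSE)
  write.csv(speciesTraits(world), file.path(dir, "traits.csv"),
            row.names = FALSE)
  jsonlite::write_json(world@params, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeWorld
#' @export
readWorld <- function(dir) {
  layerFiles <- sub("\\.asc$", "", list.files(dir, "^layer_.*\\.asc$",
                                              full.names = TRUE))
  envFiles <- sub("\\.asc$", "", list.files(dir, "^env_.*\\.asc$",
                                            full.names = TRUE))
  layers <- lapply(layerFiles, readAsciiGrid)
  names(layers) <- sub("^layer_", "", basename(layerFiles))
  env <- lapply(envFiles, readAsciiGrid)
  names(env) <- sub("^env_", "", basename(envFiles))
  list(layers = layers, envRasters = env,
       occurrences = read.csv(file.path(dir, "occurrences.csv")),
       species = read.csv(file.path(dir, "species.csv")),
       truth = read.csv(file.path(dir, "truth.csv")),
       traits = read.csv(file.path(dir, "traits.csv")),
       params = jsonlite::read_json(file.path(dir, "config.json"),
                                    simplifyVector = TRUE))
}
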