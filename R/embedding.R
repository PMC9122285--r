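# Feature-space interpretation: PCA + t-SNE reduction, mosaics of the
# embedding, bilinear color gradients projected onto geography, 3-D
# embeddings as RGB, and per-axis linear models against traits or
# environment.

# Conditional Gaussian affinities with per-point bandwidth calibrated by
# bisection to a target perplexity (standard t-SNE input stage).
.perplexityAffinities <- function(D2, perplexity, tol = 1e-5,
                                  maxTries = 50) {
  n <- nrow(D2)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; betaMin <- -Inf; betaMax <- Inf
    di <- D2[i, -i]
    for (try in seq_len(maxTries)) {
      p <- exp(-di * beta)
      sumP <- sum(p)
      if (sumP == 0) sumP <- 1e-12
      H <- log(sumP) + beta * sum(di * p) / sumP
      diff <- H - logU
      if (abs(diff) < tol) break
      if (diff > 0) {
        betaMin <- beta
        beta <- if (is.finite(betaMax)) (beta + betaMax) / 2 else beta * 2
      } else {
        betaMax <- beta
        beta <- if (is.finite(betaMin)) (beta + betaMin) / 2 else beta / 2
      }
    }
    P[i, -i] <- p / max(sum(p), 1e-12)
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

# Exact t-SNE. Deterministic given the input order and the R RNG state
# (used only for the initial layout).
.tsne <- function(X, dims = 2, perplexity = 30, maxIter = 500, lr = 200,
                  exaggeration = 12, exagIter = 100) {
  n <- nrow(X)
  if (perplexity >= (n - 1) / 3)
    perplexity <- max(2, floor((n - 1) / 3))
  D2 <- as.matrix(stats::dist(X))^2
  P <- .perplexityAffinities(D2, perplexity)
  Y0 <- matrix(rnorm(n * dims, sd = 1e-4), n, dims)
  cpp_tsne_grad(P, Y0, as.integer(maxIter), lr, exaggeration,
                as.integer(exagIter), 0.5, 0.8, 20L)
}

#' Reduce feature vectors to a 2-D or 3-D embedding
#'
#' Optionally subsamples the occurrences (seeded), optionally reduces to 50
#' principal components first (recommended for high-dimensional features),
#' then runs t-SNE to 2 or 3 dimensions by minimizing the
#' Kullback-Leibler divergence between input- and embedding-space
#' neighbor distributions. Deterministic given the seed and settings.
#'
#' @param features N x d matrix (rownames = occ ids).
#' @param outDim 2 or 3.
#' @param pcaDim PCA dimension before t-SNE (`NULL` or `0` skips PCA; the
#'   3-D map variant conventionally skips it).
#' @param sampleSize seeded subsample size (`NULL` = all rows).
#' @param seed RNG seed.
#' @param perplexity,maxIter,lr t-SNE settings.
#' @return data.frame `occ_id, tsne_1, tsne_2[, tsne_3]`, one row per
#'   embedded occurrence.
#' @export
reduceFeatures <- function(features, outDim = 2, pcaDim = 50,
                           sampleSize = NULL, seed = 1, perplexity = 30,
                           maxIter = 500, lr = 200) {
  if (!outDim %in% c(2, 3)) stop("outDim must be 2 or 3")
  set.seed(seed)
  ids <- rownames(features) %||% as.character(seq_len(nrow(features)))
  if (!is.null(sampleSize)) {
    if (sampleSize > nrow(features))
      stop("sampleSize exceeds the number of feature vectors")
    keep <- sort(sample.int(nrow(features), sampleSize))
    features <- features[keep, , drop = FALSE]
    ids <- ids[keep]
  }
  X <- scale(features, center = TRUE, scale = FALSE)
  if (!is.null(pcaDim) && pcaDim > 0 && pcaDim < ncol(X)) {
    pc <- stats::prcomp(X, center = FALSE, rank. = pcaDim)
    X <- pc$x
  }
  Y <- .tsne(X, dims = outDim, perplexity = perplexity,
             maxIter = maxIter, lr = lr)
  out <- data.frame(occ_id = ids, Y)
  names(out)[-1] <- paste0("tsne_", seq_len(outDim))
  out
}

.embeddingCoords <- function(embedding) {
  as.matrix(embedding[, grep("^tsne_", names(embedding)), drop = FALSE])
}

#' Discretize an embedding into an occupancy mosaic
#'
#' Overlays an n x n grid on the embedding bounding box; each cell with at
#' least one occurrence is occupied by the in-cell occurrence closest
#' (Euclidean) to the cell center. Cells without occurrences stay empty.
#'
#' @param embedding 2-D embedding from [reduceFeatures()].
#' @param n number of discretizations per axis.
#' @param payload optional function(occ_id) evaluated on each occupant
#'   (e.g. returning an RGB patch, a trait or an environment value).
#' @return data.frame `row, col, occ_id, dist` (one row per occupied cell;
#'   `row` 1 is the top of the embedding), with grid geometry in
#'   attributes; a `payload` list-column if requested.
#' @export
buildMosaic <- function(embedding, n, payload = NULL) {
  if (nrow(embedding) == 0) stop("empty embedding")
  stopifnot(n >= 1)
  Y <- .embeddingCoords(embedding)[, 1:2, drop = FALSE]
  rngX <- range(Y[, 1]); rngY <- range(Y[, 2])
  w <- max(rngX[2] - rngX[1], 1e-12) / n
  h <- max(rngY[2] - rngY[1], 1e-12) / n
  col <- pmin(floor((Y[, 1] - rngX[1]) / w) + 1, n)
  row <- pmin(floor((rngY[2] - Y[, 2]) / h) + 1, n)
  cx <- rngX[1] + (col - 0.5) * w
  cy <- rngY[2] - (row - 0.5) * h
  d <- sqrt((Y[, 1] - cx)^2 + (Y[, 2] - cy)^2)
  ord <- order(row, col, d)
  first <- !duplicated(paste(row, col)[ord])
  sel <- ord[first]
  out <- data.frame(row = row[sel], col = col[sel],
                    occ_id = embedding$occ_id[sel], dist = d[sel])
  if (!is.null(payload)) out$payload <- lapply(out$occ_id, payload)
  attr(out, "n") <- n
  attr(out, "bbox") <- c(xmin = rngX[1], xmax = rngX[2],
                         ymin = rngY[1], ymax = rngY[2])
  out
}

#' Bilinear color gradient over a 2-D embedding
#'
#' Normalizes the embedding to the unit square via its bounding box and
#' colors each point by bilinear interpolation of four corner colors, so
#' color varies continuously with embedding position.
#'
#' @param embedding 2-D embedding from [reduceFeatures()].
#' @param cornerColors 4 x 3 matrix of RGB in [0, 1], rows = lower-left,
#'   lower-right, upper-left, upper-right. Defaults to four maximally
#'   distinct colors.
#' @return N x 3 matrix of RGB values in [0, 1].
#' @export
bilinearEmbeddingColors <- function(embedding,
                                    cornerColors = rbind(c(0, 0, 1),
                                                         c(1, 0, 0),
                                                         c(0, 1, 0),
                                                         c(1, 1, 0))) {
  Y <- .embeddingCoords(embedding)
  if (ncol(Y) != 2) stop("bilinear gradient requires a 2-D embedding")
  rngX <- range(Y[, 1]); rngY <- range(Y[, 2])
  if (diff(rngX) == 0 || diff(rngY) == 0)
    stop("degenerate embedding: zero extent on an axis")
  u <- (Y[, 1] - rngX[1]) / diff(rngX)
  v <- (Y[, 2] - rngY[1]) / diff(rngY)
  out <- sapply(1:3, function(ch) {
    (1 - u) * (1 - v) * cornerColors[1, ch] +
      u * (1 - v) * cornerColors[2, ch] +
      (1 - u) * v * cornerColors[3, ch] +
      u * v * cornerColors[4, ch]
  })
  colnames(out) <- c("r", "g", "b")
  out
}

#' Project embedding colors onto geographic space
#'
#' Lays a regular grid of points over the territory and colors each grid
#' point by its geographically nearest embedded occurrence (planar 1-NN),
#' producing a color raster of the learned ecological regions.
#'
#' @param occ data.frame with `x`, `y` for the embedded occurrences.
#' @param colors N x 3 RGB matrix aligned with `occ` rows (e.g. from
#'   [bilinearEmbeddingColors()]).
#' @param step grid step in coordinate units.
#' @param bounds `c(xmin, xmax, ymin, ymax)`; defaults to the occurrence
#'   bounding box.
#' @return list of three [RasterLayer-class] (`r`, `g`, `b`) at resolution
#'   `step`.
#' @export
geographicProjection <- function(occ, colors, step, bounds = NULL) {
  if (nrow(occ) == 0) stop("empty occurrence set")
  if (is.null(bounds))
    bounds <- c(min(occ$x), max(occ$x), min(occ$y), max(occ$y))
  xs <- seq(bounds[1], bounds[2], by = step)
  ys <- seq(bounds[3], bounds[4], by = step)
  pts <- cbind(x = rep(xs, times = length(ys)),
               y = rep(rev(ys), each = length(xs)))  # row 1 = north
  nn <- as.integer(as.character(class::knn1(occ[, c("x", "y")], pts,
                                            cl = factor(seq_len(nrow(occ))))))
  mk <- function(ch, nm) rasterLayer(
    matrix(colors[nn, ch], nrow = length(ys), byrow = TRUE),
    resolution = step,
    origin = c(bounds[1] - step / 2, max(ys) + step / 2),
    kind = "continuous", name = nm)
  list(r = mk(1, "r"), g = mk(2, "g"), b = mk(3, "b"))
}

#' Map a 3-D embedding to RGB colors
#'
#' Rescales each embedding axis to [0, 255] by min-max and reads the three
#' axes as (R, G, B), so embedding position becomes color directly.
#'
#' @param embedding 3-D embedding from [reduceFeatures()].
#' @return N x 3 matrix of values in [0, 255].
#' @export
embedding3ToRGB <- function(embedding) {
  Y <- .embeddingCoords(embedding)
  if (ncol(Y) != 3) stop("requires a 3-D embedding")
  out <- apply(Y, 2, function(v) {
    r <- range(v)
    if (diff(r) == 0) stop("constant embedding axis: RGB rescale undefined")
    (v - r[1]) / diff(r) * 255
  })
  colnames(out) <- c("r", "g", "b")
  out
}

# Predictors that are exact differences of two others (like a temperature
# annual range defined as max minus min) are dropped before regression.
# Such a dependency is symmetric (if a = b - c then b = a + c), so the
# exclusion is minimal: one column per dependency, preferring the
# latest-declared column, matching the convention that derived variables
# are declared after their components.
.findDerivedDifferences <- function(df, tol = 1e-8) {
  nms <- names(df)
  alive <- rep(TRUE, length(nms))
  dropped <- character()
  repeat {
    cand <- integer()
    idx <- which(alive)
    for (i in idx) {
      found <- FALSE
      for (j in idx) {
        for (k in idx) {
          if (length(unique(c(i, j, k))) < 3) next
          if (max(abs(df[[i]] - (df[[j]] - df[[k]]))) < tol) {
            found <- TRUE; break
          }
        }
        if (found) break
      }
      if (found) cand <- c(cand, i)
    }
    if (!length(cand)) break
    drop <- max(cand)
    alive[drop] <- FALSE
    dropped <- c(dropped, nms[drop])
  }
  dropped
}

#' Linear models of embedding axes on traits or environment
#'
#' Fits an ordinary least-squares model per embedding axis with the given
#' predictor table, reporting estimates, standard errors, two-sided
#' p-values with significance stars, R-squared and adjusted R-squared. Rows
#' with missing predictors are dropped (and counted). With
#' `predictorSet = "environment"`, any predictor that is an exact
#' difference of two others is excluded automatically before fitting.
#'
#' @param embedding embedding from [reduceFeatures()].
#' @param predictors data.frame of predictors aligned with embedding rows
#'   (same order and length).
#' @param predictorSet `"traits"` or `"environment"`.
#' @return list of class `AxisRegressionReport`: per-axis data.frames of
#'   coefficients, `r2`/`adj_r2`/F-test `p_value` per axis, `dropped` (rows
#'   lost to missingness) and `excluded` (predictors removed).
#' @export
axisLinearModels <- function(embedding, predictors,
                             predictorSet = c("traits", "environment")) {
  predictorSet <- match.arg(predictorSet)
  Y <- .embeddingCoords(embedding)
  stopifnot(nrow(predictors) == nrow(Y))
  excluded <- character()
  if (predictorSet == "environment") {
    complete <- predictors[complete.cases(predictors), , drop = FALSE]
    excluded <- .findDerivedDifferences(complete)
    predictors <- predictors[, setdiff(names(predictors), excluded),
                             drop = FALSE]
  }
  keep <- complete.cases(predictors)
  dropped <- sum(!keep)
  predictors <- predictors[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  axes <- lapply(seq_len(ncol(Y)), function(a) {
    df <- data.frame(..axis = Y[, a], predictors)
    fit <- lm(..axis ~ ., data = df)
    if (anyNA(stats::coef(fit)))
      stop("rank-deficient design; collinear columns: ",
           paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
    sm <- summary(fit)
    co <- as.data.frame(sm$coefficients)
    names(co) <- c("estimate", "std_error", "t_value", "p_value")
    co$stars <- cut(co$p_value, c(-Inf, 0.01, 0.05, 0.1, Inf),
                    labels = c("***", "**", "*", ""))
    fstat <- sm$fstatistic
    list(coefficients = data.frame(term = rownames(co), co,
                                   row.names = NULL),
         r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
         p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                    lower.tail = FALSE)))
  })
  names(axes) <- colnames(Y)
  structure(list(axes = axes, predictorSet = predictorSet,
                 dropped = dropped, excluded = excluded),
            class = "AxisRegressionReport")
}

#' @export
print.AxisRegressionReport <- function(x, ...) {
  cat(sprintf("Axis linear models (%s predictors); %d rows dropped%s\n",
              x$predictorSet, x$dropped,
              if (length(x$excluded))
                paste0("; excluded: ", paste(x$excluded, collapse = ", "))
              else ""))
  for (nm in names(x$axes)) {
    a <- x$axes[[nm]]
    cat(sprintf("  %s: R2 = %.3f, adj R2 = %.3f, F-test p = %.3g\n",
                nm, a$r2, a$adj_r2, a$p_value))
  }
  invisible(x)
}
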