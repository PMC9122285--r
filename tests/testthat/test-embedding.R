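test_that("dimension reduction is deterministic and validates arguments", {
  set.seed(1)
  X <- matrix(rnorm(60 * 10), 60, 10)
  e1 <- reduceFeatures(X, outDim = 2, pcaDim = 5, seed = 4, maxIter = 120)
  e2 <- reduceFeatures(X, outDim = 2, pcaDim = 5, seed = 4, maxIter = 120)
  expect_identical(e1, e2)
  expect_named(e1, c("occ_id", "tsne_1", "tsne_2"))
  e3 <- reduceFeatures(X, outDim = 3, pcaDim = NULL, seed = 4,
                       maxIter = 120)
  expect_named(e3, c("occ_id", "tsne_1", "tsne_2", "tsne_3"))
  expect_error(reduceFeatures(X, outDim = 4), "outDim")
  expect_error(reduceFeatures(X, sampleSize = 1000), "sampleSize")
})

test_that("t-SNE keeps well-separated clusters apart", {
  set.seed(2)
  n <- 80
  X <- rbind(matrix(rnorm(n * 8, 0), n, 8), matrix(rnorm(n * 8, 6), n, 8))
  lab <- rep(1:2, each = n)
  emb <- reduceFeatures(X, outDim = 2, pcaDim = NULL, seed = 5,
                        maxIter = 300)
  Y <- as.matrix(emb[, 2:3])
  D <- as.matrix(dist(Y))
  sil <- vapply(seq_len(nrow(Y)), function(i) {
    same <- lab == lab[i]
    a <- sum(D[i, same]) / (sum(same) - 1)  # excludes the zero self-term
    b <- mean(D[i, !same])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gte(mean(sil), 0.2)
})

test_that("a 50-component PCA preamble preserves pairwise geometry", {
  set.seed(3)
  n <- 150
  basis <- matrix(rnorm(10 * 300), 10, 300)
  X <- matrix(rnorm(n * 10), n, 10) %*% basis  # intrinsic dimension 10
  Xc <- scale(X, center = TRUE, scale = FALSE)
  pc <- prcomp(Xc, center = FALSE, rank. = 50)
  dFull <- as.vector(dist(Xc))
  dPca <- as.vector(dist(pc$x))
  expect_gte(cor(dFull, dPca), 0.99)
})

test_that("mosaic occupancy matches the brute-force oracle", {
  set.seed(6)
  for (i in 1:5) {
    emb <- data.frame(occ_id = 1:300, tsne_1 = runif(300, -5, 5),
                      tsne_2 = runif(300, -3, 7))
    mos <- buildMosaic(emb, n = 8)
    oracle <- oracleMosaic(emb, 8)
    got <- mos[order(mos$row, mos$col), c("row", "col", "occ_id")]
    want <- oracle[order(oracle$row, oracle$col), ]
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("mosaic picks the in-cell occurrence nearest the cell center", {
  # unit square embedding, one cell (n = 1); center is (0.5, 0.5)
  emb <- data.frame(occ_id = c("far", "near", "corner1", "corner2"),
                    tsne_1 = c(0.9, 0.55, 0, 1),
                    tsne_2 = c(0.9, 0.45, 0, 1))
  mos <- buildMosaic(emb, n = 1)
  expect_equal(nrow(mos), 1)
  expect_equal(mos$occ_id, "near")
  # an occurrence exactly at a cell center occupies that cell
  emb2 <- data.frame(occ_id = c("a", "center", "b"),
                     tsne_1 = c(0, 0.5, 1), tsne_2 = c(0, 0.5, 1))
  mos2 <- buildMosaic(emb2, n = 1)
  expect_equal(mos2$occ_id, "center")
  expect_error(buildMosaic(emb[0, ], 4), "empty")
  # unoccupied cells are simply absent
  emb3 <- data.frame(occ_id = 1:2, tsne_1 = c(0, 1), tsne_2 = c(0, 1))
  mos3 <- buildMosaic(emb3, n = 4)
  expect_lte(nrow(mos3), 2)
  # payload selector is applied to occupants
  mos4 <- buildMosaic(emb2, n = 1, payload = function(id) paste0("p_", id))
  expect_equal(mos4$payload[[1]], "p_center")
})

test_that("bilinear embedding colors interpolate the corner colors", {
  corners <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  emb <- data.frame(occ_id = 1:6,
                    tsne_1 = c(0, 1, 0, 1, 0.5, 0.25),
                    tsne_2 = c(0, 0, 1, 1, 0.5, 0))
  cols <- bilinearEmbeddingColors(emb, corners)
  expect_equal(cols[1, ], c(r = 0, g = 0, b = 1))    # lower-left corner
  expect_equal(cols[2, ], c(r = 1, g = 0, b = 0))    # lower-right corner
  expect_equal(cols[3, ], c(r = 0, g = 1, b = 0))
  expect_equal(cols[4, ], c(r = 1, g = 1, b = 0))
  expect_equal(cols[5, ], colMeans(corners),
               ignore_attr = TRUE)                   # bbox center
  # along the bottom edge colors interpolate linearly between ll and lr
  expect_equal(cols[6, ], 0.75 * corners[1, ] + 0.25 * corners[2, ],
               ignore_attr = TRUE)
  degenerate <- data.frame(occ_id = 1:3, tsne_1 = c(1, 1, 1),
                           tsne_2 = c(0, 1, 2))
  expect_error(bilinearEmbeddingColors(degenerate), "degenerate")
})

test_that("geographic projection equals a brute-force nearest-neighbor scan", {
  set.seed(8)
  occ <- data.frame(x = runif(40, 0, 100), y = runif(40, 0, 100))
  cols <- matrix(runif(120), 40, 3)
  proj <- geographicProjection(occ, cols, step = 7)
  e <- rasterExtent(proj$r)
  xs <- seq(min(occ$x), max(occ$x), by = 7)
  ys <- seq(min(occ$y), max(occ$y), by = 7)
  queries <- data.frame(x = rep(xs, times = length(ys)),
                        y = rep(rev(ys), each = length(xs)))
  nn <- oracleNN(occ, queries)
  want <- matrix(cols[nn, 1], nrow = length(ys), byrow = TRUE)
  expect_equal(rasterGrid(proj$r), want)
})

test_that("geographic projection degenerate cases", {
  one <- data.frame(x = 5, y = 5)
  proj <- geographicProjection(one, matrix(c(0.2, 0.4, 0.6), 1), step = 2,
                               bounds = c(0, 10, 0, 10))
  expect_true(all(rasterGrid(proj$g) == 0.4))
  # a grid point coincident with an occurrence takes its color
  two <- data.frame(x = c(0, 10), y = c(0, 0))
  cols <- rbind(c(1, 0, 0), c(0, 1, 0))
  proj2 <- geographicProjection(two, cols, step = 4,
                                bounds = c(0, 10, 0, 0.1))
  g <- rasterGrid(proj2$r)
  # the map partitions along the perpendicular bisector at x = 5:
  # grid points 0 and 4 take the first color, 8 the second
  expect_equal(as.numeric(g[1, ]), c(1, 1, 0))
  expect_error(geographicProjection(one[0, ], matrix(0, 0, 3), 1), "empty")
})

test_that("3-D embeddings rescale to RGB by per-axis min-max", {
  emb <- data.frame(occ_id = 1:3,
                    tsne_1 = c(0, 5, 10), tsne_2 = c(-2, 0, 2),
                    tsne_3 = c(1, 2, 3))
  rgb <- embedding3ToRGB(emb)
  expect_equal(rgb[1, ], c(r = 0, g = 0, b = 0))
  expect_equal(rgb[3, ], c(r = 255, g = 255, b = 255))
  expect_equal(rgb[2, ], c(r = 127.5, g = 127.5, b = 127.5))
  # invariance under per-axis positive affine transforms
  emb2 <- emb
  emb2$tsne_1 <- emb$tsne_1 * 3 + 10
  emb2$tsne_2 <- emb$tsne_2 * 0.5 - 4
  expect_equal(embedding3ToRGB(emb2), rgb)
  emb3 <- emb; emb3$tsne_2 <- 1
  expect_error(embedding3ToRGB(emb3), "constant")
  expect_error(embedding3ToRGB(emb[, 1:3]), "3-D")
})

test_that("axis regressions recover exact linear structure", {
  set.seed(9)
  pred <- data.frame(a = rnorm(50), b = rnorm(50))
  emb <- data.frame(occ_id = 1:50,
                    tsne_1 = 2 * pred$a - 3 * pred$b + 1,
                    tsne_2 = pred$a + pred$b)
  rep <- suppressWarnings(axisLinearModels(emb, pred,
                                           predictorSet = "traits"))
  expect_equal(rep$axes$tsne_1$r2, 1, tolerance = 1e-10)
  co <- rep$axes$tsne_1$coefficients
  expect_equal(co$estimate[co$term == "a"], 2, tolerance = 1e-8)
  expect_equal(co$estimate[co$term == "b"], -3, tolerance = 1e-8)
  expect_lte(rep$axes$tsne_1$adj_r2, rep$axes$tsne_1$r2 + 1e-12)
})

test_that("pure-noise predictors explain nothing", {
  set.seed(10)
  n <- 1000
  pred <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  emb <- data.frame(occ_id = 1:n, tsne_1 = rnorm(n), tsne_2 = rnorm(n))
  rep <- axisLinearModels(emb, pred, predictorSet = "traits")
  expect_lte(rep$axes$tsne_1$adj_r2, 0.02)
  expect_lte(rep$axes$tsne_2$adj_r2, 0.02)
})

test_that("four-point OLS matches the hand-solved normal equations", {
  # y = b0 + b1 x on points (0,1), (1,3), (2,3), (3,5):
  # X'X = [[4, 6], [6, 14]], X'y = [12, 24] -> b = (1.2, 1.2)
  emb <- data.frame(occ_id = 1:4, tsne_1 = c(1, 3, 3, 5),
                    tsne_2 = c(0, 0, 0, 1))
  pred <- data.frame(x = c(0, 1, 2, 3))
  rep <- axisLinearModels(emb, pred, predictorSet = "traits")
  co <- rep$axes$tsne_1$coefficients
  expect_equal(co$estimate[co$term == "(Intercept)"], 1.2,
               tolerance = 1e-10)
  expect_equal(co$estimate[co$term == "x"], 1.2, tolerance = 1e-10)
})

test_that("difference-derived predictors are excluded, collinearity errors", {
  set.seed(11)
  n <- 60
  pred <- data.frame(bio5 = rnorm(n), bio6 = rnorm(n))
  pred$bio7 <- pred$bio5 - pred$bio6
  pred$soil <- rnorm(n)
  emb <- data.frame(occ_id = 1:n, tsne_1 = rnorm(n), tsne_2 = rnorm(n))
  rep <- axisLinearModels(emb, pred, predictorSet = "environment")
  expect_equal(rep$excluded, "bio7")
  expect_false("bio7" %in% rep$axes$tsne_1$coefficients$term)
  # duplicated column: rank deficiency is reported, not silently dropped
  pred2 <- data.frame(a = rnorm(n))
  pred2$b <- pred2$a
  expect_error(axisLinearModels(emb, pred2, predictorSet = "traits"),
               "collinear")
})

test_that("rows with missing predictors are dropped and counted", {
  set.seed(12)
  pred <- data.frame(a = c(NA, rnorm(29)))
  emb <- data.frame(occ_id = 1:30, tsne_1 = rnorm(30), tsne_2 = rnorm(30))
  rep <- axisLinearModels(emb, pred, predictorSet = "traits")
  expect_equal(rep$dropped, 1)
})
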