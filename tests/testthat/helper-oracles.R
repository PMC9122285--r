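# Independent brute-force oracles used to cross-check the package's metric
# and geometry implementations. These deliberately use a different
# computational path (explicit sorting, all-pairs enumeration, full scans).

# Rank of the true species by explicitly sorting scores descending, with
# the true species ordered after its ties (pessimistic rule).
oracleRank <- function(scores, trueIdx) {
  isTrue <- seq_along(scores) == trueIdx
  ord <- order(-scores, isTrue)  # among equal scores, true species last
  which(ord == trueIdx)
}

oracleTopK <- function(ranks, k) sum(ranks <= k) / length(ranks)

oracleMSA <- function(ranks, species, k) {
  specs <- unique(species)
  sa <- vapply(specs, function(s) {
    r <- ranks[species == s]
    sum(r <= k) / length(r)
  }, numeric(1))
  mean(sa)
}

# AUC by enumerating every presence-absence pair; ties count one half.
oracleAUC <- function(pres, abs) {
  wins <- 0
  for (p in pres) for (a in abs)
    wins <- wins + if (p > a) 1 else if (p == a) 0.5 else 0
  wins / (length(pres) * length(abs))
}

# Nearest embedded occurrence for each query point, by full scan.
oracleNN <- function(occ, queries) {
  vapply(seq_len(nrow(queries)), function(i) {
    d <- (occ$x - queries$x[i])^2 + (occ$y - queries$y[i])^2
    which.min(d)
  }, integer(1))
}

# Mosaic occupancy by scanning all occurrences for each cell.
oracleMosaic <- function(emb, n) {
  Y <- as.matrix(emb[, c("tsne_1", "tsne_2")])
  rngX <- range(Y[, 1]); rngY <- range(Y[, 2])
  w <- max(rngX[2] - rngX[1], 1e-12) / n
  h <- max(rngY[2] - rngY[1], 1e-12) / n
  out <- list()
  for (row in seq_len(n)) for (col in seq_len(n)) {
    cx <- rngX[1] + (col - 0.5) * w
    cy <- rngY[2] - (row - 0.5) * h
    colIdx <- pmin(floor((Y[, 1] - rngX[1]) / w) + 1, n)
    rowIdx <- pmin(floor((rngY[2] - Y[, 2]) / h) + 1, n)
    inCell <- which(colIdx == col & rowIdx == row)
    if (!length(inCell)) next
    d <- sqrt((Y[inCell, 1] - cx)^2 + (Y[inCell, 2] - cy)^2)
    out[[length(out) + 1]] <- data.frame(
      row = row, col = col, occ_id = emb$occ_id[inCell[which.min(d)]])
  }
  do.call(rbind, out)
}

# Mean absolute difference between 4-neighbors: the roughness statistic
# used for field-smoothness checks.
neighborRoughness <- function(g) {
  mean(c(abs(diff(g)), abs(t(diff(t(g))))))
}

# A small fully-assembled world shared by tests that need one; built once.
smallWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- syntheticWorld(extent = 400, resolution = 2, nSpecies = 6,
                               nContext = 2, nOccurrences = 600,
                               patchPx = 16, seed = 11)
    cache
  }
})
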