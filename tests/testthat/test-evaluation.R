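test_that("true-species ranks follow the pessimistic tie rule", {
  s <- matrix(c(0.5, 0.3, 0.3, 0.1), 1,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  expect_equal(rankTrueSpecies(s, "a"), 1L)
  expect_equal(rankTrueSpecies(s, "c"), 3L)  # second of the tied 0.3s
  expect_equal(rankTrueSpecies(s, "b"), 3L)  # ties share the last position
  flat <- matrix(rep(0.25, 4), 1, dimnames = list(NULL, letters[1:4]))
  expect_equal(rankTrueSpecies(flat, "b"), 4L)
  expect_error(rankTrueSpecies(s, "zz"), "unknown species")
})

test_that("top-k accuracy matches hand enumeration and its bounds", {
  expect_equal(topKAccuracy(c(1, 3, 5), k = 3), 2 / 3)
  expect_equal(topKAccuracy(1:7, k = 99), 1.0)
  expect_equal(topKAccuracy(1:7, k = 0), 0.0)
  expect_error(topKAccuracy(integer(), 3), "empty")
})

test_that("species-wise accuracy weights species, not occurrences", {
  ranks <- c(1, 99, 2)
  species <- c("A", "A", "B")
  out <- meanSpeciesTopK(ranks, species, k = 30)
  expect_equal(out$perSpecies$sa[out$perSpecies$species_id == "A"], 0.5)
  expect_equal(out$perSpecies$sa[out$perSpecies$species_id == "B"], 1.0)
  expect_equal(out$msa, 0.75)
  expect_equal(topKAccuracy(ranks, 30), 2 / 3)  # MSA != A_k
  # one occurrence per species: the two metrics coincide
  r2 <- c(1, 40, 2, 31)
  expect_equal(meanSpeciesTopK(r2, letters[1:4], 30)$msa,
               topKAccuracy(r2, 30))
  expect_equal(meanSpeciesTopK(c(1, 2, 3), c("a", "b", "c"), 5)$msa, 1)
})

test_that("metrics agree exactly with brute-force oracles", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(5:60, 1); S <- sample(2:20, 1)
    scores <- matrix(sample(seq(0, 1, 0.05), n * S, TRUE), n, S,
                     dimnames = list(NULL, paste0("s", seq_len(S))))
    true <- paste0("s", sample(S, n, TRUE))
    ranks <- rankTrueSpecies(scores, true)
    oracle <- vapply(seq_len(n), function(j)
      oracleRank(scores[j, ], match(true[j], colnames(scores))),
      integer(1))
    expect_identical(ranks, as.integer(oracle))
    k <- sample(S, 1)
    expect_identical(topKAccuracy(ranks, k), oracleTopK(oracle, k))
    expect_identical(meanSpeciesTopK(ranks, true, k)$msa,
                     oracleMSA(oracle, true, k))
  }
})

test_that("monotonicity of A_k and MSA_k in k, with A_S = 1", {
  set.seed(55)
  S <- 12; n <- 80
  scores <- matrix(rnorm(n * S), n, S,
                   dimnames = list(NULL, paste0("s", 1:S)))
  true <- paste0("s", sample(S, n, TRUE))
  ranks <- rankTrueSpecies(scores, true)
  a <- vapply(1:S, function(k) topKAccuracy(ranks, k), numeric(1))
  m <- vapply(1:S, function(k) meanSpeciesTopK(ranks, true, k)$msa,
              numeric(1))
  expect_true(all(diff(a) >= 0))
  expect_true(all(diff(m) >= 0))
  expect_equal(a[S], 1)
})

test_that("spatial block split never leaks quadrats and hits the target", {
  set.seed(3)
  occ <- data.frame(occ_id = 1:5000, x = runif(5000, 0, 500),
                    y = runif(5000, 0, 500),
                    species_id = sample(10, 5000, TRUE))
  sp <- spatialBlockSplit(occ, quadratSize = 25, testFraction = 0.1,
                          valFraction = 0.01, seed = 9)
  testQ <- unique(sp$quadrat[sp$split == "test"])
  expect_equal(sum(sp$split %in% c("train", "val") &
                     sp$quadrat %in% testQ), 0)
  frac <- mean(sp$split == "test")
  expect_gte(frac, 0.1)          # first crossing of the target
  expect_lt(frac, 0.15)          # quadrat granularity keeps it close
  expect_equal(sum(sp$split == "val"), round(0.01 * sum(sp$split != "test")))
  expect_error(spatialBlockSplit(occ, 0, 0.1), "quadratSize")
  expect_error(spatialBlockSplit(occ, 10, 1.5), "testFraction")
})

test_that("a single shared quadrat degenerates to an all-test split", {
  occ <- data.frame(occ_id = 1:20, x = runif(20, 0, 2),
                    y = runif(20, 0, 2))
  expect_warning(sp <- spatialBlockSplit(occ, quadratSize = 10,
                                         testFraction = 0.25, seed = 1),
                 "unachievable")
  expect_true(all(sp$split == "test"))
})

test_that("pseudo-absence counts follow the presence rule", {
  testOcc <- data.frame(
    occ_id = seq_len(30 + 150 + 40),
    species_id = rep(c("t30", "t150", "other"), c(30, 150, 40)))
  expect_length(drawPseudoAbsences("t30", testOcc, seed = 1), 100)
  expect_length(drawPseudoAbsences("t150", testOcc, seed = 1), 150)
  # drawn ids never belong to the target species
  ids <- drawPseudoAbsences("t30", testOcc, seed = 2)
  expect_true(all(testOcc$species_id[match(ids, testOcc$occ_id)] != "t30"))
  only <- testOcc[testOcc$species_id == "t30", ]
  expect_error(drawPseudoAbsences("t30", only, seed = 1), "eligible")
})

test_that("pseudo-absence draws are species-uniform, not occurrence-uniform", {
  testOcc <- data.frame(
    occ_id = seq_len(1 + 10 + 1000 + 5),
    species_id = rep(c("s1", "s10", "s1000", "target"), c(1, 10, 1000, 5)))
  set.seed(12)
  draws <- unlist(replicate(60, drawPseudoAbsences("target", testOcc),
                            simplify = FALSE))
  sp <- testOcc$species_id[match(draws, testOcc$occ_id)]
  counts <- table(sp)
  chi <- sum((counts - length(sp) / 3)^2 / (length(sp) / 3))
  p <- pchisq(chi, df = 2, lower.tail = FALSE)
  expect_gt(p, 0.001)
})

test_that("rank AUC matches closed forms and the all-pairs oracle", {
  expect_equal(speciesAUC(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_equal(speciesAUC(c(0.5, 0.5), c(0.5, 0.5)), 0.5)
  expect_equal(speciesAUC(c(0.9, 0.4), c(0.6, 0.1)), 0.75)
  expect_error(speciesAUC(numeric(), 1), "both sides")
  set.seed(77)
  for (i in 1:40) {
    pres <- sample(seq(0, 1, 0.1), sample(1:20, 1), TRUE)
    abs <- sample(seq(0, 1, 0.1), sample(1:20, 1), TRUE)
    expect_equal(speciesAUC(pres, abs), oracleAUC(pres, abs))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  set.seed(13)
  pres <- rnorm(30); abs <- rnorm(45)
  base <- speciesAUC(pres, abs)
  expect_identical(speciesAUC(plogis(pres), plogis(abs)), base)
  expect_identical(speciesAUC(3 * pres + 7, 3 * abs + 7), base)
})

test_that("MeanAUC averages species and reports regions separately", {
  set.seed(21)
  n <- 120
  testOcc <- data.frame(occ_id = as.character(1:n),
                        species_id = sample(c("a", "b", "c"), n, TRUE),
                        region = rep(c("FR", "US"), each = n / 2))
  scores <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(testOcc$occ_id, c("a", "b", "c")))
  out <- evaluateMeanAUC(scores, testOcc, seed = 5)
  expect_equal(out$meanAUC, mean(out$perSpecies$auc))
  expect_equal(sort(names(out$regional)), c("FR", "US"))
  # single-region-with-one-species is reported absent, not zero
  testOcc2 <- testOcc
  testOcc2$region[testOcc2$region == "US"] <- "FR"
  testOcc2$region[1] <- "LONE"
  out2 <- evaluateMeanAUC(scores, testOcc2, seed = 5)
  expect_true(is.na(out2$regional[["LONE"]]))
})
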