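# Evaluation protocol: true-species ranks, top-k accuracy A_k, species-wise
# top-k SA_{k,s} and its unweighted species mean MSA_k, spatial block
# holdout, and the species-balanced pseudo-absence AUC with regional means.

#' Rank of the true species in a score vector
#'
#' Descending-score rank with the pessimistic tie rule: the true species is
#' placed last among its ties, i.e. r = #\{j : s_j >= s_true\}. A constant
#' predictor therefore gets rank S, never rank 1.
#'
#' @param scores numeric matrix (occurrences x species, named columns) or a
#'   single named vector.
#' @param trueSpecies character/integer vector of true species ids.
#' @return integer vector of ranks in 1..S.
#' @export
rankTrueSpecies <- function(scores, trueSpecies) {
  if (!is.matrix(scores)) scores <- matrix(scores, 1,
                                           dimnames = list(NULL,
                                                           names(scores)))
  cols <- match(as.character(trueSpecies), colnames(scores))
  if (anyNA(cols)) stop("unknown species id: ",
                        paste(unique(trueSpecies[is.na(cols)]),
                              collapse = ", "))
  sTrue <- scores[cbind(seq_len(nrow(scores)), cols)]
  as.integer(rowSums(scores >= sTrue))
}

#' Top-k accuracy A_k
#'
#' Fraction of test occurrences whose true-species rank is at most k.
#'
#' @param ranks integer ranks from [rankTrueSpecies()].
#' @param k cutoff (default 30).
#' @return A_k in [0, 1].
#' @export
topKAccuracy <- function(ranks, k = 30) {
  if (length(ranks) == 0) stop("top-k accuracy is undefined on an empty set")
  mean(ranks <= k)
}

#' Species-wise top-k accuracy and its species mean
#'
#' SA_{k,s} is the top-k indicator averaged over the j occurrences of
#' species s; MSA_k is the unweighted mean of SA_{k,s} over species with at
#' least one test occurrence, which avoids giving frequent species more
#' weight than rare ones.
#'
#' @param ranks integer ranks from [rankTrueSpecies()].
#' @param species species id per rank.
#' @param k cutoff (default 30).
#' @return list with `perSpecies` (data.frame `species_id, j, sa`) and
#'   `msa`.
#' @export
meanSpeciesTopK <- function(ranks, species, k = 30) {
  if (length(ranks) == 0) stop("MSA is undefined on an empty set")
  hit <- ranks <= k
  sa <- tapply(hit, as.character(species), mean)
  j <- tapply(hit, as.character(species), length)
  per <- data.frame(species_id = names(sa), j = as.integer(j),
                    sa = as.numeric(sa), row.names = NULL)
  list(perSpecies = per, msa = mean(per$sa))
}

#' Spatial block holdout split
#'
#' Grids the occurrence bounding box into square quadrats anchored at its
#' lower-left corner, draws quadrats uniformly at random (seeded) and
#' assigns them wholly to the test set until the cumulative occurrence
#' count first reaches the target fraction; the validation set is then
#' drawn uniformly from the remaining (train) occurrences. No quadrat ever
#' contains both train and test occurrences.
#'
#' @param occ data.frame with `x`, `y` (planar coordinates).
#' @param quadratSize quadrat side length (same units as coordinates).
#' @param testFraction target test share of all occurrences (in (0, 1)).
#' @param valFraction share of the remaining train set used for validation.
#' @param seed RNG seed.
#' @return `occ` with columns `split` ("train"/"val"/"test") and `quadrat`.
#' @export
spatialBlockSplit <- function(occ, quadratSize, testFraction = 0.025,
                              valFraction = 0.005, seed = 1) {
  if (quadratSize <= 0) stop("quadratSize must be positive")
  if (testFraction <= 0 || testFraction >= 1)
    stop("testFraction must lie in (0, 1)")
  set.seed(seed)
  qx <- floor((occ$x - min(occ$x)) / quadratSize)
  qy <- floor((occ$y - min(occ$y)) / quadratSize)
  occ$quadrat <- paste(qx, qy, sep = "_")
  quadrats <- unique(occ$quadrat)
  counts <- table(occ$quadrat)
  target <- testFraction * nrow(occ)
  drawn <- sample(quadrats)
  cum <- cumsum(as.numeric(counts[drawn]))
  nTest <- which(cum >= target)[1]
  if (is.na(nTest)) nTest <- length(drawn)
  testQ <- drawn[seq_len(nTest)]
  occ$split <- ifelse(occ$quadrat %in% testQ, "test", "train")
  if (all(occ$split == "test"))
    warning("target test fraction unachievable: ",
            "all occurrences fall in the drawn quadrats")
  trainIdx <- which(occ$split == "train")
  nVal <- round(valFraction * length(trainIdx))
  if (nVal >= 1)
    occ$split[sample(trainIdx, nVal)] <- "val"
  occ
}

#' Draw pseudo-absences for one species
#'
#' Two-stage species-balanced draw: each pseudo-absence first picks a
#' species uniformly among species other than the target that have at
#' least one test occurrence, then picks one of that species' test
#' occurrences uniformly. Draws are independent (with replacement across
#' draws). The number drawn is 100, or the target's presence count if it
#' exceeds 100.
#'
#' @param targetSpecies species being evaluated.
#' @param testOcc data.frame of test occurrences (`occ_id`, `species_id`).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return integer/character vector of pseudo-absence occ ids.
#' @export
drawPseudoAbsences <- function(targetSpecies, testOcc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pres <- sum(testOcc$species_id == targetSpecies)
  eligible <- setdiff(unique(testOcc$species_id), targetSpecies)
  if (length(eligible) == 0)
    stop("no eligible species for pseudo-absence drawing")
  nDraw <- max(100, pres)
  sp <- sample(length(eligible), nDraw, replace = TRUE)
  bySpecies <- split(testOcc$occ_id, testOcc$species_id)
  vapply(sp, function(s) {
    pool <- bySpecies[[as.character(eligible[s])]]
    pool[sample.int(length(pool), 1)]
  }, testOcc$occ_id[1])
}

#' Rank-based AUC of presence vs pseudo-absence scores
#'
#' Mann-Whitney AUC with midrank tie handling: the probability that a
#' random presence outscores a random pseudo-absence, ties counting half.
#' Invariant under any strictly increasing transform of the scores.
#'
#' @param presenceScores,absenceScores numeric score vectors (each
#'   non-empty).
#' @return AUC in [0, 1].
#' @export
speciesAUC <- function(presenceScores, absenceScores) {
  np <- length(presenceScores); na <- length(absenceScores)
  if (np == 0 || na == 0) stop("AUC needs scores on both sides")
  r <- rank(c(presenceScores, absenceScores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Species-balanced pseudo-absence MeanAUC
#'
#' For each species with test presences, draws pseudo-absences with
#' [drawPseudoAbsences()], computes the rank AUC of its scores at presences
#' vs pseudo-absences, and averages unweighted over species. With a
#' `region` column in `testOcc`, regional MeanAUCs restrict both presences
#' and the pseudo-absence pool to the region's test occurrences; regions
#' with no evaluable species are reported absent (`NA`).
#'
#' @param scoreMatrix occurrences x species matrix of the model's AUC score
#'   (logits for the convolutional model, probabilities for the baseline);
#'   rownames are occ ids, colnames species ids.
#' @param testOcc data.frame of test occurrences (`occ_id`, `species_id`,
#'   optional `region`).
#' @param seed RNG seed for the pseudo-absence draws.
#' @return list with `perSpecies` (data.frame `species_id, presences, auc`),
#'   `meanAUC`, and `regional` (named numeric, if regions are present).
#' @export
evaluateMeanAUC <- function(scoreMatrix, testOcc, seed = 1) {
  set.seed(seed)
  one <- function(occSub) {
    ids <- as.character(occSub$occ_id)
    specs <- unique(occSub$species_id)
    if (length(specs) < 2) return(NULL)
    res <- lapply(specs, function(s) {
      presIds <- as.character(occSub$occ_id[occSub$species_id == s])
      absIds <- as.character(drawPseudoAbsences(s, occSub))
      sc <- scoreMatrix[, as.character(s)]
      data.frame(species_id = as.character(s),
                 presences = length(presIds),
                 auc = speciesAUC(sc[presIds], sc[absIds]))
    })
    do.call(rbind, res)
  }
  per <- one(testOcc)
  if (is.null(per)) stop("MeanAUC needs at least 2 species with test occurrences")
  out <- list(perSpecies = per, meanAUC = mean(per$auc))
  if (!is.null(testOcc$region)) {
    regs <- sort(unique(testOcc$region))
    out$regional <- vapply(regs, function(rg) {
      p <- one(testOcc[testOcc$region == rg, , drop = FALSE])
      if (is.null(p)) NA_real_ else mean(p$auc)
    }, numeric(1))
    names(out$regional) <- regs
  }
  out
}

#' Full metric report for a set of scored test occurrences
#'
#' Computes ranks, A_k, SA/MSA_k and the pseudo-absence MeanAUC in one
#' pass.
#'
#' @param scores a [SpeciesScores-class] covering the test occurrences.
#' @param testOcc data.frame (`occ_id`, `species_id`, optional `region`).
#' @param k top-k cutoff (default 30).
#' @param aucScore which assay to use as the AUC score: `"logits"` (the
#'   convolutional model's habitat-suitability score) or
#'   `"probabilities"`.
#' @param seed seed for pseudo-absence draws.
#' @return list: `n`, `k`, `A_k`, `perSpecies`, `MSA_k`, `meanAUC`,
#'   `regional` (when regions present), `ranks`.
#' @export
evaluateScores <- function(scores, testOcc, k = 30,
                           aucScore = c("logits", "probabilities"),
                           seed = 1) {
  aucScore <- match.arg(aucScore)
  probs <- t(speciesProbabilities(scores))
  ids <- as.character(testOcc$occ_id)
  stopifnot(all(ids %in% rownames(probs)))
  probs <- probs[ids, , drop = FALSE]
  ranks <- rankTrueSpecies(probs, testOcc$species_id)
  msa <- meanSpeciesTopK(ranks, testOcc$species_id, k)
  scoreM <- if (aucScore == "logits" &&
                "logits" %in% SummarizedExperiment::assayNames(scores))
    t(speciesLogits(scores))[ids, , drop = FALSE] else probs
  auc <- evaluateMeanAUC(scoreM, testOcc, seed = seed)
  per <- merge(msa$perSpecies, auc$perSpecies, by = "species_id",
               all = TRUE)
  list(n = length(ranks), k = k,
       A_k = topKAccuracy(ranks, k),
       MSA_k = msa$msa,
       perSpecies = per,
       meanAUC = auc$meanAUC,
       regional = auc$regional,
       ranks = ranks)
}
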