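# Point-environment baseline: a multi-class random forest on the
# environment vector extracted at each occurrence, the classical SDM the
# convolutional model is compared against.

#' Train the point-environment baseline and score occurrences
#'
#' Fits a probability random forest (100 trees, maximum depth 10, other
#' parameters at their defaults) on per-occurrence environment vectors and
#' returns per-species relative probabilities for the prediction set. The
#' probabilities are the AUC score for this model.
#'
#' @param envTrain data.frame of environment vectors for training
#'   occurrences (no missing values).
#' @param labels species id per training row.
#' @param envPredict data.frame of environment vectors to score.
#' @param numTrees,maxDepth forest size and depth cap.
#' @param seed RNG seed passed to the forest.
#' @return a [SpeciesScores-class] with a `probabilities` assay (no logits;
#'   columns are the rows of `envPredict`).
#' @export
trainEnvBaseline <- function(envTrain, labels, envPredict,
                             numTrees = 100, maxDepth = 10, seed = 1) {
  if (anyNA(envTrain) || anyNA(envPredict))
    stop("environment vectors contain missing values; ",
         "remove occurrences outside raster coverage first")
  if (length(unique(labels)) < 2)
    stop("baseline requires at least 2 species")
  df <- data.frame(envTrain)
  df$..species <- factor(as.character(labels))
  fit <- ranger::ranger(dependent.variable.name = "..species", data = df,
                        num.trees = numTrees, max.depth = maxDepth,
                        probability = TRUE, seed = seed,
                        num.threads = 1)
  pr <- predict(fit, data = data.frame(envPredict),
                num.threads = 1)$predictions
  # ranger orders columns by factor level; rows are prediction occurrences
  ids <- rownames(envPredict) %||% as.character(seq_len(nrow(envPredict)))
  speciesScores(probabilities = t(pr), species = colnames(pr),
                occ_id = ids)
}
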