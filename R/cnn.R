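# Multi-species convolutional SDM: a small strided conv stack phi ending in
# global average pooling, a linear species head psi, trained by
# cross-entropy so softmax(psi(phi(x))) estimates relative species
# probabilities. Conv forward/backward run through compiled im2col kernels;
# the optimiser and loss live here.

#' Numerically stable softmax
#'
#' Maps logits to relative probabilities with the max-shift trick; invariant
#' under adding a constant to all logits and order-preserving.
#'
#' @param logits numeric vector, or matrix with one column per observation
#'   (species in rows).
#' @return probabilities of the same shape; each column sums to 1.
#' @export
softmaxProbabilities <- function(logits) {
  if (is.matrix(logits)) {
    shifted <- sweep(logits, 2, apply(logits, 2, max))
    e <- exp(shifted)
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(logits - max(logits))
    e / sum(e)
  }
}

#' Model configuration for a convolutional SDM
#'
#' The backbone is a stack of strided 3x3 convolution blocks with ReLU,
#' ending in global average pooling to a feature vector of dimension equal
#' to the last block width. Serializes round-trip through JSON.
#'
#' @param blocks integer vector of conv block widths (filters); the last
#'   entry is the feature dimension d.
#' @param kernel,pad conv geometry shared by all blocks.
#' @param stride per-block strides (recycled). The default keeps the first
#'   block at stride 1 so fine texture survives into the nonlinearity —
#'   local contrast rectified by ReLU and pooled downstream is what lets
#'   the network measure neighborhood variability — and downsamples by 2
#'   in the remaining blocks.
#' @param pooling `"avg"` pools the last conv map by global average only
#'   (feature dimension = last block width); `"avgsd"` concatenates the
#'   per-channel spatial standard deviation (feature dimension = twice the
#'   last block width), which exposes within-patch texture variability to
#'   the linear head directly.
#' @param epochs,batchSize,lr,seed training specification.
#' @param valFraction fraction of the training set held out as a validation
#'   split for monitoring (default 0.5%).
#' @param landcoverClasses one-hot width for the categorical land-cover
#'   channel; `NULL` infers it from the training tensors.
#' @return a list of class `convSDMConfig`.
#' @export
convSDMConfig <- function(blocks = c(32, 64, 64), kernel = 3,
                          stride = c(1, rep(2, length(blocks) - 1)),
                          pad = 1, pooling = c("avgsd", "avg"),
                          epochs = 8, batchSize = 64, lr = 1e-3,
                          seed = 1, valFraction = 0.005,
                          landcoverClasses = NULL) {
  stopifnot(length(blocks) >= 1, all(blocks >= 1), kernel >= 1,
            all(stride >= 1))
  pooling <- match.arg(pooling)
  structure(list(blocks = as.integer(blocks), kernel = as.integer(kernel),
                 stride = as.integer(rep_len(stride, length(blocks))),
                 pad = as.integer(pad), pooling = pooling,
                 featureDim = as.integer(blocks[length(blocks)] *
                                           if (pooling == "avgsd") 2 else 1),
                 epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 lr = lr, seed = as.integer(seed),
                 valFraction = valFraction,
                 landcoverClasses = landcoverClasses),
            class = "convSDMConfig")
}

# Expand stored tensors (integer-coded categorical channels) into the
# model's input layout: continuous channels as-is, categorical channels
# one-hot over their declared class count.
.modelInput <- function(x, meta, landcoverClasses) {
  d <- dim(x)
  nOut <- sum(ifelse(meta$kind == "categorical", landcoverClasses, 1))
  out <- array(0, dim = c(d[1], d[2], nOut, d[4]))
  nms <- character(nOut); kinds <- character(nOut)
  ci <- 0L
  for (i in seq_len(d[3])) {
    if (meta$kind[i] == "categorical") {
      k <- landcoverClasses
      codes <- x[, , i, ]
      if (any(codes < 0 | codes > k - 1))
        stop("categorical channel '", meta$name[i],
             "' holds codes outside 0..", k - 1)
      for (cls in 0:(k - 1)) {
        ci <- ci + 1L
        out[, , ci, ] <- (codes == cls) * 1
        nms[ci] <- paste0(meta$name[i], "_", cls)
        kinds[ci] <- "onehot"
      }
    } else {
      ci <- ci + 1L
      out[, , ci, ] <- x[, , i, ]
      nms[ci] <- meta$name[i]
      kinds[ci] <- "continuous"
    }
  }
  list(x = out, names = nms, kinds = kinds)
}

.standardize <- function(x, kinds, stats) {
  for (i in seq_along(kinds)) {
    if (kinds[i] != "continuous") next
    x[, , i, ] <- (x[, , i, ] - stats$mean[i]) / stats$sd[i]
  }
  x
}

.initWeights <- function(config, cin, nSpecies) {
  k <- config$kernel
  conv <- list()
  for (b in seq_along(config$blocks)) {
    cout <- config$blocks[b]
    fanIn <- k * k * cin
    conv[[b]] <- list(W = matrix(rnorm(fanIn * cout, sd = sqrt(2 / fanIn)),
                                 fanIn, cout),
                      b = rep(0, cout))
    cin <- cout
  }
  d <- config$featureDim
  list(conv = conv,
       head = list(W = matrix(rnorm(nSpecies * d, sd = sqrt(1 / d)),
                              nSpecies, d),
                   b = rep(0, nSpecies)))
}

# Forward pass on a standardized input batch. Returns features (d x N),
# logits (S x N) and, if cache = TRUE, the per-layer inputs and pre-ReLU
# outputs needed for backprop.
.forwardPass <- function(x, weights, config, cache = FALSE) {
  a <- x
  pre <- list(); inp <- list()
  for (b in seq_along(weights$conv)) {
    if (cache) inp[[b]] <- a
    z <- cpp_conv_fwd(a, weights$conv[[b]]$W, weights$conv[[b]]$b,
                      config$stride[[min(b, length(config$stride))]],
                      config$pad)
    if (cache) pre[[b]] <- z
    a <- z * (z > 0)
  }
  d <- dim(a)
  hw <- d[1] * d[2]
  am <- matrix(a, hw, d[3] * d[4])
  mu <- colMeans(am)
  if ((config$pooling %||% "avg") == "avgsd") {
    sdv <- sqrt(colSums((am - rep(mu, each = hw))^2) / max(hw - 1, 1))
    sdv <- pmax(sdv, 1e-8)
    feat <- rbind(matrix(mu, d[3], d[4]), matrix(sdv, d[3], d[4]))
  } else {
    sdv <- NULL
    feat <- matrix(mu, d[3], d[4])
  }
  logits <- weights$head$W %*% feat + weights$head$b
  out <- list(features = feat, logits = logits, poolDim = d,
              poolMu = mu, poolSd = sdv)
  if (cache) { out$pre <- pre; out$inp <- inp }
  out
}

.adamInit <- function(w) lapply(w, function(x)
  if (is.list(x)) lapply(x, function(y)
    if (is.list(y)) lapply(y, function(z) z * 0) else y * 0) else x * 0)

.adamStep <- function(w, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mh <- m / (1 - beta1^t)
  vh <- v / (1 - beta2^t)
  list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
}

#' Train a convolutional species distribution model
#'
#' Minimizes the multinomial cross-entropy of
#' \eqn{P(Y = k | X = x) = \mathrm{softmax}_k(\psi(\phi(x)))} with Adam on
#' seeded minibatches. Per-channel standardization statistics are computed
#' on the training portion only and stored with the model. The categorical
#' land-cover channel is one-hot expanded at the model input.
#'
#' @param tensors (H, W, C, N) array from [assembleTensors()] (integer-coded
#'   categorical channels), with its `"channelMeta"` attribute.
#' @param labels species id per tensor (length N); at least 2 distinct.
#' @param config a [convSDMConfig()].
#' @return a [ConvSDM-class] with a per-epoch training log.
#' @export
trainConvSDM <- function(tensors, labels, config = convSDMConfig()) {
  meta <- attr(tensors, "channelMeta")
  stopifnot(!is.null(meta))
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("training requires at least 2 species (softmax is degenerate)")
  y <- match(labels, classes)
  n <- dim(tensors)[4]
  set.seed(config$seed)
  nVal <- round(config$valFraction * n)
  valIdx <- if (nVal >= 1) sample.int(n, nVal) else integer()
  trainIdx <- setdiff(seq_len(n), valIdx)

  K <- config$landcoverClasses
  if (is.null(K)) {
    catCh <- which(meta$kind == "categorical")
    K <- if (length(catCh)) max(tensors[, , catCh, , drop = FALSE]) + 1 else 0
    K <- as.integer(K)
    config$landcoverClasses <- K
  }
  mi <- .modelInput(tensors, meta, K)
  stats <- list(mean = rep(0, length(mi$kinds)),
                sd = rep(1, length(mi$kinds)))
  for (i in seq_along(mi$kinds)) {
    if (mi$kinds[i] != "continuous") next
    v <- mi$x[, , i, trainIdx]
    stats$mean[i] <- mean(v)
    stats$sd[i] <- max(stats::sd(v), 1e-8)
  }
  X <- .standardize(mi$x, mi$kinds, stats)

  S <- length(classes)
  weights <- .initWeights(config, dim(X)[3], S)
  mState <- .adamInit(weights); vState <- .adamInit(weights)
  t <- 0
  log <- data.frame(epoch = integer(), loss = numeric(),
                    val_loss = numeric())
  for (epoch in seq_len(config$epochs)) {
    perm <- sample(trainIdx)
    lossSum <- 0
    for (start in seq(1, length(perm), by = config$batchSize)) {
      idx <- perm[start:min(start + config$batchSize - 1, length(perm))]
      xb <- X[, , , idx, drop = FALSE]
      yb <- y[idx]; nb <- length(idx)
      fw <- .forwardPass(xb, weights, config, cache = TRUE)
      probs <- softmaxProbabilities(fw$logits)
      picked <- probs[cbind(yb, seq_len(nb))]
      lossSum <- lossSum + sum(-log(pmax(picked, 1e-12)))
      dLogits <- probs
      dLogits[cbind(yb, seq_len(nb))] <-
        dLogits[cbind(yb, seq_len(nb))] - 1
      dLogits <- dLogits / nb
      grads <- .backwardPass(fw, dLogits, weights, config)
      t <- t + 1
      for (b in seq_along(weights$conv)) {
        for (p in c("W", "b")) {
          up <- .adamStep(weights$conv[[b]][[p]], grads$conv[[b]][[p]],
                          mState$conv[[b]][[p]], vState$conv[[b]][[p]],
                          config$lr, t)
          weights$conv[[b]][[p]] <- up$w
          mState$conv[[b]][[p]] <- up$m; vState$conv[[b]][[p]] <- up$v
        }
      }
      for (p in c("W", "b")) {
        up <- .adamStep(weights$head[[p]], grads$head[[p]],
                        mState$head[[p]], vState$head[[p]], config$lr, t)
        weights$head[[p]] <- up$w
        mState$head[[p]] <- up$m; vState$head[[p]] <- up$v
      }
    }
    valLoss <- NA_real_
    if (length(valIdx)) {
      fv <- .forwardPass(X[, , , valIdx, drop = FALSE], weights, config)
      pv <- softmaxProbabilities(fv$logits)
      valLoss <- mean(-log(pmax(pv[cbind(y[valIdx],
                                         seq_along(valIdx))], 1e-12)))
    }
    log <- rbind(log, data.frame(epoch = epoch,
                                 loss = lossSum / length(perm),
                                 val_loss = valLoss))
  }
  new("ConvSDM", config = unclass(config), weights = weights,
      channelStats = c(stats, list(kinds = mi$kinds, names = mi$names,
                                   inputMeta = meta)),
      species = as.character(classes), log = log)
}

.backwardPass <- function(fw, dLogits, weights, config) {
  feat <- fw$features
  gHead <- list(W = dLogits %*% t(feat), b = rowSums(dLogits))
  dFeat <- t(weights$head$W) %*% dLogits
  d <- fw$poolDim
  hw <- d[1] * d[2]
  if ((config$pooling %||% "avg") == "avgsd") {
    C <- d[3]
    dMu <- as.vector(dFeat[seq_len(C), , drop = FALSE])
    dSd <- as.vector(dFeat[C + seq_len(C), , drop = FALSE])
    B <- fw$pre[[length(fw$pre)]]
    aLast <- B * (B > 0)
    am <- matrix(aLast, hw, C * d[4])
    centered <- am - rep(fw$poolMu, each = hw)
    dAm <- rep(dMu, each = hw) / hw +
      rep(dSd, each = hw) * centered /
        (max(hw - 1, 1) * rep(fw$poolSd, each = hw))
    dA <- array(dAm, dim = d)
  } else {
    dA <- array(rep(as.vector(dFeat) / hw, each = hw), dim = d)
  }
  gConv <- vector("list", length(weights$conv))
  for (b in rev(seq_along(weights$conv))) {
    dZ <- dA * (fw$pre[[b]] > 0)
    bw <- cpp_conv_bwd(fw$inp[[b]], weights$conv[[b]]$W, dZ,
                       config$stride[[min(b, length(config$stride))]],
                       config$pad)
    gConv[[b]] <- list(W = bw$dw, b = bw$db)
    dA <- bw$dx
  }
  list(conv = gConv, head = gHead)
}

#' Forward pass of a trained model
#'
#' Deterministic inference: returns the feature vectors z = phi(x) and the
#' species scores (logits psi(z) and softmax probabilities) for a batch of
#' tensors. Input channel layout must match the model's training layout.
#'
#' @param model a [ConvSDM-class].
#' @param tensors an [EnvironmentalTensor-class] or an (H, W, C, N) array
#'   from [assembleTensors()].
#' @param batchSize inference batch size.
#' @return list with `features` (N x d matrix) and `scores`
#'   (a [SpeciesScores-class]).
#' @export
predictConvSDM <- function(model, tensors, batchSize = 256) {
  if (is(tensors, "EnvironmentalTensor")) {
    meta <- channelMeta(tensors)
    x <- array(tensorValues(tensors),
               dim = c(dim(tensorValues(tensors)), 1))
    ids <- "1"
  } else {
    meta <- attr(tensors, "channelMeta")
    x <- tensors
    ids <- dimnames(tensors)[[4]] %||% as.character(seq_len(dim(x)[4]))
  }
  ref <- model@channelStats$inputMeta
  if (nrow(meta) != nrow(ref) || any(meta$name != ref$name) ||
      any(meta$kind != ref$kind))
    stop("tensor channel layout does not match the model's configuration")
  mi <- .modelInput(x, meta, model@config$landcoverClasses)
  X <- .standardize(mi$x, model@channelStats$kinds,
                    model@channelStats)
  n <- dim(X)[4]
  d <- model@config$featureDim
  S <- length(model@species)
  features <- matrix(NA_real_, n, d)
  logits <- matrix(NA_real_, S, n)
  for (start in seq(1, n, by = batchSize)) {
    idx <- start:min(start + batchSize - 1, n)
    fw <- .forwardPass(X[, , , idx, drop = FALSE], model@weights,
                       model@config)
    features[idx, ] <- t(fw$features)
    logits[, idx] <- fw$logits
  }
  rownames(features) <- ids
  scores <- speciesScores(logits = logits, species = model@species,
                          occ_id = ids)
  list(features = features, scores = scores)
}

#' Construct a SpeciesScores container
#'
#' @param probabilities S x N matrix of per-occurrence species
#'   probabilities (columns sum to 1). Computed from `logits` when omitted.
#' @param logits optional S x N matrix of pre-softmax scores.
#' @param species species ids (rows).
#' @param occ_id occurrence ids (columns).
#' @return a [SpeciesScores-class].
#' @export
speciesScores <- function(probabilities = NULL, logits = NULL,
                          species, occ_id) {
  if (is.null(probabilities)) {
    stopifnot(!is.null(logits))
    probabilities <- softmaxProbabilities(logits)
  }
  assays <- list(probabilities = probabilities)
  if (!is.null(logits)) assays$logits <- logits
  assays <- lapply(assays, function(a) {
    rownames(a) <- as.character(species)
    colnames(a) <- as.character(occ_id)
    a
  })
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    colData = S4Vectors::DataFrame(occ_id = as.character(occ_id),
                                   row.names = as.character(occ_id)))
  new("SpeciesScores", se)
}
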