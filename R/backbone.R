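#' Backbone architecture configuration
#'
#' The typing-pattern backbone is a stack of 2 LSTM layers of 128 units with
#' recurrent dropout 0.2, a dropout layer of 0.5 between them, and an input
#' masking contract: rows of the 150 x 4 input at or beyond the window's
#' valid length contribute neither to the embedding nor to any gradient.
#' The embedding v(x) is the final-step output of the last layer (the
#' adopted sequence-to-vector readout), so its dimension equals the last
#' layer's unit count.
#'
#' @param nRecurrentLayers number of LSTM layers (2).
#' @param unitsPerLayer units per layer (128).
#' @param recurrentDropout recurrent dropout rate (training only).
#' @param interLayerDropout dropout between the layers (training only).
#' @param inputShape `(keys, features)` of one window.
#' @param embeddingDim must equal `unitsPerLayer`.
#' @param maskPaddedRows must be TRUE whenever padding is used.
#' @return validated config list.
#' @export
backboneConfig <- function(nRecurrentLayers = 2L, unitsPerLayer = 128L,
                           recurrentDropout = 0.2, interLayerDropout = 0.5,
                           inputShape = c(150L, 4L),
                           embeddingDim = unitsPerLayer,
                           maskPaddedRows = TRUE) {
  if (embeddingDim != unitsPerLayer)
    stop("embeddingDim must equal unitsPerLayer (final-step readout)")
  if (!maskPaddedRows)
    stop("maskPaddedRows must be TRUE: zero-padded inputs require masking")
  if (nRecurrentLayers < 1L) stop("need at least one recurrent layer")
  list(nRecurrentLayers = as.integer(nRecurrentLayers),
       unitsPerLayer = as.integer(unitsPerLayer),
       recurrentDropout = recurrentDropout,
       interLayerDropout = interLayerDropout,
       inputShape = as.integer(inputShape),
       embeddingDim = as.integer(embeddingDim),
       maskPaddedRows = TRUE)
}

#' Build the typing-pattern embedding backbone
#'
#' Initialises the LSTM stack with seeded Glorot weights (forget-gate biases
#' at 1). Inference is deterministic: dropout is active only inside
#' training loops.
#'
#' @param config from [backboneConfig()].
#' @param seed RNG seed for the weight initialisation.
#' @return an untrained [KeystrokeBackbone-class].
#' @export
buildBackbone <- function(config = backboneConfig(), seed = 1L) {
  weights <- withSeed(seed, lstmInitWeights(config))
  new("KeystrokeBackbone", config = config, weights = weights,
      history = data.frame())
}

# Normalize the accepted input forms to (array, lens).
asWindowArray <- function(x, inputShape) {
  if (is(x, "FeatureMatrix")) x <- list(x)
  if (is.list(x) && !is.null(x$x) && !is.null(x$validLength))
    return(list(x = x$x, lens = x$validLength))
  if (is.list(x) && all(vapply(x, is, logical(1), "FeatureMatrix"))) {
    n <- length(x)
    arr <- array(0, dim = c(n, inputShape[1L], inputShape[2L]))
    for (k in seq_len(n)) arr[k, , ] <- featureValues(x[[k]])
    return(list(x = arr, lens = vapply(x, validLength, integer(1))))
  }
  stop("x must be a FeatureMatrix, a list of them, or a cohortWindows() set")
}

#' @rdname embed
#' @param batchSize windows embedded per forward pass.
setMethod("embed", signature("KeystrokeBackbone", "ANY"),
  function(object, x, batchSize = 256L) {
    w <- asWindowArray(x, object@config$inputShape)
    n <- dim(w$x)[1L]
    out <- matrix(0, n, object@config$embeddingDim)
    for (s in seq.int(1L, n, by = batchSize)) {
      e <- min(s + batchSize - 1L, n)
      idx <- s:e
      out[idx, ] <- lstmForward(object@weights,
                                w$x[idx, , , drop = FALSE],
                                w$lens[idx], training = FALSE)$emb
    }
    out
  })

# Identity triplets: anchor/positive = distinct windows of one user,
# negative = a window of a different user.
sampleIdentityTriplets <- function(userIds, B) {
  tab <- table(userIds)
  elig <- names(tab)[tab >= 2L]
  if (!length(elig)) stop("no user with >= 2 windows")
  byUser <- split(seq_along(userIds), userIds)
  a <- p <- n <- integer(B)
  for (k in seq_len(B)) {
    u <- sample(elig, 1L)
    ap <- sample(byUser[[u]], 2L)
    a[k] <- ap[1L]; p[k] <- ap[2L]
    n[k] <- sample(which(userIds != u), 1L)
  }
  list(a = a, p = p, n = n)
}

#' Pretrain the backbone on identity triplets
#'
#' Desk-scale pretraining of the typing embedding: triplets whose classes
#' are user identities (anchor/positive from one user, negative from
#' another) shape the embedding space so that same-user windows cluster,
#' which is the transferable typing-pattern signal the fatigue head later
#' adapts. Uses the hinge triplet loss on Euclidean distances and Adam.
#' A per-user tail of sessions is held out to track validation loss.
#'
#' @param backbone a [KeystrokeBackbone-class].
#' @param corpus a [SimulatedCorpus-class] with >= 2 users (user identity
#'   taken from the session participant ids).
#' @param epochs,batchesPerEpoch,tripletsPerBatch training schedule.
#' @param margin triplet margin alpha.
#' @param learningRate,beta1,beta2,epsilon Adam hyperparameters.
#' @param valFraction fraction of each user's sessions held out.
#' @param seed RNG seed (sampling, dropout).
#' @return the trained backbone; `@history` has per-epoch train/validation
#'   loss, and attribute-free bookkeeping of the held-out indices is kept in
#'   the history's `valLoss` column.
#' @export
pretrainBackbone <- function(backbone, corpus, epochs = 10L,
                             batchesPerEpoch = 50L, tripletsPerBatch = 64L,
                             margin = 1.5, learningRate = 0.001,
                             beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                             valFraction = 0.2, seed = 1L) {
  win <- cohortWindows(corpus, policy = "first_only")
  users <- win$participant
  if (length(unique(users)) < 2L)
    stop("degenerate corpus: pretraining needs >= 2 users")
  withSeed(seed, {
    byUser <- split(seq_along(users), users)
    # a val user must keep >= 2 windows to form same-user pairs
    valIdx <- unlist(lapply(byUser, function(i) {
      nv <- max(2L, floor(valFraction * length(i)))
      if (length(i) - nv >= 2L) utils::tail(i, nv) else integer()
    }))
    trainIdx <- setdiff(seq_along(users), valIdx)
    valTrip <- if (length(valIdx) >= 4L &&
                   length(unique(users[valIdx])) >= 2L) {
      tr <- sampleIdentityTriplets(users[valIdx],
                                   min(200L, 4L * length(valIdx)))
      lapply(tr, function(i) valIdx[i])
    }
    valLoss <- function(w) {
      if (is.null(valTrip)) return(NA_real_)
      idx <- c(valTrip$a, valTrip$p, valTrip$n)
      E <- lstmForward(w, win$x[idx, , , drop = FALSE],
                       win$validLength[idx], training = FALSE)$emb
      tripletEmbGrad(E, length(valTrip$a), margin)$loss
    }
    weights <- backbone@weights
    opt <- adamInit(weights)
    cfg <- backbone@config
    hist <- data.frame()
    v0 <- valLoss(weights)
    totalIter <- epochs * batchesPerEpoch
    iter <- 0L
    for (ep in seq_len(epochs)) {
      lossAcc <- 0
      for (bt in seq_len(batchesPerEpoch)) {
        iter <- iter + 1L
        # linear decay to 10% of the base rate stabilises the small-batch
        # triplet updates late in training
        lrNow <- learningRate *
          (1 - 0.9 * (iter - 1L) / max(1L, totalIter - 1L))
        tr <- sampleIdentityTriplets(users[trainIdx], tripletsPerBatch)
        idx <- trainIdx[c(tr$a, tr$p, tr$n)]
        fw <- lstmForward(weights, win$x[idx, , , drop = FALSE],
                          win$validLength[idx], training = TRUE,
                          recurrentDropout = cfg$recurrentDropout,
                          interLayerDropout = cfg$interLayerDropout,
                          cache = TRUE)
        tg <- tripletEmbGrad(fw$emb, tripletsPerBatch, margin)
        grads <- lstmBackward(weights, fw, tg$dEmb)
        st <- adamStep(opt, weights, grads, lrNow, beta1, beta2,
                       epsilon)
        weights <- st$params
        opt <- st$state
        lossAcc <- lossAcc + tg$loss
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     loss = lossAcc / batchesPerEpoch,
                                     valLoss = valLoss(weights),
                                     initialValLoss = v0))
    }
    backbone@weights <- weights
    backbone@history <- hist
    backbone
  })
}

#' Held-out identity-verification AUC of a backbone
#'
#' Measures how well embedding distances separate same-user from
#' different-user window pairs: AUC = P(different-user distance >
#' same-user distance). 0.5 means no identity signal.
#'
#' @param backbone a [KeystrokeBackbone-class].
#' @param corpus corpus (or `cohortWindows()` set) to evaluate on.
#' @param nPairs pairs sampled per class.
#' @param seed RNG seed for pair sampling.
#' @return AUC in `[0,1]`.
#' @export
identityVerificationAuc <- function(backbone, corpus, nPairs = 1000L,
                                    seed = 1L) {
  win <- if (inherits(corpus, "kfWindows")) corpus else
    cohortWindows(corpus, policy = "first_only")
  E <- embed(backbone, win)
  users <- win$participant
  withSeed(seed, {
    tr <- sampleIdentityTriplets(users, nPairs)
    dSame <- rowDistance(E[tr$a, , drop = FALSE], E[tr$p, , drop = FALSE])
    dDiff <- rowDistance(E[tr$a, , drop = FALSE], E[tr$n, , drop = FALSE])
    scoreAuc(c(dSame, dDiff), c(rep(FALSE, length(dSame)),
                                rep(TRUE, length(dDiff))))
  })
}

# Rank (Mann-Whitney) AUC of `score` for predicting `positive`.
scoreAuc <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC")
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Save / load backbone weights
#'
#' Weights go to an RDS checkpoint with a JSON sidecar (`<path>.json`)
#' recording the architecture config, so a checkpoint can be re-imported
#' (or externally produced weights of matching shape can be loaded).
#'
#' @param backbone a [KeystrokeBackbone-class].
#' @param path checkpoint path.
#' @return `saveWeights`: `path` invisibly; `loadWeights`: the backbone.
#' @export
saveWeights <- function(backbone, path) {
  saveRDS(list(config = backbone@config, weights = backbone@weights,
               history = backbone@history), path)
  jsonlite::write_json(backbone@config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname saveWeights
#' @param config optional [backboneConfig()]; if supplied it must match the
#'   checkpoint's shapes exactly.
#' @export
loadWeights <- function(path, config = NULL) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  obj <- readRDS(path)
  if (!is.null(config)) {
    same <- config$nRecurrentLayers == obj$config$nRecurrentLayers &&
      config$unitsPerLayer == obj$config$unitsPerLayer &&
      all(config$inputShape == obj$config$inputShape)
    if (!same)
      stop("config/checkpoint shape mismatch: checkpoint has ",
           obj$config$nRecurrentLayers, " layers x ",
           obj$config$unitsPerLayer, " units")
    obj$config <- config
  }
  new("KeystrokeBackbone", config = obj$config, weights = obj$weights,
      history = obj$history)
}

#' Parameter checksum of a backbone
#'
#' Cheap numeric signature used to assert the frozen-backbone contract
#' (adaptation must leave it bit-identical).
#'
#' @param backbone a [KeystrokeBackbone-class].
#' @return named numeric `(sum, sumsq, n)`.
#' @export
backboneChecksum <- function(backbone) paramChecksum(backbone@weights)
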