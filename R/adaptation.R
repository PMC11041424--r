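#' Adaptation (fatigue head) training configuration
#'
#' Defaults follow the published training recipe for the transfer stage:
#' a dense 128-unit relu layer trained with Adam (learning rate 0.005,
#' beta1 0.9, beta2 0.999, epsilon 1e-8) for 30 epochs of 100 batches of 64
#' triplets. The margin alpha defaults to 1.5, the upstream typing-network
#' convention. The backbone is frozen throughout; only the head learns.
#'
#' @param units head width (equals the embedding dimension).
#' @param margin triplet margin alpha (> 0).
#' @param learningRate,beta1,beta2,epsilon Adam hyperparameters.
#' @param epochs,batchesPerEpoch,tripletsPerBatch training schedule
#'   (reducible for desk-scale runs).
#' @param seed base RNG seed for triplet sampling and initialisation.
#' @return validated config list.
#' @export
adaptationConfig <- function(units = 128L, margin = 1.5,
                             learningRate = 0.005, beta1 = 0.9,
                             beta2 = 0.999, epsilon = 1e-8, epochs = 30L,
                             batchesPerEpoch = 100L, tripletsPerBatch = 64L,
                             seed = 1L) {
  if (margin <= 0) stop("margin alpha must be > 0")
  as.list(environment())
}

#' Euclidean distance between two embeddings
#'
#' The fatigue score of a sample pair is the Euclidean (L2) distance
#' between their fatigue-space embeddings.
#'
#' @param e1,e2 numeric vectors of equal length (same embedding space).
#' @return non-negative scalar.
#' @export
euclideanDistance <- function(e1, e2) {
  if (length(e1) != length(e2))
    stop("embedding dimension mismatch: ", length(e1), " vs ", length(e2))
  sqrt(sum((e1 - e2)^2))
}

#' Hinge triplet loss
#'
#' `max(0, dAP - dAN + margin)`: zero when the anchor-negative distance
#' exceeds the anchor-positive distance by at least the margin, otherwise
#' the margin violation. Vectorized over triplets.
#'
#' @param dAP anchor-positive distance(s), `>= 0`.
#' @param dAN anchor-negative distance(s), `>= 0`.
#' @param margin margin alpha (> 0).
#' @return non-negative loss value(s).
#' @export
tripletLoss <- function(dAP, dAN, margin = 1.5) {
  if (margin <= 0) stop("margin alpha must be > 0")
  if (any(dAP < 0) || any(dAN < 0)) stop("distances must be >= 0")
  pmax(0, dAP - dAN + margin)
}

#' Sample same-participant rest/fatigue triplets
#'
#' Anchor and positive are distinct samples of the same class, the negative
#' is a sample of the other class, and all three belong to the same
#' participant (to avoid intra-user variation contaminating the fatigue
#' signal). Sampling is uniform: an eligible participant is drawn, then an
#' eligible anchor class, then A, P, N uniformly.
#'
#' @param labels character vector, `"rest"`/`"fatigue"` per sample.
#' @param participants participant id per sample.
#' @param nTriplets number of triplets to draw.
#' @param seed optional RNG seed.
#' @return data.frame with columns `a`, `p`, `n` (sample indices),
#'   `participant`, `anchorClass`.
#' @export
sampleTriplets <- function(labels, participants, nTriplets, seed = NULL) {
  stopifnot(length(labels) == length(participants))
  keep <- labels %in% c("rest", "fatigue")
  counts <- table(factor(participants[keep]),
                  factor(labels[keep], levels = c("rest", "fatigue")))
  eligClass <- function(pid) {
    cr <- counts[pid, "rest"]; cf <- counts[pid, "fatigue"]
    c("rest", "fatigue")[c(cr >= 2L && cf >= 1L, cf >= 2L && cr >= 1L)]
  }
  pids <- rownames(counts)
  elig <- pids[vapply(pids, function(p) length(eligClass(p)) > 0L, logical(1))]
  if (!length(elig)) {
    stop("no eligible participant (need >= 2 samples in one class and >= 1 ",
         "in the other); counts: ",
         paste(utils::capture.output(print(counts)), collapse = "\n"))
  }
  withSeed(seed, {
    a <- p <- n <- integer(nTriplets)
    pid <- cls <- character(nTriplets)
    for (k in seq_len(nTriplets)) {
      u <- sample(elig, 1L)
      cl <- sample(eligClass(u), 1L)
      other <- setdiff(c("rest", "fatigue"), cl)
      same <- which(participants == u & labels == cl)
      opp <- which(participants == u & labels == other)
      ap <- sample(same, 2L)
      a[k] <- ap[1L]; p[k] <- ap[2L]
      n[k] <- opp[sample.int(length(opp), 1L)]
      pid[k] <- u; cls[k] <- cl
    }
    data.frame(a = a, p = p, n = n, participant = pid, anchorClass = cls,
               stringsAsFactors = FALSE)
  })
}

# Core head training on precomputed embeddings.
trainHeadCore <- function(E, labels, participants, config, seed) {
  H <- ncol(E)
  withSeed(seed, {
    W <- glorot(H, config$units)
    b <- numeric(config$units)
    params <- list(W = W, b = b)
    opt <- adamInit(params)
    hist <- data.frame()
    for (ep in seq_len(config$epochs)) {
      lossAcc <- 0
      for (bt in seq_len(config$batchesPerEpoch)) {
        tr <- sampleTriplets(labels, participants, config$tripletsPerBatch)
        idx <- c(tr$a, tr$p, tr$n)
        V <- E[idx, , drop = FALSE]
        Z <- V %*% params$W +
          matrix(params$b, nrow(V), config$units, byrow = TRUE)
        G <- relu(Z)
        tg <- tripletEmbGrad(G, config$tripletsPerBatch, config$margin)
        dZ <- tg$dEmb * (Z > 0)
        grads <- list(W = crossprod(V, dZ), b = colSums(dZ))
        st <- adamStep(opt, params, grads, config$learningRate,
                       config$beta1, config$beta2, config$epsilon)
        params <- st$params; opt <- st$state
        lossAcc <- lossAcc + tg$loss
      }
      hist <- rbind(hist,
                    data.frame(epoch = ep,
                               loss = lossAcc / config$batchesPerEpoch))
    }
    new("FatigueHead", W = params$W, b = params$b, config = config,
        history = hist)
  })
}

#' Train the fatigue-detection head over a frozen backbone
#'
#' The backbone embeds every labeled window once; the dense relu head
#' g(.) is then trained on those fixed embeddings by minimizing the mean
#' hinge triplet loss over same-participant rest/fatigue triplets. The
#' backbone weights are asserted bit-identical before and after.
#'
#' @param backbone a (typically pretrained) [KeystrokeBackbone-class].
#' @param windows labeled window set from [cohortWindows()].
#' @param config from [adaptationConfig()].
#' @param embeddings optional precomputed backbone embeddings for
#'   `windows` (rows aligned), to avoid re-embedding across folds.
#' @return a [FatigueHead-class] with per-epoch loss history.
#' @export
trainFatigueHead <- function(backbone, windows, config = adaptationConfig(),
                             embeddings = NULL) {
  frozen <- backbone@weights
  keep <- windows$label %in% c("rest", "fatigue")
  if (!any(keep)) stop("no labeled rest/fatigue windows")
  E <- if (is.null(embeddings)) embed(backbone, windows) else embeddings
  head <- trainHeadCore(E[keep, , drop = FALSE], windows$label[keep],
                        windows$participant[keep], config,
                        seed = config$seed)
  if (!identical(frozen, backbone@weights))
    stop("frozen-backbone contract violated: backbone weights changed")
  head
}

#' @rdname transformEmbeddings
setMethod("transformEmbeddings", "FatigueHead", function(object, embeddings) {
  relu(embeddings %*% object@W +
         matrix(object@b, nrow(embeddings), length(object@b), byrow = TRUE))
})

#' Leave-one-participant-out protocol
#'
#' Trains one fatigue model per participant, each time excluding every
#' sample of the held-out participant from the training triplets (asserted),
#' then scores the held-out participant's intra-participant sample pairs by
#' Euclidean distance in the fatigue space (`method = "dml"`), or by
#' per-sample fatigue probability (`method = "softmax"`, the binary
#' cross-entropy comparison arm).
#'
#' @param backbone frozen [KeystrokeBackbone-class].
#' @param cohort a labeled [SimulatedCorpus-class] or a `cohortWindows()`
#'   set.
#' @param config from [adaptationConfig()].
#' @param method `"dml"` or `"softmax"`.
#' @param pairPolicy,maxPairsPerClass pair construction for the held-out
#'   participant, see [buildPairs()].
#' @param maxWindowsPerSession optional cap passed to [cohortWindows()].
#' @param embeddings optional precomputed backbone embeddings for the
#'   cohort's windows (rows aligned with the window set).
#' @return list with `method`, `folds` (per-fold head and held-out scores)
#'   and `scores`: for `"dml"` a pair table (participant, distance, truth),
#'   for `"softmax"` a sample table (participant, prob, label).
#' @export
looProtocol <- function(backbone, cohort, config = adaptationConfig(),
                        method = c("dml", "softmax"),
                        pairPolicy = "balanced", maxPairsPerClass = 50L,
                        maxWindowsPerSession = NULL, embeddings = NULL) {
  method <- match.arg(method)
  windows <- if (inherits(cohort, "kfWindows")) cohort else
    cohortWindows(cohort, maxWindowsPerSession = maxWindowsPerSession)
  keep <- windows$label %in% c("rest", "fatigue")
  E <- if (is.null(embeddings)) embed(backbone, windows) else embeddings
  E <- E[keep, , drop = FALSE]
  labels <- windows$label[keep]
  participants <- windows$participant[keep]
  pids <- sort(unique(participants))
  if (length(pids) < 2L) stop("LOO needs >= 2 participants")
  folds <- vector("list", length(pids))
  names(folds) <- pids
  for (f in seq_along(pids)) {
    held <- participants == pids[f]
    foldSeed <- (config$seed %||% 1L) + f
    cfg <- config; cfg$seed <- foldSeed
    if (any(participants[!held] == pids[f]))
      stop("leakage: held-out participant present in training fold")
    if (method == "dml") {
      head <- trainHeadCore(E[!held, , drop = FALSE], labels[!held],
                            participants[!held], cfg, seed = foldSeed)
      G <- transformEmbeddings(head, E[held, , drop = FALSE])
      sc <- buildPairs(G, labels[held], participants[held],
                       policy = pairPolicy, maxPerClass = maxPairsPerClass,
                       seed = foldSeed)
      folds[[f]] <- list(participant = pids[f], head = head, pairs = sc)
    } else {
      head <- trainSoftmaxCore(E[!held, , drop = FALSE], labels[!held],
                               cfg, seed = foldSeed)
      prob <- predictProb(head, E[held, , drop = FALSE])[, "fatigue"]
      sc <- data.frame(participant = pids[f], prob = prob,
                       label = labels[held], stringsAsFactors = FALSE)
      folds[[f]] <- list(participant = pids[f], head = head, scores = sc)
    }
  }
  scores <- do.call(rbind, lapply(folds, function(x)
    if (method == "dml") x$pairs else x$scores))
  rownames(scores) <- NULL
  list(method = method, folds = folds, scores = scores)
}

# Softmax comparison head: dense relu + 2-way softmax, binary cross-entropy.
trainSoftmaxCore <- function(E, labels, config, seed) {
  H <- ncol(E)
  y <- as.integer(labels == "fatigue")  # 1 = fatigue
  withSeed(seed, {
    params <- list(W1 = glorot(H, config$units), b1 = numeric(config$units),
                   W2 = glorot(config$units, 2L), b2 = numeric(2L))
    opt <- adamInit(params)
    hist <- data.frame()
    B <- config$tripletsPerBatch
    for (ep in seq_len(config$epochs)) {
      lossAcc <- 0
      for (bt in seq_len(config$batchesPerEpoch)) {
        idx <- sample.int(nrow(E), min(B, nrow(E)))
        V <- E[idx, , drop = FALSE]
        Z1 <- V %*% params$W1 +
          matrix(params$b1, length(idx), config$units, byrow = TRUE)
        A1 <- relu(Z1)
        Z2 <- A1 %*% params$W2 +
          matrix(params$b2, length(idx), 2L, byrow = TRUE)
        Z2 <- Z2 - apply(Z2, 1L, max)
        P <- exp(Z2) / rowSums(exp(Z2))
        yk <- cbind(1 - y[idx], y[idx])
        lossAcc <- lossAcc - mean(log(pmax(rowSums(P * yk), 1e-12)))
        dZ2 <- (P - yk) / length(idx)
        dA1 <- tcrossprod(dZ2, params$W2)
        dZ1 <- dA1 * (Z1 > 0)
        grads <- list(W1 = crossprod(V, dZ1), b1 = colSums(dZ1),
                      W2 = crossprod(A1, dZ2), b2 = colSums(dZ2))
        st <- adamStep(opt, params, grads, config$learningRate,
                       config$beta1, config$beta2, config$epsilon)
        params <- st$params; opt <- st$state
      }
      hist <- rbind(hist, data.frame(epoch = ep,
                                     loss = lossAcc / config$batchesPerEpoch))
    }
    new("SoftmaxHead", W1 = params$W1, b1 = params$b1, W2 = params$W2,
        b2 = params$b2, config = config, history = hist)
  })
}

#' Train the softmax comparison head over a frozen backbone
#'
#' Same frozen-backbone regime as [trainFatigueHead()], but the head is a
#' binary rest/fatigue classifier (dense relu + softmax, binary
#' cross-entropy) instead of a metric-learning transformation. Used only as
#' a comparison arm.
#'
#' @inheritParams trainFatigueHead
#' @return a [SoftmaxHead-class].
#' @export
trainSoftmaxVariant <- function(backbone, windows,
                                config = adaptationConfig(),
                                embeddings = NULL) {
  frozen <- backbone@weights
  keep <- windows$label %in% c("rest", "fatigue")
  if (!any(keep)) stop("no labeled rest/fatigue windows")
  E <- if (is.null(embeddings)) embed(backbone, windows) else embeddings
  head <- trainSoftmaxCore(E[keep, , drop = FALSE], windows$label[keep],
                           config, seed = config$seed)
  if (!identical(frozen, backbone@weights))
    stop("frozen-backbone contract violated: backbone weights changed")
  head
}

#' @rdname predictProb
setMethod("predictProb", "SoftmaxHead", function(object, embeddings) {
  A1 <- relu(embeddings %*% object@W1 +
               matrix(object@b1, nrow(embeddings), length(object@b1),
                      byrow = TRUE))
  Z2 <- A1 %*% object@W2 +
    matrix(object@b2, nrow(embeddings), 2L, byrow = TRUE)
  Z2 <- Z2 - apply(Z2, 1L, max)
  P <- exp(Z2) / rowSums(exp(Z2))
  colnames(P) <- c("rest", "fatigue")
  P
})
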