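#' Build intra-participant change/no-change sample pairs
#'
#' Every pair joins two samples of one participant; the pair is a *change*
#' pair when the two labels differ (fatigue-to-rest or rest-to-fatigue) and
#' *no_change* otherwise. Pairs are unordered. Under the `"balanced"`
#' policy each truth class is subsampled to at most `maxPerClass` pairs per
#' participant, with the two classes equalised.
#'
#' @param embeddings fatigue-space embedding matrix (one sample per row).
#' @param labels `"rest"`/`"fatigue"` per sample.
#' @param participants participant id per sample.
#' @param policy `"balanced"` or `"all"`.
#' @param maxPerClass per-participant, per-class pair cap (balanced policy).
#' @param seed RNG seed for subsampling.
#' @param setupTag free tag recorded on the pairs (e.g. `"150keys"`).
#' @return data.frame with columns participant, i, j, distance, truth
#'   (`"change"`/`"no_change"`), setup.
#' @export
buildPairs <- function(embeddings, labels, participants,
                       policy = c("balanced", "all"), maxPerClass = 50L,
                       seed = NULL, setupTag = "150keys") {
  policy <- match.arg(policy)
  stopifnot(nrow(embeddings) == length(labels),
            length(labels) == length(participants))
  withSeed(seed, {
    out <- list()
    for (pid in unique(participants)) {
      idx <- which(participants == pid)
      if (length(idx) < 2L) next
      cmb <- utils::combn(idx, 2L)
      truth <- ifelse(labels[cmb[1L, ]] == labels[cmb[2L, ]],
                      "no_change", "change")
      if (policy == "balanced") {
        chg <- which(truth == "change"); noc <- which(truth == "no_change")
        m <- min(length(chg), length(noc), maxPerClass)
        pick <- c(if (length(chg) > m) sample(chg, m) else chg,
                  if (length(noc) > m) sample(noc, m) else noc)
        cmb <- cmb[, pick, drop = FALSE]; truth <- truth[pick]
      }
      if (!ncol(cmb)) next
      d <- rowDistance(embeddings[cmb[1L, ], , drop = FALSE],
                       embeddings[cmb[2L, ], , drop = FALSE])
      out[[pid]] <- data.frame(participant = pid, i = cmb[1L, ],
                               j = cmb[2L, ], distance = d, truth = truth,
                               setup = setupTag, stringsAsFactors = FALSE)
    }
    if (!length(out)) stop("no participant with >= 2 samples")
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

# Full ROC of `score` predicting `positive` (higher score => positive call):
# one point per distinct cutoff, plus the two trivial endpoints.
rocPoints <- function(score, positive) {
  o <- order(score, decreasing = TRUE)
  tp <- cumsum(positive[o]); fp <- cumsum(!positive[o])
  keep <- c(diff(score[o]) != 0, TRUE)  # last point of each tied block
  data.frame(fpr = c(0, fp[keep] / sum(!positive)),
             tpr = c(0, tp[keep] / sum(positive)),
             cutoff = c(Inf, score[o][keep]))
}

#' ROC analysis of change/no-change pair scores
#'
#' A pair's score is its fatigue-space distance; a score above the cutoff
#' calls a change. `aggregation = "pooled"` computes one ROC over all
#' cross-validated pairs; `"averaged"` computes each participant's ROC
#' independently and vertically averages the TPR on a common FPR grid.
#' AUC is the trapezoid area. Operating-point metrics (sensitivity,
#' specificity, precision, F1) are taken at the closest-to-(0,1) ROC corner
#' on the pooled scores.
#'
#' @param pairs data.frame from [buildPairs()] (or any table with columns
#'   participant, distance, truth).
#' @param aggregation `"pooled"` or `"averaged"`.
#' @param fprGrid FPR grid for vertical averaging.
#' @return a [DetectionReport-class] (rates in percent).
#' @export
rocAnalysis <- function(pairs, aggregation = c("pooled", "averaged"),
                        fprGrid = seq(0, 1, length.out = 101L)) {
  aggregation <- match.arg(aggregation)
  positive <- pairs$truth == "change"
  if (all(positive) || !any(positive))
    stop("both truth classes (change / no_change) are required")
  if (aggregation == "pooled") {
    roc <- rocPoints(pairs$distance, positive)[, c("fpr", "tpr")]
    auc <- trapezoid(roc$fpr, roc$tpr)
  } else {
    pids <- unique(pairs$participant)
    tprs <- vapply(pids, function(pid) {
      sub <- pairs[pairs$participant == pid, ]
      pos <- sub$truth == "change"
      if (all(pos) || !any(pos)) return(rep(NA_real_, length(fprGrid)))
      r <- rocPoints(sub$distance, pos)
      stats::approx(r$fpr, r$tpr, xout = fprGrid, ties = max,
                    rule = 2L)$y
    }, numeric(length(fprGrid)))
    tpr <- rowMeans(tprs, na.rm = TRUE)
    roc <- data.frame(fpr = fprGrid, tpr = tpr)
    auc <- trapezoid(fprGrid, tpr)
  }
  op <- operatingPoint(pairs$distance, positive)
  new("DetectionReport", auc = 100 * auc, sensitivity = op$sensitivity,
      specificity = op$specificity, precision = op$precision, f1 = op$f1,
      roc = roc, aggregation = aggregation, nPairs = nrow(pairs))
}

#' Operating point at the closest-to-(0,1) ROC corner
#'
#' Chooses the cutoff minimising the Euclidean distance to the ideal corner
#' (FPR 0, TPR 1) in the ROC plane, ties broken toward higher TPR, and
#' reports the confusion metrics at that cutoff.
#'
#' @param score numeric scores (higher = more likely positive).
#' @param positive logical truth per score.
#' @return list with cutoff and sensitivity, specificity, precision, f1
#'   (percent).
#' @export
operatingPoint <- function(score, positive) {
  positive <- as.logical(positive)
  r <- rocPoints(score, positive)
  d2 <- r$fpr^2 + (1 - r$tpr)^2
  best <- which(d2 == min(d2))
  best <- best[which.max(r$tpr[best])]
  cutoff <- r$cutoff[best]
  call <- score >= cutoff
  tp <- sum(call & positive); fn <- sum(!call & positive)
  fp <- sum(call & !positive); tn <- sum(!call & !positive)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && prec + sens > 0)
    2 * prec * sens / (prec + sens) else NA_real_
  list(cutoff = cutoff, sensitivity = 100 * sens, specificity = 100 * spec,
       precision = 100 * prec, f1 = 100 * f1)
}

# Per-sample summary statistics: 4 timing features x
# (mean, median, sd, q25, q75) over the valid rows = 20 columns.
summaryFeatures <- function(mats) {
  stats5 <- function(v) c(mean = mean(v), median = stats::median(v),
                          sd = stats::sd(v),
                          q25 = unname(stats::quantile(v, 0.25)),
                          q75 = unname(stats::quantile(v, 0.75)))
  t(vapply(mats, function(m) {
    unlist(lapply(seq_len(ncol(m)), function(j) stats5(m[, j])))
  }, numeric(20L)))
}

#' Statistical-feature baseline classifiers
#'
#' The comparison arm built on classical classifiers: each sample (a
#' 150-key window, or a full 5-minute span for the `"5min"` setup) is
#' summarised by 20 statistics (mean, median, sd, 25th and 75th percentile
#' of each timing feature) and classified rest vs fatigue by random forest,
#' Gaussian-kernel SVM and k-NN under the same leave-one-participant-out
#' folds as the metric-learning model. AUC is computed from the pooled
#' held-out fatigue probabilities.
#'
#' @param corpus labeled [SimulatedCorpus-class].
#' @param setup `"150keys"` (fixed-length windows) or `"5min"`
#'   (time-based windows, not truncated).
#' @param methods subset of `c("rf", "svm", "knn")`.
#' @param seed RNG seed (forest bootstrap etc.).
#' @param ntree random-forest size.
#' @param k k-NN neighbourhood size.
#' @param minutes span of a time window in the `"5min"` setup.
#' @param maxWindowsPerSession optional per-session cap (150keys setup).
#' @return named list of [DetectionReport-class], one per method, each with
#'   the held-out score table in attribute `"scores"`.
#' @export
baselineClassifiers <- function(corpus, setup = c("150keys", "5min"),
                                methods = c("rf", "svm", "knn"), seed = 1L,
                                ntree = 100L, k = 5L, minutes = 5,
                                maxWindowsPerSession = NULL) {
  setup <- match.arg(setup)
  sess <- sessions(corpus)
  labs <- vapply(sess, sessionLabel, character(1))
  keep <- which(labs %in% c("rest", "fatigue"))
  mats <- list(); pid <- lab <- character()
  for (i in keep) {
    wins <- if (setup == "150keys") {
      w <- segmentSession(sess[[i]])
      if (!is.null(maxWindowsPerSession))
        w <- w[seq_len(min(length(w), maxWindowsPerSession))]
      lapply(w, function(fm)
        featureValues(fm)[seq_len(validLength(fm)), , drop = FALSE])
    } else timeWindowFeatures(sess[[i]], minutes = minutes)
    for (m in wins) {
      mats[[length(mats) + 1L]] <- m
      pid <- c(pid, participantId(sess[[i]]))
      lab <- c(lab, sessionLabel(sess[[i]]))
    }
  }
  X <- summaryFeatures(mats)
  y <- factor(lab, levels = c("rest", "fatigue"))
  pids <- sort(unique(pid))
  out <- list()
  for (mth in methods) {
    prob <- numeric(nrow(X))
    withSeed(seed, {
      for (f in pids) {
        held <- pid == f
        if (nlevels(droplevels(y[!held])) < 2L)
          stop("training fold with a single class for held-out ", f)
        xtr <- X[!held, , drop = FALSE]; ytr <- y[!held]
        xte <- X[held, , drop = FALSE]
        prob[held] <- switch(mth,
          rf = {
            fit <- randomForest::randomForest(xtr, ytr, ntree = ntree)
            stats::predict(fit, xte, type = "prob")[, "fatigue"]
          },
          svm = {
            fit <- e1071::svm(xtr, ytr, kernel = "radial",
                              probability = TRUE)
            attr(stats::predict(fit, xte, probability = TRUE),
                 "probabilities")[, "fatigue"]
          },
          knn = {
            mu <- colMeans(xtr); sg <- pmax(apply(xtr, 2L, stats::sd), 1e-12)
            fit <- caret::knn3(scale(xtr, mu, sg), ytr, k = k)
            stats::predict(fit, scale(xte, mu, sg),
                           type = "prob")[, "fatigue"]
          },
          stop("unknown method: ", mth))
      }
    })
    pos <- y == "fatigue"
    roc <- rocPoints(prob, pos)[, c("fpr", "tpr")]
    op <- operatingPoint(prob, pos)
    rep <- new("DetectionReport", auc = 100 * trapezoid(roc$fpr, roc$tpr),
               sensitivity = op$sensitivity, specificity = op$specificity,
               precision = op$precision, f1 = op$f1, roc = roc,
               aggregation = "pooled", nPairs = nrow(X))
    attr(rep, "scores") <- data.frame(participant = pid, prob = prob,
                                      label = lab, stringsAsFactors = FALSE)
    out[[mth]] <- rep
  }
  out
}
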