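#' Project fatigue embeddings to a one-dimensional score
#'
#' The active detector works on a scalar per session. Two projections are
#' offered. `"centroid_axis"` (default, deterministic and inductive):
#' the signed projection of g(v(x)) onto the unit vector from the rest
#' centroid to the fatigue centroid of the labeled reference embeddings.
#' `"tsne1d"`: a seeded one-dimensional t-SNE fitted jointly on the
#' reference and incoming embeddings (transductive and seed-sensitive;
#' retained for fidelity to the original design), sign-aligned so fatigue
#' reference scores exceed rest ones.
#'
#' @param embeddings matrix of incoming fatigue-space embeddings.
#' @param method `"centroid_axis"` or `"tsne1d"`.
#' @param reference list with `embeddings` (matrix) and `labels`
#'   (`"rest"`/`"fatigue"`) — required for `centroid_axis`, used for
#'   orientation by `tsne1d`.
#' @param seed RNG seed (`tsne1d` initialisation).
#' @param perplexity t-SNE perplexity.
#' @return numeric scalar score per incoming embedding.
#' @export
projectToScalar <- function(embeddings, method = c("centroid_axis", "tsne1d"),
                            reference = NULL, seed = 1L, perplexity = 10) {
  method <- match.arg(method)
  if (is.vector(embeddings)) embeddings <- matrix(embeddings, nrow = 1L)
  if (method == "centroid_axis") {
    if (is.null(reference))
      stop("centroid_axis needs labeled reference embeddings")
    cr <- colMeans(reference$embeddings[reference$labels == "rest", ,
                                        drop = FALSE])
    cf <- colMeans(reference$embeddings[reference$labels == "fatigue", ,
                                        drop = FALSE])
    axis <- cf - cr
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-12) stop("rest and fatigue centroids coincide")
    return(as.numeric((embeddings - matrix(cr, nrow(embeddings),
                                           length(cr), byrow = TRUE)) %*%
                        (axis / nrm)))
  }
  refE <- if (!is.null(reference)) reference$embeddings else NULL
  X <- rbind(refE, embeddings)
  if (nrow(X) < 2L) stop("tsne1d needs at least 2 points")
  y <- tsne1dFit(X, perplexity = perplexity, seed = seed)
  nRef <- if (is.null(refE)) 0L else nrow(refE)
  if (nRef > 0L && !is.null(reference$labels)) {
    mr <- mean(y[seq_len(nRef)][reference$labels == "rest"])
    mf <- mean(y[seq_len(nRef)][reference$labels == "fatigue"])
    if (is.finite(mr) && is.finite(mf) && mf < mr) y <- -y
  }
  y[(nRef + 1L):nrow(X)]
}

# Minimal exact 1-D t-SNE (perplexity-calibrated Gaussian affinities,
# Student-t low-dimensional kernel, momentum gradient descent with early
# exaggeration). O(n^2) per iteration; intended for the modest per-
# participant sample counts this detector sees.
tsne1dFit <- function(X, perplexity = 10, maxIter = 300L, eta = 50,
                      seed = 1L) {
  n <- nrow(X)
  perplexity <- min(perplexity, (n - 1) / 3)
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) { beta <- beta / 2; next }
      H <- log(sw) + beta * sum(di * w) / sw
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- w / sum(w)
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  withSeed(seed, {
    y <- stats::rnorm(n) * 1e-4
    inc <- numeric(n)
    for (it in seq_len(maxIter)) {
      Pe <- if (it <= 50L) P * 4 else P
      num <- 1 / (1 + outer(y, y, "-")^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      g <- 4 * colSums((Pe - Q) * num * outer(y, y, "-") * -1)
      mom <- if (it <= 20L) 0.5 else 0.8
      inc <- mom * inc - eta * g
      y <- y + inc
      y <- y - mean(y)
    }
    y
  })
}

#' Estimate rest/fatigue score densities
#'
#' Gaussian kernel density estimators of the scalar fatigue scores of each
#' class, with Silverman's rule-of-thumb bandwidth by default and a small
#' positive floor applied at evaluation so the log-likelihood ratio stays
#' finite outside the kernel support.
#'
#' @param restScores,fatigueScores numeric score samples.
#' @param bw `"silverman"` or a numeric bandwidth (used for both classes).
#' @param minScores minimum scores per class.
#' @param floor density evaluation floor.
#' @return a [ScoreDensities-class].
#' @export
estimateDensities <- function(restScores, fatigueScores, bw = "silverman",
                              minScores = 5L, floor = 1e-12) {
  if (length(restScores) < minScores || length(fatigueScores) < minScores)
    stop("too few scores per class (need >= ", minScores,
         "); consider falling back to pooled-cohort densities")
  if (stats::sd(restScores) == 0 || stats::sd(fatigueScores) == 0)
    stop("degenerate bandwidth: all scores in one class are equal")
  bws <- if (is.numeric(bw)) c(rest = bw, fatigue = bw) else
    c(rest = stats::bw.nrd0(restScores),
      fatigue = stats::bw.nrd0(fatigueScores))
  if (any(!is.finite(bws)) || any(bws <= 0))
    stop("degenerate bandwidth (all scores equal?)")
  new("ScoreDensities", restScores = as.numeric(restScores),
      fatigueScores = as.numeric(fatigueScores), bw = bws,
      floor = floor)
}

#' Evaluate a fitted score density
#'
#' @param densities a [ScoreDensities-class].
#' @param x evaluation points.
#' @param class `"rest"` or `"fatigue"`.
#' @return kernel density values at `x`, floored at the density floor.
#' @export
densityValues <- function(densities, x, class = c("rest", "fatigue")) {
  class <- match.arg(class)
  s <- if (class == "rest") densities@restScores else
    densities@fatigueScores
  h <- densities@bw[[class]]
  v <- vapply(x, function(xx) mean(stats::dnorm(xx, s, h)), numeric(1))
  pmax(v, densities@floor)
}

#' Session log-likelihood ratio
#'
#' `L = ln f_F(score) - ln f_R(score)`: negative when the score looks like
#' a rested session, positive when it looks fatigued. Densities are floored
#' so L is always finite.
#'
#' @param score scalar fatigue score(s).
#' @param densities a [ScoreDensities-class].
#' @return log-likelihood ratio(s).
#' @export
llr <- function(score, densities) {
  log(densityValues(densities, score, "fatigue")) -
    log(densityValues(densities, score, "rest"))
}

#' Initialise an active-detector state
#'
#' @param tau detection threshold.
#' @return an [AFDState-class] with S = 0, j = 0 and empty history.
#' @export
afdState <- function(tau = Inf) {
  new("AFDState", S = 0, j = 0L, tau = tau,
      history = data.frame(score = numeric(), L = numeric(),
                           S = numeric()))
}

#' Update the cumulative detector with one session
#'
#' Page-style clamped CUSUM: `S_j = max(0, S_{j-1} + L_j)`, so the score
#' idles near zero while the typist is rested and climbs once consecutive
#' sessions look fatigued. Detection is flagged when S reaches the
#' threshold tau.
#'
#' @param state an [AFDState-class].
#' @param L log-likelihood ratio of the new session.
#' @param score optional raw score, recorded in the history.
#' @return the updated state.
#' @export
updateCusum <- function(state, L, score = NA_real_) {
  state@S <- max(0, state@S + L)
  state@j <- state@j + 1L
  state@history <- rbind(state@history,
                         data.frame(score = score, L = L, S = state@S))
  state
}

#' @rdname updateCusum
#' @param object an [AFDState-class].
#' @return `afdDetected`: TRUE once S has reached tau.
#' @export
afdDetected <- function(object) object@S >= object@tau

#' Run the clamped CUSUM recursion over a score sequence
#'
#' @param L numeric vector of per-session log-likelihood ratios.
#' @return numeric vector of cumulative scores S_j.
#' @export
runCusum <- function(L) {
  S <- numeric(length(L))
  s <- 0
  for (j in seq_along(L)) {
    s <- max(0, s + L[j])
    S[j] <- s
  }
  S
}

#' Threshold-sweep evaluation of the active detector
#'
#' Each input sequence is a per-session log-likelihood ratio trace with a
#' known change point (sessions at and after `changeIndex` are fatigued).
#' Sweeping the threshold tau yields: PFD, the fraction of sequences whose
#' cumulative score crosses tau before the change point; PND, the fraction
#' never crossing at or after it; and ADD, the mean number of sessions from
#' the change to the first crossing, with non-detections censored at the
#' sequence end (this censored mean is non-decreasing in tau, unlike the
#' mean over the shrinking detected subset, which is also reported). The
#' EER is the PFD = PND crossing, found by linear interpolation on the
#' grid.
#'
#' @param sequences list of lists with elements `L` (numeric trace) and
#'   `changeIndex` (first fatigued session, 1-based).
#' @param thresholds optional threshold grid; default 200 values spanning
#'   the observed cumulative-score range from 0.
#' @param nThresholds grid size when `thresholds` is NULL.
#' @return an [AFDMetrics-class].
#' @export
evaluateAfd <- function(sequences, thresholds = NULL, nThresholds = 200L) {
  if (!length(sequences)) stop("no sequences")
  Ss <- lapply(sequences, function(q) runCusum(q$L))
  chg <- vapply(sequences, function(q) as.integer(q$changeIndex),
                integer(1))
  if (is.null(thresholds)) {
    smax <- max(unlist(Ss))
    thresholds <- seq(0, smax * (1 + 1e-9) + 1e-12,
                      length.out = nThresholds)
  }
  evalAt <- function(tau) {
    pre <- post <- logical(length(Ss))
    delay <- numeric(length(Ss))
    for (i in seq_along(Ss)) {
      S <- Ss[[i]]; ci <- chg[i]
      hit <- which(S >= tau)
      pre[i] <- any(hit < ci)
      hp <- hit[hit >= ci]
      post[i] <- length(hp) > 0L
      delay[i] <- if (post[i]) hp[1L] - ci + 1L else length(S) - ci + 1L
    }
    c(pfd = mean(pre), pnd = mean(!post),
      add = mean(delay),
      addDet = if (any(post)) mean(delay[post]) else NA_real_,
      addMed = stats::median(delay))
  }
  m <- vapply(thresholds, evalAt, numeric(5L))
  if (is.null(dim(m))) m <- matrix(m, ncol = 1L,
                                   dimnames = list(names(m), NULL))
  pfd <- unname(m["pfd", ]); pnd <- unname(m["pnd", ])
  dd <- pfd - pnd
  cross <- which(dd[-length(dd)] >= 0 & dd[-1L] < 0)
  if (length(cross)) {
    k <- cross[1L]
    w <- dd[k] / (dd[k] - dd[k + 1L])
    eerTau <- thresholds[k] + w * (thresholds[k + 1L] - thresholds[k])
    eer <- pfd[k] + w * (pfd[k + 1L] - pfd[k])
  } else if (any(dd == 0)) {
    k <- which(dd == 0)[1L]
    eerTau <- thresholds[k]; eer <- pfd[k]
  } else {
    k <- which.min(abs(dd))
    eerTau <- thresholds[k]; eer <- (pfd[k] + pnd[k]) / 2
  }
  atEer <- evalAt(eerTau)
  new("AFDMetrics", thresholds = thresholds, pfd = pfd, pnd = pnd,
      add = unname(m["add", ]), addDetected = unname(m["addDet", ]),
      eer = unname(eer), eerThreshold = unname(eerTau),
      addAtEer = atEer[["add"]], addMedianAtEer = atEer[["addMed"]])
}

#' Hourly fatigue trend from an unlabeled daily stream
#'
#' Scores every eligible consecutive-session pair of each participant's
#' stream — sessions less than `maxGapHours` apart within the same day —
#' against the participant's running reference (the mean of all their
#' earlier session embeddings), then aggregates the scores by hour of day
#' of the later session with bootstrap confidence intervals. Hours with no
#' eligible pair are absent from the result (missing, not zero).
#'
#' Two pair scores are available. With a labeled `reference` (embeddings
#' of a supervised cohort in the same space), the default `"axis"` score
#' is the component of the session's deviation from the running reference
#' along the cohort's rest-to-fatigue centroid axis: signed, so slowing
#' beyond the personal baseline raises the score and unusually brisk
#' typing lowers it. `"distance"` is the plain Euclidean distance to the
#' running reference (unsigned: any atypicality raises it).
#'
#' @param corpus a stream [SimulatedCorpus-class] (or session list) whose
#'   sessions carry wall-clock starts.
#' @param backbone frozen [KeystrokeBackbone-class].
#' @param head optional [FatigueHead-class]; if given, scoring happens in
#'   the fatigue space g(v(x)), otherwise in the typing space v(x).
#' @param reference optional list with `embeddings` and `labels`
#'   (`"rest"`/`"fatigue"`), already in the scoring space, defining the
#'   rest-to-fatigue axis.
#' @param scoreType `"axis"` (default when a reference is given) or
#'   `"distance"`.
#' @param maxGapHours maximum elapsed time between paired sessions.
#' @param nBoot bootstrap resamples per hourly bin.
#' @param ciLevel confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame with columns hour, mean, ciLow, ciHigh, n; attribute
#'   `"pairScores"` holds the per-pair table (participant, hour, score,
#'   startTime).
#' @export
dailyFatigueTrend <- function(corpus, backbone, head = NULL,
                              reference = NULL, scoreType = NULL,
                              maxGapHours = 2, nBoot = 200L,
                              ciLevel = 0.95, seed = 1L) {
  scoreType <- scoreType %||% if (!is.null(reference)) "axis" else "distance"
  scoreType <- match.arg(scoreType, c("axis", "distance"))
  win <- cohortWindows(corpus, policy = "first_only")
  if (any(is.na(win$startTime)))
    stop("stream sessions must carry wall-clock start times")
  E <- embed(backbone, win)
  if (!is.null(head)) E <- transformEmbeddings(head, E)
  axis <- NULL
  if (scoreType == "axis") {
    if (is.null(reference))
      stop("scoreType 'axis' needs a labeled reference")
    cr <- colMeans(reference$embeddings[reference$labels == "rest", ,
                                        drop = FALSE])
    cf <- colMeans(reference$embeddings[reference$labels == "fatigue", ,
                                        drop = FALSE])
    axis <- cf - cr
    nrm <- sqrt(sum(axis^2))
    if (nrm < 1e-12) stop("rest and fatigue centroids coincide")
    axis <- axis / nrm
  }
  pairs <- list()
  for (pid in unique(win$participant)) {
    idx <- which(win$participant == pid)
    idx <- idx[order(win$startTime[idx])]
    if (length(idx) < 2L) next
    st <- win$startTime[idx]
    ref <- E[idx[1L], ]
    for (k in 2L:length(idx)) {
      gap <- st[k] - st[k - 1L]
      sameDay <- floor(st[k] / 86400) == floor(st[k - 1L] / 86400)
      if (gap > 0 && gap < maxGapHours * 3600 && sameDay) {
        dev <- E[idx[k], ] - ref
        score <- if (scoreType == "axis") sum(dev * axis) else
          sqrt(sum(dev^2))
        pairs[[length(pairs) + 1L]] <- data.frame(
          participant = pid, hour = floor((st[k] %% 86400) / 3600),
          score = score, startTime = st[k], stringsAsFactors = FALSE)
      }
      # running reference: mean of this participant's first k embeddings
      ref <- ref + (E[idx[k], ] - ref) / k
    }
  }
  if (!length(pairs)) stop("no eligible consecutive-session pair")
  tab <- do.call(rbind, pairs)
  alpha <- (1 - ciLevel) / 2
  out <- withSeed(seed, {
    do.call(rbind, lapply(sort(unique(tab$hour)), function(h) {
      sc <- tab$score[tab$hour == h]
      bm <- vapply(seq_len(nBoot), function(b)
        mean(sample(sc, length(sc), replace = TRUE)), numeric(1))
      data.frame(hour = h, mean = mean(sc),
                 ciLow = unname(stats::quantile(bm, alpha)),
                 ciHigh = unname(stats::quantile(bm, 1 - alpha)),
                 n = length(sc))
    }))
  })
  attr(out, "pairScores") <- tab
  out
}

#' Assemble simulated rest-to-fatigue session sequences for the detector
#'
#' Reproduces the continuous-detection construction: for every held-out
#' participant of a leave-one-out run, a monitoring sequence is simulated
#' by concatenating `nRest` rest windows followed by `nFatigue` fatigue
#' windows of that participant. Each window's fatigue embedding is
#' projected to a scalar score (against the training folds' labeled
#' reference), class score densities are fitted, and the per-session
#' log-likelihood ratios are returned ready for [evaluateAfd()].
#'
#' By default the densities are the participant's own remaining rest and
#' fatigue scores (each scored session is compared against the
#' distribution of the participant's other sessions), which absorbs the
#' strong participant-specific score offsets; `"training"` fits them from
#' the training participants' scores instead (fully subject-independent
#' calibration, at the cost of those offsets).
#'
#' @param backbone frozen [KeystrokeBackbone-class].
#' @param cohort the labeled cohort (corpus or `cohortWindows()` set) the
#'   LOO run was computed on.
#' @param loo result of [looProtocol()] (`method = "dml"`) on that cohort.
#' @param nRest,nFatigue windows per phase (change point at `nRest + 1`).
#' @param method projection, see [projectToScalar()].
#' @param densitySource `"participant"` (default; the held-out
#'   participant's remaining scores) or `"training"` (training folds'
#'   scores only).
#' @param seed RNG seed (window sampling, t-SNE).
#' @param embeddings optional precomputed backbone embeddings for the
#'   cohort's windows.
#' @return list of per-participant lists with `L`, `changeIndex`,
#'   `scores`, `participant`.
#' @export
afdSequences <- function(backbone, cohort, loo, nRest = 15L,
                         nFatigue = 15L, method = "centroid_axis",
                         densitySource = c("participant", "training"),
                         seed = 1L, embeddings = NULL) {
  densitySource <- match.arg(densitySource)
  windows <- if (inherits(cohort, "kfWindows")) cohort else
    cohortWindows(cohort)
  keep <- windows$label %in% c("rest", "fatigue")
  E <- if (is.null(embeddings)) embed(backbone, windows) else embeddings
  E <- E[keep, , drop = FALSE]
  labels <- windows$label[keep]
  participants <- windows$participant[keep]
  withSeed(seed, {
    out <- list()
    for (fold in loo$folds) {
      pid <- fold$participant
      held <- participants == pid
      G <- transformEmbeddings(fold$head, E)
      ref <- list(embeddings = G[!held, , drop = FALSE],
                  labels = labels[!held])
      pick <- function(cls, n) {
        i <- which(held & labels == cls)
        if (!length(i)) stop("held-out participant ", pid, " has no ",
                             cls, " windows")
        sample(i, n, replace = length(i) < n)
      }
      seqIdx <- c(pick("rest", nRest), pick("fatigue", nFatigue))
      sc <- projectToScalar(G[seqIdx, , drop = FALSE], method = method,
                            reference = ref, seed = seed)
      dens <- if (densitySource == "training") {
        trSc <- projectToScalar(ref$embeddings, method = method,
                                reference = ref, seed = seed)
        estimateDensities(trSc[ref$labels == "rest"],
                          trSc[ref$labels == "fatigue"])
      } else {
        hSc <- projectToScalar(G[held, , drop = FALSE], method = method,
                               reference = ref, seed = seed)
        estimateDensities(hSc[labels[held] == "rest"],
                          hSc[labels[held] == "fatigue"])
      }
      out[[pid]] <- list(L = llr(sc, dens), changeIndex = nRest + 1L,
                         scores = sc, participant = pid)
    }
    out
  })
}
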