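#' @import methods
NULL

#' KeystrokeSession: one typing sitting for one participant
#'
#' Ordered press/release events for a single keystroke session, together with
#' the participant identifier, an optional fatigue label and an optional
#' wall-clock start. Times are stored in seconds; `events` must be ordered by
#' press time and every release must be at or after its press.
#'
#' @slot participantId character, opaque participant identifier.
#' @slot events data.frame with numeric columns `pressTime`, `releaseTime`
#'   and (optionally all-`NA`) `keycode`, ordered by `pressTime`.
#' @slot label one of `"rest"`, `"fatigue"`, `"unknown"`.
#' @slot startTime numeric wall-clock start in seconds since an arbitrary
#'   epoch (UTC), or `NA` when unknown.
#' @slot contextTag free-form cohort/session tag.
#' @exportClass KeystrokeSession
setClass("KeystrokeSession",
  representation(
    participantId = "character",
    events = "data.frame",
    label = "character",
    startTime = "numeric",
    contextTag = "character"
  ),
  prototype(label = "unknown", startTime = NA_real_, contextTag = "")
)

setValidity("KeystrokeSession", function(object) {
  ev <- object@events
  msg <- character()
  if (!all(c("pressTime", "releaseTime") %in% names(ev)))
    msg <- c(msg, "events must have pressTime and releaseTime columns")
  else {
    if (nrow(ev) < 1L) msg <- c(msg, "events must be non-empty")
    if (nrow(ev) >= 1L) {
      if (!all(is.finite(ev$pressTime)) || !all(is.finite(ev$releaseTime)))
        msg <- c(msg, "event times must be finite")
      else {
        if (any(ev$releaseTime < ev$pressTime))
          msg <- c(msg, "releaseTime must be >= pressTime for every event")
        if (is.unsorted(ev$pressTime))
          msg <- c(msg, "events must be ordered by non-decreasing pressTime")
      }
    }
  }
  if (!object@label %in% c("rest", "fatigue", "unknown"))
    msg <- c(msg, "label must be one of rest, fatigue, unknown")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: fixed-size timing representation of a typing window
#'
#' The 150 x 4 matrix of per-key timing features (hold, flight, inter-key
#' latency, inter-release latency), in seconds, fed to the embedding network.
#' Rows at and beyond `validLength` are exactly zero (padding).
#'
#' @slot values 150 x 4 numeric matrix, columns hold/flight/ikl/irl.
#' @slot validLength integer in 1..150, number of non-padded rows.
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  representation(values = "matrix", validLength = "integer")
)

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v) || ncol(v) != 4L)
    msg <- c(msg, "values must be a numeric matrix with 4 columns")
  else {
    n <- nrow(v)
    vl <- object@validLength
    if (length(vl) != 1L || is.na(vl) || vl < 1L || vl > n)
      msg <- c(msg, "validLength must be a single integer in 1..nrow")
    else {
      if (vl < n && any(v[(vl + 1L):n, ] != 0))
        msg <- c(msg, "rows beyond validLength must be exactly zero")
      if (any(v[seq_len(vl), 1L] < 0))
        msg <- c(msg, "hold times must be >= 0 for valid rows")
    }
    if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' TypistProfile: generative timing model for one synthetic typist
#'
#' Parametrizes the synthetic typist: log-normal hold and inter-key latency
#' distributions, a rollover probability (key pressed before the previous
#' release, giving negative inter-key latencies), a multiplicative fatigue
#' effect on the log-scale mean and dispersion, and a circadian profile used
#' by the daily-stream generator.
#'
#' @slot userId character identifier.
#' @slot holdLogNorm named numeric `(mu, sigma)` of log hold time (log-seconds).
#' @slot iklLogNorm named numeric `(mu, sigma)` of log inter-key latency.
#' @slot rolloverProb probability in `[0,1]` of a rollover keypress.
#' @slot fatigueEffect named numeric `(meanScale, sdScale)`, both `>= 1`:
#'   multiplicative slowing of the median and inflation of the log-sd under
#'   full fatigue.
#' @slot circadian named numeric `(amplitude, acrophaseHour, postlunchDip)`;
#'   amplitude in `[0,1]`, acrophase = hour of peak fatigue.
#' @exportClass TypistProfile
setClass("TypistProfile",
  representation(
    userId = "character",
    holdLogNorm = "numeric",
    iklLogNorm = "numeric",
    rolloverProb = "numeric",
    fatigueEffect = "numeric",
    circadian = "numeric"
  )
)

setValidity("TypistProfile", function(object) {
  msg <- character()
  if (length(object@holdLogNorm) != 2L || object@holdLogNorm[2L] < 0)
    msg <- c(msg, "holdLogNorm must be (mu, sigma) with sigma >= 0")
  if (length(object@iklLogNorm) != 2L || object@iklLogNorm[2L] < 0)
    msg <- c(msg, "iklLogNorm must be (mu, sigma) with sigma >= 0")
  if (object@rolloverProb < 0 || object@rolloverProb > 1)
    msg <- c(msg, "rolloverProb must be in [0,1]")
  if (length(object@fatigueEffect) != 2L || any(object@fatigueEffect < 1))
    msg <- c(msg, "fatigueEffect must be (meanScale, sdScale), both >= 1")
  if (length(object@circadian) != 3L ||
      object@circadian[1L] < 0 || object@circadian[1L] > 1)
    msg <- c(msg, "circadian must be (amplitude in [0,1], acrophaseHour, postlunchDip)")
  if (length(msg)) msg else TRUE
})

#' SimulatedCorpus: labeled synthetic keystroke sessions with ground truth
#'
#' @slot sessions list of [KeystrokeSession-class] objects.
#' @slot groundTruth numeric latent fatigue level in `[0,1]`, one per session.
#' @slot manifest list recording the generation parameters.
#' @exportClass SimulatedCorpus
setClass("SimulatedCorpus",
  representation(sessions = "list", groundTruth = "numeric", manifest = "list")
)

setValidity("SimulatedCorpus", function(object) {
  msg <- character()
  if (length(object@sessions) != length(object@groundTruth))
    msg <- c(msg, "groundTruth must align 1:1 with sessions")
  if (length(object@groundTruth) &&
      (any(object@groundTruth < 0) || any(object@groundTruth > 1)))
    msg <- c(msg, "groundTruth levels must be in [0,1]")
  if (length(object@sessions) &&
      !all(vapply(object@sessions, is, logical(1), "KeystrokeSession")))
    msg <- c(msg, "sessions must all be KeystrokeSession objects")
  if (length(msg)) msg else TRUE
})

#' KeystrokeBackbone: recurrent typing-pattern embedding network
#'
#' A 2-layer LSTM (128 units each, masked padding) mapping a 150 x 4 timing
#' matrix to a 128-dimensional typing embedding v(x). Weights live in
#' `weights` (one list of input kernel W, recurrent kernel U and bias b per
#' layer); `history` records pretraining progress.
#'
#' @slot config list from [backboneConfig()].
#' @slot weights list of per-layer parameter lists.
#' @slot history data.frame of per-epoch pretraining loss (empty if untrained).
#' @exportClass KeystrokeBackbone
setClass("KeystrokeBackbone",
  representation(config = "list", weights = "list", history = "data.frame")
)

#' FatigueHead: triplet-trained fatigue-adaptation layer
#'
#' Dense 128-unit relu layer g(.) applied on top of the frozen backbone
#' embedding, trained with the triplet loss to separate rest from fatigue in
#' the transformed space g(v(x)).
#'
#' @slot W 128 x 128 weight matrix.
#' @slot b length-128 bias.
#' @slot config list from [adaptationConfig()].
#' @slot history data.frame of per-epoch mean triplet loss.
#' @exportClass FatigueHead
setClass("FatigueHead",
  representation(W = "matrix", b = "numeric", config = "list",
                 history = "data.frame")
)

#' SoftmaxHead: binary-classification comparison head
#'
#' Dense 128-unit relu layer followed by a 2-way softmax trained with binary
#' cross-entropy on rest/fatigue labels; the comparison arm for the
#' distance-metric-learning head.
#'
#' @slot W1 128 x 128 weights, @slot b1 biases of the hidden layer.
#' @slot W2 128 x 2 weights, @slot b2 biases of the softmax layer.
#' @slot config,history as in [FatigueHead-class].
#' @exportClass SoftmaxHead
setClass("SoftmaxHead",
  representation(W1 = "matrix", b1 = "numeric", W2 = "matrix", b2 = "numeric",
                 config = "list", history = "data.frame")
)

#' ScoreDensities: rest/fatigue score density estimators
#'
#' Gaussian kernel density estimates of the one-dimensional fatigue scores of
#' the rest and fatigue classes, used by the log-likelihood-ratio step of the
#' active detector. Evaluations are floored at `floor` to keep the
#' log-likelihood ratio finite outside the kernel support.
#'
#' @slot restScores,fatigueScores numeric score samples.
#' @slot bw named numeric `(rest, fatigue)` kernel bandwidths.
#' @slot floor positive density floor (default 1e-12).
#' @exportClass ScoreDensities
setClass("ScoreDensities",
  representation(restScores = "numeric", fatigueScores = "numeric",
                 bw = "numeric", floor = "numeric")
)

setValidity("ScoreDensities", function(object) {
  msg <- character()
  if (any(object@bw <= 0)) msg <- c(msg, "bandwidths must be positive")
  if (object@floor <= 0) msg <- c(msg, "density floor must be positive")
  if (length(msg)) msg else TRUE
})

#' AFDState: running state of the active fatigue detector
#'
#' Holds the clamped cumulative sum S of per-session log-likelihood ratios,
#' the session counter, the detection threshold tau, and an append-only
#' history of (score, L, S).
#'
#' @slot S current cumulative score, always `>= 0`.
#' @slot j integer session counter.
#' @slot tau detection threshold.
#' @slot history data.frame with columns score, L, S.
#' @exportClass AFDState
setClass("AFDState",
  representation(S = "numeric", j = "integer", tau = "numeric",
                 history = "data.frame")
)

setValidity("AFDState", function(object) {
  if (object@S < 0) "cumulative score S must be >= 0" else TRUE
})

#' DetectionReport: ROC summary of the onetime change/no-change detector
#'
#' @slot auc area under the ROC curve, percent.
#' @slot sensitivity,specificity,precision,f1 operating-point metrics
#'   (percent) at the closest-to-(0,1) ROC corner.
#' @slot roc data.frame with columns fpr, tpr in `[0,1]`.
#' @slot aggregation `"pooled"` or `"averaged"` (per-participant vertical mean).
#' @slot nPairs number of scored pairs (or samples, for probability scores).
#' @exportClass DetectionReport
setClass("DetectionReport",
  representation(auc = "numeric", sensitivity = "numeric",
                 specificity = "numeric", precision = "numeric",
                 f1 = "numeric", roc = "data.frame",
                 aggregation = "character", nPairs = "integer")
)

#' AFDMetrics: threshold-sweep calibration of the active detector
#'
#' @slot thresholds threshold grid over the cumulative-score range.
#' @slot pfd probability of false detection (alarm before the change) per
#'   threshold; non-increasing in the threshold.
#' @slot pnd probability of non-detection (no alarm after the change);
#'   non-decreasing in the threshold.
#' @slot add average detection delay in sessions, non-detections censored at
#'   the sequence end (monotone definition).
#' @slot addDetected mean delay among detected sequences only (may be NA).
#' @slot eer equal error rate where pfd = pnd, by linear interpolation.
#' @slot eerThreshold threshold at the crossing.
#' @slot addAtEer,addMedianAtEer mean and median censored delay at the EER
#'   threshold.
#' @exportClass AFDMetrics
setClass("AFDMetrics",
  representation(thresholds = "numeric", pfd = "numeric", pnd = "numeric",
                 add = "numeric", addDetected = "numeric", eer = "numeric",
                 eerThreshold = "numeric", addAtEer = "numeric",
                 addMedianAtEer = "numeric")
)
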