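#' @rdname KeystrokeSession-class
setMethod("participantId", "KeystrokeSession", function(object) object@participantId)

#' @rdname KeystrokeSession-class
setMethod("sessionLabel", "KeystrokeSession", function(object) object@label)

#' @rdname KeystrokeSession-class
setMethod("sessionEvents", "KeystrokeSession", function(object) object@events)

#' @rdname KeystrokeSession-class
setMethod("sessionStart", "KeystrokeSession", function(object) object@startTime)

#' @rdname KeystrokeSession-class
setMethod("nKeys", "KeystrokeSession", function(object) nrow(object@events))

#' @rdname FeatureMatrix-class
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname FeatureMatrix-class
setMethod("validLength", "FeatureMatrix", function(object) object@validLength)

#' @rdname SimulatedCorpus-class
setMethod("sessions", "SimulatedCorpus", function(object) object@sessions)

#' @rdname SimulatedCorpus-class
setMethod("groundTruth", "SimulatedCorpus", function(object) object@groundTruth)

#' @rdname SimulatedCorpus-class
setMethod("manifest", "SimulatedCorpus", function(object) object@manifest)

#' @rdname SimulatedCorpus-class
setMethod("length", "SimulatedCorpus", function(x) length(x@sessions))

setMethod("show", "KeystrokeSession", function(object) {
  ev <- object@events
  cat("KeystrokeSession:", object@participantId,
      sprintf("[%s]", object@label), "\n")
  cat("  ", nrow(ev), "keys, span",
      sprintf("%.2f s", ev$pressTime[nrow(ev)] - ev$pressTime[1L]), "\n")
  if (!is.na(object@startTime))
    cat("  wall-clock start:", format(object@startTime, nsmall = 0), "s\n")
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "x", ncol(object@values),
      "(hold, flight, ikl, irl), validLength =", object@validLength, "\n")
})

setMethod("show", "TypistProfile", function(object) {
  cat("TypistProfile:", object@userId, "\n")
  cat(sprintf("  hold ~ lognormal(%.3f, %.3f); ikl ~ lognormal(%.3f, %.3f)\n",
              object@holdLogNorm[1L], object@holdLogNorm[2L],
              object@iklLogNorm[1L], object@iklLogNorm[2L]))
  cat(sprintf("  rollover %.2f; fatigue meanScale %.2f sdScale %.2f\n",
              object@rolloverProb, object@fatigueEffect[1L],
              object@fatigueEffect[2L]))
})

setMethod("show", "SimulatedCorpus", function(object) {
  labs <- vapply(object@sessions, function(s) s@label, character(1))
  cat("SimulatedCorpus:", length(object@sessions), "sessions,",
      length(unique(vapply(object@sessions, participantId, character(1)))),
      "participants\n")
  cat("  labels:", paste(sprintf("%s=%d", names(table(labs)), table(labs)),
                         collapse = ", "), "\n")
})

setMethod("show", "KeystrokeBackbone", function(object) {
  cfg <- object@config
  cat("KeystrokeBackbone:", cfg$nRecurrentLayers, "LSTM layers x",
      cfg$unitsPerLayer, "units, input",
      paste(cfg$inputShape, collapse = " x "), "\n")
  cat("  embedding dim:", cfg$embeddingDim,
      if (nrow(object@history)) sprintf("(pretrained, %d epochs)",
                                        max(object@history$epoch))
      else "(untrained)", "\n")
})

setMethod("show", "FatigueHead", function(object) {
  cat("FatigueHead: dense", ncol(object@W), "units, relu",
      if (nrow(object@history))
        sprintf("(final triplet loss %.4f)",
                object@history$loss[nrow(object@history)]) else "", "\n")
})

setMethod("show", "ScoreDensities", function(object) {
  cat("ScoreDensities: rest n =", length(object@restScores),
      sprintf("(bw %.4g),", object@bw[1L]),
      "fatigue n =", length(object@fatigueScores),
      sprintf("(bw %.4g)", object@bw[2L]), "\n")
})

setMethod("show", "AFDState", function(object) {
  cat(sprintf("AFDState: j = %d, S = %.4f, tau = %.4f (%s)\n",
              object@j, object@S, object@tau,
              if (object@S >= object@tau) "DETECTED" else "below threshold"))
})

setMethod("show", "DetectionReport", function(object) {
  cat(sprintf("DetectionReport (%s, %d pairs)\n", object@aggregation,
              object@nPairs))
  cat(sprintf("  AUC %.1f%% | sens %.1f%% spec %.1f%% prec %.1f%% F1 %.1f%%\n",
              object@auc, object@sensitivity, object@specificity,
              object@precision, object@f1))
})

setMethod("show", "AFDMetrics", function(object) {
  cat(sprintf("AFDMetrics: %d thresholds, EER %.3f at tau %.3f, ADD at EER %.2f (median %.1f)\n",
              length(object@thresholds), object@eer, object@eerThreshold,
              object@addAtEer, object@addMedianAtEer))
})
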