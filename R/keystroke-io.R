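#' Construct a keystroke session
#'
#' Low-level constructor used by the reader and the simulator.
#'
#' @param participantId participant identifier.
#' @param pressTime,releaseTime numeric vectors, seconds.
#' @param keycode optional integer vector (keycodes are never used by the
#'   feature extractor; they may be absent or redacted).
#' @param label `"rest"`, `"fatigue"` or `"unknown"`.
#' @param startTime wall-clock start in seconds (NA if unknown).
#' @param contextTag free-form tag (e.g. cohort or session name).
#' @return a [KeystrokeSession-class].
#' @export
keystrokeSession <- function(participantId, pressTime, releaseTime,
                             keycode = NULL, label = "unknown",
                             startTime = NA_real_, contextTag = "") {
  o <- order(pressTime)
  ev <- data.frame(pressTime = as.numeric(pressTime)[o],
                   releaseTime = as.numeric(releaseTime)[o])
  ev$keycode <- if (is.null(keycode)) NA_integer_ else as.integer(keycode)[o]
  new("KeystrokeSession", participantId = as.character(participantId),
      events = ev, label = label, startTime = as.numeric(startTime),
      contextTag = contextTag)
}

#' Read keystroke sessions from delimited event records
#'
#' Parses a delimited text file (or an already-loaded data.frame) of per-key
#' events, groups rows into sessions by (participant, session), sorts each
#' session by press time, and converts timestamps to seconds. Rows with
#' unparseable (non-finite) times are dropped, counted and reported via the
#' `"malformed"` attribute and a warning. A release before its press is a
#' hard validation error naming the offending row.
#'
#' @param source path to a CSV/TSV file with a header, or a data.frame.
#' @param schema named list mapping roles to column names; roles
#'   `participant`, `session`, `press`, `release` are required, `keycode`
#'   and `wallClock` optional.
#' @param unit time unit of the source timestamps: `"s"`, `"ms"` or `"us"`.
#' @param sep field separator when `source` is a path (default `","`;
#'   `"\t"` for `.tsv` files).
#' @return list of [KeystrokeSession-class], with attribute `"malformed"`
#'   giving the number of dropped rows.
#' @export
readSessions <- function(source,
                         schema = list(participant = "participant",
                                       session = "session",
                                       press = "press_time",
                                       release = "release_time",
                                       keycode = "keycode",
                                       wallClock = "wall_clock"),
                         unit = c("s", "ms", "us"), sep = NULL) {
  unit <- match.arg(unit)
  if (is.character(source)) {
    if (is.null(sep)) sep <- if (grepl("\\.tsv$", source)) "\t" else ","
    source <- utils::read.table(source, header = TRUE, sep = sep,
                                stringsAsFactors = FALSE)
  }
  req <- c("participant", "session", "press", "release")
  cols <- unlist(schema[req])
  if (length(cols) < 4L || !all(cols %in% names(source)))
    stop("schema error: required column(s) missing: ",
         paste(setdiff(cols, names(source)), collapse = ", "))
  press <- suppressWarnings(as.numeric(source[[schema$press]]))
  release <- suppressWarnings(as.numeric(source[[schema$release]]))
  bad <- !is.finite(press) | !is.finite(release)
  nBad <- sum(bad)
  if (nBad) {
    warning(nBad, " malformed row(s) with unparseable times dropped")
    source <- source[!bad, , drop = FALSE]
    press <- press[!bad]; release <- release[!bad]
  }
  if (any(release < press))
    stop("validation error: release_time < press_time at row(s) ",
         paste(utils::head(which(release < press), 5L), collapse = ", "))
  fac <- c(s = 1, ms = 1e-3, us = 1e-6)[[unit]]
  key <- interaction(source[[schema$participant]], source[[schema$session]],
                     drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(source)), key)
  out <- lapply(idx, function(i) {
    wc <- if (!is.null(schema$wallClock) && schema$wallClock %in% names(source))
      min(as.numeric(source[[schema$wallClock]][i])) * fac else NA_real_
    kc <- if (!is.null(schema$keycode) && schema$keycode %in% names(source))
      source[[schema$keycode]][i] else NULL
    keystrokeSession(source[[schema$participant]][i][1L],
                     press[i] * fac, release[i] * fac, keycode = kc,
                     startTime = wc,
                     contextTag = as.character(source[[schema$session]][i][1L]))
  })
  names(out) <- NULL
  attr(out, "malformed") <- nBad
  out
}

#' Write keystroke sessions as delimited event records
#'
#' Inverse of [readSessions()]: one row per key, times in seconds.
#'
#' @param x a list of sessions or a [SimulatedCorpus-class].
#' @param path output CSV path.
#' @param manifestPath optional JSON path for the ground-truth manifest of a
#'   simulated corpus.
#' @return `path`, invisibly.
#' @export
writeSessions <- function(x, path, manifestPath = NULL) {
  sess <- if (is(x, "SimulatedCorpus")) sessions(x) else x
  tabs <- lapply(seq_along(sess), function(i) {
    s <- sess[[i]]
    ev <- sessionEvents(s)
    data.frame(participant = participantId(s), session = i,
               press_time = ev$pressTime, release_time = ev$releaseTime,
               keycode = ev$keycode,
               wall_clock = sessionStart(s) + (ev$pressTime - ev$pressTime[1L]),
               label = sessionLabel(s))
  })
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  if (!is.null(manifestPath) && is(x, "SimulatedCorpus"))
    jsonlite::write_json(list(groundTruth = groundTruth(x),
                              manifest = manifest(x)),
                         manifestPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Convert session timestamps to seconds
#'
#' @param session a [KeystrokeSession-class].
#' @param inputResolution unit the session's times are currently expressed
#'   in: `"s"` (identity), `"ms"` or `"us"`.
#' @return the session with all times in seconds; relative intervals are
#'   preserved exactly up to the unit factor.
#' @export
normalizeTimestamps <- function(session, inputResolution = c("s", "ms", "us")) {
  inputResolution <- match.arg(inputResolution)
  fac <- c(s = 1, ms = 1e-3, us = 1e-6)[[inputResolution]]
  if (fac == 1) return(session)
  session@events$pressTime <- session@events$pressTime * fac
  session@events$releaseTime <- session@events$releaseTime * fac
  if (!is.na(session@startTime)) session@startTime <- session@startTime * fac
  validObject(session)
  session
}

#' Extract per-key timing features
#'
#' Computes, for each key i of a session (times in seconds):
#' hold = release_i - press_i; flight = press_i - press_{i-1};
#' inter-key latency (ikl) = press_i - release_{i-1}; inter-release latency
#' (irl) = release_i - release_{i-1}. The first key has no predecessor, so
#' its flight/ikl/irl are 0. Negative ikl/irl from key rollover are
#' preserved; an optional symmetric clip guards against clock glitches.
#'
#' @param session a [KeystrokeSession-class] with times in seconds.
#' @param clip optional positive bound: latencies are clipped to
#'   `[-clip, clip]` (default `NULL`, no clipping).
#' @return an L x 4 numeric matrix with columns hold, flight, ikl, irl.
#' @export
extractFeatures <- function(session, clip = NULL) {
  ev <- sessionEvents(session)
  n <- nrow(ev)
  if (n < 1L) stop("empty session")
  p <- ev$pressTime; r <- ev$releaseTime
  m <- cbind(hold = r - p,
             flight = c(0, diff(p)),
             ikl = c(0, p[-1L] - r[-n]),
             irl = c(0, diff(r)))
  if (!is.null(clip)) {
    stopifnot(clip > 0)
    m[, -1L] <- pmin(pmax(m[, -1L], -clip), clip)
    m[, 1L] <- pmin(m[, 1L], clip)
  }
  m
}

#' Pad or truncate a timing matrix to the model input length
#'
#' Sequences shorter than `targetLength` keys are zero-padded (the padded
#' rows are masked by the embedding network); longer sequences keep their
#' first `targetLength` keys.
#'
#' @param m an L x 4 timing matrix from [extractFeatures()].
#' @param targetLength model input length (150).
#' @return a [FeatureMatrix-class].
#' @export
fixLength <- function(m, targetLength = 150L) {
  L <- nrow(m)
  if (L < 1L) stop("empty timing matrix")
  out <- matrix(0, targetLength, 4L,
                dimnames = list(NULL, c("hold", "flight", "ikl", "irl")))
  vl <- min(L, targetLength)
  out[seq_len(vl), ] <- m[seq_len(vl), ]
  new("FeatureMatrix", values = out, validLength = as.integer(vl))
}

#' Segment a session into fixed-size analysis windows
#'
#' A 15-minute supervised session contains many more than 150 keys; this
#' yields the multiple per-participant samples the adaptation and pairing
#' stages need. The session is featurized once and then sliced, so windows
#' concatenated (up to padding) reproduce the featurized session exactly.
#'
#' @param session a [KeystrokeSession-class] (seconds).
#' @param windowKeys keys per window (150).
#' @param policy `"nonoverlapping"` (consecutive windows) or `"first_only"`
#'   (a single window from the session start).
#' @param minWindowKeys a trailing partial window is kept (zero-padded) only
#'   if it has at least this many keys.
#' @param clip passed to [extractFeatures()].
#' @return list of [FeatureMatrix-class] (possibly empty if the session is
#'   shorter than `minWindowKeys` under the nonoverlapping policy).
#' @export
segmentSession <- function(session, windowKeys = 150L,
                           policy = c("nonoverlapping", "first_only"),
                           minWindowKeys = 30L, clip = NULL) {
  policy <- match.arg(policy)
  feats <- extractFeatures(session, clip = clip)
  L <- nrow(feats)
  if (policy == "first_only")
    return(list(fixLength(feats[seq_len(min(L, windowKeys)), , drop = FALSE],
                          windowKeys)))
  starts <- seq.int(1L, L, by = windowKeys)
  out <- lapply(starts, function(s) {
    e <- min(s + windowKeys - 1L, L)
    if (e - s + 1L < minWindowKeys) return(NULL)
    fixLength(feats[s:e, , drop = FALSE], windowKeys)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Split a continuous keystroke stream at typing pauses
#'
#' Real-world streams arrive as continuous logs; a new session starts
#' whenever the gap between consecutive press events exceeds
#' `pauseThreshold` seconds. Each output session carries its wall-clock
#' start (the press time of its first key, offset by the stream's start if
#' one is recorded).
#'
#' @param session a [KeystrokeSession-class] holding the full stream,
#'   time-sorted, in seconds.
#' @param pauseThreshold inter-press gap (seconds) that opens a new session.
#' @return list of [KeystrokeSession-class].
#' @export
splitStream <- function(session, pauseThreshold = 60) {
  ev <- sessionEvents(session)
  gaps <- diff(ev$pressTime)
  grp <- cumsum(c(0, gaps > pauseThreshold))
  base <- if (is.na(sessionStart(session))) 0 else
    sessionStart(session) - ev$pressTime[1L]
  out <- lapply(split(seq_len(nrow(ev)), grp), function(i) {
    keystrokeSession(participantId(session), ev$pressTime[i],
                     ev$releaseTime[i], keycode = ev$keycode[i],
                     label = sessionLabel(session),
                     startTime = base + ev$pressTime[i][1L],
                     contextTag = session@contextTag)
  })
  names(out) <- NULL
  out
}

#' Featurize a cohort into a stacked window set
#'
#' Applies [segmentSession()] to every session and stacks the resulting
#' feature matrices into the array form consumed by the embedding network,
#' keeping per-window metadata (participant, label, session index, wall
#' clock, latent ground truth when available).
#'
#' @param x a [SimulatedCorpus-class] or list of sessions.
#' @param policy,windowKeys,minWindowKeys,clip see [segmentSession()].
#' @param maxWindowsPerSession optional cap (first windows kept).
#' @return a list of class `kfWindows` with elements `x` (n x 150 x 4
#'   array), `validLength`, `participant`, `label`, `sessionIndex`,
#'   `startTime`, `groundTruth`.
#' @export
cohortWindows <- function(x, policy = "nonoverlapping", windowKeys = 150L,
                          minWindowKeys = 30L, maxWindowsPerSession = NULL,
                          clip = NULL) {
  sess <- if (is(x, "SimulatedCorpus")) sessions(x) else x
  gt <- if (is(x, "SimulatedCorpus")) groundTruth(x) else
    rep(NA_real_, length(sess))
  acc <- list()
  for (i in seq_along(sess)) {
    w <- segmentSession(sess[[i]], windowKeys = windowKeys, policy = policy,
                        minWindowKeys = minWindowKeys, clip = clip)
    if (!is.null(maxWindowsPerSession) && length(w) > maxWindowsPerSession)
      w <- w[seq_len(maxWindowsPerSession)]
    for (fm in w)
      acc[[length(acc) + 1L]] <- list(
        v = featureValues(fm), vl = validLength(fm),
        pid = participantId(sess[[i]]), lab = sessionLabel(sess[[i]]),
        si = i, st = sessionStart(sess[[i]]), gt = gt[i])
  }
  if (!length(acc)) stop("no windows produced (sessions too short?)")
  n <- length(acc)
  arr <- array(0, dim = c(n, windowKeys, 4L))
  for (k in seq_len(n)) arr[k, , ] <- acc[[k]]$v
  structure(list(
    x = arr,
    validLength = vapply(acc, `[[`, integer(1), "vl"),
    participant = vapply(acc, `[[`, character(1), "pid"),
    label = vapply(acc, `[[`, character(1), "lab"),
    sessionIndex = vapply(acc, `[[`, integer(1), "si"),
    startTime = vapply(acc, `[[`, numeric(1), "st"),
    groundTruth = vapply(acc, `[[`, numeric(1), "gt")
  ), class = "kfWindows")
}

# Variable-length windows cut by elapsed time rather than key count; used by
# the 5-minute baseline setup (samples average ~1100 keys, never truncated).
timeWindowFeatures <- function(session, minutes = 5, minKeys = 30L,
                               clip = NULL) {
  feats <- extractFeatures(session, clip = clip)
  p <- sessionEvents(session)$pressTime
  bin <- floor((p - p[1L]) / (minutes * 60))
  idx <- split(seq_along(p), bin)
  idx <- idx[vapply(idx, length, integer(1)) >= minKeys]
  lapply(idx, function(i) feats[i, , drop = FALSE])
}
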