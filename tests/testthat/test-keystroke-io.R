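test_that("readSessions groups, sorts and validates event records", {
  sess <- readSessions(toyEvents())
  expect_length(sess, 2L)
  expect_equal(attr(sess, "malformed"), 0L)
  ids <- vapply(sess, participantId, character(1))
  expect_setequal(ids, c("a", "b"))
  a <- sess[[which(ids == "a")]]
  expect_equal(nKeys(a), 4L)
  # internally time-sorted even though the input rows were shuffled
  expect_false(is.unsorted(sessionEvents(a)$pressTime))

  # malformed times are dropped and counted
  ev <- toyEvents()
  ev$press_time[2L] <- "oops"
  expect_warning(s2 <- readSessions(ev), "malformed")
  expect_equal(attr(s2, "malformed"), 1L)

  # release before press is a hard validation error
  ev2 <- toyEvents()
  ev2$release_time[3L] <- ev2$press_time[3L] - 0.05
  expect_error(readSessions(ev2), "release_time < press_time")

  # missing required column is a schema error
  expect_error(readSessions(toyEvents()[, -3L]), "schema error")
})

test_that("readSessions round-trips through the CSV event format", {
  co <- simulateSupervisedCohort(2L, sessionsPerState = 1L,
                                 sessionMinutes = 0.2, seed = 5L)
  f <- tempfile(fileext = ".csv")
  writeSessions(co, f)
  back <- readSessions(f)
  expect_length(back, length(sessions(co)))
  orig <- sessions(co)[[1L]]
  match <- Filter(function(s) isTRUE(all.equal(
    sessionEvents(s)$pressTime,
    sessionEvents(orig)$pressTime - sessionEvents(orig)$pressTime[1L] +
      sessionEvents(s)$pressTime[1L])), back)
  expect_gte(length(match), 1L)
  # identical bytes parse to identical structures
  expect_identical(readSessions(f), readSessions(f))
})

test_that("normalizeTimestamps converts units and preserves intervals", {
  s <- keystrokeSession("p", c(0, 1500), c(500, 2000))
  ms <- normalizeTimestamps(s, "ms")
  expect_equal(sessionEvents(ms)$pressTime, c(0, 1.5))
  expect_equal(sessionEvents(ms)$releaseTime, c(0.5, 2))
  expect_identical(normalizeTimestamps(ms, "s"), ms)
  us <- normalizeTimestamps(keystrokeSession("p", c(1.2e6), c(1.35e6)), "us")
  expect_equal(unname(extractFeatures(us)[1L, "hold"]), 0.15)
  expect_error(normalizeTimestamps(s, "ns"))
})

test_that("extractFeatures matches hand-computed toys", {
  m <- extractFeatures(toySession())
  expect_equal(unname(m[1L, ]), c(0.10, 0, 0, 0))
  expect_equal(unname(m[2L, ]), c(0.15, 0.15, 0.05, 0.20))
  # rollover gives a preserved negative inter-key latency
  m2 <- extractFeatures(rolloverSession())
  expect_equal(unname(m2[2L, "ikl"]), -0.10)
  # single key
  m3 <- extractFeatures(keystrokeSession("p", 0.2, 0.31))
  expect_equal(dim(m3), c(1L, 4L))
  expect_equal(unname(m3[1L, ]), c(0.11, 0, 0, 0))
})

test_that("features are invariant to a constant timestamp offset", {
  s <- sampleSession(typistProfile(), "rest", 50L, seed = 3L)
  ev <- sessionEvents(s)
  shifted <- keystrokeSession("p", ev$pressTime + 1234.5,
                              ev$releaseTime + 1234.5)
  expect_equal(extractFeatures(shifted), extractFeatures(s))
})

test_that("fixLength pads, truncates and is reversible up to validLength", {
  m10 <- extractFeatures(sampleSession(typistProfile(), "rest", 10L,
                                       seed = 1L))
  fm <- fixLength(m10)
  expect_equal(dim(featureValues(fm)), c(150L, 4L))
  expect_equal(validLength(fm), 10L)
  expect_true(all(featureValues(fm)[11:150, ] == 0))
  expect_equal(featureValues(fm)[1:10, ], unname(m10),
               ignore_attr = TRUE)

  m150 <- extractFeatures(sampleSession(typistProfile(), "rest", 150L,
                                        seed = 2L))
  fm150 <- fixLength(m150)
  expect_equal(validLength(fm150), 150L)
  expect_equal(featureValues(fm150), m150, ignore_attr = TRUE)

  m400 <- extractFeatures(sampleSession(typistProfile(), "rest", 400L,
                                        seed = 3L))
  fm400 <- fixLength(m400)
  expect_equal(validLength(fm400), 150L)
  expect_equal(featureValues(fm400), m400[1:150, ], ignore_attr = TRUE)
})

test_that("segmentSession window counts follow the stated policy", {
  prof <- typistProfile()
  w450 <- segmentSession(sampleSession(prof, "rest", 450L, seed = 4L))
  expect_length(w450, 3L)
  expect_true(all(vapply(w450, validLength, integer(1)) == 150L))

  # 160 keys: the 10-key tail is below the 30-key minimum and is dropped
  w160 <- segmentSession(sampleSession(prof, "rest", 160L, seed = 5L))
  expect_length(w160, 1L)

  w100 <- segmentSession(sampleSession(prof, "rest", 100L, seed = 6L))
  expect_length(w100, 1L)
  expect_equal(validLength(w100[[1L]]), 100L)

  wf <- segmentSession(sampleSession(prof, "rest", 450L, seed = 4L),
                       policy = "first_only")
  expect_length(wf, 1L)
})

test_that("nonoverlapping windows concatenate to the featurized session", {
  s <- sampleSession(typistProfile(), "rest", 325L, seed = 7L)
  feats <- extractFeatures(s)
  wins <- segmentSession(s, minWindowKeys = 1L)
  rec <- do.call(rbind, lapply(wins, function(fm)
    featureValues(fm)[seq_len(validLength(fm)), , drop = FALSE]))
  expect_equal(rec, unname(feats), ignore_attr = TRUE)
})

test_that("splitStream opens a session at every long pause", {
  prof <- typistProfile()
  base <- sampleSession(prof, "rest", 40L, seed = 8L)
  ev <- sessionEvents(base)
  # inject three 61 s pauses -> 4 sessions
  shift <- cumsum(ifelse(seq_len(40L) %in% c(11L, 21L, 31L), 61, 0))
  s <- keystrokeSession("p", ev$pressTime + shift, ev$releaseTime + shift,
                        startTime = 1000)
  out <- splitStream(s, pauseThreshold = 60)
  expect_length(out, 4L)
  expect_equal(vapply(out, nKeys, integer(1)), rep(10L, 4L))
  # wall-clock starts carried through
  expect_equal(sessionStart(out[[1L]]), 1000)
  expect_gt(sessionStart(out[[2L]]), sessionStart(out[[1L]]) + 60)
  # no gap above threshold -> single session
  expect_length(splitStream(base, pauseThreshold = 60), 1L)
})

test_that("session and feature-matrix validity contracts hold", {
  expect_error(keystrokeSession("p", c(0, 1), c(0.5, 0.5)),
               "releaseTime")
  expect_error(keystrokeSession("p", numeric(), numeric()))
  expect_error(new("FeatureMatrix",
                   values = matrix(1, 150, 4), validLength = 10L),
               "beyond validLength")
})
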