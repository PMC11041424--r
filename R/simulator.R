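#' Construct a typist profile
#'
#' Keystroke latencies are positive and right-skewed, so hold times and
#' inter-key latencies are modelled as log-normal; the default medians
#' (0.1 s hold, 0.2 s inter-key latency) keep all timing features near 1
#' second or below in natural units, matching the seconds-only normalization
#' the embedding network expects. Fatigue acts multiplicatively: under full
#' fatigue the log-means shift by `log(meanScale)` (slowing) and the log-sds
#' inflate by `sdScale` (more variable psychomotor output); intermediate
#' latent levels interpolate linearly on the log scale.
#'
#' @param userId identifier.
#' @param holdLogNorm,iklLogNorm `(mu, sigma)` of the log latencies.
#' @param rolloverProb probability a key is pressed before the previous
#'   release (produces negative inter-key latencies).
#' @param fatigueEffect `(meanScale, sdScale)`, both `>= 1`.
#' @param circadian `(amplitude, acrophaseHour, postlunchDip)` for the
#'   daily-stream generator.
#' @return a [TypistProfile-class].
#' @export
typistProfile <- function(userId = "u1",
                          holdLogNorm = c(mu = log(0.10), sigma = 0.35),
                          iklLogNorm = c(mu = log(0.20), sigma = 0.50),
                          rolloverProb = 0.15,
                          fatigueEffect = c(meanScale = 1.3, sdScale = 1.5),
                          circadian = c(amplitude = 0.8, acrophaseHour = 23,
                                        postlunchDip = 0.15)) {
  new("TypistProfile", userId = as.character(userId),
      holdLogNorm = holdLogNorm, iklLogNorm = iklLogNorm,
      rolloverProb = rolloverProb, fatigueEffect = fatigueEffect,
      circadian = circadian)
}

#' Population hyper-distribution for typist profiles
#'
#' Per-user profiles are drawn from these hyper-priors so that the identity
#' signal (between-user separation of timing parameters) and the intra-user
#' pairing logic are genuinely exercised. Setting the spreads to zero yields
#' statistically indistinguishable users (the negative control for backbone
#' pretraining). The per-user fatigue effect is drawn around the population
#' value with a log-normal spread, so cohorts include weaker responders.
#'
#' @param holdMu,holdMuSd mean and SD of the per-user log-hold mu.
#' @param holdSigmaRange uniform range of the per-user log-hold sigma.
#' @param iklMu,iklMuSd,iklSigmaRange same for the inter-key latency.
#' @param rolloverRange uniform range of per-user rollover probability.
#' @param meanScale,sdScale population fatigue effect (>= 1).
#' @param effectSpread log-normal sd of the per-user effect multiplier
#'   (0 = identical effects).
#' @param amplitude,acrophaseHour,postlunchDip circadian defaults.
#' @return named list of hyper-parameters.
#' @export
typistPopulation <- function(holdMu = log(0.10), holdMuSd = 0.15,
                             holdSigmaRange = c(0.25, 0.45),
                             iklMu = log(0.20), iklMuSd = 0.20,
                             iklSigmaRange = c(0.35, 0.60),
                             rolloverRange = c(0.05, 0.25),
                             meanScale = 1.3, sdScale = 1.5,
                             effectSpread = 0.25,
                             amplitude = 0.8, acrophaseHour = 23,
                             postlunchDip = 0.15) {
  as.list(environment())
}

#' Draw one typist profile from a population
#'
#' @param userId identifier for the drawn typist.
#' @param population a list from [typistPopulation()].
#' @param seed optional RNG seed.
#' @return a [TypistProfile-class].
#' @export
sampleTypistProfile <- function(userId, population = typistPopulation(),
                                seed = NULL) {
  withSeed(seed, {
    p <- population
    eff <- function(scale) 1 + (scale - 1) *
      stats::rlnorm(1L, 0, p$effectSpread)
    typistProfile(
      userId = userId,
      holdLogNorm = c(mu = stats::rnorm(1L, p$holdMu, p$holdMuSd),
                      sigma = stats::runif(1L, p$holdSigmaRange[1L],
                                           p$holdSigmaRange[2L])),
      iklLogNorm = c(mu = stats::rnorm(1L, p$iklMu, p$iklMuSd),
                     sigma = stats::runif(1L, p$iklSigmaRange[1L],
                                          p$iklSigmaRange[2L])),
      rolloverProb = stats::runif(1L, p$rolloverRange[1L], p$rolloverRange[2L]),
      fatigueEffect = c(meanScale = eff(p$meanScale),
                        sdScale = eff(p$sdScale)),
      circadian = c(amplitude = p$amplitude, acrophaseHour = p$acrophaseHour,
                    postlunchDip = p$postlunchDip))
  })
}

# Latent fatigue level at a given state token or numeric level.
latentLevel <- function(state) {
  if (is.numeric(state)) {
    stopifnot(state >= 0, state <= 1)
    return(state)
  }
  switch(as.character(state), rest = 0, fatigue = 1,
         stop("invalid state token: ", state))
}

#' Simulate one keystroke session
#'
#' Hold times and inter-key latencies are drawn i.i.d. log-normal from the
#' profile, with the log-mean shifted by `level * log(meanScale)` and the
#' log-sd inflated by `1 + level * (sdScale - 1)` at latent fatigue `level`.
#' With probability `rolloverProb` a key is pressed before the previous
#' release (negative inter-key latency). Press times accumulate, so the
#' session is a valid ordered event stream.
#'
#' @param profile a [TypistProfile-class].
#' @param state `"rest"`, `"fatigue"`, or a latent level in `[0,1]`.
#' @param nKeys number of keys (>= 1).
#' @param startTime wall-clock start (seconds) stamped on the session.
#' @param seed optional RNG seed.
#' @return a [KeystrokeSession-class] labeled rest/fatigue for levels 0/1
#'   and `"unknown"` for intermediate levels.
#' @export
sampleSession <- function(profile, state = "rest", nKeys = 150L,
                          startTime = NA_real_, seed = NULL) {
  stopifnot(nKeys >= 1L)
  level <- latentLevel(state)
  withSeed(seed, {
    shift <- level * log(profile@fatigueEffect[["meanScale"]])
    infl <- 1 + level * (profile@fatigueEffect[["sdScale"]] - 1)
    hold <- stats::rlnorm(nKeys, profile@holdLogNorm[["mu"]] + shift,
                          profile@holdLogNorm[["sigma"]] * infl)
    ikl <- stats::rlnorm(nKeys, profile@iklLogNorm[["mu"]] + shift,
                         profile@iklLogNorm[["sigma"]] * infl)
    if (nKeys > 1L && profile@rolloverProb > 0) {
      ro <- which(stats::runif(nKeys - 1L) < profile@rolloverProb) + 1L
      # rollover: next key lands before the previous release, but after the
      # previous press (bounded overlap keeps press times non-decreasing)
      ikl[ro] <- -stats::runif(length(ro), 0, 0.5) * hold[ro - 1L]
    }
    press <- c(0, cumsum(hold[-nKeys] + ikl[-1L]))
    release <- press + hold
    t0 <- if (is.na(startTime)) 0 else startTime
    lab <- if (level == 0) "rest" else if (level == 1) "fatigue" else "unknown"
    keystrokeSession(profile@userId, press + 0, release,
                     label = lab, startTime = startTime,
                     contextTag = sprintf("sim_level_%.2f", level))
  })
}

# Expected seconds per key at a latent level (median-based, close enough for
# sizing sessions to a wall-clock duration).
keyPeriod <- function(profile, level = 0) {
  shift <- level * log(profile@fatigueEffect[["meanScale"]])
  infl <- 1 + level * (profile@fatigueEffect[["sdScale"]] - 1)
  eh <- exp(profile@holdLogNorm[["mu"]] + shift +
              (profile@holdLogNorm[["sigma"]] * infl)^2 / 2)
  ei <- exp(profile@iklLogNorm[["mu"]] + shift +
              (profile@iklLogNorm[["sigma"]] * infl)^2 / 2)
  # a rollover key replaces its positive latency with a small negative one
  ei <- (1 - profile@rolloverProb) * ei - profile@rolloverProb * 0.25 * eh
  eh + ei
}

#' Simulate a supervised rest/fatigue cohort
#'
#' Emulates a supervised sleep-inertia protocol: each participant
#' contributes `sessionsPerState` rest sessions (captured during the day)
#' and the same number of fatigue sessions (captured at midnight), each of
#' `sessionMinutes` typing. Per-participant profiles are drawn from the
#' population hyper-distribution.
#'
#' @param nParticipants cohort size (>= 2; default 14).
#' @param sessionsPerState labeled sessions per state per participant.
#' @param sessionMinutes session duration in minutes (keys are sized from
#'   the profile's typing rate).
#' @param population hyper-priors from [typistPopulation()].
#' @param seed RNG seed (the whole corpus is reproducible from it).
#' @return a [SimulatedCorpus-class]; ground truth is 0 for rest sessions
#'   and 1 for fatigue sessions.
#' @export
simulateSupervisedCohort <- function(nParticipants = 14L,
                                     sessionsPerState = 2L,
                                     sessionMinutes = 15,
                                     population = typistPopulation(),
                                     seed = 1L) {
  stopifnot(nParticipants >= 2L)
  withSeed(seed, {
    sess <- list(); gt <- numeric()
    for (i in seq_len(nParticipants)) {
      prof <- sampleTypistProfile(sprintf("p%02d", i), population)
      day <- 0L
      for (k in seq_len(sessionsPerState)) {
        for (state in c("rest", "fatigue")) {
          lev <- latentLevel(state)
          n <- max(2L, round(sessionMinutes * 60 / keyPeriod(prof, lev)))
          hour <- if (state == "rest") stats::runif(1L, 10, 18) else 0
          st <- (i * 100L + day) * 86400 + hour * 3600
          sess[[length(sess) + 1L]] <- sampleSession(prof, state, n,
                                                     startTime = st)
          gt <- c(gt, lev)
          day <- day + 1L
        }
      }
    }
    new("SimulatedCorpus", sessions = sess, groundTruth = gt,
        manifest = list(kind = "supervised", nParticipants = nParticipants,
                        sessionsPerState = sessionsPerState,
                        sessionMinutes = sessionMinutes, seed = seed,
                        population = population))
  })
}

#' Circadian latent fatigue curve
#'
#' Latent fatigue over the day: a cosine peaked at the acrophase hour,
#' sharpened so that fatigue is concentrated around the peak (alertness
#' dominates most of the waking day), plus an early-afternoon post-lunch dip
#' bump. Values are clamped to `[0,1]`.
#'
#' @param hour hour of day (possibly fractional).
#' @param circadian `(amplitude, acrophaseHour, postlunchDip)`.
#' @param sharpness exponent applied to the raised cosine (default 3).
#' @return latent fatigue in `[0,1]`.
#' @export
circadianFatigue <- function(hour, circadian, sharpness = 3) {
  base <- (0.5 + 0.5 * cos(2 * pi * (hour - circadian[["acrophaseHour"]]) /
                             24))^sharpness
  dip <- circadian[["postlunchDip"]] * exp(-((hour - 14)^2) / (2 * 1.5^2))
  pmin(1, pmax(0, circadian[["amplitude"]] * base + dip))
}

#' Simulate an unsupervised daily typing stream
#'
#' Emulates passive real-world capture: short (~3-minute) unlabeled sessions
#' stamped with wall-clock times, whose latent fatigue follows the
#' profile's circadian curve plus noise. The latent level of every session
#' is recorded in the corpus ground truth.
#'
#' @param profile a [TypistProfile-class] or list of them (one stream each).
#' @param nDays days of data per typist.
#' @param sessionHours hours of day at which sessions occur (default:
#'   hourly over typical waking/typing hours, 07..23); a few minutes of
#'   jitter are added.
#' @param sessionMinutes session duration.
#' @param noiseSd sd of the latent-level noise.
#' @param sharpness circadian sharpness, see [circadianFatigue()].
#' @param seed RNG seed.
#' @return a [SimulatedCorpus-class] of unlabeled sessions.
#' @export
simulateDailyStream <- function(profile, nDays = 3L, sessionHours = 7:23,
                                sessionMinutes = 3, noiseSd = 0.05,
                                sharpness = 3, seed = 1L) {
  stopifnot(nDays >= 1L)
  profiles <- if (is(profile, "TypistProfile")) list(profile) else profile
  withSeed(seed, {
    sess <- list(); gt <- numeric()
    for (pi in seq_along(profiles)) {
      prof <- profiles[[pi]]
      for (d in seq_len(nDays)) {
        for (h in sessionHours) {
          hh <- h + stats::runif(1L, 0, 10) / 60
          lev <- min(1, max(0, circadianFatigue(hh, prof@circadian,
                                                sharpness) +
                              stats::rnorm(1L, 0, noiseSd)))
          n <- max(2L, round(sessionMinutes * 60 / keyPeriod(prof, lev)))
          st <- (pi * 1000L + d) * 86400 + hh * 3600
          s <- sampleSession(prof, lev, n, startTime = st)
          s@label <- "unknown"
          sess[[length(sess) + 1L]] <- s
          gt <- c(gt, lev)
        }
      }
    }
    new("SimulatedCorpus", sessions = sess, groundTruth = gt,
        manifest = list(kind = "daily", nDays = nDays,
                        sessionHours = sessionHours,
                        sessionMinutes = sessionMinutes, noiseSd = noiseSd,
                        sharpness = sharpness, seed = seed))
  })
}

#' Simulate an identity-pretraining corpus
#'
#' Desk-scale stand-in for a large sentence-typing corpus: many users with
#' distinct timing profiles, several short (~70-key) sessions each, all in
#' the rest state and unlabeled for fatigue. The identity signal is the
#' between-user separation of the log-normal timing parameters.
#'
#' @param nUsers number of users (>= 2; default 200).
#' @param sessionsPerUser sessions per user (default 15).
#' @param keysPerSession mean keys per session (default 70; small Poisson
#'   jitter around it).
#' @param population hyper-priors; zero spreads give indistinguishable
#'   users (a pretraining negative control).
#' @param seed RNG seed.
#' @return a [SimulatedCorpus-class].
#' @export
simulatePretrainingCorpus <- function(nUsers = 200L, sessionsPerUser = 15L,
                                      keysPerSession = 70L,
                                      population = typistPopulation(),
                                      seed = 1L) {
  stopifnot(nUsers >= 2L)
  withSeed(seed, {
    sess <- list()
    for (i in seq_len(nUsers)) {
      prof <- sampleTypistProfile(sprintf("u%04d", i), population)
      for (k in seq_len(sessionsPerUser)) {
        n <- max(5L, stats::rpois(1L, keysPerSession))
        sess[[length(sess) + 1L]] <- sampleSession(prof, "rest", n)
      }
    }
    new("SimulatedCorpus", sessions = sess,
        groundTruth = rep(0, length(sess)),
        manifest = list(kind = "pretrain", nUsers = nUsers,
                        sessionsPerUser = sessionsPerUser,
                        keysPerSession = keysPerSession, seed = seed))
  })
}
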