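# Shared fixtures, built once per test run and cached. The heavy objects
# (pretrained backbone, LOO runs) are reused by several files; everything is
# generated in code from fixed seeds.

kfCache <- new.env(parent = emptyenv())

kfFixture <- function(name, builder) {
  if (!exists(name, envir = kfCache, inherits = FALSE))
    assign(name, builder(), envir = kfCache)
  get(name, envir = kfCache, inherits = FALSE)
}

# Two-key toy sessions with hand-computable features.
toySession <- function() keystrokeSession("p1", c(0, 0.15), c(0.10, 0.30))
rolloverSession <- function() keystrokeSession("p1", c(0, 0.10), c(0.20, 0.25))

# Small event table for the reader tests.
toyEvents <- function() data.frame(
  participant = c("a", "a", "a", "a", "b", "b"),
  session = c(1, 1, 1, 1, 1, 1),
  press_time = c(0.0, 0.3, 0.15, 0.45, 5.0, 5.2),
  release_time = c(0.1, 0.42, 0.27, 0.6, 5.09, 5.33),
  keycode = c(10L, 11L, 12L, 13L, 20L, 21L))

# Bind two n x T x D arrays along the first dimension.
abind_rows <- function(a, b) {
  out <- array(0, c(dim(a)[1L] + dim(b)[1L], dim(a)[2L], dim(a)[3L]))
  out[seq_len(dim(a)[1L]), , ] <- a
  out[dim(a)[1L] + seq_len(dim(b)[1L]), , ] <- b
  out
}

# Desk-scale pretrained backbone (shared by the recovery tests).
kfBackbone <- function() kfFixture("backbone", function() {
  pre <- simulatePretrainingCorpus(nUsers = 40L, sessionsPerUser = 10L,
                                   seed = 11L)
  pretrainBackbone(buildBackbone(seed = 1L), pre, epochs = 10L,
                   batchesPerEpoch = 20L, tripletsPerBatch = 32L,
                   seed = 7L)
})

kfPretrainCorpus <- function() kfFixture("preCorpus", function()
  simulatePretrainingCorpus(nUsers = 40L, sessionsPerUser = 10L, seed = 11L))

# Study-condition cohorts: strong effect (population meanScale 1.3,
# sdScale 1.5) and the zero-effect null control.
kfStrongCohort <- function() kfFixture("strong", function()
  simulateSupervisedCohort(14L, sessionsPerState = 2L, sessionMinutes = 6,
                           seed = 31L))

kfNullCohort <- function() kfFixture("null", function()
  simulateSupervisedCohort(14L, sessionsPerState = 2L, sessionMinutes = 6,
                           population = typistPopulation(meanScale = 1,
                                                         sdScale = 1,
                                                         effectSpread = 0),
                           seed = 32L))

# Reduced-epoch adaptation schedule used across the recovery tests.
kfAdaptConfig <- function() adaptationConfig(epochs = 6L,
                                             batchesPerEpoch = 40L,
                                             tripletsPerBatch = 48L)

kfStrongWindows <- function() kfFixture("strongWin", function()
  cohortWindows(kfStrongCohort()))

kfStrongEmbeddings <- function() kfFixture("strongEmb", function()
  embed(kfBackbone(), kfStrongWindows()))

kfLooStrong <- function() kfFixture("looStrong", function()
  looProtocol(kfBackbone(), kfStrongWindows(), kfAdaptConfig(),
              maxPairsPerClass = 100L, embeddings = kfStrongEmbeddings()))

kfLooNull <- function() kfFixture("looNull", function()
  looProtocol(kfBackbone(), kfNullCohort(), kfAdaptConfig(),
              maxPairsPerClass = 100L))
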