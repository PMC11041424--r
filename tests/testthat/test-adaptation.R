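test_that("euclideanDistance is the plain L2 metric", {
  expect_equal(euclideanDistance(rep(0, 128), rep(0, 128)), 0)
  v <- numeric(128); v[1:2] <- c(3, 4)
  expect_equal(euclideanDistance(numeric(128), v), 5)
  a <- rnorm(128); b <- rnorm(128)
  expect_equal(euclideanDistance(a, b), euclideanDistance(b, a))
  expect_error(euclideanDistance(1:3, 1:4), "mismatch")
})

test_that("triplet loss matches its analytic values and stays non-negative", {
  expect_equal(tripletLoss(0.2, 1.0, 0.5), 0)      # margin satisfied
  expect_equal(tripletLoss(0.8, 0.6, 0.5), 0.7)    # hinge arithmetic
  expect_equal(tripletLoss(0.37, 0.37, 1.5), 1.5)  # tie -> alpha
  set.seed(30)
  dAP <- runif(1e4, 0, 5); dAN <- runif(1e4, 0, 5); al <- runif(1e4, 0.1, 3)
  l <- tripletLoss(dAP, dAN, 1.5)
  expect_true(all(l >= 0))
  # zero iff the margin is satisfied
  expect_equal(l == 0, dAN - dAP >= 1.5)
  expect_error(tripletLoss(1, 1, 0), "margin")
  expect_error(tripletLoss(-0.1, 1, 1), "distances")
})

test_that("sampleTriplets honours the same-participant class constraints", {
  # tiny inventory: 2 rest + 1 fatigue -> rest anchors only, N fixed
  labels <- c("rest", "rest", "fatigue")
  parts <- rep("p1", 3L)
  tr <- sampleTriplets(labels, parts, 500L, seed = 2L)
  expect_true(all(tr$anchorClass == "rest"))
  expect_true(all(tr$n == 3L))
  expect_true(all(tr$a %in% 1:2 & tr$p %in% 1:2 & tr$a != tr$p))
  # both ordered anchor/positive pairs occur
  expect_setequal(unique(paste(tr$a, tr$p)), c("1 2", "2 1"))

  # property over a larger inventory: constraints always hold, seeded
  set.seed(31)
  labels2 <- sample(c("rest", "fatigue"), 60L, replace = TRUE)
  parts2 <- sample(paste0("q", 1:5), 60L, replace = TRUE)
  tr2 <- sampleTriplets(labels2, parts2, 1000L, seed = 3L)
  expect_true(all(parts2[tr2$a] == tr2$participant &
                    parts2[tr2$p] == tr2$participant &
                    parts2[tr2$n] == tr2$participant))
  expect_true(all(labels2[tr2$a] == labels2[tr2$p]))
  expect_true(all(labels2[tr2$a] != labels2[tr2$n]))
  expect_true(all(tr2$a != tr2$p))
  expect_identical(tr2, sampleTriplets(labels2, parts2, 1000L, seed = 3L))

  # no eligible participant -> informative error
  expect_error(sampleTriplets(c("rest", "fatigue"), c("a", "a"), 10L),
               "no eligible participant")
})

test_that("head training separates classes and never touches the backbone", {
  bb <- kfBackbone()
  before <- backboneChecksum(bb)
  weightsBefore <- bb@weights
  win <- kfStrongWindows()
  cfg <- adaptationConfig(epochs = 3L, batchesPerEpoch = 25L,
                          tripletsPerBatch = 32L)
  head <- trainFatigueHead(bb, win, cfg, embeddings = kfStrongEmbeddings())
  expect_identical(backboneChecksum(bb), before)
  expect_identical(bb@weights, weightsBefore)
  # training-curve bookkeeping
  expect_equal(nrow(head@history), 3L)
  # mean within-class distance < mean between-class distance on training data
  G <- transformEmbeddings(head, kfStrongEmbeddings())
  tr <- sampleTriplets(win$label, win$participant, 800L, seed = 4L)
  dAP <- sqrt(rowSums((G[tr$a, ] - G[tr$p, ])^2))
  dAN <- sqrt(rowSums((G[tr$a, ] - G[tr$n, ])^2))
  expect_lt(mean(dAP), mean(dAN))
})

test_that("a zero-effect cohort cannot beat the margin", {
  # with no learnable separation the triplet loss settles near alpha
  bb <- kfBackbone()
  win <- cohortWindows(kfNullCohort())
  cfg <- adaptationConfig(epochs = 3L, batchesPerEpoch = 25L,
                          tripletsPerBatch = 32L)
  head <- trainFatigueHead(bb, win, cfg)
  finalLoss <- head@history$loss[nrow(head@history)]
  expect_gt(finalLoss, 0.5 * cfg$margin)
})

test_that("looProtocol yields one leak-free fold per participant", {
  bb <- kfBackbone()
  co <- simulateSupervisedCohort(4L, sessionsPerState = 2L,
                                 sessionMinutes = 2, seed = 33L)
  cfg <- adaptationConfig(epochs = 2L, batchesPerEpoch = 10L,
                          tripletsPerBatch = 16L)
  loo <- looProtocol(bb, co, cfg, maxPairsPerClass = 10L)
  expect_length(loo$folds, 4L)
  for (f in loo$folds)
    expect_true(all(f$pairs$participant == f$participant))
  # 2-participant cohort -> 2 folds
  co2 <- simulateSupervisedCohort(2L, sessionsPerState = 2L,
                                  sessionMinutes = 1, seed = 34L)
  expect_length(looProtocol(bb, co2, cfg)$folds, 2L)
  # shuffled session order: same fold membership
  sh <- co
  perm <- rev(seq_along(sessions(co)))
  sh@sessions <- sh@sessions[perm]
  sh@groundTruth <- sh@groundTruth[perm]
  looSh <- looProtocol(bb, sh, cfg, maxPairsPerClass = 10L)
  expect_identical(names(loo$folds), names(looSh$folds))
})

test_that("corrupting held-out labels cannot change a fold's trained head", {
  bb <- kfBackbone()
  co <- simulateSupervisedCohort(3L, sessionsPerState = 2L,
                                 sessionMinutes = 2, seed = 35L)
  win <- cohortWindows(co)
  cfg <- adaptationConfig(epochs = 2L, batchesPerEpoch = 10L,
                          tripletsPerBatch = 16L)
  loo <- looProtocol(bb, win, cfg, maxPairsPerClass = 10L)
  held <- "p01"
  corrupt <- win
  flip <- corrupt$participant == held
  corrupt$label[flip] <- ifelse(corrupt$label[flip] == "rest", "fatigue",
                                "rest")
  looC <- looProtocol(bb, corrupt, cfg, maxPairsPerClass = 10L)
  expect_identical(loo$folds[[held]]$head@W, looC$folds[[held]]$head@W)
  expect_identical(loo$folds[[held]]$head@b, looC$folds[[held]]$head@b)
})

test_that("softmax comparison head produces calibrated probabilities", {
  bb <- kfBackbone()
  win <- kfStrongWindows()
  before <- backboneChecksum(bb)
  cfg <- adaptationConfig(epochs = 2L, batchesPerEpoch = 20L,
                          tripletsPerBatch = 32L)
  head <- trainSoftmaxVariant(bb, win, cfg, embeddings = kfStrongEmbeddings())
  expect_identical(backboneChecksum(bb), before)
  P <- predictProb(head, kfStrongEmbeddings())
  expect_true(all(P >= 0 & P <= 1))
  expect_equal(unname(rowSums(P)), rep(1, nrow(P)))
})
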