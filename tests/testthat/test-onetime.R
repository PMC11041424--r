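test_that("buildPairs enumerates intra-participant pairs correctly", {
  # 2 rest + 2 fatigue samples: 1 + 1 no-change pairs and 4 change pairs
  E <- matrix(rnorm(4 * 8), 4, 8)
  labels <- c("rest", "rest", "fatigue", "fatigue")
  pairs <- buildPairs(E, labels, rep("p1", 4L), policy = "all")
  expect_equal(nrow(pairs), 6L)
  expect_equal(sum(pairs$truth == "change"), 4L)
  expect_equal(sum(pairs$truth == "no_change"), 2L)
  # distances match the direct computation
  expect_equal(pairs$distance[1L],
               euclideanDistance(E[pairs$i[1L], ], E[pairs$j[1L], ]))
})

test_that("pairs never mix participants and balance per class", {
  set.seed(36)
  E <- matrix(rnorm(60 * 4), 60, 4)
  labels <- sample(c("rest", "fatigue"), 60, replace = TRUE)
  parts <- sample(paste0("p", 1:5), 60, replace = TRUE)
  pairs <- buildPairs(E, labels, parts, policy = "all")
  expect_true(all(parts[pairs$i] == pairs$participant &
                    parts[pairs$j] == pairs$participant))
  expect_equal(pairs$truth == "no_change",
               labels[pairs$i] == labels[pairs$j])
  bal <- buildPairs(E, labels, parts, policy = "balanced",
                    maxPerClass = 10L, seed = 1L)
  for (pid in unique(bal$participant)) {
    tab <- table(bal$truth[bal$participant == pid])
    expect_lte(abs(diff(range(tab))), 1L)
    expect_lte(max(tab), 10L)
  }
})

test_that("rocAnalysis recovers analytic extremes and is rank-invariant", {
  # perfectly separated distances -> AUC 100 and a perfect operating point
  pairs <- data.frame(participant = "p1",
                      distance = c(1:5, 11:15) / 10,
                      truth = rep(c("no_change", "change"), each = 5L))
  rep1 <- rocAnalysis(pairs)
  expect_equal(rep1@auc, 100)
  expect_equal(rep1@sensitivity, 100)
  expect_equal(rep1@specificity, 100)

  # labels random wrt distances -> AUC near 50%
  set.seed(37)
  pr <- data.frame(participant = rep(paste0("p", 1:4), each = 500L),
                   distance = rexp(2000),
                   truth = sample(c("change", "no_change"), 2000,
                                  replace = TRUE))
  expect_lt(abs(rocAnalysis(pr)@auc - 50), 5)

  # AUC is a rank statistic: invariant under strictly increasing transforms
  pr2 <- pr; pr2$distance <- log1p(pr$distance) * 3 + 1
  expect_equal(rocAnalysis(pr)@auc, rocAnalysis(pr2)@auc)

  # ROC is monotone nondecreasing
  r <- rocAnalysis(pr)@roc
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
  expect_error(rocAnalysis(pr[pr$truth == "change", ]), "both truth classes")
})

test_that("pooled AUC agrees with an independent ROC implementation", {
  set.seed(38)
  d <- c(rnorm(300, 1), rnorm(300, 1.8))
  truth <- rep(c("no_change", "change"), each = 300L)
  pairs <- data.frame(participant = "p1", distance = d, truth = truth)
  ours <- rocAnalysis(pairs)@auc / 100
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = d, levels = c("no_change", "change"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("averaged and pooled ROC agree under a shared score distribution", {
  set.seed(39)
  mk <- function(pid) data.frame(
    participant = pid, distance = c(rnorm(400, 0), rnorm(400, 2)),
    truth = rep(c("no_change", "change"), each = 400L))
  pairs <- do.call(rbind, lapply(paste0("p", 1:6), mk))
  a1 <- rocAnalysis(pairs, "pooled")@auc
  a2 <- rocAnalysis(pairs, "averaged")@auc
  expect_lt(abs(a1 - a2), 2)
})

test_that("operating point sits at the closest-to-(0,1) corner", {
  # symmetric equal-variance Gaussian overlap: the closed-form corner sits
  # at cutoff mu/2 with sensitivity = specificity = pnorm(mu/2) = 77.34%
  set.seed(40)
  score <- c(rnorm(1e4, 0), rnorm(1e4, 1.5))
  pos <- rep(c(FALSE, TRUE), each = 1e4)
  op <- operatingPoint(score, pos)
  corner <- 100 * stats::pnorm(0.75)
  expect_lt(abs(op$sensitivity - corner), 3)
  expect_lt(abs(op$specificity - corner), 3)
  expect_lt(abs(op$cutoff - 0.75), 0.1)
  # F1 recomputed from its definition
  expect_equal(op$f1, 2 * op$precision * op$sensitivity /
                 (op$precision + op$sensitivity))
})

test_that("baseline feature table is 20 summary statistics per sample", {
  co <- simulateSupervisedCohort(2L, sessionsPerState = 1L,
                                 sessionMinutes = 1, seed = 41L)
  mats <- lapply(sessions(co), extractFeatures)
  X <- keyfatigue:::summaryFeatures(mats)
  expect_equal(ncol(X), 20L)
  expect_equal(nrow(X), length(mats))
  expect_equal(unname(X[1L, 1L]), mean(mats[[1L]][, 1L]))
})

test_that("baselines are at chance on a null cohort and recover on effect", {
  null <- baselineClassifiers(kfNullCohort(), "150keys", seed = 5L,
                              maxWindowsPerSession = 4L)
  for (m in names(null)) expect_lt(abs(null[[m]]@auc - 50), 6)

  # strong-effect cohort: every classical baseline recovers the effect in
  # both window setups, and the 5-minute samples really are richer
  co <- simulateSupervisedCohort(8L, sessionsPerState = 2L,
                                 sessionMinutes = 6, seed = 42L)
  b150 <- baselineClassifiers(co, "150keys", seed = 5L)
  b5 <- baselineClassifiers(co, "5min", seed = 5L)
  for (m in c("rf", "svm", "knn")) {
    expect_gt(b150[[m]]@auc, 70)
    expect_gt(b5[[m]]@auc, 70)
  }
  # a 5-minute sample carries ~7x more keys than a 150-key window, so its
  # per-sample mean-hold feature is less noisy: within one session, the
  # scatter of per-window mean holds shrinks with the window length
  s1 <- sessions(co)[[1L]]
  mh150 <- vapply(segmentSession(s1), function(fm)
    mean(featureValues(fm)[seq_len(validLength(fm)), 1L]), numeric(1))
  mh5 <- vapply(keyfatigue:::timeWindowFeatures(s1, minutes = 2),
                function(m) mean(m[, 1L]), numeric(1))
  expect_lt(stats::sd(mh5), stats::sd(mh150))
})
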