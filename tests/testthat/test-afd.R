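test_that("centroid-axis projection follows the stated geometry", {
  d <- 16L
  restRef <- matrix(0, 4, d)
  fatRef <- matrix(0, 4, d); fatRef[, 1L] <- 1
  ref <- list(embeddings = rbind(restRef, fatRef),
              labels = rep(c("rest", "fatigue"), each = 4L))
  g <- numeric(d); g[1L] <- 0.75
  expect_equal(projectToScalar(matrix(g, 1L), reference = ref), 0.75)
  # invariance to components orthogonal to the axis
  g2 <- g; g2[5L] <- 42
  expect_equal(projectToScalar(matrix(g2, 1L), reference = ref), 0.75)
  # coincident centroids are an error
  badRef <- list(embeddings = rbind(restRef, restRef),
                 labels = rep(c("rest", "fatigue"), each = 4L))
  expect_error(projectToScalar(matrix(g, 1L), reference = badRef),
               "coincide")
  expect_error(projectToScalar(matrix(g, 1L)), "reference")
})

test_that("tsne1d is seeded, reproducible and orients rest below fatigue", {
  set.seed(43)
  ref <- list(embeddings = rbind(matrix(rnorm(20 * 8, 0), 20, 8),
                                 matrix(rnorm(20 * 8, 3), 20, 8)),
              labels = rep(c("rest", "fatigue"), each = 20L))
  inc <- rbind(matrix(rnorm(5 * 8, 0), 5, 8), matrix(rnorm(5 * 8, 3), 5, 8))
  s1 <- projectToScalar(inc, method = "tsne1d", reference = ref, seed = 5L)
  s2 <- projectToScalar(inc, method = "tsne1d", reference = ref, seed = 5L)
  expect_identical(s1, s2)
  # the two well-separated clusters stay separated and oriented in 1-D
  expect_lt(mean(s1[1:5]), mean(s1[6:10]))
  expect_error(projectToScalar(matrix(1, 1L, 8L), method = "tsne1d"),
               "2 points")
})

test_that("score densities integrate to one and match the normal pdf", {
  set.seed(44)
  x <- rnorm(1e4)
  dens <- estimateDensities(x, x + 2)
  expect_lt(abs(densityValues(dens, 0, "rest") - stats::dnorm(0)) /
              stats::dnorm(0), 0.05)
  grid <- seq(-6, 6, length.out = 2001L)
  integral <- keyfatigue:::trapezoid(grid, densityValues(dens, grid, "rest"))
  expect_lt(abs(integral - 1), 0.01)
  expect_error(estimateDensities(1:3, 1:10), "too few")
  expect_error(estimateDensities(rep(1, 10), rnorm(10)), "degenerate")
})

test_that("log-likelihood ratio matches Gaussian symmetry cases", {
  set.seed(45)
  dens <- estimateDensities(rnorm(1e4), rnorm(1e4, 2))
  # equidistant point: L ~ 0
  expect_lt(abs(llr(1, dens)), 0.05)
  # closed form mu*s - mu^2/2 at s = 2 gives 2
  expect_lt(abs(llr(2, dens) - 2), 0.15)
  # identical densities -> L identically 0
  same <- estimateDensities(rnorm(200), rnorm(200), bw = 0.3)
  same@fatigueScores <- same@restScores
  expect_equal(llr(seq(-2, 2, 0.5), same), rep(0, 9L))
})

test_that("KDE log-likelihood ratio converges to the closed form centrally", {
  # where both classes are well represented the KDE-based L tracks
  # mu*s - mu^2/2 closely at n = 1e4 per class
  set.seed(46)
  mu <- 1
  dens <- estimateDensities(rnorm(1e4), rnorm(1e4, mu))
  grid <- seq(-0.5, mu + 0.5, length.out = 101L)
  dev <- max(abs(llr(grid, dens) - (mu * grid - mu^2 / 2)))
  expect_lt(dev, 0.1)
})

test_that("the clamped CUSUM recursion matches hand and brute-force oracles", {
  expect_equal(runCusum(c(-1, -1, 2, 3)), c(0, 0, 2, 5))
  expect_equal(runCusum(c(-2, -0.5, -3)), c(0, 0, 0))
  # stateful interface agrees with the vector recursion
  st <- afdState(tau = 4)
  for (L in c(-1, -1, 2, 3)) st <- updateCusum(st, L)
  expect_equal(st@S, 5)
  expect_equal(st@history$S, c(0, 0, 2, 5))
  expect_true(afdDetected(st))
  expect_equal(st@j, 4L)

  # brute force: S_j = max(0, max_k sum_{i=k..j} L_i)
  brute <- function(L) vapply(seq_along(L), function(j) {
    sums <- vapply(seq_len(j), function(k) sum(L[k:j]), numeric(1))
    max(0, max(sums))
  }, numeric(1))
  set.seed(47)
  for (r in 1:50) {
    L <- rnorm(40, sd = 2)
    expect_equal(runCusum(L), brute(L), tolerance = 1e-10)
  }
})

test_that("threshold sweep reproduces the deterministic toy and extremes", {
  toy <- list(list(L = c(rep(-0.5, 15L), rep(1, 15L)), changeIndex = 16L))
  m <- evaluateAfd(toy, thresholds = 2.5)
  expect_equal(m@pfd, 0)
  expect_equal(m@pnd, 0)
  expect_equal(m@add, 3)  # S reaches 2.5 at the 3rd post-change session

  m0 <- evaluateAfd(toy, thresholds = 0)
  expect_equal(m0@pfd, 1)  # S >= 0 always: triggers before the change
  expect_equal(m0@pnd, 0)
  mInf <- evaluateAfd(toy, thresholds = 1e9)
  expect_equal(mInf@pfd, 0)
  expect_equal(mInf@pnd, 1)
  expect_error(evaluateAfd(list()), "no sequences")
})

test_that("PFD/PND/ADD are monotone in the threshold on random inputs", {
  set.seed(48)
  for (r in 1:30) {
    seqs <- lapply(1:6, function(i) {
      n <- sample(10:30, 1L)
      ci <- sample(3:(n - 2L), 1L)
      list(L = rnorm(n, mean = c(rep(-0.5, ci - 1L),
                                 rep(0.7, n - ci + 1L)), sd = 1.5),
           changeIndex = ci)
    })
    m <- evaluateAfd(seqs, nThresholds = 60L)
    expect_true(all(diff(m@pfd) <= 1e-12))
    expect_true(all(diff(m@pnd) >= -1e-12))
    expect_true(all(diff(m@add) >= -1e-12))
  }
})

test_that("daily trend applies the under-2-hour same-day pairing rule", {
  bb <- buildBackbone(seed = 6L)
  prof <- typistProfile()
  mk <- function(hours, day = 1) lapply(hours, function(h)
    sampleSession(prof, "rest", 40L, startTime = day * 86400 + h * 3600,
                  seed = round(100 * h)))
  # 09:00 + 10:30 -> one pair binned at hour 10; 09:00 + 11:30 -> excluded;
  # 23:30 day 1 + 00:30 day 2 -> crosses midnight, excluded
  sess <- c(mk(c(9, 10.5), day = 1), mk(c(9, 11.5), day = 3),
            mk(23.5, day = 5), mk(0.5, day = 6))
  sess <- lapply(seq_along(sess), function(i) sess[[i]])
  tr <- dailyFatigueTrend(sess, bb, nBoot = 20L)
  expect_equal(tr$hour, 10L)
  expect_equal(tr$n, 1L)
  ps <- attr(tr, "pairScores")
  expect_equal(nrow(ps), 1L)
})
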