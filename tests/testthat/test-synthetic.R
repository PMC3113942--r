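test_that("reference parameterization pools class covariances and keeps means", {
  set.seed(100)
  # two classes built from the same underlying rows, one shifted by a
  # constant: identical class covariances, so pooling must return them
  base <- matrix(rnorm(20 * 6), 20, 6)
  X <- rbind(base, sweep(base, 2, rep(2, 6), "+"))
  ref <- LabeledMatrix(X, labels = rep(c("a", "b"), each = 20))
  par <- paramsFromReference(ref)
  expect_equal(par@mean1, colMeans(base), ignore_attr = TRUE)
  expect_equal(par@mean2, colMeans(base) + 2, ignore_attr = TRUE)
  Omega <- tcrossprod(par@factorMatrix)
  expect_equal(Omega, cov(base), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("identical class means are rejected as non-separable", {
  set.seed(101)
  base <- matrix(rnorm(10 * 4), 10, 4)
  ref <- LabeledMatrix(rbind(base, base), labels = rep(c("a", "b"), each = 10))
  expect_error(paramsFromReference(ref), "not separable")
  three <- LabeledMatrix(matrix(rnorm(30), 10, 3),
                         labels = rep(c("a", "b", "c"), c(4, 3, 3)))
  expect_error(paramsFromReference(three), "two classes")
})

test_that("simulated moments converge to the design parameters", {
  set.seed(102)
  # small full-rank reference so standard errors are computable
  X <- matrix(rnorm(40 * 5), 40, 5) %*% matrix(rnorm(25, sd = 0.6), 5, 5)
  X[21:40, ] <- X[21:40, ] + rep(c(1.5, -1, 0.5, 0, 2), each = 20)
  ref <- LabeledMatrix(X, labels = rep(c("a", "b"), each = 20))
  par <- paramsFromReference(ref)
  N <- 25000
  sim <- simulateClasses(par, N, seed = 103)
  Omega <- tcrossprod(par@factorMatrix)
  for (cl in 1:2) {
    Xi <- values(sim)[classLabels(sim) == par@classLabels[cl], ]
    mu <- if (cl == 1) par@mean1 else par@mean2
    # means within 4 standard errors elementwise
    se_mu <- sqrt(diag(Omega) / N)
    expect_true(all(abs(colMeans(Xi) - mu) < 4 * se_mu))
    # covariances within 4 standard errors elementwise
    emp <- cov(Xi)
    se_cov <- sqrt((outer(diag(Omega), diag(Omega)) + Omega^2) / N)
    expect_true(all(abs(emp - Omega) < 4 * se_cov))
  }
})

test_that("degenerate and deterministic sampling behave exactly", {
  par <- new("SimulationParams", mean1 = c(1, 2, 3), mean2 = c(3, 2, 1),
             factorMatrix = matrix(0, 3, 1),
             featureNames = c("x", "y", "z"), classLabels = c("a", "b"))
  sim <- simulateClasses(par, 4, seed = 5)
  expect_equal(unname(values(sim)[1:4, ]),
               matrix(rep(c(1, 2, 3), each = 4), 4, 3))
  expect_equal(unname(values(sim)[5:8, ]),
               matrix(rep(c(3, 2, 1), each = 4), 4, 3))
  # bit-for-bit reproducibility under a fixed seed
  p2 <- new("SimulationParams", mean1 = c(0, 0), mean2 = c(1, 1),
            factorMatrix = diag(2), featureNames = c("u", "v"),
            classLabels = c("a", "b"))
  expect_identical(values(simulateClasses(p2, 50, seed = 7)),
                   values(simulateClasses(p2, 50, seed = 7)))
  expect_false(identical(values(simulateClasses(p2, 50, seed = 7)),
                         values(simulateClasses(p2, 50, seed = 8))))
})

test_that("both simulated classes share one covariance by construction", {
  set.seed(104)
  X <- matrix(rnorm(30 * 4), 30, 4)
  X[16:30, 1] <- X[16:30, 1] + 3
  X[1:15, ] <- X[1:15, ] %*% diag(c(2, 1, 1, 0.5))   # unequal class covs
  ref <- LabeledMatrix(X, labels = rep(c("a", "b"), each = 15))
  par <- paramsFromReference(ref)
  sim <- simulateClasses(par, 4000, seed = 105)
  v <- values(sim)
  C1 <- cov(v[classLabels(sim) == "a", ])
  C2 <- cov(v[classLabels(sim) == "b", ])
  # empirical class covariances agree with each other (common Omega)
  expect_lt(max(abs(C1 - C2)) / max(abs(C1)), 0.15)
})

test_that("planted-signal data carries the advertised moments and guards", {
  expect_error(plantedSignalData(5, 10, 11, 1, 1), "nInformative")
  expect_error(plantedSignalData(5, 10, 2, 0, 1), "shift")
  x <- plantedSignalData(10000, 6, 3, shift = 0.8, seed = 106)
  v <- values(x)
  d <- colMeans(v[classLabels(x) == "g1", ]) -
       colMeans(v[classLabels(x) == "g2", ])
  se <- sqrt(2 / 10000)
  expect_true(all(abs(d[1:3] - 0.8) < 3 * se))
  expect_true(all(abs(d[4:6]) < 3 * se))
})

test_that("aggregated test error never beats the Bayes bound", {
  # Bayes error for equal-covariance Gaussians: Phi(-Delta/2) with
  # Delta = shift * sqrt(nInformative)
  shift <- 0.93; k <- 5
  bayes <- pnorm(-shift * sqrt(k) / 2)
  x <- plantedSignalData(15, 20, k, shift, seed = 107)
  ens <- aggregatePCDA(x, runConfig(outerFolds = 5, replicates = 3,
                                    componentCandidates = 1:4, seed = 108))
  xt <- plantedSignalData(150, 20, k, shift, seed = 109)
  pr <- predict(ens, xt)
  test_err <- mean(as.character(pr$labels) != as.character(classLabels(xt)))
  expect_gte(test_err, bayes - 0.02)
})

test_that("the learning curve improves with training size at reduced scale", {
  sim <- plantedSignalData(100, 60, 10, shift = 1, seed = 110)
  cfg <- runConfig(outerFolds = 10, replicates = 11,
                   componentCandidates = 1:6, seed = 111)
  lc <- learningCurve(sim, trainSizes = c(12, 30, 50), nTest = 40,
                      nRepeats = 10, seed = 112, config = cfg)
  expect_identical(nrow(lc), 12L)   # 3 sizes x {single, aggregated} x {cv, test}
  agg_cv <- lc[lc$classifier == "aggregated" & lc$split == "cv", ]
  # mean error non-increasing in train size, allowing one inversion <= 1 sd
  dd <- diff(agg_cv$meanError)
  expect_lte(sum(dd > 0), 1)
  expect_true(all(dd <= agg_cv$sdError[-1] + 1e-12))
  # single repeat reports zero-width spread
  lc1 <- learningCurve(sim, trainSizes = 20, nTest = 30, nRepeats = 1,
                       seed = 113, config = runConfig(outerFolds = 5,
                           replicates = 2, componentCandidates = 1:3,
                           seed = 113))
  expect_true(all(lc1$sdError == 0))
})
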