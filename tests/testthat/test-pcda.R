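test_that("scatter matrices follow the defining sums", {
  # two 1-D classes at {0,0} and {2,2}: centroids 0 and 2, grand 1
  s <- computeScatter(matrix(c(0, 0, 2, 2)), c("a", "a", "b", "b"))
  expect_equal(s@within, matrix(0))
  expect_equal(s@between, matrix(4))
  expect_equal(unname(s@classCentroids[, 1]), c(0, 2))

  # one sample per class: within-scatter exactly zero
  s1 <- computeScatter(matrix(rnorm(6), 2, 3), c("a", "b"))
  expect_equal(s1@within, matrix(0, 3, 3), ignore_attr = TRUE)
})

test_that("between plus within equals total scatter (conservation)", {
  set.seed(50)
  for (rep in 1:5) {
    X <- matrix(rnorm(36), 12, 3)
    y <- sample(rep(c("a", "b"), 6))
    s <- computeScatter(X, y)
    expect_equal(s@between + s@within, oracle_total_scatter(X),
                 tolerance = 1e-8, ignore_attr = TRUE)
  }
})

test_that("Fisher directions solve the generalized eigenproblem", {
  set.seed(51)
  # identity within-scatter: directions are the leading eigenvectors of Sb
  A <- crossprod(matrix(rnorm(16), 4, 4))
  sc <- new("ScatterPair", between = A, within = diag(4),
            classCentroids = matrix(0, 3, 4), grandCentroid = numeric(4),
            classCounts = c(2L, 2L, 2L), classLabels = c("a", "b", "c"))
  D <- fisherDirections(sc, 2)
  eA <- eigen(A, symmetric = TRUE)
  expect_gt(abs_cos(D[, 1], eA$vectors[, 1]), 1 - 1e-10)
  expect_gt(abs_cos(D[, 2], eA$vectors[, 2]), 1 - 1e-10)

  # two classes: direction parallel to Sw^{-1} (xbar_1 - xbar_2)
  X <- matrix(rnorm(40), 10, 4)
  y <- rep(c("a", "b"), 5)
  s2 <- computeScatter(X, y)
  d <- fisherDirections(s2, 1)
  dm <- colMeans(X[y == "a", ]) - colMeans(X[y == "b", ])
  expect_gt(abs_cos(d[, 1], solve(s2@within, dm)), 1 - 1e-10)
})

test_that("first Fisher direction beats random probes on the Rayleigh quotient", {
  set.seed(52)
  X <- matrix(rnorm(60), 20, 3)
  X[1:10, 1] <- X[1:10, 1] + 2
  s <- computeScatter(X, rep(c("a", "b"), each = 10))
  d <- fisherDirections(s, 1)[, 1]
  rq <- function(v) drop(crossprod(v, s@between %*% v) /
                         crossprod(v, s@within %*% v))
  probes <- matrix(rnorm(200 * 3), 200, 3)
  expect_true(all(rq(d) >= apply(probes, 1, rq) - 1e-10))
})

test_that("Rayleigh quotients of successive directions are non-increasing", {
  set.seed(53)
  X <- matrix(rnorm(30 * 4), 30, 4)
  y <- rep(c("a", "b", "c"), 10)
  X[y == "b", 1] <- X[y == "b", 1] + 3
  X[y == "c", 2] <- X[y == "c", 2] + 2
  s <- computeScatter(X, y)
  D <- fisherDirections(s, 2)
  rq <- function(v) drop(crossprod(v, s@between %*% v) /
                         crossprod(v, s@within %*% v))
  expect_gte(rq(D[, 1]), rq(D[, 2]) - 1e-10)
})

test_that("PCA basis is orthonormal, variance-complete and reconstructs rank-1 data", {
  # data on an exact line in 3-D: one component reconstructs exactly
  t <- seq(-2, 2, length.out = 8)
  X <- cbind(2 * t, -t, 0.5 * t)
  x <- LabeledMatrix(X, labels = rep(c("a", "b"), 4))
  p <- fitPCA(x, 1)
  rec <- sweep(p$scores %*% t(p$loadings), 2, p$center, "+")
  expect_equal(rec, X, tolerance = 1e-10, ignore_attr = TRUE)

  set.seed(54)
  Y <- matrix(rnorm(15 * 6), 15, 6)
  y <- LabeledMatrix(Y, labels = rep(c("a", "b", "c"), 5))
  pf <- fitPCA(y, 6)   # a = min(m - 1, n) = 6
  expect_equal(sum(pf$sdev^2), sum(apply(Y, 2, var)), tolerance = 1e-8)
  cv <- cov(pf$scores)
  expect_lt(max(abs(cv - diag(diag(cv)))), 1e-8)
  expect_equal(crossprod(pf$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(pf$sdev) <= 1e-10))
})

test_that("PCDA separates well-separated clouds and respects dimension bookkeeping", {
  x <- separable_clouds(10, 50)
  mod <- fitPCDA(x, 3)
  expect_equal(as.character(predict(mod, x)), as.character(classLabels(x)))

  # r classes with a >= r gives q = r - 1 discriminant directions
  set.seed(55)
  y3 <- LabeledMatrix(matrix(rnorm(30 * 8), 30, 8),
                      labels = rep(c("a", "b", "c"), 10))
  m3 <- fitPCDA(y3, 5)
  expect_identical(ncol(m3@directions), 2L)
  expect_identical(ncol(discriminantDirections(m3)), 2L)

  # component count beyond m - r is refused (singular within-scatter regime)
  expect_error(fitPCDA(x, 19), "nComponents")
})

test_that("prediction is nearest projected centroid with ties to the first class", {
  train <- LabeledMatrix(matrix(c(-2, -1, 1, 2), 4, 1),
                         labels = c("a", "a", "b", "b"))
  mod <- fitPCDA(train, 1, mode = "center")
  # 0 is exactly midway between projected centroids -1.5 and +1.5
  expect_identical(as.character(predict(mod, matrix(0))), "a")
  expect_identical(as.character(predict(mod, matrix(c(-0.1, 0.1), 2, 1))),
                   c("a", "b"))
})

test_that("PCDA agrees with an independent LDA oracle on the PCA scores", {
  skip_if_not_installed("MASS")
  set.seed(56)
  x <- plantedSignalData(15, 40, 8, shift = 1.2, seed = 56)
  a <- 5
  mod <- fitPCDA(x, a, mode = "center")
  # oracle: MASS::lda with equal priors on the same PCA scores
  xs <- applyScaler(fitScaler(x, "center"), x)
  p <- fitPCA(xs, a)
  fit <- MASS::lda(p$scores, grouping = classLabels(x), prior = c(0.5, 0.5))
  Xtest <- matrix(rnorm(100 * 40), 100, 40)
  stest <- sweep(sweep(Xtest, 2, fitScaler(x, "center")@featureMeans, "-"),
                 2, p$center, "-") %*% p$loadings
  expect_identical(as.character(predict(mod, Xtest)),
                   as.character(predict(fit, stest)$class))
})

test_that("with a = n and m > n, PCDA reproduces classical FLDA", {
  set.seed(57)
  for (r in 2:3) {
    X <- matrix(rnorm(30 * 5), 30, 5)
    y <- rep(letters[1:r], length.out = 30)
    for (k in seq_len(r - 1)) X[y == letters[k + 1], k] <- X[y == letters[k + 1], k] + 2
    x <- LabeledMatrix(X, labels = y)
    mod <- fitPCDA(x, 5, mode = "center")
    D <- discriminantDirections(mod, "feature")
    O <- oracle_flda(X, y, r - 1)
    for (j in seq_len(r - 1))
      expect_gt(abs_cos(D[, j], O[, j]), 1 - 1e-8)
  }
})

test_that("prediction is invariant to a consistent feature permutation", {
  set.seed(58)
  x <- plantedSignalData(12, 20, 4, shift = 1.5, seed = 58)
  perm <- sample(20)
  xp <- LabeledMatrix(values(x)[, perm], labels = classLabels(x),
                      featureNames = featureNames(x)[perm])
  mod <- fitPCDA(x, 4)
  modp <- fitPCDA(xp, 4)
  Xtest <- matrix(rnorm(30 * 20), 30, 20)
  expect_identical(as.character(predict(mod, Xtest)),
                   as.character(predict(modp, Xtest[, perm])))
})

test_that("feature-space discriminant vectors are unit back-projections", {
  x <- separable_clouds(10, 30, shift = 5, seed = 59)
  mod <- fitPCDA(x, 4)
  D <- discriminantDirections(mod, "feature")
  expect_equal(unname(sqrt(colSums(D^2))), rep(1, ncol(D)), tolerance = 1e-10)
  # the planted signal sits on features 1..5: the largest coefficient
  # magnitudes must be exactly those features
  expect_setequal(order(-abs(D[, 1]))[1:5], 1:5)

  # a = n: back-projection is an exact rotation of the score-space direction
  set.seed(59)
  y <- LabeledMatrix(matrix(rnorm(40), 10, 4), labels = rep(c("a", "b"), 5))
  m2 <- fitPCDA(y, 4, mode = "center")
  expect_equal(discriminantDirections(m2, "feature"),
               m2@pcaLoadings %*% m2@directions, tolerance = 1e-10,
               ignore_attr = TRUE)
})
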