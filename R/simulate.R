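# Two-class Gaussian simulation design.
#
# Both classes are multivariate normal N(v_i, Omega) with their own
# means but one shared covariance: v_i is taken as the class mean u_i of
# an auto-scaled two-class reference data set (preserving separability),
# and Omega is the pooled within-class covariance
#   ((m1-1) Omega_1 + (m2-1) Omega_2) / (m1 + m2 - 2).
# A covariance estimated from fewer samples than features is singular;
# it is held in factor form Omega = F F' (eigenvectors scaled by root
# eigenvalues, negatives clipped at zero) and samples are drawn as
# v_i + F z, z ~ N(0, I_k) -- an exact draw from the degenerate
# Gaussian, with no artificial full-rank noise added.

#' Simulation parameters from a two-class reference data set
#'
#' @param ref an auto-scaled [LabeledMatrix-class] with exactly two
#'   classes of at least 2 samples each.
#' @return a [SimulationParams-class] with the class means of `ref` and
#'   the pooled within-class covariance in factor form.
#' @export
paramsFromReference <- function(ref) {
    stopifnot(is(ref, "LabeledMatrix"))
    if (nlevels(ref@labels) != 2L)
        stop("reference must have exactly two classes")
    cnt <- tabulate(ref@labels, nbins = 2L)
    if (any(cnt < 2L))
        stop("each reference class needs at least 2 samples")
    idx1 <- ref@labels == levels(ref@labels)[1L]
    X1 <- ref@values[idx1, , drop = FALSE]
    X2 <- ref@values[!idx1, , drop = FALSE]
    u1 <- colMeans(X1); u2 <- colMeans(X2)
    if (isTRUE(all.equal(u1, u2, tolerance = 0)))
        stop("classes not separable: identical class means")
    pooled <- ((cnt[1L] - 1L) * stats::cov(X1) +
               (cnt[2L] - 1L) * stats::cov(X2)) / (sum(cnt) - 2L)
    e <- eigen(pooled, symmetric = TRUE)
    ev <- pmax(e$values, 0)
    keep <- ev > max(ev) * 1e-12
    Fm <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(ev[keep]),
                                                   nrow = sum(keep))
    new("SimulationParams", mean1 = u1, mean2 = u2, factorMatrix = Fm,
        featureNames = ref@featureNames, classLabels = levels(ref@labels))
}

#' Draw a simulated two-class data set
#'
#' Class i samples are v_i + F z with z standard normal of length k,
#' so both classes share the covariance F F'. Deterministic under
#' `seed`.
#'
#' @param params a [SimulationParams-class].
#' @param nPerClass samples per class.
#' @param seed integer seed.
#' @return a [LabeledMatrix-class] of 2 * nPerClass samples.
#' @export
simulateClasses <- function(params, nPerClass, seed) {
    stopifnot(is(params, "SimulationParams"))
    nPerClass <- as.integer(nPerClass)
    if (nPerClass < 1L) stop("nPerClass must be >= 1")
    k <- ncol(params@factorMatrix)
    n <- length(params@mean1)
    X <- .with_seed(as.integer(seed), {
        Z <- matrix(stats::rnorm(2L * nPerClass * k), 2L * nPerClass, k)
        Z %*% t(params@factorMatrix)
    })
    X <- X + rbind(matrix(params@mean1, nPerClass, n, byrow = TRUE),
                   matrix(params@mean2, nPerClass, n, byrow = TRUE))
    LabeledMatrix(X,
        labels = factor(rep(params@classLabels, each = nPerClass),
                        levels = params@classLabels),
        sampleIds = sprintf("sim%d", seq_len(2L * nPerClass)),
        featureNames = params@featureNames)
}

#' Planted-signal two-class Gaussian data
#'
#' Identity covariance; the class means differ by `shift` on the first
#' `nInformative` features and are equal elsewhere. A fully synthetic
#' fixture for recovery and stability experiments: the Bayes-optimal
#' error is pnorm(-shift * sqrt(nInformative) / 2) in closed form.
#'
#' @param nPerClass samples per class.
#' @param nFeatures total features n.
#' @param nInformative number of shifted features (<= n).
#' @param shift mean difference on informative features; must be > 0
#'   (for null experiments permute labels instead of zeroing the shift).
#' @param seed integer seed.
#' @return a [LabeledMatrix-class] with classes "g1", "g2".
#' @export
plantedSignalData <- function(nPerClass, nFeatures, nInformative, shift, seed) {
    nPerClass <- as.integer(nPerClass); nFeatures <- as.integer(nFeatures)
    nInformative <- as.integer(nInformative)
    if (nInformative > nFeatures) stop("nInformative must be <= nFeatures")
    if (shift <= 0) stop("shift must be > 0; use permuted labels for nulls")
    m <- 2L * nPerClass
    X <- .with_seed(as.integer(seed),
                    matrix(stats::rnorm(m * nFeatures), m, nFeatures))
    X[seq_len(nPerClass), seq_len(nInformative)] <-
        X[seq_len(nPerClass), seq_len(nInformative)] + shift
    LabeledMatrix(X,
        labels = factor(rep(c("g1", "g2"), each = nPerClass)),
        sampleIds = sprintf("P%d", seq_len(m)),
        featureNames = sprintf("F%d", seq_len(nFeatures)))
}

#' Learning-curve sampling protocol
#'
#' For each training size and repeat: draw a stratified training set of
#' that size from `sim`, draw `nTest` test samples (stratified, without
#' replacement) from the remainder, then run a single double-CV PCDA and
#' an aggregated PCDA (R replicates per `config`) and record their
#' cross-validation and test errors. Test predictions use the outer-fold
#' models of the run voting by majority. Summaries are the mean, sd and
#' standard error of the mean over repeats (sd is 0 for a single
#' repeat). When a training draw is too small for the configured K, K is
#' capped at the smallest class size of the draw.
#'
#' @param sim a [LabeledMatrix-class] to sample from.
#' @param trainSizes integer vector of training-set sizes.
#' @param nTest test samples per repeat.
#' @param nRepeats repeats per size.
#' @param seed master seed; draw (size s, repeat t) derives its own seed.
#' @param config a [RunConfig-class]; `replicates` is the aggregation R.
#' @return data.frame with one row per (size, classifier, split) and
#'   columns `trainSize`, `classifier` ("single"/"aggregated"), `split`
#'   ("cv"/"test"), `meanError`, `sdError`, `semError`, `nRepeats`.
#' @export
learningCurve <- function(sim, trainSizes, nTest, nRepeats, seed,
                          config = runConfig()) {
    stopifnot(is(sim, "LabeledMatrix"), is(config, "RunConfig"))
    trainSizes <- as.integer(trainSizes)
    m <- nSamples(sim)
    if (max(trainSizes) + nTest > m)
        stop("max(trainSizes) + nTest must be <= ", m)
    lev <- levels(sim@labels)
    rows <- list()
    for (s in trainSizes) {
        errs <- array(NA_real_, c(nRepeats, 2L, 2L))  # repeat x {single,agg} x {cv,test}
        for (t in seq_len(nRepeats)) {
            dseed <- .derive_seed(seed, s * 1000L + t)
            pick <- .with_seed(dseed, {
                tr <- unlist(lapply(lev, function(cl) {
                    idx <- which(sim@labels == cl)
                    sample(idx, round(s * length(idx) / m))
                }))
                rest <- setdiff(seq_len(m), tr)
                te <- unlist(lapply(lev, function(cl) {
                    idx <- intersect(rest, which(sim@labels == cl))
                    sample(idx, round(nTest * length(which(sim@labels == cl)) / m))
                }))
                list(train = tr, test = te)
            })
            train <- sim[pick$train, ]
            test <- sim[pick$test, ]
            Keff <- min(config@outerFolds,
                        min(tabulate(train@labels, nlevels(train@labels))))
            cfg <- runConfig(outerFolds = Keff, replicates = config@replicates,
                             componentCandidates = config@componentCandidates,
                             seed = dseed, scalingMode = config@scalingMode)
            single <- doubleCV(train, cfg)
            ens1 <- .ensemble_from_votes(list(single),
                        .votes_of(list(single), train), train, cfg)
            agg <- aggregatePCDA(train, cfg)
            truth <- as.character(test@labels)
            p1 <- predict(ens1, test)
            pa <- predict(agg, test)
            errs[t, 1L, 1L] <- single@cvError
            errs[t, 1L, 2L] <- mean(as.character(p1$labels) != truth)
            errs[t, 2L, 1L] <- agg@aggregatedCvError
            errs[t, 2L, 2L] <- mean(as.character(pa$labels) != truth)
        }
        for (ci in 1:2) for (si in 1:2) {
            e <- errs[, ci, si]
            sdv <- if (nRepeats > 1L) stats::sd(e) else 0
            rows[[length(rows) + 1L]] <- data.frame(
                trainSize = s,
                classifier = c("single", "aggregated")[ci],
                split = c("cv", "test")[si],
                meanError = mean(e), sdError = sdv,
                semError = sdv / sqrt(nRepeats), nRepeats = nRepeats,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, rows)
}

.votes_of <- function(reps, data) {
    lev <- levels(data@labels)
    m <- nSamples(data)
    votes <- matrix(0L, m, length(lev), dimnames = list(data@sampleIds, lev))
    for (rep in reps) {
        p <- as.integer(rep@heldoutPredictions)
        votes[cbind(seq_len(m), p)] <- votes[cbind(seq_len(m), p)] + 1L
    }
    votes
}
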