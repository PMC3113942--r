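# Principal component discriminant analysis.
#
# Fisher LDA seeks the direction d maximizing the Rayleigh quotient
# d' S_b d / d' S_w d of the between-class scatter
#   S_b = sum_i m_i (xbar_i - xbar)(xbar_i - xbar)'
# against the within-class scatter
#   S_w = sum_i sum_{j in class i} (x_j - xbar_i)(x_j - xbar_i)',
# i.e. the leading eigenvector of S_w^{-1} S_b. With more features than
# samples S_w is singular and the eigenproblem is undefined, so the data
# are first projected onto a low-dimensional PCA subspace where S_w is
# invertible; LDA in that score space is PCDA. The eigenproblem is
# solved through a Cholesky factor of S_w (mathematically identical to
# inverting S_w, numerically safer).

#' Between- and within-class scatter matrices
#'
#' @param scores numeric matrix (samples x dimensions), e.g. PCA scores.
#' @param labels class label per row (factor or coercible).
#' @return a [ScatterPair-class] holding S_b, S_w, the class centroids,
#'   the global centroid and class counts. S_b + S_w equals the total
#'   scatter about the global centroid; S_b has rank at most r - 1.
#' @examples
#' s <- computeScatter(matrix(c(0, 0, 2, 2)), c("a", "a", "b", "b"))
#' s@between   # 4: two classes of 2 at distance 1 from the global centroid
#' @export
computeScatter <- function(scores, labels) {
    scores <- as.matrix(scores)
    if (!is.factor(labels)) labels <- factor(labels)
    labels <- droplevels(labels)
    r <- nlevels(labels)
    if (r < 2L) stop("at least two classes required")
    if (any(tabulate(labels, nbins = r) < 1L))
        stop("every class needs at least one member")
    st <- .scatter(scores, as.integer(labels), r)
    new("ScatterPair", between = st$Sb, within = st$Sw,
        classCentroids = st$centroids, grandCentroid = st$grand,
        classCounts = st$counts, classLabels = levels(labels))
}

#' Fisher discriminant directions from a scatter pair
#'
#' Returns the top-q generalized eigenvectors of (S_b, S_w): the
#' directions with the largest between- to within-class scatter ratio,
#' ordered by decreasing eigenvalue. Each column has unit norm and its
#' largest-magnitude entry is made positive, fixing the arbitrary sign.
#'
#' @param scatter a [ScatterPair-class] with nonsingular S_w (guaranteed
#'   in PCA score space when the dimension is at most m - r).
#' @param q number of directions, at most r - 1.
#' @return an a x q matrix of directions.
#' @export
fisherDirections <- function(scatter, q = length(scatter@classLabels) - 1L) {
    stopifnot(is(scatter, "ScatterPair"))
    a <- nrow(scatter@within)
    q <- as.integer(q)
    if (q < 1L || q > min(length(scatter@classLabels) - 1L, a))
        stop("q must be in 1..min(r - 1, a)")
    .fisher(scatter@between, scatter@within, q)$directions
}

#' Principal component basis of a (scaled) data set
#'
#' Column-centers the matrix and takes the top-a right singular vectors;
#' scores are the centered data projected on the loadings, with
#' non-increasing component variances.
#'
#' @param x a [LabeledMatrix-class] (typically already scaled).
#' @param nComponents a, with 1 <= a <= min(m - 1, n).
#' @return list with `center` (length-n mean), `loadings` (n x a,
#'   orthonormal columns), `scores` (m x a) and `sdev` (component
#'   standard deviations).
#' @export
fitPCA <- function(x, nComponents) {
    stopifnot(is(x, "LabeledMatrix"))
    a <- as.integer(nComponents)
    m <- nSamples(x); n <- nFeatures(x)
    if (a < 1L || a > min(m - 1L, n))
        stop("nComponents must be in 1..min(m - 1, n) = ", min(m - 1L, n))
    p <- .pca_fit(x@values, a)
    list(center = p$center, loadings = p$loadings, scores = p$scores,
         sdev = p$singular / sqrt(m - 1))
}

#' Fit a PCDA model
#'
#' Pipeline: fit the scaler on the training rows, apply it, fit a PCA
#' basis of `nComponents` loadings, compute the scatter pair on the
#' scores, extract the Fisher directions, and project the class
#' centroids. `nComponents` must not exceed (training samples - number
#' of classes) so that the within-class scatter in score space stays
#' invertible.
#'
#' @param train a [LabeledMatrix-class] of training samples.
#' @param nComponents number of principal components a.
#' @param mode scaling mode (see [fitScaler()]).
#' @return a [PCDAModel-class].
#' @examples
#' set.seed(1)
#' x <- plantedSignalData(10, 50, 5, shift = 4, seed = 1)
#' mod <- fitPCDA(x, nComponents = 3)
#' mean(predict(mod, x) == classLabels(x))   # separable: 1
#' @export
fitPCDA <- function(train, nComponents, mode = c("autoscale", "center", "none")) {
    mode <- match.arg(mode)
    stopifnot(is(train, "LabeledMatrix"))
    r <- nlevels(train@labels)
    fit <- .pcda_fit(train@values, as.integer(train@labels), r,
                     as.integer(nComponents), mode)
    .as_model(fit, train@featureNames, levels(train@labels))
}

#' Predict class labels with a fitted PCDA model
#'
#' Each sample is scaled with the training-derived parameters, centered,
#' projected into the PCA score space and then onto the discriminant
#' directions, and assigned the label of the nearest projected class
#' centroid (Euclidean distance; exact ties resolve to the first class
#' in stored label order).
#'
#' @param object a [PCDAModel-class].
#' @param newdata a [LabeledMatrix-class] or bare numeric matrix with the
#'   model's features.
#' @param ... unused.
#' @return factor of predicted labels.
#' @export
setMethod("predict", "PCDAModel", function(object, newdata, ...) {
    X <- if (is(newdata, "LabeledMatrix")) newdata@values else as.matrix(newdata)
    .check_features(object, newdata)
    idx <- .pcda_predict(.as_fit(object), X)
    factor(object@classLabels[idx], levels = object@classLabels)
})

#' @rdname discriminantDirections
#' @export
setMethod("discriminantDirections", "PCDAModel", function(object,
        space = c("feature", "score")) {
    space <- match.arg(space)
    if (space == "score") return(object@directions)
    D <- object@pcaLoadings %*% object@directions
    for (j in seq_len(ncol(D)))
        D[, j] <- D[, j] / sqrt(sum(D[, j]^2))
    rownames(D) <- object@scaler@featureNames
    D
})
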