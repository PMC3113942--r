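#' @import methods
NULL

#' Labeled sample-by-feature matrix
#'
#' The central data container: a numeric matrix with samples as rows and
#' features as columns, together with unique sample identifiers, unique
#' feature names, and a class label per sample. Missing values are not
#' permitted; they must be dealt with upstream.
#'
#' @slot values numeric matrix, m samples x n features.
#' @slot sampleIds character vector of m unique sample identifiers.
#' @slot featureNames character vector of n unique feature names.
#' @slot labels factor of length m with at least two levels, every level
#'   represented by at least one sample.
#'
#' @seealso [LabeledMatrix()] for the user-facing constructor,
#'   [readLabeledMatrix()] to load one from a delimited file.
#' @name LabeledMatrix-class
#' @aliases LabeledMatrix-class
#' @exportClass LabeledMatrix
setClass("LabeledMatrix",
    representation(
        values = "matrix",
        sampleIds = "character",
        featureNames = "character",
        labels = "factor"
    )
)

setValidity("LabeledMatrix", function(object) {
    v <- object@values
    msg <- character()
    if (!is.numeric(v))
        msg <- c(msg, "'values' must be a numeric matrix")
    if (nrow(v) != length(object@sampleIds))
        msg <- c(msg, "row count of 'values' must equal length of 'sampleIds'")
    if (nrow(v) != length(object@labels))
        msg <- c(msg, "row count of 'values' must equal length of 'labels'")
    if (ncol(v) != length(object@featureNames))
        msg <- c(msg, "column count of 'values' must equal length of 'featureNames'")
    if (anyDuplicated(object@sampleIds))
        msg <- c(msg, "duplicate sample id")
    if (anyDuplicated(object@featureNames))
        msg <- c(msg, "duplicate feature name")
    if (anyNA(v))
        msg <- c(msg, "missing value in 'values'")
    if (nlevels(object@labels) < 2L)
        msg <- c(msg, "fewer than 2 classes")
    if (any(tabulate(object@labels, nbins = nlevels(object@labels)) == 0L))
        msg <- c(msg, "every class must have at least one member")
    if (anyNA(object@labels))
        msg <- c(msg, "missing class label")
    if (length(msg)) msg else TRUE
})

#' Construct a LabeledMatrix
#'
#' @param values numeric matrix, samples as rows.
#' @param labels class label per row; coerced to factor. Factor level
#'   order is preserved when a factor is supplied, otherwise levels are
#'   sorted unique values.
#' @param sampleIds sample identifiers; defaults to rownames or
#'   \code{S1..Sm}.
#' @param featureNames feature names; defaults to colnames or
#'   \code{V1..Vn}.
#' @return A validated [LabeledMatrix-class] object.
#' @examples
#' x <- LabeledMatrix(matrix(rnorm(20), 4, 5), labels = c("a", "a", "b", "b"))
#' nSamples(x); nFeatures(x); classLevels(x)
#' @export
LabeledMatrix <- function(values, labels, sampleIds = NULL, featureNames = NULL) {
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (is.null(sampleIds))
        sampleIds <- if (!is.null(rownames(values))) rownames(values)
                     else sprintf("S%d", seq_len(nrow(values)))
    if (is.null(featureNames))
        featureNames <- if (!is.null(colnames(values))) colnames(values)
                        else sprintf("V%d", seq_len(ncol(values)))
    if (!is.factor(labels)) labels <- factor(labels)
    labels <- droplevels(labels)
    dimnames(values) <- NULL
    new("LabeledMatrix", values = values, sampleIds = as.character(sampleIds),
        featureNames = as.character(featureNames), labels = labels)
}

#' Run configuration for cross-validated PCDA
#'
#' Holds every tunable of the double cross-validation and aggregation
#' machinery. The defaults are the canonical settings of the method:
#' 10 outer folds with 9 inner folds (always outer folds minus one), 51
#' replicates for aggregation, auto-scaling fitted on training data, and
#' deterministic first-class tie-breaking in majority votes.
#'
#' @slot outerFolds integer K >= 2, number of outer cross-validation folds;
#'   the inner loop always uses K - 1 folds.
#' @slot replicates integer R >= 1, number of repeated double-CV runs to
#'   aggregate.
#' @slot componentCandidates ordered integer vector of candidate numbers of
#'   principal components; empty means "auto": 1..min(20, inner training
#'   size minus the number of classes).
#' @slot seed integer master seed; replicate t runs with seed + t.
#' @slot scalingMode one of "none", "center", "autoscale".
#' @slot voteTieRule fixed to "first-class": vote ties resolve to the first
#'   class in stored label order.
#' @exportClass RunConfig
setClass("RunConfig",
    representation(
        outerFolds = "integer",
        replicates = "integer",
        componentCandidates = "integer",
        seed = "integer",
        scalingMode = "character",
        voteTieRule = "character"
    )
)

setValidity("RunConfig", function(object) {
    msg <- character()
    if (length(object@outerFolds) != 1L || object@outerFolds < 2L)
        msg <- c(msg, "'outerFolds' must be a single integer >= 2")
    if (length(object@replicates) != 1L || object@replicates < 1L)
        msg <- c(msg, "'replicates' must be a single integer >= 1")
    if (length(object@componentCandidates) &&
        (any(object@componentCandidates < 1L) ||
         is.unsorted(object@componentCandidates, strictly = TRUE)))
        msg <- c(msg, "'componentCandidates' must be strictly increasing integers >= 1")
    if (!object@scalingMode %in% c("none", "center", "autoscale"))
        msg <- c(msg, "'scalingMode' must be one of none/center/autoscale")
    if (!identical(object@voteTieRule, "first-class"))
        msg <- c(msg, "'voteTieRule' is fixed to \"first-class\"")
    if (length(msg)) msg else TRUE
})

#' @rdname RunConfig-class
#' @param outerFolds,replicates,componentCandidates,seed,scalingMode see slots.
#' @return A `RunConfig` object.
#' @examples
#' runConfig(outerFolds = 10, replicates = 51, seed = 7)
#' @export
runConfig <- function(outerFolds = 10L, replicates = 51L,
                      componentCandidates = integer(0), seed = 1L,
                      scalingMode = c("autoscale", "center", "none")) {
    scalingMode <- match.arg(scalingMode)
    new("RunConfig",
        outerFolds = as.integer(outerFolds),
        replicates = as.integer(replicates),
        componentCandidates = as.integer(componentCandidates),
        seed = as.integer(seed),
        scalingMode = scalingMode,
        voteTieRule = "first-class")
}

#' Training-fitted feature scaling parameters
#'
#' @slot featureMeans per-feature training means (0 when mode = "none").
#' @slot featureSds per-feature training standard deviations (all 1 unless
#'   mode = "autoscale"); strictly positive by construction -- constant
#'   features are dropped, not epsilon-padded.
#' @slot mode scaling mode used at fit time.
#' @slot featureNames names of the retained features, in order.
#' @slot droppedFeatures names of zero-variance features removed under
#'   auto-scaling.
#' @exportClass ScalerParams
setClass("ScalerParams",
    representation(
        featureMeans = "numeric",
        featureSds = "numeric",
        mode = "character",
        featureNames = "character",
        droppedFeatures = "character"
    )
)

setValidity("ScalerParams", function(object) {
    msg <- character()
    n <- length(object@featureNames)
    if (length(object@featureMeans) != n || length(object@featureSds) != n)
        msg <- c(msg, "means/sds must match the number of retained features")
    if (any(object@featureSds <= 0))
        msg <- c(msg, "feature sds must be strictly positive")
    if (!object@mode %in% c("none", "center", "autoscale"))
        msg <- c(msg, "invalid scaling mode")
    if (length(msg)) msg else TRUE
})

#' Between- and within-class scatter of a labeled point cloud
#'
#' @slot between the between-class scatter matrix S_b (rank <= r - 1).
#' @slot within the within-class scatter matrix S_w.
#' @slot classCentroids r x a matrix of class centroids.
#' @slot grandCentroid length-a global centroid.
#' @slot classCounts integer class sizes.
#' @slot classLabels the r class labels in stored order.
#' @exportClass ScatterPair
setClass("ScatterPair",
    representation(
        between = "matrix",
        within = "matrix",
        classCentroids = "matrix",
        grandCentroid = "numeric",
        classCounts = "integer",
        classLabels = "character"
    )
)

setValidity("ScatterPair", function(object) {
    msg <- character()
    if (max(abs(object@between - t(object@between))) > 1e-10)
        msg <- c(msg, "'between' must be symmetric")
    if (max(abs(object@within - t(object@within))) > 1e-10)
        msg <- c(msg, "'within' must be symmetric")
    if (length(msg)) msg else TRUE
})

#' Fitted principal component discriminant analysis model
#'
#' A PCDA model is the composition of a training-fitted scaler, a PCA
#' basis of `nComponents` orthonormal loadings, Fisher discriminant
#' directions computed in the score space, and the projected class
#' centroids used by the nearest-centroid decision rule.
#'
#' @slot scaler [ScalerParams-class] fitted on the training rows.
#' @slot pcaMean length-n centering vector of the (scaled) training data.
#' @slot pcaLoadings n x a matrix with orthonormal columns.
#' @slot nComponents a, the retained number of principal components.
#' @slot directions a x q matrix of discriminant directions in score space,
#'   q = min(r - 1, a), unit columns, sign fixed so the largest-magnitude
#'   entry is positive.
#' @slot centroids r x q projected class centroids.
#' @slot classLabels the r class labels in stored order (ties in the
#'   decision rule resolve to the first).
#' @slot featureNames names of the features the model consumes.
#' @exportClass PCDAModel
setClass("PCDAModel",
    representation(
        scaler = "ScalerParams",
        pcaMean = "numeric",
        pcaLoadings = "matrix",
        nComponents = "integer",
        directions = "matrix",
        centroids = "matrix",
        classLabels = "character",
        featureNames = "character"
    )
)

setValidity("PCDAModel", function(object) {
    msg <- character()
    a <- object@nComponents
    L <- object@pcaLoadings
    if (ncol(L) != a)
        msg <- c(msg, "'pcaLoadings' must have nComponents columns")
    if (nrow(L) != length(object@pcaMean))
        msg <- c(msg, "'pcaMean' length must match loading rows")
    G <- crossprod(L)
    if (max(abs(G - diag(nrow = ncol(L)))) > 1e-8)
        msg <- c(msg, "'pcaLoadings' columns must be orthonormal")
    q <- ncol(object@directions)
    r <- length(object@classLabels)
    if (q != min(r - 1L, a))
        msg <- c(msg, "number of discriminant directions must be min(r-1, a)")
    if (nrow(object@centroids) != r || ncol(object@centroids) != q)
        msg <- c(msg, "'centroids' must be r x q")
    if (length(msg)) msg else TRUE
})

#' Result of one nested (double) cross-validation run
#'
#' @slot models list of K [PCDAModel-class] objects, one per outer fold,
#'   each fitted on the K-1 remaining parts at the component count chosen
#'   by the inner loop.
#' @slot selectedNcomp integer vector of the K selected component counts.
#' @slot foldOfSample outer-fold index (1..K) of every sample.
#' @slot heldoutPredictions factor: each sample's label predicted by the
#'   model that excluded it.
#' @slot trueLabels the observed labels.
#' @slot cvError misclassification fraction of the held-out predictions.
#' @slot config the [RunConfig-class] used.
#' @slot seed the seed this run actually used (differs from the config
#'   seed inside an aggregated run).
#' @slot sampleIds sample identifiers.
#' @exportClass DoubleCVResult
setClass("DoubleCVResult",
    representation(
        models = "list",
        selectedNcomp = "integer",
        foldOfSample = "integer",
        heldoutPredictions = "factor",
        trueLabels = "factor",
        cvError = "numeric",
        config = "RunConfig",
        seed = "integer",
        sampleIds = "character"
    )
)

setValidity("DoubleCVResult", function(object) {
    msg <- character()
    m <- length(object@trueLabels)
    if (length(object@heldoutPredictions) != m ||
        length(object@foldOfSample) != m)
        msg <- c(msg, "per-sample slots must have one entry per sample")
    err <- mean(as.character(object@heldoutPredictions) !=
                as.character(object@trueLabels))
    if (abs(err - object@cvError) > 1e-12)
        msg <- c(msg, "'cvError' must equal the held-out misclassification fraction")
    if (length(msg)) msg else TRUE
})

#' Aggregated classifier from repeated double cross-validation
#'
#' @slot replicates list of R [DoubleCVResult-class] runs (seeds
#'   seed+1..seed+R).
#' @slot voteCounts m x r integer matrix; sample j receives exactly one
#'   vote per replicate, cast by the outer-fold model that held j out.
#' @slot aggregatedLabels majority-vote label per sample (ties to the
#'   first class in stored label order).
#' @slot aggregatedCvError misclassification fraction of the aggregated
#'   labels.
#' @slot margins per-sample margin in [-1, 1]: (correct votes minus
#'   incorrect votes) / R.
#' @slot classLabels class labels in stored order.
#' @slot trueLabels observed labels.
#' @slot sampleIds sample identifiers.
#' @slot config the [RunConfig-class] used.
#' @slot seed the master seed.
#' @exportClass EnsembleResult
setClass("EnsembleResult",
    representation(
        replicates = "list",
        voteCounts = "matrix",
        aggregatedLabels = "factor",
        aggregatedCvError = "numeric",
        margins = "numeric",
        classLabels = "character",
        trueLabels = "factor",
        sampleIds = "character",
        config = "RunConfig",
        seed = "integer"
    )
)

setValidity("EnsembleResult", function(object) {
    msg <- character()
    R <- length(object@replicates)
    if (R && any(rowSums(object@voteCounts) != R))
        msg <- c(msg, "every row of 'voteCounts' must sum to the number of replicates")
    if (any(object@margins < -1 - 1e-12) || any(object@margins > 1 + 1e-12))
        msg <- c(msg, "margins must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' Rank-product feature importance table
#'
#' @slot featureNames the n feature names.
#' @slot logRankProduct mean log rank per feature over the pooled
#'   discriminant vectors (monotone-equivalent to the literal product of
#'   ranks, but immune to overflow).
#' @slot ordering permutation of 1..n sorting `logRankProduct` ascending,
#'   ties broken by feature index; the head of the ordering holds the
#'   most discriminative features.
#' @slot nVectors number of discriminant vectors pooled.
#' @exportClass RankProductTable
setClass("RankProductTable",
    representation(
        featureNames = "character",
        logRankProduct = "numeric",
        ordering = "integer",
        nVectors = "integer"
    )
)

setValidity("RankProductTable", function(object) {
    msg <- character()
    n <- length(object@featureNames)
    if (length(object@logRankProduct) != n || length(object@ordering) != n)
        msg <- c(msg, "slot lengths must agree")
    if (n && !identical(sort(object@ordering), seq_len(n)))
        msg <- c(msg, "'ordering' must be a permutation of 1..n")
    if (length(msg)) msg else TRUE
})

#' Parameters of the two-class Gaussian simulation design
#'
#' Both classes share a single covariance held in factor form: class i is
#' sampled as mean_i + F z with z standard normal, so the covariance is
#' F F' regardless of its rank. Estimating the pooled covariance from
#' fewer samples than features yields a singular matrix; factor-form
#' sampling draws from that degenerate Gaussian exactly rather than
#' padding it to full rank.
#'
#' @slot mean1,mean2 length-n class mean vectors (must differ).
#' @slot factorMatrix n x k factor F of the common covariance.
#' @slot featureNames feature names.
#' @slot classLabels the two class labels.
#' @exportClass SimulationParams
setClass("SimulationParams",
    representation(
        mean1 = "numeric",
        mean2 = "numeric",
        factorMatrix = "matrix",
        featureNames = "character",
        classLabels = "character"
    )
)

setValidity("SimulationParams", function(object) {
    msg <- character()
    n <- length(object@mean1)
    if (length(object@mean2) != n || nrow(object@factorMatrix) != n ||
        length(object@featureNames) != n)
        msg <- c(msg, "mean/factor/name dimensions must agree")
    if (isTRUE(all.equal(object@mean1, object@mean2, tolerance = 0)))
        msg <- c(msg, "classes not separable: identical class means")
    if (length(object@classLabels) != 2L)
        msg <- c(msg, "exactly two class labels required")
    if (length(msg)) msg else TRUE
})
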