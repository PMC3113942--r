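# Generics and accessors. Slots are never touched directly by user code.

#' @rdname LabeledMatrix-class
#' @param x,object a \code{LabeledMatrix} (or other pcdagg object, where noted)
#' @export
setGeneric("values", function(x, ...) standardGeneric("values"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname LabeledMatrix-class
#' @export
setGeneric("classLevels", function(x) standardGeneric("classLevels"))

#' @rdname DoubleCVResult-class
#' @export
setGeneric("cvError", function(x) standardGeneric("cvError"))

#' @rdname DoubleCVResult-class
#' @export
setGeneric("selectedNcomp", function(x) standardGeneric("selectedNcomp"))

#' @rdname DoubleCVResult-class
#' @export
setGeneric("heldoutPredictions", function(x) standardGeneric("heldoutPredictions"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("voteCounts", function(x) standardGeneric("voteCounts"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("margins", function(x) standardGeneric("margins"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("aggregatedLabels", function(x) standardGeneric("aggregatedLabels"))

#' @rdname EnsembleResult-class
#' @export
setGeneric("replicates", function(x) standardGeneric("replicates"))

#' Discriminant directions of a fitted model
#'
#' In `"score"` space the columns are the Fisher directions the model
#' classifies with; in `"feature"` space they are back-projected through
#' the PCA loadings (loadings times score-space directions) and
#' re-normalized to unit length, giving one coefficient per feature --
#' the vectors pooled by [rankProducts()].
#'
#' @param object a [PCDAModel-class].
#' @param space `"feature"` (default) or `"score"`.
#' @return a matrix with one column per discriminant direction.
#' @export
setGeneric("discriminantDirections",
    function(object, space = c("feature", "score"))
        standardGeneric("discriminantDirections"))

#' Write a result object to a reproducible plain-text report
#'
#' Reports carry a `# key=value` header (package version, seed, run
#' configuration) followed by a tab-separated body. Identical input,
#' seed and configuration reproduce a byte-identical file; no wall-clock
#' timestamps are embedded.
#'
#' @param result a [DoubleCVResult-class], [EnsembleResult-class] or
#'   [RankProductTable-class].
#' @param path file path to write.
#' @return invisibly, the path.
#' @export
setGeneric("writeReport", function(result, path) standardGeneric("writeReport"))

#' Aggregated error as a function of the number of aggregated replicates
#'
#' Reuses the single stream of fitted replicates: for each grid value g
#' the aggregated cross-validation error is recomputed from the votes of
#' the first g replicates only (prefix voting; nothing is refitted).
#'
#' @param x an [EnsembleResult-class], or a [LabeledMatrix-class] (in
#'   which case an ensemble with R = max(grid) replicates is fitted
#'   first using `config`).
#' @param grid strictly increasing integers, max(grid) <= R.
#' @param config used only for the `LabeledMatrix` method.
#' @return a data.frame with columns `nAggregated` and `cvError`.
#' @export
setGeneric("stabilityCurve", function(x, grid, ...) standardGeneric("stabilityCurve"))

#' Rank-product feature ranking from an aggregated run
#'
#' Collects the feature-space discriminant vector of every member model
#' (R replicates x K outer folds) and ranks features by rank products:
#' within each vector features are ranked by absolute coefficient
#' (rank 1 = largest), and each feature's ranks are combined across
#' vectors on the log scale. Features with the lowest rank products are
#' the most consistently discriminative.
#'
#' @param x an [EnsembleResult-class].
#' @param column which discriminant column to pool when there are more
#'   than two classes; with two classes there is only one.
#' @return a [RankProductTable-class].
#' @export
setGeneric("rankProducts", function(x, column = 1L) standardGeneric("rankProducts"))
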