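# Nested (double) cross-validation.
#
# The outer K-fold split estimates the cross-validation error; for each
# outer fold, a (K-1)-fold inner cross-validation on the remaining
# parts alone selects the number of principal components. The model
# that predicts an outer fold is refitted on all K-1 remaining parts at
# the selected component count, and every pretreatment statistic is
# refitted inside every training partition, so no held-out sample ever
# influences the model that scores it.

#' Stratified K-fold assignment
#'
#' Within each class, samples are shuffled under the seed and dealt
#' round-robin into the K folds, so per class the fold counts differ by
#' at most one and every fold mirrors the class proportions of the full
#' data. K may not exceed the smallest class size: beyond that a fold
#' would lack a class entirely.
#'
#' @param labels class label per sample.
#' @param K number of folds (>= 2).
#' @param seed integer seed; the same seed reproduces the assignment.
#' @return integer vector of fold indices in 1..K, with attributes `K`
#'   and `seed`.
#' @export
stratifiedFolds <- function(labels, K, seed) {
    if (!is.factor(labels)) labels <- factor(labels)
    labels <- droplevels(labels)
    K <- as.integer(K)
    if (K < 2L) stop("K must be >= 2")
    folds <- .strat_folds(as.integer(labels), nlevels(labels), K,
                          as.integer(seed))
    structure(folds, K = K, seed = as.integer(seed))
}

#' Inner-loop selection of the number of principal components
#'
#' Runs a stratified `kInner`-fold cross-validation inside `data`,
#' computes the misclassification fraction for every candidate
#' component count, and returns the candidate with minimal inner error;
#' ties break toward the smallest candidate (parsimony). Candidates
#' infeasible for the realized fold sizes (those exceeding inner
#' training size minus the number of classes) are removed first.
#'
#' @param data the [LabeledMatrix-class] available to the inner loop
#'   (i.e. the outer-training portion).
#' @param candidates integer candidate grid; empty for the default
#'   1..min(20, inner training size - r).
#' @param kInner number of inner folds.
#' @param seed integer seed for the inner fold assignment.
#' @param mode scaling mode.
#' @return list with `best` (the selected count), `candidates` (the
#'   feasible grid) and `errors` (inner CV error per candidate).
#' @export
selectNcomp <- function(data, candidates = integer(0), kInner = 9L, seed = 1L,
                        mode = c("autoscale", "center", "none")) {
    mode <- match.arg(mode)
    stopifnot(is(data, "LabeledMatrix"))
    y <- as.integer(data@labels); r <- nlevels(data@labels)
    kInner <- as.integer(kInner)
    if (kInner < 2L) stop("kInner must be >= 2")
    if (!length(candidates)) {
        min_train <- nSamples(data) -
            max(tabulate(.strat_folds(y, r, kInner, as.integer(seed)),
                         nbins = kInner))
        candidates <- seq_len(max(1L, min(20L, min_train - r)))
    }
    .select_ncomp(data@values, y, r, kInner, as.integer(candidates), mode,
                  as.integer(seed))
}

#' Double (nested) cross-validation of PCDA
#'
#' For each of the K outer folds: a (K-1)-fold inner cross-validation on
#' the remaining parts picks the component count with minimal inner
#' error; a PCDA model with that count is refitted on all K-1 parts and
#' predicts the held-out fold. The cross-validation error aggregates
#' all held-out predictions. The inner fold count is always K - 1,
#' mirroring the canonical 10-outer / 9-inner usage.
#'
#' @param data a [LabeledMatrix-class].
#' @param config a [RunConfig-class]; `outerFolds`, `componentCandidates`,
#'   `scalingMode` and `seed` are honored (set `seed` to override the
#'   config via [runConfig()]).
#' @param seed optional override of `config@seed` for this run.
#' @return a [DoubleCVResult-class].
#' @examples
#' x <- plantedSignalData(20, 30, 5, shift = 3, seed = 2)
#' res <- doubleCV(x, runConfig(outerFolds = 5, seed = 2,
#'                              componentCandidates = 1:4))
#' cvError(res)
#' @export
doubleCV <- function(data, config = runConfig(), seed = NULL) {
    stopifnot(is(data, "LabeledMatrix"), is(config, "RunConfig"))
    if (is.null(seed)) seed <- config@seed
    seed <- as.integer(seed)
    y <- as.integer(data@labels); r <- nlevels(data@labels)
    K <- config@outerFolds
    res <- .double_cv(data@values, y, r, K, config@componentCandidates,
                      config@scalingMode, seed)
    lev <- levels(data@labels)
    models <- lapply(res$fits, .as_model, featureNames = data@featureNames,
                     classLabels = lev)
    new("DoubleCVResult",
        models = models,
        selectedNcomp = res$selected,
        foldOfSample = res$folds,
        heldoutPredictions = factor(lev[res$predictions], levels = lev),
        trueLabels = data@labels,
        cvError = res$error,
        config = config,
        seed = seed,
        sampleIds = data@sampleIds)
}

#' @rdname DoubleCVResult-class
#' @param x a `DoubleCVResult`
#' @export
setMethod("cvError", "DoubleCVResult", function(x) x@cvError)

#' @rdname DoubleCVResult-class
#' @export
setMethod("selectedNcomp", "DoubleCVResult", function(x) x@selectedNcomp)

#' @rdname DoubleCVResult-class
#' @export
setMethod("heldoutPredictions", "DoubleCVResult", function(x) {
    stats::setNames(x@heldoutPredictions, x@sampleIds)
})
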