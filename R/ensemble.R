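# Aggregation of repeated double-CV runs by majority voting.
#
# Every replicate is a complete double cross-validation under its own
# random partition (replicate t runs with seed + t). For the aggregated
# cross-validation error, sample j receives exactly one vote per
# replicate -- from the outer-fold model that held j out -- because any
# other member model saw j during training and its vote would leak.
# Test-set prediction, where no sample was seen by any model, pools all
# R x K member models by default.

#' Majority vote over per-class counts
#'
#' @param counts named nonnegative vote counts, one per class, summing
#'   to at least 1.
#' @return the winning class name; exact ties resolve deterministically
#'   to the first class in the vector's order.
#' @examples
#' majorityVote(c(A = 3, B = 2))  # "A"
#' majorityVote(c(A = 2, B = 2))  # "A" (first on ties)
#' @export
majorityVote <- function(counts) {
    if (!length(counts)) stop("empty vote vector")
    if (any(counts < 0) || sum(counts) < 1)
        stop("vote counts must be nonnegative and sum to at least 1")
    names(counts)[which.max(counts)]
}

#' Aggregate repeated double cross-validation by majority voting
#'
#' Runs [doubleCV()] R times with derived seeds seed+1..seed+R (each
#' replicate reproducible in isolation), tallies each sample's R
#' held-out votes, and forms the aggregated label by majority vote.
#' The per-sample margin is the fraction of correct votes minus the
#' fraction of incorrect votes: 1 means unanimously correct, values
#' near 0 flag samples the classifier is unstable on, and negative
#' values mean the aggregated label is wrong (binary case).
#'
#' @param data a [LabeledMatrix-class].
#' @param config a [RunConfig-class]; `replicates` is R.
#' @return an [EnsembleResult-class].
#' @examples
#' x <- plantedSignalData(15, 30, 5, shift = 3, seed = 3)
#' ens <- aggregatePCDA(x, runConfig(outerFolds = 5, replicates = 5,
#'                                   componentCandidates = 1:3, seed = 3))
#' ens
#' @export
aggregatePCDA <- function(data, config = runConfig()) {
    stopifnot(is(data, "LabeledMatrix"), is(config, "RunConfig"))
    R <- config@replicates
    lev <- levels(data@labels)
    r <- length(lev)
    m <- nSamples(data)
    reps <- vector("list", R)
    votes <- matrix(0L, m, r, dimnames = list(data@sampleIds, lev))
    for (t in seq_len(R)) {
        reps[[t]] <- doubleCV(data, config, seed = config@seed + t)
        p <- as.integer(reps[[t]]@heldoutPredictions)
        votes[cbind(seq_len(m), p)] <- votes[cbind(seq_len(m), p)] + 1L
    }
    .ensemble_from_votes(reps, votes, data, config)
}

.ensemble_from_votes <- function(reps, votes, data, config) {
    lev <- colnames(votes)
    m <- nrow(votes)
    R <- length(reps)
    agg <- max.col(votes, ties.method = "first")
    correct <- votes[cbind(seq_len(m), as.integer(data@labels))]
    new("EnsembleResult",
        replicates = reps,
        voteCounts = votes,
        aggregatedLabels = factor(lev[agg], levels = lev),
        aggregatedCvError = mean(lev[agg] != as.character(data@labels)),
        margins = (2 * correct - R) / R,
        classLabels = lev,
        trueLabels = data@labels,
        sampleIds = data@sampleIds,
        config = config,
        seed = config@seed)
}

#' @rdname EnsembleResult-class
#' @param x an `EnsembleResult`
#' @export
setMethod("cvError", "EnsembleResult", function(x) x@aggregatedCvError)

#' @rdname EnsembleResult-class
#' @export
setMethod("voteCounts", "EnsembleResult", function(x) x@voteCounts)

#' @rdname EnsembleResult-class
#' @export
setMethod("margins", "EnsembleResult", function(x) {
    stats::setNames(x@margins, x@sampleIds)
})

#' @rdname EnsembleResult-class
#' @export
setMethod("aggregatedLabels", "EnsembleResult", function(x) {
    stats::setNames(x@aggregatedLabels, x@sampleIds)
})

#' @rdname EnsembleResult-class
#' @export
setMethod("replicates", "EnsembleResult", function(x) x@replicates)

#' Predict new samples with an aggregated classifier
#'
#' By default every member model (R replicates x K outer-fold models)
#' votes on every test sample; `level = "replicate"` first forms one
#' vote per replicate by intra-replicate majority and then votes over
#' the R replicate verdicts. The test margin of a sample is the vote
#' fraction of the winning class minus the fraction of all other votes.
#'
#' @param object an [EnsembleResult-class].
#' @param newdata a [LabeledMatrix-class] or numeric matrix.
#' @param level `"model"` (default, R x K votes) or `"replicate"` (R votes).
#' @param ... unused.
#' @return list with `labels` (factor) and `margins` (numeric).
#' @export
setMethod("predict", "EnsembleResult", function(object, newdata,
        level = c("model", "replicate"), ...) {
    level <- match.arg(level)
    X <- if (is(newdata, "LabeledMatrix")) newdata@values else as.matrix(newdata)
    lev <- object@classLabels
    r <- length(lev)
    mt <- nrow(X)
    votes <- matrix(0L, mt, r, dimnames = list(NULL, lev))
    for (rep in object@replicates) {
        if (level == "replicate")
            repvotes <- matrix(0L, mt, r)
        for (mod in rep@models) {
            .check_features(mod, X)
            p <- .pcda_predict(.as_fit(mod), X)
            if (level == "replicate")
                repvotes[cbind(seq_len(mt), p)] <- repvotes[cbind(seq_len(mt), p)] + 1L
            else
                votes[cbind(seq_len(mt), p)] <- votes[cbind(seq_len(mt), p)] + 1L
        }
        if (level == "replicate") {
            p <- max.col(repvotes, ties.method = "first")
            votes[cbind(seq_len(mt), p)] <- votes[cbind(seq_len(mt), p)] + 1L
        }
    }
    win <- max.col(votes, ties.method = "first")
    tot <- rowSums(votes)
    wv <- votes[cbind(seq_len(mt), win)]
    list(labels = factor(lev[win], levels = lev),
         margins = (2 * wv - tot) / tot,
         voteCounts = votes)
})

#' @rdname stabilityCurve
#' @export
setMethod("stabilityCurve", "EnsembleResult", function(x, grid, ...) {
    grid <- as.integer(grid)
    R <- length(x@replicates)
    if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
    if (max(grid) > R) stop("grid exceeds the number of replicates (", R, ")")
    lev <- x@classLabels
    r <- length(lev)
    m <- length(x@trueLabels)
    votes <- matrix(0L, m, r)
    err <- numeric(length(grid))
    gi <- 1L
    truth <- as.integer(x@trueLabels)
    for (t in seq_len(max(grid))) {
        p <- as.integer(x@replicates[[t]]@heldoutPredictions)
        votes[cbind(seq_len(m), p)] <- votes[cbind(seq_len(m), p)] + 1L
        if (gi <= length(grid) && t == grid[gi]) {
            err[gi] <- mean(max.col(votes, ties.method = "first") != truth)
            gi <- gi + 1L
        }
    }
    data.frame(nAggregated = grid, cvError = err)
})

#' @rdname stabilityCurve
#' @export
setMethod("stabilityCurve", "LabeledMatrix", function(x, grid,
        config = runConfig(), ...) {
    grid <- as.integer(grid)
    cfg <- runConfig(outerFolds = config@outerFolds,
                     replicates = max(grid),
                     componentCandidates = config@componentCandidates,
                     seed = config@seed, scalingMode = config@scalingMode)
    stabilityCurve(aggregatePCDA(x, cfg), grid)
})
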