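# Training-fitted scaling, spectral median normalization, and the
# Kennard-Stone representative splitter.
#
# All pretreatment statistics are estimated on training rows only and
# then applied, frozen, to test rows: a test column is shifted by the
# TRAINING mean and divided by the TRAINING standard deviation. This is
# what keeps cross-validation honest -- refitting the scaler on data
# that includes the evaluation samples leaks information.

#' Fit a feature scaler on training data
#'
#' `mode = "center"` subtracts the per-feature training mean;
#' `mode = "autoscale"` additionally divides by the per-feature training
#' standard deviation (denominator m - 1). Features with zero training
#' variance carry no discriminant information and cannot be autoscaled;
#' they are dropped with a warning rather than inflated by an epsilon,
#' which would distort the subsequent PCA.
#'
#' @param train a [LabeledMatrix-class] of training samples.
#' @param mode one of "autoscale", "center", "none".
#' @return a [ScalerParams-class].
#' @examples
#' x <- LabeledMatrix(matrix(c(1, 3, 2, 8), 2, 2), labels = c("a", "b"))
#' sp <- fitScaler(x, "autoscale")   # means (2, 5), sds (sqrt(2), sqrt(18))
#' @export
fitScaler <- function(train, mode = c("autoscale", "center", "none")) {
    mode <- match.arg(mode)
    stopifnot(is(train, "LabeledMatrix"))
    if (mode == "autoscale" && nSamples(train) < 2L)
        stop("autoscaling needs at least 2 training samples")
    sc <- .scale_fit(train@values, mode)
    if (!all(sc$keep))
        warning("dropping ", sum(!sc$keep),
                " zero-variance feature(s) under auto-scaling: ",
                paste(utils::head(train@featureNames[!sc$keep], 5L),
                      collapse = ", "))
    new("ScalerParams",
        featureMeans = sc$means[sc$keep],
        featureSds = sc$sds[sc$keep],
        mode = mode,
        featureNames = train@featureNames[sc$keep],
        droppedFeatures = train@featureNames[!sc$keep])
}

#' Apply fitted scaling parameters
#'
#' Transforms each retained feature as (x - mean) / sd using the
#' training-derived parameters; labels and sample ids pass through.
#'
#' @param params a [ScalerParams-class] from [fitScaler()].
#' @param x a [LabeledMatrix-class] with a compatible feature set.
#' @return the transformed [LabeledMatrix-class] (dropped features removed).
#' @export
applyScaler <- function(params, x) {
    stopifnot(is(params, "ScalerParams"), is(x, "LabeledMatrix"))
    pos <- match(params@featureNames, x@featureNames)
    if (anyNA(pos))
        stop("feature mismatch: data lacks ",
             sum(is.na(pos)), " feature(s) the scaler was fitted on")
    v <- x@values[, pos, drop = FALSE]
    if (params@mode != "none") {
        v <- sweep(v, 2L, params@featureMeans, "-")
        if (params@mode == "autoscale")
            v <- sweep(v, 2L, params@featureSds, "/")
    }
    LabeledMatrix(v, labels = x@labels, sampleIds = x@sampleIds,
                  featureNames = params@featureNames)
}

#' Median-normalize spectra
#'
#' Divides each sample's profile elementwise by that profile's median,
#' bringing spectra recorded at different overall intensities onto a
#' comparable scale (each output row has median 1). Applied before any
#' scaling when both are requested.
#'
#' @param x a [LabeledMatrix-class]; every row median must be nonzero.
#' @return the normalized [LabeledMatrix-class].
#' @export
medianNormalize <- function(x) {
    stopifnot(is(x, "LabeledMatrix"))
    med <- apply(x@values, 1L, stats::median)
    if (any(med == 0))
        stop("zero row median for sample(s): ",
             paste(x@sampleIds[med == 0], collapse = ", "))
    LabeledMatrix(x@values / med, labels = x@labels,
                  sampleIds = x@sampleIds, featureNames = x@featureNames)
}

.ks_select <- function(D, n_train) {
    m <- nrow(D)
    # seed pair: the two most distant points, lowest indices on ties
    best <- which(D == max(D), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    sel <- unname(as.integer(best[1L, ]))
    mind <- unname(pmin(D[, sel[1L]], D[, sel[2L]]))
    mind[sel] <- -Inf
    while (length(sel) < n_train) {
        nxt <- which.max(mind)   # ties -> lowest index
        sel <- c(sel, nxt)
        mind <- pmin(mind, D[, nxt])
        mind[nxt] <- -Inf
    }
    sel
}

#' Kennard-Stone representative train/test split
#'
#' Classic deterministic max-min selection on Euclidean distances: the
#' two most distant samples seed the training set, and each subsequent
#' pick maximizes its minimum distance to the already-selected samples,
#' yielding a training set uniformly scattered over the sampled space.
#' Ties (duplicate rows) resolve to the lowest sample index.
#'
#' With `stratify = TRUE` the selection runs per class with quotas
#' proportional to class sizes (largest-remainder rounding), so the
#' train/test class ratio mirrors the full data -- plain Kennard-Stone
#' ignores labels.
#'
#' @param x a [LabeledMatrix-class].
#' @param nTrain number of training samples, 2 <= nTrain < m.
#' @param stratify split within classes with proportional quotas.
#' @return list with integer index vectors `train` (in selection order,
#'   for the plain variant) and `test`; together a partition of 1..m.
#' @export
kennardStone <- function(x, nTrain, stratify = FALSE) {
    stopifnot(is(x, "LabeledMatrix"))
    m <- nSamples(x)
    nTrain <- as.integer(nTrain)
    if (nTrain < 2L || nTrain >= m)
        stop("nTrain must satisfy 2 <= nTrain < ", m)
    if (!stratify) {
        D <- as.matrix(stats::dist(x@values))
        sel <- .ks_select(D, nTrain)
        return(list(train = sel, test = setdiff(seq_len(m), sel)))
    }
    y <- x@labels
    counts <- table(y)
    quota <- .largest_remainder(as.numeric(counts) * nTrain / m, nTrain)
    if (any(quota < 2L) || any(quota >= as.numeric(counts)))
        stop("stratified quota infeasible: per-class quotas ",
             paste(quota, collapse = "/"), " for class sizes ",
             paste(as.numeric(counts), collapse = "/"))
    sel <- integer(0)
    for (k in seq_along(counts)) {
        idx <- which(y == names(counts)[k])
        D <- as.matrix(stats::dist(x@values[idx, , drop = FALSE]))
        sel <- c(sel, idx[.ks_select(D, quota[k])])
    }
    list(train = sort(sel), test = setdiff(seq_len(m), sel))
}

# Integer apportionment: round to nearest, then repair the total on the
# entries whose fractional parts argue least against the change.
.largest_remainder <- function(target, total) {
    q <- as.integer(round(target))
    while (sum(q) != total) {
        if (sum(q) < total) {
            i <- which.max(target - q)
            q[i] <- q[i] + 1L
        } else {
            i <- which.min(target - q)
            q[i] <- q[i] - 1L
        }
    }
    q
}
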