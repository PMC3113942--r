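# Rank-products feature importance over pooled discriminant vectors.
#
# Within each discriminant vector the features are ranked by absolute
# coefficient (rank 1 = largest magnitude -- the sign of a discriminant
# vector is arbitrary, so magnitude is the discriminative weight). A
# feature that ranks high in many vectors has a small product of ranks;
# the product is computed as the mean of log ranks, which orders
# features identically but cannot overflow even at thousands of
# features times thousands of vectors.

#' Rank products of a set of discriminant vectors
#'
#' @param vectors a list of V numeric vectors of equal length n, or an
#'   n x V matrix with one vector per column.
#' @param featureNames the n feature names (defaults to names/rownames
#'   or V1..Vn).
#' @return a [RankProductTable-class]; `ordering` sorts features by
#'   ascending mean log rank (most discriminative first), ties broken
#'   by feature index.
#' @examples
#' tab <- computeRankProducts(c(0.9, -0.1, 0.5), c("f1", "f2", "f3"))
#' tab@featureNames[tab@ordering]   # f1, f3, f2
#' @export
computeRankProducts <- function(vectors, featureNames = NULL) {
    if (is.list(vectors)) {
        if (!length(vectors)) stop("at least one discriminant vector required")
        n <- length(vectors[[1L]])
        if (any(lengths(vectors) != n))
            stop("all discriminant vectors must have equal length")
        M <- matrix(unlist(vectors, use.names = FALSE), nrow = n)
    } else {
        M <- as.matrix(vectors)
        n <- nrow(M)
    }
    if (ncol(M) < 1L) stop("at least one discriminant vector required")
    if (is.null(featureNames))
        featureNames <- if (!is.null(rownames(M))) rownames(M)
                        else sprintf("V%d", seq_len(n))
    if (length(featureNames) != n)
        stop("featureNames length must match vector length")
    logsum <- numeric(n)
    for (j in seq_len(ncol(M))) {
        rk <- rank(-abs(M[, j]), ties.method = "first")
        logsum <- logsum + log(rk)
    }
    lrp <- logsum / ncol(M)
    new("RankProductTable",
        featureNames = as.character(featureNames),
        logRankProduct = lrp,
        ordering = order(lrp, seq_len(n)),
        nVectors = ncol(M))
}

#' @rdname rankProducts
#' @export
setMethod("rankProducts", "EnsembleResult", function(x, column = 1L) {
    vecs <- list()
    fn <- NULL
    for (rep in x@replicates) {
        for (mod in rep@models) {
            D <- discriminantDirections(mod, "feature")
            if (column > ncol(D))
                stop("model has only ", ncol(D), " discriminant column(s)")
            keyfn <- rownames(D)
            if (is.null(fn)) fn <- keyfn
            else if (!identical(fn, keyfn))
                stop("member models disagree on the feature set")
            vecs[[length(vecs) + 1L]] <- D[, column]
        }
    }
    computeRankProducts(vecs, fn)
})

#' Turn a rank-product table into a data.frame
#'
#' @param x a [RankProductTable-class].
#' @param row.names,optional,... passed through / ignored.
#' @return data.frame ordered most-discriminative-first with columns
#'   `rank`, `feature`, `meanLogRank`, `geomMeanRank`.
#' @export
as.data.frame.RankProductTable <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
    o <- x@ordering
    data.frame(rank = seq_along(o),
               feature = x@featureNames[o],
               meanLogRank = x@logRankProduct[o],
               geomMeanRank = exp(x@logRankProduct[o]),
               stringsAsFactors = FALSE)
}
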