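# Accessors, display, subsetting, and delimited-file input/output.

#' @rdname LabeledMatrix-class
#' @export
setMethod("values", "LabeledMatrix", function(x, ...) {
    v <- x@values
    dimnames(v) <- list(x@sampleIds, x@featureNames)
    v
})

#' @rdname LabeledMatrix-class
#' @export
setMethod("sampleIds", "LabeledMatrix", function(x) x@sampleIds)

#' @rdname LabeledMatrix-class
#' @export
setMethod("featureNames", "LabeledMatrix", function(x) x@featureNames)

#' @rdname LabeledMatrix-class
#' @export
setMethod("classLabels", "LabeledMatrix", function(x) x@labels)

#' @rdname LabeledMatrix-class
#' @export
setMethod("nSamples", "LabeledMatrix", function(x) nrow(x@values))

#' @rdname LabeledMatrix-class
#' @export
setMethod("nFeatures", "LabeledMatrix", function(x) ncol(x@values))

#' @rdname LabeledMatrix-class
#' @export
setMethod("classLevels", "LabeledMatrix", function(x) levels(x@labels))

#' @rdname LabeledMatrix-class
#' @export
setMethod("dim", "LabeledMatrix", function(x) dim(x@values))

#' @rdname LabeledMatrix-class
#' @param i,j row (sample) and column (feature) indices
#' @param drop ignored; subsetting always returns a \code{LabeledMatrix}
#' @param ... unused
#' @export
setMethod("[", "LabeledMatrix", function(x, i, j, ..., drop = FALSE) {
    if (missing(i)) i <- seq_len(nrow(x@values))
    if (missing(j)) j <- seq_len(ncol(x@values))
    LabeledMatrix(x@values[i, j, drop = FALSE],
                  labels = droplevels(x@labels[i]),
                  sampleIds = x@sampleIds[i],
                  featureNames = x@featureNames[j])
})

setMethod("show", "LabeledMatrix", function(object) {
    tab <- table(object@labels)
    cat("LabeledMatrix: ", nrow(object@values), " samples x ",
        ncol(object@values), " features\n", sep = "")
    cat("classes: ",
        paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n",
        sep = "")
})

setMethod("show", "RunConfig", function(object) {
    cands <- if (length(object@componentCandidates))
        paste(range(object@componentCandidates), collapse = "..")
    else "auto (1..min(20, inner train - r))"
    cat("RunConfig: K =", object@outerFolds,
        "(inner", object@outerFolds - 1L, "), R =", object@replicates,
        ", scaling =", object@scalingMode,
        ", seed =", object@seed, "\n  component candidates:", cands, "\n")
})

setMethod("show", "PCDAModel", function(object) {
    cat("PCDAModel:", length(object@featureNames), "features ->",
        object@nComponents, "PCs ->", ncol(object@directions),
        "discriminant direction(s);", length(object@classLabels),
        "classes:", paste(object@classLabels, collapse = ", "), "\n")
})

setMethod("show", "DoubleCVResult", function(object) {
    cat("DoubleCVResult: K =", max(object@foldOfSample),
        "outer folds, cv error =", format(object@cvError, digits = 4),
        "\n  selected components per fold:",
        paste(object@selectedNcomp, collapse = " "), "\n")
})

setMethod("show", "EnsembleResult", function(object) {
    cat("EnsembleResult:", length(object@replicates),
        "aggregated double-CV replicates\n  aggregated cv error =",
        format(object@aggregatedCvError, digits = 4),
        "; margin range = [",
        format(min(object@margins), digits = 3), ",",
        format(max(object@margins), digits = 3), "]\n")
})

setMethod("show", "RankProductTable", function(object) {
    cat("RankProductTable over", object@nVectors, "discriminant vectors,",
        length(object@featureNames), "features\n  top features:",
        paste(utils::head(object@featureNames[object@ordering], 5L),
              collapse = ", "), "\n")
})

setMethod("show", "SimulationParams", function(object) {
    cat("SimulationParams:", length(object@mean1), "features, covariance rank",
        ncol(object@factorMatrix), "; classes",
        paste(object@classLabels, collapse = " vs "), "\n")
})

.detect_sep <- function(path) {
    line <- readLines(path, n = 1L)
    if (lengths(regmatches(line, gregexpr("\t", line))) >=
        lengths(regmatches(line, gregexpr(",", line)))) "\t" else ","
}

#' Read a labeled sample-by-feature matrix from delimited text
#'
#' Expects one header row of feature names and one sample per row. The
#' field separator (tab or comma) is auto-detected. Class labels are
#' taken from `labelColumn` inside the file, or from a separate
#' two-column (sample id, label) file via `labelFile`. A column named
#' `sample_id` (written by [writeLabeledMatrix()]) supplies sample
#' identifiers when present. Feature-major files (features as rows) are
#' handled with `transpose = TRUE`, in which case the first column holds
#' feature names, the header holds sample ids, and labels must come from
#' `labelFile`.
#'
#' Missing values and non-numeric feature cells are rejected: the method
#' has no imputation step, so gaps must be resolved upstream.
#'
#' @param path file to read.
#' @param labelColumn name of the label column (default "class").
#' @param labelFile optional separate label file.
#' @param sep field separator; NULL (default) auto-detects tab vs comma.
#' @param transpose set TRUE for feature-major files.
#' @return a [LabeledMatrix-class].
#' @export
readLabeledMatrix <- function(path, labelColumn = "class", labelFile = NULL,
                              sep = NULL, transpose = FALSE) {
    if (!file.exists(path)) stop("file not found: ", path)
    if (is.null(sep)) sep <- .detect_sep(path)
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", comment.char = "")
    if (transpose) {
        fn <- df[[1L]]
        ids <- colnames(df)[-1L]
        vals <- t(as.matrix(df[, -1L, drop = FALSE]))
        colnames(vals) <- fn; rownames(vals) <- ids
        df <- data.frame(sample_id = ids, vals, check.names = FALSE,
                         stringsAsFactors = FALSE)
    }
    ids <- if ("sample_id" %in% colnames(df)) {
        v <- df[["sample_id"]]; df[["sample_id"]] <- NULL; v
    } else sprintf("S%d", seq_len(nrow(df)))
    if (anyDuplicated(ids)) stop("duplicate sample id in ", path)

    labels <- NULL
    if (!is.null(labelFile)) {
        lsep <- .detect_sep(labelFile)
        ldf <- utils::read.table(labelFile, header = TRUE, sep = lsep,
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
        if (ncol(ldf) < 2L) stop("label file must have two columns (id, label)")
        pos <- match(ids, ldf[[1L]])
        if (anyNA(pos)) stop("label file is missing labels for some samples")
        labels <- ldf[[2L]][pos]
    } else {
        if (!labelColumn %in% colnames(df))
            stop("missing label column '", labelColumn, "' in ", path)
        labels <- df[[labelColumn]]
        df[[labelColumn]] <- NULL
    }
    if (anyNA(labels) || any(!nzchar(labels)))
        stop("missing value in label column")
    featNames <- colnames(df)
    vals <- suppressWarnings(
        matrix(as.numeric(as.matrix(df)), nrow = nrow(df),
               dimnames = list(NULL, featNames)))
    raw <- as.matrix(df)
    if (anyNA(vals)) {
        bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
        cell <- raw[bad[1L], bad[2L]]
        if (is.na(cell) || !nzchar(trimws(cell)))
            stop("missing value at sample ", ids[bad[1L]], ", feature '",
                 featNames[bad[2L]], "'")
        stop("non-numeric value '", cell, "' at sample ", ids[bad[1L]],
             ", feature '", featNames[bad[2L]], "'")
    }
    if (length(unique(labels)) < 2L)
        stop("fewer than 2 classes in ", path)
    LabeledMatrix(vals, labels = labels, sampleIds = ids,
                  featureNames = featNames)
}

#' Write a LabeledMatrix to delimited text
#'
#' Writes a `sample_id` column, a `class` label column, and one column
#' per feature. Values are printed with 17 significant digits so that a
#' write/read round trip reproduces every double bit-for-bit.
#'
#' @param x a [LabeledMatrix-class].
#' @param path output path.
#' @param sep field separator (default tab).
#' @return invisibly, `path`.
#' @export
writeLabeledMatrix <- function(x, path, sep = "\t") {
    stopifnot(is(x, "LabeledMatrix"))
    vals <- x@values
    chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
    body <- cbind(x@sampleIds, as.character(x@labels), chr)
    header <- c("sample_id", "class", x@featureNames)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(header, collapse = sep), con)
    writeLines(apply(body, 1L, paste, collapse = sep), con)
    invisible(path)
}
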