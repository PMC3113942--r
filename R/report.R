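# Plain-text result reports: a key=value header followed by TSV body.
# Reports never embed wall-clock time, so identical seed + config give
# byte-identical files.

.report_header <- function(config, seed, extra = character()) {
    cands <- if (length(config@componentCandidates))
        paste(config@componentCandidates, collapse = ",") else "auto"
    c(sprintf("# pcdagg_version=%s", as.character(utils::packageVersion("pcdagg"))),
      sprintf("# seed=%d", seed),
      sprintf("# outer_folds=%d", config@outerFolds),
      sprintf("# inner_folds=%d", config@outerFolds - 1L),
      sprintf("# replicates=%d", config@replicates),
      sprintf("# scaling_mode=%s", config@scalingMode),
      sprintf("# component_candidates=%s", cands),
      sprintf("# vote_tie_rule=%s", config@voteTieRule),
      extra)
}

.write_tsv_block <- function(con, df) {
    writeLines(paste(colnames(df), collapse = "\t"), con)
    cols <- lapply(df, function(x) trimws(as.character(x)))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
    invisible(NULL)
}

#' @rdname writeReport
#' @export
setMethod("writeReport", signature("DoubleCVResult", "character"),
    function(result, path) {
        con <- file(path, "w")
        on.exit(close(con))
        conf <- table(truth = result@trueLabels,
                      predicted = result@heldoutPredictions)
        writeLines(.report_header(result@config, result@seed,
            sprintf("# cv_error=%.17g", result@cvError)), con)
        writeLines("[selected_components]", con)
        .write_tsv_block(con, data.frame(fold = seq_along(result@selectedNcomp),
                                         n_components = result@selectedNcomp))
        writeLines("[heldout_predictions]", con)
        .write_tsv_block(con, data.frame(
            sample_id = result@sampleIds,
            fold = result@foldOfSample,
            true_label = as.character(result@trueLabels),
            predicted = as.character(result@heldoutPredictions)))
        writeLines("[confusion]", con)
        .write_tsv_block(con, as.data.frame(conf, stringsAsFactors = FALSE))
        invisible(path)
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", signature("EnsembleResult", "character"),
    function(result, path) {
        con <- file(path, "w")
        on.exit(close(con))
        R <- length(result@replicates)
        truth <- as.integer(result@trueLabels)
        correct <- result@voteCounts[cbind(seq_len(nrow(result@voteCounts)), truth)]
        writeLines(.report_header(result@config, result@seed, c(
            sprintf("# aggregated_cv_error=%.17g", result@aggregatedCvError),
            sprintf("# replicate_seeds=%d..%d", result@seed + 1L,
                    result@seed + R))), con)
        writeLines("[margins]", con)
        .write_tsv_block(con, data.frame(
            sample_id = result@sampleIds,
            true_label = as.character(result@trueLabels),
            aggregated_label = as.character(result@aggregatedLabels),
            votes_correct = correct,
            votes_incorrect = R - correct,
            margin = sprintf("%.17g", result@margins)))
        writeLines("[replicate_cv_errors]", con)
        .write_tsv_block(con, data.frame(
            replicate = seq_len(R),
            seed = result@seed + seq_len(R),
            cv_error = sprintf("%.17g",
                vapply(result@replicates, function(r) r@cvError, numeric(1)))))
        invisible(path)
    })

#' @rdname writeReport
#' @export
setMethod("writeReport", signature("RankProductTable", "character"),
    function(result, path) {
        con <- file(path, "w")
        on.exit(close(con))
        writeLines(c(
            sprintf("# pcdagg_version=%s",
                    as.character(utils::packageVersion("pcdagg"))),
            sprintf("# n_vectors=%d", result@nVectors)), con)
        df <- as.data.frame(result)
        df$meanLogRank <- sprintf("%.17g", df$meanLogRank)
        df$geomMeanRank <- sprintf("%.17g", df$geomMeanRank)
        colnames(df) <- c("rank", "feature", "mean_log_rank", "geom_mean_rank")
        .write_tsv_block(con, df)
        invisible(path)
    })
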