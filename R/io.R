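# Plain-text serialization of the pipeline's objects. Floats are written
# with 17 significant digits so a write/read round trip is lossless for
# doubles.

.fmt <- function(x) {
    if (is.double(x)) vapply(x, function(v) sprintf("%.17g", v), character(1))
    else as.character(x)
}

.write_delim <- function(df, file, sep) {
    out <- df
    for (j in seq_along(out)) out[[j]] <- .fmt(out[[j]])
    utils::write.table(out, file, sep = sep, quote = FALSE,
        row.names = FALSE, col.names = TRUE)
}

#' Write / read a FeatureTable as TSV
#'
#' Dialect: tab-separated, header row of feature ids, first column
#' \code{sample_id}; floats at 17 significant digits.
#'
#' @param table a \code{\link{FeatureTable}}; @param file path.
#' @return \code{readFeatureTable} returns a \code{FeatureTable} at the
#'   given stage.
#' @export
writeFeatureTable <- function(table, file) {
    x <- intensities(table)
    df <- data.frame(sample_id = rownames(x), x, check.names = FALSE,
        stringsAsFactors = FALSE)
    .write_delim(df, file, "\t")
    invisible(file)
}

#' @rdname writeFeatureTable
#' @param stage stage tag to assign to the read table (the TSV carries data
#'   only).
#' @export
readFeatureTable <- function(file, stage = "raw") {
    df <- utils::read.delim(file, check.names = FALSE,
        stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$sample_id
    FeatureTable(m, stage = stage)
}

#' Write / read a cohort as CSV (sample_id,group,urine_creatinine)
#' @param cohort cohort data.frame; @param file path.
#' @export
writeCohort <- function(cohort, file) {
    .write_delim(cohort, file, ",")
    invisible(file)
}

#' @rdname writeCohort
#' @export
readCohort <- function(file) {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
    df$group <- as.integer(df$group)
    df
}

#' Write ground truth as JSON (17 significant digits)
#' @param truth a \code{"SyntheticTruth"} list; @param file path.
#' @export
writeTruth <- function(truth, file) {
    jsonlite::write_json(unclass(truth), file, digits = NA, auto_unbox = TRUE,
        matrix = "rowmajor")
    invisible(file)
}

#' Write a generic result data.frame as CSV with full float precision
#' @param df data.frame; @param file path.
#' @export
writeResultCSV <- function(df, file) {
    .write_delim(df, file, ",")
    invisible(file)
}

#' Write a symmetric matrix (adjacency, TOM, dissimilarity) as TSV
#' @param m matrix; @param file path.
#' @export
writeMatrixTSV <- function(m, file) {
    df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    .write_delim(df, file, "\t")
    invisible(file)
}
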