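#' Instrument-blank ratio filter
#'
#' Removes feature j unless \code{max_i(x_ij) / blank_j >= threshold}; the
#' rule removes strictly-less-than, so a ratio exactly at the threshold is
#' kept. A blank average of zero means the feature is absent from the blank;
#' its ratio is treated as infinite and the feature is kept.
#'
#' @param table raw-stage \code{\link{FeatureTable}}.
#' @param blank_means named per-feature blank-average intensities covering
#'   every feature of \code{table}.
#' @param threshold minimum sample-max / blank-average ratio (default 10).
#' @return list with \code{table} (stage \code{"blank_filtered"}, surviving
#'   columns in original order) and \code{report} (data.frame: feature_id,
#'   ratio, kept).
#' @examples
#' m <- matrix(c(900, 800, 1000, 950), 2,
#'     dimnames = list(c("a", "b"), c("F1", "F2")))
#' bf <- blankFilter(FeatureTable(m), c(F1 = 100, F2 = 100))
#' bf$report
#' @export
blankFilter <- function(table, blank_means, threshold = 10) {
    # accepting blank_filtered keeps the filter idempotent: re-filtering with
    # the same blanks removes nothing
    .check_stage(table, c("raw", "blank_filtered"), "blankFilter")
    ids <- featureIds(table)
    if (!all(ids %in% names(blank_means)))
        stop("missing blank value for feature(s): ",
            paste(utils::head(setdiff(ids, names(blank_means)), 5), collapse = ", "),
            call. = FALSE)
    b <- blank_means[ids]
    if (any(b < 0)) stop("blank averages must be >= 0", call. = FALSE)
    smax <- apply(intensities(table), 2, max)
    ratio <- ifelse(b == 0, Inf, smax / b)
    keep <- ratio >= threshold
    report <- data.frame(feature_id = ids, ratio = ratio, kept = keep,
        row.names = NULL, stringsAsFactors = FALSE)
    out <- FeatureTable(intensities(table)[, keep, drop = FALSE],
        stage = "blank_filtered")
    list(table = out, report = report)
}

#' mTIC normalization
#'
#' Divides every intensity by its sample's total over the annotated
#' ("known") features — the metabolite total ion chromatogram — so each
#' sample's annotated features afterwards sum to exactly 1. Unannotated
#' features are divided by the same per-sample constant. Use
#' \code{annotated_ids = featureIds(table)} for an all-feature TIC.
#'
#' @param table \code{\link{FeatureTable}} at stage raw or blank_filtered.
#' @param annotated_ids non-empty subset of the table's feature ids forming
#'   the mTIC divisor; defaults to all features.
#' @return \code{FeatureTable} at stage \code{"mtic"}.
#' @export
mticNormalize <- function(table, annotated_ids = featureIds(table)) {
    .check_stage(table, c("raw", "blank_filtered"), "mticNormalize")
    ids <- featureIds(table)
    if (length(annotated_ids) == 0)
        stop("'annotated_ids' must be non-empty", call. = FALSE)
    if (!all(annotated_ids %in% ids))
        stop("annotated ids absent from table: ",
            paste(utils::head(setdiff(annotated_ids, ids), 5), collapse = ", "),
            call. = FALSE)
    x <- intensities(table)
    tot <- rowSums(x[, annotated_ids, drop = FALSE])
    if (any(tot <= 0))
        stop("sample(s) with zero annotated-feature total: ",
            paste(rownames(x)[tot <= 0], collapse = ", "), call. = FALSE)
    FeatureTable(x / tot, stage = "mtic")
}

#' log(value + 1) transform
#'
#' Natural-log transform \code{y = ln(x + 1)}. The natural base is what makes
#' the downstream fold-change convention work: a log-mean difference divided
#' by ln(2) is then a base-2 exponent, so a log2 fold change of 1 is a
#' doubling.
#'
#' @param table \code{\link{FeatureTable}} at any stage before \code{"log"}.
#' @return \code{FeatureTable} at stage \code{"log"}.
#' @export
logTransform <- function(table) {
    .check_stage(table, c("raw", "blank_filtered", "mtic"), "logTransform")
    x <- intensities(table)
    if (any(x <= -1))
        stop("log(value + 1) undefined for values <= -1", call. = FALSE)
    FeatureTable(log1p(x), stage = "log")
}

#' Pareto scaling
#'
#' Per feature: mean-center and divide by the square root of the sample
#' standard deviation (n - 1 denominator), an intermediate between plain
#' centering and unit-variance scaling that tempers the dominance of
#' high-intensity features without amplifying noise as much as
#' autoscaling. Zero-variance features are set to all-zero and reported via a
#' warning. The per-feature center and divisor are stored on the result so
#' the affine map can be inverted when log-scale group means are needed.
#'
#' @param table \code{\link{FeatureTable}} at stage \code{"log"}, >= 2 samples.
#' @return \code{FeatureTable} at stage \code{"pareto"}.
#' @export
paretoScale <- function(table) {
    .check_stage(table, "log", "paretoScale")
    y <- intensities(table)
    if (nrow(y) < 2)
        stop("Pareto scaling needs at least 2 samples", call. = FALSE)
    ctr <- colMeans(y)
    sdv <- apply(y, 2, stats::sd)
    zero <- sdv == 0
    scl <- sqrt(sdv)
    scl[zero] <- 1                      # placeholder; columns forced to zero
    s <- sweep(sweep(y, 2, ctr), 2, scl, "/")
    if (any(zero)) {
        s[, zero] <- 0
        warning("zero-variance feature(s) set to all-zero: ",
            paste(colnames(y)[zero], collapse = ", "), call. = FALSE)
    }
    FeatureTable(s, stage = "pareto", paretoCenter = ctr, paretoScale = scl)
}

#' Run the full preprocessing chain
#'
#' Convenience wrapper applying, in order: blank-ratio filter (if blanks are
#' given), mTIC normalization, log(value + 1), Pareto scaling.
#'
#' @param table raw-stage \code{\link{FeatureTable}}.
#' @param blank_means optional named per-feature blank averages.
#' @param annotated_ids mTIC divisor features (default all).
#' @param threshold blank-ratio threshold (default 10).
#' @return list with \code{table} (pareto stage), \code{log_table} (log
#'   stage, used for reporting log-scale means) and \code{filter_report}
#'   (NULL when no blanks given).
#' @export
preprocessPipeline <- function(table, blank_means = NULL,
                               annotated_ids = NULL, threshold = 10) {
    report <- NULL
    if (!is.null(blank_means)) {
        bf <- blankFilter(table, blank_means, threshold)
        table <- bf$table
        report <- bf$report
    }
    if (is.null(annotated_ids)) annotated_ids <- featureIds(table)
    annotated_ids <- intersect(annotated_ids, featureIds(table))
    mt <- mticNormalize(table, annotated_ids)
    lg <- logTransform(mt)
    list(table = paretoScale(lg), log_table = lg, filter_report = report)
}
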