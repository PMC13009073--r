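#' Per-feature one-way ANOVA between outcome groups
#'
#' Classical (equal-variance) one-way ANOVA per feature, vectorized over the
#' whole table: F = (SSB / (g - 1)) / (SSW / (n - g)); with two groups F
#' equals the square of the pooled-variance t statistic. Group means are
#' always reported on the log(value + 1) scale: when the input is at the
#' pareto stage, the stored per-feature center/divisor invert the affine
#' scaling first (which leaves F unchanged, since F is invariant to
#' per-feature affine maps).
#'
#' Features with zero within-group variance get, by convention, p = 0 when
#' the group means differ and p = 1 otherwise, with a warning.
#'
#' @param table \code{\link{FeatureTable}} at stage log or pareto.
#' @param cohort data.frame with sample_id and group (0/1), both groups with
#'   >= 2 samples.
#' @return data.frame: feature_id, mean_log_control, mean_log_case, diff
#'   (case - control), fc, l2fc, f_stat, p_raw.
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
#'     dimnames = list(paste0("S", 1:6), "M1"))
#' ft <- FeatureTable(m, stage = "log")
#' coh <- data.frame(sample_id = paste0("S", 1:6), group = rep(0:1, each = 3))
#' onewayAnovaPerFeature(ft, coh)   # F = 13.5
#' @export
onewayAnovaPerFeature <- function(table, cohort) {
    .check_stage(table, c("log", "pareto"), "onewayAnovaPerFeature")
    .check_cohort(cohort)
    y <- intensities(table)
    idx <- match(rownames(y), cohort$sample_id)
    if (anyNA(idx))
        stop("cohort is missing sample(s): ",
            paste(rownames(y)[is.na(idx)], collapse = ", "), call. = FALSE)
    g <- cohort$group[idx]
    n0 <- sum(g == 0); n1 <- sum(g == 1)
    if (n0 < 2 || n1 < 2)
        stop("each group needs at least 2 samples", call. = FALSE)
    n <- n0 + n1

    # invert Pareto's per-feature affine map to report log-scale means
    ylog <- y
    if (stage(table) == "pareto")
        ylog <- sweep(sweep(y, 2, table@paretoScale, "*"), 2,
            table@paretoCenter, "+")

    m0 <- colMeans(ylog[g == 0, , drop = FALSE])
    m1 <- colMeans(ylog[g == 1, , drop = FALSE])
    mall <- colMeans(ylog)
    ssb <- n0 * (m0 - mall)^2 + n1 * (m1 - mall)^2
    ssw <- colSums(sweep(ylog[g == 0, , drop = FALSE], 2, m0)^2) +
        colSums(sweep(ylog[g == 1, , drop = FALSE], 2, m1)^2)
    df1 <- 1L
    df2 <- n - 2L
    fstat <- (ssb / df1) / (ssw / df2)
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)

    tol <- 1e-12 * pmax(ssb, 1)
    degenerate <- ssw <= tol
    if (any(degenerate)) {
        sep <- ssb[degenerate] > tol[degenerate]
        fstat[degenerate] <- ifelse(sep, Inf, 0)
        p[degenerate] <- ifelse(sep, 0, 1)
        warning("zero within-group variance for feature(s): ",
            paste(colnames(y)[degenerate], collapse = ", "),
            "; p set by convention", call. = FALSE)
    }

    fcv <- foldChange(m1, m0)
    data.frame(feature_id = colnames(y),
        mean_log_control = m0, mean_log_case = m1,
        diff = m1 - m0, fc = fcv$fc, l2fc = fcv$l2fc,
        f_stat = fstat, p_raw = p,
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Fold change from log-scale group means
#'
#' The group difference is taken on the log(value + 1) scale as
#' \code{d = case - control}; the fold change is \code{exp(d)} (a ratio of
#' shifted geometric means) and the log2 fold change is \code{d / ln(2)}, so
#' an l2fc of 1 corresponds to a doubling. The case-minus-control direction
#' makes analytes elevated in the hyperthyroid group come out with FC > 1.
#'
#' @param mean_log_case,mean_log_control numeric vectors of log-scale means.
#' @return list with \code{fc} and \code{l2fc}; \code{fc == 2^l2fc}
#'   identically.
#' @examples
#' foldChange(log(2), 0)   # fc = 2, l2fc = 1
#' @export
foldChange <- function(mean_log_case, mean_log_control) {
    d <- mean_log_case - mean_log_control
    list(fc = exp(d), l2fc = d / log(2))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' \code{monotone = TRUE} (default) gives the standard step-up adjustment
#' \code{q_(i) = min_(j >= i) p_(j) * m / j}, capped at 1. The non-monotone
#' variant returns the plain \code{p * m / rank} (capped at 1) without the
#' step-up minimum, with tied p-values ranked in order of appearance; some
#' published enrichment tables report this variant, so it is provided for
#' exact comparison against such tables.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @param monotone use the standard step-up rule (default TRUE).
#' @return adjusted values in the original order.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03))         # all 0.03
#' bhAdjust(c(0.01, 0.02, 0.03), FALSE)  # 0.03 0.03 0.03 here too
#' @export
bhAdjust <- function(p, monotone = TRUE) {
    if (any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    if (monotone) return(stats::p.adjust(p, method = "BH"))
    r <- rank(p, ties.method = "first")
    pmin(p * length(p) / r, 1)
}

#' Two-group differential abundance with BH FDR
#'
#' Wrapper chaining \code{\link{onewayAnovaPerFeature}} and
#' \code{\link{bhAdjust}}, flagging features with adjusted p below
#' \code{alpha}.
#'
#' @inheritParams onewayAnovaPerFeature
#' @param alpha adjusted-p significance threshold (default 0.05).
#' @param monotone BH convention, see \code{\link{bhAdjust}}.
#' @return the ANOVA result data.frame with added \code{q_bh} and
#'   \code{significant} columns.
#' @export
differentialAbundance <- function(table, cohort, alpha = 0.05, monotone = TRUE) {
    res <- onewayAnovaPerFeature(table, cohort)
    res$q_bh <- bhAdjust(res$p_raw, monotone = monotone)
    res$significant <- res$q_bh < alpha
    res
}
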