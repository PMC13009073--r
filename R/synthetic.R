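#' Generate a two-group cohort with urine creatinine
#'
#' Samples a case-control cohort of the kind used in feline-hyperthyroidism
#' metabolome studies: \code{n_control} euthyroid controls (group 0) and
#' \code{n_case} untreated hyperthyroid cases (group 1), each with a urine
#' creatinine concentration drawn log-normally (creatinine varies with urine
#' dilution and is used downstream to adjust urinary analyte levels).
#'
#' @param n_control,n_case group sizes (each >= 2); defaults mirror a typical
#'   19-control / 16-case design.
#' @param creat_log_mean,creat_log_sd mean and sd of log creatinine (mg/dL);
#'   defaults give a geometric mean of 150 mg/dL with moderate spread,
#'   a realistic range for feline urine.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return data.frame with columns \code{sample_id}, \code{group} (0/1),
#'   \code{urine_creatinine} (mg/dL).
#' @examples
#' cohort <- generateCohort(19, 16, seed = 1)
#' table(cohort$group)
#' @export
generateCohort <- function(n_control = 19, n_case = 16,
                           creat_log_mean = log(150), creat_log_sd = 0.5,
                           seed = 1) {
    if (n_control < 2 || n_case < 2)
        stop("both groups need at least 2 samples", call. = FALSE)
    if (creat_log_sd < 0)
        stop("'creat_log_sd' must be >= 0", call. = FALSE)
    set.seed(as.integer(seed))
    n <- n_control + n_case
    data.frame(
        sample_id = sprintf("S%03d", seq_len(n)),
        group = rep(c(0L, 1L), c(n_control, n_case)),
        urine_creatinine = exp(stats::rnorm(n, creat_log_mean, creat_log_sd)),
        stringsAsFactors = FALSE
    )
}

.check_cohort <- function(cohort) {
    stopifnot(is.data.frame(cohort),
        all(c("sample_id", "group") %in% names(cohort)))
    if (anyDuplicated(cohort$sample_id))
        stop("cohort sample ids must be unique", call. = FALSE)
    if (!all(cohort$group %in% c(0L, 1L)))
        stop("group codes must be 0 (control) or 1 (case)", call. = FALSE)
    invisible(cohort)
}

#' Generate a synthetic metabolome feature table with known ground truth
#'
#' Draws latent per-sample, per-feature values
#' \code{z_ij ~ N(base_log_mean + d_j * group_i, Sigma)} and reports observed
#' intensities \code{x_ij = exp(z_ij)} (stage \code{"raw"}). \code{Sigma} is
#' block-exchangeable: features inside a module share a constant pairwise
#' correlation \code{within_corr} (implemented as a shared latent factor),
#' features in different modules (or outside all modules) are independent;
#' all marginal latent sds equal \code{noise_sd}. Pathway labels over nine
#' groups are assigned with the given sizes, either as contiguous blocks in
#' feature order (\code{pathway_shuffle = FALSE}) or randomly permuted
#' (default), which keeps pathway membership independent of module
#' membership.
#'
#' The returned truth object records the planted effect \code{d_j} per
#' feature, module labels (0 = background), pathway labels, and the index of
#' the nominally enriched pathway, so that differential, enrichment and
#' network stages can be scored against ground truth.
#'
#' @param cohort data.frame from \code{\link{generateCohort}}.
#' @param n_features number of features; the default 389 matches the size of
#'   a combined serum-metabolite + urinary-EDC dataset.
#' @param modules data.frame with columns \code{size} and \code{within_corr}
#'   (each in [0, 1)); module features occupy the first \code{sum(size)}
#'   feature positions, in order. \code{NULL} for no modules.
#' @param effects data.frame with columns \code{feature} (index) and \code{d}
#'   (log-scale group shift for cases); \code{NULL} for a global null.
#' @param base_log_mean latent log-intensity baseline. Default 11.5, i.e.
#'   intensities around exp(11.5) ~ 1e5, the scale of instrument peak heights
#'   that survive a typical minimum-peak-height cutoff.
#' @param noise_sd latent log-scale sd (default 0.7).
#' @param pathway_sizes integer vector of nine pathway sizes summing to
#'   \code{n_features}; default matches the nine-pathway composition of the
#'   389-feature design (22, 106, 74, 7, 108, 5, 8, 6, 53).
#' @param enriched_pathway index (1..9) recorded in the truth as the pathway
#'   nominally carrying enrichment; default 3 (lipid metabolism).
#' @param pathway_shuffle randomly permute pathway labels (default TRUE).
#' @param seed integer seed.
#' @return list with elements \code{table} (a raw-stage
#'   \code{\link{FeatureTable}}) and \code{truth} (class
#'   \code{"SyntheticTruth"}: \code{effect}, \code{module_label},
#'   \code{pathway_label}, \code{enriched_pathway}).
#' @examples
#' cohort <- generateCohort(5, 5, seed = 1)
#' sim <- generateMetabolome(cohort, n_features = 30,
#'     pathway_sizes = c(4, 4, 4, 3, 3, 3, 3, 3, 3), seed = 1)
#' sim$table
#' @export
generateMetabolome <- function(cohort, n_features = 389,
                               modules = NULL, effects = NULL,
                               base_log_mean = 11.5, noise_sd = 0.7,
                               pathway_sizes = c(22, 106, 74, 7, 108, 5, 8, 6, 53),
                               enriched_pathway = 3,
                               pathway_shuffle = TRUE,
                               seed = 1) {
    .check_cohort(cohort)
    if (length(unique(cohort$group)) < 2)
        stop("both group codes must be present", call. = FALSE)
    if (length(pathway_sizes) != 9L || sum(pathway_sizes) != n_features)
        stop("'pathway_sizes' must be nine counts summing to 'n_features'",
            call. = FALSE)
    if (!is.null(modules)) {
        stopifnot(all(c("size", "within_corr") %in% names(modules)))
        if (any(modules$within_corr < 0) || any(modules$within_corr >= 1))
            stop("module 'within_corr' must lie in [0, 1)", call. = FALSE)
        if (sum(modules$size) > n_features)
            stop("module sizes exceed 'n_features'", call. = FALSE)
    }
    set.seed(as.integer(seed))
    n <- nrow(cohort)

    d <- numeric(n_features)
    if (!is.null(effects) && nrow(effects)) {
        stopifnot(all(c("feature", "d") %in% names(effects)))
        if (any(effects$feature < 1) || any(effects$feature > n_features))
            stop("effect feature index out of range", call. = FALSE)
        d[effects$feature] <- effects$d
    }

    module_label <- integer(n_features)
    z <- matrix(stats::rnorm(n * n_features), n, n_features)
    if (!is.null(modules) && nrow(modules)) {
        pos <- 0L
        for (m in seq_len(nrow(modules))) {
            sz <- modules$size[m]
            rho <- modules$within_corr[m]
            idx <- pos + seq_len(sz)
            module_label[idx] <- m
            shared <- stats::rnorm(n)
            z[, idx] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, idx]
            pos <- pos + sz
        }
    }
    z <- base_log_mean + noise_sd * z +
        outer(cohort$group, d)               # planted case shift, log scale
    x <- exp(z)
    dimnames(x) <- list(cohort$sample_id, sprintf("M%03d", seq_len(n_features)))

    pathway_label <- rep(seq_len(9L), pathway_sizes)
    if (pathway_shuffle) pathway_label <- sample(pathway_label)

    truth <- structure(list(
        effect = d,
        module_label = module_label,
        pathway_label = pathway_label,
        enriched_pathway = as.integer(enriched_pathway)
    ), class = "SyntheticTruth")
    list(table = FeatureTable(x, stage = "raw"), truth = truth)
}

#' Generate a per-feature instrument-blank profile
#'
#' Produces the blank-average intensities that the blank-ratio filter
#' compares against: a chosen fraction of features is "contaminated" (their
#' blank average is set high enough that sample-max / blank < 10, so the
#' filter removes them) while the remainder get near-zero blank levels that
#' pass comfortably.
#'
#' @param table the paired raw-stage \code{\link{FeatureTable}} (needed to
#'   place blanks relative to each feature's sample maximum).
#' @param fraction_contaminated fraction in [0, 1]; exactly
#'   \code{round(fraction * n_features)} features are contaminated.
#' @param seed integer seed.
#' @return list with \code{blank_means} (named per-feature numeric) and
#'   \code{contaminated_ids} (feature ids planted to fail the filter).
#' @export
generateBlankProfile <- function(table, fraction_contaminated = 0.2, seed = 1) {
    stopifnot(is(table, "FeatureTable"))
    if (fraction_contaminated < 0 || fraction_contaminated > 1)
        stop("'fraction_contaminated' must lie in [0, 1]", call. = FALSE)
    set.seed(as.integer(seed))
    ids <- featureIds(table)
    p <- length(ids)
    smax <- apply(intensities(table), 2, max)
    n_bad <- round(fraction_contaminated * p)
    bad <- sort(sample.int(p, n_bad))
    blank <- smax / 1000                      # ratio 1000: clean pass
    blank[bad] <- smax[bad] / 5               # ratio 5: fails the 10x rule
    names(blank) <- ids
    list(blank_means = blank, contaminated_ids = ids[bad])
}

#' Generate censored urinary EDC measurements
#'
#' Draws per-sample concentrations (ng/mL) for each analyte in the panel from
#' a log-normal with analyte-specific geometric mean and geometric sd; cases
#' (group 1) have their geometric mean multiplied by \code{case_multiplier}.
#' Draws below the analyte's limit of quantitation are flagged as censored.
#' Measurements keep the true drawn value (what the assay would have seen)
#' and the truth records it too, so the LOQ/sqrt(2) imputation error is
#' measurable.
#'
#' @param cohort data.frame from \code{\link{generateCohort}}.
#' @param panel analyte panel data.frame (see \code{\link{analytePanel}}).
#' @param geo_mean named per-analyte geometric mean (ng/mL); analytes must
#'   exist in the panel. Defaults to 4x each analyte's LOQ.
#' @param geo_sd named per-analyte geometric sd (> 1); default 2.5, a typical
#'   spread for urinary biomarkers.
#' @param case_multiplier named per-analyte multiplicative group effect on
#'   the geometric mean; default 1 (no effect).
#' @param seed integer seed.
#' @return list with \code{measurements} (long data.frame: sample_id,
#'   analyte, value_ng_ml, below_loq) and \code{truth} (class
#'   \code{"SyntheticTruth"}: true values and censor flags in sample x
#'   analyte matrices, plus the multipliers).
#' @export
generateEDC <- function(cohort, panel = analytePanel(),
                        geo_mean = NULL, geo_sd = NULL,
                        case_multiplier = NULL, seed = 1) {
    .check_cohort(cohort)
    analytes <- panel$analyte
    loq <- stats::setNames(panel$loq_ng_ml, analytes)
    if (any(loq <= 0)) stop("panel LOQs must be positive", call. = FALSE)
    fill <- function(x, default) {
        out <- stats::setNames(rep(default, length(analytes)), analytes)
        if (!is.null(x)) {
            if (!all(names(x) %in% analytes))
                stop("unknown analyte(s): ",
                    paste(setdiff(names(x), analytes), collapse = ", "),
                    call. = FALSE)
            out[names(x)] <- x
        }
        out
    }
    gm <- fill(geo_mean, NA_real_)
    gm[is.na(gm)] <- 4 * loq[is.na(gm)]
    gs <- fill(geo_sd, 2.5)
    if (any(gs <= 1)) stop("'geo_sd' must exceed 1", call. = FALSE)
    cm <- fill(case_multiplier, 1)

    set.seed(as.integer(seed))
    n <- nrow(cohort)
    val <- matrix(NA_real_, n, length(analytes),
        dimnames = list(cohort$sample_id, analytes))
    for (a in seq_along(analytes)) {
        mu <- log(gm[a]) + log(cm[a]) * cohort$group
        val[, a] <- exp(stats::rnorm(n, mu, log(gs[a])))
    }
    cens <- sweep(val, 2, loq, "<")

    meas <- data.frame(
        sample_id = rep(cohort$sample_id, times = length(analytes)),
        analyte = rep(analytes, each = n),
        value_ng_ml = as.vector(val),
        below_loq = as.vector(cens),
        stringsAsFactors = FALSE
    )
    truth <- structure(list(
        true_value = val,
        censored = cens,
        case_multiplier = cm
    ), class = "SyntheticTruth")
    list(measurements = meas, truth = truth)
}
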