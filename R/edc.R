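#' The default urinary EDC analyte panel
#'
#' Registry of the four parabens and ten phthalate metabolites measured by
#' the targeted urinary assay, with each analyte's limit of quantitation
#' (LOQ, ng/mL), parent compound, family, and molar mass (ug/umol) used by
#' the molar-sum exposure indices. Shipped as a plain-CSV fixture; pass a
#' modified copy to override LOQs or molar masses.
#'
#' @param file path to a panel CSV (columns: analyte, parent, loq_ng_ml,
#'   molar_mass_ug_per_umol, family); defaults to the packaged panel.
#' @return data.frame with one row per analyte.
#' @examples
#' analytePanel()
#' @export
analytePanel <- function(file = system.file("extdata", "edc_panel.csv",
                                            package = "ThyroMetab")) {
    panel <- utils::read.csv(file, stringsAsFactors = FALSE)
    stopifnot(all(c("analyte", "parent", "loq_ng_ml",
        "molar_mass_ug_per_umol", "family") %in% names(panel)))
    if (anyDuplicated(panel$analyte))
        stop("panel analyte names must be unique", call. = FALSE)
    panel
}

.check_measurements <- function(meas) {
    stopifnot(is.data.frame(meas),
        all(c("sample_id", "analyte", "value_ng_ml") %in% names(meas)))
    invisible(meas)
}

#' Impute measurements below the limit of quantitation
#'
#' Values strictly below their analyte's LOQ are replaced by LOQ/sqrt(2),
#' the standard single-value substitution for left-censored biomonitoring
#' data; values at or above the LOQ are untouched. The \code{below_loq}
#' column records which values were substituted.
#'
#' @param meas long-format measurements (sample_id, analyte, value_ng_ml).
#' @param panel analyte panel (see \code{\link{analytePanel}}).
#' @return the measurements with censored values replaced and
#'   \code{below_loq} set.
#' @examples
#' m <- data.frame(sample_id = "S1", analyte = "Methylparaben",
#'     value_ng_ml = 0.2)
#' imputeBelowLOQ(m)$value_ng_ml   # 0.50 / sqrt(2)
#' @export
imputeBelowLOQ <- function(meas, panel = analytePanel()) {
    .check_measurements(meas)
    unknown <- setdiff(meas$analyte, panel$analyte)
    if (length(unknown))
        stop("analyte(s) not in panel: ", paste(unknown, collapse = ", "),
            call. = FALSE)
    loq <- stats::setNames(panel$loq_ng_ml, panel$analyte)[meas$analyte]
    cens <- meas$value_ng_ml < loq
    meas$value_ng_ml[cens] <- loq[cens] / sqrt(2)
    meas$below_loq <- cens
    meas
}

#' Creatinine-adjust urinary concentrations
#'
#' Converts ng analyte per mL urine to ug analyte per g creatinine:
#' \code{adjusted = 100 * value_ng_ml / creatinine_mg_dl} (the factor 100
#' is the unit identity ng/mg = ug/g after converting mg/dL to mg/mL).
#' Correcting by creatinine removes between-sample differences in urine
#' dilution.
#'
#' @param meas long-format measurements (after LOQ imputation).
#' @param cohort data.frame with sample_id and urine_creatinine (mg/dL, > 0).
#' @return measurements with an added \code{adjusted_ug_g} column.
#' @export
creatinineAdjust <- function(meas, cohort) {
    .check_measurements(meas)
    if (!"urine_creatinine" %in% names(cohort))
        stop("cohort lacks 'urine_creatinine'", call. = FALSE)
    cr <- stats::setNames(cohort$urine_creatinine, cohort$sample_id)
    missing <- setdiff(meas$sample_id, names(cr))
    if (length(missing))
        stop("no creatinine for sample(s): ", paste(missing, collapse = ", "),
            call. = FALSE)
    crv <- cr[meas$sample_id]
    if (any(!is.finite(crv)) || any(crv <= 0))
        stop("non-positive creatinine for sample(s): ",
            paste(unique(meas$sample_id[!is.finite(crv) | crv <= 0]),
                collapse = ", "), call. = FALSE)
    meas$adjusted_ug_g <- 100 * meas$value_ng_ml / crv
    meas
}

# the analytes whose molar concentrations are pooled per exposure index
.MOLAR_SUMS <- list(
    sum_pcp = c("MBP", "MEP"),
    sum_dehp = c("MECPP", "MEHHP", "MEOHP", "MEHP"),
    sum_aa = c("MBP", "MBzP", "MiBP")
)

#' Per-sample EDC exposure indices
#'
#' Aggregates creatinine-adjusted concentrations into the standard exposure
#' indices. Molar sums divide each constituent's concentration (ug/g) by its
#' molar mass (ug/umol) before summing, so every metabolite contributes on a
#' common molar scale (umol/g creatinine):
#' \itemize{
#'   \item \code{sum_pcp} = MBP/222 + MEP/194 (personal-care-product
#'     phthalate exposure);
#'   \item \code{sum_dehp} = MECPP/308 + MEHHP/294 + MEOHP/292 + MEHP/278
#'     (DEHP-derived exposure);
#'   \item \code{sum_aa} = molar sum of MBP, MBzP, MiBP (anti-androgenic
#'     phthalate metabolites).
#' }
#' \code{sum_paraben} and \code{sum_phthalate} are family mass sums (ug/g)
#' over the paraben and phthalate-metabolite panels respectively (set
#' \code{family_molar = TRUE} for molar versions). A sample missing any
#' constituent of an index gets \code{NA} for that index, never a silent
#' zero.
#'
#' @param adjusted measurements carrying \code{adjusted_ug_g} (from
#'   \code{\link{creatinineAdjust}}).
#' @param panel analyte panel supplying molar masses and families.
#' @param family_molar compute the family sums on the molar scale too.
#' @return data.frame: sample_id, sum_pcp, sum_dehp, sum_aa (umol/g),
#'   sum_paraben, sum_phthalate.
#' @export
molarSums <- function(adjusted, panel = analytePanel(), family_molar = FALSE) {
    .check_measurements(adjusted)
    if (!"adjusted_ug_g" %in% names(adjusted))
        stop("run creatinineAdjust() first ('adjusted_ug_g' missing)",
            call. = FALSE)
    mm <- stats::setNames(panel$molar_mass_ug_per_umol, panel$analyte)
    fam <- stats::setNames(panel$family, panel$analyte)
    samples <- unique(adjusted$sample_id)

    value_of <- function(sub, analytes, divisor) {
        idx <- match(analytes, sub$analyte)
        if (anyNA(idx)) return(NA_real_)
        sum(sub$adjusted_ug_g[idx] / divisor)
    }
    one_sample <- function(sid) {
        sub <- adjusted[adjusted$sample_id == sid, ]
        out <- vapply(.MOLAR_SUMS, function(an) {
            needed <- mm[an]
            if (anyNA(needed))
                stop("molar mass missing for: ",
                    paste(an[is.na(needed)], collapse = ", "), call. = FALSE)
            value_of(sub, an, needed)
        }, numeric(1))
        fam_sum <- function(f) {
            an <- panel$analyte[fam[panel$analyte] == f]
            div <- if (family_molar) mm[an] else rep(1, length(an))
            value_of(sub, an, div)
        }
        c(out, sum_paraben = fam_sum("paraben"),
            sum_phthalate = fam_sum("phthalate_metabolite"))
    }
    res <- t(vapply(samples, one_sample, numeric(5)))
    data.frame(sample_id = samples, res, row.names = NULL,
        stringsAsFactors = FALSE)
}
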