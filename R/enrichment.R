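#' Two-sided Fisher's exact p for a 2x2 table
#'
#' Minimum-likelihood convention: with margins fixed, the p-value is the sum
#' of hypergeometric probabilities of all outcomes no more probable than the
#' observed one (the convention of \code{stats::fisher.test} and of the
#' major statistical packages; two-sided Fisher conventions differ, so the
#' choice is stated explicitly). Computed by direct summation over the
#' hypergeometric support.
#'
#' @param sig_in,notsig_in counts inside the pathway (significant / not).
#' @param sig_out,notsig_out counts outside the pathway.
#' @return two-sided p-value.
#' @export
fisherExactTwoSided <- function(sig_in, notsig_in, sig_out, notsig_out) {
    counts <- c(sig_in, notsig_in, sig_out, notsig_out)
    if (any(counts < 0) || any(counts != round(counts)))
        stop("counts must be non-negative integers", call. = FALSE)
    S <- sig_in + sig_out          # total significant (white balls)
    NS <- notsig_in + notsig_out   # total non-significant (black balls)
    t <- sig_in + notsig_in        # pathway size (draws)
    support <- max(0, t - NS):min(t, S)
    pr <- stats::dhyper(support, S, NS, t)
    obs <- stats::dhyper(sig_in, S, NS, t)
    min(sum(pr[pr <= obs * (1 + 1e-7)]), 1)
}

#' Pathway over-representation by Fisher's exact test
#'
#' For each pathway, tests the 2x2 table of significant / non-significant
#' features inside versus outside the pathway with a two-sided Fisher exact
#' test, then adjusts the per-pathway p-values with Benjamini-Hochberg
#' across exactly the tested pathways. A pathway containing every feature
#' has an empty out-group; its p is defined as 1 with a warning.
#'
#' @param sig_flags named logical vector: feature -> significant (typically
#'   \code{q_bh < 0.05} from \code{\link{differentialAbundance}}).
#' @param pathways named integer/character vector or data.frame
#'   (feature_id, pathway_group) assigning every flagged feature to exactly
#'   one pathway.
#' @param monotone BH convention for the pathway-level adjustment.
#' @return data.frame: pathway, sig_count, notsig_count, total, p_fisher,
#'   p_bh — one row per pathway, in pathway order.
#' @export
fisherEnrichment <- function(sig_flags, pathways, monotone = TRUE) {
    if (is.data.frame(pathways)) {
        stopifnot(all(c("feature_id", "pathway_group") %in% names(pathways)))
        pathways <- stats::setNames(pathways$pathway_group, pathways$feature_id)
    }
    if (length(sig_flags) == 0)
        stop("at least one feature required", call. = FALSE)
    if (is.null(names(sig_flags)) || is.null(names(pathways)))
        stop("'sig_flags' and 'pathways' must be named by feature id",
            call. = FALSE)
    missing <- setdiff(names(sig_flags), names(pathways))
    if (length(missing))
        stop("feature(s) without a pathway: ",
            paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    pw <- pathways[names(sig_flags)]
    groups <- sort(unique(pw))
    S <- sum(sig_flags)
    N <- length(sig_flags)
    rows <- lapply(groups, function(gp) {
        inn <- pw == gp
        si <- sum(sig_flags[inn]); ni <- sum(inn) - si
        so <- S - si; no <- (N - sum(inn)) - so
        if (sum(inn) == N) {
            warning("pathway '", gp, "' contains all features; p set to 1",
                call. = FALSE)
            p <- 1
        } else {
            p <- fisherExactTwoSided(si, ni, so, no)
        }
        data.frame(pathway = gp, sig_count = si, notsig_count = ni,
            total = si + ni, p_fisher = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_bh <- bhAdjust(out$p_fisher, monotone = monotone)
    out
}

#' Recompute pathway enrichment from printed count triples
#'
#' Entry point for checking a published enrichment summary: reads the
#' per-pathway significant / non-significant counts and recomputes the
#' two-sided Fisher exact p and both BH variants from scratch.
#'
#' @param counts data.frame with columns pathway, sig, notsig (nine rows),
#'   or a path to such a CSV; defaults to the packaged nine-pathway count
#'   fixture.
#' @return data.frame: pathway, sig_count, notsig_count, total, p_fisher,
#'   p_bh (monotone step-up), p_bh_rank (non-monotone p*m/rank).
#' @examples
#' enrichmentFromCounts()
#' @export
enrichmentFromCounts <- function(counts = system.file("extdata",
                                     "pathway_counts.csv",
                                     package = "ThyroMetab")) {
    if (is.character(counts)) counts <- utils::read.csv(counts,
        stringsAsFactors = FALSE)
    stopifnot(all(c("pathway", "sig", "notsig") %in% names(counts)))
    if (nrow(counts) != 9L)
        stop("expected nine pathway rows, got ", nrow(counts), call. = FALSE)
    S <- sum(counts$sig)
    N <- sum(counts$sig) + sum(counts$notsig)
    p <- mapply(function(si, ni) {
        fisherExactTwoSided(si, ni, S - si, (N - si - ni) - (S - si))
    }, counts$sig, counts$notsig)
    data.frame(pathway = counts$pathway,
        sig_count = counts$sig, notsig_count = counts$notsig,
        total = counts$sig + counts$notsig,
        p_fisher = p,
        p_bh = bhAdjust(p, monotone = TRUE),
        p_bh_rank = bhAdjust(p, monotone = FALSE),
        row.names = NULL, stringsAsFactors = FALSE)
}

#' Format an enrichment table for display
#'
#' Emits one line per pathway (name, counts, raw and BH p) plus a checksum
#' line with the summed totals, mirroring the layout of a published
#' nine-pathway enrichment summary.
#'
#' @param rows data.frame from \code{\link{fisherEnrichment}} or
#'   \code{\link{enrichmentFromCounts}}.
#' @return character vector of formatted lines (invisibly printable with
#'   \code{cat(..., sep = "\n")}).
#' @export
formatEnrichment <- function(rows) {
    if (!nrow(rows)) stop("empty enrichment table", call. = FALSE)
    header <- sprintf("%-52s %5s %8s %6s %8s %8s",
        "Pathway", "sig", "notsig", "total", "p", "p_BH")
    body <- sprintf("%-52s %5d %8d %6d %8.3f %8.3f",
        rows$pathway, rows$sig_count, rows$notsig_count, rows$total,
        rows$p_fisher, rows$p_bh)
    checksum <- sprintf("Total features: %d (significant: %d)",
        sum(rows$total), sum(rows$sig_count))
    c(header, body, checksum)
}
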