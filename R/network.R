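#' Pairwise Pearson correlation of features
#'
#' @param table \code{\link{FeatureTable}} at stage pareto, >= 3 samples.
#' @return symmetric feature x feature correlation matrix; zero-variance
#'   features are excluded with a warning.
#' @export
correlationMatrix <- function(table) {
    .check_stage(table, "pareto", "correlationMatrix")
    x <- intensities(table)
    if (nrow(x) < 3)
        stop("need at least 3 samples", call. = FALSE)
    sdv <- apply(x, 2, stats::sd)
    if (any(sdv == 0)) {
        warning("excluding zero-variance feature(s): ",
            paste(colnames(x)[sdv == 0], collapse = ", "), call. = FALSE)
        x <- x[, sdv > 0, drop = FALSE]
    }
    stats::cor(x)
}

#' Signed soft-power adjacency with hard threshold
#'
#' \code{a_ij = sign(r_ij) * |r_ij|^beta} when \code{|r_ij| >= tau}, else 0;
#' diagonal set to zero. Raising to a power \code{beta} enhances strong
#' correlations relative to weak ones while keeping their sign; the hard
#' threshold \code{tau} zeroes out the weakest links entirely.
#'
#' @param r correlation matrix.
#' @param beta soft-threshold power (> 0, default 6, the customary signed-
#'   network default).
#' @param tau hard threshold on |r| in [0, 1) (default 0.1).
#' @return signed adjacency matrix.
#' @export
signedPowerAdjacency <- function(r, beta = 6, tau = 0.1) {
    if (beta <= 0) stop("'beta' must be > 0", call. = FALSE)
    if (tau < 0 || tau >= 1) stop("'tau' must lie in [0, 1)", call. = FALSE)
    a <- sign(r) * abs(r)^beta
    a[abs(r) < tau] <- 0
    diag(a) <- 0
    a
}

#' Topological overlap matrix and normalized dissimilarity
#'
#' With \code{u = |a|} (TOM requires non-negative weights; the sign lives in
#' r and a), connectivity \code{k_i = sum_u u_iu} and
#' \deqn{tom_{ij} = (\sum_l u_{il} u_{lj} + u_{ij}) / (\min(k_i, k_j) + 1 - u_{ij})}
#' for i != j, \code{tom_ii = 1}. Two features overlap topologically when
#' they share neighbours, not merely when they are directly linked. The raw
#' dissimilarity 1 - TOM is divided by its maximum off-diagonal entry (so
#' the most dissimilar pair is at 1; identity map if that maximum is 0) and
#' the diagonal forced to zero.
#'
#' @param a symmetric signed adjacency with zero diagonal, |a_ij| <= 1.
#' @return list: \code{tom}, \code{diss}, \code{connectivity}.
#' @export
tomDissimilarity <- function(a) {
    if (!isSymmetric(unname(a), tol = 1e-10))
        stop("adjacency must be symmetric", call. = FALSE)
    if (max(abs(diag(a))) > 1e-12)
        stop("adjacency diagonal must be zero", call. = FALSE)
    if (max(abs(a)) > 1 + 1e-12)
        stop("adjacency entries must lie in [-1, 1]", call. = FALSE)
    u <- abs(a)
    k <- rowSums(u)
    num <- u %*% u + u
    den <- outer(k, k, pmin) + 1 - u
    tom <- num / den
    diag(tom) <- 1
    raw <- 1 - tom
    off <- raw[upper.tri(raw)]
    mx <- if (length(off)) max(off) else 0
    diss <- if (mx > 0) raw / mx else raw
    diag(diss) <- 0
    list(tom = tom, diss = diss, connectivity = k)
}

#' Build the full network model
#'
#' Convenience chain: correlation -> signed power adjacency -> TOM
#' dissimilarity, returned as a validated \code{\link{NetworkModel}}.
#'
#' @inheritParams correlationMatrix
#' @inheritParams signedPowerAdjacency
#' @return a \code{NetworkModel}.
#' @export
buildNetwork <- function(table, beta = 6, tau = 0.1) {
    r <- correlationMatrix(table)
    a <- signedPowerAdjacency(r, beta, tau)
    td <- tomDissimilarity(a)
    new("NetworkModel", correlation = r, adjacency = a,
        connectivity = td$connectivity, tom = td$tom, diss = td$diss,
        beta = beta, tau = tau)
}

# relabel cluster ids by decreasing size; ties broken by smallest member index
.relabel_by_size <- function(cl) {
    sz <- table(cl)
    first <- vapply(names(sz), function(g) min(which(cl == g)), integer(1))
    ord <- order(-as.integer(sz), first)
    map <- stats::setNames(seq_along(ord), names(sz)[ord])
    out <- unname(map[as.character(cl)])
    names(out) <- names(cl)
    out
}

#' Detect modules by Ward clustering of the TOM dissimilarity
#'
#' Agglomerative hierarchical clustering with Ward linkage (squared-distance
#' update convention, \code{hclust(method = "ward.D2")}) on the normalized
#' TOM dissimilarity treated as a distance, cut to exactly \code{k} modules.
#' Labels 1..k are ordered by decreasing module size, ties broken by the
#' smallest member index.
#'
#' @param diss symmetric dissimilarity matrix with zero diagonal (from
#'   \code{\link{tomDissimilarity}} or a \code{NetworkModel}).
#' @param k number of modules (default 5).
#' @return named integer vector of module labels.
#' @export
clusterModules <- function(diss, k = 5) {
    if (is(diss, "NetworkModel")) diss <- diss@diss
    p <- nrow(diss)
    if (k < 2 || k > p)
        stop("'k' must lie in [2, number of features]", call. = FALSE)
    h <- stats::hclust(stats::as.dist(diss), method = "ward.D2")
    cl <- stats::cutree(h, k = k)
    names(cl) <- colnames(diss)
    .relabel_by_size(cl)
}

#' Module eigenmetabolites
#'
#' For every module, the first principal component of its member submatrix:
#' the unit-norm left-singular vector of the (column-centered, Pareto-scaled)
#' samples x members matrix, oriented so that the mean Pearson correlation
#' with the member features is positive. \code{varExplained} is the first
#' singular value's share of the total variance. A single-feature module's
#' eigenmetabolite is the standardized feature itself (with a warning).
#'
#' @param table pareto-stage \code{\link{FeatureTable}}.
#' @param labels named module labels from \code{\link{clusterModules}}.
#' @return a \code{\link{ModuleSet}}.
#' @export
eigenmetabolites <- function(table, labels) {
    .check_stage(table, "pareto", "eigenmetabolites")
    x <- intensities(table)
    stopifnot(!is.null(names(labels)), all(names(labels) %in% colnames(x)))
    k <- max(labels)
    n <- nrow(x)
    scores <- matrix(NA_real_, n, k,
        dimnames = list(rownames(x), paste0("module", seq_len(k))))
    ve <- numeric(k)
    osign <- numeric(k)
    for (m in seq_len(k)) {
        members <- names(labels)[labels == m]
        xm <- x[, members, drop = FALSE]
        xm <- sweep(xm, 2, colMeans(xm))     # guard centering within module
        if (length(members) == 1L) {
            warning("module ", m, " has a single feature; eigenmetabolite is ",
                "the standardized feature", call. = FALSE)
            v <- xm[, 1]
            sc <- v / sqrt(sum(v^2))
            ve[m] <- 1
        } else {
            sv <- svd(xm)
            sc <- sv$u[, 1]
            ve[m] <- sv$d[1]^2 / sum(sv$d^2)
        }
        s <- sign(mean(stats::cor(sc, xm)))
        if (s == 0) s <- 1
        scores[, m] <- s * sc
        osign[m] <- s
    }
    new("ModuleSet", labels = as.integer(labels) |>
            stats::setNames(names(labels)),
        eigenmetabolites = scores, varExplained = ve, orientationSign = osign)
}

#' Associate module eigenmetabolites with the binary outcome
#'
#' Per module: the point-biserial Pearson correlation of the eigenmetabolite
#' with the group indicator (two-sided t-based p), and a univariate logistic
#' regression of outcome on the eigenmetabolite standardized to unit
#' variance (so odds ratios are per SD of module score). The logistic fit is
#' iteratively reweighted least squares with a tight convergence tolerance;
#' the Wald chi-square is \code{(coef/se)^2} and the 95\% CI is
#' \code{exp(coef +/- 1.96 se)}. Complete separation is flagged (no crash)
#' and the CI reported as unbounded.
#'
#' @param modules a \code{\link{ModuleSet}}.
#' @param cohort data.frame with sample_id and group; both classes present.
#' @return data.frame: module, pearson_r, pearson_p, logit_coef, or_,
#'   se, wald_chi2, wald_p, ci95_low, ci95_high, separation.
#' @export
moduleOutcomeAssociation <- function(modules, cohort) {
    .check_cohort(cohort)
    em <- eigenmetaboliteScores(modules)
    idx <- match(rownames(em), cohort$sample_id)
    if (anyNA(idx))
        stop("cohort is missing sample(s) present in the module scores",
            call. = FALSE)
    y <- cohort$group[idx]
    if (length(unique(y)) < 2)
        stop("both outcome classes must be present", call. = FALSE)
    rows <- lapply(seq_len(ncol(em)), function(m) {
        e <- em[, m]
        ct <- stats::cor.test(e, y)
        z <- as.vector(scale(e))
        sep <- FALSE
        fit <- withCallingHandlers(
            stats::glm(y ~ z, family = stats::binomial(),
                control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
            warning = function(w) {
                if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                        conditionMessage(w))) {
                    sep <<- TRUE
                    invokeRestart("muffleWarning")
                }
            })
        # perfect fit (residual deviance ~ 0) is separation even when IRLS
        # stops before the fitted probabilities reach numerical 0/1
        if (fit$deviance < 1e-6) sep <- TRUE
        co <- summary(fit)$coefficients
        b <- co["z", "Estimate"]; se <- co["z", "Std. Error"]
        wald <- (b / se)^2
        lo <- exp(b - 1.96 * se); hi <- exp(b + 1.96 * se)
        if (sep) { lo <- 0; hi <- Inf }
        data.frame(module = m,
            pearson_r = unname(ct$estimate), pearson_p = ct$p.value,
            logit_coef = b, or_ = exp(b), se = se,
            wald_chi2 = wald,
            wald_p = stats::pchisq(wald, 1, lower.tail = FALSE),
            ci95_low = lo, ci95_high = hi, separation = sep,
            stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
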