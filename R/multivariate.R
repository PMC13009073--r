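#' Principal component analysis of a scaled feature table
#'
#' SVD of the column-centered matrix (the Pareto-scaled data are already
#' centered; centering is applied again defensively and no re-scaling is
#' done — the data were scaled once, upstream). Explained-variance ratios
#' are the squared singular values over their total. A deterministic sign
#' convention is applied per component: the loading entry of largest
#' magnitude is made positive.
#'
#' @param table pareto-stage \code{\link{FeatureTable}} with >= 2 samples
#'   and >= 2 features.
#' @return list of class \code{"pcaResult"}: \code{loadings} (features x
#'   components, orthonormal), \code{scores} (samples x components),
#'   \code{explained_ratio}, \code{sdev}.
#' @export
runPCA <- function(table) {
    .check_stage(table, "pareto", "runPCA")
    x <- intensities(table)
    if (nrow(x) < 2 || ncol(x) < 2)
        stop("PCA needs >= 2 samples and >= 2 features", call. = FALSE)
    x <- sweep(x, 2, colMeans(x))
    if (all(x == 0))
        stop("degenerate input: matrix is identically zero", call. = FALSE)
    sv <- svd(x)
    ncomp <- length(sv$d)
    loadings <- sv$v
    scores <- sv$u %*% diag(sv$d, ncomp)
    for (j in seq_len(ncomp)) {           # sign convention
        i <- which.max(abs(loadings[, j]))
        if (loadings[i, j] < 0) {
            loadings[, j] <- -loadings[, j]
            scores[, j] <- -scores[, j]
        }
    }
    dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(ncomp)))
    dimnames(scores) <- list(rownames(x), paste0("PC", seq_len(ncomp)))
    structure(list(
        loadings = loadings, scores = scores,
        explained_ratio = sv$d^2 / sum(sv$d^2), sdev = sv$d / sqrt(nrow(x) - 1)
    ), class = "pcaResult")
}

#' @export
print.pcaResult <- function(x, ...) {
    cat(sprintf("PCA: %d samples x %d features, %d components\n",
        nrow(x$scores), nrow(x$loadings), ncol(x$scores)))
    cat("  explained ratio (first 5):",
        paste(sprintf("%.3f", utils::head(x$explained_ratio, 5)), collapse = ", "),
        "\n")
    invisible(x)
}

#' Number of components needed to reach a variance fraction
#'
#' @param result a \code{"pcaResult"}.
#' @param fraction target cumulative explained-variance fraction in (0, 1].
#' @return the smallest m with cumulative explained ratio >= fraction.
#' @export
nComponentsForVariance <- function(result, fraction = 0.90) {
    if (fraction <= 0 || fraction > 1)
        stop("'fraction' must lie in (0, 1]", call. = FALSE)
    cs <- cumsum(result$explained_ratio)
    if (fraction == 1) return(sum(result$explained_ratio > 1e-12))
    which(cs >= fraction - 1e-12)[1]
}

#' Cluster features by their PCA loadings
#'
#' Ward clustering (\code{ward.D2}) of each feature's loading vector over
#' the first \code{n_pcs} components, cut at \code{k}; cluster ids ordered
#' by decreasing size (ties by smallest member index). Features cluster
#' together when they contribute similarly to the retained components.
#'
#' @param result a \code{"pcaResult"}.
#' @param n_pcs number of leading components to use (e.g. from
#'   \code{\link{nComponentsForVariance}}).
#' @param k number of clusters (default 15).
#' @return named integer vector of cluster labels.
#' @export
clusterLoadings <- function(result, n_pcs, k = 15) {
    L <- result$loadings
    if (n_pcs > ncol(L))
        stop("'n_pcs' exceeds available components", call. = FALSE)
    if (k < 2 || k > nrow(L))
        stop("'k' must lie in [2, number of features]", call. = FALSE)
    h <- stats::hclust(stats::dist(L[, seq_len(n_pcs), drop = FALSE]),
        method = "ward.D2")
    cl <- stats::cutree(h, k = k)
    names(cl) <- rownames(L)
    .relabel_by_size(cl)
}

#' Point-biserial feature-outcome correlations
#'
#' Pearson correlation of every feature with the binary group indicator.
#' When cluster labels are supplied, rows are returned grouped by cluster
#' and ordered within each cluster from most positive to most negative
#' correlation — the layout consumed by a cluster-by-feature heatmap.
#'
#' @param table pareto-stage \code{\link{FeatureTable}}.
#' @param cohort data.frame with sample_id and group (both classes present).
#' @param clusters optional named cluster labels (e.g. from
#'   \code{\link{clusterLoadings}}).
#' @return data.frame: feature_id, r (and cluster, position when clusters
#'   are given).
#' @export
featureOutcomeCorrelations <- function(table, cohort, clusters = NULL) {
    .check_stage(table, "pareto", "featureOutcomeCorrelations")
    .check_cohort(cohort)
    x <- intensities(table)
    idx <- match(rownames(x), cohort$sample_id)
    if (anyNA(idx)) stop("cohort is missing samples", call. = FALSE)
    y <- cohort$group[idx]
    if (length(unique(y)) < 2)
        stop("both groups must be present", call. = FALSE)
    r <- as.vector(stats::cor(x, y))
    out <- data.frame(feature_id = colnames(x), r = r,
        stringsAsFactors = FALSE)
    if (!is.null(clusters)) {
        out$cluster <- unname(clusters[out$feature_id])
        out <- out[order(out$cluster, -out$r), ]
        out$position <- stats::ave(out$r, out$cluster,
            FUN = seq_along)
        rownames(out) <- NULL
    }
    out
}

#' Partial least squares discriminant analysis (NIPALS, single response)
#'
#' One-component-at-a-time fit for a two-class outcome coded as a single
#' centered indicator column: for each latent variable, the weight vector is
#' the covariance of the deflated predictors with the centered response,
#' unit-normalized; scores are deflated predictors times weights; predictors
#' and response are then deflated by regression on the scores. Per-LV
#' variance-explained percentages come from the deflation sums of squares.
#'
#' VIP for feature j over A retained LVs:
#' \deqn{VIP_j = \sqrt{P \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}}
#' with unit-norm weights, so mean(VIP^2) = 1 by construction; features
#' with VIP > 1 contribute more than an average feature to the modelled
#' response variance.
#'
#' @param table pareto-stage \code{\link{FeatureTable}}.
#' @param cohort data.frame with sample_id and group.
#' @param n_lv number of latent variables (default 2); must be <=
#'   min(samples - 1, features).
#' @return list of class \code{"plsdaResult"}: \code{weights},
#'   \code{x_loadings}, \code{scores}, \code{y_loadings},
#'   \code{x_var_pct}, \code{y_var_pct}, \code{vip}.
#' @export
runPLSDA <- function(table, cohort, n_lv = 2) {
    .check_stage(table, "pareto", "runPLSDA")
    .check_cohort(cohort)
    x <- intensities(table)
    idx <- match(rownames(x), cohort$sample_id)
    if (anyNA(idx)) stop("cohort is missing samples", call. = FALSE)
    yraw <- cohort$group[idx]
    if (length(unique(yraw)) < 2)
        stop("response has zero variance (one class only)", call. = FALSE)
    if (n_lv > min(nrow(x) - 1, ncol(x)))
        stop("'n_lv' exceeds min(samples - 1, features)", call. = FALSE)
    X <- sweep(x, 2, colMeans(x))
    y <- yraw - mean(yraw)
    p <- ncol(X)
    ssx0 <- sum(X^2); ssy0 <- sum(y^2)
    W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
    Tm <- matrix(0, nrow(X), n_lv); q <- numeric(n_lv)
    ssx_pct <- numeric(n_lv); ssy_pct <- numeric(n_lv)
    for (a in seq_len(n_lv)) {
        w <- crossprod(X, y)
        nw <- sqrt(sum(w^2))
        if (nw < 1e-14)
            stop("response variance exhausted before LV ", a, call. = FALSE)
        w <- w / nw
        t <- as.vector(X %*% w)
        tt <- sum(t^2)
        pl <- as.vector(crossprod(X, t)) / tt
        qa <- sum(y * t) / tt
        X <- X - tcrossprod(t, pl)
        y <- y - t * qa
        W[, a] <- w; P[, a] <- pl; Tm[, a] <- t; q[a] <- qa
        ssx_pct[a] <- 100 * tt * sum(pl^2) / ssx0
        ssy_pct[a] <- 100 * qa^2 * tt / ssy0
    }
    ssy_lv <- q^2 * colSums(Tm^2)
    vip <- sqrt(p * as.vector(W^2 %*% ssy_lv) / sum(ssy_lv))
    dimnames(W) <- dimnames(P) <- list(colnames(x), paste0("LV", seq_len(n_lv)))
    dimnames(Tm) <- list(rownames(x), paste0("LV", seq_len(n_lv)))
    structure(list(
        weights = W, x_loadings = P, scores = Tm, y_loadings = q,
        x_var_pct = ssx_pct, y_var_pct = ssy_pct,
        vip = stats::setNames(vip, colnames(x))
    ), class = "plsdaResult")
}

#' @export
print.plsdaResult <- function(x, ...) {
    a <- length(x$y_var_pct)
    cat(sprintf("PLS-DA: %d LVs; X var %% = %s; Y var %% = %s\n", a,
        paste(sprintf("%.1f", x$x_var_pct), collapse = ", "),
        paste(sprintf("%.1f", x$y_var_pct), collapse = ", ")))
    invisible(x)
}
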