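make_cohort_for <- function(pt, n1) {
    ids <- sampleIds(pt)
    data.frame(sample_id = ids,
        group = rep(c(0L, 1L), c(length(ids) - n1, n1)))
}

test_that("PCA matches brute-force eigen-decomposition of the covariance", {
    set.seed(31)
    x <- matrix(rnorm(60, 10), 10, 6)
    pt <- pareto_of(x)
    pca <- runPCA(pt)
    xm <- sweep(intensities(pt), 2, colMeans(intensities(pt)))
    ev <- eigen(cov(xm))
    compvar <- apply(pca$scores, 2, var)
    expect_equal(unname(compvar), ev$values[seq_along(compvar)],
        tolerance = 1e-10)
    expect_equal(sum(pca$explained_ratio), 1)
    # loadings orthonormal, scores centered with diagonal covariance
    expect_equal(crossprod(pca$loadings), diag(ncol(pca$loadings)),
        tolerance = 1e-8, ignore_attr = TRUE)
    expect_equal(unname(colMeans(pca$scores)), rep(0, ncol(pca$scores)),
        tolerance = 1e-12)
    offdiag <- cov(pca$scores); diag(offdiag) <- 0
    expect_lt(max(abs(offdiag)), 1e-10)
    # deterministic sign: largest-magnitude loading entry positive
    for (j in seq_len(ncol(pca$loadings)))
        expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("rank-one data put all variance on the first component", {
    t1 <- seq(-2, 2, length.out = 8)
    x <- outer(t1, c(1, 2, -1)) + 5
    pca <- runPCA(pareto_of(x))
    expect_equal(pca$explained_ratio[1], 1, tolerance = 1e-12)
    expect_equal(pca$explained_ratio[-1], rep(0, 2), tolerance = 1e-12)
    zero <- FeatureTable(matrix(0, 3, 3,
        dimnames = list(letters[1:3], LETTERS[1:3])), stage = "pareto",
        paretoCenter = rep(0, 3), paretoScale = rep(1, 3))
    expect_error(runPCA(zero), "degenerate")
})

test_that("component count for a variance fraction scans the cumulative sum", {
    fake <- structure(list(explained_ratio = c(0.6, 0.3, 0.1)),
        class = "pcaResult")
    expect_equal(nComponentsForVariance(fake, 0.9), 2)
    expect_equal(nComponentsForVariance(fake, 1), 3)
    expect_equal(nComponentsForVariance(fake, 0.5), 1)
    pca <- runPCA(pareto_of(matrix(rnorm(80, 10), 10, 8)))
    for (f in c(0.5, 0.75, 0.9)) {
        expect_equal(nComponentsForVariance(pca, f),
            which(cumsum(pca$explained_ratio) >= f)[1])
    }
    expect_error(nComponentsForVariance(pca, 0), "fraction")
})

test_that("loading clusters recover orthogonal feature blocks", {
    set.seed(32)
    t1 <- rnorm(20); t2 <- rnorm(20)
    x <- cbind(outer(t1, rep(1, 3)) + matrix(rnorm(60, 0, 0.05), 20),
               outer(t2, rep(1, 3)) + matrix(rnorm(60, 0, 0.05), 20))
    pca <- runPCA(pareto_of(x + 10))
    cl <- clusterLoadings(pca, n_pcs = 2, k = 2)
    expect_equal(length(unique(cl[1:3])), 1)
    expect_equal(length(unique(cl[4:6])), 1)
    expect_false(cl[1] == cl[4])
    expect_equal(sort(unique(clusterLoadings(pca, 2, k = 6))), 1:6)
    expect_error(clusterLoadings(pca, n_pcs = 99, k = 2), "n_pcs")
})

test_that("point-biserial correlations match the direct formula and ordering", {
    set.seed(33)
    x <- matrix(rnorm(12 * 5, 10), 12, 5)
    pt <- pareto_of(x)
    coh <- make_cohort_for(pt, 6)
    out <- featureOutcomeCorrelations(pt, coh)
    y <- coh$group
    for (j in 1:5)
        expect_equal(out$r[j], cor(intensities(pt)[, j], y), tolerance = 1e-12)

    # a feature equal to the group indicator correlates perfectly
    x2 <- cbind(x, ind = 5 + y)
    pt2 <- pareto_of(x2)
    out2 <- featureOutcomeCorrelations(pt2, coh)
    expect_equal(out2$r[6], 1, tolerance = 1e-12)

    cl <- setNames(rep(1:2, c(3, 3)), featureIds(pt2))
    ordered <- featureOutcomeCorrelations(pt2, coh, clusters = cl)
    for (g in 1:2) {
        rs <- ordered$r[ordered$cluster == g]
        expect_true(all(diff(rs) <= 0))     # most positive first
    }
})

test_that("PLS-DA: perfect single predictor, VIP identity, orthogonality", {
    y <- rep(c(0L, 1L), each = 5)
    ids <- sprintf("S%02d", 1:10)
    x <- matrix(y - mean(y), 10, 1, dimnames = list(ids, "M001"))
    pt <- FeatureTable(x, stage = "pareto",
        paretoCenter = 0, paretoScale = 1)
    coh <- data.frame(sample_id = ids, group = y)
    fit <- runPLSDA(pt, coh, n_lv = 1)
    expect_equal(fit$y_var_pct[1], 100)
    expect_equal(unname(fit$vip), 1)

    set.seed(34)
    pt2 <- pareto_of(matrix(rnorm(35 * 20, 10), 35, 20))
    coh2 <- make_cohort_for(pt2, 16)
    fit2 <- runPLSDA(pt2, coh2, n_lv = 3)
    expect_equal(mean(fit2$vip^2), 1, tolerance = 1e-8)
    ortho <- crossprod(fit2$scores); diag(ortho) <- 0
    expect_lt(max(abs(ortho)), 1e-8)
    expect_true(all(fit2$y_var_pct >= 0))
    expect_lte(sum(fit2$y_var_pct), 100 + 1e-8)
    expect_error(runPLSDA(pt2, coh2, n_lv = 40), "n_lv")
})

test_that("informative features earn higher VIP than noise features", {
    wins <- 0L
    n_rep <- 25
    for (i in seq_len(n_rep)) {
        coh <- generateCohort(19, 16, seed = 700 + i)
        eff <- data.frame(feature = 1:10, d = 1.0)
        sim <- generateMetabolome(coh, n_features = 200,
            pathway_sizes = c(23, 23, 23, 23, 22, 22, 22, 21, 21),
            effects = eff, seed = 700 + i)
        pt <- paretoScale(logTransform(sim$table))
        fit <- runPLSDA(pt, coh, n_lv = 2)
        if (mean(fit$vip[1:10]) > mean(fit$vip[11:200])) wins <- wins + 1L
    }
    expect_gte(wins / n_rep, 0.95)
})

test_that("outputs are invariant to sample reordering", {
    set.seed(35)
    sim <- generateMetabolome(generateCohort(6, 6, seed = 35),
        n_features = 12, pathway_sizes = c(2, 2, 2, 1, 1, 1, 1, 1, 1),
        seed = 35)
    coh <- generateCohort(6, 6, seed = 35)
    pt <- paretoScale(logTransform(sim$table))
    pca <- runPCA(pt)

    perm <- sample(12)[1:12]
    sperm <- sample(nrow(intensities(sim$table)))
    shuf <- FeatureTable(intensities(sim$table)[sperm, ], stage = "raw")
    pca2 <- runPCA(paretoScale(logTransform(shuf)))
    expect_equal(pca2$explained_ratio, pca$explained_ratio, tolerance = 1e-9)
    expect_equal(pca2$scores[sampleIds(pt), 1], pca$scores[, 1],
        tolerance = 1e-8)
})
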