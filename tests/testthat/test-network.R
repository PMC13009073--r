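pareto_random <- function(n = 8, p = 6, seed = 1) {
    set.seed(seed)
    pareto_of(matrix(rnorm(n * p, 10), n, p))
}

test_that("correlation matrix matches the textbook Pearson formula", {
    pt <- pareto_random(5, 4, seed = 21)
    r <- correlationMatrix(pt)
    x <- intensities(pt)
    pearson <- function(a, b) {
        sum((a - mean(a)) * (b - mean(b))) /
            sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    }
    for (i in 1:4) for (j in 1:4)
        expect_equal(r[i, j], pearson(x[, i], x[, j]), tolerance = 1e-12)
    expect_equal(unname(diag(r)), rep(1, 4))

    # duplicated feature with sign flip
    y <- intensities(pt)
    y <- cbind(y, flip = -y[, 1])
    pt2 <- FeatureTable(y, stage = "pareto",
        paretoCenter = rep(0, 5), paretoScale = rep(1, 5))
    expect_equal(correlationMatrix(pt2)[1, 5], -1)
})

test_that("signed power adjacency preserves sign, powers and thresholds", {
    r <- matrix(c(1, -0.5, 0.05, -0.5, 1, 0.9, 0.05, 0.9, 1), 3)
    a <- signedPowerAdjacency(r, beta = 2, tau = 0.1)
    expect_equal(a[1, 2], -0.25)
    expect_equal(a[1, 3], 0)                 # below tau
    expect_equal(a[2, 3], 0.81)
    expect_equal(unname(diag(a)), rep(0, 3))
    expect_equal(signedPowerAdjacency(matrix(1, 1, 1), beta = 7)[1, 1], 0) # diag
    expect_error(signedPowerAdjacency(r, beta = 0), "beta")
    expect_error(signedPowerAdjacency(r, tau = 1), "tau")
})

test_that("TOM matches hand values and the direct-summation oracle", {
    # two features, perfect link
    a2 <- matrix(c(0, 1, 1, 0), 2)
    td2 <- tomDissimilarity(a2)
    expect_equal(td2$tom[1, 2], 1)
    expect_equal(td2$diss[1, 2], 0)

    # all-zero adjacency: no overlap anywhere
    a0 <- matrix(0, 3, 3)
    td0 <- tomDissimilarity(a0)
    expect_equal(td0$tom[1, 2], 0)
    expect_equal(td0$diss[upper.tri(td0$diss)], rep(1, 3))

    # three features: u12 = u13 = 0.5, u23 = 0 -> tom23 = 1/6
    a3 <- matrix(0, 3, 3)
    a3[1, 2] <- a3[2, 1] <- 0.5
    a3[1, 3] <- a3[3, 1] <- 0.5
    expect_equal(tomDissimilarity(a3)$tom[2, 3], 1 / 6)

    # random adjacencies up to 6 features vs the explicit-loop oracle
    set.seed(22)
    for (p in 2:6) {
        r <- cor(matrix(rnorm(40 * p), 40, p))
        a <- signedPowerAdjacency(r, beta = 3, tau = 0)
        td <- tomDissimilarity(a)
        expect_lt(max(abs(td$tom - tom_oracle(a))), 1e-12)
        expect_true(all(td$tom >= -1e-12 & td$tom <= 1 + 1e-12))
    }
    expect_error(tomDissimilarity(matrix(c(0, 1, 0, 0), 2)), "symmetric")
})

test_that("Ward clustering of the dissimilarity recovers planted blocks", {
    d <- matrix(1, 6, 6)
    d[1:3, 1:3] <- 0
    d[4:6, 4:6] <- 0
    diag(d) <- 0
    dimnames(d) <- list(letters[1:6], letters[1:6])
    cl <- clusterModules(d, k = 2)
    expect_equal(length(unique(cl[1:3])), 1)
    expect_equal(length(unique(cl[4:6])), 1)
    expect_false(cl[1] == cl[4])
    # labels ordered by size then first member: both size 3 -> block with 'a' is 1
    expect_equal(unname(cl[1]), 1)

    singletons <- clusterModules(d, k = 6)
    expect_equal(sort(unique(singletons)), 1:6)
    expect_error(clusterModules(d, k = 1), "k")
    expect_error(clusterModules(d, k = 7), "k")
})

test_that("module recovery on planted block-correlated data", {
    ok <- 0L
    n_seeds <- 15
    for (s in seq_len(n_seeds)) {
        coh <- generateCohort(19, 16, seed = 500 + s)
        sim <- generateMetabolome(coh, n_features = 100,
            modules = data.frame(size = c(30, 25, 20, 15, 10),
                within_corr = 0.8),
            pathway_sizes = c(12, 12, 12, 11, 11, 11, 11, 10, 10),
            seed = 500 + s)
        pt <- paretoScale(logTransform(sim$table))
        net <- buildNetwork(pt)
        cl <- clusterModules(net@diss, k = 5)
        ari <- mclust::adjustedRandIndex(cl[featureIds(pt)],
            sim$truth$module_label)
        if (ari >= 0.8) ok <- ok + 1L
    }
    expect_gte(ok / n_seeds, 0.9)
})

test_that("eigenmetabolites equal brute-force PCA and orient consistently", {
    set.seed(23)
    x <- matrix(rnorm(35 * 10), 35, 10)
    pt <- pareto_of(x + 10)
    labels <- setNames(rep(1L, 10), featureIds(pt))
    ms <- eigenmetabolites(pt, labels)
    sc <- eigenmetaboliteScores(ms)[, 1]

    xm <- sweep(intensities(pt), 2, colMeans(intensities(pt)))
    ev <- eigen(xm %*% t(xm))
    ref <- ev$vectors[, 1]
    ref <- ref * sign(mean(cor(ref, xm)))
    expect_equal(unname(sc), ref, tolerance = 1e-8)
    expect_equal(sum(sc^2), 1)
    expect_equal(varExplained(ms)[1], ev$values[1] / sum(pmax(ev$values, 0)),
        tolerance = 1e-8)

    # negating all member columns leaves the oriented eigenmetabolite unchanged
    neg <- FeatureTable(-intensities(pt), stage = "pareto",
        paretoCenter = pt@paretoCenter, paretoScale = pt@paretoScale)
    ms2 <- eigenmetabolites(neg, labels)
    expect_equal(abs(cor(eigenmetaboliteScores(ms2)[, 1], sc)), 1,
        tolerance = 1e-8)

    # two identical features: eigenmetabolite is that feature, var = 1
    dup <- pareto_of(cbind(x[, 1], x[, 1]) + 10)
    msd <- eigenmetabolites(dup, setNames(c(1L, 1L), featureIds(dup)))
    expect_equal(varExplained(msd)[1], 1)
    expect_equal(abs(cor(eigenmetaboliteScores(msd)[, 1],
        intensities(dup)[, 1])), 1, tolerance = 1e-10)

    # single-feature module warns
    expect_warning(eigenmetabolites(pt,
        setNames(c(1L, rep(2L, 9)), featureIds(pt))), "single feature")
})

test_that("module-outcome association: statistics and separation flag", {
    set.seed(24)
    g <- rep(0:1, each = 10)
    x <- matrix(rnorm(20 * 6, 10), 20, 6)
    x[g == 1, 1:3] <- x[g == 1, 1:3] + 2
    pt <- paretoScale(logTransform(make_table(x)))
    coh <- data.frame(sample_id = sampleIds(pt), group = g)
    labels <- setNames(rep(1:2, each = 3), featureIds(pt))
    ms <- eigenmetabolites(pt, labels)
    assoc <- moduleOutcomeAssociation(ms, coh)
    expect_equal(nrow(assoc), 2)
    expect_true(all(is.finite(assoc$pearson_r)))
    expect_true(all((assoc$or_ > 1) == (assoc$logit_coef > 0)))
    expect_true(all(assoc$ci95_low <= assoc$or_ &
        assoc$or_ <= assoc$ci95_high))
    # cross-check the correlation p against cor.test
    ct <- cor.test(eigenmetaboliteScores(ms)[, 1], coh$group)
    expect_equal(assoc$pearson_p[1], ct$p.value)

    # perfectly separated toy design
    coh4 <- data.frame(sample_id = sprintf("S%02d", 1:4),
        group = c(0L, 0L, 1L, 1L))
    sep_scores <- matrix(c(-1, -1, 1, 1) / 2, 4, 1,
        dimnames = list(coh4$sample_id, "module1"))
    ms_sep <- new("ModuleSet",
        labels = setNames(1L, "f1"), eigenmetabolites = sep_scores,
        varExplained = 1, orientationSign = 1)
    a_sep <- moduleOutcomeAssociation(ms_sep, coh4)
    expect_true(a_sep$separation)
    expect_equal(a_sep$ci95_low, 0)
    expect_equal(a_sep$ci95_high, Inf)
})

test_that("feature permutation permutes module labels equivariantly", {
    coh <- generateCohort(8, 8, seed = 25)
    sim <- generateMetabolome(coh, n_features = 30,
        modules = data.frame(size = c(10, 10, 10), within_corr = 0.8),
        pathway_sizes = c(4, 4, 4, 3, 3, 3, 3, 3, 3), seed = 25)
    pt <- paretoScale(logTransform(sim$table))
    cl <- clusterModules(buildNetwork(pt)@diss, k = 3)

    set.seed(26)
    perm <- sample(30)
    ptp <- paretoScale(logTransform(
        FeatureTable(intensities(sim$table)[, perm], stage = "raw")))
    clp <- clusterModules(buildNetwork(ptp)@diss, k = 3)
    # same partition up to label names
    expect_equal(mclust::adjustedRandIndex(cl[featureIds(pt)],
        clp[featureIds(pt)]), 1)
})
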