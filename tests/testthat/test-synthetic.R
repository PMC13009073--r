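test_that("generateCohort sizes, creatinine distribution and determinism", {
    coh <- generateCohort(19, 16, seed = 3)
    expect_equal(nrow(coh), 35)
    expect_equal(sum(coh$group == 0), 19)
    expect_equal(sum(coh$group == 1), 16)
    expect_false(anyDuplicated(coh$sample_id) > 0)

    # zero spread: every creatinine equals exp(mu)
    c0 <- generateCohort(2, 2, creat_log_mean = log(120), creat_log_sd = 0,
        seed = 1)
    expect_equal(c0$urine_creatinine, rep(120, 4))

    # geometric mean recovers the log-normal median over 10,000 draws
    big <- generateCohort(5000, 5000, creat_log_mean = log(100),
        creat_log_sd = 0.3, seed = 11)
    gm <- exp(mean(log(big$urine_creatinine)))
    se <- 0.3 / sqrt(10000)
    expect_lt(abs(log(gm) - log(100)), 3 * se)

    expect_identical(generateCohort(5, 5, seed = 42),
        generateCohort(5, 5, seed = 42))
    expect_false(identical(generateCohort(5, 5, seed = 42),
        generateCohort(5, 5, seed = 43)))
    expect_error(generateCohort(1, 5), "at least 2")
})

test_that("generateMetabolome plants effects, modules and pathway sizes", {
    coh <- generateCohort(19, 16, seed = 1)
    sim <- generateMetabolome(coh, seed = 1)
    expect_identical(dim(sim$table), c(35L, 389L))
    expect_identical(stage(sim$table), "raw")
    expect_equal(unname(table(sim$truth$pathway_label)),
        c(22, 106, 74, 7, 108, 5, 8, 6, 53), ignore_attr = TRUE)
    expect_true(all(sim$truth$effect == 0))

    eff <- data.frame(feature = c(3, 10), d = c(1, -0.5))
    sim2 <- generateMetabolome(coh, n_features = 20,
        pathway_sizes = c(3, 3, 2, 2, 2, 2, 2, 2, 2), effects = eff, seed = 1)
    expect_equal(sim2$truth$effect[c(3, 10)], c(1, -0.5))
    expect_equal(sum(sim2$truth$effect != 0), 2)

    expect_error(generateMetabolome(coh, n_features = 10,
        pathway_sizes = rep(1, 9)), "summing")
    expect_error(generateMetabolome(coh, n_features = 9,
        pathway_sizes = rep(1, 9),
        modules = data.frame(size = 3, within_corr = 1.2)), "within_corr")
    expect_identical(generateMetabolome(coh, seed = 9),
        generateMetabolome(coh, seed = 9))
})

test_that("block-exchangeable correlation matches its target at large n", {
    coh <- generateCohort(500, 500, seed = 2)
    sim <- generateMetabolome(coh, n_features = 30,
        modules = data.frame(size = 10, within_corr = 0.8),
        pathway_sizes = c(4, 4, 4, 3, 3, 3, 3, 3, 3), seed = 2)
    z <- log(intensities(sim$table))        # latent scale
    r <- cor(z)
    within <- r[1:10, 1:10][upper.tri(diag(10))]
    between <- r[1:10, 11:30]
    expect_gt(mean(within), 0.75)
    expect_lt(mean(within), 0.85)
    expect_lt(mean(abs(between)), 0.05)
})

test_that("blank profiles plant exactly the requested contamination", {
    ft <- random_raw_table(10, 100, seed = 5)
    bp0 <- generateBlankProfile(ft, 0, seed = 1)
    expect_length(bp0$contaminated_ids, 0)
    expect_true(all(apply(intensities(ft), 2, max) / bp0$blank_means >= 10))

    bp1 <- generateBlankProfile(ft, 1, seed = 1)
    expect_equal(ncol(blankFilter(ft, bp1$blank_means)$table), 0)

    bp <- generateBlankProfile(ft, 0.2, seed = 7)
    expect_length(bp$contaminated_ids, 20)
    flt <- blankFilter(ft, bp$blank_means)
    expect_setequal(flt$report$feature_id[!flt$report$kept],
        bp$contaminated_ids)
})

test_that("generateEDC censors below LOQ and plants group multipliers", {
    coh <- generateCohort(5, 5, seed = 1)
    panel <- analytePanel()

    edc <- generateEDC(coh, panel, seed = 1)
    expect_true(all(edc$truth$case_multiplier == 1))
    expect_setequal(unique(edc$measurements$analyte), panel$analyte)

    # far above LOQ with tiny spread: no censoring
    gm <- setNames(rep(1000, nrow(panel)), panel$analyte)
    gs <- setNames(rep(1.0001, nrow(panel)), panel$analyte)
    clean <- generateEDC(coh, panel, geo_mean = gm, geo_sd = gs, seed = 2)
    expect_equal(sum(clean$measurements$below_loq), 0)

    # geometric mean at the LOQ: half the draws censor (log-normal median)
    big <- generateCohort(5000, 5000, seed = 3)
    half <- generateEDC(big, panel,
        geo_mean = c(Methylparaben = 0.5), seed = 3)
    frac <- mean(half$truth$censored[, "Methylparaben"])
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

    expect_error(generateEDC(coh, panel, geo_mean = c(Nonsense = 1)),
        "unknown analyte")
    expect_identical(generateEDC(coh, panel, seed = 8),
        generateEDC(coh, panel, seed = 8))
})
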