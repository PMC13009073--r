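# Small fixtures built in code; everything is seeded.

make_table <- function(values, stage = "raw") {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
    cn <- colnames(values)
    if (is.null(cn) || any(cn == ""))
        colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
    FeatureTable(values, stage = stage)
}

random_raw_table <- function(n = 8, p = 12, seed = 1) {
    set.seed(seed)
    make_table(matrix(rlnorm(n * p, meanlog = 8), n, p))
}

small_cohort <- function(n0 = 4, n1 = 4, seed = 1) {
    generateCohort(n0, n1, seed = seed)
}

# log -> pareto chain for tables constructed at the log stage
pareto_of <- function(values) {
    paretoScale(make_table(values, stage = "log"))
}

# hand one-way ANOVA oracle (two groups, equal variance)
anova_oracle <- function(y, g) {
    fit <- stats::anova(stats::lm(y ~ factor(g)))
    list(f = fit$`F value`[1], p = fit$`Pr(>F)`[1])
}

# direct-summation TOM oracle: explicit loops, no matrix algebra
tom_oracle <- function(a) {
    u <- abs(a)
    p <- nrow(u)
    k <- sapply(seq_len(p), function(i) sum(u[i, ]))
    tom <- diag(p)
    for (i in seq_len(p)) for (j in seq_len(p)) {
        if (i == j) next
        s <- 0
        for (l in seq_len(p)) s <- s + u[i, l] * u[l, j]
        tom[i, j] <- (s + u[i, j]) / (min(k[i], k[j]) + 1 - u[i, j])
    }
    tom
}

expect_rel_equal <- function(x, y, tol = 1e-9) {
    expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
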