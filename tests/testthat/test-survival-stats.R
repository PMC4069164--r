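test_that("median split follows the strict-below rule", {
    sp <- medianSplit(c(a = 1, b = 2, c = 3, d = 4))
    expect_equal(sp$median, 2.5)
    expect_identical(names(sp$labels)[sp$labels == "Low"], c("a", "b"))
    expect_identical(names(sp$labels)[sp$labels == "High"], c("c", "d"))
    # 108 distinct values -> 54 / 54
    v <- setNames(sample(108), sprintf("s%03d", 1:108))
    sp2 <- medianSplit(v)
    expect_equal(unname(table(sp2$labels)), c(54L, 54L),
                 ignore_attr = TRUE)
    # all-tied values: everyone at the median, i.e. High
    expect_warning(sp3 <- medianSplit(c(5, 5, 5)), "Low group is empty")
    expect_true(all(sp3$labels == "High"))
})

test_that("KM curves reproduce the product-limit estimator", {
    # no events: survival identically 1
    km0 <- kmCurve(c(3, 5, 9), c(0, 0, 0))
    expect_true(all(km0$survival == 1))
    # hand computation: (1,event), (2,censor), (3,event)
    km <- kmCurve(c(1, 2, 3), c(1, 0, 1))
    expect_equal(km$survival[km$time == 1], 2 / 3)
    expect_equal(km$survival[km$time == 3], 0)
    # duplicating every record doubles counts, survival unchanged
    t1 <- c(2, 4, 4, 7, 9); e1 <- c(1, 0, 1, 1, 0)
    a <- kmCurve(t1, e1); b <- kmCurve(rep(t1, 2), rep(e1, 2))
    expect_equal(b$survival, a$survival)
    expect_equal(b$n_risk, 2 * a$n_risk)
    # oracle equivalence on random small cohorts
    for (s in 1:10) {
        rc <- randomCohort(8, s)
        km <- kmCurve(rc$time, rc$event)
        orc <- oracleKM(rc$time, rc$event)
        expect_equal(km$survival, orc$survival[match(km$time, orc$time)],
                     tolerance = 1e-6)
    }
    expect_error(kmCurve(numeric(), integer()), "empty")
})

test_that("log-rank test matches the exhaustive O/E/V oracle", {
    # the two groups are copies of the same records -> chi2 = 0, p = 1
    t1 <- c(1, 2, 3, 4); e1 <- c(1, 1, 0, 1)
    lr0 <- logrankTest(rep(t1, 2), rep(e1, 2),
                       rep(c("A", "B"), each = 4))
    expect_equal(lr0$chi2, 0, tolerance = 1e-12)
    expect_equal(lr0$p, 1, tolerance = 1e-12)
    # small tie-free instances against the brute-force tabulation
    for (s in 1:10) {
        rc <- randomCohort(6, s + 100)
        if (sum(rc$event) == 0) next
        lr <- logrankTest(rc$time, rc$event, rc$group)
        orc <- oracleLogrank(rc$time, rc$event, rc$group)
        expect_equal(lr$chi2, orc$chi2, tolerance = 1e-6)
        expect_equal(lr$p, orc$p, tolerance = 1e-6)
        # invariance under group relabeling
        flipped <- factor(ifelse(rc$group == "A", "B", "A"))
        expect_equal(logrankTest(rc$time, rc$event, flipped)$chi2,
                     lr$chi2, tolerance = 1e-10)
    }
    expect_error(logrankTest(t1, e1, rep("A", 4)), "two non-empty")
})

test_that("log-rank equals the Cox score test at beta = 0 on tie-free data", {
    for (s in 1:5) {
        rc <- randomCohort(30, s + 200)
        lr <- logrankTest(rc$time, rc$event, rc$group)
        cf <- survival::coxph(
            survival::Surv(rc$time, rc$event) ~ I(rc$group == "B"))
        expect_equal(lr$chi2, unname(cf$score), tolerance = 1e-6)
    }
})

test_that("Cox fit matches a one-dimensional brute-force partial likelihood search", {
    for (s in 1:8) {
        rc <- randomCohort(8, s + 300)
        x <- as.integer(rc$group == "B")
        if (sum(rc$event) < 2 || length(unique(x[rc$event == 1])) < 2)
            next
        coh <- SurvivalCohort(sprintf("s%d", 1:8), rc$time, rc$event,
                              data.frame(g = factor(rc$group)))
        fit <- coxFit(coh, "g")
        if (!fit$converged) next   # separation on tiny samples
        expect_equal(fit$table$coef, oracleCoxCoef(rc$time, rc$event, x),
                     tolerance = 1e-6)
    }
})

test_that("Cox output reports HR with Wald intervals and flags degeneracies", {
    set.seed(7)
    n <- 120
    flags <- rep(c(0, 1), each = n / 2)
    coh <- generateSurvival(flags, beta = log(2.0), seed = 17)
    fit <- coxFit(coh, "group")
    expect_true(fit$converged)
    tab <- fit$table
    expect_equal(tab$hazard_ratio, exp(tab$coef))
    expect_equal(tab$ci_low, exp(tab$coef - 1.96 * tab$se))
    expect_equal(tab$ci_high, exp(tab$coef + 1.96 * tab$se))
    # invariance to time rescaling (months -> days)
    cohD <- SurvivalCohort(sampleIds(coh), survTime(coh) * 30.44,
                           survEvent(coh), covariates(coh))
    expect_equal(coxFit(cohD, "group")$table$coef, tab$coef,
                 tolerance = 1e-8)
    # null covariate: HR near 1, CI covering 1 in most replicates
    covered <- vapply(1:20, function(s) {
        set.seed(s)
        cohP <- SurvivalCohort(sampleIds(coh), survTime(coh),
                               survEvent(coh),
                               data.frame(g = factor(sample(covariates(coh)$group))))
        t2 <- coxFit(cohP, "g")$table
        t2$ci_low <= 1 && t2$ci_high >= 1
    }, NA)
    expect_gte(mean(covered), 0.9)
    # complete separation is flagged, not silently reported
    sep <- SurvivalCohort(sprintf("s%d", 1:6),
                          c(1, 2, 3, 10, 11, 12), rep(1L, 6),
                          data.frame(g = factor(rep(c("A", "B"),
                                                    each = 3))))
    expect_false(coxFit(sep, "g")$converged)
    expect_error(coxFit(coh, "nonexistent"), "unknown covariate")
})

test_that("chi-square test follows the Pearson formula without correction", {
    r0 <- chiSquare2xk(matrix(c(10, 10, 10, 10), 2))
    expect_equal(r0$chi2, 0); expect_equal(r0$p, 1)
    r1 <- chiSquare2xk(matrix(c(20, 5, 5, 20), 2))
    expect_equal(r1$chi2, 18, tolerance = 1e-12)
    expect_equal(r1$df, 1L, ignore_attr = TRUE)
    # swapping rows leaves the statistic unchanged
    r2 <- chiSquare2xk(matrix(c(5, 20, 20, 5), 2))
    expect_equal(r2$chi2, r1$chi2)
    expect_error(chiSquare2xk(matrix(c(0, 0, 3, 4), 2)), "marginal")
    expect_error(chiSquare2xk(matrix(c(1.5, 2, 3, 4), 2)), "integer")
})

test_that("the univariate screen applies the raw threshold rule", {
    set.seed(23)
    n <- 200
    prognostic <- rep(c(0, 1), each = n / 2)
    coh <- generateSurvival(prognostic, beta = log(3), seed = 29)
    covar <- covariates(coh)
    covar$noise <- factor(sample(c("x", "y"), n, replace = TRUE))
    covar$chemo <- factor(sample(c("Yes", "No", "Not sure"), n,
                                 replace = TRUE))
    coh2 <- SurvivalCohort(sampleIds(coh), survTime(coh), survEvent(coh),
                           covar)
    tab <- univariateScreen(coh2, c("group", "noise", "chemo"))
    expect_true(tab$selected[tab$factor == "group"])
    expect_false(tab$selected[tab$factor == "noise"])
    # excluded levels shrink the per-factor sample size
    expect_lt(tab$n_used[tab$factor == "chemo"], n)
    expect_error(univariateScreen(coh2, "missing_factor"), "unknown")
})
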