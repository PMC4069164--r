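test_that("marker masks encode exclusivity and drop ambiguous genes", {
    msc <- MarkerSetCollection(list(B = "a", T = "b"))
    m <- buildMarkerMask(msc, c("a", "b"))
    expect_identical(unname(m), matrix(c(TRUE, FALSE, FALSE, TRUE), 2))
    # a gene claimed by both sets is excluded from both
    msc2 <- MarkerSetCollection(list(B = c("a", "x"), T = c("b", "x")))
    expect_warning(m2 <- buildMarkerMask(msc2, c("a", "b", "x")),
                   "multiple cell types")
    expect_equal(nrow(m2), 2L)
    expect_false("x" %in% rownames(m2))
    # five-set scheme: every row has exactly one allowed column
    sig <- generateSignatures(c("B", "T", "NK", "DC", "Mono"), 4, 0,
                              seed = 1)
    m5 <- buildMarkerMask(sig$markerSets, rownames(sig$basis))
    expect_equal(ncol(m5), 5L)
    expect_true(all(rowSums(m5) == 1))
    # a type with no matched markers is an error naming the type
    expect_error(buildMarkerMask(msc, c("a", "zzz")), "T")
})

test_that("generalized KL divergence matches closed forms and the brute-force oracle", {
    sig <- generateSignatures(c("a", "b"), 3, 2, seed = 5)
    mix <- generateMixtures(sig, 4, noiseSd = 0, seed = 6)
    W <- sig$basis; H <- trueProportions(mix)
    expect_equal(klDivergence(exprs(mix), W, H), 0)
    # scalar closed form: x=1, y=e -> e - 2
    expect_equal(klDivergence(matrix(1), matrix(exp(1)), matrix(1)),
                 exp(1) - 2, tolerance = 1e-12)
    # moving y away from x strictly increases divergence (convexity)
    d1 <- klDivergence(matrix(2), matrix(3), matrix(1))
    d2 <- klDivergence(matrix(2), matrix(6), matrix(1))
    expect_gt(d2, d1)
    # zero model mass where data is positive -> infinite divergence
    expect_identical(klDivergence(matrix(1), matrix(0), matrix(1)), Inf)
    # random instances agree with the elementwise oracle
    for (s in 1:5) {
        set.seed(s)
        X <- matrix(runif(12, 0, 5), 3)
        W2 <- matrix(runif(6, 0.1, 2), 3)
        H2 <- matrix(runif(8, 0.1, 2), 2)
        expect_equal(klDivergence(X, W2, H2), oracleKL(X, W2, H2),
                     tolerance = 1e-12)
    }
})

test_that("multiplicative updates are monotone, mask-preserving and fixed at the optimum", {
    sig <- generateSignatures(c("a", "b", "c"), 4, 0, seed = 2)
    mix <- generateMixtures(sig, 6, noiseSd = 0, seed = 3)
    X <- exprs(mix)
    mask <- buildMarkerMask(sig$markerSets, rownames(X))
    # exact factorization is a fixed point
    W <- sig$basis; H <- trueProportions(mix)
    upd <- klUpdateStep(W, H, X, mask)
    expect_equal(upd$W, W, tolerance = 1e-10)
    expect_equal(upd$H, H, tolerance = 1e-10)
    # divergence non-increasing over 50 sweeps from a random start
    set.seed(4)
    ini <- deconvInitialize(X, mask, seed = 4)
    W <- ini$W; H <- ini$H
    d <- klDivergence(X, W, H)
    tolAbs <- 1e-8 * (d + 1)   # round-off floor set by the problem scale
    for (it in 1:50) {
        upd <- klUpdateStep(W, H, X, mask)
        W <- upd$W; H <- upd$H
        dNew <- klDivergence(X, W, H)
        expect_lte(dNew, d + tolAbs)
        d <- dNew
    }
    # masked entries stay exactly zero across 100 sweeps
    for (it in 1:100) {
        upd <- klUpdateStep(W, H, X, mask)
        W <- upd$W; H <- upd$H
    }
    expect_true(all(W[!mask] == 0))
})

test_that("initialization is seeded, masked and sensibly scaled", {
    sig <- generateSignatures(c("a", "b"), 5, 5, seed = 7)
    mix <- generateMixtures(sig, 8, noiseSd = 10, seed = 8)
    X <- exprs(mix)
    mask <- buildMarkerMask(sig$markerSets, rownames(X))
    Xm <- X[rownames(mask), ]
    i1 <- deconvInitialize(Xm, mask, seed = 11)
    i2 <- deconvInitialize(Xm, mask, seed = 11)
    expect_identical(i1, i2)
    expect_true(all(i1$W[!mask] == 0))
    ratio <- mean(i1$W %*% i1$H) / mean(Xm)
    expect_gte(ratio, 0.5); expect_lte(ratio, 2)
    expect_error(deconvInitialize(matrix(0, 2, 2), mask, 1), "zero")
})

test_that("noiseless mixtures are recovered against the least-squares oracle", {
    sig <- generateSignatures(c("B", "T", "NK"), 10, 0, seed = 21)
    mix <- generateMixtures(sig, 15, noiseSd = 0, seed = 22)
    fit <- deconvolve(exprs(mix), markerSets(mix), nRestarts = 3, seed = 1)
    oracle <- oracleNoiselessProportions(exprs(mix), sig$basis)
    expect_lt(oracleMad(oracle, proportions(fit)), 0.01)
    expect_lt(oracleMad(trueProportions(mix), proportions(fit)), 0.01)
    expect_lt(tail(divergenceTrace(fit), 1), 1e-6)
})

test_that("fit results satisfy their structural invariants", {
    sig <- generateSignatures(c("B", "T", "NK", "DC"), 8, 0, seed = 31)
    mix <- generateMixtures(sig, 12, noiseSd = 30, seed = 32)
    fit <- deconvolve(exprs(mix), markerSets(mix), nRestarts = 5, seed = 2)
    P <- proportions(fit)
    expect_true(all(P >= 0))
    expect_true(all(abs(colSums(P) - 1) < 1e-9))
    expect_true(all(basisMatrix(fit)[!fit@mask] == 0))
    d <- divergenceTrace(fit)
    expect_true(all(diff(d) <= 1e-8 * (d[1] + 1)))
    # more restarts can only improve the attained divergence
    fit1 <- deconvolve(exprs(mix), markerSets(mix), nRestarts = 1, seed = 2)
    expect_lte(tail(divergenceTrace(fit), 1),
               tail(divergenceTrace(fit1), 1) * (1 + 1e-8))
    # scale invariance: proportions unchanged when X is rescaled
    fitC <- deconvolve(exprs(mix) * 7.5, markerSets(mix), nRestarts = 5,
                       seed = 2)
    expect_equal(proportions(fitC), P, tolerance = 1e-4)
})

test_that("recovery metrics match their textbook definitions", {
    set.seed(41)
    a <- matrix(runif(20), 4); a <- sweep(a, 2, colSums(a), "/")
    expect_equal(evaluateRecovery(a, a), list(mad = 0, pearson_r = 1))
    shifted <- a + 0.1
    expect_equal(evaluateRecovery(a, shifted)$mad, 0.1, tolerance = 1e-12)
    b <- matrix(runif(20), 4)
    r <- evaluateRecovery(a, b)
    expect_equal(r$mad, oracleMad(a, b), tolerance = 1e-12)
    expect_equal(r$pearson_r, oraclePearson(a, b), tolerance = 1e-12)
    expect_warning(r0 <- evaluateRecovery(matrix(1, 2, 2), b[1:2, 1:2]),
                   "undefined")
    expect_true(is.na(r0$pearson_r))
    expect_error(evaluateRecovery(a, b[1:2, ]), "dimensions")
})

test_that("recovery degrades with noise but stays calibrated on average", {
    types <- c("B", "T", "NK")
    madAt <- function(noiseSd) {
        mean(vapply(1:3, function(s) {
            sig <- generateSignatures(types, seed = s)
            mix <- generateMixtures(sig, 15, noiseSd = noiseSd,
                                    seed = s + 50)
            fit <- deconvolve(exprs(mix), markerSets(mix), nRestarts = 3,
                              seed = s)
            evaluateRecovery(trueProportions(mix), proportions(fit))$mad
        }, 0))
    }
    m0 <- madAt(0); m1 <- madAt(30); m2 <- madAt(150)
    expect_lt(m0, 0.01)
    expect_lte(m0, m1 + 1e-9)
    expect_lt(m1, m2)
})
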