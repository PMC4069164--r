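# Independent brute-force oracles, deliberately naive implementations:
# elementwise loops and direct textbook formulas, no shared code with the
# package internals or with the survival package.

oracleKL <- function(X, W, H) {
    Y <- W %*% H
    d <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(ncol(X))) {
        x <- X[i, j]; y <- Y[i, j]
        if (x > 0) {
            if (y == 0) return(Inf)
            d <- d + x * log(x / y) - x + y
        } else d <- d + y
    }
    d
}

oracleMad <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    s <- 0
    for (k in seq_along(a)) s <- s + abs(a[k] - b[k])
    s / length(a)
}

oraclePearson <- function(a, b) {
    a <- as.vector(a); b <- as.vector(b)
    ma <- sum(a) / length(a); mb <- sum(b) / length(b)
    num <- sum((a - ma) * (b - mb))
    num / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# Product-limit estimator by direct tabulation.
oracleKM <- function(time, event) {
    ut <- sort(unique(time))
    surv <- numeric(length(ut)); s <- 1
    for (k in seq_along(ut)) {
        atRisk <- sum(time >= ut[k])
        d <- sum(time == ut[k] & event == 1)
        if (atRisk > 0) s <- s * (1 - d / atRisk)
        surv[k] <- s
    }
    data.frame(time = ut, survival = surv)
}

# Two-group log-rank by explicit O/E/V tabulation at each event time.
oracleLogrank <- function(time, event, group) {
    g <- as.integer(as.factor(group))   # 1/2
    ts <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (tk in ts) {
        n <- sum(time >= tk)
        n1 <- sum(time >= tk & g == 1L)
        d <- sum(time == tk & event == 1)
        d1 <- sum(time == tk & event == 1 & g == 1L)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1)
            V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    chi2 <- (O - E)^2 / V
    list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Exact Cox log partial likelihood for one binary covariate, no ties.
oracleCoxLoglik <- function(beta, time, event, x) {
    ll <- 0
    for (i in which(event == 1)) {
        risk <- time >= time[i]
        ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
}

oracleCoxCoef <- function(time, event, x) {
    stats::optimize(oracleCoxLoglik, c(-10, 10), maximum = TRUE,
                    time = time, event = event, x = x,
                    tol = 1e-10)$maximum
}

# Unconstrained least squares on a noiseless mixture given the true
# basis, columns then normalized to the simplex: exact on noiseless data.
oracleNoiselessProportions <- function(X, basis) {
    H <- solve(crossprod(basis), crossprod(basis, X))
    sweep(H, 2L, colSums(H), "/")
}

# Small random tie-free cohort for oracle comparisons.
randomCohort <- function(n, seed, eventProb = 0.7) {
    set.seed(seed)
    list(time = round(rexp(n, 0.05), 6) + seq_len(n) * 1e-4,  # tie-free
         event = rbinom(n, 1, eventProb),
         group = factor(rep(c("A", "B"), length.out = n)))
}
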