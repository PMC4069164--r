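#' @include methods-accessors.R
#' @importFrom survival Surv survfit survdiff coxph
NULL

#' Median split of a per-sample statistic into Low/High groups
#'
#' Samples strictly below the sample median are labeled Low, samples at
#' or above it High. For even n the median is the mean of the two
#' central order statistics. When all values are identical every sample
#' is High (the median equals every value) and a warning is issued.
#'
#' @param values named numeric vector (one value per sample, finite).
#' @return list with `labels` (factor, levels c("Low","High"), named as
#'   `values`) and `median` (the split value).
#' @examples
#' medianSplit(c(a = 1, b = 2, c = 3, d = 4))
#' @export
medianSplit <- function(values) {
    if (length(values) < 2L) stop("need at least 2 samples to split")
    if (any(!is.finite(values))) stop("values must be finite")
    m <- stats::median(values)
    lab <- factor(ifelse(values < m, "Low", "High"),
                  levels = c("Low", "High"))
    names(lab) <- names(values)
    if (all(lab == "High"))
        warning("all values at or above the median; Low group is empty")
    list(labels = lab, median = m)
}

#' Kaplan-Meier product-limit curve
#'
#' S(t) = prod over event times t_i <= t of (1 - d_i / n_i), with d_i
#' events among n_i at risk. Computed via [survival::survfit()].
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicator.
#' @return data.frame with columns `time` (distinct observed times),
#'   `n_risk`, `n_event`, `n_censor` and `survival`.
#' @export
kmCurve <- function(time, event) {
    if (length(time) == 0L) stop("empty group: no records for KM curve")
    if (any(time < 0)) stop("negative survival time")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                             conf.type = "none")
    data.frame(time = fit$time, n_risk = fit$n.risk,
               n_event = fit$n.event, n_censor = fit$n.censor,
               survival = fit$surv)
}

#' Two-group (or k-group) log-rank test
#'
#' Standard log-rank comparison of survival distributions, chi-square
#' statistic with k - 1 degrees of freedom, via [survival::survdiff()].
#'
#' @param time,event survival outcome vectors.
#' @param group factor of group membership (every level non-empty).
#' @return list with `chi2`, `df` and `p`.
#' @export
logrankTest <- function(time, event, group) {
    group <- droplevels(as.factor(group))
    if (nlevels(group) < 2L)
        stop("log-rank test needs at least two non-empty groups")
    if (sum(event) == 0L) stop("no events observed; log-rank undefined")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
    df <- length(sd$n) - 1L
    list(chi2 = unname(sd$chisq), df = df,
         p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Multivariate Cox proportional-hazards fit
#'
#' Maximizes the Efron-tie-corrected partial likelihood by
#' Newton-Raphson ([survival::coxph()]) and reports, per coefficient,
#' the hazard ratio with Wald 95% confidence interval
#' exp(coef +/- 1.96 se) and Wald p-value. Non-convergence or a
#' monotone likelihood (complete separation, recognisable by an
#' exploding standard error) sets `converged = FALSE` rather than
#' failing silently.
#'
#' @param cohort a [SurvivalCohort-class]
#' @param covariateNames columns of `covariates(cohort)` to include;
#'   factors are dummy-coded against their first level.
#' @param data optional extra per-sample columns (e.g. a median-split
#'   grouping) cbound to the cohort covariates before selection.
#' @return list with `table` (data.frame: term, coef, se, hazard_ratio,
#'   ci_low, ci_high, p), `loglik` (at the optimum), `converged`.
#' @export
coxFit <- function(cohort, covariateNames, data = NULL) {
    stopifnot(is(cohort, "SurvivalCohort"))
    if (sum(survEvent(cohort)) == 0L) stop("no events: Cox fit undefined")
    covar <- covariates(cohort)
    if (!is.null(data)) covar <- cbind(covar, data)
    miss <- setdiff(covariateNames, colnames(covar))
    if (length(miss)) stop("unknown covariate(s): ",
                           paste(miss, collapse = ", "))
    d <- covar[, covariateNames, drop = FALSE]
    for (cc in covariateNames) {
        v <- d[[cc]]
        if (is.factor(v)) v <- droplevels(v)
        if ((is.factor(v) && nlevels(v) < 2L) ||
            (!is.factor(v) && length(unique(v)) < 2L))
            stop("covariate '", cc, "' is constant")
        d[[cc]] <- v
    }
    d$..time <- survTime(cohort)
    d$..event <- survEvent(cohort)
    fml <- stats::as.formula(paste("survival::Surv(..time, ..event) ~",
                                   paste(sprintf("`%s`", covariateNames),
                                         collapse = " + ")))
    converged <- TRUE
    fit <- withCallingHandlers(
        survival::coxph(fml, data = d, ties = "efron"),
        warning = function(w) {
            if (grepl("converge|infinite|singular", conditionMessage(w)))
                converged <<- FALSE
            invokeRestart("muffleWarning")
        })
    sm <- summary(fit)
    co <- sm$coefficients
    if (any(!is.finite(co[, "se(coef)"])) || any(co[, "se(coef)"] > 1e3))
        converged <- FALSE
    tab <- data.frame(term = rownames(co),
                      coef = co[, "coef"],
                      se = co[, "se(coef)"],
                      hazard_ratio = exp(co[, "coef"]),
                      ci_low = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
                      ci_high = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
                      p = co[, "Pr(>|z|)"],
                      row.names = NULL, stringsAsFactors = FALSE)
    list(table = tab, loglik = fit$loglik[2L], converged = converged)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction, df = (rows - 1)(cols - 1). All row and
#' column marginals must be positive.
#'
#' @param tab matrix of non-negative integer counts.
#' @return list with `chi2`, `df`, `p`.
#' @examples
#' chiSquare2xk(matrix(c(20, 5, 5, 20), 2))
#' @export
chiSquare2xk <- function(tab) {
    tab <- as.matrix(tab)
    if (any(tab < 0) || any(tab != round(tab)))
        stop("contingency table must hold non-negative integer counts")
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
        stop("zero marginal in contingency table")
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
         p = unname(ct$p.value))
}

#' Univariate log-rank screen of candidate prognostic factors
#'
#' Runs a log-rank test of overall survival against each candidate
#' factor and selects those with p below `alpha` (raw, no
#' multiple-testing adjustment — each factor is screened on its own)
#' for the subsequent multivariate model. Levels listed in
#' `excludeLevels` (e.g. "Not sure") are removed from that factor's test
#' but the samples stay in the cohort for other factors.
#'
#' @param cohort a [SurvivalCohort-class]
#' @param factorNames covariate columns to screen.
#' @param alpha significance threshold (default .05).
#' @param excludeLevels factor levels ignored per test.
#' @return data.frame with columns factor, n_used, df, chi2, p, selected.
#' @export
univariateScreen <- function(cohort, factorNames, alpha = 0.05,
                             excludeLevels = c("Not sure", "NA")) {
    stopifnot(is(cohort, "SurvivalCohort"), alpha > 0, alpha < 1)
    covar <- covariates(cohort)
    rows <- lapply(factorNames, function(fn) {
        if (!fn %in% colnames(covar))
            stop("unknown factor: ", fn)
        g <- as.factor(covar[[fn]])
        keep <- !(as.character(g) %in% excludeLevels)
        g <- droplevels(g[keep])
        if (nlevels(g) < 2L)
            return(data.frame(factor = fn, n_used = sum(keep),
                              df = NA_integer_, chi2 = NA_real_,
                              p = NA_real_, selected = FALSE))
        lr <- logrankTest(survTime(cohort)[keep], survEvent(cohort)[keep], g)
        data.frame(factor = fn, n_used = sum(keep), df = lr$df,
                   chi2 = lr$chi2, p = lr$p, selected = lr$p < alpha)
    })
    do.call(rbind, rows)
}
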