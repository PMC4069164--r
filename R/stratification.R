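#' @include survival-stats.R
NULL

#' Euclidean distance between two samples over a gene panel
#'
#' d(u, v) = sqrt(sum_g (e_gu - e_gv)^2) over the m panel genes.
#'
#' @param u,v numeric vectors of equal length (>= 1).
#' @return non-negative scalar.
#' @examples
#' euclideanDistance(c(0, 0), c(3, 4))  # 5
#' @export
euclideanDistance <- function(u, v) {
    if (length(u) != length(v) || length(u) < 1L)
        stop("vectors must have equal positive length")
    sqrt(sum((u - v)^2))
}

## One Lloyd run from given initial centroids; returns assignment,
## centroids, per-iteration objective. An emptied cluster is re-seeded at
## the point farthest from the surviving centroid.
.lloydTwo <- function(P, init, maxIter) {
    cen <- P[init, , drop = FALSE]
    trace <- numeric(0)
    assign <- rep(0L, nrow(P))
    for (it in seq_len(maxIter)) {
        d1 <- rowSums(sweep(P, 2L, cen[1L, ])^2)
        d2 <- rowSums(sweep(P, 2L, cen[2L, ])^2)
        newAssign <- ifelse(d1 <= d2, 1L, 2L)
        for (k in 1:2) {
            if (!any(newAssign == k)) {
                far <- which.max(if (k == 1L) d2 else d1)
                newAssign[far] <- k
            }
        }
        trace[it] <- sum(pmin(d1, d2))
        if (all(newAssign == assign)) break
        assign <- newAssign
        cen <- rbind(colMeans(P[assign == 1L, , drop = FALSE]),
                     colMeans(P[assign == 2L, , drop = FALSE]))
    }
    wss <- sum((P - cen[assign, , drop = FALSE])^2)
    list(assign = assign, centroids = cen, wss = wss, trace = trace,
         nIter = length(trace))
}

#' Two-means clustering of samples on an expression panel
#'
#' Lloyd's algorithm with k = 2 and Euclidean distance, run from
#' `nRestarts` seeded random initializations (two distinct samples as
#' starting centroids); the run with the smallest within-cluster sum of
#' squares is kept. The cluster whose centroid has the smaller mean
#' across the panel genes is labeled Low (see [labelLowHigh()]).
#'
#' @param panel samples x genes numeric matrix (rownames = sample IDs).
#' @param nRestarts seeded restarts (default 25).
#' @param maxIter Lloyd iteration cap per restart.
#' @param seed base seed; restart k uses seed + k - 1.
#' @return a [StratificationResult-class]
#' @examples
#' pan <- generateMhcPanel(40, separation = 6, seed = 2)
#' res <- kmeansTwo(t(pan$expression), seed = 1)
#' table(groupLabels(res), pan$trueLabels)
#' @export
kmeansTwo <- function(panel, nRestarts = 25L, maxIter = 100L, seed = 1L) {
    P <- as.matrix(panel)
    if (nrow(P) < 2L) stop("need at least two samples")
    if (nrow(unique(P)) < 2L) stop("all samples identical; cannot split")
    best <- NULL
    for (k in seq_len(nRestarts)) {
        set.seed(as.integer(seed) + k - 1L)
        init <- sample.int(nrow(P), 2L)
        while (identical(P[init[1L], ], P[init[2L], ]))
            init[2L] <- sample.int(nrow(P), 1L)
        run <- .lloydTwo(P, init, maxIter)
        if (is.null(best) || run$wss < best$wss) best <- run
    }
    res <- new("StratificationResult",
               labels = factor(c("Low", "High")[best$assign],
                               levels = c("Low", "High")),
               centroids = best$centroids, withinss = best$wss,
               objectiveTrace = best$trace,
               nIter = as.integer(best$nIter), seed = as.integer(seed))
    res@labels <- stats::setNames(res@labels, rownames(P))
    labelLowHigh(res)
}

#' Label the two clusters Low/High by centroid mean
#'
#' The cluster whose centroid has the smaller mean over the panel genes
#' becomes Low; ties (equal centroid means) are broken toward the
#' smaller cluster, with a message. Idempotent and invariant to the
#' original cluster indexing.
#'
#' @param result a [StratificationResult-class]
#' @return the relabeled [StratificationResult-class]
#' @export
labelLowHigh <- function(result) {
    stopifnot(is(result, "StratificationResult"))
    m <- rowMeans(result@centroids)
    if (m[1L] == m[2L]) {
        message("equal centroid means; labeling the smaller cluster Low")
        lowIdx <- which.min(table(result@labels))
    } else lowIdx <- which.min(m)
    if (lowIdx != 1L) {   # swap so row 1 / label "Low" is the low cluster
        nm <- names(result@labels)
        result@labels <- factor(
            ifelse(result@labels == "Low", "High", "Low"),
            levels = c("Low", "High"))
        names(result@labels) <- nm
        result@centroids <- result@centroids[2:1, , drop = FALSE]
    }
    rownames(result@centroids) <- c("Low", "High")
    validObject(result)
    result
}

#' Stratify a tissue cohort on a gene panel and test prognosis
#'
#' Composes the tissue-arm analysis: two-means clustering of samples on
#' the panel, Low/High labeling, log-rank comparison of overall survival
#' between the groups, multivariate Cox adjusting for the supplied
#' clinical covariates, and (when relapse status is available) a
#' chi-square test of the label x relapse table. Samples with unknown
#' relapse are excluded from the chi-square only.
#'
#' @param exprPanel genes x samples matrix restricted to the panel genes.
#' @param cohort a [SurvivalCohort-class]; sample IDs must cover the
#'   expression columns.
#' @param adjustFor covariate columns for the multivariate Cox model
#'   (default stage and age group).
#' @param relapseColumn optional name of a covariate column holding
#'   relapse status; values in `excludeLevels` are treated as unknown.
#' @param excludeLevels levels meaning "unknown" for the relapse test.
#' @param nRestarts,seed passed to [kmeansTwo()].
#' @return list with `stratification` (the
#'   [StratificationResult-class]), `logrank`, `cox` and (optionally)
#'   `chisq_relapse` including the underlying contingency table.
#' @export
stratifyAndTest <- function(exprPanel, cohort, adjustFor = c("stage", "age"),
                            relapseColumn = NULL,
                            excludeLevels = c("Not sure", "NA", "Unknown"),
                            nRestarts = 25L, seed = 1L) {
    stopifnot(is(cohort, "SurvivalCohort"))
    ids <- colnames(exprPanel)
    missing <- setdiff(ids, sampleIds(cohort))
    if (length(missing))
        stop("samples absent from the clinical table: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    cohort <- cohort[ids]
    strat <- kmeansTwo(t(exprPanel), nRestarts = nRestarts, seed = seed)
    lab <- groupLabels(strat)
    lr <- logrankTest(survTime(cohort), survEvent(cohort), lab)
    grp <- data.frame(mhc_group = factor(lab, levels = c("High", "Low")),
                      row.names = sampleIds(cohort))
    cox <- coxFit(cohort, c("mhc_group", adjustFor), data = grp)
    out <- list(stratification = strat, logrank = lr, cox = cox)
    if (!is.null(relapseColumn)) {
        rel <- as.character(covariates(cohort)[[relapseColumn]])
        keep <- !(rel %in% excludeLevels) & !is.na(rel)
        tab <- table(label = factor(lab[keep], levels = c("Low", "High")),
                     relapse = rel[keep])
        out$chisq_relapse <- c(chiSquare2xk(unclass(tab)),
                               list(table = tab, n_excluded = sum(!keep)))
    }
    out
}
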