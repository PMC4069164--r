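#' @include methods-accessors.R
NULL

## Allowed basis entries are floored at this value during the
## multiplicative updates so the support never collapses numerically.
.NMF_FLOOR <- 1e-12

#' Build the marker mask constraining the basis matrix
#'
#' Semi-supervision device of the deconvolution: entry (i, t) of the mask
#' is TRUE iff gene i may have non-zero expression in cell type t. In the
#' default markers-only design, rows are restricted to the union of
#' marker genes found in `geneIds`, and each marker row allows exactly
#' its owning type. Genes claimed by two or more sets are ambiguous and
#' dropped with a warning; marker genes absent from `geneIds` are dropped
#' with a message.
#'
#' @param markers a [MarkerSetCollection-class]
#' @param geneIds gene identifiers available in the expression matrix
#'   (case-sensitive matching).
#' @return logical matrix, matched marker genes x cell types; each row
#'   has exactly one TRUE.
#' @examples
#' msc <- MarkerSetCollection(list(B = "a", T = "b"))
#' buildMarkerMask(msc, c("a", "b", "c"))
#' @export
buildMarkerMask <- function(markers, geneIds) {
    stopifnot(is(markers, "MarkerSetCollection"))
    types <- cellTypes(markers)
    sets <- lapply(markers@sets, intersect, geneIds)
    allMarkers <- unlist(sets, use.names = FALSE)
    dup <- unique(allMarkers[duplicated(allMarkers)])
    if (length(dup)) {
        warning(sprintf("%d marker gene(s) claimed by multiple cell types dropped: %s",
                        length(dup), paste(utils::head(dup, 5L), collapse = ", ")))
        sets <- lapply(sets, setdiff, dup)
    }
    nDropped <- sum(lengths(markers@sets)) - sum(lengths(sets)) - length(dup)
    if (nDropped > 0L)
        message(nDropped, " marker gene(s) not present in the expression matrix")
    empty <- types[lengths(sets) == 0L]
    if (length(empty))
        stop("no usable marker genes matched for cell type(s): ",
             paste(empty, collapse = ", "))
    rows <- geneIds[geneIds %in% unlist(sets, use.names = FALSE)]
    mask <- matrix(FALSE, length(rows), length(types),
                   dimnames = list(rows, types))
    for (t in types) mask[sets[[t]], t] <- TRUE
    mask
}

#' Generalized Kullback-Leibler divergence of a factorization
#'
#' D(X || WH) = sum_ij x_ij log(x_ij / y_ij) - x_ij + y_ij with y = WH and
#' the convention 0 log 0 = 0. Zero iff X = WH; infinite if some y_ij = 0
#' where x_ij > 0.
#'
#' @param X non-negative data matrix.
#' @param W,H non-negative factors with conformable dimensions.
#' @return non-negative scalar (possibly `Inf`).
#' @examples
#' X <- matrix(1); klDivergence(X, matrix(exp(1)), matrix(1))  # e - 2
#' @export
klDivergence <- function(X, W, H) {
    Y <- W %*% H
    if (any(X < 0) || any(Y < 0)) stop("factors and data must be non-negative")
    pos <- X > 0
    if (any(Y[pos] == 0)) return(Inf)
    d <- sum(X[pos] * log(X[pos] / Y[pos])) - sum(X) + sum(Y)
    max(d, 0)   # guard tiny negative round-off at the optimum
}

#' One masked multiplicative KL update
#'
#' Standard Lee-Seung updates for the generalized KL objective, H first
#' then W, with the marker constraint re-imposed after the W update
#' (disallowed entries forced to exactly zero) and allowed entries
#' floored at 1e-12 against underflow. Each sweep does not increase
#' D(X || WH).
#'
#' @param W,H current non-negative factors (allowed support strictly
#'   positive).
#' @param X non-negative data matrix.
#' @param mask logical genes x types matrix of allowed basis support.
#' @return list with updated `W` and `H`.
#' @export
klUpdateStep <- function(W, H, X, mask) {
    WH <- W %*% H
    H <- H * (t(W) %*% (X / pmax(WH, .NMF_FLOOR))) / pmax(colSums(W), .NMF_FLOOR)
    WH <- W %*% H
    W <- W * ((X / pmax(WH, .NMF_FLOOR)) %*% t(H)) /
        pmax(matrix(rowSums(H), nrow(W), ncol(W), byrow = TRUE), .NMF_FLOOR)
    W[!mask] <- 0
    W[mask] <- pmax(W[mask], .NMF_FLOOR)
    H <- pmax(H, .NMF_FLOOR)
    list(W = W, H = H)
}

#' Seeded random initialization of the factors
#'
#' Entries i.i.d. uniform on (eps, 1), jointly rescaled so that
#' mean(W0 H0) matches mean(X); entries disallowed by the mask are zeroed.
#'
#' @param X non-negative data matrix (not all zero).
#' @param mask logical genes x types support matrix.
#' @param seed integer seed.
#' @param eps lower bound of the uniform draw.
#' @return list with `W` and `H`.
#' @export
deconvInitialize <- function(X, mask, seed, eps = 1e-3) {
    if (all(X == 0)) stop("expression matrix is all zero")
    r <- ncol(mask)
    set.seed(as.integer(seed))
    W <- matrix(stats::runif(nrow(X) * r, eps, 1), nrow(X), r,
                dimnames = list(rownames(X), colnames(mask)))
    H <- matrix(stats::runif(r * ncol(X), eps, 1), r, ncol(X),
                dimnames = list(colnames(mask), colnames(X)))
    W[!mask] <- 0
    s <- sqrt(mean(X) / mean(W %*% H))
    list(W = W * s, H = H * s)
}

#' Estimate cell-type proportions by marker-constrained KL-NMF
#'
#' Fits the approximate decomposition X ~ W H, with W constrained so each
#' marker gene loads only on its own cell type, by multiplicative updates
#' minimizing the generalized Kullback-Leibler divergence. Multiple
#' seeded restarts are run and the lowest-divergence fit kept. At output
#' the per-type scale freedom of the factorization is fixed by rescaling
#' each basis column to unit mean over that type's marker genes (a
#' KL-invariant transformation), after which each column of H is rescaled
#' to sum to one: these are the estimated cell-type proportions, under
#' the convention that the cell types jointly make up 100% of the sample.
#'
#' @param X non-negative genes x samples matrix with dimnames.
#' @param markers a [MarkerSetCollection-class]; the factorization rank is
#'   the number of cell types.
#' @param mode `"markers_only"` (default) restricts the fit to the
#'   matched marker genes; `"all_genes"` retains all rows, non-marker
#'   rows unconstrained.
#' @param maxIter maximum multiplicative sweeps per restart.
#' @param tol relative divergence-change convergence threshold.
#' @param nRestarts number of seeded random restarts.
#' @param seed base seed; restart k uses seed + k - 1.
#' @return a [DeconvolutionResult-class]
#' @examples
#' sig <- generateSignatures(c("B", "T", "NK"), 5, 0, seed = 1)
#' mix <- generateMixtures(sig, 10, noiseSd = 0, seed = 2)
#' fit <- deconvolve(exprs(mix), markerSets(mix), nRestarts = 2, seed = 5)
#' evaluateRecovery(trueProportions(mix), proportions(fit))
#' @export
deconvolve <- function(X, markers, mode = c("markers_only", "all_genes"),
                       maxIter = 2000L, tol = 1e-6, nRestarts = 10L,
                       seed = 42L) {
    mode <- match.arg(mode)
    .checkExpressionMatrix(X)
    if (maxIter < 1L) stop("maxIter must be >= 1")
    markerMask <- buildMarkerMask(markers, rownames(X))
    if (mode == "markers_only") {
        mask <- markerMask
    } else {
        others <- setdiff(rownames(X), rownames(markerMask))
        free <- matrix(TRUE, length(others), ncol(markerMask),
                       dimnames = list(others, colnames(markerMask)))
        mask <- rbind(markerMask, free)
        mask <- mask[rownames(X)[rownames(X) %in% rownames(mask)], ,
                     drop = FALSE]
    }
    Xf <- X[rownames(mask), , drop = FALSE]
    if (all(Xf == 0)) stop("expression on the fitted gene set is all zero")

    best <- NULL
    for (k in seq_len(nRestarts)) {
        init <- deconvInitialize(Xf, mask, seed = as.integer(seed) + k - 1L)
        W <- init$W; H <- init$H
        trace <- numeric(0)
        dPrev <- klDivergence(Xf, W, H)
        for (it in seq_len(maxIter)) {
            upd <- klUpdateStep(W, H, Xf, mask)
            W <- upd$W; H <- upd$H
            d <- klDivergence(Xf, W, H)
            trace[it] <- d
            if (!is.finite(d)) break
            if (abs(dPrev - d) / max(dPrev, .NMF_FLOOR) < tol) {
                dPrev <- d
                break
            }
            dPrev <- d
        }
        if (!is.finite(dPrev)) next
        if (is.null(best) || dPrev < best$d)
            best <- list(W = W, H = H, d = dPrev, trace = trace,
                         nIter = length(trace))
    }
    if (is.null(best))
        stop("deconvolution failed: non-finite divergence in every restart",
             " (", nRestarts, " tried)")

    W <- best$W; H <- best$H
    ## gauge fix: unit mean basis over each type's own marker genes
    for (t in colnames(markerMask)) {
        mg <- rownames(markerMask)[markerMask[, t]]
        m <- mean(W[mg, t])
        if (m > 0) { W[, t] <- W[, t] / m; H[t, ] <- H[t, ] * m }
    }
    ## simplex projection of the mixing columns -> proportions
    cs <- colSums(H)
    zeroType <- rownames(H)[rowSums(H) <= 2 * ncol(H) * .NMF_FLOOR]
    if (length(zeroType))
        warning("estimated mixing is (numerically) all-zero for type(s): ",
                paste(zeroType, collapse = ", "))
    P <- sweep(H, 2L, cs, "/")
    W[!mask] <- 0   # exact zeros in the returned basis
    new("DeconvolutionResult", basis = W, rawMixing = H, proportions = P,
        mask = mask, divergenceTrace = best$trace,
        nIter = as.integer(best$nIter), seed = as.integer(seed),
        restartsTried = as.integer(nRestarts))
}

#' Accuracy of estimated proportions against ground truth
#'
#' Mean absolute difference and Pearson correlation over all entries of
#' the flattened true and estimated proportion matrices — the two
#' summary statistics conventionally reported for deconvolution
#' validation.
#'
#' @param trueH,estH cell-types x samples matrices of identical shape
#'   (cell-type identity fixed by the marker scheme, so no column
#'   matching is performed).
#' @return list with `mad` and `pearson_r` (`NA` with a warning when
#'   either input has zero variance).
#' @export
evaluateRecovery <- function(trueH, estH) {
    if (!all(dim(trueH) == dim(estH)))
        stop("true and estimated proportion matrices must have equal dimensions")
    a <- as.vector(trueH); b <- as.vector(estH)
    madv <- mean(abs(a - b))
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
        warning("zero-variance proportions: Pearson correlation undefined")
        r <- NA_real_
    } else r <- stats::cor(a, b)
    list(mad = madv, pearson_r = r)
}
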