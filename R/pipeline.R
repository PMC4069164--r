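#' @include stratification.R
#' @include deconvolution.R
#' @include expression-io.R
NULL

.configHash <- function(config) {
    tf <- tempfile(fileext = ".json")
    on.exit(unlink(tf))
    jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA)
    unname(tools::md5sum(tf))
}

.stamp <- function(config) {
    sprintf("seed=%d config_hash=%s", config$seed, .configHash(config))
}

.writeTableStamped <- function(df, path, stamp) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", stamp), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read and validate a YAML run configuration
#'
#' Expected keys: `expression`, `markers` (PBMC arm) or `panel` (tissue
#' arm), `clinical`, `output_dir`, `seed`, and optional blocks
#' `deconvolution` (mode, restarts, max_iter, tol), `survival` (screen,
#' alpha, relapse) and `stratification` (restarts). Defaults are filled
#' in for anything omitted.
#'
#' @param path YAML file path.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- yaml::read_yaml(path)
    defaults <- list(
        seed = 42L,
        deconvolution = list(mode = "markers_only", restarts = 10L,
                             max_iter = 2000L, tol = 1e-6),
        survival = list(screen = character(), alpha = 0.05,
                        relapse = NULL),
        stratification = list(restarts = 25L))
    for (k in names(defaults)) {
        if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
        else if (is.list(defaults[[k]]))
            for (kk in names(defaults[[k]]))
                if (is.null(config[[k]][[kk]]))
                    config[[k]][[kk]] <- defaults[[k]][[kk]]
    }
    config$seed <- as.integer(config$seed)
    a <- config$survival$alpha
    if (!is.numeric(a) || a <= 0 || a >= 1)
        stop("survival alpha must lie in (0, 1)")
    for (p in c("expression", "markers", "clinical", "panel")) {
        if (!is.null(config[[p]]) && !file.exists(config[[p]]))
            stop("configured ", p, " file not found: ", config[[p]])
    }
    if (is.null(config$output_dir)) stop("config lacks output_dir")
    config
}

.kmLong <- function(time, event, labels, splitName) {
    out <- lapply(levels(labels), function(lv) {
        sel <- labels == lv
        if (!any(sel)) return(NULL)
        km <- kmCurve(time[sel], event[sel])
        cbind(variable = splitName, group = lv, km)
    })
    do.call(rbind, out)
}

#' Run the blood (PBMC) arm of the pipeline
#'
#' Deconvolves immune-cell proportions from the configured expression
#' matrix and marker sets, median-splits each cell type into Low/High
#' groups, screens the cell-type groups and configured clinical factors
#' by univariate log-rank tests, and fits a multivariate Cox model on
#' everything that passes the screen. Writes proportions, per-group KM
#' curves, the univariate table and the Cox table (TSV, stamped with
#' seed and config hash) plus a JSON report to `output_dir`. Fully
#' deterministic under a fixed config and seed.
#'
#' @param config a config list from [readRunConfig()] (requires
#'   `expression`, `markers`, `clinical`).
#' @return the report list, invisibly.
#' @export
runPbmcArm <- function(config) {
    for (p in c("expression", "markers", "clinical"))
        if (is.null(config[[p]])) stop("PBMC arm config lacks '", p, "'")
    t0 <- Sys.time()
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- .stamp(config)

    X <- readExpression(config$expression)
    markers <- readGMT(config$markers)
    cohort <- readClinical(config$clinical)
    missing <- setdiff(colnames(X), sampleIds(cohort))
    if (length(missing))
        stop("expression samples absent from clinical table: ",
             paste(utils::head(missing, 5L), collapse = ", "))
    cohort <- cohort[colnames(X)]
    message(sprintf("[pbmc] loaded %d genes x %d samples (%.1fs)",
                    nrow(X), ncol(X),
                    as.numeric(Sys.time() - t0, units = "secs")))

    dc <- config$deconvolution
    fit <- deconvolve(X, markers, mode = dc$mode,
                      maxIter = as.integer(dc$max_iter), tol = dc$tol,
                      nRestarts = as.integer(dc$restarts),
                      seed = config$seed)
    P <- proportions(fit)
    writeProportions(P, file.path(config$output_dir, "proportions.tsv"),
                     header = stamp)
    message(sprintf("[pbmc] deconvolved %d cell types, final KL %.4g",
                    nrow(P), utils::tail(divergenceTrace(fit), 1L)))

    ## per-cell-type median split + log-rank
    alpha <- config$survival$alpha
    groupData <- data.frame(row.names = sampleIds(cohort))
    cellRows <- lapply(rownames(P), function(ct) {
        sp <- medianSplit(P[ct, ])
        col <- paste0(ct, "_group")
        groupData[[col]] <<- factor(sp$labels, levels = c("High", "Low"))
        if (any(sp$labels == "Low") && any(sp$labels == "High")) {
            lr <- logrankTest(survTime(cohort), survEvent(cohort),
                              sp$labels)
            data.frame(cell_type = ct, split_value = sp$median,
                       n_low = sum(sp$labels == "Low"),
                       n_high = sum(sp$labels == "High"),
                       chi2 = lr$chi2, p = lr$p,
                       selected = lr$p < alpha)
        } else data.frame(cell_type = ct, split_value = sp$median,
                          n_low = sum(sp$labels == "Low"),
                          n_high = sum(sp$labels == "High"),
                          chi2 = NA_real_, p = NA_real_, selected = FALSE)
    })
    cellTab <- do.call(rbind, cellRows)
    .writeTableStamped(cellTab,
                       file.path(config$output_dir, "cell_type_logrank.tsv"),
                       stamp)

    km <- do.call(rbind, lapply(rownames(P), function(ct) {
        sp <- medianSplit(P[ct, ])
        .kmLong(survTime(cohort), survEvent(cohort),
                droplevels(sp$labels), ct)
    }))
    .writeTableStamped(km, file.path(config$output_dir, "km_curves.tsv"),
                       stamp)

    ## clinical factor screen
    screen <- config$survival$screen
    clinTab <- if (length(screen))
        univariateScreen(cohort, screen, alpha = alpha) else NULL
    if (!is.null(clinTab))
        .writeTableStamped(clinTab,
                           file.path(config$output_dir,
                                     "univariate_clinical.tsv"), stamp)

    ## multivariate Cox on everything selected
    selCells <- cellTab$cell_type[cellTab$selected]
    selClin <- if (is.null(clinTab)) character() else
        clinTab$factor[clinTab$selected]
    coxRes <- NULL
    if (length(selCells) + length(selClin) > 0L) {
        covNames <- c(if (length(selCells)) paste0(selCells, "_group"),
                      selClin)
        coxRes <- coxFit(cohort, covNames, data = groupData)
        .writeTableStamped(coxRes$table,
                           file.path(config$output_dir, "cox.tsv"), stamp)
    } else {
        message("[pbmc] univariate screen selected nothing; multivariate model skipped")
    }

    report <- list(
        arm = "pbmc", seed = config$seed, config_hash = .configHash(config),
        n_genes = nrow(X), n_samples = ncol(X),
        deconvolution = list(
            final_divergence = utils::tail(divergenceTrace(fit), 1L),
            n_iter = fit@nIter, restarts = fit@restartsTried),
        cell_type_logrank = cellTab,
        univariate_clinical = clinTab,
        multivariate_cox = if (is.null(coxRes)) NULL else
            list(table = coxRes$table, loglik = coxRes$loglik,
                 converged = coxRes$converged))
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    message(sprintf("[pbmc] done in %.1fs",
                    as.numeric(Sys.time() - t0, units = "secs")))
    invisible(report)
}

#' Run the tissue arm of the pipeline
#'
#' Restricts the configured tissue expression matrix to a gene panel
#' (one gene ID per line in the `panel` file), stratifies samples into
#' Low/High groups by two-means clustering, and tests the groups by
#' log-rank, multivariate Cox (adjusting for the configured screen
#' factors that pass univariate selection) and, if configured, a
#' chi-square test of relapse enrichment. Writes labels, centroids and
#' test tables plus a JSON report to `output_dir`.
#'
#' @param config a config list from [readRunConfig()] (requires
#'   `expression`, `panel`, `clinical`).
#' @return the report list, invisibly.
#' @export
runTissueArm <- function(config) {
    for (p in c("expression", "panel", "clinical"))
        if (is.null(config[[p]])) stop("tissue arm config lacks '", p, "'")
    t0 <- Sys.time()
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    stamp <- .stamp(config)

    X <- readExpression(config$expression)
    panelGenes <- readLines(config$panel)
    panelGenes <- panelGenes[nzchar(panelGenes)]
    found <- intersect(panelGenes, rownames(X))
    if (length(found) == 0L)
        stop("no panel gene found in the expression matrix")
    if (length(found) < length(panelGenes))
        message(length(panelGenes) - length(found),
                " panel gene(s) missing from the expression matrix")
    cohort <- readClinical(config$clinical)

    alpha <- config$survival$alpha
    screen <- config$survival$screen
    clinTab <- if (length(screen)) {
        ids <- intersect(colnames(X), sampleIds(cohort))
        univariateScreen(cohort[ids], screen, alpha = alpha)
    } else NULL
    adjustFor <- if (is.null(clinTab)) character() else
        as.character(clinTab$factor[clinTab$selected])

    res <- stratifyAndTest(X[found, , drop = FALSE], cohort,
                           adjustFor = adjustFor,
                           relapseColumn = config$survival$relapse,
                           nRestarts = as.integer(config$stratification$restarts),
                           seed = config$seed)
    lab <- groupLabels(res$stratification)
    .writeTableStamped(data.frame(sample_id = names(lab),
                                  mhc_group = as.character(lab)),
                       file.path(config$output_dir, "labels.tsv"), stamp)
    cen <- centroids(res$stratification)
    .writeTableStamped(data.frame(group = rownames(cen), cen,
                                  check.names = FALSE),
                       file.path(config$output_dir, "centroids.tsv"), stamp)
    .writeTableStamped(res$cox$table,
                       file.path(config$output_dir, "cox.tsv"), stamp)
    km <- .kmLong(survTime(cohort[names(lab)]), survEvent(cohort[names(lab)]),
                  lab, "mhc_group")
    .writeTableStamped(km, file.path(config$output_dir, "km_curves.tsv"),
                       stamp)

    report <- list(
        arm = "tissue", seed = config$seed,
        config_hash = .configHash(config),
        n_panel_genes = length(found), n_samples = length(lab),
        group_sizes = as.list(table(lab)),
        logrank = res$logrank,
        univariate_clinical = clinTab,
        multivariate_cox = list(table = res$cox$table,
                                loglik = res$cox$loglik,
                                converged = res$cox$converged),
        chisq_relapse = if (is.null(res$chisq_relapse)) NULL else
            list(chi2 = res$chisq_relapse$chi2,
                 df = res$chisq_relapse$df,
                 p = res$chisq_relapse$p,
                 n_excluded = res$chisq_relapse$n_excluded))
    jsonlite::write_json(report,
                         file.path(config$output_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         null = "null")
    message(sprintf("[tissue] done in %.1fs",
                    as.numeric(Sys.time() - t0, units = "secs")))
    invisible(report)
}
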