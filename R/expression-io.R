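#' @include methods-accessors.R
NULL

#' Read a tab-separated expression table
#'
#' Expects a header row of sample IDs; the first column holds probe or
#' gene identifiers, remaining columns numeric intensities. Row and
#' column order of the file is preserved.
#'
#' @param path file path.
#' @param floorNegative floor negative values (e.g. left by background
#'   subtraction upstream) at 0; default TRUE. NMF requires non-negative
#'   input.
#' @return numeric matrix, genes/probes in rows, samples in columns.
#' @export
readExpression <- function(path, floorNegative = TRUE) {
    lines <- readLines(path)
    if (length(lines) < 2L) stop("expression file has no data rows: ", path)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    nc <- length(header)
    if (nc < 2L) stop("expression header needs an ID column plus samples")
    samples <- header[-1L]
    if (anyDuplicated(samples)) stop("duplicate sample IDs in header")
    n <- length(lines) - 1L
    ids <- character(n)
    vals <- matrix(NA_real_, n, nc - 1L)
    for (k in seq_len(n)) {
        f <- fields[[k + 1L]]
        if (length(f) != nc)
            stop(sprintf("line %d: expected %d fields, found %d",
                         k + 1L, nc, length(f)))
        ids[k] <- f[1L]
        v <- suppressWarnings(as.numeric(f[-1L]))
        if (anyNA(v))
            stop(sprintf("line %d: non-numeric expression value", k + 1L))
        vals[k, ] <- v
    }
    if (anyDuplicated(ids)) {
        dup <- ids[duplicated(ids)][1L]
        stop("duplicate row identifier: ", dup)
    }
    dimnames(vals) <- list(ids, samples)
    if (floorNegative && any(vals < 0)) vals[vals < 0] <- 0
    .checkExpressionMatrix(vals, "expression matrix")
    vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [readExpression()]: tab-delimited, header `gene_id` then
#' sample IDs, deterministic ordering.
#'
#' @param x genes x samples numeric matrix with dimnames.
#' @param path output file path.
#' @param idColumn name of the identifier column header.
#' @return the path, invisibly.
#' @export
writeExpression <- function(x, path, idColumn = "gene_id") {
    .checkExpressionMatrix(x, allowNegative = TRUE)
    df <- data.frame(id = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    colnames(df)[1L] <- idColumn
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Collapse a probe-level matrix to gene level
#'
#' Probes that map to no gene or to more than one gene are removed; the
#' per-sample expression of a gene is the arithmetic mean of its
#' remaining (uniquely mapped) probes.
#'
#' @param pm probes x samples numeric matrix (probe IDs as rownames).
#' @param annotation either a named list mapping probe ID to a character
#'   vector of gene IDs, or a data.frame with columns `probe_id` and
#'   `gene_id` (one row per probe-gene pair). Probes absent from the
#'   annotation are treated as unmapped.
#' @return genes x samples numeric matrix.
#' @examples
#' pm <- matrix(c(2, 4), 2, 1, dimnames = list(c("p1", "p2"), "s1"))
#' collapseProbes(pm, data.frame(probe_id = c("p1", "p2"),
#'                               gene_id = c("gA", "gA")))
#' @export
collapseProbes <- function(pm, annotation) {
    .checkExpressionMatrix(pm, "probe matrix")
    if (is.data.frame(annotation)) {
        stopifnot(all(c("probe_id", "gene_id") %in% colnames(annotation)))
        ann <- split(as.character(annotation$gene_id),
                     as.character(annotation$probe_id))
    } else ann <- annotation
    ann <- lapply(ann, function(g) unique(g[!is.na(g) & nzchar(g)]))
    nGenes <- vapply(ann, length, 0L)
    keepProbe <- names(ann)[nGenes == 1L]
    keepProbe <- intersect(rownames(pm), keepProbe)
    if (length(keepProbe) == 0L)
        stop("no probe maps uniquely to a gene; nothing to collapse")
    gene <- vapply(ann[keepProbe], `[[`, "", 1L)
    sub <- pm[keepProbe, , drop = FALSE]
    out <- rowsum(sub, group = gene) / as.vector(table(gene)[sort(unique(gene))])
    ## rowsum orders groups by sort(); keep first-appearance order instead
    firstSeen <- gene[!duplicated(gene)]
    out <- out[firstSeen, , drop = FALSE]
    .checkExpressionMatrix(out, "gene matrix")
    out
}

#' Read a GMT marker-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB gene ...`.
#' Duplicate genes within a set are stored once (with a warning); set
#' order is preserved.
#'
#' @param path GMT file path.
#' @return a [MarkerSetCollection-class]
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) stop("empty GMT file: ", path)
    sets <- list(); desc <- character()
    for (k in seq_along(lines)) {
        f <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1L]]
        if (length(f) < 3L)
            stop(sprintf("GMT line %d: expected name, description and at least one gene", k))
        genes <- f[-(1:2)]
        genes <- genes[nzchar(genes)]
        if (length(genes) == 0L)
            stop(sprintf("GMT line %d: set '%s' has no genes", k, f[1L]))
        if (anyDuplicated(genes)) {
            warning(sprintf("GMT set '%s': duplicated genes de-duplicated", f[1L]))
            genes <- unique(genes)
        }
        sets[[f[1L]]] <- genes
        desc[f[1L]] <- f[2L]
    }
    MarkerSetCollection(sets, desc)
}

#' Write marker sets to a GMT file
#'
#' @param msc a [MarkerSetCollection-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGMT <- function(msc, path) {
    stopifnot(is(msc, "MarkerSetCollection"))
    lines <- vapply(cellTypes(msc), function(nm) {
        d <- msc@descriptions[nm]
        if (is.na(d) || !nzchar(d)) d <- nm
        paste(c(nm, d, msc@sets[[nm]]), collapse = "\t")
    }, "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a clinical table into a SurvivalCohort
#'
#' Requires columns `sample_id`, `os_months` (non-negative overall
#' survival in months) and `event` (0/1). Every other column is kept as a
#' categorical covariate; missing cells become category "NA" and the
#' literal category "Not sure" is preserved as its own level.
#'
#' @param path tab-separated file path.
#' @return a [SurvivalCohort-class]
#' @export
readClinical <- function(path) {
    df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            check.names = FALSE,
                            colClasses = "character")
    req <- c("sample_id", "os_months", "event")
    miss <- setdiff(req, colnames(df))
    if (length(miss))
        stop("clinical table lacks required columns: ",
             paste(miss, collapse = ", "))
    time <- suppressWarnings(as.numeric(df$os_months))
    if (anyNA(time) || any(time < 0)) {
        bad <- df$sample_id[which(is.na(time) | time < 0)[1L]]
        stop("invalid os_months for sample ", bad)
    }
    ev <- suppressWarnings(as.numeric(df$event))
    if (anyNA(ev) || !all(ev %in% c(0, 1))) {
        bad <- df$sample_id[which(is.na(ev) | !ev %in% c(0, 1))[1L]]
        stop("event must be 0/1; offending sample ", bad)
    }
    covarCols <- setdiff(colnames(df), req)
    covar <- df[, covarCols, drop = FALSE]
    for (cc in covarCols) {
        v <- covar[[cc]]
        v[is.na(v) | !nzchar(v)] <- "NA"
        covar[[cc]] <- factor(v)
    }
    rownames(covar) <- df$sample_id
    SurvivalCohort(df$sample_id, time, as.integer(ev), covar)
}

#' Write a SurvivalCohort as a clinical TSV
#'
#' @param cohort a [SurvivalCohort-class]
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeClinical <- function(cohort, path) {
    stopifnot(is(cohort, "SurvivalCohort"))
    df <- data.frame(sample_id = sampleIds(cohort),
                     os_months = survTime(cohort),
                     event = survEvent(cohort),
                     stringsAsFactors = FALSE)
    cv <- covariates(cohort)
    for (cc in colnames(cv)) df[[cc]] <- as.character(cv[[cc]])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
    invisible(path)
}

#' Write a proportions matrix (cell types x samples) as TSV
#'
#' Output is samples in rows, one column per cell type — the orientation
#' a clinician-facing table uses.
#'
#' @param H cell-types x samples matrix (e.g. `proportions(fit)`).
#' @param path output path.
#' @param header optional comment lines written before the table, each
#'   prefixed with `#`.
#' @return the path, invisibly.
#' @export
writeProportions <- function(H, path, header = NULL) {
    df <- data.frame(sample_id = colnames(H), t(H), check.names = FALSE,
                     stringsAsFactors = FALSE)
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
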