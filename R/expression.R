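#' Construct a TissueExpression object
#'
#' @param nrc numeric matrix of normalized read counts, genes in rows
#'   (unique rownames), one column per sequencing library.
#' @param sex,tissue character vectors, one entry per column of `nrc`.
#' @param replicate integer replicate index within each sex-tissue
#'   group, one entry per column.
#' @return a [TissueExpression-class].
#' @examples
#' nrc <- matrix(c(5, 0, 7, 1), 2, 2,
#'               dimnames = list(c("g1", "g2"), NULL))
#' te <- TissueExpression(nrc, sex = c("f", "f"),
#'                        tissue = c("gonad", "head"),
#'                        replicate = c(1L, 1L))
#' @export
TissueExpression <- function(nrc, sex, tissue, replicate) {
    nrc <- as.matrix(nrc)
    stopifnot(length(sex) == ncol(nrc), length(tissue) == ncol(nrc),
              length(replicate) == ncol(nrc))
    colnames(nrc) <- paste(sex, tissue, replicate, sep = ".")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(nrc = nrc),
        colData = S4Vectors::DataFrame(sex = as.character(sex),
                                       tissue = as.character(tissue),
                                       replicate = as.integer(replicate)))
    new("TissueExpression", se)
}

#' Read a TissueExpression from TSV
#'
#' Expects a header of `gene_id` followed by one column per library
#' named `sex.tissue.replicate` (e.g. `f.gonad.1`, `m.head.3`).
#' Tissue names may themselves contain dots; the first field is the
#' sex and the last the replicate index.
#'
#' @param path TSV file path.
#' @return a [TissueExpression-class].
#' @export
readExpressionTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1L] != "gene_id")
        stop("first column must be 'gene_id': ", path)
    genes <- df[[1L]]
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- genes
    parts <- strsplit(colnames(m), ".", fixed = TRUE)
    bad <- lengths(parts) < 3L
    if (any(bad))
        stop("sample columns must be named sex.tissue.replicate; bad: ",
             paste(colnames(m)[bad], collapse = ", "))
    sex <- vapply(parts, `[`, "", 1L)
    rep <- vapply(parts, function(p) p[length(p)], "")
    tissue <- vapply(parts, function(p)
        paste(p[2:(length(p) - 1L)], collapse = "."), "")
    TissueExpression(m, sex = sex, tissue = tissue,
                     replicate = as.integer(rep))
}

#' Write a TissueExpression to TSV
#'
#' Inverse of [readExpressionTable()].
#'
#' @param te a [TissueExpression-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeExpressionTable <- function(te, path) {
    a <- SummarizedExperiment::assay(te, "nrc")
    df <- data.frame(gene_id = rownames(a), a, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Median NRC per gene within each sex-by-tissue group
#'
#' Collapses replicate libraries to their per-gene median (the
#' NRC_TS value): for even replicate numbers the midpoint of the two
#' central order statistics.
#'
#' @param te a [TissueExpression-class].
#' @return numeric matrix, genes x `sex.tissue` groups.
#' @export
medianByGroup <- function(te) {
    stopifnot(is(te, "TissueExpression"))
    a <- SummarizedExperiment::assay(te, "nrc")
    cd <- SummarizedExperiment::colData(te)
    grp <- paste(cd$sex, cd$tissue, sep = ".")
    ug <- unique(grp)
    out <- vapply(ug, function(g)
        apply(a[, grp == g, drop = FALSE], 1L, stats::median),
        numeric(nrow(a)))
    if (nrow(a) == 1L) out <- matrix(out, nrow = 1L,
                                     dimnames = list(rownames(a), ug))
    out
}

#' Log-scale expression transform
#'
#' `log10(x + 1)`: maps 0 to 0 and keeps every value finite, which is
#' why the offset is used on NRC tables containing exact zeros.
#'
#' @param x nonnegative finite numeric.
#' @return `log10(x + 1)`.
#' @examples
#' logExpression(c(0, 9, 99))  # 0 1 2
#' @export
logExpression <- function(x) {
    if (any(!is.finite(x)) || any(x < 0))
        stop("expression values must be finite and nonnegative")
    log10(x + 1)
}

#' Tissue-specificity index tau
#'
#' For a profile of N log-scale expression values
#' \eqn{S_1, \dots, S_N} with maximum \eqn{S_{max}},
#' \deqn{\tau = \frac{\sum_{i=1}^{N} (1 - S_i / S_{max})}{N - 1}.}
#' tau ranges from 0 (equal expression in all tissues) to 1
#' (expression confined to a single tissue). When every entry is zero
#' the index is undefined (the formula divides by \eqn{S_{max}}) and
#' `NA` is returned with a warning rather than silently calling an
#' unexpressed gene broad or narrow.
#'
#' @param s numeric vector of N >= 2 nonnegative log-scale values,
#'   typically `logExpression(nrc_ts)`.
#' @return tau in \[0, 1\], or `NA` for an all-zero profile.
#' @examples
#' computeTau(c(2, 0, 0, 0, 0, 0))            # 1
#' computeTau(rep(3, 6))                      # 0
#' computeTau(logExpression(c(100, 10, 10, 10, 10, 10)))
#' @export
computeTau <- function(s) {
    if (length(s) < 2L)
        stop("tau requires at least two tissues")
    if (any(!is.finite(s)) || any(s < 0))
        stop("profile entries must be finite and nonnegative")
    smax <- max(s)
    if (smax == 0) {
        warning("all-zero profile: tau undefined")
        return(NA_real_)
    }
    sum(1 - s / smax) / (length(s) - 1L)
}

#' Tau per gene and sex from a TissueExpression
#'
#' Medians replicates to NRC_TS, applies `log10(x + 1)`, and
#' evaluates tau over the configured tissue set separately for each
#' sex. Whole-body libraries (or any other tissue not listed in
#' `tissues`) are excluded, so tau measures breadth over
#' nonoverlapping tissue samples only.
#'
#' @param te a [TissueExpression-class].
#' @param tissues character vector of tissue names defining the
#'   breadth panel; every (sex, tissue) group must be present.
#' @param sexes sexes to evaluate (default: those present).
#' @return `data.frame` with `gene_id`, `sex`, `tau`, and one
#'   `log_<tissue>` column per panel tissue.
#' @export
tauTable <- function(te, tissues, sexes = NULL) {
    med <- medianByGroup(te)
    cd <- SummarizedExperiment::colData(te)
    if (is.null(sexes)) sexes <- unique(cd$sex)
    out <- list()
    for (sx in sexes) {
        cols <- paste(sx, tissues, sep = ".")
        miss <- setdiff(cols, colnames(med))
        if (length(miss))
            stop("no samples for group(s): ",
                 paste(miss, collapse = ", "))
        s <- logExpression(med[, cols, drop = FALSE])
        tau <- suppressWarnings(apply(s, 1L, computeTau))
        df <- data.frame(gene_id = rownames(med), sex = sx, tau = tau,
                         row.names = NULL)
        colnames(s) <- paste0("log_", tissues)
        out[[sx]] <- cbind(df, as.data.frame(s, row.names = NULL))
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Genome-wide percentile of an expression value
#'
#' Mid-rank percentile: `100 * (#below + 0.5 * #equal) / n`, a
#' deterministic convention under ties.
#'
#' @param value expression value of the focal gene.
#' @param genome numeric vector of genome-wide values on the same
#'   scale.
#' @return percentile in \[0, 100\].
#' @examples
#' expressionPercentile(3, c(1, 2, 3, 4, 5))  # 50
#' @export
expressionPercentile <- function(value, genome) {
    if (!length(genome))
        stop("genome-wide distribution is empty")
    100 * (sum(genome < value) + 0.5 * sum(genome == value)) /
        length(genome)
}
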