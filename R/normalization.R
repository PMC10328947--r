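# Median-of-ratios size factors, log2 normalization and the
# expressed-gene filter.

#' Median-of-ratios size factors
#'
#' For every gene with positive counts in all samples, compute the ratio of
#' each sample's count to the gene's geometric mean; the per-sample size
#' factor is the median of those ratios, rescaled so the size factors have
#' geometric mean 1. With \code{method = "poscounts"} the geometric mean is
#' taken over positive counts only and genes with any positive count
#' contribute, for matrices with no all-positive gene.
#'
#' @param counts non-negative count matrix, genes in rows.
#' @param method "ratio" (default) or "poscounts".
#' @return named positive numeric vector, one per sample, geometric mean 1.
#' @export
computeSizeFactors <- function(counts, method = c("ratio", "poscounts")) {
    method <- match.arg(method)
    counts <- as.matrix(counts)
    if (method == "ratio") {
        allPos <- rowSums(counts > 0) == ncol(counts)
        if (!any(allPos))
            stop("no gene has positive counts in all samples; ",
                 "rerun with method = \"poscounts\"")
        logGeo <- rowMeans(log(counts[allPos, , drop = FALSE]))
        logRatios <- log(counts[allPos, , drop = FALSE]) - logGeo
    } else {
        anyPos <- rowSums(counts > 0) > 0
        sub <- counts[anyPos, , drop = FALSE]
        logc <- log(sub)
        logc[!is.finite(logc)] <- NA
        logGeo <- rowMeans(logc, na.rm = TRUE)
        logRatios <- logc - logGeo
    }
    sf <- exp(apply(logRatios, 2, median, na.rm = TRUE))
    sf <- sf / exp(mean(log(sf)))
    setNames(sf, colnames(counts))
}

#' Log2 size-factor-normalized expression
#'
#' \code{log2(count / size_factor + pseudocount)} per cell.
#'
#' @param counts count matrix, genes in rows.
#' @param sizeFactors per-sample positive factors; computed with
#'   \code{\link{computeSizeFactors}} when NULL.
#' @param pseudocount added before the log2 transform (default 1).
#' @return a \code{\linkS4class{NormalizedMatrix}}.
#' @export
log2Normalized <- function(counts, sizeFactors = NULL, pseudocount = 1) {
    counts <- as.matrix(counts)
    if (is.null(sizeFactors)) sizeFactors <- computeSizeFactors(counts)
    if (any(sizeFactors <= 0)) stop("size factors must be positive")
    vals <- log2(sweep(counts, 2, sizeFactors, "/") + pseudocount)
    new("NormalizedMatrix", values = vals,
        sizeFactors = as.numeric(sizeFactors), pseudocount = pseudocount)
}

#' Expressed-gene filter
#'
#' Simplified filterByExpr-style rule: keep genes with CPM at or above
#' \code{min_count / median(library size) * 1e6} in at least as many
#' samples as the smallest group, and with total count at or above
#' \code{minTotal}.
#'
#' @param counts count matrix, genes in rows.
#' @param groupLabels per-sample group labels (>= 2 groups).
#' @param minCount,minTotal rule parameters (defaults 10 and 15).
#' @return logical vector, TRUE for genes kept.
#' @export
expressedGeneFilter <- function(counts, groupLabels, minCount = 10,
                                minTotal = 15) {
    counts <- as.matrix(counts)
    groupLabels <- as.factor(groupLabels)
    if (nlevels(groupLabels) < 2)
        stop("at least 2 groups required")
    lib <- colSums(counts)
    cpm <- sweep(counts, 2, lib, "/") * 1e6
    cutoff <- minCount / median(lib) * 1e6
    nMin <- min(table(groupLabels))
    keep <- rowSums(cpm >= cutoff) >= nMin & rowSums(counts) >= minTotal
    setNames(keep, rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement
#' (delegates to \code{stats::p.adjust} after range validation).
#'
#' @param pvalues numeric vector of p-values in [0, 1] (NA allowed).
#' @return adjusted values, same length and order.
#' @export
bhAdjust <- function(pvalues) {
    if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvalues, method = "BH")
}
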