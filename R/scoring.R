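# Single-sample GSEA, preranked GSEA, the HOXB13/IL17BR ratio, and the
# correlation analyses between scores, covariates and each other.

# Average ranks with deterministic resolution: tied expression values are
# ordered by gene identifier before ranking so running sums are
# reproducible across platforms.
.detOrder <- function(values, genes) {
    order(-values, genes)
}

#' Single-sample GSEA enrichment score
#'
#' Genes are ranked by expression (descending). Walking down the ranking,
#' the running sum accumulates the weighted in-set empirical CDF (weights
#' are rank^alpha, normalized over the set) minus the uniform out-of-set
#' ECDF; the score is the sum of the differences over all positions
#' (the integral form). Depends on ranks only, so it is invariant to any
#' strictly increasing transform of the expression values.
#'
#' @param sampleExpression named numeric vector of expression for one
#'   sample.
#' @param geneSet character vector of gene identifiers.
#' @param alpha rank weighting exponent (default 0.25).
#' @return numeric score, or NA with a warning when the set does not
#'   intersect the expressed genes.
#' @export
ssgseaScore <- function(sampleExpression, geneSet, alpha = 0.25) {
    genes <- names(sampleExpression)
    inSet <- genes %in% geneSet
    if (!any(inSet)) {
        warning("gene set has no genes in the expression vector")
        return(NA_real_)
    }
    n <- length(sampleExpression)
    ord <- .detOrder(sampleExpression, genes)
    inOrd <- inSet[ord]
    # rank weight: position from the bottom (top gene has rank n)
    rnk <- rank(sampleExpression, ties.method = "average")[ord]
    w <- ifelse(inOrd, rnk^alpha, 0)
    pIn <- cumsum(w) / sum(w)
    nOut <- n - sum(inOrd)
    pOut <- if (nOut > 0) cumsum(!inOrd) / nOut else rep(0, n)
    sum(pIn - pOut)
}

#' Score a gene-set collection on every sample
#'
#' Sets outside the size bounds (after intersection-free de-duplication)
#' are dropped with a message. Scores can optionally be cohort-normalized
#' by the total range of scores, the usual presentation scale.
#'
#' @param norm a \code{NormalizedMatrix} or matrix, genes in rows.
#' @param sets named list of gene identifier vectors.
#' @param minSize,maxSize set size bounds (defaults 5 and 2000).
#' @param alpha rank weighting exponent.
#' @param normalize divide all scores by the overall score range.
#' @return matrix, sets in rows, samples in columns.
#' @export
scoreMatrix <- function(norm, sets, minSize = 5, maxSize = 2000,
                        alpha = 0.25, normalize = FALSE) {
    vals <- .asValueMatrix(norm)
    sizes <- vapply(sets, function(s) length(unique(s)), 1L)
    keep <- sizes >= minSize & sizes <= maxSize
    if (any(!keep))
        message(sprintf("dropping %d set(s) outside size bounds [%d, %d]",
                        sum(!keep), minSize, maxSize))
    sets <- sets[keep]
    out <- matrix(NA_real_, length(sets), ncol(vals),
                  dimnames = list(names(sets), colnames(vals)))
    for (j in seq_len(ncol(vals))) {
        v <- vals[, j]
        names(v) <- rownames(vals)
        for (i in seq_along(sets))
            out[i, j] <- suppressWarnings(ssgseaScore(v, sets[[i]], alpha))
    }
    if (normalize && length(out) > 0) {
        rng <- diff(range(out, na.rm = TRUE))
        if (rng > 0) out <- out / rng
    }
    out
}

# Weighted Kolmogorov-Smirnov enrichment score for a preranked statistic:
# maximum deviation of the running sum (weight |stat| inside the set,
# uniform decrement outside).
.gseaES <- function(ordStats, inOrd) {
    nr <- sum(abs(ordStats[inOrd]))
    n <- length(ordStats)
    nOut <- n - sum(inOrd)
    if (nr == 0) nr <- 1e-12
    steps <- ifelse(inOrd, abs(ordStats) / nr, -1 / nOut)
    rs <- cumsum(steps)
    rs[which.max(abs(rs))]
}

#' Preranked GSEA with a gene-permutation null
#'
#' Weighted Kolmogorov-Smirnov enrichment score (weight = |statistic|) on
#' the descending ranking of the per-gene statistic. The null distribution
#' is obtained by permuting gene labels; NES = ES / mean(|null ES| of the
#' same sign); BH FDR across sets.
#'
#' @param rankedStats named per-gene statistic (no duplicate names).
#' @param sets named list of gene sets.
#' @param nPerm number of permutations (at least 100).
#' @param seed integer seed.
#' @param minSize,maxSize set size bounds.
#' @return data.frame per set: \code{set}, \code{size}, \code{es},
#'   \code{nes}, \code{p_value}, \code{fdr}, \code{leading_edge}
#'   (comma-separated gene list).
#' @export
prerankedGsea <- function(rankedStats, sets, nPerm = 1000, seed = 1,
                          minSize = 5, maxSize = 2000) {
    if (nPerm < 100) stop("nPerm must be at least 100")
    genes <- names(rankedStats)
    if (anyDuplicated(genes)) stop("duplicate gene identifiers")
    ord <- .detOrder(rankedStats, genes)
    ordStats <- rankedStats[ord]
    ordGenes <- genes[ord]
    n <- length(ordStats)
    sizes <- vapply(sets, function(s) sum(ordGenes %in% s), 1L)
    keep <- sizes >= minSize & sizes <= maxSize
    sets <- sets[keep]; sizes <- sizes[keep]
    set.seed(seed)
    rows <- vector("list", length(sets))
    for (i in seq_along(sets)) {
        inOrd <- ordGenes %in% sets[[i]]
        es <- .gseaES(ordStats, inOrd)
        m <- sizes[i]
        nullEs <- vapply(seq_len(nPerm), function(p) {
            pick <- sample.int(n, m)
            io <- logical(n); io[pick] <- TRUE
            .gseaES(ordStats, io)
        }, 0)
        sameSign <- nullEs[sign(nullEs) == sign(es)]
        denom <- if (length(sameSign) > 0) mean(abs(sameSign)) else abs(es)
        nes <- if (denom > 0) es / denom else 0
        p <- (1 + sum(sign(nullEs) == sign(es) &
                      abs(nullEs) >= abs(es))) /
             (1 + length(sameSign))
        # leading edge: genes contributing before/at the ES extremum
        steps <- ifelse(inOrd, abs(ordStats) /
                        max(sum(abs(ordStats[inOrd])), 1e-12),
                        -1 / (n - m))
        peak <- which.max(abs(cumsum(steps)))
        le <- if (es >= 0) ordGenes[seq_len(peak)][inOrd[seq_len(peak)]]
              else ordGenes[peak:n][inOrd[peak:n]]
        rows[[i]] <- data.frame(set = names(sets)[i], size = m, es = es,
                                nes = nes, p_value = min(1, p),
                                leading_edge = paste(le, collapse = ","),
                                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (!is.null(out)) out$fdr <- bhAdjust(out$p_value)
    out
}

#' HOXB13/IL17BR (H/I) expression ratio
#'
#' Difference of log2 normalized expression of the two genes per sample,
#' i.e. the log2 of the linear-scale expression ratio.
#'
#' @param norm a \code{NormalizedMatrix} or matrix of log2 values.
#' @param numerator,denominator gene identifiers (defaults HOXB13,
#'   IL17BR).
#' @return named per-sample numeric vector.
#' @export
hiRatio <- function(norm, numerator = "HOXB13", denominator = "IL17BR") {
    vals <- .asValueMatrix(norm)
    for (g in c(numerator, denominator))
        if (!g %in% rownames(vals))
            stop(sprintf("gene %s absent from the matrix", g))
    vals[numerator, ] - vals[denominator, ]
}

#' Pairwise correlation of signature scores
#'
#' Symmetric Spearman (or Pearson) correlation matrix across score rows,
#' with BH-adjusted p-values over the strict upper triangle.
#'
#' @param scores score matrix, sets in rows, samples in columns (>= 3
#'   samples).
#' @param method "spearman" (default) or "pearson".
#' @return list with \code{rho} (symmetric matrix, unit diagonal),
#'   \code{p} and \code{fdr} matrices (FDR computed over the upper
#'   triangle, mirrored).
#' @export
scoreCorrelationMatrix <- function(scores, method = "spearman") {
    method <- match.arg(method, c("spearman", "pearson"))
    if (ncol(scores) < 3) stop("at least 3 samples required")
    k <- nrow(scores)
    rho <- diag(1, k); p <- matrix(NA_real_, k, k)
    dimnames(rho) <- dimnames(p) <- list(rownames(scores), rownames(scores))
    for (i in seq_len(k)) for (j in seq_len(k)) {
        if (j <= i) next
        r <- if (method == "spearman")
            spearmanTest(scores[i, ], scores[j, ])
        else {
            ct <- stats::cor.test(scores[i, ], scores[j, ])
            list(rho = unname(ct$estimate), p.value = ct$p.value)
        }
        rho[i, j] <- rho[j, i] <- r$rho
        p[i, j] <- p[j, i] <- r$p.value
    }
    fdr <- p
    up <- upper.tri(p)
    fdr[up] <- bhAdjust(p[up])
    fdr[lower.tri(fdr)] <- t(fdr)[lower.tri(fdr)]
    list(rho = rho, p = p, fdr = fdr)
}

#' Correlate a clinical covariate with every signature score
#'
#' Samples with a missing covariate, or a covariate above the exclusion
#' threshold (e.g. implausibly premenopausal estradiol), are dropped;
#' Spearman rho and p per set, BH across sets.
#'
#' @param covariate named per-sample numeric vector (names = sample ids).
#' @param scores score matrix, sets in rows, samples in columns.
#' @param exclusionThreshold drop samples with covariate strictly above
#'   this value (default Inf = keep all).
#' @return data.frame per set: \code{set}, \code{n}, \code{rho},
#'   \code{p_value}, \code{fdr}.
#' @export
covariateScoreCorrelation <- function(covariate, scores,
                                      exclusionThreshold = Inf) {
    common <- intersect(names(covariate), colnames(scores))
    cov <- covariate[common]
    usable <- !is.na(cov) & cov <= exclusionThreshold
    if (sum(usable) < 3)
        stop("fewer than 3 usable samples after exclusions")
    cov <- cov[usable]
    sc <- scores[, names(cov), drop = FALSE]
    rows <- lapply(seq_len(nrow(sc)), function(i) {
        r <- spearmanTest(cov, sc[i, ])
        data.frame(set = rownames(sc)[i], n = length(cov), rho = r$rho,
                   p_value = r$p.value, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p_value)
    out
}
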