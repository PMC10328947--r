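# Exact and rank-based tests used throughout the pipeline. These are kept
# deliberately small and brute-force-verifiable: the unit tests compare each
# against exhaustive enumeration on small inputs.

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value obtained by summing, over all tables with the
#' observed margins, the hypergeometric point probabilities that do not
#' exceed the observed table's probability (with a 1e-7 relative slack for
#' floating-point ties) -- the convention used by \code{stats::fisher.test}.
#'
#' @param a,b,c,d non-negative integer cells, laid out as rows
#'   \code{(a, b)} and \code{(c, d)}.
#' @return two-sided p-value in [0, 1].
#' @examples
#' fisherExact2x2(115, 61, 79, 84)  # ~0.002
#' @export
fisherExact2x2 <- function(a, b, c, d) {
    cells <- c(a, b, c, d)
    if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
        stop("cells must be non-negative integers")
    n <- sum(cells)
    if (n == 0)
        stop("table total must be positive")
    m <- a + b          # row 1 margin
    k <- a + c          # column 1 margin
    lo <- max(0L, k - (n - m))
    hi <- min(k, m)
    support <- lo:hi
    probs <- dhyper(support, m, n - m, k)
    p.obs <- dhyper(a, m, n - m, k)
    p <- sum(probs[probs <= p.obs * (1 + 1e-7)])
    min(1, p)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided rank-sum test. For group sizes of at most 8 on each side and
#' no ties, the exact null distribution of U is enumerated by dynamic
#' programming; otherwise the normal approximation with tie correction and
#' a 0.5 continuity correction is used.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with \code{U} (statistic for group \code{a}),
#'   \code{p.value}, and \code{method} ("exact" or "normal").
#' @export
mannWhitney <- function(a, b) {
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) == 0 || length(b) == 0)
        stop("both samples must be non-empty")
    n1 <- length(a); n2 <- length(b)
    r <- rank(c(a, b))
    U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
    ties <- anyDuplicated(c(a, b)) > 0
    if (!ties && n1 <= 8 && n2 <= 8) {
        dist <- .uCountDistribution(n1, n2)        # counts of U = 0..n1*n2
        total <- sum(dist)
        mid <- n1 * n2 / 2
        uLo <- min(U, n1 * n2 - U)
        uHi <- max(U, n1 * n2 - U)
        p <- (sum(dist[seq_len(uLo + 1)]) +
              sum(dist[(uHi + 1):(n1 * n2 + 1)])) / total
        if (uLo == uHi)  # central value counted twice
            p <- p - dist[uLo + 1] / total
        return(list(U = U, p.value = min(1, p), method = "exact"))
    }
    n <- n1 + n2
    tieTab <- table(r)
    tieCorr <- sum(tieTab^3 - tieTab) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tieCorr)
    mu <- n1 * n2 / 2
    z <- (abs(U - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    list(U = U, p.value = min(1, 2 * pnorm(-z)), method = "normal")
}

# Number of ways to choose n1 ranks out of n1+n2 giving each value of U,
# via the standard rank-sum recursion on the largest remaining observation.
.uCountDistribution <- function(n1, n2) {
    # f[i+1, j+1, ] = distribution of U for sizes i, j
    maxU <- n1 * n2
    f <- vector("list", n1 + 1)
    for (i in 0:n1) f[[i + 1]] <- vector("list", n2 + 1)
    for (j in 0:n2) f[[1]][[j + 1]] <- c(1, rep(0, maxU))
    for (i in 1:n1) f[[i + 1]][[1]] <- c(1, rep(0, maxU))
    for (i in 1:n1) {
        for (j in 1:n2) {
            # largest observation comes from group 1 (adds j to U) or group 2
            v1 <- f[[i]][[j + 1]]
            v2 <- f[[i + 1]][[j]]
            shifted <- c(rep(0, j), v1[seq_len(maxU + 1 - j)])
            f[[i + 1]][[j + 1]] <- shifted + v2
        }
    }
    f[[n1 + 1]][[n2 + 1]]
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks; the p-value uses the
#' t-distribution approximation with n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 3 complete pairs.
#' @return list with \code{rho} and \code{p.value}.
#' @export
spearmanTest <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    n <- length(x)
    if (n < 3)
        stop("at least 3 complete pairs required")
    rho <- cor(rank(x), rank(y))
    if (is.na(rho)) return(list(rho = NA_real_, p.value = NA_real_))
    if (abs(rho) >= 1) return(list(rho = rho, p.value = 0))
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    list(rho = rho, p.value = 2 * pt(-abs(tstat), df = n - 2))
}

#' Upper-tail hypergeometric overlap test
#'
#' P(X >= overlap) where X is the overlap of a random set of
#' \code{set2Size} elements with a fixed set of \code{set1Size} elements
#' drawn from a universe of \code{universe} elements.
#'
#' @param set1Size,set2Size,overlap,universe non-negative integers with
#'   \code{overlap <= min(set1Size, set2Size) <= universe}.
#' @return upper-tail p-value.
#' @export
hypergeometricOverlap <- function(set1Size, set2Size, overlap, universe) {
    if (overlap > min(set1Size, set2Size) || max(set1Size, set2Size) > universe)
        stop("require overlap <= min(set sizes) <= universe")
    if (overlap == 0) return(1)
    phyper(overlap - 1, set1Size, universe - set1Size, set2Size,
           lower.tail = FALSE)
}

#' Demographics-style group summary table
#'
#' Per-covariate comparison of two response groups: categorical covariates
#' are tested level-vs-rest with two-sided Fisher exact tests (unknowns/NA
#' excluded), continuous covariates with the two-sided Mann-Whitney test;
#' medians and counts per group are reported.
#'
#' @param clinical data.frame with a \code{patient_id} column.
#' @param assignment data.frame with \code{patient_id} and
#'   \code{response_class} columns; rows with class \code{"unassigned"} are
#'   ignored.
#' @param categorical,continuous character vectors naming the clinical
#'   columns to summarize.
#' @return data.frame with one row per covariate level (categorical) or per
#'   covariate (continuous): group counts or medians and the test p-value.
#' @export
table1Summary <- function(clinical, assignment,
                          categorical = c("grade", "histology", "chemo"),
                          continuous = c("ki67_baseline", "ki67_2wk")) {
    assignment <- assignment[assignment$response_class %in% c("GR", "PR"), ]
    groups <- split(assignment$patient_id, assignment$response_class)
    if (length(groups) < 2)
        stop("assignment must cover at least 2 groups")
    clin <- clinical[match(assignment$patient_id, clinical$patient_id), ]
    grp <- assignment$response_class
    rows <- list()
    for (v in categorical) {
        x <- as.character(clin[[v]])
        known <- !is.na(x) & x != "unknown"
        if (!any(known & grp == "GR") || !any(known & grp == "PR")) {
            warning(sprintf("covariate '%s' all-unknown in a group; skipped", v))
            next
        }
        for (lev in sort(unique(x[known]))) {
            a <- sum(known & grp == "GR" & x == lev)
            b <- sum(known & grp == "GR" & x != lev)
            cc <- sum(known & grp == "PR" & x == lev)
            d <- sum(known & grp == "PR" & x != lev)
            rows[[length(rows) + 1]] <- data.frame(
                covariate = v, level = lev,
                GR = a, PR = cc,
                GR_stat = a / (a + b), PR_stat = cc / (cc + d),
                p.value = fisherExact2x2(a, b, cc, d), test = "fisher",
                stringsAsFactors = FALSE)
        }
    }
    for (v in continuous) {
        x <- clin[[v]]
        xa <- x[grp == "GR" & !is.na(x)]
        xb <- x[grp == "PR" & !is.na(x)]
        if (length(xa) == 0 || length(xb) == 0) {
            warning(sprintf("covariate '%s' missing in a group; skipped", v))
            next
        }
        rows[[length(rows) + 1]] <- data.frame(
            covariate = v, level = NA_character_,
            GR = length(xa), PR = length(xb),
            GR_stat = median(xa), PR_stat = median(xb),
            p.value = mannWhitney(xa, xb)$p.value, test = "mann-whitney",
            stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
}
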