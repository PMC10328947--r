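# Shared fixtures: a small simulation configuration and brute-force
# oracles used across test files.

SUBTYPES <- c("LumA", "LumB", "HER2e", "Basal")

smallConfig <- function(seed = 1, ...) {
    simConfig(nPatients = 150, nBackgroundGenes = 150, seed = seed, ...)
}

# direct hypergeometric pmf from binomial coefficients (no dhyper)
chooseLog <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

hyperPmf <- function(a, m, nn, k) {
    exp(chooseLog(m, a) + chooseLog(nn, k - a) - chooseLog(m + nn, k))
}

# enumeration oracle for the two-sided Fisher test on (a, b; c, d)
fisherOracle <- function(a, b, c, d) {
    m <- a + b; nn <- c + d; k <- a + c
    lo <- max(0, k - nn); hi <- min(k, m)
    probs <- vapply(lo:hi, function(x) hyperPmf(x, m, nn, k), 0)
    pObs <- hyperPmf(a, m, nn, k)
    min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

# brute-force ssGSEA: literal walk down the ranking
ssgseaOracle <- function(expr, set, alpha = 0.25) {
    genes <- names(expr)
    ord <- order(-expr, genes)
    rnk <- rank(expr)[ord]
    inSet <- genes[ord] %in% set
    num <- 0; den <- sum(rnk[inSet]^alpha)
    nOut <- sum(!inSet); outCum <- 0; total <- 0
    for (i in seq_along(ord)) {
        if (inSet[i]) num <- num + rnk[i]^alpha else outCum <- outCum + 1
        total <- total + num / den - outCum / nOut
    }
    unname(total)
}
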