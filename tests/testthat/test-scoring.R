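test_that("ssGSEA matches the brute-force weighted-ECDF oracle", {
    set.seed(61)
    expr <- setNames(rnorm(5, 5), paste0("g", 1:5))
    expect_equal(ssgseaScore(expr, c("g1", "g3")),
                 ssgseaOracle(expr, c("g1", "g3")), tolerance = 1e-12)
    # top-ranked set genes give the maximal score over placements
    exprTop <- setNames(c(10, 9, 1, 0.5, 0.2), paste0("g", 1:5))
    sTop <- ssgseaScore(exprTop, c("g1", "g2"))
    others <- combn(paste0("g", 1:5), 2, function(s)
        ssgseaScore(exprTop, s))
    expect_equal(sTop, max(others))
    expect_gt(sTop, 0)
    # identical expression vectors give identical scores
    expect_equal(ssgseaScore(expr, c("g2", "g4")),
                 ssgseaScore(expr, c("g2", "g4")))
    expect_warning(s <- ssgseaScore(expr, "absent"), "no genes")
    expect_true(is.na(s))
})

test_that("ssGSEA depends only on ranks", {
    set.seed(62)
    expr <- setNames(rnorm(30), sprintf("g%02d", 1:30))
    set <- sample(names(expr), 8)
    expect_equal(ssgseaScore(expr, set),
                 ssgseaScore(10 * exp(expr) + 3, set))
})

test_that("with alpha=0, complementary sets score equal and opposite", {
    set.seed(63)
    expr <- setNames(rnorm(20), sprintf("g%02d", 1:20))
    A <- names(expr)[1:8]
    B <- setdiff(names(expr), A)
    expect_equal(ssgseaScore(expr, A, alpha = 0),
                 -ssgseaScore(expr, B, alpha = 0), tolerance = 1e-10)
})

test_that("score matrix drops sets outside size bounds and duplicates rows for duplicate sets", {
    set.seed(64)
    m <- matrix(rnorm(60, 6), 20, 3,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
    sets <- list(big = sprintf("g%02d", 1:10),
                 tiny = c("g01", "g02"),
                 bigCopy = sprintf("g%02d", 1:10))
    expect_message(sm <- scoreMatrix(m, sets, minSize = 5), "dropping 1")
    expect_equal(rownames(sm), c("big", "bigCopy"))
    expect_equal(sm["big", ], sm["bigCopy", ])
    expect_equal(nrow(scoreMatrix(m, list(), minSize = 5)), 0)
})

test_that("preranked GSEA: extreme sets, reversal antisymmetry, uniform null p", {
    set.seed(65)
    stats <- setNames(sort(rnorm(100), decreasing = TRUE),
                      sprintf("g%03d", 1:100))
    topSet <- list(top = names(stats)[1:10])
    res <- prerankedGsea(stats, topSet, nPerm = 500, seed = 1)
    expect_gt(res$es, 0)
    expect_lte(res$p_value, 0.01)
    # reversing the ranking flips the sign of ES
    resRev <- prerankedGsea(-stats, topSet, nPerm = 200, seed = 1)
    expect_equal(resRev$es, -res$es, tolerance = 1e-12)
    # random sets under a random ranking: uniform p-values
    set.seed(66)
    rstats <- setNames(rnorm(300), sprintf("r%03d", 1:300))
    rsets <- lapply(1:60, function(i) sample(names(rstats), 15))
    names(rsets) <- paste0("S", 1:60)
    rres <- prerankedGsea(rstats, rsets, nPerm = 200, seed = 2)
    # permutation p-values are discrete; suppress the KS ties warning
    expect_gt(suppressWarnings(ks.test(rres$p_value, "punif")$p.value), 0.01)
    expect_error(prerankedGsea(rstats, rsets, nPerm = 50), "100")
})

test_that("preranked enrichment scores agree with fgsea", {
    skip_if_not_installed("fgsea")
    set.seed(67)
    stats <- setNames(rnorm(200), sprintf("g%03d", 1:200))
    sets <- lapply(1:10, function(i) sample(names(stats), 20))
    names(sets) <- paste0("S", 1:10)
    mine <- prerankedGsea(stats, sets, nPerm = 200, seed = 3)
    ours <- vapply(sets, function(s) {
        so <- sort(stats, decreasing = TRUE)
        fgsea::calcGseaStat(so, which(names(so) %in% s), gseaParam = 1)
    }, 0)
    expect_equal(mine$es, unname(ours[mine$set]), tolerance = 1e-8)
})

test_that("H/I ratio is the log2 expression difference", {
    m <- rbind(HOXB13 = c(3, 8), IL17BR = c(3, 6))
    colnames(m) <- c("s1", "s2")
    expect_equal(unname(hiRatio(m)), c(0, 2))
    expect_error(hiRatio(m[1, , drop = FALSE]), "IL17BR")
})

test_that("H/I is higher in resistant tumours on the synthetic cohort", {
    co <- generateCohort(smallConfig(seed = 71))
    norm <- log2Normalized(cohortCounts(co))
    hi <- hiRatio(norm)
    truth <- cohortTruth(co)
    expect_gt(mean(hi[truth$sample_id[truth$resistant]]),
              mean(hi[truth$sample_id[!truth$resistant]]))
})

test_that("score correlation matrix is symmetric with unit diagonal", {
    set.seed(68)
    sc <- rbind(a = rnorm(30), b = rnorm(30))
    sc <- rbind(sc, c = sc["a", ], d = -sc["a", ])
    out <- scoreCorrelationMatrix(sc)
    expect_equal(out$rho["a", "c"], 1)
    expect_equal(out$rho["a", "d"], -1)
    expect_equal(out$rho, t(out$rho))
    expect_equal(diag(out$rho), setNames(rep(1, 4), rownames(sc)))
    expect_error(scoreCorrelationMatrix(sc[, 1:2]), "3 samples")
})

test_that("covariate correlation applies the exclusion rule and recovers couplings", {
    set.seed(69)
    sc <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("x", "y"), sprintf("s%02d", 1:20)))
    cov <- setNames(c(135, rnorm(19, 50, 10)), colnames(sc))
    out <- covariateScoreCorrelation(cov, sc, exclusionThreshold = 130)
    expect_equal(out$n, c(19, 19))
    # covariate equal to a score row correlates 1
    cov2 <- setNames(sc["x", ], colnames(sc))
    out2 <- covariateScoreCorrelation(cov2, sc)
    expect_equal(out2$rho[out2$set == "x"], 1)
    expect_error(covariateScoreCorrelation(cov[1:2], sc[, 1:2]), "3 usable")
})

test_that("configured estradiol-to-estrogen-response coupling is recovered", {
    co <- generateCohort(smallConfig(seed = 70, estrogenCoupling = 0.6))
    norm <- log2Normalized(cohortCounts(co))
    gt <- geneTruth(co)
    estSet <- list(estrogen_response = gt$gene[gt$panel == "estrogen"])
    sm <- scoreMatrix(norm, estSet)
    clin <- clinicalTable(co)
    cov <- setNames(clin$estradiol, clin$patient_id)
    out <- covariateScoreCorrelation(cov, sm, exclusionThreshold = 130)
    expect_gt(out$rho, 0)
    expect_lt(out$fdr, 0.05)
})
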