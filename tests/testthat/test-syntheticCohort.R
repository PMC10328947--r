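test_that("generation is reproducible under a fixed seed", {
    cfg <- smallConfig(seed = 4)
    a <- generateCohort(cfg)
    b <- generateCohort(cfg)
    expect_identical(cohortCounts(a), cohortCounts(b))
    expect_identical(clinicalTable(a), clinicalTable(b))
    expect_identical(mutationTable(a), mutationTable(b))
    expect_identical(cohortTruth(a), cohortTruth(b))
    expect_true(all(segmentTable(a) == segmentTable(b)))
})

test_that("counts are NB-like non-negative integers with complete truth", {
    co <- generateCohort(smallConfig(seed = 14))
    cts <- cohortCounts(co)
    expect_true(all(cts >= 0))
    expect_true(all(cts == round(cts)))
    truth <- cohortTruth(co)
    expect_equal(nrow(truth), ncol(cts))
    expect_true(all(truth$subtype %in% SUBTYPES))
    clin <- clinicalTable(co)
    expect_true(all(clin$ki67_baseline > 0))
    expect_true(all(clin$ki67_2wk >= 0 & clin$ki67_2wk <= 100))
    # resistant samples' proportional change was drawn from the
    # poor-responder distribution (support up to +184)
    expect_true(all(truth$pc_true[truth$resistant] >= -48 - 1e-9))
    expect_true(all(truth$pc_true[!truth$resistant] <= -80 + 1e-9))
})

test_that("configured marginals are recovered within 3 binomial SEs", {
    cfg <- simConfig(nPatients = 1000, nBackgroundGenes = 50, seed = 15)
    co <- generateCohort(cfg)
    truth <- cohortTruth(co)
    filt <- filterSomatic(mutationTable(co))
    n <- nrow(truth)
    se <- function(p) sqrt(p * (1 - p) / n)
    for (g in c("PIK3CA", "TP53")) {
        p <- cfg$mutationPrevalence[[g]]
        obs <- length(unique(filt$sample_id[filt$gene == g])) / n
        expect_lt(abs(obs - p), 3 * se(p))
    }
    expect_lt(abs(mean(truth$resistant) - 0.15), 3 * se(0.15))
    for (s in SUBTYPES) {
        p <- cfg$subtypeProportions[[s]]
        expect_lt(abs(mean(truth$subtype == s) - p), 3 * se(p))
    }
})

test_that("ESR1 expression is bimodal with the configured low fraction", {
    cfg <- simConfig(nPatients = 400, nBackgroundGenes = 50,
                     esr1LowFraction = 0.15, seed = 16)
    co <- generateCohort(cfg)
    norm <- log2Normalized(cohortCounts(co))
    esr1 <- normValues(norm)["ESR1", ]
    obs <- mean(esr1 < 12)
    expect_lt(abs(obs - 0.15), 3 * sqrt(0.15 * 0.85 / 400))
    # the modes are separated: few values near the boundary
    expect_lt(mean(esr1 > 11.3 & esr1 < 11.9), 0.05)
})

test_that("training set is balanced, shares panel genes, and mean-agrees without shift", {
    cfg <- smallConfig(seed = 17, platformShiftSd = 0)
    tr <- generateTrainingSet(cfg, 10)
    expect_equal(ncol(tr$matrix), 40)
    expect_equal(as.vector(table(tr$labels)), rep(10, 4))
    co <- generateCohort(cfg)
    expect_true(all(rownames(tr$matrix) %in% rownames(cohortCounts(co))))
    # per-subtype per-gene means agree within sampling error (no shift)
    norm <- log2Normalized(cohortCounts(co))
    truth <- cohortTruth(co)
    pam <- setdiff(rownames(tr$matrix), "ESR1")
    diffs <- vapply(SUBTYPES, function(s) {
        st <- truth$sample_id[truth$subtype == s]
        if (length(st) < 10) return(0)
        mean(rowMeans(normValues(norm)[pam, st, drop = FALSE]) -
             rowMeans(tr$matrix[pam, tr$labels == s, drop = FALSE]))
    }, 0)
    expect_lt(max(abs(diffs)), 0.25)
    expect_error(generateTrainingSet(cfg, 0), "at least 1")
})

test_that("platform offsets have the half-normal mean when sd is 1", {
    cfg <- simConfig(nPatients = 10, nBackgroundGenes = 2000,
                     platformShiftSd = 1, seed = 18)
    co <- generateCohort(cfg)
    gt <- geneTruth(co)
    shifts <- gt$platform_shift[gt$gene != "ESR1"]
    # E|N(0,1)| = sqrt(2/pi) = 0.7979; MC error at ~2100 genes
    expect_lt(abs(mean(abs(shifts)) - sqrt(2 / pi)),
              3 * 0.6 / sqrt(length(shifts)))
})

test_that("reference calls carry the configured error rate", {
    co <- generateCohort(smallConfig(seed = 19))
    truth <- cohortTruth(co)
    rc0 <- generateReferenceCalls(truth, 50, 0, seed = 2)
    expect_equal(rc0$label, rc0$true_subtype)
    # expected concordant calls: binomial mean n * (1 - error)
    conc <- vapply(1:40, function(s)
        sum(generateReferenceCalls(truth, 59, 0.03,
                                   seed = s)$label ==
            truth$subtype[match(generateReferenceCalls(truth, 59, 0.03,
                                                       seed = s)$sample_id,
                                truth$sample_id)]), 0)
    expect_lt(abs(mean(conc) - 59 * 0.97), 3 * sqrt(59 * 0.97 * 0.03) /
              sqrt(40))
    expect_error(generateReferenceCalls(truth, 0), "at least 1")
    expect_error(generateReferenceCalls(truth, nrow(truth) + 1), "exceeds")
})

test_that("zeroed resistance effects decouple resistance from covariates", {
    pvals <- vapply(1:8, function(s) {
        eff <- c(esr1_low = 0, her2e = 0, basal = 0, tp53_mut = 0,
                 immune_score = 0)
        co <- generateCohort(smallConfig(seed = 100 + s,
                                         resistanceEffects = eff))
        truth <- cohortTruth(co)
        suppressWarnings(chisq.test(table(truth$resistant,
                                          truth$subtype))$p.value)
    }, 0)
    expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("segments are valid and CNA truth flags match the segment data", {
    co <- generateCohort(smallConfig(seed = 20))
    segs <- segmentTable(co)
    expect_true(all(GenomicRanges::start(segs) <= GenomicRanges::end(segs)))
    called <- callSegments(segs)
    truth <- cohortTruth(co)
    st <- tp53CompoundStatus(data.frame(sample_id = character(),
                                        gene = character()),
                             called, truth$sample_id)
    expect_equal(unname(st == "loss_only"), truth$tp53_loss)
})

test_that("invalid configurations are rejected", {
    expect_error(simConfig(subtypeProportions = c(LumA = 0.5, LumB = 0.5,
                                                  HER2e = 0.2, Basal = 0)),
                 "sum to 1")
    expect_error(simConfig(nPatients = -5), "positive")
    expect_error(simConfig(esr1LowFraction = 1.4), "fractions")
    expect_error(generateCohort(list(nPatients = 10)), "simConfig")
})
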