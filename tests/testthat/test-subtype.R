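mkCentroids <- function(m) new("CentroidSet", centroids = m)

test_that("gene centering and the median centering vector are exact", {
    m <- matrix(rnorm(20), 5, 4,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
    expect_equal(geneCenter(m, setNames(rep(0, 5), rownames(m))), m)
    cvec <- setNames(rep(2, 5), rownames(m))
    expect_equal(geneCenter(m, cvec), m - 2)
    med <- medianCenteringVector(m)
    expect_equal(med, apply(m, 1, median))
    centered <- geneCenter(m, med)
    expect_equal(unname(apply(centered, 1, median)), rep(0, 5))
    # single sample: the vector is that sample
    expect_equal(medianCenteringVector(m[, 1, drop = FALSE]), m[, 1])
    expect_error(geneCenter(m, cvec[1:3]), "missing gene")
})

test_that("centroid correlation recovers self, flags flats, matches a rank oracle", {
    set.seed(31)
    cm <- matrix(rnorm(24), 6, 4,
                 dimnames = list(paste0("g", 1:6), SUBTYPES))
    cents <- mkCentroids(cm)
    # a sample equal to the LumA centroid correlates 1 with it
    call <- centroidCorrelate(cm[, "LumA"], cents)
    expect_equal(call$label, "LumA")
    expect_equal(call$cor_LumA, 1)
    # anti-correlated profile puts Basal last
    callNeg <- centroidCorrelate(-cm[, "Basal"], cents)
    expect_equal(callNeg$cor_Basal, -1)
    expect_true(all(callNeg$cor_Basal <= unlist(
        callNeg[paste0("cor_", SUBTYPES)])))
    # brute-force Spearman oracle on a toy profile
    x <- c(g1 = 2.3, g2 = -1, g3 = 0.4, g4 = 5, g5 = -2, g6 = 0)
    call2 <- centroidCorrelate(x, cents)
    for (s in SUBTYPES)
        expect_equal(call2[[paste0("cor_", s)]],
                     cor(rank(x), rank(cm[, s])))
    # constant profile is unclassifiable
    flat <- centroidCorrelate(setNames(rep(1, 6), rownames(cm)), cents)
    expect_true(flat$unclassifiable)
    expect_true(is.na(flat$label))
})

test_that("composition-matched subsets have exact composition or signal resample", {
    labels <- rep(SUBTYPES, c(10, 10, 5, 5))
    idx <- compositionMatchedSubset(labels,
                                    c(Basal = 4, HER2e = 3, LumB = 1),
                                    seed = 3)
    expect_length(idx, 8)
    expect_equal(as.vector(table(factor(labels[idx], levels = SUBTYPES))),
                 c(0, 1, 3, 4))
    expect_error(compositionMatchedSubset(labels, c(Basal = 0)), "empty")
    expect_identical(
        compositionMatchedSubset(labels, c(Basal = 6), seed = 1),
        "resample")
})

test_that("calibration search attains perfect concordance in the shift-free limit", {
    cfg <- smallConfig(seed = 5, platformShiftSd = 0, latentNoiseSd = 0.1,
                       sampleNoiseSd = 0.1, nbDispersion = 0.01)
    co <- generateCohort(cfg)
    tr <- generateTrainingSet(cfg, 40)
    cents <- centroidsFromTraining(tr$matrix, tr$labels)
    rc <- generateReferenceCalls(cohortTruth(co), 40, 0, seed = 6)
    norm <- log2Normalized(cohortCounts(co))
    cal <- calibrationSearch(norm, rc, tr$matrix, tr$labels, cents,
                             nIter = 1000, seed = 7)
    expect_equal(cal@bestConcordance, 1.0)
    expect_true(cal@bestK >= 5 && cal@bestK <= 15)
    # whole-cohort calls recover the truth in this easy regime
    calls <- assignSubtypes(norm, cal, cents)
    truth <- cohortTruth(co)
    acc <- mean(calls$label ==
                truth$subtype[match(calls$sample_id, truth$sample_id)])
    expect_gte(acc, 0.95)
})

test_that("calibrated calls are deterministic and shift-invariant", {
    cfg <- smallConfig(seed = 8)
    co <- generateCohort(cfg)
    tr <- generateTrainingSet(cfg, 40)
    cents <- centroidsFromTraining(tr$matrix, tr$labels)
    rc <- generateReferenceCalls(cohortTruth(co), 30, 0.03, seed = 9)
    norm <- log2Normalized(cohortCounts(co))
    cal1 <- calibrationSearch(norm, rc, tr$matrix, tr$labels, cents,
                              nIter = 2000, seed = 10)
    cal2 <- calibrationSearch(norm, rc, tr$matrix, tr$labels, cents,
                              nIter = 2000, seed = 10)
    expect_identical(centeringVector(cal1), centeringVector(cal2))
    expect_identical(assignSubtypes(norm, cal1, cents),
                     assignSubtypes(norm, cal2, cents))
    # adding one constant per-gene vector to study AND training leaves
    # calibrated calls invariant (it cancels in the centering vector)
    offset <- setNames(rnorm(nrow(tr$matrix)), rownames(tr$matrix))
    vals <- normValues(norm)[rownames(tr$matrix), ]
    cal3 <- calibrationSearch(vals + offset, rc, tr$matrix + offset,
                              tr$labels, cents, nIter = 2000, seed = 10)
    expect_equal(centeringVector(cal3) - centeringVector(cal1),
                 offset[names(centeringVector(cal1))], tolerance = 1e-10)
    expect_identical(assignSubtypes(vals + offset, cal3, cents),
                     assignSubtypes(vals, cal1, cents))
})

test_that("rank-based classification is invariant to monotone per-sample transforms", {
    set.seed(41)
    cm <- matrix(rnorm(200), 50, 4,
                 dimnames = list(sprintf("g%02d", 1:50), SUBTYPES))
    cents <- mkCentroids(cm)
    x <- matrix(rnorm(100, 5), 50, 2,
                dimnames = list(rownames(cm), c("s1", "s2")))
    a <- centroidCorrelate(x, cents)
    b <- centroidCorrelate(exp(x / 2) + 7, cents)   # strictly monotone
    expect_equal(a[, paste0("cor_", SUBTYPES)], b[, paste0("cor_", SUBTYPES)])
})

test_that("best concordance is non-decreasing with more iterations", {
    cfg <- smallConfig(seed = 12)
    co <- generateCohort(cfg)
    tr <- generateTrainingSet(cfg, 40)
    cents <- centroidsFromTraining(tr$matrix, tr$labels)
    rc <- generateReferenceCalls(cohortTruth(co), 40, 0.05, seed = 13)
    norm <- log2Normalized(cohortCounts(co))
    concs <- vapply(c(200, 2000, 10000), function(ni)
        calibrationSearch(norm, rc, tr$matrix, tr$labels, cents,
                          nIter = ni, seed = 14)@bestConcordance, 0)
    expect_true(all(diff(concs) >= 0))
})

test_that("centroid tables round-trip through TSV", {
    set.seed(51)
    cm <- matrix(rnorm(20), 5, 4,
                 dimnames = list(paste0("g", 1:5), SUBTYPES))
    f <- tempfile(fileext = ".tsv")
    writeCentroids(mkCentroids(cm), f)
    expect_equal(centroidMatrix(readCentroids(f)), cm)
})
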