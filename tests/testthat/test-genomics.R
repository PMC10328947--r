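mkSeg <- function(sample, chrom, start, end, lr) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                           sample_id = sample, log2_ratio = lr)
}

test_that("somatic filters are conjunctive with a removal log", {
    muts <- data.frame(
        sample_id = paste0("S", 1:5), gene = "TP53",
        vaf = c(0.04, 0.2, 0.2, 0.2, 0.2),
        alt_reads = c(20, 4, 20, 20, 20),
        consequence_class = c("high", "high", "low", "high", "moderate"),
        pop_af = c(0, 0, 0, 1e-3, 0),
        variant_classification = "Missense_Mutation",
        stringsAsFactors = FALSE)
    out <- filterSomatic(muts)
    expect_equal(out$sample_id, "S5")
    log <- attr(out, "filter_log")
    expect_equal(unname(log["removed_vaf"]), 1)
    expect_equal(unname(log["removed_alt_reads"]), 1)
    expect_equal(unname(log["removed_consequence"]), 1)
    expect_equal(unname(log["removed_pop_af"]), 1)
    # retained set is a subset of the input regardless of filter order
    expect_true(all(out$sample_id %in% muts$sample_id))
})

test_that("TMB counts zeros and the group comparison recovers enrichment", {
    filtered <- data.frame(sample_id = c("A", "A", "B"), gene = c("X", "Y", "X"),
                           stringsAsFactors = FALSE)
    expect_equal(tmb(filtered, samples = c("A", "B", "C")),
                 c(A = 2L, B = 1L, C = 0L))
    cmp <- groupTmbCompare(c(1, 2, 3), c(1, 2, 3))
    expect_equal(cmp$p.value, 1)
    co <- generateCohort(smallConfig(seed = 77))
    truth <- cohortTruth(co)
    filt <- filterSomatic(mutationTable(co))
    burden <- tmb(filt, samples = truth$sample_id)
    cmpT <- groupTmbCompare(burden[truth$tp53_mut], burden[!truth$tp53_mut])
    expect_gt(cmpT$mean_a, cmpT$mean_b)
})

test_that("per-gene mutation comparison skips rare genes and bounds false discoveries", {
    fA <- data.frame(sample_id = c("A1", "A2", "A3", "A1"),
                     gene = c("TP53", "TP53", "TP53", "RARE"),
                     stringsAsFactors = FALSE)
    fB <- data.frame(sample_id = "B1", gene = "TP53",
                     stringsAsFactors = FALSE)
    out <- geneMutationCompare(fA, fB, paste0("A", 1:10), paste0("B", 1:10))
    expect_false("RARE" %in% out$gene)
    expect_equal(out$p_value[out$gene == "TP53"],
                 fisherExact2x2(3, 7, 1, 9))
    # equal-prevalence simulation: BH-significant fraction at most nominal
    set.seed(79)
    sig <- 0L; tests <- 0L
    for (rep in 1:5) {
        sa <- sprintf("A%02d", 1:40); sb <- sprintf("B%02d", 1:40)
        mk <- function(samples) {
            hits <- lapply(sprintf("G%02d", 1:25), function(g)
                data.frame(sample_id = samples[runif(40) < 0.15], gene = g,
                           stringsAsFactors = FALSE))
            do.call(rbind, hits)
        }
        out <- geneMutationCompare(mk(sa), mk(sb), sa, sb)
        sig <- sig + sum(out$fdr < 0.05)
        tests <- tests + nrow(out)
    }
    expect_lte(sig / tests, 0.05)
})

test_that("segment calls respect inclusive thresholds", {
    segs <- mkSeg("S1", "chr1", c(1, 100, 200), c(50, 150, 250),
                  c(0, 0.2, -0.5))
    called <- callSegments(segs)
    expect_equal(called$call, c("neutral", "gain", "loss"))
})

test_that("binning assigns majority-overlap calls and flags uncovered bins", {
    lens <- c(chr1 = 9e6)
    # whole-chromosome gain: every bin gains
    segs <- callSegments(mkSeg("S1", "chr1", 1, 9e6, 0.5))
    bc <- binCna(segs, lens)
    expect_equal(unname(bc$calls[, "S1"]), rep("gain", 3))
    # 40%/60% split within one bin: majority wins
    segs2 <- callSegments(c(mkSeg("S2", "chr1", 1, 1.2e6, 0.5),
                            mkSeg("S2", "chr1", 1200001, 3e6, -0.5)))
    bc2 <- binCna(segs2, lens)
    expect_equal(unname(bc2$calls[1, "S2"]), "loss")
    expect_true(all(is.na(bc2$calls[2:3, "S2"])))  # uncovered bins
})

test_that("bin group comparison flags a strong differential bin", {
    lens <- c(chr1 = 3e6)
    gainers <- do.call(c, lapply(sprintf("A%03d", 1:100), function(s)
        callSegments(mkSeg(s, "chr1", 1, 3e6, 0.5))))
    mixedB <- do.call(c, lapply(seq_len(100), function(i)
        callSegments(mkSeg(sprintf("B%03d", i), "chr1", 1, 3e6,
                           if (i <= 5) 0.5 else 0))))
    # 80 of A gain vs 5 of B
    binsA <- binCna(gainers[gainers$sample_id <= "A080"], lens)
    binsB <- binCna(mixedB, lens)
    out <- binGroupCompare(binsA, binsB)
    gainRow <- out[out$direction == "gain", ]
    expect_equal(gainRow$p_value, fisherExact2x2(80, 0, 5, 95))
    expect_lt(gainRow$fdr, 0.05)
    # identical groups: nothing significant
    out2 <- binGroupCompare(binsB, binsB)
    expect_true(all(out2$fdr > 0.05))
})

test_that("chromosomal instability is a length fraction, split-invariant", {
    segs <- callSegments(c(mkSeg("S1", "chr1", 1, 50, 0),
                           mkSeg("S1", "chr1", 51, 100, 0.5)))
    expect_equal(unname(chromosomalInstability(segs)), 0.5)
    allNeutral <- callSegments(mkSeg("S2", "chr1", 1, 100, 0))
    expect_equal(unname(chromosomalInstability(allNeutral)), 0)
    allGain <- callSegments(mkSeg("S3", "chr1", 1, 100, 1))
    expect_equal(unname(chromosomalInstability(allGain)), 1)
    # splitting a segment with the same ratio changes nothing
    split <- callSegments(c(mkSeg("S1", "chr1", 1, 25, 0),
                            mkSeg("S1", "chr1", 26, 50, 0),
                            mkSeg("S1", "chr1", 51, 80, 0.5),
                            mkSeg("S1", "chr1", 81, 100, 0.5)))
    expect_equal(chromosomalInstability(split),
                 chromosomalInstability(segs))
})

test_that("compound TP53 status needs both mutation and overlapping loss", {
    muts <- data.frame(sample_id = c("S1", "S2"), gene = "TP53",
                       stringsAsFactors = FALSE)
    segs <- callSegments(c(
        mkSeg("S1", "chr17", 7e6, 8e6, -0.5),   # loss over the locus
        mkSeg("S2", "chr17", 7e6, 8e6, 0),      # neutral locus
        mkSeg("S3", "chr17", 7e6, 8e6, -0.5),   # loss, no mutation
        mkSeg("S4", "chr17", 7e6, 8e6, 0)))
    st <- tp53CompoundStatus(muts, segs, paste0("S", 1:4))
    expect_equal(unname(st), c("compound", "mut_only", "loss_only",
                               "neither"))
    cmp <- tp53CompoundCompare(st[1:2], st[3:4])
    expect_equal(cmp$frac_a, 0.5)
    expect_equal(cmp$frac_b, 0)
})
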