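# Somatic-mutation filtering, burden and per-gene comparison, copy-number
# binning and comparison, chromosomal instability and compound TP53 status.

#' Filter somatic mutations
#'
#' Retains rows with VAF >= 0.05, at least 5 alternative reads, high or
#' moderate protein consequence, and population allele frequency below
#' 1e-5. Filters are conjunctive and order-independent; a per-rule removal
#' log is attached as the \code{"filter_log"} attribute.
#'
#' @param muts mutation data.frame (see \code{\link{readMaf}}).
#' @param minVaf,minAltReads,maxPopAf filter thresholds.
#' @param consequences retained consequence classes.
#' @return the retained subset, with attribute \code{filter_log}.
#' @export
filterSomatic <- function(muts, minVaf = 0.05, minAltReads = 5,
                          maxPopAf = 1e-5,
                          consequences = c("high", "moderate")) {
    passVaf <- !is.na(muts$vaf) & muts$vaf >= minVaf
    passAlt <- !is.na(muts$alt_reads) & muts$alt_reads >= minAltReads
    passCons <- !is.na(muts$consequence_class) &
        muts$consequence_class %in% consequences
    passPop <- is.na(muts$pop_af) | muts$pop_af < maxPopAf
    keep <- passVaf & passAlt & passCons & passPop
    out <- muts[keep, , drop = FALSE]
    attr(out, "filter_log") <- c(
        input = nrow(muts),
        removed_vaf = sum(!passVaf),
        removed_alt_reads = sum(!passAlt),
        removed_consequence = sum(!passCons),
        removed_pop_af = sum(!passPop),
        retained = nrow(out))
    out
}

#' Tumour mutation burden
#'
#' Retained mutations per tumour; samples without retained mutations count
#' zero when listed in \code{samples}.
#'
#' @param filtered filtered mutation data.frame.
#' @param samples optional character vector of all sample ids.
#' @return named integer vector of mutation counts.
#' @export
tmb <- function(filtered, samples = NULL) {
    if (is.null(samples)) samples <- unique(filtered$sample_id)
    counts <- table(factor(filtered$sample_id, levels = samples))
    setNames(as.integer(counts), samples)
}

#' Compare tumour mutation burden between two groups
#'
#' @param tmbA,tmbB per-sample burdens of the two groups.
#' @return list with per-group means and the two-sided Mann-Whitney
#'   p-value.
#' @export
groupTmbCompare <- function(tmbA, tmbB) {
    if (length(tmbA) == 0 || length(tmbB) == 0)
        stop("both groups must be non-empty")
    mw <- mannWhitney(tmbA, tmbB)
    list(mean_a = mean(tmbA), mean_b = mean(tmbB),
         U = mw$U, p.value = mw$p.value)
}

#' Per-gene mutation prevalence comparison
#'
#' For each gene mutated in at least \code{minMutated} samples overall, a
#' two-sided Fisher exact test on the (mutated, wild-type) x group 2x2
#' table, with BH adjustment across tested genes.
#'
#' @param filteredA,filteredB filtered mutation tables of the two groups.
#' @param samplesA,samplesB sample ids per group (denominators).
#' @param minMutated minimum total mutated samples for a gene to be tested.
#' @return data.frame per tested gene: mutated/wild-type counts per group,
#'   p-value and FDR.
#' @export
geneMutationCompare <- function(filteredA, filteredB, samplesA, samplesB,
                                minMutated = 3) {
    if (length(samplesA) == 0 || length(samplesB) == 0)
        stop("both groups need at least one sample")
    genes <- sort(unique(c(filteredA$gene, filteredB$gene)))
    rows <- list()
    for (g in genes) {
        mutA <- length(unique(filteredA$sample_id[filteredA$gene == g]))
        mutB <- length(unique(filteredB$sample_id[filteredB$gene == g]))
        if (mutA + mutB < minMutated) next
        wtA <- length(samplesA) - mutA
        wtB <- length(samplesB) - mutB
        rows[[g]] <- data.frame(
            gene = g, mutated_a = mutA, wildtype_a = wtA,
            mutated_b = mutB, wildtype_b = wtB,
            p_value = fisherExact2x2(mutA, wtA, mutB, wtB),
            stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (!is.null(out)) {
        out$fdr <- bhAdjust(out$p_value)
        rownames(out) <- NULL
    }
    out
}

#' Call gains and losses on copy-number segments
#'
#' Gain iff log2 ratio >= \code{gainLog2} (boundary inclusive), loss iff
#' <= \code{lossLog2}, neutral otherwise.
#'
#' @param segments GRanges with \code{log2_ratio} metadata.
#' @param gainLog2,lossLog2 thresholds (defaults +0.2 / -0.2).
#' @return the same GRanges with an added \code{call} column
#'   (gain/neutral/loss).
#' @export
callSegments <- function(segments, gainLog2 = 0.2, lossLog2 = -0.2) {
    lr <- segments$log2_ratio
    segments$call <- ifelse(lr >= gainLog2, "gain",
                     ifelse(lr <= lossLog2, "loss", "neutral"))
    segments
}

#' Tile the genome into fixed-size bins
#'
#' @param chromLengths named vector of chromosome lengths (bp).
#' @param binSize bin width in bp (default 3 Mbp).
#' @return GRanges of non-overlapping bins tiling every chromosome.
#' @export
genomeBins <- function(chromLengths, binSize = 3e6) {
    grs <- lapply(names(chromLengths), function(ch) {
        starts <- seq(1, chromLengths[[ch]], by = binSize)
        ends <- pmin(starts + binSize - 1, chromLengths[[ch]])
        GenomicRanges::GRanges(ch, IRanges::IRanges(starts, ends))
    })
    do.call(c, grs)
}

#' Bin per-sample segment calls onto a fixed tiling
#'
#' Each bin takes the call of the segment covering the largest part of it
#' (majority overlap; exact ties resolve to neutral); bins with no
#' overlapping segment are flagged uncovered (NA).
#'
#' @param calledSegments GRanges with \code{sample_id} and \code{call}.
#' @param chromLengths named chromosome lengths.
#' @param binSize bin width (default 3 Mbp).
#' @param samples optional sample ids (columns); defaults to those present.
#' @return list with \code{bins} (GRanges) and \code{calls} (character
#'   matrix, bins x samples, values gain/neutral/loss/NA).
#' @export
binCna <- function(calledSegments, chromLengths, binSize = 3e6,
                   samples = NULL) {
    bins <- genomeBins(chromLengths, binSize)
    if (is.null(samples)) samples <- unique(calledSegments$sample_id)
    calls <- matrix(NA_character_, length(bins), length(samples),
                    dimnames = list(NULL, samples))
    hits <- GenomicRanges::findOverlaps(bins, calledSegments)
    ov <- IRanges::pintersect(bins[S4Vectors::queryHits(hits)],
                              calledSegments[S4Vectors::subjectHits(hits)])
    df <- data.frame(bin = S4Vectors::queryHits(hits),
                     sample = calledSegments$sample_id[
                         S4Vectors::subjectHits(hits)],
                     call = calledSegments$call[
                         S4Vectors::subjectHits(hits)],
                     width = GenomicRanges::width(ov),
                     stringsAsFactors = FALSE)
    if (nrow(df) > 0) {
        agg <- stats::aggregate(width ~ bin + sample + call, df, sum)
        sp <- split(agg, paste(agg$bin, agg$sample))
        for (part in sp) {
            best <- max(part$width)
            winners <- part$call[part$width == best]
            call <- if (length(winners) > 1) "neutral" else winners
            calls[part$bin[1], part$sample[1]] <- call
        }
    }
    list(bins = bins, calls = calls)
}

#' Per-bin, per-direction group comparison of CNA calls
#'
#' For every bin and each direction (gain, loss), a two-sided Fisher exact
#' test of (has that call, does not) x group, with BH across all
#' bin-direction tests. Uncovered bins count as no-call.
#'
#' @param binsA,binsB \code{binCna} results for the two groups (same
#'   tiling).
#' @return data.frame per bin x direction: counts, p-value, FDR.
#' @export
binGroupCompare <- function(binsA, binsB) {
    if (length(binsA$bins) != length(binsB$bins))
        stop("bin tilings differ between groups")
    nA <- ncol(binsA$calls); nB <- ncol(binsB$calls)
    rows <- list()
    for (dir in c("gain", "loss")) {
        hitA <- rowSums(binsA$calls == dir, na.rm = TRUE)
        hitB <- rowSums(binsB$calls == dir, na.rm = TRUE)
        for (i in seq_along(hitA)) {
            rows[[length(rows) + 1]] <- data.frame(
                bin = i,
                chrom = as.character(GenomicRanges::seqnames(binsA$bins))[i],
                start = GenomicRanges::start(binsA$bins)[i],
                end = GenomicRanges::end(binsA$bins)[i],
                direction = dir,
                n_a = hitA[i], n_b = hitB[i],
                p_value = fisherExact2x2(hitA[i], nA - hitA[i],
                                         hitB[i], nB - hitB[i]),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    out$fdr <- bhAdjust(out$p_value)
    out
}

#' Chromosomal instability per sample
#'
#' Fraction of the covered genome (total segment length) carrying a gain or
#' loss call. Invariant to splitting segments with unchanged ratios.
#'
#' @param calledSegments GRanges with \code{sample_id} and \code{call}.
#' @return named numeric vector in [0, 1], one value per sample.
#' @export
chromosomalInstability <- function(calledSegments) {
    w <- GenomicRanges::width(calledSegments)
    samples <- unique(calledSegments$sample_id)
    out <- vapply(samples, function(s) {
        sel <- calledSegments$sample_id == s
        tot <- sum(w[sel])
        if (tot == 0) stop(sprintf("sample %s has zero covered length", s))
        sum(w[sel & calledSegments$call != "neutral"]) / tot
    }, 0)
    setNames(out, samples)
}

#' Compound TP53 status
#'
#' A sample is \code{compound} iff it carries at least one retained TP53
#' mutation AND at least one loss-called segment overlapping the TP53
#' locus; otherwise \code{mut_only}, \code{loss_only} or \code{neither}.
#' The group comparison is a Fisher exact test of compound-vs-not.
#'
#' @param filteredMuts filtered mutation table.
#' @param calledSegments GRanges with \code{sample_id} and \code{call}.
#' @param samples character vector of all sample ids to report.
#' @param tp53Locus GRanges of the TP53 gene body (default hg38
#'   chr17:7668421-7687490).
#' @return named character vector of per-sample statuses.
#' @export
tp53CompoundStatus <- function(filteredMuts, calledSegments, samples,
                               tp53Locus = GenomicRanges::GRanges(
                                   "chr17",
                                   IRanges::IRanges(7668421, 7687490))) {
    mutSamples <- unique(filteredMuts$sample_id[filteredMuts$gene == "TP53"])
    lossSegs <- calledSegments[calledSegments$call == "loss"]
    hits <- GenomicRanges::findOverlaps(lossSegs, tp53Locus)
    lossSamples <- unique(lossSegs$sample_id[S4Vectors::queryHits(hits)])
    status <- ifelse(samples %in% mutSamples & samples %in% lossSamples,
                     "compound",
              ifelse(samples %in% mutSamples, "mut_only",
              ifelse(samples %in% lossSamples, "loss_only", "neither")))
    setNames(status, samples)
}

#' Compare compound TP53 prevalence between groups
#'
#' @param statusA,statusB per-sample statuses from
#'   \code{\link{tp53CompoundStatus}}.
#' @return list with per-group compound fractions and the Fisher p-value.
#' @export
tp53CompoundCompare <- function(statusA, statusB) {
    a <- sum(statusA == "compound"); b <- sum(statusA != "compound")
    cc <- sum(statusB == "compound"); d <- sum(statusB != "compound")
    list(frac_a = a / (a + b), frac_b = cc / (cc + d),
         p.value = fisherExact2x2(a, b, cc, d))
}
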