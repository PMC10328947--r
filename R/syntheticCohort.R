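# Synthetic-cohort generator. Produces count matrices, clinical tables,
# mutation tables, copy-number segments and complete ground truth with the
# statistical structure the downstream analysis assumes, so every stage is
# testable without access-controlled patient data.

# 50-gene intrinsic-subtyping panel (standard symbols)
.pamPanel <- function() {
    c("ACTR3B", "ANLN", "BAG1", "BCL2", "BIRC5", "BLVRA", "CCNB1", "CCNE1",
      "CDC20", "CDC6", "CDH3", "CENPF", "CEP55", "CXXC5", "EGFR", "ERBB2",
      "ESR1", "EXO1", "FGFR4", "FOXA1", "FOXC1", "GPR160", "GRB7", "KIF2C",
      "KRT14", "KRT17", "KRT5", "MAPT", "MDM2", "MELK", "MIA", "MKI67",
      "MLPH", "MMP11", "MYBL2", "MYC", "NAT1", "NDC80", "NUF2", "ORC6",
      "PGR", "PHGDH", "PTTG1", "RRM2", "SFRP1", "SLC39A6", "TMEM45B",
      "TYMS", "UBE2C", "UBE2T")
}

.immunePanel <- function() {
    c("CD3D", "CD3E", "CD8A", "CD2", "CD247", "MS4A1", "CD19", "FOXP3",
      "CTLA4", "GZMB", "GZMA", "PRF1", "CD274", "PDCD1", "LAG3", "IL2RB",
      "CXCL9", "CXCL10", "CXCL11", "STAT1", "IDO1", "IRF1", "HLA-DRA",
      "HLA-DPB1", "TIGIT", "IKZF1", "CCL5", "NKG7", "TBX21", "ICOS")
}

.estrogenPanel <- function() {
    c("GREB1", "TFF1", "TFF3", "AGR2", "IGFBP4", "MYB", "ANXA9", "SCUBE2",
      "CA12", "SLC7A5", "RET", "KDM4B", "SIAH2", "STC2", "PDZK1", "ELOVL2",
      "CELSR1", "NPY1R", "ABAT", "RERG", "AREG", "SGK3", "MREG", "FMN1",
      "GJA1", "KRT13", "OLFM1", "RAPGEFL1", "SLC27A2", "SYBU")
}

# Subtype positions on four latent expression axes (luminal/ER,
# proliferation, HER2, basal-keratin). Panel genes load on the axes, so
# subtype signal is correlated across gene modules -- like real tumours,
# where LumA/LumB form a proliferation continuum rather than separated
# point clouds.
.axisPositions <- function() {
    m <- rbind(lum    = c(1.0, 0.75, -0.6, -1.4),
               prolif = c(-1.2, 0.6, 0.7, 1.3),
               her2   = c(-0.3, -0.2, 1.5, -0.4),
               basal  = c(-0.4, -0.3, -0.2, 1.5))
    colnames(m) <- SUBTYPES
    m
}

# Deterministic per-config panel parameters: gene identifiers, baseline
# log2 means, axis loadings (hence true subtype centroids), the per-gene
# platform offsets and the DE gene assignment. Drawn from config$seed so
# generateCohort and generateTrainingSet share one truth.
.panelParams <- function(config) {
    set.seed(config$seed)
    pam <- .pamPanel()[seq_len(config$nPamGenes)]
    imm <- .immunePanel()
    est <- .estrogenPanel()
    markers <- c("HOXB13", "IL17BR")
    bg <- sprintf("BG%05d", seq_len(config$nBackgroundGenes))
    genes <- c(pam, imm, est, markers, bg)
    mu <- c(runif(length(pam), 6, 13),
            runif(length(imm), 5, 10),
            runif(length(est), 6, 12),
            runif(2, 8, 11),
            runif(length(bg), 4, 12))
    names(mu) <- genes
    # axis loadings: each panel gene loads mainly on one module
    axes <- .axisPositions()
    primary <- sample(rownames(axes), length(pam), replace = TRUE,
                      prob = c(0.30, 0.35, 0.15, 0.20))
    names(primary) <- pam
    anchors <- c(ESR1 = "lum", FOXA1 = "lum", PGR = "lum", BCL2 = "lum",
                 MKI67 = "prolif", BIRC5 = "prolif", CCNB1 = "prolif",
                 ERBB2 = "her2", GRB7 = "her2", FGFR4 = "her2",
                 FOXC1 = "basal", KRT5 = "basal", KRT14 = "basal")
    anchors <- anchors[names(anchors) %in% pam]
    primary[names(anchors)] <- anchors
    loadings <- matrix(rnorm(length(pam) * 4, 0, 0.15), length(pam), 4,
                       dimnames = list(pam, rownames(axes)))
    mainLoad <- abs(rnorm(length(pam), 1, 0.3)) *
        sample(c(1, -1), length(pam), replace = TRUE, prob = c(0.8, 0.2))
    mainLoad[names(anchors)] <- abs(mainLoad[names(anchors)])
    for (i in seq_along(pam))
        loadings[i, primary[i]] <- mainLoad[i]
    loadings <- loadings * config$centroidSeparation
    if ("ESR1" %in% pam) mu["ESR1"] <- 12.5
    delta <- loadings %*% axes                     # true centroids
    shift <- rnorm(length(genes), 0, config$platformShiftSd)
    names(shift) <- genes
    shift["ESR1"] <- 0  # ESR1 modes are defined on the observed study scale
    nDe <- min(config$nDeGenes, length(bg))
    deGenes <- bg[seq_len(nDe)]
    deLfc <- setNames(rep(0, length(genes)), genes)
    if (nDe > 0)
        deLfc[deGenes] <- config$deLog2Fc *
            rep_len(c(1, -1), nDe)
    list(genes = genes, pam = pam, imm = imm, est = est, markers = markers,
         bg = bg, mu = mu, axes = axes, loadings = loadings, delta = delta,
         shift = shift, deLfc = deLfc)
}

.solveResistanceIntercept <- function(eta, target) {
    f <- function(b0) mean(plogis(b0 + eta)) - target
    uniroot(f, c(-30, 10), tol = 1e-10)$root
}

# per-sample copy-number segments for one chromosome partition
.sampleSegments <- function(config, resistant, sampleId) {
    cp <- config$cnaParams
    lens <- config$chromLengths
    tp53Start <- 7668421; tp53End <- 7687490
    chr6qStart <- 108000001; chr6qEnd <- 111000000
    rows <- list()
    tp53Loss <- runif(1) < if (resistant) cp$tp53LossResistantProb else
        cp$tp53LossProb
    chr6qGain <- runif(1) < if (resistant) cp$chr6qGainResistantProb else
        cp$chr6qGainProb
    for (ch in names(lens)) {
        L <- lens[[ch]]
        nBreak <- rpois(1, cp$breakpointRate * L / 1e8)
        breaks <- sort(unique(round(runif(nBreak, 1, L - 1))))
        special <- NULL
        if (ch == "chr17") {
            special <- c(7000000, 8500000)
            breaks <- breaks[breaks <= special[1] | breaks > special[2]]
        }
        if (ch == "chr6") {
            special <- c(chr6qStart - 1, chr6qEnd)
            breaks <- breaks[breaks <= special[1] | breaks > special[2]]
        }
        bounds <- sort(unique(c(0, breaks, special, L)))
        starts <- bounds[-length(bounds)] + 1
        ends <- bounds[-1]
        u <- runif(length(starts))
        call <- ifelse(u < cp$gainProb, "gain",
                ifelse(u < cp$gainProb + cp$lossProb, "loss", "neutral"))
        if (ch == "chr17") {
            i <- which(starts <= tp53Start & ends >= tp53End)
            call[i] <- if (tp53Loss) "loss" else "neutral"
        }
        if (ch == "chr6") {
            i <- which(starts == chr6qStart & ends == chr6qEnd)
            call[i] <- if (chr6qGain) "gain" else "neutral"
        }
        lr <- numeric(length(call))
        lr[call == "gain"] <- runif(sum(call == "gain"), 0.25, 0.7)
        lr[call == "loss"] <- -runif(sum(call == "loss"), 0.25, 0.7)
        lr[call == "neutral"] <- runif(sum(call == "neutral"), -0.1, 0.1)
        rows[[ch]] <- data.frame(sample_id = sampleId, chrom = ch,
                                 start = starts, end = ends,
                                 log2_ratio = round(lr, 4),
                                 stringsAsFactors = FALSE)
    }
    list(segs = do.call(rbind, rows), tp53Loss = tp53Loss,
         chr6qGain = chr6qGain)
}

#' Generate a synthetic study cohort with ground truth
#'
#' Draws subtypes, a latent immune score, the ESR1 stratum, TP53 and other
#' mutations, a resistance indicator (Bernoulli with configured log-odds
#' effects; intercept solved so the marginal resistant fraction matches the
#' configured target), paired Ki67 values, plasma estradiol, stromal TILs,
#' NB counts with mean \code{library_factor * 2^(log2 expression)},
#' MAF-like mutation rows (plus artifact rows that fail the somatic
#' filters) and per-sample copy-number segments.
#'
#' @param config a \code{\link{simConfig}}.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
generateCohort <- function(config = simConfig()) {
    if (!inherits(config, "SimConfig"))
        stop("config must be created by simConfig()")
    panel <- .panelParams(config)   # also seeds the RNG stream
    n <- config$nPatients
    ids <- sprintf("S%04d", seq_len(n))

    subtype <- sample(SUBTYPES, n, replace = TRUE,
                      prob = config$subtypeProportions[SUBTYPES])
    immune <- rnorm(n)
    esr1Low <- runif(n) < config$esr1LowFraction
    tp53Mut <- runif(n) < config$mutationPrevalence[["TP53"]]

    eff <- config$resistanceEffects
    eta <- eff[["esr1_low"]] * esr1Low +
        eff[["her2e"]] * (subtype == "HER2e") +
        eff[["basal"]] * (subtype == "Basal") +
        eff[["tp53_mut"]] * tp53Mut +
        eff[["immune_score"]] * immune
    b0 <- .solveResistanceIntercept(eta, config$resistantFraction)
    resistant <- runif(n) < plogis(b0 + eta)

    ki67Base <- exp(rnorm(n, config$ki67BaselineMeanLog[subtype],
                          config$ki67BaselineSdLog))
    ki67Base <- round(pmin(pmax(ki67Base, 5), 97), 1)
    pc <- ifelse(resistant,
                 runif(n, config$prFallParams[1], config$prFallParams[2]),
                 runif(n, config$grFallParams[1], config$grFallParams[2]))
    ki67Two <- round(pmin(pmax(ki67Base * (1 + pc / 100), 0), 100), 1)

    estradiol <- round(exp(rnorm(n, config$estradiolMeanLog +
                                 config$estradiolResistantShift * resistant,
                                 config$estradiolSdLog)), 1)
    tilsMean <- plogis(-1.6 + 0.6 * immune)
    tils <- ifelse(runif(n) < config$tilsZeroProb, 0,
                   round(60 * rbeta(n, tilsMean * config$tilsPrecision,
                                    (1 - tilsMean) * config$tilsPrecision),
                         1))

    # log2 expression
    genes <- panel$genes
    expr <- matrix(rnorm(length(genes) * n, 0, config$sampleNoiseSd),
                   length(genes), n, dimnames = list(genes, ids))
    expr <- expr + panel$mu + panel$shift
    latent <- panel$axes[, subtype] +
        matrix(rnorm(4 * n, 0, config$latentNoiseSd), 4, n)
    expr[panel$pam, ] <- expr[panel$pam, ] + panel$loadings %*% latent
    expr[panel$imm, ] <- expr[panel$imm, ] +
        matrix(config$immuneEffect * immune, length(panel$imm), n,
               byrow = TRUE)
    zE2 <- as.numeric(scale(log(estradiol)))
    expr[panel$est, ] <- expr[panel$est, ] +
        matrix(config$estrogenCoupling * zE2 - 0.4 * resistant,
               length(panel$est), n, byrow = TRUE)
    expr["HOXB13", ] <- expr["HOXB13", ] + 0.3 * resistant
    if ("ESR1" %in% genes)
        expr["ESR1", ] <- ifelse(esr1Low, rnorm(n, 9.5, 0.8),
                                 rnorm(n, 13.2, 0.5))
    de <- panel$deLfc != 0
    expr[de, ] <- expr[de, ] + outer(panel$deLfc[de], as.numeric(resistant))

    lib <- exp(rnorm(n, config$librarySizeLogMean, config$librarySizeLogSd))
    muCounts <- sweep(2^expr, 2, lib, "*")
    counts <- matrix(rnbinom(length(muCounts), mu = muCounts,
                             size = 1 / config$nbDispersion),
                     nrow(muCounts), ncol(muCounts),
                     dimnames = dimnames(muCounts))

    grade <- ifelse(subtype %in% c("Basal", "HER2e"),
                    sample(c("2", "3"), n, TRUE, c(0.3, 0.7)),
                    sample(c("1", "2", "3"), n, TRUE, c(0.1, 0.6, 0.3)))
    chemo <- ifelse(grade == "3",
                    sample(c("yes", "no"), n, TRUE, c(0.6, 0.4)),
                    sample(c("yes", "no"), n, TRUE, c(0.2, 0.8)))
    histology <- sample(c("IDC", "ILC", "other"), n, TRUE,
                        c(0.85, 0.12, 0.03))
    clinical <- data.frame(
        patient_id = ids, ki67_baseline = ki67Base, ki67_2wk = ki67Two,
        er_status = "pos", her2_status = "neg", grade = grade,
        histology = histology, chemo = chemo, estradiol = estradiol,
        tils = tils, stringsAsFactors = FALSE)

    # mutations: retained somatic rows per configured prevalences
    prev <- config$mutationPrevalence
    mutGenes <- names(prev)
    mutRows <- list()
    classes <- c("Missense_Mutation", "Nonsense_Mutation",
                 "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site")
    # TP53-mutant tumours carry more co-mutations; the base rate is scaled
    # down so each gene's marginal prevalence stays at its configured value
    fT <- prev[["TP53"]]; mult <- config$tp53MutTmbMultiplier
    baseScale <- 1 / (1 - fT + fT * mult)
    for (i in seq_len(n)) {
        p <- prev
        others <- setdiff(mutGenes, "TP53")
        p[others] <- pmin(p[others] * baseScale *
                          (if (tp53Mut[i]) mult else 1), 0.95)
        hit <- runif(length(mutGenes)) < p
        hit[mutGenes == "TP53"] <- tp53Mut[i]
        gs <- mutGenes[hit]
        nArtifact <- rpois(1, 0.8)
        if (length(gs) + nArtifact == 0) next
        real <- if (length(gs) > 0) data.frame(
            sample_id = ids[i], gene = gs,
            vaf = round(runif(length(gs), 0.08, 0.6), 3),
            alt_reads = 5 + rpois(length(gs), 25),
            consequence_class = sample(c("high", "moderate"),
                                       length(gs), TRUE),
            pop_af = 0,
            variant_classification = sample(classes, length(gs), TRUE),
            stringsAsFactors = FALSE) else NULL
        art <- if (nArtifact > 0) {
            kind <- sample(c("vaf", "alt", "cons", "pop"), nArtifact, TRUE)
            data.frame(
                sample_id = ids[i],
                gene = sample(mutGenes, nArtifact, TRUE),
                vaf = ifelse(kind == "vaf",
                             round(runif(nArtifact, 0.005, 0.049), 3),
                             round(runif(nArtifact, 0.08, 0.6), 3)),
                alt_reads = ifelse(kind == "alt",
                                   sample(1:4, nArtifact, TRUE),
                                   5 + rpois(nArtifact, 25)),
                consequence_class = ifelse(kind == "cons",
                                           sample(c("low", "modifier"),
                                                  nArtifact, TRUE),
                                           "moderate"),
                pop_af = ifelse(kind == "pop", 1e-3, 0),
                variant_classification = sample(classes, nArtifact, TRUE),
                stringsAsFactors = FALSE)
        } else NULL
        mutRows[[i]] <- rbind(real, art)
    }
    mutations <- do.call(rbind, mutRows)
    rownames(mutations) <- NULL

    segRows <- vector("list", n)
    tp53Loss <- logical(n); chr6qGain <- logical(n)
    for (i in seq_len(n)) {
        s <- .sampleSegments(config, resistant[i], ids[i])
        segRows[[i]] <- s$segs
        tp53Loss[i] <- s$tp53Loss
        chr6qGain[i] <- s$chr6qGain
    }
    segDf <- do.call(rbind, segRows)
    segments <- GenomicRanges::GRanges(
        seqnames = segDf$chrom,
        ranges = IRanges::IRanges(segDf$start, segDf$end),
        sample_id = segDf$sample_id, log2_ratio = segDf$log2_ratio)

    truth <- data.frame(
        sample_id = ids, subtype = subtype, resistant = resistant,
        immune_score = immune,
        esr1_stratum = ifelse(esr1Low, "LOW", "HIGH"),
        tp53_mut = tp53Mut, tp53_loss = tp53Loss, chr6q_gain = chr6qGain,
        pc_true = pc, stringsAsFactors = FALSE)
    geneTruth <- data.frame(
        gene = genes,
        panel = rep(c("pam", "immune", "estrogen", "marker", "background"),
                    c(length(panel$pam), length(panel$imm),
                      length(panel$est), 2, length(panel$bg))),
        baseline_log2 = unname(panel$mu),
        platform_shift = unname(panel$shift),
        true_lfc = unname(panel$deLfc),
        is_de = panel$deLfc != 0,
        stringsAsFactors = FALSE)

    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts),
        colData = S4Vectors::DataFrame(clinical, row.names = ids))
    new("SyntheticCohort", se = se, mutations = mutations,
        segments = segments, truth = truth, geneTruth = geneTruth,
        config = unclass(config))
}

#' Generate a balanced training expression set
#'
#' Microarray-like log2 expression for the subtyping panel genes on the
#' training (reference) scale: baseline + true centroid deviation + noise,
#' with no platform offset and balanced subtype labels. Shares the panel
#' truth of \code{config} (same gene identifiers and centroids as the study
#' cohort).
#'
#' @param config a \code{\link{simConfig}}.
#' @param nPerSubtype training samples per subtype (>= 1).
#' @return list with \code{matrix} (panel genes x 4*nPerSubtype) and
#'   \code{labels}.
#' @export
generateTrainingSet <- function(config = simConfig(), nPerSubtype = 55) {
    if (nPerSubtype < 1) stop("nPerSubtype must be at least 1")
    panel <- .panelParams(config)
    set.seed(config$seed + 1000003L)
    labels <- rep(SUBTYPES, each = nPerSubtype)
    ids <- sprintf("T%04d", seq_along(labels))
    pam <- panel$pam
    m <- matrix(rnorm(length(pam) * length(labels), 0,
                      config$sampleNoiseSd),
                length(pam), length(labels), dimnames = list(pam, ids))
    latent <- panel$axes[, labels] +
        matrix(rnorm(4 * length(labels), 0, config$latentNoiseSd), 4,
               length(labels))
    m <- m + panel$mu[pam] + panel$loadings %*% latent
    list(matrix = m, labels = labels)
}

#' Generate imperfect reference subtype calls
#'
#' Emulates an externally subtyped subset: \code{nRef} samples are drawn
#' without replacement and each call equals the true subtype with
#' probability \code{1 - errorRate} (errors uniform over the other three).
#'
#' @param truth truth table from \code{\link{generateCohort}}.
#' @param nRef subset size (1 <= nRef <= cohort size).
#' @param errorRate per-call error probability.
#' @param seed integer seed.
#' @return data.frame with \code{sample_id}, \code{label},
#'   \code{true_subtype}.
#' @export
generateReferenceCalls <- function(truth, nRef = 59, errorRate = 0.03,
                                   seed = 1) {
    if (nRef < 1) stop("nRef must be at least 1")
    if (nRef > nrow(truth)) stop("nRef exceeds the cohort size")
    set.seed(seed)
    idx <- sort(sample.int(nrow(truth), nRef))
    true <- truth$subtype[idx]
    flip <- runif(nRef) < errorRate
    label <- true
    for (i in which(flip))
        label[i] <- sample(setdiff(SUBTYPES, true[i]), 1)
    data.frame(sample_id = truth$sample_id[idx], label = label,
               true_subtype = true, stringsAsFactors = FALSE)
}
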