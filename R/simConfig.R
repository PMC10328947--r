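# Simulation configuration: the generator's defaults are the study
# conditions the downstream analysis assumes (skewed luminal composition,
# per-gene platform shift between study and training, bimodal ESR1,
# resistance odds driven by ESR1 stratum / subtype / immune infiltration /
# TP53 status, published ER+ mutation prevalences, TP53-loss and chr6q-gain
# CNA enrichment in resistant tumours).

# hg38-like autosome lengths (bp), rounded to 10 kb
.hg38Autosomes <- function() {
    setNames(as.numeric(c(
        248956000, 242193000, 198295000, 190215000, 181538000, 170806000,
        159346000, 145139000, 138395000, 133797000, 135087000, 133275000,
        114364000, 107044000, 101991000, 90338000, 83257000, 80373000,
        58618000, 64444000, 46710000, 50818000)),
        paste0("chr", 1:22))
}

#' Simulation configuration
#'
#' Validated parameter list for \code{\link{generateCohort}} and
#' \code{\link{generateTrainingSet}}. Defaults emulate an ER+HER2- cohort
#' under neoadjuvant aromatase inhibition: 85% luminal composition, ESR1
#' bimodal on the log2 scale with the low mode under the threshold-12
#' analogue, resistance log-odds driven by low ESR1, non-luminal subtype,
#' TP53 mutation and immune infiltration with a 15% marginal resistant
#' fraction, proportional Ki67 falls of -100..-80% (sensitive) and
#' -48..+184% (resistant), ER+-typical mutation prevalences (PIK3CA 0.35,
#' TP53 0.24, CDH1/KMT2C/GATA3 0.10, MAP3K1 0.09), and segment-level CNA
#' with TP53-loss and chr6q-gain enrichment in resistant tumours.
#'
#' @param nPatients cohort size.
#' @param subtypeProportions named fractions over LumA/LumB/HER2e/Basal,
#'   summing to 1.
#' @param nPamGenes number of subtyping panel genes (<= 50 built-in).
#' @param nBackgroundGenes additional background genes.
#' @param centroidSeparation scale (log2) of the axis loadings driving
#'   subtype separation.
#' @param latentNoiseSd per-sample sd of the latent axis positions
#'   (within-subtype biological heterogeneity, shared across a module's
#'   genes).
#' @param sampleNoiseSd per-gene, per-sample log2 noise sd.
#' @param platformShiftSd sd of the per-gene study-minus-training offset.
#' @param nbDispersion negative-binomial dispersion of counts.
#' @param librarySizeLogMean,librarySizeLogSd log-normal library factor.
#' @param esr1LowFraction fraction of samples in the low ESR1 mode.
#' @param resistanceEffects named log-odds for esr1_low, her2e, basal,
#'   tp53_mut and immune_score (per sd).
#' @param resistantFraction marginal resistant fraction the intercept is
#'   solved for.
#' @param ki67BaselineMeanLog named per-subtype log-mean of baseline Ki67.
#' @param ki67BaselineSdLog log-sd of baseline Ki67.
#' @param grFallParams,prFallParams uniform bounds (percent) of the
#'   proportional Ki67 change for sensitive / resistant tumours.
#' @param mutationPrevalence named per-gene mutation fractions.
#' @param tp53MutTmbMultiplier prevalence multiplier for non-TP53 genes in
#'   TP53-mutant tumours (drives the burden difference).
#' @param cnaParams list: breakpointRate (expected breakpoints per 100 Mb),
#'   gainProb/lossProb per background segment, tp53LossProb /
#'   tp53LossResistantProb, chr6qGainProb / chr6qGainResistantProb.
#' @param estradiolMeanLog,estradiolSdLog log-normal plasma estradiol
#'   (pmol/L).
#' @param estradiolResistantShift log-scale shift for resistant samples.
#' @param tilsZeroProb,tilsPrecision zero-inflated Beta TILs on [0, 60].
#' @param immuneEffect log2 expression shift of immune genes per sd of the
#'   immune score.
#' @param estrogenCoupling log2 shift of estrogen-response genes per sd of
#'   log estradiol.
#' @param nDeGenes,deLog2Fc background genes truly differentially expressed
#'   between resistant and sensitive tumours, and their |log2 FC|.
#' @param chromLengths named chromosome lengths (bp).
#' @param seed integer seed; fixes panel parameters and all draws.
#' @return validated list of class \code{SimConfig}.
#' @export
simConfig <- function(nPatients = 400,
                      subtypeProportions = c(LumA = 0.42, LumB = 0.43,
                                             HER2e = 0.08, Basal = 0.07),
                      nPamGenes = 50,
                      nBackgroundGenes = 1000,
                      centroidSeparation = 1.0,
                      latentNoiseSd = 0.35,
                      sampleNoiseSd = 0.4,
                      platformShiftSd = 0.8,
                      nbDispersion = 0.05,
                      librarySizeLogMean = 0,
                      librarySizeLogSd = 0.3,
                      esr1LowFraction = 0.10,
                      resistanceEffects = c(esr1_low = 2.0, her2e = 1.0,
                                            basal = 1.5, tp53_mut = 0.8,
                                            immune_score = 0.5),
                      resistantFraction = 0.15,
                      ki67BaselineMeanLog = c(LumA = log(18), LumB = log(28),
                                              HER2e = log(30),
                                              Basal = log(40)),
                      ki67BaselineSdLog = 0.35,
                      grFallParams = c(-100, -80),
                      prFallParams = c(-48, 184),
                      mutationPrevalence = NULL,
                      tp53MutTmbMultiplier = 1.5,
                      cnaParams = list(breakpointRate = 0.8,
                                       gainProb = 0.06, lossProb = 0.06,
                                       tp53LossProb = 0.18,
                                       tp53LossResistantProb = 0.35,
                                       chr6qGainProb = 0.08,
                                       chr6qGainResistantProb = 0.25),
                      estradiolMeanLog = log(38),
                      estradiolSdLog = 0.6,
                      estradiolResistantShift = -0.35,
                      tilsZeroProb = 0.25,
                      tilsPrecision = 10,
                      immuneEffect = 0.8,
                      estrogenCoupling = 0.3,
                      nDeGenes = 100,
                      deLog2Fc = 1.0,
                      chromLengths = .hg38Autosomes(),
                      seed = 1L) {
    if (is.null(mutationPrevalence)) {
        named <- c(PIK3CA = 0.35, TP53 = 0.24, CDH1 = 0.10, KMT2C = 0.10,
                   GATA3 = 0.10, MAP3K1 = 0.09, RB1 = 0.04, PTEN = 0.05,
                   ARID1B = 0.05, DNAH11 = 0.05, AKT1 = 0.04)
        bg <- setNames(rep(0.02, 76), sprintf("PANEL%02d", seq_len(76)))
        mutationPrevalence <- c(named, bg)
    }
    if (abs(sum(subtypeProportions) - 1) > 1e-9)
        stop("subtype proportions must sum to 1")
    if (!identical(sort(names(subtypeProportions)), sort(SUBTYPES)))
        stop("subtype proportions must name LumA, LumB, HER2e, Basal")
    fracs <- c(subtypeProportions, esr1LowFraction, resistantFraction,
               mutationPrevalence, tilsZeroProb)
    if (any(fracs < 0 | fracs > 1))
        stop("all fractions must lie in [0, 1]")
    counts <- c(nPatients, nPamGenes, nBackgroundGenes)
    if (any(counts <= 0 | counts != round(counts)))
        stop("counts must be positive integers")
    if (nPamGenes > 50) stop("at most 50 panel genes are built in")
    stopifnot(centroidSeparation > 0, sampleNoiseSd >= 0,
              platformShiftSd >= 0, nbDispersion > 0)
    cfg <- as.list(environment())
    cfg <- cfg[setdiff(names(cfg), c("named", "bg", "fracs", "counts"))]
    cfg$seed <- as.integer(seed)
    structure(cfg, class = "SimConfig")
}
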