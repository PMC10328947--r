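# Eligibility, good/poor-responder selection, baseline-Ki67 category
# matching and ESR1 stratification.

#' Analysis configuration
#'
#' Thresholds governing responder selection and stratification. Defaults:
#' poor responders are the worst 15% of the proportional Ki67 change, the
#' good-responder pool is the best 50%, eligibility requires baseline Ki67
#' strictly above 10%, ESR1 strata split at log2 normalized counts of 12
#' (boundary assigned HIGH), estradiol values strictly above 130 pmol/L are
#' excluded from correlation analyses, and stromal TILs categories are
#' low < 11, intermediate 11-59, high >= 60 percent.
#'
#' @param prFraction,grPoolFraction selection fractions in (0, 1).
#' @param ki67EligibilityThreshold percent, strict lower bound.
#' @param esr1Log2Threshold log2 normalized counts.
#' @param estradiolExclusion pmol/L, strict upper bound.
#' @param tilsLow,tilsHigh category boundaries (percent).
#' @param matchSeed seed for the random within-category matching.
#' @return a validated list of class \code{AnalysisConfig}.
#' @export
analysisConfig <- function(prFraction = 0.15, grPoolFraction = 0.50,
                           ki67EligibilityThreshold = 10,
                           esr1Log2Threshold = 12,
                           estradiolExclusion = 130,
                           tilsLow = 11, tilsHigh = 60, matchSeed = 1L) {
    stopifnot(prFraction > 0, prFraction < 1,
              grPoolFraction > 0, grPoolFraction < 1,
              ki67EligibilityThreshold > 0, esr1Log2Threshold > 0,
              estradiolExclusion > 0, tilsLow > 0, tilsHigh > tilsLow)
    structure(list(prFraction = prFraction,
                   grPoolFraction = grPoolFraction,
                   ki67EligibilityThreshold = ki67EligibilityThreshold,
                   esr1Log2Threshold = esr1Log2Threshold,
                   estradiolExclusion = estradiolExclusion,
                   tilsLow = tilsLow, tilsHigh = tilsHigh,
                   matchSeed = as.integer(matchSeed)),
              class = "AnalysisConfig")
}

#' Proportional Ki67 change
#'
#' \code{100 * (two_week - baseline) / baseline}, percent scale; negative
#' values mean suppression. Scale-invariant in the Ki67 units.
#'
#' @param baseline,twoWeek Ki67 percentages; baseline must be positive.
#' @return proportional change in percent.
#' @examples
#' proportionalKi67Change(26, 2)   # -92.31
#' @export
proportionalKi67Change <- function(baseline, twoWeek) {
    if (any(is.na(baseline)) || any(baseline <= 0))
        stop("baseline Ki67 must be positive")
    100 * (twoWeek - baseline) / baseline
}

#' Baseline-Ki67 category
#'
#' Half-open categories [10, 20), [20, 30), [30, 100].
#'
#' @param ki67 baseline Ki67 percent.
#' @return factor with levels "10-20", "20-30", ">=30".
#' @export
ki67Category <- function(ki67) {
    cut(ki67, breaks = c(10, 20, 30, 100.0001), right = FALSE,
        labels = c("10-20", "20-30", ">=30"))
}

#' Eligibility filter
#'
#' Retains ER+, HER2- patients with both Ki67 values present and baseline
#' Ki67 strictly above the threshold.
#'
#' @param clinical clinical data.frame.
#' @param config an \code{\link{analysisConfig}}.
#' @return character vector of eligible patient ids (possibly empty).
#' @export
eligibilityFilter <- function(clinical, config = analysisConfig()) {
    ok <- clinical$er_status == "pos" & clinical$her2_status == "neg" &
        !is.na(clinical$ki67_baseline) & !is.na(clinical$ki67_2wk) &
        clinical$ki67_baseline > config$ki67EligibilityThreshold
    clinical$patient_id[which(ok)]
}

#' Select good and poor responder groups
#'
#' Poor responders (PR) are eligible patients whose proportional Ki67
#' change lies at or above the (1 - prFraction) linear-interpolation sample
#' quantile (ties at the threshold are all included). The good-responder
#' pool is the patients below the median change; good responders (GR) are
#' drawn at random within each baseline-Ki67 category to match the PR
#' per-category counts 1:1 where the pool permits (all available with a
#' warning otherwise), under \code{matchSeed}.
#'
#' @param clinical clinical data.frame.
#' @param config an \code{\link{analysisConfig}}.
#' @return data.frame, one row per eligible patient: \code{patient_id},
#'   \code{pc}, \code{ki67_category}, \code{response_class}
#'   (GR/PR/unassigned).
#' @export
selectResponderGroups <- function(clinical, config = analysisConfig()) {
    eligible <- eligibilityFilter(clinical, config)
    if (length(eligible) == 0) stop("no eligible patients")
    clin <- clinical[match(eligible, clinical$patient_id), ]
    pc <- proportionalKi67Change(clin$ki67_baseline, clin$ki67_2wk)
    cat3 <- ki67Category(clin$ki67_baseline)
    prCut <- quantile(pc, 1 - config$prFraction, type = 7)
    grCut <- quantile(pc, config$grPoolFraction, type = 7)
    isPR <- pc >= prCut
    inGrPool <- pc < grCut & !isPR
    cls <- rep("unassigned", length(eligible))
    cls[isPR] <- "PR"
    set.seed(config$matchSeed)
    for (lev in levels(cat3)) {
        need <- sum(isPR & cat3 == lev)
        if (need == 0) next
        pool <- which(inGrPool & cat3 == lev)
        if (length(pool) < need) {
            warning(sprintf(
                "Ki67 category %s: GR pool (%d) smaller than PR count (%d); under-matched",
                lev, length(pool), need))
            take <- pool
        } else {
            take <- sample(pool, need)
        }
        cls[take] <- "GR"
    }
    data.frame(patient_id = eligible, pc = pc,
               ki67_category = as.character(cat3), response_class = cls,
               stringsAsFactors = FALSE)
}

#' Stratify assigned patients by ESR1 expression
#'
#' Adds \code{esr1_log2} and \code{esr1_stratum} (HIGH iff value >=
#' threshold; the boundary value is HIGH) to a response assignment. Samples
#' absent from the matrix get stratum NA.
#'
#' @param norm a \code{NormalizedMatrix} (or matrix of log2 values) with an
#'   ESR1 row.
#' @param assignment data.frame from \code{\link{selectResponderGroups}}.
#' @param config an \code{\link{analysisConfig}}.
#' @param gene ESR1 row identifier (default "ESR1").
#' @return the assignment with \code{esr1_log2} and \code{esr1_stratum}
#'   columns added.
#' @export
stratifyByEsr1 <- function(norm, assignment, config = analysisConfig(),
                           gene = "ESR1") {
    vals <- .asValueMatrix(norm)
    if (!gene %in% rownames(vals))
        stop(sprintf("gene %s absent from the normalized matrix", gene))
    esr1 <- vals[gene, ]
    assignment$esr1_log2 <- unname(esr1[assignment$patient_id])
    assignment$esr1_stratum <- ifelse(
        is.na(assignment$esr1_log2), NA_character_,
        ifelse(assignment$esr1_log2 >= config$esr1Log2Threshold,
               "HIGH", "LOW"))
    assignment
}

#' Stromal TILs category
#'
#' low < 11, intermediate 11-59, high >= 60 (percent of stromal area).
#'
#' @param tils percent in [0, 100].
#' @param config an \code{\link{analysisConfig}}.
#' @return character vector of categories.
#' @export
tilsCategory <- function(tils, config = analysisConfig()) {
    if (any(!is.na(tils) & (tils < 0 | tils > 100)))
        stop("TILs must lie in [0, 100]")
    ifelse(is.na(tils), NA_character_,
           ifelse(tils < config$tilsLow, "low",
                  ifelse(tils < config$tilsHigh, "intermediate", "high")))
}

#' Cohort representation of the selected groups
#'
#' Fraction of the full population represented by the poor-responder and
#' good-responder-pool selections, given the eligible fraction of that
#' population; reported as nearest-integer percents.
#'
#' @param eligibleFraction fraction of the population eligible (e.g. the
#'   fraction with baseline Ki67 above threshold).
#' @param config an \code{\link{analysisConfig}}.
#' @return named integer vector: \code{pr_percent}, \code{gr_pool_percent}.
#' @export
cohortRepresentation <- function(eligibleFraction,
                                 config = analysisConfig()) {
    c(pr_percent = round(100 * config$prFraction * eligibleFraction),
      gr_pool_percent = round(100 * config$grPoolFraction * eligibleFraction))
}
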