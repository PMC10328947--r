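#' @import methods
#' @importFrom stats median quantile rnorm runif rbinom rpois rnbinom rbeta
#'   plogis qlogis uniroot optimize pnorm pt p.adjust cor sd setNames
#'   complete.cases dhyper phyper lm coef
#' @importFrom utils read.delim write.table head combn
#' @useDynLib EndoResist, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom GenomicRanges GRanges seqnames start end width mcols
#' @importFrom IRanges IRanges findOverlaps pintersect
#' @importFrom S4Vectors DataFrame queryHits subjectHits
NULL

SUBTYPES <- c("LumA", "LumB", "HER2e", "Basal")

#' Normalized expression matrix with size factors
#'
#' Container for log2 size-factor-normalized expression values,
#' \code{log2(count / size_factor + pseudocount)}, together with the
#' per-sample size factors used. Size factors are constrained to have
#' geometric mean 1 so the normalized scale is anchored to the cohort.
#'
#' @slot values numeric matrix, genes in rows, samples in columns.
#' @slot sizeFactors positive numeric vector, one per sample.
#' @slot pseudocount pseudocount added before the log2 transform.
#'
#' @export
setClass("NormalizedMatrix",
    representation(values = "matrix", sizeFactors = "numeric",
                   pseudocount = "numeric"))

setValidity("NormalizedMatrix", function(object) {
    msg <- NULL
    if (ncol(object@values) != length(object@sizeFactors))
        msg <- c(msg, "one size factor per sample required")
    if (any(object@sizeFactors <= 0))
        msg <- c(msg, "size factors must be positive")
    gm <- exp(mean(log(object@sizeFactors)))
    if (abs(gm - 1) > 1e-6)
        msg <- c(msg, "size factors must have geometric mean 1 (+/- 1e-6)")
    if (is.null(rownames(object@values)))
        msg <- c(msg, "values must carry gene identifiers as rownames")
    if (anyDuplicated(rownames(object@values)))
        msg <- c(msg, "duplicate gene identifiers")
    if (is.null(msg)) TRUE else msg
})

#' Nearest-centroid subtype centroids
#'
#' Per-gene centroid values (log2 scale, gene-centered) for the four
#' intrinsic subtypes LumA, LumB, HER2e and Basal.
#'
#' @slot centroids numeric matrix, genes in rows, exactly the four
#'   subtype columns.
#'
#' @export
setClass("CentroidSet", representation(centroids = "matrix"))

setValidity("CentroidSet", function(object) {
    msg <- NULL
    if (!identical(colnames(object@centroids), SUBTYPES))
        msg <- c(msg, sprintf("centroid columns must be exactly: %s",
                              paste(SUBTYPES, collapse = ", ")))
    if (is.null(rownames(object@centroids)) ||
        anyDuplicated(rownames(object@centroids)))
        msg <- c(msg, "centroid genes must be unique, named rows")
    if (is.null(msg)) TRUE else msg
})

#' Result of the composition-matched calibration search
#'
#' Best per-gene centering vector found by the random-subset search,
#' plus the metadata of the winning iteration.
#'
#' @slot centeringVector named per-gene offset (log2 units) subtracted
#'   from study expression before centroid correlation.
#' @slot bestK number of reference samples used by the best iteration.
#' @slot bestComposition named integer vector, per-subtype counts of the
#'   best iteration's matched subset.
#' @slot bestConcordance fraction of reference calls reproduced.
#' @slot iterationsRun number of search iterations performed.
#' @slot skippedIterations iterations skipped because no composition match
#'   was available after bounded redraws.
#' @slot seed integer seed used for the search.
#'
#' @export
setClass("CalibrationResult",
    representation(centeringVector = "numeric", bestK = "integer",
                   bestComposition = "integer", bestConcordance = "numeric",
                   iterationsRun = "integer", skippedIterations = "integer",
                   seed = "integer"))

setValidity("CalibrationResult", function(object) {
    msg <- NULL
    if (object@bestConcordance < 0 || object@bestConcordance > 1)
        msg <- c(msg, "concordance must lie in [0, 1]")
    if (is.null(names(object@centeringVector)))
        msg <- c(msg, "centering vector must be named by gene")
    if (is.null(msg)) TRUE else msg
})

#' Synthetic cohort with ground truth
#'
#' Bundles the simulated expression data (a SummarizedExperiment whose
#' \code{counts} assay holds gene-by-sample integer counts and whose
#' colData holds the clinical table), the simulated mutation table,
#' copy-number segments (GRanges), the per-sample/per-gene ground truth,
#' and the generating configuration.
#'
#' @slot se SummarizedExperiment with a \code{counts} assay and clinical
#'   covariates in colData.
#' @slot mutations data.frame in MAF-like layout.
#' @slot segments GRanges with \code{sample_id} and \code{log2_ratio}
#'   metadata columns.
#' @slot truth data.frame of ground-truth labels, one row per sample.
#' @slot geneTruth data.frame of per-gene truth (DE status, log2 fold
#'   change, platform offset).
#' @slot config the \code{simConfig} list used for generation.
#'
#' @export
setClass("SyntheticCohort",
    representation(se = "SummarizedExperiment", mutations = "data.frame",
                   segments = "GRanges", truth = "data.frame",
                   geneTruth = "data.frame", config = "list"))

setValidity("SyntheticCohort", function(object) {
    msg <- NULL
    cts <- SummarizedExperiment::assay(object@se, "counts")
    if (any(cts < 0) || any(cts != round(cts)))
        msg <- c(msg, "counts must be non-negative integers")
    if (!identical(sort(colnames(cts)), sort(object@truth$sample_id)))
        msg <- c(msg, "truth must have one row per simulated sample")
    if (is.null(msg)) TRUE else msg
})

setMethod("show", "NormalizedMatrix", function(object) {
    cat(sprintf("NormalizedMatrix: %d genes x %d samples (pseudocount %g)\n",
                nrow(object@values), ncol(object@values), object@pseudocount))
})

setMethod("show", "CentroidSet", function(object) {
    cat(sprintf("CentroidSet: %d genes x %d subtypes (%s)\n",
                nrow(object@centroids), ncol(object@centroids),
                paste(colnames(object@centroids), collapse = ", ")))
})

setMethod("show", "CalibrationResult", function(object) {
    comp <- paste(sprintf("%s=%d", names(object@bestComposition),
                          object@bestComposition), collapse = ", ")
    cat("CalibrationResult\n",
        sprintf("  best concordance : %.4f\n", object@bestConcordance),
        sprintf("  best k           : %d (%s)\n", object@bestK, comp),
        sprintf("  iterations       : %d (%d skipped)\n",
                object@iterationsRun, object@skippedIterations),
        sprintf("  seed             : %d\n", object@seed), sep = "")
})

setMethod("show", "SyntheticCohort", function(object) {
    cat(sprintf(
        "SyntheticCohort: %d genes x %d samples, %d mutation rows, %d segments\n",
        nrow(object@se), ncol(object@se), nrow(object@mutations),
        length(object@segments)))
})

#' Accessors for package containers
#'
#' \code{normValues} returns the log2-normalized matrix,
#' \code{normSizeFactors} the per-sample size factors,
#' \code{centroidMatrix} the gene-by-subtype centroid matrix,
#' \code{centeringVector} the calibrated per-gene offsets,
#' \code{cohortCounts}/\code{clinicalTable}/\code{mutationTable}/
#' \code{segmentTable}/\code{cohortTruth}/\code{geneTruth} the parts of a
#' \code{SyntheticCohort}.
#'
#' @param x a package container object.
#' @return the requested component.
#' @name accessors
#' @aliases normValues normSizeFactors centroidMatrix centeringVector
#'   cohortCounts clinicalTable mutationTable segmentTable cohortTruth
#'   geneTruth
NULL

#' @rdname accessors
#' @export
setGeneric("normValues", function(x) standardGeneric("normValues"))
#' @rdname accessors
#' @export
setGeneric("normSizeFactors", function(x) standardGeneric("normSizeFactors"))
#' @rdname accessors
#' @export
setGeneric("centroidMatrix", function(x) standardGeneric("centroidMatrix"))
#' @rdname accessors
#' @export
setGeneric("centeringVector", function(x) standardGeneric("centeringVector"))
#' @rdname accessors
#' @export
setGeneric("cohortCounts", function(x) standardGeneric("cohortCounts"))
#' @rdname accessors
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname accessors
#' @export
setGeneric("mutationTable", function(x) standardGeneric("mutationTable"))
#' @rdname accessors
#' @export
setGeneric("segmentTable", function(x) standardGeneric("segmentTable"))
#' @rdname accessors
#' @export
setGeneric("cohortTruth", function(x) standardGeneric("cohortTruth"))
#' @rdname accessors
#' @export
setGeneric("geneTruth", function(x) standardGeneric("geneTruth"))

#' @rdname accessors
setMethod("normValues", "NormalizedMatrix", function(x) x@values)
#' @rdname accessors
setMethod("normSizeFactors", "NormalizedMatrix", function(x) x@sizeFactors)
#' @rdname accessors
setMethod("centroidMatrix", "CentroidSet", function(x) x@centroids)
#' @rdname accessors
setMethod("centeringVector", "CalibrationResult", function(x) x@centeringVector)
#' @rdname accessors
setMethod("cohortCounts", "SyntheticCohort",
          function(x) SummarizedExperiment::assay(x@se, "counts"))
#' @rdname accessors
setMethod("clinicalTable", "SyntheticCohort",
          function(x) as.data.frame(SummarizedExperiment::colData(x@se)))
#' @rdname accessors
setMethod("mutationTable", "SyntheticCohort", function(x) x@mutations)
#' @rdname accessors
setMethod("segmentTable", "SyntheticCohort", function(x) x@segments)
#' @rdname accessors
setMethod("cohortTruth", "SyntheticCohort", function(x) x@truth)
#' @rdname accessors
setMethod("geneTruth", "SyntheticCohort", function(x) x@geneTruth)
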