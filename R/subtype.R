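# Nearest-centroid intrinsic subtyping with cross-platform calibration.
#
# Baseline: whole-cohort gene-level median centering. Headline: a random
# subset search that draws 5-15 reference samples, matches a training
# subset to their subtype composition, and uses the per-gene difference of
# subset means as the centering vector; the vector maximizing concordance
# with the reference calls over many iterations is the calibration factor
# applied to the whole cohort. Classification is by Spearman rank
# correlation to the four subtype centroids.

.subtypeLevels <- function() SUBTYPES

.asValueMatrix <- function(x) {
    if (is(x, "NormalizedMatrix")) normValues(x) else as.matrix(x)
}

#' Subtract a per-gene centering vector
#'
#' @param matrix a \code{NormalizedMatrix} or plain matrix, genes in rows.
#' @param centering named per-gene offset covering all rows of
#'   \code{matrix}.
#' @return matrix of centered values.
#' @export
geneCenter <- function(matrix, centering) {
    vals <- .asValueMatrix(matrix)
    missing <- setdiff(rownames(vals), names(centering))
    if (length(missing) > 0)
        stop(sprintf("centering vector missing gene(s): %s",
                     paste(head(missing, 5), collapse = ", ")))
    vals - centering[rownames(vals)]
}

#' Whole-cohort per-gene median centering vector
#'
#' @param matrix a \code{NormalizedMatrix} or plain matrix, genes in rows,
#'   at least one sample.
#' @return named numeric vector of per-gene cohort medians.
#' @export
medianCenteringVector <- function(matrix) {
    vals <- .asValueMatrix(matrix)
    if (ncol(vals) < 1) stop("at least one sample required")
    apply(vals, 1, median)
}

#' Build centroids from a labelled training matrix
#'
#' The training matrix is gene-median-centered (the convention for centroid
#' reference files), then per-subtype per-gene means are taken.
#'
#' @param training expression matrix, genes in rows.
#' @param labels per-column subtype labels (all four subtypes present).
#' @param center median-center the training matrix first (default TRUE).
#' @return a \code{\linkS4class{CentroidSet}}.
#' @export
centroidsFromTraining <- function(training, labels, center = TRUE) {
    training <- .asValueMatrix(training)
    labels <- as.character(labels)
    if (!all(SUBTYPES %in% labels))
        stop("training must contain all four subtypes")
    if (center)
        training <- training - apply(training, 1, median)
    cent <- vapply(SUBTYPES, function(s)
        rowMeans(training[, labels == s, drop = FALSE]),
        numeric(nrow(training)))
    new("CentroidSet", centroids = cent)
}

#' Read / write a centroid table (TSV, genes x subtypes)
#'
#' @param path file path. Columns must be the four subtypes LumA, LumB,
#'   HER2e, Basal (any order; matched by name).
#' @return a \code{\linkS4class{CentroidSet}}.
#' @export
readCentroids <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    genes <- df[[1]]
    if (!all(SUBTYPES %in% names(df)))
        stop(sprintf("centroid table must have columns: %s",
                     paste(SUBTYPES, collapse = ", ")))
    m <- as.matrix(df[, SUBTYPES])
    rownames(m) <- genes
    new("CentroidSet", centroids = m)
}

#' @rdname readCentroids
#' @param centroids a \code{CentroidSet}.
#' @export
writeCentroids <- function(centroids, path) {
    m <- centroidMatrix(centroids)
    df <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Correlate centered sample profiles with subtype centroids
#'
#' Spearman rank correlation (default; Pearson available) of each centered
#' sample profile with each centroid over the shared genes. The call is the
#' argmax correlation, ties broken by the fixed subtype order with a tie
#' flag; a constant profile has undefined correlation and is flagged
#' unclassifiable.
#'
#' @param centered matrix of centered expression (genes x samples) or a
#'   single named vector.
#' @param centroids a \code{\linkS4class{CentroidSet}}.
#' @param method "spearman" (default) or "pearson".
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{label}, one correlation column per subtype, \code{confidence}
#'   (the maximum correlation), \code{tie}, \code{unclassifiable}.
#' @export
centroidCorrelate <- function(centered, centroids, method = "spearman") {
    method <- match.arg(method, c("spearman", "pearson"))
    if (is.null(dim(centered)))
        centered <- matrix(centered, ncol = 1,
                           dimnames = list(names(centered), "sample1"))
    cm <- centroidMatrix(centroids)
    shared <- intersect(rownames(centered), rownames(cm))
    if (length(shared) < 3)
        stop("fewer than 3 genes shared with the centroid set")
    x <- centered[shared, , drop = FALSE]
    cm <- cm[shared, , drop = FALSE]
    if (method == "spearman") {
        x <- apply(x, 2, rank)
        cm <- apply(cm, 2, rank)
    }
    flat <- apply(x, 2, sd) == 0
    suppressWarnings(cors <- cor(x, cm))
    labels <- character(ncol(x)); ties <- logical(ncol(x))
    conf <- numeric(ncol(x))
    for (j in seq_len(ncol(x))) {
        if (flat[j]) {
            labels[j] <- NA_character_; conf[j] <- NA_real_
            next
        }
        best <- max(cors[j, ])
        hit <- which(cors[j, ] >= best - 1e-12)
        labels[j] <- SUBTYPES[hit[1]]
        ties[j] <- length(hit) > 1
        conf[j] <- best
    }
    out <- data.frame(sample_id = colnames(centered), label = labels,
                      stringsAsFactors = FALSE)
    for (s in SUBTYPES) out[[paste0("cor_", s)]] <- cors[, s]
    out$confidence <- conf
    out$tie <- ties
    out$unclassifiable <- flat
    rownames(out) <- NULL
    out
}

#' Draw a composition-matched training subset
#'
#' Uniform sampling without replacement of exactly the requested number of
#' training columns per subtype.
#'
#' @param trainingLabels per-column subtype labels of the training set.
#' @param targetComposition named integer vector (subtype -> count).
#' @param seed optional integer seed.
#' @return integer vector of training column indices, or the character
#'   signal \code{"resample"} when some subtype's pool is too small (the
#'   caller redraws its reference subset).
#' @export
compositionMatchedSubset <- function(trainingLabels, targetComposition,
                                     seed = NULL) {
    if (!is.null(seed)) set.seed(seed)
    targetComposition <- targetComposition[targetComposition > 0]
    if (length(targetComposition) == 0)
        stop("target composition is empty")
    idx <- integer(0)
    for (s in names(targetComposition)) {
        pool <- which(trainingLabels == s)
        if (length(pool) < targetComposition[[s]])
            return("resample")
        idx <- c(idx, sample(pool, targetComposition[[s]]))
    }
    sort(idx)
}

#' Composition-matched random-subset calibration search
#'
#' Each iteration draws k (uniform in \code{kRange}) reference samples,
#' builds the target subtype composition from their reference calls, draws
#' a composition-matched training subset, sets the centering vector to the
#' per-gene difference of subset means (study minus training), classifies
#' all reference samples by Spearman correlation to the centroids after
#' centering, and records concordance with the reference calls. The
#' argmax-concordance iteration wins (ties: higher mean assigned-centroid
#' correlation, then earliest iteration). The training matrix is
#' gene-median-centered internally so subset means live on the centroid
#' scale.
#'
#' @param studyMatrix \code{NormalizedMatrix} or matrix of study expression
#'   restricted to (or containing) the centroid genes.
#' @param referenceCalls data.frame with \code{sample_id} and \code{label}
#'   columns (the externally subtyped subset).
#' @param trainingMatrix training expression matrix, same gene identifiers.
#' @param trainingLabels per-column training subtype labels.
#' @param centroids a \code{\linkS4class{CentroidSet}}.
#' @param kRange integer range of subset sizes (default 5 to 15).
#' @param nIter number of random iterations (default 50000).
#' @param seed integer seed.
#' @param maxRedraw bounded redraws when a composition cannot be matched
#'   before the iteration is skipped.
#' @return a \code{\linkS4class{CalibrationResult}}.
#' @export
calibrationSearch <- function(studyMatrix, referenceCalls, trainingMatrix,
                              trainingLabels, centroids, kRange = c(5, 15),
                              nIter = 50000, seed = 1, maxRedraw = 10) {
    if (nIter < 1) stop("nIter must be at least 1")
    if (nrow(referenceCalls) == 0) stop("reference calls must be non-empty")
    study <- .asValueMatrix(studyMatrix)
    training <- .asValueMatrix(trainingMatrix)
    cm <- centroidMatrix(centroids)
    genes <- intersect(rownames(cm),
                       intersect(rownames(study), rownames(training)))
    if (length(genes) < 3)
        stop("fewer than 3 centroid genes shared across matrices")
    ref <- referenceCalls[referenceCalls$sample_id %in% colnames(study), ]
    if (nrow(ref) < nrow(referenceCalls))
        stop("reference calls name samples absent from the study matrix")
    studyRef <- study[genes, ref$sample_id, drop = FALSE]
    training <- training[genes, , drop = FALSE]
    training <- training - apply(training, 1, median)
    cmRank <- apply(cm[genes, SUBTYPES, drop = FALSE], 2, rank)
    refCode <- match(ref$label, SUBTYPES)
    if (any(is.na(refCode)))
        stop("reference calls contain labels outside the four subtypes")
    labCode <- match(as.character(trainingLabels), SUBTYPES)
    set.seed(seed)
    res <- calibration_search_cpp(studyRef, refCode, training, labCode,
                                  cmRank, as.integer(kRange[1]),
                                  as.integer(kRange[2]), as.integer(nIter),
                                  as.integer(maxRedraw))
    centering <- setNames(res$centering, genes)
    comp <- setNames(as.integer(res$composition), SUBTYPES)
    new("CalibrationResult", centeringVector = centering,
        bestK = as.integer(res$k), bestComposition = comp,
        bestConcordance = res$concordance,
        iterationsRun = as.integer(nIter),
        skippedIterations = as.integer(res$skipped),
        seed = as.integer(seed))
}

#' Apply a calibration to call subtypes on a whole cohort
#'
#' @param fullMatrix \code{NormalizedMatrix} or matrix of study expression.
#' @param calibration a \code{\linkS4class{CalibrationResult}} (or any
#'   named centering vector).
#' @param centroids a \code{\linkS4class{CentroidSet}}.
#' @param method correlation method passed to
#'   \code{\link{centroidCorrelate}}.
#' @return data.frame of subtype calls (see \code{centroidCorrelate}).
#' @export
assignSubtypes <- function(fullMatrix, calibration, centroids,
                           method = "spearman") {
    centering <- if (is(calibration, "CalibrationResult"))
        centeringVector(calibration) else calibration
    vals <- .asValueMatrix(fullMatrix)
    genes <- intersect(rownames(vals), names(centering))
    centered <- geneCenter(vals[genes, , drop = FALSE], centering)
    centroidCorrelate(centered, centroids, method = method)
}
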