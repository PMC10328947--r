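# Readers and writers for the on-disk formats the pipeline touches:
# gene-by-sample count TSV, clinical CSV, GMT gene-set collections,
# MAF-like mutation TSV and SEG copy-number segments. All readers validate
# and fail with actionable messages; writer/reader pairs are inverse on
# valid data. Gene identity is by exact, case-sensitive symbol.

.requireCols <- function(df, required, what) {
    have <- tolower(names(df))
    missing <- required[!required %in% have]
    if (length(missing) > 0)
        stop(sprintf("%s: missing required column(s): %s", what,
                     paste(missing, collapse = ", ")))
    names(df) <- have
    df
}

#' Read / write a gene-by-sample count matrix (TSV)
#'
#' TSV with gene identifiers in the first column and one column per sample.
#' Counts must be non-negative integers; duplicate gene or sample
#' identifiers and ragged rows are rejected with the offending line named.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCounts <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 1) stop("counts file is empty")
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1]]
    nc <- length(header)
    samples <- header[-1]
    if (anyDuplicated(samples))
        stop("duplicate sample identifiers in header")
    genes <- character(length(fields) - 1)
    mat <- matrix(0L, nrow = length(fields) - 1, ncol = nc - 1)
    for (i in seq_along(fields)[-1]) {
        f <- fields[[i]]
        if (length(f) != nc)
            stop(sprintf("line %d: expected %d fields, found %d", i, nc,
                         length(f)))
        genes[i - 1] <- f[1]
        v <- suppressWarnings(as.numeric(f[-1]))
        if (any(is.na(v)))
            stop(sprintf("line %d: non-numeric count", i))
        if (any(v < 0))
            stop(sprintf("line %d: negative count", i))
        if (any(v != round(v)))
            stop(sprintf("line %d: non-integer count", i))
        mat[i - 1, ] <- as.integer(v)
    }
    if (anyDuplicated(genes))
        stop(sprintf("duplicate gene identifier(s): %s",
                     paste(unique(genes[duplicated(genes)]), collapse = ", ")))
    dimnames(mat) <- list(genes, samples)
    mat
}

#' @rdname readCounts
#' @param counts integer matrix, genes in rows.
#' @export
writeCounts <- function(counts, path) {
    df <- data.frame(gene_id = rownames(counts), counts,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. The description is
#' discarded, duplicate genes within a set are collapsed, and duplicate set
#' names are an error.
#'
#' @param path file path.
#' @return named list of character vectors (gene identifiers).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(setNames(list(), character()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(vapply(fields, length, 1L) < 3)
    if (length(short) > 0)
        stop(sprintf("line %d: GMT lines need >= 3 tab-separated fields",
                     short[1]))
    nm <- vapply(fields, `[`, "", 1)
    if (anyDuplicated(nm))
        stop(sprintf("duplicate gene-set name(s): %s",
                     paste(unique(nm[duplicated(nm)]), collapse = ", ")))
    sets <- lapply(fields, function(f) unique(f[-(1:2)]))
    setNames(sets, nm)
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param descriptions optional character vector of descriptions.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
    if (is.null(descriptions)) descriptions <- rep("na", length(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
        "")
    writeLines(lines, path)
    invisible(path)
}

#' Read a MAF-like somatic mutation table (TSV)
#'
#' Column names are matched case-insensitively. Requires
#' \code{sample_id} (or \code{tumor_sample_barcode}) and \code{gene} (or
#' \code{hugo_symbol}). If a \code{vaf} column is absent it is derived as
#' \code{t_alt_count / t_depth} when those columns are present. Missing
#' optional columns are tolerated as NA.
#'
#' @param path file path.
#' @return data.frame with columns \code{sample_id}, \code{gene},
#'   \code{vaf}, \code{alt_reads}, \code{consequence_class}, \code{pop_af},
#'   \code{variant_classification}.
#' @export
readMaf <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- tolower(names(df))
    if ("tumor_sample_barcode" %in% names(df) && !"sample_id" %in% names(df))
        names(df)[names(df) == "tumor_sample_barcode"] <- "sample_id"
    if ("hugo_symbol" %in% names(df) && !"gene" %in% names(df))
        names(df)[names(df) == "hugo_symbol"] <- "gene"
    df <- .requireCols(df, c("sample_id", "gene"), "MAF")
    if (!"alt_reads" %in% names(df) && "t_alt_count" %in% names(df))
        df$alt_reads <- df$t_alt_count
    if (!"vaf" %in% names(df)) {
        if (all(c("t_alt_count", "t_depth") %in% names(df)))
            df$vaf <- df$t_alt_count / df$t_depth
        else df$vaf <- NA_real_
    }
    for (opt in c("alt_reads", "pop_af"))
        if (!opt %in% names(df)) df[[opt]] <- NA_real_
    for (opt in c("consequence_class", "variant_classification"))
        if (!opt %in% names(df)) df[[opt]] <- NA_character_
    bad <- which(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1))
    if (length(bad) > 0)
        stop(sprintf("MAF line %d: vaf outside [0, 1]", bad[1] + 1))
    bad <- which(!is.na(df$alt_reads) & df$alt_reads < 0)
    if (length(bad) > 0)
        stop(sprintf("MAF line %d: negative alt_reads", bad[1] + 1))
    df[, c("sample_id", "gene", "vaf", "alt_reads", "consequence_class",
           "pop_af", "variant_classification")]
}

#' @rdname readMaf
#' @param muts mutation data.frame.
#' @export
writeMaf <- function(muts, path) {
    write.table(muts, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write SEG copy-number segments
#'
#' SEG convention: 1-based inclusive coordinates, whitespace/tab-separated
#' columns sample, chrom, start, end, log2 ratio (a header line is
#' tolerated). Segments of one sample must not overlap within a chromosome.
#' Returned as a GRanges (1-based closed, the Bioconductor convention) with
#' \code{sample_id} and \code{log2_ratio} metadata columns.
#'
#' @param path file path.
#' @return GRanges of segments.
#' @export
readSeg <- function(path) {
    df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                     sep = "")
    names(df) <- tolower(names(df))
    if ("id" %in% names(df) && !"sample_id" %in% names(df))
        names(df)[names(df) == "id"] <- "sample_id"
    if ("seg.mean" %in% names(df) && !"log2_ratio" %in% names(df))
        names(df)[names(df) == "seg.mean"] <- "log2_ratio"
    if ("loc.start" %in% names(df)) names(df)[names(df) == "loc.start"] <- "start"
    if ("loc.end" %in% names(df)) names(df)[names(df) == "loc.end"] <- "end"
    df <- .requireCols(df, c("sample_id", "chrom", "start", "end",
                             "log2_ratio"), "SEG")
    bad <- which(df$start > df$end)
    if (length(bad) > 0)
        stop(sprintf("SEG line %d: start > end", bad[1] + 1))
    gr <- GenomicRanges::GRanges(
        seqnames = as.character(df$chrom),
        ranges = IRanges::IRanges(start = df$start, end = df$end),
        sample_id = as.character(df$sample_id),
        log2_ratio = as.numeric(df$log2_ratio))
    .checkSegmentOverlap(gr)
    gr
}

.checkSegmentOverlap <- function(gr) {
    for (s in unique(gr$sample_id)) {
        sub <- gr[gr$sample_id == s]
        hits <- GenomicRanges::findOverlaps(sub, sub)
        if (length(hits) > length(sub))
            stop(sprintf("sample %s: overlapping segments on one chromosome", s))
    }
    invisible(TRUE)
}

#' @rdname readSeg
#' @param segments GRanges with \code{sample_id} and \code{log2_ratio}.
#' @export
writeSeg <- function(segments, path) {
    df <- data.frame(sample_id = segments$sample_id,
                     chrom = as.character(GenomicRanges::seqnames(segments)),
                     start = GenomicRanges::start(segments),
                     end = GenomicRanges::end(segments),
                     log2_ratio = segments$log2_ratio)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write the clinical covariate table (CSV)
#'
#' Column names are matched case-insensitively; requires
#' \code{patient_id}, \code{ki67_baseline}, \code{ki67_2wk},
#' \code{er_status}, \code{her2_status}. Optional columns
#' (\code{grade}, \code{histology}, \code{chemo}, \code{estradiol},
#' \code{tils}) default to NA/unknown. Ki67 values must lie in [0, 100]
#' where present; estradiol must be non-negative.
#'
#' @param path file path.
#' @return data.frame, one row per patient.
#' @export
readClinical <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    df <- .requireCols(df, c("patient_id", "ki67_baseline", "ki67_2wk",
                             "er_status", "her2_status"), "clinical")
    if (anyDuplicated(df$patient_id))
        stop("duplicate patient_id in clinical table")
    for (v in c("grade", "histology", "chemo"))
        if (!v %in% names(df)) df[[v]] <- "unknown"
    for (v in c("estradiol", "tils"))
        if (!v %in% names(df)) df[[v]] <- NA_real_
    for (v in c("ki67_baseline", "ki67_2wk")) {
        bad <- which(!is.na(df[[v]]) & (df[[v]] < 0 | df[[v]] > 100))
        if (length(bad) > 0)
            stop(sprintf("clinical line %d: %s outside [0, 100]",
                         bad[1] + 1, v))
    }
    bad <- which(!is.na(df$estradiol) & df$estradiol < 0)
    if (length(bad) > 0)
        stop(sprintf("clinical line %d: negative estradiol", bad[1] + 1))
    df
}

#' @rdname readClinical
#' @param clinical clinical data.frame.
#' @export
writeClinical <- function(clinical, path) {
    utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
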