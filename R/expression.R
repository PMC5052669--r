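#' Read / write a transcript-by-sample expression matrix
#'
#' The TSV dialect has a first column `transcript_id`, one column per sample
#' and an optional leading comment line `#unit=FPKM` (or `counts`) recording
#' the unit. `writeExpressionMatrix()` always emits that header line so a
#' write/read round trip is the identity.
#'
#' @param path file path.
#' @param unit unit override; when `NULL` the `#unit=` header is used and
#'   `"counts"` is assumed if absent.
#' @param annotations optional per-sample annotation data.frame passed to
#'   [LandscapeExperiment()].
#' @param lengths,biotype optional per-transcript metadata vectors.
#' @return `readExpressionMatrix()` returns a [LandscapeExperiment-class];
#'   `writeExpressionMatrix()` returns `path` invisibly.
#' @export
readExpressionMatrix <- function(path, unit = NULL, annotations = NULL,
                                 lengths = NULL, biotype = NULL) {
    first <- readLines(path, n = 1L)
    if (is.null(unit)) {
        unit <- if (grepl("^#unit=", first)) sub("^#unit=", "", first) else "counts"
    }
    df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (colnames(df)[1] != "transcript_id")
        stop("expected first column 'transcript_id' in ", path)
    ids <- as.character(df[[1]])
    if (anyDuplicated(ids))
        stop("duplicate transcript id in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    m <- as.matrix(df[, -1, drop = FALSE])
    if (nrow(m) == 0L) storage.mode(m) <- "double"
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    if (any(m < 0)) {
        bad <- ids[which(rowSums(m < 0) > 0)[1]]
        stop("negative expression value at transcript ", bad, " in ", path)
    }
    rownames(m) <- ids
    LandscapeExperiment(m, unit = unit, lengths = lengths, biotype = biotype,
                        annotations = annotations)
}

#' @rdname readExpressionMatrix
#' @param m a [LandscapeExperiment-class]
#' @export
writeExpressionMatrix <- function(m, path) {
    stopifnot(is(m, "LandscapeExperiment"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("#unit=", exprUnit(m)), con)
    df <- data.frame(transcript_id = rownames(m), exprValues(m),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' FPKM / fragment-count interconversion
#'
#' Approximate fragment counts are recovered from FPKM abundances by
#' multiplying by the transcript length in kilobases and by the per-sample
#' mapped-fragment mass divided by 1e6: `fragments = fpkm * (length_bp/1000) *
#' (map_mass/1e6)`. `fragmentsToFpkm()` is the exact inverse.
#'
#' @param fpkm,fragments non-negative numeric vector.
#' @param length_bp transcript length in bp, > 0.
#' @param map_mass total mapped-fragment mass of the sample, > 0.
#' @return numeric vector.
#' @examples
#' fpkmToFragments(2, 2000, 5e7) # 200
#' @export
fpkmToFragments <- function(fpkm, length_bp, map_mass) {
    if (any(length_bp <= 0)) stop("length_bp must be > 0")
    if (any(map_mass <= 0)) stop("map_mass must be > 0")
    if (any(fpkm < 0)) stop("fpkm must be >= 0")
    fpkm * (length_bp / 1000) * (map_mass / 1e6)
}

#' @rdname fpkmToFragments
#' @export
fragmentsToFpkm <- function(fragments, length_bp, map_mass) {
    if (any(length_bp <= 0)) stop("length_bp must be > 0")
    if (any(map_mass <= 0)) stop("map_mass must be > 0")
    if (any(fragments < 0)) stop("fragments must be >= 0")
    fragments / (length_bp / 1000) / (map_mass / 1e6)
}

#' Convert a count matrix to FPKM
#'
#' Per-sample map mass defaults to the sample's total fragment count.
#'
#' @param m [LandscapeExperiment-class] in counts, with transcript lengths.
#' @param map_mass optional per-sample mapped-fragment mass.
#' @return a [LandscapeExperiment-class] in FPKM units.
#' @export
countsToFpkm <- function(m, map_mass = NULL) {
    stopifnot(is(m, "LandscapeExperiment"))
    if (exprUnit(m) != "counts") stop("countsToFpkm() expects unit 'counts'")
    len <- transcriptLengths(m)
    if (is.null(len)) stop("transcript lengths are required for FPKM conversion")
    v <- exprValues(m)
    if (is.null(map_mass)) map_mass <- colSums(v)
    if (any(map_mass <= 0)) stop("map_mass must be > 0 for all samples")
    fpkm <- sweep(v / (len / 1000), 2, map_mass / 1e6, "/")
    out <- m
    SummarizedExperiment::assay(out, "expr") <- fpkm
    out@unit <- "FPKM"
    validObject(out)
    out
}

#' Nearest-rank percentile of a sample's expression values
#'
#' The value of the sample sitting at the `ceiling(q * n)`-th position of the
#' ascending sort (1-based), i.e. the expression level of an actual sample such
#' as "the 95th percentile sample", not an interpolated quantile.
#'
#' @param values numeric vector, one expression value per sample.
#' @param q quantile in (0, 1].
#' @return the nearest-rank quantile value.
#' @examples
#' percentileExpression(1:20, 0.95) # 19
#' @export
percentileExpression <- function(values, q = 0.95) {
    if (length(values) < 1L) stop("percentileExpression() needs >= 1 value")
    if (q <= 0 || q > 1) stop("q must be in (0, 1]")
    sort(values)[ceiling(q * length(values))]
}

#' Expression filter on the percentile metric
#'
#' Keeps transcripts whose expression at the `q` sample quantile is at least
#' `min_fpkm` ("at least one FPKM in the top 5% of samples" with defaults).
#' The inequality is inclusive.
#'
#' @param m [LandscapeExperiment-class] in FPKM units.
#' @param q sample quantile (default 0.95).
#' @param min_fpkm inclusive minimum (default 1).
#' @return character vector of retained transcript ids.
#' @export
expressionFilter <- function(m, q = 0.95, min_fpkm = 1.0) {
    stopifnot(is(m, "LandscapeExperiment"))
    if (exprUnit(m) != "FPKM") stop("expressionFilter() expects unit 'FPKM'")
    v <- exprValues(m)
    if (nrow(v) == 0L) stop("empty expression matrix")
    keep <- apply(v, 1L, percentileExpression, q = q) >= min_fpkm
    rownames(v)[keep]
}

#' Log2 fold change over the median of reference samples
#'
#' `out[g, s] = log2((m[g, s] + pseudocount) / (median_ref(m[g, ]) + pseudocount))`,
#' the normalization used for tumor-versus-normal heatmaps (reference = the
#' normal samples, or the ER-negative samples for the ER contrast).
#'
#' @param m [LandscapeExperiment-class] or numeric matrix.
#' @param reference_sample_ids character vector, subset of sample ids.
#' @param pseudocount positive offset guarding exact zeros (default 0.1).
#' @return numeric matrix of log2 fold changes, same dimnames as the input.
#' @export
log2FoldOverReference <- function(m, reference_sample_ids, pseudocount = 0.1) {
    v <- if (is(m, "LandscapeExperiment")) exprValues(m) else as.matrix(m)
    if (length(reference_sample_ids) == 0L) stop("empty reference sample set")
    if (!all(reference_sample_ids %in% colnames(v)))
        stop("reference sample ids not found in matrix")
    if (pseudocount <= 0) stop("pseudocount must be > 0")
    ref_med <- apply(v[, reference_sample_ids, drop = FALSE], 1L, stats::median)
    log2((v + pseudocount) / (ref_med + pseudocount))
}

#' Per-sample counts-per-million normalization
#'
#' The count normalization applied before sample-set enrichment testing: each
#' sample is scaled so its total is 1e6.
#'
#' @param m [LandscapeExperiment-class] in counts.
#' @return a [LandscapeExperiment-class] whose assay sums to 1e6 per sample;
#'   the unit tag stays `"counts"` and the method is recorded in `metadata()`.
#' @export
normalizeCounts <- function(m) {
    stopifnot(is(m, "LandscapeExperiment"))
    if (exprUnit(m) != "counts") stop("normalizeCounts() expects unit 'counts'")
    v <- exprValues(m)
    tot <- colSums(v)
    if (any(tot == 0)) {
        stop("sample with zero total count: ",
             paste(colnames(v)[tot == 0], collapse = ", "))
    }
    out <- m
    SummarizedExperiment::assay(out, "expr") <- sweep(v, 2, tot / 1e6, "/")
    S4Vectors::metadata(out)$normalization <- "CPM"
    out
}
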