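#' @importFrom GenomicRanges GRanges promoters reduce findOverlaps pintersect
#'   countOverlaps seqnames strand start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

#' Convert a transcript-model table to a GRanges of TSS anchors
#'
#' @param models data.frame with columns `transcript_id`, `chrom`, `tss`
#'   (0-based bp), `strand` (`+`/`-`).
#' @return width-1 `GRanges` named by transcript id (1-based internally; the
#'   0-based `tss` maps to start `tss + 1`).
#' @export
tssAnchors <- function(models) {
    models <- as.data.frame(models)
    need <- c("transcript_id", "chrom", "tss", "strand")
    if (!all(need %in% colnames(models)))
        stop("models must have columns: ", paste(need, collapse = ", "))
    if (any(models$tss < 0)) stop("tss must be >= 0")
    if (!all(models$strand %in% c("+", "-"))) stop("strand must be + or -")
    gr <- GenomicRanges::GRanges(models$chrom,
                                 IRanges::IRanges(models$tss + 1L, width = 1L),
                                 strand = models$strand)
    names(gr) <- models$transcript_id
    gr
}

#' Promoter windows around unique transcription start sites
#'
#' `symmetric` mode builds strand-adjusted `[tss - upstream, tss + downstream)`
#' windows (0-based half-open); `upstream_only` builds `[tss - upstream, tss)`
#' on the plus strand and the strand-mirrored window on the minus strand.
#' Duplicate TSS positions (same chrom/strand/position) are collapsed to one
#' window; windows are truncated at coordinate 0.
#'
#' @param models transcript-model data.frame (see [tssAnchors()]).
#' @param mode `"symmetric"` or `"upstream_only"`.
#' @param upstream_bp,downstream_bp window extents in bp (> 0; `downstream_bp`
#'   is ignored in `upstream_only` mode).
#' @return `GRanges` of promoter windows; `mcols()$transcript_ids` holds the
#'   comma-joined ids sharing each TSS.
#' @export
promoterWindows <- function(models, mode = c("symmetric", "upstream_only"),
                            upstream_bp = 5000, downstream_bp = 5000) {
    mode <- match.arg(mode)
    if (upstream_bp <= 0) stop("window sizes must be > 0")
    if (mode == "symmetric" && downstream_bp <= 0)
        stop("window sizes must be > 0")
    anchors <- tssAnchors(models)
    key <- paste(GenomicRanges::seqnames(anchors),
                 GenomicRanges::start(anchors),
                 GenomicRanges::strand(anchors))
    first <- !duplicated(key)
    ids <- vapply(split(names(anchors), key), paste, "", collapse = ",")
    uniq <- anchors[first]
    win <- if (mode == "symmetric") {
        GenomicRanges::promoters(uniq, upstream = upstream_bp,
                                 downstream = downstream_bp)
    } else {
        ## strictly-upstream window: [tss - u, tss) on +, [tss, tss + u) on -
        ## (0-based half-open; tss0 = start(uniq) - 1)
        tss0 <- GenomicRanges::start(uniq) - 1L
        plus <- as.character(GenomicRanges::strand(uniq)) == "+"
        st1 <- ifelse(plus, tss0 - upstream_bp + 1L, tss0 + 1L)
        en1 <- ifelse(plus, tss0, tss0 + upstream_bp)
        out <- GenomicRanges::GRanges(GenomicRanges::seqnames(uniq),
                                      IRanges::IRanges(pmax(st1, 1L),
                                                       pmax(en1, 1L)),
                                      strand = GenomicRanges::strand(uniq))
        names(out) <- names(uniq)
        out
    }
    ## clamp at the chromosome origin
    GenomicRanges::start(win) <- pmax(GenomicRanges::start(win), 1L)
    S4Vectors::mcols(win)$transcript_ids <- ids[key[first]]
    win
}

#' Overlap ChIP peaks with promoter windows
#'
#' Half-open interval semantics: a peak and promoter on the same chromosome
#' overlap iff `max(starts) < min(ends)` in 0-based coordinates. Reports per
#' promoter a binding flag (>= 1 peak), the number of overlapping peaks and
#' the total covered bases (peaks merged before summing).
#'
#' @param peaks `GRanges` of peaks (strand ignored).
#' @param promoters `GRanges` of promoter windows, e.g. [promoterWindows()].
#' @return data.frame with `flag`, `n_peaks` and `overlap_bp` per promoter,
#'   carrying over `transcript_ids` when present.
#' @export
peakPromoterOverlap <- function(peaks, promoters) {
    ps <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                                 IRanges::IRanges(GenomicRanges::start(peaks),
                                                  GenomicRanges::end(peaks)))
    pr <- GenomicRanges::GRanges(GenomicRanges::seqnames(promoters),
                                 IRanges::IRanges(GenomicRanges::start(promoters),
                                                  GenomicRanges::end(promoters)))
    n_peaks <- GenomicRanges::countOverlaps(pr, ps)
    red <- GenomicRanges::reduce(ps)
    hits <- GenomicRanges::findOverlaps(pr, red)
    ov <- GenomicRanges::pintersect(pr[S4Vectors::queryHits(hits)],
                                    red[S4Vectors::subjectHits(hits)])
    bp <- rep(0L, length(pr))
    if (length(hits) > 0L) {
        agg <- tapply(GenomicRanges::width(ov), S4Vectors::queryHits(hits), sum)
        bp[as.integer(names(agg))] <- as.integer(agg)
    }
    out <- data.frame(flag = n_peaks >= 1L, n_peaks = n_peaks,
                      overlap_bp = bp)
    mc <- S4Vectors::mcols(promoters)
    if ("transcript_ids" %in% colnames(mc))
        out$transcript_ids <- mc$transcript_ids
    out
}

#' Per-transcript regulator binding flags from peak/promoter overlap
#'
#' Convenience wrapper combining [promoterWindows()] and
#' [peakPromoterOverlap()] for one or more cell lines.
#'
#' @param models transcript-model data.frame.
#' @param peaks named list of `GRanges`, one per cell line (or a single
#'   `GRanges`).
#' @param ... passed to [promoterWindows()].
#' @return data.frame with `transcript_id` and one logical column per cell
#'   line.
#' @export
bindingFlags <- function(models, peaks, ...) {
    if (is(peaks, "GRanges")) peaks <- list(binding = peaks)
    win <- promoterWindows(models, ...)
    ids <- strsplit(S4Vectors::mcols(win)$transcript_ids, ",", fixed = TRUE)
    out <- data.frame(transcript_id = as.character(models$transcript_id),
                      stringsAsFactors = FALSE)
    for (cl in names(peaks)) {
        ov <- peakPromoterOverlap(peaks[[cl]], win)
        flagged <- unlist(ids[ov$flag])
        out[[cl]] <- out$transcript_id %in% flagged
    }
    out
}

#' Estrogen-induction category from a fold change
#'
#' `"high"` for fold change > 2.5, `"low"` for 1.5 < fold change <= 2.5,
#' `"none"` otherwise (inequalities strict, matching the one-arrow / three-
#' arrow induction annotation).
#'
#' @param fold_change estrogen/vehicle expression ratio, > 0 (vectorized).
#' @return character vector in `{"none", "low", "high"}`.
#' @examples
#' inductionCategory(c(1.5, 2, 3)) # none, low, high
#' @export
inductionCategory <- function(fold_change) {
    if (any(is.na(fold_change)) || any(fold_change <= 0))
        stop("fold_change must be > 0")
    ifelse(fold_change > 2.5, "high",
           ifelse(fold_change > 1.5, "low", "none"))
}

#' Read / write BED peak files
#'
#' Thin wrappers over `rtracklayer` keeping the 0-based half-open BED
#' convention at the file boundary.
#'
#' @param path BED file path.
#' @return `readPeaks()` returns a `GRanges`.
#' @export
readPeaks <- function(path) {
    rtracklayer::import(path, format = "BED")
}

#' @rdname readPeaks
#' @param peaks a `GRanges`
#' @export
writePeaks <- function(peaks, path) {
    rtracklayer::export(peaks, path, format = "BED")
    invisible(path)
}
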