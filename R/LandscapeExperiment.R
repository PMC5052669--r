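#' Construct a LandscapeExperiment
#'
#' @param values numeric matrix, transcripts in rows, samples in columns.
#'   Dimnames are required and become transcript/sample ids.
#' @param unit unit of `values`, `"counts"` or `"FPKM"`.
#' @param lengths optional numeric vector of transcript lengths in bp, one per
#'   row (recycled from a named vector by rowname).
#' @param biotype optional character vector per transcript, e.g. `"lncRNA"` or
#'   `"protein_coding"`.
#' @param annotations optional data.frame of per-sample annotations. When given
#'   it must have one row per sample; a `sample_id` column, if present, is
#'   matched against colnames.
#'
#' @return A [LandscapeExperiment-class] object.
#' @examples
#' m <- matrix(rpois(20, 10), 4, 5,
#'     dimnames = list(paste0("T", 1:4), paste0("S", 1:5)))
#' le <- LandscapeExperiment(m, unit = "counts")
#' exprUnit(le)
#' @export
LandscapeExperiment <- function(values, unit = c("counts", "FPKM"),
                                lengths = NULL, biotype = NULL,
                                annotations = NULL) {
    unit <- match.arg(unit)
    values <- as.matrix(values)
    if ((nrow(values) > 0L && is.null(rownames(values))) ||
        (ncol(values) > 0L && is.null(colnames(values))))
        stop("`values` must have row (transcript) and column (sample) names")
    if (is.null(rownames(values))) rownames(values) <- character(0)
    if (is.null(colnames(values))) colnames(values) <- character(0)
    storage.mode(values) <- "double"
    rd <- S4Vectors::DataFrame(row.names = rownames(values))
    if (!is.null(lengths)) {
        if (!is.null(names(lengths))) lengths <- lengths[rownames(values)]
        rd$length_bp <- as.numeric(lengths)
    }
    if (!is.null(biotype)) {
        if (!is.null(names(biotype))) biotype <- biotype[rownames(values)]
        rd$biotype <- as.character(biotype)
    }
    cd <- S4Vectors::DataFrame(row.names = colnames(values))
    if (!is.null(annotations)) {
        annotations <- as.data.frame(annotations)
        if ("sample_id" %in% colnames(annotations)) {
            rownames(annotations) <- annotations$sample_id
            annotations$sample_id <- NULL
        }
        if (nrow(annotations) != ncol(values))
            stop("annotations must have one row per sample")
        annotations <- annotations[colnames(values), , drop = FALSE]
        cd <- S4Vectors::DataFrame(annotations, row.names = colnames(values))
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(expr = values),
        rowData = rd, colData = cd)
    new("LandscapeExperiment", se, unit = unit)
}

#' @rdname LandscapeExperiment
#' @param x,object a LandscapeExperiment
#' @export
setGeneric("exprUnit", function(x) standardGeneric("exprUnit"))

#' @rdname LandscapeExperiment
#' @export
setMethod("exprUnit", "LandscapeExperiment", function(x) x@unit)

#' @rdname LandscapeExperiment
#' @param value replacement value
#' @export
setGeneric("exprUnit<-", function(x, value) standardGeneric("exprUnit<-"))

#' @rdname LandscapeExperiment
#' @export
setReplaceMethod("exprUnit", "LandscapeExperiment", function(x, value) {
    x@unit <- value
    validObject(x)
    x
})

#' @rdname LandscapeExperiment
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname LandscapeExperiment
#' @export
setMethod("exprValues", "LandscapeExperiment",
    function(x) SummarizedExperiment::assay(x, "expr"))

#' @rdname LandscapeExperiment
#' @export
setGeneric("transcriptLengths", function(x) standardGeneric("transcriptLengths"))

#' @rdname LandscapeExperiment
#' @export
setMethod("transcriptLengths", "LandscapeExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"length_bp" %in% colnames(rd)) return(NULL)
    stats::setNames(rd$length_bp, rownames(x))
})

#' @rdname LandscapeExperiment
#' @export
setGeneric("transcriptBiotype", function(x) standardGeneric("transcriptBiotype"))

#' @rdname LandscapeExperiment
#' @export
setMethod("transcriptBiotype", "LandscapeExperiment", function(x) {
    rd <- SummarizedExperiment::rowData(x)
    if (!"biotype" %in% colnames(rd)) return(NULL)
    stats::setNames(as.character(rd$biotype), rownames(x))
})

#' @rdname LandscapeExperiment
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname LandscapeExperiment
#' @export
setMethod("sampleInfo", "LandscapeExperiment", function(x)
    as.data.frame(SummarizedExperiment::colData(x)))

setMethod("show", "LandscapeExperiment", function(object) {
    cat("LandscapeExperiment:", nrow(object), "transcripts x",
        ncol(object), "samples [unit:", object@unit, "]\n")
    callNextMethod()
})
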