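#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importClassesFrom S4Vectors DFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' Transcript-by-sample expression container
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one expression
#' assay (\code{"expr"}) tagged with its unit (\code{"counts"} or \code{"FPKM"}),
#' per-transcript length and biotype in \code{rowData}, and sample annotations
#' (cohort, ER/PR/HER2 IHC status, PAM50 label) in \code{colData}. All
#' SummarizedExperiment subsetting and accessor machinery applies.
#'
#' @slot unit character scalar, the unit of the expression assay.
#' @seealso [LandscapeExperiment()] for the constructor.
#' @export
setClass("LandscapeExperiment",
    contains = "SummarizedExperiment",
    representation(unit = "character"))

setValidity("LandscapeExperiment", function(object) {
    msg <- NULL
    if (length(object@unit) != 1L || !object@unit %in% c("counts", "FPKM"))
        msg <- c(msg, "unit must be one of 'counts', 'FPKM'")
    if (!"expr" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'expr' is required")
    else {
        v <- SummarizedExperiment::assay(object, "expr")
        if (anyNA(v) || any(v < 0))
            msg <- c(msg, "expression values must be non-negative and non-missing")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "transcript ids must be unique")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be unique")
    rd <- SummarizedExperiment::rowData(object)
    if ("length_bp" %in% colnames(rd) && any(rd$length_bp <= 0, na.rm = TRUE))
        msg <- c(msg, "transcript lengths must be positive")
    if (is.null(msg)) TRUE else msg
})

#' Per-transcript SSEA results
#'
#' A \linkS4class{DFrame} with one row per tested transcript and columns
#' \code{es}, \code{nes}, \code{p_nominal}, \code{fdr_q}, \code{direction},
#' \code{percentile_value} and \code{significant}. Run parameters are kept in
#' \code{metadata()}.
#'
#' @export
setClass("SseaResults", contains = "DFrame")
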