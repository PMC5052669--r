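#' Hierarchical clustering with Pearson-correlation distance and Ward linkage
#'
#' Dissimilarity is `1 - Pearson r`; agglomeration uses the historical
#' `hclust` "ward" update (method `"ward.D"`) applied to those dissimilarities
#' as-is. Constant profiles, for which Pearson correlation is undefined, are
#' assigned distance 1 to everything (0 to themselves).
#'
#' @param m numeric matrix or [LandscapeExperiment-class] of (typically
#'   log-fold normalized) expression.
#' @param axis `"transcripts"` (rows) or `"samples"` (columns).
#' @return list of class `ClusterResult` with the `hclust` tree, the leaf
#'   `order`, item `labels` and a `cut(k)` helper returning cluster labels.
#' @export
hierarchicalCluster <- function(m, axis = c("transcripts", "samples")) {
    axis <- match.arg(axis)
    v <- if (is(m, "LandscapeExperiment")) exprValues(m) else as.matrix(m)
    x <- if (axis == "transcripts") v else t(v)
    if (nrow(x) < 2L) stop("need >= 2 items to cluster")
    cc <- suppressWarnings(stats::cor(t(x)))
    cc[is.na(cc)] <- 0 # constant profiles: r undefined -> distance 1
    d <- 1 - cc
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D")
    structure(list(hclust = hc, order = hc$order, labels = rownames(x),
                   axis = axis,
                   cut = function(k) stats::cutree(hc, k = k)),
              class = "ClusterResult")
}

#' Label lncRNA clusters as Luminal / Upregulated / Downregulated
#'
#' Rule-based stand-in for visual cluster annotation, applied to k = 3
#' clusters of a log2-fold-over-normal matrix: a cluster is `Downregulated`
#' if its median over tumor samples is below 0; `Luminal` if its median over
#' luminal (PAM50 LumA/LumB) tumors exceeds the median over non-luminal tumors
#' by more than `margin` log2 units; otherwise `Upregulated`.
#'
#' @param norm_m log2 fold-change matrix (transcripts x samples).
#' @param cluster_labels named integer vector of cluster ids per transcript
#'   (e.g. from `ClusterResult$cut(3)`).
#' @param annotations data.frame per sample with columns `cohort`
#'   (`"tumor"`/`"normal"`) and `pam50`; rownames or `sample_id` column must
#'   match the matrix columns.
#' @param luminal_subtypes PAM50 labels counted as luminal.
#' @param margin log2-unit margin for the Luminal call (default 1).
#' @return named character vector cluster-id -> label.
#' @export
labelLncrnaClusters <- function(norm_m, cluster_labels, annotations,
                                luminal_subtypes = c("LumA", "LumB"),
                                margin = 1.0) {
    norm_m <- as.matrix(norm_m)
    annotations <- as.data.frame(annotations)
    if ("sample_id" %in% colnames(annotations))
        rownames(annotations) <- annotations$sample_id
    if (!all(c("cohort", "pam50") %in% colnames(annotations)))
        stop("annotations must provide 'cohort' and 'pam50' columns")
    if (!all(colnames(norm_m) %in% rownames(annotations)))
        stop("annotations missing for some samples")
    ann <- annotations[colnames(norm_m), ]
    tumor <- ann$cohort == "tumor"
    if (!any(tumor)) stop("no tumor samples annotated")
    luminal <- tumor & ann$pam50 %in% luminal_subtypes
    nonlum <- tumor & !ann$pam50 %in% luminal_subtypes
    out <- character(0)
    for (cl in sort(unique(cluster_labels))) {
        rows <- names(cluster_labels)[cluster_labels == cl]
        sub <- norm_m[rows, , drop = FALSE]
        tumor_med <- stats::median(sub[, tumor, drop = FALSE])
        if (tumor_med < 0) {
            lab <- "Downregulated"
        } else {
            lum_med <- stats::median(sub[, luminal, drop = FALSE])
            non_med <- stats::median(sub[, nonlum, drop = FALSE])
            lab <- if (!is.na(lum_med) && !is.na(non_med) &&
                       (lum_med - non_med) > margin) "Luminal" else "Upregulated"
        }
        out[as.character(cl)] <- lab
    }
    out
}

#' Intersect two differential-expression id sets
#'
#' @param up_a,up_b character vectors of transcript ids (e.g. upregulated in
#'   cancer-vs-normal and in ER-positive-vs-negative).
#' @return list with the `intersection` ids and `venn` counts
#'   (`a_only`, `b_only`, `both`).
#' @export
intersectDeSets <- function(up_a, up_b) {
    up_a <- unique(as.character(up_a))
    up_b <- unique(as.character(up_b))
    both <- intersect(up_a, up_b)
    list(intersection = both,
         venn = c(a_only = length(setdiff(up_a, up_b)),
                  b_only = length(setdiff(up_b, up_a)),
                  both = length(both)))
}

#' Prioritize candidate lncRNAs by tissue expression
#'
#' Ranks the intersection ids by the expression value of the 95th-percentile
#' sample (descending; ties broken by transcript id, lexicographic) and
#' attaches per-cell-line regulator promoter-binding flags and the
#' estrogen-induction category.
#'
#' @param ids transcript ids (typically the up-in-both intersection).
#' @param m [LandscapeExperiment-class] in FPKM units.
#' @param binding data.frame with column `transcript_id` plus one logical
#'   column per cell line, or `NULL`.
#' @param induction data.frame with columns `transcript_id` and either
#'   `fold_change` or `vehicle`/`estrogen` columns, or `NULL`. Missing ids get
#'   category `"none"`.
#' @param n_top number of candidates returned (default 10).
#' @param q percentile used for the ranking metric (default 0.95).
#' @return data.frame of candidate records, best first, with a `rank` column.
#' @export
prioritizeCandidates <- function(ids, m, binding = NULL, induction = NULL,
                                 n_top = 10, q = 0.95) {
    stopifnot(is(m, "LandscapeExperiment"))
    ids <- unique(as.character(ids))
    missing <- setdiff(ids, rownames(m))
    if (length(missing) > 0L)
        stop("transcript id missing from matrix: ",
             paste(missing, collapse = ", "))
    if (length(ids) == 0L) {
        return(data.frame(transcript_id = character(0),
                          percentile95_fpkm = numeric(0),
                          induction_fold = numeric(0),
                          induction_category = character(0),
                          rank = integer(0)))
    }
    v <- exprValues(m)[ids, , drop = FALSE]
    pctl <- apply(v, 1L, percentileExpression, q = q)
    ord <- order(-pctl, ids)
    out <- data.frame(transcript_id = ids[ord],
                      percentile95_fpkm = pctl[ord],
                      stringsAsFactors = FALSE)
    fold <- rep(NA_real_, nrow(out))
    if (!is.null(induction)) {
        induction <- as.data.frame(induction)
        if (!"fold_change" %in% colnames(induction)) {
            if (!all(c("vehicle", "estrogen") %in% colnames(induction)))
                stop("induction table needs fold_change or vehicle/estrogen")
            induction$fold_change <- induction$estrogen / induction$vehicle
        }
        fold <- induction$fold_change[match(out$transcript_id,
                                            induction$transcript_id)]
    }
    out$induction_fold <- fold
    cat <- rep("none", nrow(out))
    ok <- !is.na(fold) & fold > 0
    cat[ok] <- inductionCategory(fold[ok])
    out$induction_category <- cat
    if (!is.null(binding)) {
        binding <- as.data.frame(binding)
        cellcols <- setdiff(colnames(binding), "transcript_id")
        for (cl in cellcols) {
            flags <- binding[[cl]][match(out$transcript_id,
                                         binding$transcript_id)]
            out[[paste0("er_binding_", cl)]] <- !is.na(flags) & flags
        }
    }
    out <- utils::head(out, n_top)
    out$rank <- seq_len(nrow(out))
    rownames(out) <- NULL
    out
}
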