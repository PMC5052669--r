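#' Configuration of a full landscape run
#'
#' Collects the input file paths and every analysis threshold of the
#' end-to-end run. Defaults are the printed study settings: FDR cutoff 1e-5
#' with percentile cutoff 0.975 for differential expression, the 0.95 / 1 FPKM
#' expression filter, top-150 correlation signatures, the "methods" OR/p
#' network preset, and the 10 / 1 FPKM survival cuts.
#'
#' @param counts_path expression matrix TSV (counts; `#unit=` header).
#' @param models_path transcript-model TSV (id, chrom, tss, strand, length_bp,
#'   biotype).
#' @param annotations_path sample-annotation TSV (sample_id, cohort,
#'   er_status, pr_status, her2_status, pam50).
#' @param peaks_paths named character vector of BED files, one per cell line.
#' @param gmt_path concept library (GMT).
#' @param induction_path induction table TSV.
#' @param survival_path survival TSV (sample_id, time, event).
#' @param target_id transcript anchoring the guilt-by-association and
#'   survival stages.
#' @param out_dir output directory of the run.
#' @param n_permutations,seed SSEA permutation controls.
#' @param fdr_cutoff,percentile_q,min_expr SSEA significance settings.
#' @param filter_q,min_fpkm expression-filter settings on the FPKM matrix.
#' @param sig_n correlation-signature size.
#' @param n_top candidates reported.
#' @param network_preset [networkPreset()] name.
#' @param high_cut,low_cut survival FPKM cuts.
#' @return validated list of class `RunConfig`.
#' @export
landscapeConfig <- function(counts_path, models_path, annotations_path,
                            peaks_paths, gmt_path, induction_path,
                            survival_path, target_id, out_dir,
                            n_permutations = 1000, seed = 1L,
                            fdr_cutoff = 1e-5, percentile_q = 0.975,
                            min_expr = 1, filter_q = 0.95, min_fpkm = 1,
                            sig_n = 150, n_top = 10,
                            network_preset = "methods",
                            high_cut = 10, low_cut = 1) {
    cfg <- as.list(environment())
    paths <- c(counts_path, models_path, annotations_path, peaks_paths,
               gmt_path, induction_path, survival_path)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0L)
        stop("input file(s) not found: ", paste(missing, collapse = ", "))
    if (is.null(names(peaks_paths)) || any(names(peaks_paths) == ""))
        stop("peaks_paths must be a named vector (one name per cell line)")
    class(cfg) <- "RunConfig"
    cfg
}

.writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

#' Execute the full lncRNA landscape pipeline
#'
#' Runs, in order: expression filter; SSEA for the tumor-vs-normal and
#' ER-positive-vs-negative contrasts; correlation-distance Ward clustering
#' and cluster labeling; intersection of the upregulated sets; promoter
#' binding / induction annotation and candidate prioritization; concept
#' Fisher-overlap network; expression-stratified survival. Every stage's
#' outputs, seed and md5 checksum are recorded in `manifest.json`; re-running
#' the same config reproduces all outputs bit-identically.
#'
#' @param config a [landscapeConfig()].
#' @return (invisibly) a list with the per-stage results and the run
#'   directory.
#' @export
runLandscape <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

    ## ---- load and validate everything up front -------------------------
    models <- utils::read.delim(config$models_path, stringsAsFactors = FALSE)
    annotations <- utils::read.delim(config$annotations_path,
                                     stringsAsFactors = FALSE)
    need_ann <- c("sample_id", "cohort", "er_status", "pam50")
    if (!all(need_ann %in% colnames(annotations)))
        stop("validation: annotations missing column(s): ",
             paste(setdiff(need_ann, colnames(annotations)), collapse = ", "))
    counts <- readExpressionMatrix(config$counts_path,
                                   annotations = annotations,
                                   lengths = stats::setNames(models$length_bp,
                                                             models$transcript_id),
                                   biotype = stats::setNames(models$biotype,
                                                             models$transcript_id))
    if (!all(c("tumor", "normal") %in% annotations$cohort))
        stop("validation: cohort column must contain 'tumor' and 'normal'")
    if (!config$target_id %in% rownames(counts))
        stop("validation: target_id not in matrix: ", config$target_id)
    peaks <- lapply(config$peaks_paths, readPeaks)
    concepts <- readGmt(config$gmt_path)
    induction <- utils::read.delim(config$induction_path,
                                   stringsAsFactors = FALSE)
    surv <- readSurvival(config$survival_path)

    manifest <- list(config = config[!vapply(config, is.null, TRUE)],
                     stages = list())
    seed0 <- as.integer(config$seed)
    stage_out <- function(name, seed, files) {
        manifest$stages[[length(manifest$stages) + 1L]] <<- list(
            stage = name, seed = seed,
            outputs = lapply(files, function(f)
                list(path = basename(f),
                     md5 = unname(tools::md5sum(f)))))
    }

    ann <- annotations
    rownames(ann) <- ann$sample_id
    tumor_ids <- ann$sample_id[ann$cohort == "tumor"]
    normal_ids <- ann$sample_id[ann$cohort == "normal"]
    fpkm <- countsToFpkm(counts)

    ## ---- stage 1: expression filter ------------------------------------
    kept <- expressionFilter(fpkm, q = config$filter_q,
                             min_fpkm = config$min_fpkm)
    f1 <- .writeTsv(data.frame(transcript_id = kept),
                    file.path(config$out_dir, "filtered_transcripts.tsv"))
    stage_out("expression_filter", seed0, f1)

    ## ---- stages 2-3: SSEA contrasts ------------------------------------
    lnc_kept <- intersect(kept, rownames(counts)[
        transcriptBiotype(counts) == "lncRNA"])
    run_contrast <- function(m_sub, set, seed, fname) {
        res <- runSsea(m_sub, set,
                       params = sseaParams(n_permutations = config$n_permutations,
                                           seed = seed),
                       percentile_q = config$percentile_q,
                       min_expr = config$min_expr,
                       fdr_cutoff = config$fdr_cutoff)
        df <- data.frame(transcript_id = rownames(res),
                         as.data.frame(res), stringsAsFactors = FALSE)
        .writeTsv(df, file.path(config$out_dir, fname))
        res
    }
    m_lnc <- counts[lnc_kept, ]
    ssea_cancer <- run_contrast(m_lnc, sampleSet("tumor", tumor_ids),
                                seed0 + 1L, "ssea_cancer.tsv")
    stage_out("ssea_cancer", seed0 + 1L,
              file.path(config$out_dir, "ssea_cancer.tsv"))

    er_ids <- ann$sample_id[ann$cohort == "tumor" &
                            !is.na(ann$er_status) &
                            ann$er_status == "positive"]
    er_tested <- ann$sample_id[ann$cohort == "tumor" & !is.na(ann$er_status)]
    ssea_er <- run_contrast(m_lnc[, er_tested],
                            sampleSet("er_positive", er_ids),
                            seed0 + 2L, "ssea_er.tsv")
    stage_out("ssea_er", seed0 + 2L, file.path(config$out_dir, "ssea_er.tsv"))

    ## ---- stage 4: clustering and cluster labels ------------------------
    de_cancer <- rownames(ssea_cancer)[ssea_cancer$significant]
    clusters <- NULL
    labels <- character(0)
    if (length(de_cancer) >= 3L) {
        norm_m <- log2FoldOverReference(fpkm[de_cancer, ], normal_ids)
        tr_clust <- hierarchicalCluster(norm_m, "transcripts")
        sm_clust <- hierarchicalCluster(norm_m, "samples")
        k3 <- tr_clust$cut(3)
        labels <- labelLncrnaClusters(norm_m, k3, ann)
        clusters <- data.frame(transcript_id = names(k3), cluster = k3,
                               label = labels[as.character(k3)],
                               stringsAsFactors = FALSE)
        f4 <- c(.writeTsv(clusters,
                          file.path(config$out_dir, "lncrna_clusters.tsv")),
                .writeTsv(data.frame(sample_id = names(sm_clust$cut(3)),
                                     cluster = sm_clust$cut(3)),
                          file.path(config$out_dir, "sample_clusters.tsv")))
    } else {
        f4 <- .writeTsv(data.frame(transcript_id = character(0),
                                   cluster = integer(0)),
                        file.path(config$out_dir, "lncrna_clusters.tsv"))
    }
    stage_out("clustering", seed0, f4)

    ## ---- stage 5: intersection -----------------------------------------
    up_cancer <- rownames(ssea_cancer)[ssea_cancer$significant &
                                       ssea_cancer$direction == "+"]
    up_er <- rownames(ssea_er)[ssea_er$significant & ssea_er$direction == "+"]
    inter <- intersectDeSets(up_cancer, up_er)
    f5 <- c(.writeTsv(data.frame(transcript_id = inter$intersection),
                      file.path(config$out_dir, "intersection.tsv")),
            .writeTsv(data.frame(set = names(inter$venn),
                                 count = as.integer(inter$venn)),
                      file.path(config$out_dir, "venn_counts.tsv")))
    stage_out("intersection", seed0, f5)

    ## ---- stage 6: binding / induction / prioritization ------------------
    flags <- bindingFlags(models, peaks)
    candidates <- prioritizeCandidates(inter$intersection, fpkm,
                                       binding = flags,
                                       induction = induction,
                                       n_top = config$n_top)
    f6 <- .writeTsv(candidates, file.path(config$out_dir, "candidates.tsv"))
    stage_out("prioritization", seed0, f6)

    ## ---- stage 7: concept association network --------------------------
    coding <- rownames(counts)[transcriptBiotype(counts) == "protein_coding"]
    ranked <- spearmanCorrelations(fpkm, config$target_id,
                                   sample_ids = er_ids)
    sigs <- topSignatures(ranked, n = config$sig_n,
                          name_prefix = config$target_id)
    universe <- coding
    assoc <- do.call(rbind, c(
        lapply(names(concepts), function(nm) {
            fisherOverlap(sigs$positive,
                          geneSignature(nm, intersect(concepts[[nm]], universe)),
                          universe)
        }),
        lapply(names(concepts), function(nm) {
            fisherOverlap(sigs$negative,
                          geneSignature(nm, intersect(concepts[[nm]], universe)),
                          universe)
        })))
    thr <- networkPreset(config$network_preset)
    net <- conceptNetwork(assoc, thr$or_threshold_pos, thr$or_threshold_neg,
                          thr$p_threshold)
    f7 <- c(.writeTsv(assoc, file.path(config$out_dir, "associations.tsv")),
            writeNetwork(net, config$out_dir))
    stage_out("association", seed0, f7)

    ## ---- stage 8: survival ----------------------------------------------
    target_fpkm <- exprValues(fpkm)[config$target_id, ]
    sv <- survivalByExpression(surv, target_fpkm,
                               high_cut = config$high_cut,
                               low_cut = config$low_cut)
    f8 <- .writeTsv(data.frame(chi_square = sv$test$chi_square,
                               p = sv$test$p,
                               n_high = sum(sv$group == "high"),
                               n_low = sum(sv$group == "low")),
                    file.path(config$out_dir, "survival_test.tsv"))
    stage_out("survival", seed0, f8)

    manifest_path <- file.path(config$out_dir, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    invisible(list(dir = config$out_dir, filtered = kept,
                   ssea_cancer = ssea_cancer, ssea_er = ssea_er,
                   clusters = clusters, cluster_labels = labels,
                   intersection = inter, candidates = candidates,
                   associations = assoc, network = net, survival = sv,
                   manifest = manifest_path))
}

#' Summarize a completed run as a markdown report
#'
#' @param run_dir directory written by [runLandscape()].
#' @return path of the written `report.md`, invisibly.
#' @export
writeReport <- function(run_dir) {
    manifest_path <- file.path(run_dir, "manifest.json")
    if (!file.exists(manifest_path))
        stop("incomplete run: no manifest in ", run_dir)
    manifest <- jsonlite::read_json(manifest_path)
    if (length(manifest$stages) < 8L)
        stop("incomplete run: expected 8 stages, found ",
             length(manifest$stages))
    rd <- function(f) utils::read.delim(file.path(run_dir, f),
                                        stringsAsFactors = FALSE)
    cancer <- rd("ssea_cancer.tsv"); er <- rd("ssea_er.tsv")
    venn <- rd("venn_counts.tsv"); cand <- rd("candidates.tsv")
    edges <- rd("network_edges.tsv"); svt <- rd("survival_test.tsv")
    lines <- c(
        "# lncRNA landscape run report", "",
        sprintf("- Differentially expressed (tumor vs normal): %d of %d tested",
                sum(cancer$significant), nrow(cancer)),
        sprintf("- Differentially expressed (ER+ vs ER-): %d of %d tested",
                sum(er$significant), nrow(er)),
        sprintf("- Upregulated intersection: %d (A only %d, B only %d)",
                venn$count[venn$set == "both"],
                venn$count[venn$set == "a_only"],
                venn$count[venn$set == "b_only"]),
        sprintf("- Concept network edges: %d", nrow(edges)),
        sprintf("- Survival log-rank: chi2 = %.3f, p = %.3g (high n=%d, low n=%d)",
                svt$chi_square, svt$p, svt$n_high, svt$n_low),
        "", "## Top candidates", "")
    if (nrow(cand) > 0) {
        lines <- c(lines,
                   paste(colnames(cand), collapse = " | "),
                   paste(rep("---", ncol(cand)), collapse = " | "),
                   apply(cand, 1, paste, collapse = " | "))
    } else {
        lines <- c(lines, "(empty intersection: no candidates)")
    }
    out <- file.path(run_dir, "report.md")
    writeLines(lines, out)
    invisible(out)
}

#' Write a complete demo cohort to disk and return its run config
#'
#' Simulates a cohort, derives the target's correlation signature, plants a
#' concept library against it, simulates ChIP peaks, the induction experiment
#' and survival outcomes, writes every input file the pipeline reads, and
#' returns the matching [landscapeConfig()] (plus the generator truth).
#'
#' @param dir directory for the input files.
#' @param config a [cohortConfig()].
#' @param out_dir run output directory (default `file.path(dir, "run")`).
#' @param n_permutations SSEA permutations for the run config.
#' @param sig_n,concept_size correlation-signature and concept sizes, scaled
#'   to the demo universe (a few hundred coding genes rather than ~20,000).
#' @param fdr_cutoff DE cutoff for the run config. The pooled-null FDR floor
#'   is roughly `1 / (transcripts x permutations)`, so a 1e-5 cutoff is only
#'   resolvable at transcriptome scale; in addition, transcripts with on/off
#'   expression (bright in one sample block, silent elsewhere) have their NES
#'   capped near the ratio of value-share to count-share of the bright block,
#'   which pools unfavourably against smooth expression patterns. 0.1 is the
#'   working cutoff matched to the bundled cohort's resolution.
#' @return list with `config` (a `RunConfig`), `sim` (the generator output)
#'   and `truth`.
#' @export
demoCohortFiles <- function(dir, config = cohortConfig(),
                            out_dir = file.path(dir, "run"),
                            n_permutations = 1000, sig_n = 50,
                            concept_size = 50, fdr_cutoff = 0.1) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    sim <- simulateCohort(config)
    seed <- config$seed
    fpkm <- countsToFpkm(sim$counts)
    ann <- sim$annotations
    er_ids <- ann$sample_id[ann$cohort == "tumor" &
                            !is.na(ann$er_status) &
                            ann$er_status == "positive"]
    target <- sim$truth$best_candidate
    ranked <- spearmanCorrelations(fpkm, target, sample_ids = er_ids)
    sig_n <- min(sig_n, floor(nrow(ranked) / 2))
    sigs <- topSignatures(ranked, n = sig_n)
    coding <- rownames(sim$counts)[transcriptBiotype(sim$counts) ==
                                   "protein_coding"]
    ## overlap fractions strong enough to clear the OR/p presets at this
    ## universe size (a few hundred genes vs the plan's native ~20,000)
    plan <- stats::setNames(
        pmin(round(concept_size * seq(0.5, 0.3,
                                      length.out = length(sim$truth$concept_overlap_plan))),
             min(concept_size, sig_n)),
        names(sim$truth$concept_overlap_plan))
    concepts <- simulateConceptLibrary(plan, coding, sigs$positive$genes,
                                       concept_size = concept_size,
                                       seed = seed + 10L)
    peaks <- simulateChipPeaks(sim$models, sim$truth, seed = seed + 11L)
    induction <- simulateInduction(sim$truth, noise_sd = 0,
                                   seed = seed + 12L)
    target_fpkm <- exprValues(fpkm)[target, ]
    surv <- simulateSurvival(target_fpkm, truth = sim$truth,
                             seed = seed + 13L)

    p <- function(f) file.path(dir, f)
    writeExpressionMatrix(sim$counts, p("counts.tsv"))
    .writeTsv(sim$models, p("models.tsv"))
    .writeTsv(sim$annotations, p("annotations.tsv"))
    writePeaks(peaks, p("peaks_mcf7.bed"))
    writeGmt(concepts, p("concepts.gmt"))
    .writeTsv(induction, p("induction.tsv"))
    writeSurvival(surv[, c("sample_id", "time", "event")], p("survival.tsv"))

    cfg <- landscapeConfig(
        counts_path = p("counts.tsv"), models_path = p("models.tsv"),
        annotations_path = p("annotations.tsv"),
        peaks_paths = c(MCF7 = p("peaks_mcf7.bed")),
        gmt_path = p("concepts.gmt"), induction_path = p("induction.tsv"),
        survival_path = p("survival.tsv"), target_id = target,
        out_dir = out_dir, n_permutations = n_permutations, seed = seed,
        sig_n = sig_n, fdr_cutoff = fdr_cutoff)
    list(config = cfg, sim = sim, truth = sim$truth)
}
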