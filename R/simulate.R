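#' Configuration of a synthetic breast cohort
#'
#' Desk-scale statistical stand-in for a large tumor/normal RNA-seq cohort:
#' negative-binomial counts with log-normal baselines, log-uniform library
#' sizes, planted cancer-associated and ER-associated differential expression,
#' planted PAM50 subtype blocks, and planted regulatory/clinical truths
#' recorded alongside the data.
#'
#' @param n_tumor,n_normal sample counts per cohort arm.
#' @param er_pos_fraction fraction of tumors that are ER-positive.
#' @param subtype_proportions named proportions over PAM50 labels
#'   (must sum to 1 within 1e-9).
#' @param n_transcripts total transcripts simulated.
#' @param lncrna_fraction fraction of transcripts with lncRNA biotype.
#' @param n_de_cancer planted tumor-vs-normal DE transcripts (includes the
#'   overlap set).
#' @param n_de_er planted ER-positive-vs-negative DE transcripts (includes the
#'   overlap set).
#' @param n_de_overlap transcripts planted upregulated in both contrasts
#'   (the "Luminal" pattern: fold applied in ER-positive tumors only).
#' @param n_subtype_markers protein-coding marker transcripts elevated per
#'   PAM50 subtype (drives sample clustering).
#' @param n_bound lncRNA promoters receiving planted regulator ChIP peaks.
#' @param fold_change planted fold change (> 0).
#' @param nb_dispersion negative-binomial dispersion (>= 0; 0 = Poisson).
#' @param library_size_range (min, max) total fragments, sampled log-uniform.
#' @param transcript_length_range (min, max) transcript length in bp.
#' @param low_expr_fraction fraction of unplanted lncRNAs set near zero
#'   (exercises the expression filter).
#' @param de_down_fraction fraction of the non-overlap planted DE transcripts
#'   planted downregulated (fold 1/fold_change) rather than up (default 0.5;
#'   0 plants every DE transcript upregulated).
#' @param survival_hr hazard ratio planted between expression groups.
#' @param seed integer seed; identical config + seed gives bit-identical data.
#' @return validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_tumor = 120, n_normal = 80,
                         er_pos_fraction = 0.75,
                         subtype_proportions = c(LumA = 0.40, LumB = 0.20,
                                                 Her2 = 0.10, Basal = 0.20,
                                                 Normal = 0.10),
                         n_transcripts = 1000, lncrna_fraction = 0.5,
                         n_de_cancer = 100, n_de_er = 100, n_de_overlap = 30,
                         n_subtype_markers = 25, n_bound = 20,
                         fold_change = 4, nb_dispersion = 0.2,
                         library_size_range = c(5e5, 2e6),
                         transcript_length_range = c(200, 10000),
                         low_expr_fraction = 0.2, de_down_fraction = 0.5,
                         survival_hr = 3, seed = 1L) {
    cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
                er_pos_fraction = er_pos_fraction,
                subtype_proportions = subtype_proportions,
                n_transcripts = as.integer(n_transcripts),
                lncrna_fraction = lncrna_fraction,
                n_de_cancer = as.integer(n_de_cancer),
                n_de_er = as.integer(n_de_er),
                n_de_overlap = as.integer(n_de_overlap),
                n_subtype_markers = as.integer(n_subtype_markers),
                n_bound = as.integer(n_bound),
                fold_change = fold_change, nb_dispersion = nb_dispersion,
                library_size_range = library_size_range,
                transcript_length_range = transcript_length_range,
                low_expr_fraction = low_expr_fraction,
                de_down_fraction = de_down_fraction,
                survival_hr = survival_hr, seed = as.integer(seed))
    if (cfg$n_tumor + cfg$n_normal <= 0L || cfg$n_transcripts <= 0L)
        stop("cohort must have > 0 samples and > 0 transcripts")
    if (abs(sum(cfg$subtype_proportions) - 1) > 1e-9)
        stop("subtype_proportions must sum to 1")
    if (cfg$fold_change <= 0) stop("fold_change must be > 0")
    if (cfg$nb_dispersion < 0) stop("nb_dispersion must be >= 0")
    if (cfg$n_de_cancer > cfg$n_transcripts ||
        cfg$n_de_er > cfg$n_transcripts)
        stop("n_de_* must be <= n_transcripts")
    if (cfg$n_de_overlap > min(cfg$n_de_cancer, cfg$n_de_er))
        stop("n_de_overlap must be <= both n_de_cancer and n_de_er")
    for (rng in list(cfg$library_size_range, cfg$transcript_length_range))
        if (length(rng) != 2L || rng[1] > rng[2] || rng[1] <= 0)
            stop("ranges must be (min, max) with 0 < min <= max")
    if (cfg$er_pos_fraction < 0 || cfg$er_pos_fraction > 1 ||
        cfg$lncrna_fraction < 0 || cfg$lncrna_fraction > 1 ||
        cfg$de_down_fraction < 0 || cfg$de_down_fraction > 1)
        stop("fractions must be in [0, 1]")
    if (cfg$survival_hr <= 0) stop("survival_hr must be > 0")
    class(cfg) <- "CohortConfig"
    cfg
}

.largestRemainder <- function(props, n) {
    raw <- props * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
    }
    stats::setNames(as.integer(base), names(props))
}

#' Simulate a tumor/normal expression cohort with planted truth
#'
#' Counts are drawn `NB(mean = baseline_g * fold(g, s) * libsize_s /
#' median(libsize), dispersion)`. Planted fold multipliers: tumor-up/-down
#' transcripts in all tumors; the overlap ("Luminal") set in ER-positive
#' tumors only; additional ER-up transcripts in ER-positive tumors and
#' normals; ER-down ("basal") transcripts in ER-negative tumors; subtype
#' marker blocks in their subtype's samples.
#'
#' @param config a [cohortConfig()].
#' @return list with `counts` (a [LandscapeExperiment-class] carrying lengths,
#'   biotypes and sample annotations), `models` (transcript table with
#'   chrom/tss/strand/length), `annotations` (sample table) and `truth`
#'   (planted ground truth: DE id sets with direction, lncRNA pattern labels,
#'   bound promoter ids, induction folds, concept overlap plan, survival
#'   hazard ratio, designated best candidate).
#' @export
simulateCohort <- function(config) {
    stopifnot(inherits(config, "CohortConfig"))
    cfg <- config
    withr::with_seed(cfg$seed, {
        n_s <- cfg$n_tumor + cfg$n_normal
        sample_id <- sprintf("S%04d", seq_len(n_s))
        cohort <- rep(c("tumor", "normal"), c(cfg$n_tumor, cfg$n_normal))

        ## PAM50 subtypes for tumors, ER status filled luminal-first
        counts_by <- .largestRemainder(cfg$subtype_proportions, cfg$n_tumor)
        pam50_t <- sample(rep(names(counts_by), counts_by))
        n_er <- round(cfg$er_pos_fraction * cfg$n_tumor)
        er_order <- order(match(pam50_t,
                                c("LumA", "LumB", "Normal", "Her2", "Basal")))
        er_t <- rep("negative", cfg$n_tumor)
        er_t[er_order[seq_len(n_er)]] <- "positive"
        annotations <- data.frame(
            sample_id = sample_id, cohort = cohort,
            er_status = c(er_t, rep(NA_character_, cfg$n_normal)),
            pr_status = c(ifelse(er_t == "positive" &
                                 stats::runif(cfg$n_tumor) < 0.85,
                                 "positive", "negative"),
                          rep(NA_character_, cfg$n_normal)),
            her2_status = c(ifelse(pam50_t == "Her2", "positive", "negative"),
                            rep(NA_character_, cfg$n_normal)),
            pam50 = c(pam50_t, rep(NA_character_, cfg$n_normal)),
            stringsAsFactors = FALSE)

        ## transcripts
        G <- cfg$n_transcripts
        tid <- sprintf("T%05d", seq_len(G))
        n_lnc <- round(cfg$lncrna_fraction * G)
        biotype <- rep("protein_coding", G)
        biotype[sample.int(G, n_lnc)] <- "lncRNA"
        lnc <- tid[biotype == "lncRNA"]
        cod <- tid[biotype == "protein_coding"]
        len <- sample(seq(cfg$transcript_length_range[1],
                          cfg$transcript_length_range[2]), G, replace = TRUE)
        names(len) <- tid
        baseline <- stats::setNames(
            stats::rlnorm(G, meanlog = log(200), sdlog = 1.2), tid)

        ## planted id sets (all lncRNA; overlap counted in both contrasts)
        n_cancer_only <- cfg$n_de_cancer - cfg$n_de_overlap
        n_er_only <- cfg$n_de_er - cfg$n_de_overlap
        need <- cfg$n_de_overlap + n_cancer_only + n_er_only
        if (need > length(lnc))
            stop("not enough lncRNA transcripts for the planted DE sets")
        pool <- sample(lnc, need)
        overlap_ids <- utils::head(pool, cfg$n_de_overlap)
        rest <- utils::tail(pool, length(pool) - cfg$n_de_overlap)
        cancer_ids <- rest[seq_len(n_cancer_only)]
        er_ids <- rest[n_cancer_only + seq_len(n_er_only)]
        n_c_up <- round((1 - cfg$de_down_fraction) * n_cancer_only)
        cancer_up <- utils::head(cancer_ids, n_c_up)
        cancer_down <- setdiff(cancer_ids, cancer_up)
        n_e_up <- round((1 - cfg$de_down_fraction) * n_er_only)
        er_up <- utils::head(er_ids, n_e_up)
        er_down <- setdiff(er_ids, er_up)

        ## subtype marker blocks (protein coding)
        subtypes <- names(counts_by)[counts_by > 0]
        markers <- list()
        cod_pool <- sample(cod)
        needed <- cfg$n_subtype_markers * length(subtypes)
        if (needed > length(cod_pool))
            stop("not enough protein-coding transcripts for subtype markers")
        for (i in seq_along(subtypes)) {
            markers[[subtypes[i]]] <-
                cod_pool[(i - 1) * cfg$n_subtype_markers +
                         seq_len(cfg$n_subtype_markers)]
        }

        ## keep planted DE transcripts off the extreme baseline tail so the
        ## designated best candidate can dominate without distorting library
        ## composition
        baseline[pool] <- pmin(baseline[pool],
                               stats::quantile(baseline, 0.9))

        ## designated best candidate: ER-driven on/off pattern - short
        ## transcript, near-zero outside ER-positive tumors, brightest inside
        best <- if (length(overlap_ids) > 0) overlap_ids[1] else NA_character_
        if (!is.na(best)) {
            baseline[best] <- 0.05
            len[best] <- cfg$transcript_length_range[1]
        }

        ## near-zero baselines for a fraction of unplanted lncRNAs
        unplanted_lnc <- setdiff(lnc, pool)
        n_low <- round(cfg$low_expr_fraction * length(unplanted_lnc))
        if (n_low > 0) {
            low_ids <- sample(unplanted_lnc, n_low)
            baseline[low_ids] <- baseline[low_ids] * 0.002
        }

        ## fold-multiplier matrix
        fold <- matrix(1, G, n_s, dimnames = list(tid, sample_id))
        tumor <- cohort == "tumor"
        er_pos <- tumor & c(er_t, rep("", cfg$n_normal)) == "positive"
        er_neg <- tumor & c(er_t, rep("", cfg$n_normal)) == "negative"
        normal <- !tumor
        fc <- cfg$fold_change
        fold[cancer_up, tumor] <- fc
        fold[cancer_down, tumor] <- 1 / fc
        fold[overlap_ids, er_pos] <- fc
        fold[er_up, er_pos] <- fc
        fold[er_up, normal] <- fc
        fold[er_down, er_neg] <- fc
        pam_full <- c(pam50_t, rep(NA_character_, cfg$n_normal))
        for (st in subtypes)
            fold[markers[[st]], tumor & pam_full %in% st] <- fc
        ## best candidate outranks every other planted transcript on the
        ## 95th-percentile FPKM metric (3x margin over the brightest rival)
        if (!is.na(best) && any(er_pos)) {
            rivals <- setdiff(c(overlap_ids, cancer_up, er_up), best)
            rival_fpkm <- if (length(rivals) > 0)
                max(baseline[rivals] * fc / (len[rivals] / 1000)) else 1000
            fold[best, er_pos] <- 3 * rival_fpkm * (len[best] / 1000) /
                baseline[best]
        }

        ## library sizes (log-uniform) and NB sampling
        lib <- exp(stats::runif(n_s, log(cfg$library_size_range[1]),
                                log(cfg$library_size_range[2])))
        mu <- sweep(baseline * fold, 2, lib / stats::median(lib), "*")
        counts <- if (cfg$nb_dispersion > 0) {
            matrix(stats::rnbinom(G * n_s, mu = mu,
                                  size = 1 / cfg$nb_dispersion), G, n_s)
        } else {
            matrix(stats::rpois(G * n_s, lambda = mu), G, n_s)
        }
        dimnames(counts) <- list(tid, sample_id)

        ## transcript models on a synthetic genome: TSS every 250 kb
        chrom <- paste0("chr", ((seq_len(G) - 1L) %% 4L) + 1L)
        idx_on_chrom <- stats::ave(seq_len(G), chrom, FUN = seq_along)
        tss <- 50000L + (idx_on_chrom - 1L) * 250000L
        strand <- rep(c("+", "-"), length.out = G)
        models <- data.frame(
            transcript_id = tid, chrom = chrom, tss = tss, strand = strand,
            start = ifelse(strand == "+", tss, pmax(tss - len, 0)),
            end = ifelse(strand == "+", tss + len, tss),
            length_bp = as.integer(len), biotype = biotype,
            stringsAsFactors = FALSE)

        ## planted regulatory truths
        bound <- character(0)
        if (cfg$n_bound > 0) {
            cand <- unique(c(best[!is.na(best)], overlap_ids, cancer_up, lnc))
            bound <- cand[seq_len(min(cfg$n_bound, length(cand)))]
        }
        induced <- stats::setNames(numeric(0), character(0))
        if (length(overlap_ids) > 0) {
            folds <- rep(c(1.0, 2.0, 1.2), length.out = length(overlap_ids))
            induced <- stats::setNames(folds, overlap_ids)
            induced[best] <- 3.0
        }
        truth <- list(
            de_cancer = data.frame(
                transcript_id = c(cancer_up, overlap_ids, cancer_down),
                direction = rep(c("+", "-"),
                                c(length(cancer_up) + length(overlap_ids),
                                  length(cancer_down))),
                stringsAsFactors = FALSE),
            de_er = data.frame(
                transcript_id = c(er_up, overlap_ids, er_down),
                direction = rep(c("+", "-"),
                                c(length(er_up) + length(overlap_ids),
                                  length(er_down))),
                stringsAsFactors = FALSE),
            lncrna_patterns = c(
                stats::setNames(rep("Luminal", length(overlap_ids)),
                                overlap_ids),
                stats::setNames(rep("Upregulated", length(cancer_up)),
                                cancer_up),
                stats::setNames(rep("Downregulated", length(cancer_down)),
                                cancer_down)),
            subtype_markers = markers,
            bound_promoter_ids = bound,
            induced_ids = induced,
            concept_overlap_plan = c(concept_planted_1 = 40,
                                     concept_planted_2 = 35,
                                     concept_planted_3 = 30,
                                     concept_planted_4 = 25,
                                     concept_planted_5 = 20),
            survival_hr = cfg$survival_hr,
            best_candidate = best)

        le <- LandscapeExperiment(counts, unit = "counts", lengths = len,
                                  biotype = biotype,
                                  annotations = annotations)
        list(counts = le, models = models, annotations = annotations,
             truth = truth)
    })
}

#' Simulate a concept library with planted overlaps
#'
#' Builds concept gene sets from a universe so that each planned concept
#' shares exactly the planted number of genes with a designated target gene
#' set; remaining members (and whole background concepts) are drawn uniformly
#' without replacement.
#'
#' @param truth truth list carrying `concept_overlap_plan`
#'   (named concept -> overlap count), or such a named vector directly.
#' @param universe character vector of all gene ids.
#' @param target_genes the designated correlated gene set the overlaps are
#'   planted against (must be a subset of `universe`).
#' @param concept_size size of every concept (default 150).
#' @param n_background extra concepts with no planted overlap (default 15).
#' @param seed integer seed.
#' @return named list of gene-id vectors (a GMT-style library).
#' @export
simulateConceptLibrary <- function(truth, universe, target_genes,
                                   concept_size = 150, n_background = 15,
                                   seed = 1L) {
    plan <- if (is.list(truth)) truth$concept_overlap_plan else truth
    universe <- unique(as.character(universe))
    target_genes <- unique(as.character(target_genes))
    if (!all(target_genes %in% universe))
        stop("target_genes must be a subset of the universe")
    off_target <- setdiff(universe, target_genes)
    withr::with_seed(seed, {
        sets <- list()
        for (nm in names(plan)) {
            a <- plan[[nm]]
            if (a > concept_size || a > length(target_genes) ||
                concept_size - a > length(off_target))
                stop("infeasible planted overlap for concept ", nm)
            sets[[nm]] <- c(if (a > 0) sample(target_genes, a),
                            if (concept_size - a > 0)
                                sample(off_target, concept_size - a))
        }
        for (i in seq_len(n_background)) {
            sets[[sprintf("concept_background_%02d", i)]] <-
                sample(universe, min(concept_size, length(universe)))
        }
        sets
    })
}

#' Simulate regulator ChIP peaks over planted promoters
#'
#' Every transcript in `truth$bound_promoter_ids` receives one peak placed
#' wholly inside its promoter window; decoy peaks are placed at least 100 kb
#' from any TSS.
#'
#' @param models transcript-model table from [simulateCohort()].
#' @param truth truth list with `bound_promoter_ids` (or a character vector).
#' @param peak_width peak width in bp (> 0, must fit in the promoter window).
#' @param upstream_bp,downstream_bp promoter extent around the TSS.
#' @param n_decoys number of decoy peaks (default: as many as bound ids, at
#'   least 10).
#' @param seed integer seed.
#' @return `GRanges` of peaks, named `peak_*`, with a `decoy` metadata flag.
#' @export
simulateChipPeaks <- function(models, truth, peak_width = 400,
                              upstream_bp = 5000, downstream_bp = 5000,
                              n_decoys = NULL, seed = 1L) {
    bound <- if (is.list(truth)) truth$bound_promoter_ids else truth
    if (peak_width <= 0) stop("peak_width must be > 0")
    if (peak_width > upstream_bp + downstream_bp)
        stop("promoter window smaller than peak_width")
    models <- as.data.frame(models)
    if (is.null(n_decoys)) n_decoys <- max(10L, length(bound))
    withr::with_seed(seed, {
        rows <- models[match(bound, models$transcript_id), , drop = FALSE]
        if (anyNA(rows$transcript_id))
            stop("bound ids missing from models")
        ## promoter window [tss - u, tss + d) strand-adjusted, 0-based
        plus <- rows$strand == "+"
        w_start <- ifelse(plus, rows$tss - upstream_bp,
                          rows$tss - downstream_bp)
        w_end <- ifelse(plus, rows$tss + downstream_bp,
                        rows$tss + upstream_bp)
        w_start <- pmax(w_start, 0)
        if (any(w_end - w_start < peak_width))
            stop("promoter window smaller than peak_width")
        p_start <- w_start + floor(stats::runif(nrow(rows)) *
                                   (w_end - w_start - peak_width + 1))
        peak_chrom <- rows$chrom
        ## decoys: midpoints between consecutive TSS on a chromosome,
        ## >= 100 kb from every TSS by construction of the 250 kb spacing
        mids <- unlist(lapply(split(models$tss, models$chrom), function(tt) {
            tt <- sort(unique(tt))
            if (length(tt) < 2) return(numeric(0))
            (utils::head(tt, -1) + utils::tail(tt, -1)) / 2
        }), use.names = FALSE)
        mid_chrom <- rep(names(split(models$tss, models$chrom)),
                         vapply(split(models$tss, models$chrom), function(tt)
                             max(0L, length(unique(tt)) - 1L), 0L))
        keep <- vapply(seq_along(mids), function(i) {
            tt <- models$tss[models$chrom == mid_chrom[i]]
            min(abs(tt - mids[i])) >= 1e5
        }, TRUE)
        mids <- mids[keep]; mid_chrom <- mid_chrom[keep]
        n_decoys <- min(n_decoys, length(mids))
        di <- if (n_decoys > 0) sample(length(mids), n_decoys) else integer(0)
        d_start <- floor(mids[di] - peak_width / 2)
        chroms <- c(peak_chrom, mid_chrom[di])
        starts0 <- c(p_start, d_start)
        n_all <- length(starts0)
        if (n_all == 0L)
            return(GenomicRanges::GRanges())
        gr <- GenomicRanges::GRanges(
            chroms, IRanges::IRanges(starts0 + 1, width = peak_width))
        names(gr) <- sprintf("peak_%04d", seq_len(n_all))
        S4Vectors::mcols(gr)$decoy <- rep(c(FALSE, TRUE),
                                          c(nrow(rows), length(di)))
        gr
    })
}

#' Simulate an estrogen-stimulation induction experiment
#'
#' Vehicle / estrogen / estrogen+tamoxifen expression per transcript: the
#' estrogen-to-vehicle ratio is centred on the planted induction fold and the
#' tamoxifen arm reverts most of the way toward vehicle.
#'
#' @param truth truth list with `induced_ids` (named id -> fold), or such a
#'   named numeric vector.
#' @param noise_sd lognormal noise sd (>= 0; 0 gives exact ratios).
#' @param ids transcripts to report; defaults to the induced ids. Ids without
#'   a planted fold get fold 1.
#' @param baseline vehicle expression level.
#' @param seed integer seed.
#' @return data.frame with `transcript_id`, `vehicle`, `estrogen`,
#'   `estrogen_tamoxifen` and the realized `fold_change`.
#' @export
simulateInduction <- function(truth, noise_sd = 0, ids = NULL, baseline = 10,
                              seed = 1L) {
    induced <- if (is.list(truth)) truth$induced_ids else truth
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (is.null(ids)) ids <- names(induced)
    fold <- ifelse(ids %in% names(induced), induced[ids], 1.0)
    withr::with_seed(seed, {
        n <- length(ids)
        noise <- function() exp(stats::rnorm(n, 0, noise_sd))
        vehicle <- rep(baseline, n)
        estrogen <- baseline * fold * noise()
        tam <- baseline * (1 + 0.25 * (fold - 1)) * noise()
        data.frame(transcript_id = ids, vehicle = vehicle,
                   estrogen = estrogen, estrogen_tamoxifen = tam,
                   fold_change = estrogen / vehicle,
                   stringsAsFactors = FALSE)
    })
}

#' Simulate survival outcomes with a planted hazard ratio
#'
#' Exponential event times with the baseline hazard multiplied by the planted
#' hazard ratio in the high-expression group; independent uniform censoring
#' over `(0, max_follow_up)`.
#'
#' @param expression named numeric vector of target expression (FPKM) per
#'   sample.
#' @param hr planted hazard ratio (> 0); defaults to `truth$survival_hr`.
#' @param truth optional truth list supplying `survival_hr`.
#' @param base_hazard baseline exponential hazard.
#' @param max_follow_up censoring horizon.
#' @param high_cut,low_cut FPKM grouping thresholds.
#' @param seed integer seed.
#' @return data.frame with `sample_id`, `time`, `event` and the expression
#'   `group`.
#' @export
simulateSurvival <- function(expression, hr = NULL, truth = NULL,
                             base_hazard = 0.1, max_follow_up = 10,
                             high_cut = 10, low_cut = 1, seed = 1L) {
    if (is.null(hr)) hr <- if (!is.null(truth)) truth$survival_hr else 1
    if (hr <= 0) stop("survival_hr must be > 0")
    grp <- groupByExpression(expression, high_cut, low_cut)
    withr::with_seed(seed, {
        n <- length(expression)
        hazard <- base_hazard * ifelse(grp == "high", hr, 1)
        t_event <- stats::rexp(n, rate = hazard)
        t_cens <- stats::runif(n, 0, max_follow_up)
        data.frame(sample_id = names(expression),
                   time = pmin(t_event, t_cens),
                   event = as.integer(t_event <= t_cens),
                   group = as.character(grp),
                   stringsAsFactors = FALSE)
    })
}
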