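small_cfg <- function(seed = 42L, ...) {
    cohortConfig(n_tumor = 30, n_normal = 20, n_transcripts = 200,
                 n_de_cancer = 20, n_de_er = 20, n_de_overlap = 6,
                 n_subtype_markers = 5, n_bound = 8, seed = seed, ...)
}

test_that("identical config and seed give bit-identical cohorts", {
    a <- simulateCohort(small_cfg())
    b <- simulateCohort(small_cfg())
    expect_identical(exprValues(a$counts), exprValues(b$counts))
    expect_identical(a$models, b$models)
    expect_identical(a$annotations, b$annotations)
    expect_identical(a$truth, b$truth)
    c2 <- simulateCohort(small_cfg(seed = 43L))
    expect_false(identical(exprValues(a$counts), exprValues(c2$counts)))
})

test_that("config invariants are enforced", {
    expect_error(cohortConfig(subtype_proportions = c(LumA = 0.5, Basal = 0.4)),
                 "sum to 1")
    expect_error(cohortConfig(fold_change = 0), "fold_change")
    expect_error(cohortConfig(n_de_cancer = 2000), "n_transcripts")
    expect_error(cohortConfig(n_de_overlap = 200), "n_de_overlap")
    expect_error(cohortConfig(library_size_range = c(10, 5)), "min <= max")
    expect_error(cohortConfig(n_tumor = 0, n_normal = 0), "> 0 samples")
    expect_error(cohortConfig(nb_dispersion = -1), "nb_dispersion")
})

test_that("planted truth ids all exist and directions are signed", {
    sim <- simulateCohort(small_cfg())
    tid <- rownames(sim$counts)
    expect_true(all(sim$truth$de_cancer$transcript_id %in% tid))
    expect_true(all(sim$truth$de_er$transcript_id %in% tid))
    expect_true(all(sim$truth$de_cancer$direction %in% c("+", "-")))
    expect_true(all(sim$truth$bound_promoter_ids %in% tid))
    expect_true(all(names(sim$truth$induced_ids) %in% tid))
    # planted ids are lncRNAs; overlap ids counted in both DE sets
    bt <- transcriptBiotype(sim$counts)
    expect_true(all(bt[sim$truth$de_cancer$transcript_id] == "lncRNA"))
    both <- intersect(sim$truth$de_cancer$transcript_id,
                      sim$truth$de_er$transcript_id)
    expect_length(both, 6)
    expect_identical(sort(names(which(sim$truth$lncrna_patterns == "Luminal"))),
                     sort(both))
})

test_that("a null configuration has group-mean ratios near one", {
    cfg <- cohortConfig(n_tumor = 100, n_normal = 100, n_transcripts = 150,
                        n_de_cancer = 0, n_de_er = 0, n_de_overlap = 0,
                        n_subtype_markers = 0, fold_change = 1,
                        low_expr_fraction = 0, seed = 7L)
    sim <- simulateCohort(cfg)
    cpm <- exprValues(normalizeCounts(sim$counts))
    tumor <- sim$annotations$cohort == "tumor"
    ratio <- rowMeans(cpm[, tumor]) / rowMeans(cpm[, !tumor])
    expect_lt(abs(median(ratio) - 1), 0.1)
})

test_that("planted fold change is recovered in the group means", {
    cfg <- cohortConfig(n_tumor = 100, n_normal = 100, n_transcripts = 300,
                        n_de_cancer = 100, n_de_er = 0, n_de_overlap = 0,
                        n_subtype_markers = 0, fold_change = 4,
                        de_down_fraction = 0, low_expr_fraction = 0,
                        seed = 8L)
    sim <- simulateCohort(cfg)
    # the generator's stated mean structure holds on the raw counts
    raw <- exprValues(sim$counts)
    tumor <- sim$annotations$cohort == "tumor"
    planted <- sim$truth$de_cancer$transcript_id
    ratio <- rowMeans(raw[planted, tumor]) / rowMeans(raw[planted, !tumor])
    expect_lt(abs(median(ratio) / 4 - 1), 0.2)
    expect_gt(mean(abs(ratio / 4 - 1) < 0.35), 0.95)
})

test_that("concept library plants exact overlaps and validates feasibility", {
    universe <- sprintf("G%05d", 1:2000)
    target <- sample(universe, 150)
    plan <- c(none = 0, full = 50, mid = 30)
    sets <- simulateConceptLibrary(plan, universe, target, concept_size = 50,
                                   n_background = 2, seed = 5)
    expect_length(sets, 5)
    expect_length(intersect(sets$none, target), 0)
    expect_true(all(sets$full %in% target))
    expect_length(intersect(sets$mid, target), 30)
    expect_true(all(lengths(sets[c("none", "full", "mid")]) == 50))
    expect_error(simulateConceptLibrary(c(bad = 60), universe, target,
                                        concept_size = 50),
                 "infeasible")
    expect_identical(simulateConceptLibrary(plan, universe, target,
                                            concept_size = 50, seed = 5),
                     simulateConceptLibrary(plan, universe, target,
                                            concept_size = 50, seed = 5))
})

test_that("ChIP peaks land in bound promoters and decoys stay far away", {
    sim <- simulateCohort(small_cfg())
    bound <- sim$truth$bound_promoter_ids
    peaks <- simulateChipPeaks(sim$models, sim$truth, peak_width = 400,
                               seed = 3)
    flags <- bindingFlags(sim$models, list(cl = peaks))
    expect_setequal(flags$transcript_id[flags$cl], bound)
    # decoys are >= 100 kb from every TSS on their chromosome
    dec <- peaks[S4Vectors::mcols(peaks)$decoy]
    for (i in seq_along(dec)) {
        tt <- sim$models$tss[sim$models$chrom ==
                             as.character(GenomicRanges::seqnames(dec[i]))]
        mid <- (GenomicRanges::start(dec[i]) + GenomicRanges::end(dec[i])) / 2
        expect_gte(min(abs(tt - mid)), 1e5 - 400)
    }
    # empty bound set -> all peaks are decoys, no promoter flagged
    t0 <- sim$truth; t0$bound_promoter_ids <- character(0)
    p0 <- simulateChipPeaks(sim$models, t0, seed = 3)
    expect_true(all(S4Vectors::mcols(p0)$decoy))
    f0 <- bindingFlags(sim$models, list(cl = p0))
    expect_false(any(f0$cl))
    # every transcript bound -> every promoter flagged
    t1 <- sim$truth; t1$bound_promoter_ids <- sim$models$transcript_id
    f1 <- bindingFlags(sim$models,
                       list(cl = simulateChipPeaks(sim$models, t1, seed = 3)))
    expect_true(all(f1$cl))
    expect_error(simulateChipPeaks(sim$models, sim$truth, peak_width = 50000),
                 "smaller than peak_width")
})

test_that("induction table reproduces planted folds exactly without noise", {
    truth <- list(induced_ids = c(Ta = 3.0, Tb = 2.0, Tc = 1.0))
    tab <- simulateInduction(truth, noise_sd = 0, seed = 1)
    expect_equal(tab$fold_change, c(3, 2, 1))
    expect_equal(inductionCategory(tab$fold_change), c("high", "low", "none"))
    # tamoxifen arm reverts toward vehicle
    expect_true(all(tab$estrogen_tamoxifen[1:2] < tab$estrogen[1:2]))
    expect_error(simulateInduction(truth, noise_sd = -1), "noise_sd")
})

test_that("survival generator groups by expression and plants the hazard", {
    expr <- stats::setNames(c(rep(50, 120), rep(0.2, 120)),
                            sprintf("P%03d", 1:240))
    surv <- simulateSurvival(expr, hr = 3, base_hazard = 0.2,
                             max_follow_up = 15, seed = 4)
    expect_setequal(unique(surv$group), c("high", "low"))
    expect_true(all(surv$time > 0))
    expect_true(all(surv$event %in% 0:1))
    # higher hazard -> shorter observed times in the high group
    expect_lt(median(surv$time[surv$group == "high"]),
              median(surv$time[surv$group == "low"]))
    expect_identical(simulateSurvival(expr, hr = 3, seed = 4),
                     simulateSurvival(expr, hr = 3, seed = 4))
    expect_error(simulateSurvival(expr, hr = 0), "survival_hr")
})
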