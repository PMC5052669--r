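corr_matrix <- function(n_genes = 30, n_samples = 10, seed = 40) {
    set.seed(seed)
    v <- matrix(rexp(n_genes * n_samples, 0.1), n_genes, n_samples)
    rownames(v) <- c("target", sprintf("G%03d", seq_len(n_genes - 1)))
    colnames(v) <- sprintf("S%02d", seq_len(n_samples))
    v
}

test_that("Spearman correlations match the rank-then-Pearson oracle", {
    v <- corr_matrix()
    v["G001", ] <- v["target", ]                  # identical -> rho 1
    v["G002", ] <- max(v["target", ]) - v["target", ] # reversed -> rho -1
    le <- LandscapeExperiment(v, unit = "FPKM")
    ranked <- spearmanCorrelations(le, "target", coding_only = FALSE)
    expect_false("target" %in% ranked$gene_id)
    expect_equal(ranked$rho[ranked$gene_id == "G001"], 1)
    expect_equal(ranked$rho[ranked$gene_id == "G002"], -1)
    expect_true(all(diff(ranked$rho) <= 1e-12))
    for (g in sample(ranked$gene_id, 8))
        expect_equal(ranked$rho[ranked$gene_id == g],
                     spearman_oracle(v[g, ], v["target", ]),
                     tolerance = 1e-12)
    v["target", ] <- 1
    expect_error(spearmanCorrelations(LandscapeExperiment(v, unit = "FPKM"),
                                      "target", coding_only = FALSE),
                 "constant")
})

test_that("biotype filter restricts the correlation universe to coding genes", {
    v <- corr_matrix(10)
    bt <- c(target = "lncRNA",
            stats::setNames(rep(c("protein_coding", "lncRNA"), c(5, 4)),
                            rownames(v)[-1]))
    le <- LandscapeExperiment(v, unit = "FPKM", biotype = bt)
    ranked <- spearmanCorrelations(le, "target")
    expect_equal(nrow(ranked), 5)
    expect_true(all(bt[ranked$gene_id] == "protein_coding"))
})

test_that("negating the target swaps positive and negative signatures", {
    v <- corr_matrix(40, n_samples = 25, seed = 46) # fine rho granularity
    le <- LandscapeExperiment(v, unit = "FPKM")
    r1 <- spearmanCorrelations(le, "target", coding_only = FALSE)
    v2 <- v
    v2["target", ] <- max(v["target", ]) - v["target", ]
    r2 <- spearmanCorrelations(LandscapeExperiment(v2, unit = "FPKM"),
                               "target", coding_only = FALSE)
    s1 <- topSignatures(r1, n = 10)
    s2 <- topSignatures(r2, n = 10)
    expect_setequal(s1$positive$genes, s2$negative$genes)
    expect_setequal(s1$negative$genes, s2$positive$genes)
})

test_that("top signatures are the exact order statistics", {
    ranked <- data.frame(gene_id = sprintf("G%02d", 1:10),
                         rho = seq(0.9, -0.9, length.out = 10))
    s <- topSignatures(ranked, n = 1)
    expect_identical(s$positive$genes, "G01")
    expect_identical(s$negative$genes, "G10")
    s3 <- topSignatures(ranked, n = 3)
    expect_identical(s3$positive$genes, sprintf("G%02d", 1:3))
    expect_identical(s3$negative$genes, sprintf("G%02d", 8:10))
    expect_identical(s3$positive$direction, "up")
    expect_error(topSignatures(ranked, n = 6), ">= 12")
})

test_that("Fisher overlap p equals exhaustive hypergeometric enumeration", {
    # small worked instance: |sig| = 5, |concept| = 5, a = 3, N = 20
    universe <- letters[1:20]
    sig <- letters[1:5]
    concept <- c(letters[1:3], letters[10:11])
    out <- fisherOverlap(sig, concept, universe)
    expect_equal(out$a, 3)
    expect_equal(out$p_one_sided, hyper_tail_oracle(3, 5, 5, 20),
                 tolerance = 1e-12)
    set.seed(41)
    for (i in 1:50) {
        N <- sample(8:30, 1)
        uni <- sprintf("u%02d", seq_len(N))
        s <- sample(uni, sample(2:(N - 2), 1))
        k <- sample(uni, sample(2:(N - 2), 1))
        res <- fisherOverlap(s, k, uni)
        expect_equal(res$p_one_sided,
                     hyper_tail_oracle(res$a, length(s), length(k), N),
                     tolerance = 1e-10)
        # independent cross-check against the exact conditional test
        ft <- stats::fisher.test(matrix(c(res$a, res$b, res$c, res$d), 2),
                                 alternative = "greater")
        expect_equal(res$p_one_sided, ft$p.value, tolerance = 1e-10)
    }
})

test_that("odds-ratio zero cells are corrected and flagged", {
    uni <- sprintf("u%02d", 1:20)
    out <- fisherOverlap(uni[1:5], uni[6:10], uni)   # a = 0
    expect_true(out$or_corrected)
    expect_equal(out$odds_ratio, (0.5 * 10.5) / (5.5 * 5.5))
    expect_gt(out$p_one_sided, 0.5)
    # sig subset of concept = universe: no enrichment possible, p = 1
    out2 <- fisherOverlap(uni[1:5], uni, uni)
    expect_equal(out2$a, 5)
    expect_equal(out2$p_one_sided, 1)
    expect_error(fisherOverlap(c("zz"), uni[1:3], uni), "subsets")
})

test_that("the best concept variant is selected by odds ratio", {
    uni <- sprintf("u%04d", 1:2000)
    sig <- geneSignature("sig", uni[1:100], "up")
    study <- list(
        list(percent = 1, direction = "up", genes = uni[1:20]),     # nested
        list(percent = 5, direction = "up", genes = uni[c(1:20, 300:379)]),
        list(percent = 10, direction = "down", genes = uni[500:699]))
    best <- bestVariantAssociation(sig, study, uni, "studyA")
    expect_equal(best$chosen_percent, 1)
    expect_equal(best$chosen_direction, "up")
    expect_identical(best$concept, "studyA")
    one <- bestVariantAssociation(sig, study[2], uni, "studyB")
    expect_equal(one$chosen_percent, 5)
    expect_warning(
        none <- bestVariantAssociation(sig,
                                       list(list(percent = 1,
                                                 direction = "up",
                                                 genes = character(0))),
                                       uni, "studyC"),
        "empty variant")
    expect_null(none)
})

test_that("concept network applies strict sign-appropriate thresholds", {
    assoc <- data.frame(
        signature = "sig", concept = paste0("c", 1:4),
        direction = c("up", "up", "down", "down"),
        a = 10, b = 140, c = 140, d = 19710,
        odds_ratio = c(5.9, 10, 4.5, 3.9),
        p_one_sided = c(1e-9, 1e-5, 1e-9, 1e-9))
    net <- conceptNetwork(assoc)  # methods preset: >6 pos, >4 neg, p<1e-6
    expect_setequal(net$edges$concept, "c3")
    # figure preset: OR>6 both signs, p<1e-4
    thr <- networkPreset("figure")
    net2 <- conceptNetwork(assoc, thr$or_threshold_pos, thr$or_threshold_neg,
                           thr$p_threshold)
    expect_setequal(net2$edges$concept, "c2")
    # edge set is monotone non-increasing in the thresholds
    n_loose <- nrow(conceptNetwork(assoc, 4, 3, 1e-2)$edges)
    n_tight <- nrow(conceptNetwork(assoc, 8, 6, 1e-10)$edges)
    expect_gte(n_loose, nrow(net$edges))
    expect_lte(n_tight, nrow(net$edges))
    expect_equal(nrow(conceptNetwork(assoc[0, ])$edges), 0)
})

test_that("planted passing concepts are recovered exactly as network edges", {
    set.seed(43)
    uni <- sprintf("g%05d", 1:20000)
    target <- sample(uni, 150)
    plan <- c(c1 = 40, c2 = 35, c3 = 30, c4 = 25, c5 = 20)
    sets <- simulateConceptLibrary(plan, uni, target, concept_size = 150,
                                   n_background = 10, seed = 17)
    sig <- geneSignature("target_pos", target, "up")
    assoc <- do.call(rbind, lapply(names(sets), function(nm)
        fisherOverlap(sig, geneSignature(nm, sets[[nm]]), uni)))
    net <- conceptNetwork(assoc)
    # expected passing set computed from the planted counts by direct formula
    expected <- names(plan)[vapply(plan, function(a) {
        d <- 20000 - 150 - 150 + a
        or <- (a * d) / ((150 - a) * (150 - a))
        p <- stats::phyper(a - 1, 150, 20000 - 150, 150, lower.tail = FALSE)
        or > 6 && p < 1e-6
    }, TRUE)]
    expect_setequal(net$edges$concept, expected)
})

test_that("preranked GSEA matches the running-sum oracle", {
    ranked <- data.frame(gene_id = sprintf("g%02d", 1:10),
                         rho = seq(0.95, -0.95, length.out = 10))
    # set = top ranks -> es = +1
    res <- prerankedGsea(ranked, list(top = sprintf("g%02d", 1:3)),
                         n_permutations = 50, seed = 1)
    expect_equal(res$es, 1)
    set.seed(44)
    for (i in 1:10) {
        idx <- sort(sample(10, 4))
        memb <- seq_len(10) %in% idx
        res2 <- prerankedGsea(ranked,
                              list(s = ranked$gene_id[idx]),
                              n_permutations = 10, seed = 2)
        expect_equal(res2$es, es_oracle(ranked$rho, memb), tolerance = 1e-12)
    }
    expect_warning(prerankedGsea(ranked, list(s = c("g01", "zz", "g05")),
                                 n_permutations = 10, seed = 1),
                   "dropped")
    expect_error(suppressWarnings(
        prerankedGsea(ranked, list(s = "nope"), n_permutations = 10)),
        "no usable")
})

test_that("preranked GSEA agrees with an independent implementation", {
    set.seed(45)
    rho <- sort(rnorm(200), decreasing = TRUE)
    ranked <- data.frame(gene_id = sprintf("g%03d", 1:200), rho = rho)
    for (i in 1:5) {
        sel <- sort(sample(200, 15))
        ours <- prerankedGsea(ranked, list(s = ranked$gene_id[sel]),
                              n_permutations = 5, seed = 1)$es
        theirs <- fgsea::calcGseaStat(rho, selectedStats = sel,
                                      gseaParam = 1)
        expect_equal(ours, theirs, tolerance = 1e-6)
    }
})

test_that("GMT libraries round trip through the writer and reader", {
    sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g4", "g5"))
    path <- withr::local_tempfile(fileext = ".gmt")
    writeGmt(sets, path)
    back <- readGmt(path)
    expect_identical(back, sets)
})
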