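test_that("perfect separation gives enrichment scores of exactly +/-1", {
    v <- c(a = 10, b = 9, c = 8, d = 3, e = 2, f = 1)
    expect_equal(enrichmentScore(v, c("a", "b", "c"))$es, 1)
    expect_equal(enrichmentScore(v, c("d", "e", "f"))$es, -1)
})

test_that("enrichment score matches the step-by-step oracle", {
    # small worked instance: values 9,7,5,3,1 with members at ranks 1,3
    v <- c(s1 = 9, s2 = 7, s3 = 5, s4 = 3, s5 = 1)
    m <- c(TRUE, FALSE, TRUE, FALSE, FALSE)
    expect_equal(enrichmentScore(v, m)$es, es_oracle(v, m))
    set.seed(10)
    for (i in 1:50) {
        N <- sample(4:12, 1)
        vals <- sort(rexp(N, 0.1), decreasing = TRUE) # tie-free
        names(vals) <- paste0("s", seq_len(N))
        k <- sample(seq_len(N - 1), 1)
        memb <- logical(N)
        memb[sample(N, k)] <- TRUE
        p <- sample(c(0, 1, 1.5), 1)
        es <- enrichmentScore(vals, memb, p = p)$es
        expect_equal(es, es_oracle(vals, memb, p), tolerance = 1e-12)
        expect_true(abs(es) <= 1 + 1e-12)
    }
})

test_that("the compiled ES kernel agrees with the R implementation", {
    set.seed(11)
    for (i in 1:20) {
        N <- sample(5:30, 1)
        vals <- rexp(N) + seq_len(N) * 1e-6
        memb <- logical(N)
        memb[sample(N, sample(seq_len(N - 1), 1))] <- TRUE
        esr <- enrichmentScore(stats::setNames(vals, paste0("x", 1:N)),
                               memb)$es
        esc <- lncscape:::.ssea_es_matrix(matrix(vals, 1), rep(0, N),
                                          matrix(FALSE, 0, N), memb, 1)[1, 1]
        expect_equal(esr, esc, tolerance = 1e-12)
    }
})

test_that("all-zero member values fall back to the unweighted tie rule", {
    v <- c(a = 5, b = 4, c = 0, d = 0)
    res <- enrichmentScore(v, c("c", "d"), p = 1)
    # members occupy the bottom ranks with increments 1/k
    expect_equal(res$es, -1)
})

test_that("permutation null is seeded and sized as requested", {
    v <- stats::setNames(rexp(12), paste0("s", 1:12))
    n1 <- permutationNull(v, 5, n_permutations = 50, seed = 3)
    n2 <- permutationNull(v, 5, n_permutations = 50, seed = 3)
    expect_identical(n1, n2)
    expect_length(permutationNull(v, 5, n_permutations = 1, seed = 1), 1L)
    expect_error(permutationNull(v, 12, n_permutations = 5), "set_size")
    # the unweighted statistic is sign-balanced under exchangeability
    n3 <- permutationNull(v, 6, p = 0, n_permutations = 2000, seed = 9)
    se <- sd(n3) / sqrt(length(n3))
    expect_lt(abs(mean(n3)), 3 * se + 0.02)
})

test_that("nominal p is the sign-matched relative rank, never zero", {
    null9 <- c(0.5, 0.3, 0.2, 0.1, -0.4, -0.3, -0.2, -0.1, 0.05)
    # counting oracle for es = 0.25: same-sign nulls = 5, those >= 0.25: 2
    expect_equal(nominalP(0.25, null9), (1 + 2) / (1 + 5))
    # es beyond every same-sign null (k of them) -> 1 / (k + 1)
    expect_equal(nominalP(0.9, null9), 1 / (1 + 5))
    expect_equal(nominalP(-0.9, null9), 1 / (1 + 4))
    expect_equal(nominalP(0, null9), 1)
    expect_warning(pp <- nominalP(-0.5, c(0.1, 0.2)), "no same-sign")
    expect_equal(pp, 1)
    expect_error(nominalP(0.5, numeric(0)), "non-empty")
    set.seed(12)
    for (i in 1:25) {
        nulls <- rnorm(sample(5:50, 1), sd = 0.3)
        es <- rnorm(1, sd = 0.3)
        same <- nulls[sign(nulls) == sign(es)]
        if (length(same) == 0 || es == 0) next
        expect_equal(nominalP(es, nulls),
                     (1 + sum(abs(same) >= abs(es))) / (1 + length(same)))
    }
})

test_that("NES is the ES over the mean same-sign null magnitude", {
    expect_equal(normalizeEs(0.4, rep(0.4, 10)), 1)
    expect_equal(normalizeEs(-0.4, c(-0.4, -0.4, 0.2)), -1)
    expect_equal(normalizeEs(0, c(-1, 1)), 0)
    expect_true(is.na(normalizeEs(-0.5, c(0.1, 0.3))))
    expect_equal(normalizeEs(0.6, c(0.2, 0.4, -0.3)), 0.6 / 0.3)
})

test_that("FDR Q matches hand computation on a three-transcript toy", {
    obs <- c(2.0, 1.5, -1.8)
    pooled <- c(1.0, 1.2, 1.6, 2.5, -1.0, -2.0)
    q <- fdrQ(obs, pooled)
    # positive side: nulls {1.0,1.2,1.6,2.5}, observed {2.0,1.5}
    # q(2.0) = (1/4)/(1/2) = 0.5 ; q(1.5) = (2/4)/(2/2) = 0.5
    expect_equal(q[1], 0.5)
    expect_equal(q[2], 0.5)
    # negative side: nulls {-1.0,-2.0}, observed {-1.8}
    # q(-1.8) = (1/2)/(1/1) = 0.5
    expect_equal(q[3], 0.5)
    # a transcript beyond every pooled null gets q = 0
    expect_equal(fdrQ(3.0, pooled)[1], 0)
    # q is monotone non-decreasing as |NES| decreases within a sign
    set.seed(13)
    obs2 <- sort(runif(20, 0.1, 3), decreasing = TRUE)
    q2 <- fdrQ(obs2, runif(500, 0, 2.5))
    expect_true(all(diff(q2) >= -1e-12))
    # a side with no pooled nulls is reported NA, not zero
    expect_true(is.na(fdrQ(-1.2, c(0.5, 1.5))))
})

test_that("runSsea output respects its documented invariants", {
    set.seed(14)
    v <- matrix(rpois(30 * 16, 40), 30, 16,
                dimnames = list(sprintf("T%02d", 1:30), sprintf("S%02d", 1:16)))
    v[1:3, 1:8] <- v[1:3, 1:8] * 6
    le <- LandscapeExperiment(v, unit = "counts")
    set <- sampleSet("grp", sprintf("S%02d", 1:8))
    res <- runSsea(le, set, sseaParams(n_permutations = 200, seed = 2),
                   apply_filter = FALSE, min_null_support = 5)
    expect_s4_class(res, "SseaResults")
    expect_equal(nrow(res), 30)
    expect_true(all(abs(res$es) <= 1 + 1e-12))
    expect_true(all(res$p_nominal >= 1 / 201))
    expect_true(all(res$fdr_q >= 0 & res$fdr_q <= 1, na.rm = TRUE))
    expect_true(all(res[c("T01", "T02", "T03"), "direction"] == "+"))

    # swapping set and complement flips the sign of es for every transcript
    res2 <- runSsea(le, sampleSet("comp", sprintf("S%02d", 9:16)),
                    sseaParams(n_permutations = 200, seed = 2),
                    apply_filter = FALSE, min_null_support = 5)
    nz <- res$es != 0 & res2$es != 0
    expect_true(all(sign(res$es[nz]) == -sign(res2$es[nz])))

    # relabeling transcript ids leaves every statistic unchanged
    le2 <- le
    rownames(le2) <- sprintf("X%02d", 1:30)
    res3 <- runSsea(le2, set, sseaParams(n_permutations = 200, seed = 2),
                    apply_filter = FALSE, min_null_support = 5)
    expect_equal(res3$es, res$es)
    expect_equal(res3$fdr_q, res$fdr_q)
    # reordering rows leaves the (permutation-free) es unchanged
    perm_rows <- sample(30)
    res4 <- runSsea(le[perm_rows, ], set,
                    sseaParams(n_permutations = 20, seed = 2),
                    apply_filter = FALSE, min_null_support = 5)
    expect_equal(res4[rownames(res), "es"], res$es)
})

test_that("small-sample ES and nominal p match exhaustive enumeration", {
    set.seed(15)
    v <- stats::setNames(sort(rexp(7), decreasing = TRUE) + 0.01,
                         paste0("s", 1:7))
    memb <- c("s1", "s3", "s4")
    es <- enrichmentScore(v, memb)$es
    expect_equal(es, es_oracle(v, names(v) %in% memb))
    ex_null <- all_subsets_null(v, 3)          # all C(7,3) = 35 subsets
    same <- ex_null[sign(ex_null) == sign(es)]
    expect_equal(nominalP(es, ex_null),
                 (1 + sum(abs(same) >= abs(es))) / (1 + length(same)))
})

test_that("expression pre-filter and percentile metric flow into results", {
    v <- matrix(1, 4, 40, dimnames = list(paste0("T", 1:4), paste0("S", 1:40)))
    v[1, ] <- 0            # never passes any filter
    v[2, ] <- 100
    v[3, 38:40] <- 50      # bright only in the top 2.5% of samples
    le <- LandscapeExperiment(v, unit = "FPKM")
    res <- runSsea(le, sampleSet("g", paste0("S", 1:20)),
                   sseaParams(n_permutations = 20, seed = 1),
                   percentile_q = 0.975, min_expr = 10)
    expect_false("T1" %in% rownames(res))
    expect_true(all(c("T2", "T3") %in% rownames(res)))
    expect_equal(res["T2", "percentile_value"], 100)
})
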