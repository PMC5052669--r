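# Independent brute-force oracles used to validate the package's statistics.
# Deliberately naive implementations: every quantity is recomputed from first
# principles, sharing no code with the package internals.

# Weighted KS enrichment score, step by step. Values must be tie-free (or the
# caller supplies an explicit order) so the ranking is unambiguous.
es_oracle <- function(values, members, p = 1) {
    ord <- order(values, decreasing = TRUE)
    v <- values[ord]
    m <- members[ord]
    k <- sum(m)
    N <- length(v)
    w <- abs(v)^p
    denom <- sum(w[m])
    run <- 0
    best <- 0
    for (i in seq_len(N)) {
        if (m[i]) {
            run <- run + (if (denom > 0) w[i] / denom else 1 / k)
        } else {
            run <- run - 1 / (N - k)
        }
        if (abs(run) > abs(best)) best <- run
    }
    unname(best)
}

# All same-size subsets as membership vectors (exhaustive permutation null).
all_subsets_null <- function(values, k, p = 1) {
    N <- length(values)
    combs <- utils::combn(N, k)
    apply(combs, 2, function(idx) {
        m <- logical(N)
        m[idx] <- TRUE
        es_oracle(values, m, p)
    })
}

# Hypergeometric upper-tail P(X >= a) by explicit enumeration over overlap
# sizes, using only choose().
hyper_tail_oracle <- function(a, n_sig, n_concept, n_universe) {
    amax <- min(n_sig, n_concept)
    total <- choose(n_universe, n_sig)
    sum(vapply(a:amax, function(x)
        choose(n_concept, x) * choose(n_universe - n_concept, n_sig - x),
        0)) / total
}

# Kaplan-Meier product limit computed by hand over unique event times.
km_oracle <- function(time, event) {
    tt <- sort(unique(time[event == 1]))
    s <- 1
    out <- data.frame(time = 0, surv = 1)
    for (t in tt) {
        n_risk <- sum(time >= t)
        d <- sum(time == t & event == 1)
        s <- s * (1 - d / n_risk)
        out <- rbind(out, data.frame(time = t, surv = s))
    }
    out
}

# Two-group log-rank chi-square from the aggregated O/E/V table.
logrank_oracle <- function(time, event, group) {
    g <- as.integer(factor(group)) # 1/2
    tt <- sort(unique(time[event == 1]))
    O <- 0; E <- 0; V <- 0
    for (t in tt) {
        at_risk <- time >= t
        n <- sum(at_risk)
        n1 <- sum(at_risk & g == 1)
        d <- sum(time == t & event == 1)
        d1 <- sum(time == t & event == 1 & g == 1)
        O <- O + d1
        E <- E + d * n1 / n
        if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    chisq <- (O - E)^2 / V
    list(chi_square = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Spearman rho as Pearson on average ranks.
spearman_oracle <- function(x, y) {
    stats::cor(rank(x), rank(y))
}

# All-pairs half-open interval intersection (0-based starts/ends).
brute_overlap <- function(peak_start, peak_end, prom_start, prom_end) {
    n_peaks <- integer(length(prom_start))
    bp <- integer(length(prom_start))
    for (i in seq_along(prom_start)) {
        covered <- integer(0)
        for (j in seq_along(peak_start)) {
            lo <- max(peak_start[j], prom_start[i])
            hi <- min(peak_end[j], prom_end[i])
            if (lo < hi) {
                n_peaks[i] <- n_peaks[i] + 1L
                covered <- union(covered, seq(lo, hi - 1L))
            }
        }
        bp[i] <- length(covered)
    }
    list(n_peaks = n_peaks, overlap_bp = bp, flag = n_peaks >= 1L)
}

# Nearest-rank percentile.
nearest_rank_oracle <- function(values, q) {
    sort(values)[ceiling(q * length(values))]
}

# Tiny expression container for unit tests.
make_le <- function(values, unit = "FPKM", ...) {
    if (is.null(rownames(values)))
        rownames(values) <- sprintf("T%02d", seq_len(nrow(values)))
    if (is.null(colnames(values)))
        colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
    LandscapeExperiment(values, unit = unit, ...)
}
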