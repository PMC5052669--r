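#' @useDynLib lncscape, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Define a sample set for enrichment testing
#'
#' @param name label of the set (e.g. `"tumor"` or `"er_positive"`).
#' @param members character vector of sample ids belonging to the set.
#' @return an object of class `SampleSet` (a validated list).
#' @export
sampleSet <- function(name, members) {
    members <- unique(as.character(members))
    if (length(members) == 0L) stop("sample set must be non-empty")
    structure(list(name = name, members = members), class = "SampleSet")
}

#' SSEA run parameters
#'
#' @param weight_exponent weight on expression magnitudes in the running sum
#'   (GSEA's weighted scheme; default 1). Must be >= 0.
#' @param n_permutations number of label permutations for the null (>= 1).
#' @param seed integer seed driving permutation draws and tie-breaking.
#' @return an object of class `SseaParams`.
#' @export
sseaParams <- function(weight_exponent = 1, n_permutations = 1000, seed = 1L) {
    if (weight_exponent < 0) stop("weight_exponent must be >= 0")
    if (n_permutations < 1) stop("n_permutations must be >= 1")
    structure(list(weight_exponent = weight_exponent,
                   n_permutations = as.integer(n_permutations),
                   seed = as.integer(seed)),
              class = "SseaParams")
}

.memberLogical <- function(sample_ids, set) {
    if (inherits(set, "SampleSet")) set <- set$members
    if (is.logical(set)) {
        if (length(set) != length(sample_ids)) stop("logical set length mismatch")
        members <- set
    } else {
        if (!all(set %in% sample_ids))
            stop("sample set members missing from matrix: ",
                 paste(setdiff(set, sample_ids), collapse = ", "))
        members <- sample_ids %in% set
    }
    k <- sum(members)
    if (k < 1L || k >= length(sample_ids))
        stop("sample set must be a non-empty proper subset of the samples")
    members
}

#' Weighted KS enrichment score of a sample set
#'
#' Samples are sorted by expression descending; each member sample advances the
#' running sum by `|value|^p / sum(member |value|^p)`, each non-member retreats
#' it by `1/(N - k)`. The enrichment score is the signed running-sum value of
#' maximal absolute deviation. When every member value is zero (and p > 0) the
#' member increments fall back to the unweighted `1/k`.
#'
#' @param values named numeric vector, one expression value per sample.
#' @param set a [sampleSet()], character vector of member ids, or logical
#'   vector aligned with `values`.
#' @param p weight exponent (default 1).
#' @param tie_break optional numeric vector; ties in `values` are broken by
#'   this key descending (a seeded random shuffle in [runSsea()]). Defaults to
#'   input order.
#' @return list with `es`, the `running_sum` profile and the sample `order`.
#' @export
enrichmentScore <- function(values, set, p = 1, tie_break = NULL) {
    N <- length(values)
    if (N < 2L) stop("enrichmentScore() needs >= 2 samples")
    ids <- if (is.null(names(values))) as.character(seq_len(N)) else names(values)
    members <- .memberLogical(ids, set)
    k <- sum(members)
    if (is.null(tie_break)) tie_break <- rev(seq_len(N))
    ord <- order(values, tie_break, decreasing = TRUE)
    v <- values[ord]
    m <- members[ord]
    vp <- abs(v)^p
    sum_vp <- sum(vp[m])
    inc <- if (sum_vp > 0) vp / sum_vp else rep(1 / k, N)
    steps <- ifelse(m, inc, -1 / (N - k))
    cs <- unname(cumsum(steps))
    es <- cs[which.max(abs(cs))]
    list(es = es, running_sum = cs, order = ord)
}

#' Permutation null of enrichment scores
#'
#' Each permutation draws a uniform-random sample set of size `set_size` and
#' recomputes the enrichment score; deterministic given `seed`.
#'
#' @inheritParams enrichmentScore
#' @param set_size size of the permuted sets, in `[1, N - 1]`.
#' @param n_permutations number of draws.
#' @param seed integer seed.
#' @return numeric vector of `n_permutations` null enrichment scores.
#' @export
permutationNull <- function(values, set_size, p = 1, n_permutations = 1000,
                            seed = 1L) {
    N <- length(values)
    if (set_size < 1L || set_size >= N)
        stop("set_size must be in [1, N - 1]")
    if (n_permutations < 1L) stop("n_permutations must be >= 1")
    withr::with_seed(seed, {
        perm <- matrix(FALSE, n_permutations, N)
        for (i in seq_len(n_permutations))
            perm[i, sample.int(N, set_size)] <- TRUE
        tiekey <- stats::runif(N)
        obs <- c(TRUE, rep(FALSE, N - 1L)) # placeholder observed set
        esm <- .ssea_es_matrix(matrix(values, nrow = 1L), tiekey, perm, obs, p)
        as.numeric(esm[1L, -1L])
    })
}

#' Nominal permutation p-value of an enrichment score
#'
#' One-sided and sign-matched: the relative rank of the observed score among
#' the same-sign null scores, `p = (1 + #same-sign null with |null| >= |es|) /
#' (1 + #same-sign null)`. Never zero; an observed score of 0 gives p = 1.
#'
#' @param es_observed observed enrichment score.
#' @param null_es numeric vector of null enrichment scores.
#' @return p-value in (0, 1].
#' @export
nominalP <- function(es_observed, null_es) {
    if (length(null_es) == 0L) stop("null_es must be non-empty")
    if (es_observed == 0) return(1)
    same <- null_es[sign(null_es) == sign(es_observed)]
    if (length(same) == 0L) {
        warning("no same-sign null enrichment scores; p set to 1")
        return(1)
    }
    (1 + sum(abs(same) >= abs(es_observed))) / (1 + length(same))
}

#' Normalized enrichment score
#'
#' `nes = es / mean(|null es of the same sign|)`; 0 maps to 0; `NA` when no
#' same-sign null score exists.
#'
#' @inheritParams nominalP
#' @return normalized enrichment score.
#' @export
normalizeEs <- function(es, null_es) {
    if (es == 0) return(0)
    same <- null_es[sign(null_es) == sign(es)]
    if (length(same) == 0L) return(NA_real_)
    es / mean(abs(same))
}

## number of values in `sorted` (ascending) that are >= x (vectorized over x)
.countGE <- function(sorted, x) {
    length(sorted) - findInterval(x, sorted, left.open = TRUE)
}

## number of values in `sorted` (ascending) that are <= x
.countLE <- function(sorted, x) {
    findInterval(x, sorted)
}

#' GSEA-style FDR Q values from pooled null NES
#'
#' For a positive `nes*`: `q = [fraction of pooled positive null NES >= nes*] /
#' [fraction of observed positive NES >= nes*]`, clipped to `[0, 1]`; mirrored
#' on the negative side. Monotonicity within each sign is enforced by a
#' running minimum taken from the least extreme |NES| inward, so q is
#' non-decreasing as |NES| decreases.
#'
#' @param observed_nes numeric vector of observed NES (NA allowed).
#' @param pooled_null_nes numeric vector of null NES pooled over transcripts
#'   and permutations.
#' @return numeric vector of q values aligned with `observed_nes`.
#' @export
fdrQ <- function(observed_nes, pooled_null_nes) {
    if (length(pooled_null_nes) == 0L) stop("pooled null is empty")
    q <- rep(NA_real_, length(observed_nes))
    for (sgn in c(1, -1)) {
        idx <- which(!is.na(observed_nes) &
                     sign(observed_nes) == sgn & observed_nes != 0)
        if (length(idx) == 0L) next
        obs <- observed_nes[idx]
        nulls <- pooled_null_nes[!is.na(pooled_null_nes) &
                                 sign(pooled_null_nes) == sgn]
        if (length(nulls) == 0L) next # no null support on this side: q stays NA
        aobs_sorted <- sort(abs(obs))
        anull_sorted <- sort(abs(nulls))
        num <- .countGE(anull_sorted, abs(obs)) / length(anull_sorted)
        den <- .countGE(aobs_sorted, abs(obs)) / length(aobs_sorted)
        qi <- pmin(pmax(num / den, 0), 1)
        ## running minimum: each q becomes min over all less-or-equally
        ## extreme |NES| .. itself, ordered by |NES| descending
        ord <- order(abs(obs), decreasing = TRUE)
        qs <- qi[ord]
        qs <- rev(cummin(rev(qs)))
        qi[ord] <- qs
        q[idx] <- qi
    }
    q[which(observed_nes == 0)] <- 1
    q
}

#' Run sample set enrichment analysis over all transcripts
#'
#' Normalizes counts to CPM if needed, applies the percentile expression
#' pre-filter, computes per-transcript weighted KS enrichment scores of the
#' sample set, a per-transcript permutation null (each transcript draws its
#' own independent label shuffles from the seeded RNG stream, keeping nominal
#' p values independent across transcripts), nominal p values, NES, and
#' pooled-null FDR Q values.
#'
#' @param m a [LandscapeExperiment-class] (counts or FPKM).
#' @param set a [sampleSet()].
#' @param params an [sseaParams()] object.
#' @param percentile_q sample quantile for the expression pre-filter and the
#'   reported percentile metric (default 0.975).
#' @param min_expr inclusive minimum expression at that quantile for a
#'   transcript to be tested (default 1; same units as the normalized matrix).
#' @param apply_filter set `FALSE` to test every transcript.
#' @param fdr_cutoff cutoff for the reported `significant` flag (default 1e-5).
#' @param min_null_support minimum number of same-sign null enrichment scores
#'   required to normalize an ES; below it NES and q are reported `NA`. The
#'   value-weighted walk concentrates null mass on one sign for large sample
#'   sets, so the rare-sign tail cannot be estimated from few permutations;
#'   enrichment in the complement set tests the other direction (default 30).
#' @return an [SseaResults-class] with one row per tested transcript.
#' @export
runSsea <- function(m, set, params = sseaParams(), percentile_q = 0.975,
                    min_expr = 1, apply_filter = TRUE, fdr_cutoff = 1e-5,
                    min_null_support = 30) {
    stopifnot(is(m, "LandscapeExperiment"), inherits(params, "SseaParams"))
    mn <- if (exprUnit(m) == "counts") normalizeCounts(m) else m
    v <- exprValues(mn)
    if (nrow(v) == 0L || ncol(v) == 0L) stop("empty expression matrix")
    members <- .memberLogical(colnames(v), set)
    k <- sum(members)
    N <- ncol(v)
    pctl <- apply(v, 1L, percentileExpression, q = percentile_q)
    keep <- if (apply_filter) pctl >= min_expr else rep(TRUE, nrow(v))
    if (!any(keep)) stop("no transcript passes the expression filter")
    vk <- v[keep, , drop = FALSE]

    nperm <- params$n_permutations
    esm <- withr::with_seed(params$seed, {
        tiekey <- stats::runif(N)
        .ssea_es_matrix(vk, tiekey, matrix(FALSE, 0L, N), members,
                        params$weight_exponent, nperm = nperm)
    })
    es <- esm[, 1L]
    nulls <- esm[, -1L, drop = FALSE]

    G <- nrow(vk)
    p_nom <- numeric(G)
    nes <- numeric(G)
    null_nes <- matrix(NA_real_, G, nperm)
    for (g in seq_len(G)) {
        ng <- nulls[g, ]
        p_nom[g] <- suppressWarnings(nominalP(es[g], ng))
        n_pos <- sum(ng > 0)
        n_neg <- sum(ng < 0)
        same <- if (es[g] > 0) n_pos else if (es[g] < 0) n_neg else Inf
        nes[g] <- if (same >= min_null_support) normalizeEs(es[g], ng)
                  else NA_real_
        pos_mean <- mean(ng[ng > 0])
        neg_mean <- mean(abs(ng[ng < 0]))
        nn <- ifelse(ng > 0,
                     if (n_pos >= min_null_support) ng / pos_mean else NA_real_,
              ifelse(ng < 0,
                     if (n_neg >= min_null_support) ng / neg_mean else NA_real_,
                     0))
        null_nes[g, ] <- nn
    }
    q <- fdrQ(nes, as.numeric(null_nes))

    res <- S4Vectors::DataFrame(
        es = es, nes = nes, p_nominal = p_nom, fdr_q = q,
        direction = ifelse(es > 0, "+", ifelse(es < 0, "-", "0")),
        percentile_value = unname(pctl[keep]),
        significant = !is.na(q) & q < fdr_cutoff,
        row.names = rownames(vk))
    out <- new("SseaResults", res)
    S4Vectors::metadata(out) <- list(
        set_name = if (inherits(set, "SampleSet")) set$name else NA_character_,
        params = params, percentile_q = percentile_q, min_expr = min_expr,
        fdr_cutoff = fdr_cutoff, n_samples = N, set_size = k)
    out
}

setMethod("show", "SseaResults", function(object) {
    cat("SseaResults:", nrow(object), "transcripts | set:",
        S4Vectors::metadata(object)$set_name, "|",
        sum(object$significant), "significant\n")
    callNextMethod()
})
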