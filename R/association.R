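#' Spearman correlation of every protein-coding gene to a target transcript
#'
#' Spearman rho computed as Pearson correlation on mid-ranks (average-rank
#' ties), between the target transcript and each protein-coding gene across
#' the selected samples. The target itself is excluded from the result.
#'
#' @param m [LandscapeExperiment-class].
#' @param target_id transcript id of the correlation anchor.
#' @param sample_ids samples to use (e.g. the ER-positive tumors); default all.
#' @param coding_only restrict to `biotype == "protein_coding"` rows when
#'   biotype metadata is present (default `TRUE`).
#' @return data.frame of class `RankedList` with columns `gene_id` and `rho`,
#'   sorted by rho descending (ties by gene id).
#' @export
spearmanCorrelations <- function(m, target_id, sample_ids = NULL,
                                 coding_only = TRUE) {
    stopifnot(is(m, "LandscapeExperiment"))
    if (!target_id %in% rownames(m)) stop("target not in matrix: ", target_id)
    v <- exprValues(m)
    if (is.null(sample_ids)) sample_ids <- colnames(v)
    if (length(sample_ids) < 3L) stop("need >= 3 samples for correlation")
    v <- v[, sample_ids, drop = FALSE]
    target <- v[target_id, ]
    if (stats::sd(target) == 0)
        stop("target expression is constant; Spearman rho undefined")
    bt <- transcriptBiotype(m)
    genes <- rownames(v)
    if (coding_only && !is.null(bt))
        genes <- genes[bt[genes] == "protein_coding"]
    genes <- setdiff(genes, target_id)
    if (length(genes) == 0L) stop("no genes left to correlate")
    rho <- suppressWarnings(
        as.numeric(stats::cor(t(v[genes, , drop = FALSE]), target,
                              method = "spearman")))
    out <- data.frame(gene_id = genes, rho = rho, stringsAsFactors = FALSE)
    out <- out[order(-out$rho, out$gene_id), ]
    rownames(out) <- NULL
    class(out) <- c("RankedList", "data.frame")
    out
}

#' Build a named, directed gene signature
#'
#' @param name signature name.
#' @param genes character vector of gene ids (de-duplicated).
#' @param direction `"up"`, `"down"` or `"unsigned"`.
#' @param source origin label (study or concept collection).
#' @return list of class `GeneSignature`.
#' @export
geneSignature <- function(name, genes, direction = c("unsigned", "up", "down"),
                          source = NA_character_) {
    direction <- match.arg(direction)
    structure(list(name = name, genes = unique(as.character(genes)),
                   direction = direction, source = source),
              class = "GeneSignature")
}

#' Top positively and negatively correlated gene signatures
#'
#' @param ranked a `RankedList` from [spearmanCorrelations()].
#' @param n signature size (default 150). Requires at least `2n` ranked genes.
#' @param name_prefix prefix for the signature names.
#' @return list with `positive` and `negative` [geneSignature()]s. Boundary
#'   ties are broken by gene id (the RankedList sort order).
#' @export
topSignatures <- function(ranked, n = 150, name_prefix = "target") {
    if (nrow(ranked) < 2 * n)
        stop("need >= ", 2 * n, " ranked genes, have ", nrow(ranked))
    pos <- ranked$gene_id[seq_len(n)]
    neg <- ranked$gene_id[seq(nrow(ranked) - n + 1L, nrow(ranked))]
    list(positive = geneSignature(paste0(name_prefix, "_pos"), pos, "up"),
         negative = geneSignature(paste0(name_prefix, "_neg"), neg, "down"))
}

#' One-sided Fisher overlap of two gene signatures
#'
#' Tests enrichment of the overlap `a = |sig & concept|` against the
#' hypergeometric tail `P(X >= a)` over a fixed gene universe. The odds ratio
#' is `(a d)/(b c)` from the 2x2 table; when any cell is zero the
#' Haldane-Anscombe +0.5 correction is applied to every cell and flagged.
#'
#' @param sig,concept [geneSignature()]s (or plain character vectors); both
#'   must be subsets of `universe`.
#' @param universe character vector, the measured gene universe.
#' @return one-row data.frame of class `ConceptAssociation` with the 2x2
#'   counts, `odds_ratio`, `p_one_sided`, `or_corrected` flag and labels.
#' @export
fisherOverlap <- function(sig, concept, universe) {
    sgenes <- if (inherits(sig, "GeneSignature")) sig$genes else unique(sig)
    cgenes <- if (inherits(concept, "GeneSignature")) concept$genes
              else unique(concept)
    universe <- unique(as.character(universe))
    if (!all(sgenes %in% universe) || !all(cgenes %in% universe))
        stop("signature and concept must be subsets of the universe")
    a <- length(intersect(sgenes, cgenes))
    b <- length(sgenes) - a
    c_ <- length(cgenes) - a
    d <- length(universe) - a - b - c_
    p <- stats::phyper(a - 1, length(cgenes),
                       length(universe) - length(cgenes),
                       length(sgenes), lower.tail = FALSE)
    corrected <- any(c(a, b, c_, d) == 0)
    or <- if (corrected) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
          else (a * d) / (b * c_)
    out <- data.frame(
        signature = if (inherits(sig, "GeneSignature")) sig$name else "signature",
        concept = if (inherits(concept, "GeneSignature")) concept$name
                  else "concept",
        direction = if (inherits(sig, "GeneSignature")) sig$direction
                    else "unsigned",
        a = a, b = b, c = c_, d = d, odds_ratio = or, p_one_sided = p,
        or_corrected = corrected, stringsAsFactors = FALSE)
    class(out) <- c("ConceptAssociation", "data.frame")
    out
}

#' Best concept variant by odds ratio
#'
#' A concept study typically ships several variant gene lists (top 1, 5 and
#' 10% of its up- and downregulated genes). Every variant is tested with
#' [fisherOverlap()] and the one with the greatest odds ratio is returned
#' (ties: smaller p, then smaller percent).
#'
#' @param sig the query [geneSignature()].
#' @param study list of variants; each variant is a list with elements
#'   `percent`, `direction` and `genes`.
#' @param universe gene universe for the 2x2 tables.
#' @param study_name label used in the output.
#' @return a `ConceptAssociation` row with `chosen_percent` and
#'   `chosen_direction` columns; `NULL` when every variant is empty.
#' @export
bestVariantAssociation <- function(sig, study, universe,
                                   study_name = "study") {
    rows <- list()
    for (variant in study) {
        if (length(variant$genes) == 0L) {
            warning("empty variant skipped in study ", study_name)
            next
        }
        concept <- geneSignature(
            paste0(study_name, "_", variant$direction, "_", variant$percent),
            intersect(variant$genes, universe), source = study_name)
        assoc <- fisherOverlap(sig, concept, universe)
        assoc$chosen_percent <- variant$percent
        assoc$chosen_direction <- variant$direction
        rows[[length(rows) + 1L]] <- assoc
    }
    if (length(rows) == 0L) return(NULL)
    all_rows <- do.call(rbind, rows)
    ord <- order(-all_rows$odds_ratio, all_rows$p_one_sided,
                 all_rows$chosen_percent)
    best <- all_rows[ord[1L], ]
    best$concept <- study_name
    rownames(best) <- NULL
    class(best) <- c("ConceptAssociation", "data.frame")
    best
}

#' Named OR / p threshold presets for the concept network
#'
#' `"methods"`: odds ratio > 6 for positively and > 4 for negatively
#' associated concepts with p < 1e-6. `"figure"`: odds ratio > 6 with
#' p < 1e-4 for both directions.
#'
#' @param preset preset name.
#' @return list with `or_threshold_pos`, `or_threshold_neg`, `p_threshold`.
#' @export
networkPreset <- function(preset = c("methods", "figure")) {
    preset <- match.arg(preset)
    switch(preset,
        methods = list(or_threshold_pos = 6.0, or_threshold_neg = 4.0,
                       p_threshold = 1e-6),
        figure = list(or_threshold_pos = 6.0, or_threshold_neg = 6.0,
                      p_threshold = 1e-4))
}

#' Filter concept associations into a guilt-by-association network
#'
#' Keeps associations whose odds ratio strictly exceeds the sign-appropriate
#' threshold (positive signatures against `or_threshold_pos`, negative against
#' `or_threshold_neg`) and whose p value is strictly below `p_threshold`.
#'
#' @param associations data.frame of `ConceptAssociation` rows.
#' @param or_threshold_pos,or_threshold_neg,p_threshold thresholds; the
#'   defaults are the `"methods"` preset, see [networkPreset()].
#' @return list with `nodes` (name, type, size) and `edges` (signature,
#'   concept, odds_ratio as weight, p) data.frames.
#' @export
conceptNetwork <- function(associations, or_threshold_pos = 6.0,
                           or_threshold_neg = 4.0, p_threshold = 1e-6) {
    associations <- as.data.frame(associations)
    if (nrow(associations) == 0L) {
        return(list(nodes = data.frame(name = character(0), type = character(0),
                                       size = integer(0)),
                    edges = associations))
    }
    or_thr <- ifelse(associations$direction == "down",
                     or_threshold_neg, or_threshold_pos)
    keep <- associations$odds_ratio > or_thr &
        associations$p_one_sided < p_threshold
    edges <- associations[keep, , drop = FALSE]
    rownames(edges) <- NULL
    edges$weight <- edges$odds_ratio
    sig_nodes <- unique(edges$signature)
    con_nodes <- unique(edges$concept)
    nodes <- data.frame(
        name = c(sig_nodes, con_nodes),
        type = c(rep("signature", length(sig_nodes)),
                 rep("concept", length(con_nodes))),
        size = c(vapply(sig_nodes, function(s)
                     (edges$a + edges$b)[match(s, edges$signature)], 0),
                 vapply(con_nodes, function(cn)
                     (edges$a + edges$c)[match(cn, edges$concept)], 0)),
        stringsAsFactors = FALSE)
    list(nodes = nodes, edges = edges)
}

#' Weighted preranked gene-set enrichment
#'
#' Running-sum enrichment of a gene set over a rho-ranked gene list: member
#' genes advance the sum by `|rho|^weight / sum(member |rho|^weight)`,
#' non-members retreat it by `1/(N - k)`. Significance is assessed by
#' gene-label permutation (uniform random member sets of the same size),
#' with NES and pooled-null FDR Q computed as in [runSsea()].
#'
#' @param ranked a `RankedList` (columns `gene_id`, `rho`, rho descending).
#' @param gene_sets named list of character vectors; ids absent from the
#'   ranking are dropped with a warning.
#' @param weight weight exponent on |rho| (default 1).
#' @param n_permutations,seed permutation-null controls.
#' @return data.frame with one row per retained set: `es`, `nes`,
#'   `p_nominal`, `fdr_q`, `size`.
#' @export
prerankedGsea <- function(ranked, gene_sets, weight = 1,
                          n_permutations = 1000, seed = 1L) {
    genes <- ranked$gene_id
    rho <- ranked$rho
    N <- length(genes)
    w <- abs(rho)^weight
    dec_base <- function(k) 1 / (N - k)

    es_for <- function(member_idx) {
        k <- length(member_idx)
        memb <- logical(N)
        memb[member_idx] <- TRUE
        sw <- sum(w[memb])
        inc <- if (sw > 0) w / sw else rep(1 / k, N)
        steps <- ifelse(memb, inc, -dec_base(k))
        cs <- cumsum(steps)
        cs[which.max(abs(cs))]
    }

    kept <- list()
    for (nm in names(gene_sets)) {
        inside <- intersect(gene_sets[[nm]], genes)
        if (length(inside) < length(unique(gene_sets[[nm]])))
            warning("genes outside the ranking dropped from set ", nm)
        if (length(inside) == 0L || length(inside) >= N) {
            warning("set ", nm, " skipped (empty or full after intersection)")
            next
        }
        kept[[nm]] <- match(inside, genes)
    }
    if (length(kept) == 0L) stop("no usable gene sets")

    es <- vapply(kept, es_for, 0)
    nulls <- withr::with_seed(seed, {
        lapply(kept, function(idx) {
            k <- length(idx)
            vapply(seq_len(n_permutations),
                   function(i) es_for(sample.int(N, k)), 0)
        })
    })
    p_nom <- mapply(function(e, nl) suppressWarnings(nominalP(e, nl)),
                    es, nulls)
    nes <- mapply(normalizeEs, es, nulls)
    pooled <- unlist(lapply(nulls, function(nl) {
        pos_mean <- mean(nl[nl > 0])
        neg_mean <- mean(abs(nl[nl < 0]))
        ifelse(nl > 0, nl / pos_mean, ifelse(nl < 0, nl / neg_mean, 0))
    }), use.names = FALSE)
    q <- fdrQ(nes, pooled)
    data.frame(set = names(kept), es = es, nes = nes, p_nominal = p_nom,
               fdr_q = q, size = lengths(kept),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write GMT gene-set libraries
#'
#' @param path GMT file path.
#' @return `readGmt()` returns a named list of gene-id vectors.
#' @export
readGmt <- function(path) {
    fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param description description field written to column 2.
#' @export
writeGmt <- function(sets, path, description = "na") {
    lines <- vapply(names(sets), function(nm)
        paste(c(nm, description, sets[[nm]]), collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}

#' Export a concept network as Cytoscape-loadable tables
#'
#' @param network list from [conceptNetwork()].
#' @param dir output directory.
#' @return paths of the written node and edge TSVs.
#' @export
writeNetwork <- function(network, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    np <- file.path(dir, "network_nodes.tsv")
    ep <- file.path(dir, "network_edges.tsv")
    utils::write.table(network$nodes, np, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(network$edges, ep, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(nodes = np, edges = ep))
}
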