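#' Stratify samples by target-transcript expression
#'
#' Samples with expression strictly above `high_cut` FPKM go to the `high`
#' group, strictly below `low_cut` to `low`, and the middle band is
#' `excluded` from testing (two-threshold design: > 10 / < 1 FPKM).
#'
#' @param fpkm named numeric vector of per-sample expression.
#' @param high_cut,low_cut thresholds, `high_cut > low_cut`.
#' @return factor with levels `high`, `low`, `excluded`.
#' @examples
#' groupByExpression(c(a = 25, b = 0.5, c = 10)) # high, low, excluded
#' @export
groupByExpression <- function(fpkm, high_cut = 10, low_cut = 1) {
    if (high_cut <= low_cut) stop("high_cut must be > low_cut")
    if (any(fpkm < 0)) stop("negative expression value")
    g <- ifelse(fpkm > high_cut, "high",
                ifelse(fpkm < low_cut, "low", "excluded"))
    factor(g, levels = c("high", "low", "excluded"))
}

#' Kaplan-Meier product-limit estimate for one group
#'
#' Standard convention: subjects censored at time t remain at risk for the
#' events at t. Computed with `survival::survfit`.
#'
#' @param time positive event/censoring times.
#' @param event 1 = event, 0 = censored.
#' @return data.frame step function: `time`, `n_risk`, `n_event`, `surv`,
#'   starting at `(0, 1)`.
#' @export
kmEstimate <- function(time, event) {
    if (length(time) == 0L) stop("empty group")
    if (any(time <= 0)) stop("times must be > 0")
    fit <- survival::survfit(survival::Surv(time, event) ~ 1)
    data.frame(time = c(0, fit$time),
               n_risk = c(length(time), fit$n.risk),
               n_event = c(0, fit$n.event),
               surv = c(1, fit$surv))
}

#' Two-group log-rank test
#'
#' `chi^2 = (sum(O - E))^2 / sum(V)` aggregated over event times with the
#' standard tie handling; p from the chi-squared distribution with 1 df.
#' Computed with `survival::survdiff`.
#'
#' @param time,event survival outcome per sample.
#' @param group two-level factor or character vector.
#' @return list with `chi_square`, `p`, and per-group observed/expected
#'   event counts.
#' @export
logrankTest <- function(time, event, group) {
    group <- droplevels(factor(group))
    if (nlevels(group) != 2L) stop("logrankTest() needs exactly 2 groups")
    if (any(table(group) == 0L)) stop("both groups must be non-empty")
    if (sum(event) == 0L) stop("no events observed")
    sd <- survival::survdiff(survival::Surv(time, event) ~ group)
    list(chi_square = sd$chisq,
         p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
         observed = sd$obs, expected = sd$exp)
}

#' Expression-stratified survival analysis
#'
#' Groups samples by [groupByExpression()], drops the excluded middle band,
#' and compares the high and low groups by Kaplan-Meier / log-rank.
#'
#' @param surv data.frame with `sample_id`, `time`, `event`.
#' @param fpkm named numeric vector of target expression per sample.
#' @param high_cut,low_cut FPKM thresholds (defaults 10 / 1).
#' @return list with the group factor, per-group `km` tables and the
#'   log-rank `test`.
#' @export
survivalByExpression <- function(surv, fpkm, high_cut = 10, low_cut = 1) {
    surv <- as.data.frame(surv)
    if (!all(c("sample_id", "time", "event") %in% colnames(surv)))
        stop("surv needs columns sample_id, time, event")
    fpkm <- fpkm[surv$sample_id]
    if (anyNA(fpkm)) stop("expression missing for some survival samples")
    grp <- groupByExpression(fpkm, high_cut, low_cut)
    use <- grp != "excluded"
    if (sum(use) == 0L) stop("no samples in the high/low groups")
    km <- lapply(c(high = "high", low = "low"), function(g) {
        sel <- use & grp == g
        if (!any(sel)) return(NULL)
        kmEstimate(surv$time[sel], surv$event[sel])
    })
    test <- logrankTest(surv$time[use], surv$event[use],
                        droplevels(grp[use]))
    list(group = grp, km = km, test = test)
}

#' Read / write survival tables
#'
#' @param path TSV with columns `sample_id`, `time`, `event`.
#' @return `readSurvival()` returns a data.frame.
#' @export
readSurvival <- function(path) {
    utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname readSurvival
#' @param surv survival data.frame.
#' @export
writeSurvival <- function(surv, path) {
    utils::write.table(surv, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
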