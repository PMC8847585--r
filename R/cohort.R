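# Cross-cohort validation by marker-gene expression quartiles.

#' Stratify cohort samples by marker-gene expression quartiles
#'
#' Ranks samples by the marker gene's expression and forms a low group
#' (values at or below the 25th-percentile value) and a high group
#' (values at or above the 75th-percentile value). The rule is
#' tie-inclusive, so with tied values the groups can be slightly larger
#' than n/4, as happens in real cohorts; group members and the bounds are
#' returned for audit. A degenerate cohort in which both bounds coincide
#' is rejected.
#'
#' @param cohort a \code{\linkS4class{CohortMatrix}}.
#' @param marker marker gene id (defaults to the cohort's designated
#'   marker).
#' @return a \code{\linkS4class{QuartileSplit}}.
#' @export
quartileSplit <- function(cohort, marker = markerGene(cohort)) {
    expr <- cohortExpr(cohort)
    if (nrow(expr) < 8L)
        stop("need at least 8 samples for a quartile split")
    if (!(marker %in% colnames(expr)))
        stop("marker gene ", marker, " absent from the cohort")
    v <- expr[, marker]
    q <- quantile(v, c(0.25, 0.75), names = FALSE)
    if (q[1] >= q[2])
        stop("degenerate marker distribution: 25th and 75th percentile ",
             "values coincide")
    new("QuartileSplit", marker = marker,
        lowIds = rownames(expr)[v <= q[1]],
        highIds = rownames(expr)[v >= q[2]],
        bounds = q)
}

#' Per-gene fold change between low- and high-marker groups
#'
#' Converts log2(RPM) back to the linear scale and computes, per gene,
#' \code{log2((mean RPM in low group + pseudocount) /
#' (mean RPM in high group + pseudocount))}. Positive values mean higher
#' expression where the marker (e.g. the PRC2 subunit) is low —
#' the expected direction for de-repressed PRC2 targets.
#'
#' @param cohort a \code{\linkS4class{CohortMatrix}}.
#' @param split a \code{\linkS4class{QuartileSplit}} of its samples.
#' @param pseudocount added to both group means (default 1 RPM).
#' @return named numeric vector of log2 fold changes (marker column
#'   included like any other gene).
#' @export
stratifiedFC <- function(cohort, split, pseudocount = 1) {
    expr <- cohortExpr(cohort)
    low <- lowGroup(split); high <- highGroup(split)
    if (!length(low) || !length(high)) stop("empty stratification group")
    if (!all(c(low, high) %in% rownames(expr)))
        stop("split refers to samples absent from the cohort")
    linear <- 2^expr
    mLow <- colMeans(linear[low, , drop = FALSE])
    mHigh <- colMeans(linear[high, , drop = FALSE])
    log2((mLow + pseudocount) / (mHigh + pseudocount))
}

#' Call up-regulated genes in the low-marker group
#'
#' Genes with stratified fold change at or above \code{threshold}
#' (inclusive). Optionally also requires a per-gene Wilcoxon rank-sum
#' test (low vs high group, BH-adjusted) to pass \code{alpha}.
#'
#' @param fc named fold changes from \code{\link{stratifiedFC}}.
#' @param threshold log2FC threshold (default 1).
#' @param test if TRUE, add the rank-sum filter (requires \code{cohort}
#'   and \code{split}).
#' @param cohort,split the inputs used for \code{fc}; only needed when
#'   \code{test = TRUE}.
#' @param alpha BH-adjusted p threshold for the optional test.
#' @return character vector of gene ids.
#' @export
callCohortUpDegs <- function(fc, threshold = 1, test = FALSE,
                             cohort = NULL, split = NULL, alpha = 0.05) {
    up <- names(fc)[fc >= threshold]
    if (!test) return(up)
    if (is.null(cohort) || is.null(split))
        stop("test = TRUE requires cohort and split")
    expr <- cohortExpr(cohort)
    low <- lowGroup(split); high <- highGroup(split)
    p <- vapply(colnames(expr), function(g)
        suppressWarnings(stats::wilcox.test(expr[low, g],
                                            expr[high, g])$p.value),
        numeric(1))
    padj <- bhAdjust(p)
    intersect(up, colnames(expr)[padj <= alpha])
}

#' Summarize stratified fold change by epigenetic type
#'
#' Splits per-gene fold changes by type label, reports per-type median
#' and quartiles, and compares the type distributions with the
#' Kruskal-Wallis rank-sum test. Genes without a label are dropped with
#' a message.
#'
#' @param fc named fold changes from \code{\link{stratifiedFC}}.
#' @param types named character type labels per gene (e.g. from
#'   \code{\link{typeGenes}}'s model via \code{typeMap}).
#' @return list with \code{summary} (data.frame: type, n, q25, median,
#'   q75) and \code{kruskal} (list H, p, df).
#' @export
typeFCSummary <- function(fc, types) {
    common <- intersect(names(fc), names(types))
    dropped <- setdiff(names(fc), common)
    if (length(dropped))
        message(length(dropped), " gene(s) without a type label dropped")
    fc <- fc[common]
    groups <- split(unname(fc), as.character(types[common]))
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L)
        stop("need fold changes in at least two types")
    summary <- data.frame(
        type = names(groups),
        n = lengths(groups),
        q25 = vapply(groups, quantile, numeric(1), probs = 0.25),
        median = vapply(groups, median, numeric(1)),
        q75 = vapply(groups, quantile, numeric(1), probs = 0.75),
        row.names = NULL)
    list(summary = summary, kruskal = kruskalWallis(groups))
}
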