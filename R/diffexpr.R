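#' @importFrom stats p.adjust pnorm var
NULL

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes
#' with all-positive counts, of the ratio of the gene's count in the
#' sample to the gene's geometric mean across samples.
#'
#' @param counts nonnegative integer matrix, genes x samples.
#' @return named positive numeric vector, one factor per sample.
#' @examples
#' m <- cbind(s1 = c(10, 20, 30), s2 = c(20, 40, 60))
#' medianRatioFactors(m)  # ~ (0.707, 1.414)
#' @export
medianRatioFactors <- function(counts) {
    counts <- as.matrix(counts)
    pos <- rowSums(counts > 0) == ncol(counts)
    if (!any(pos))
        stop("no gene with positive counts in every sample; ",
             "size factors are undefined")
    logc <- log(counts[pos, , drop = FALSE])
    logGeo <- rowMeans(logc)
    factors <- apply(exp(logc - logGeo), 2, median)
    setNames(factors, colnames(counts))
}

# Binned method-of-moments dispersion: genes are grouped into
# equal-occupancy bins by overall normalized mean; within each bin the
# dispersion is estimated from the pooled excess of within-condition
# variance over the mean, using a bias-corrected estimate of mu^2.
.binnedDispersion <- function(norm, condition, nBins = 20L) {
    lev <- levels(condition)
    n1 <- sum(condition == lev[1]); n2 <- sum(condition == lev[2])
    m1 <- rowMeans(norm[, condition == lev[1], drop = FALSE])
    m2 <- rowMeans(norm[, condition == lev[2], drop = FALSE])
    v1 <- apply(norm[, condition == lev[1], drop = FALSE], 1, var)
    v2 <- apply(norm[, condition == lev[2], drop = FALSE], 1, var)
    pooledVar <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    mu <- (n1 * m1 + n2 * m2) / (n1 + n2)
    # E[xbar^2] = mu^2 + Var/n, so subtract the within-group variance share
    mu2 <- pmax((m1^2 - v1 / n1 + m2^2 - v2 / n2) / 2, 1e-8)
    nGenes <- nrow(norm)
    nBins <- max(1L, min(nBins, nGenes %/% 50L + 1L))
    bin <- ceiling(rank(mu, ties.method = "first") / nGenes * nBins)
    disp <- numeric(nGenes)
    for (b in seq_len(nBins)) {
        idx <- bin == b
        est <- (mean(pooledVar[idx]) - mean(mu[idx])) / mean(mu2[idx])
        disp[idx] <- max(est, 1e-8)
    }
    disp
}

#' Negative-binomial Wald test for two-condition differential expression
#'
#' A self-contained two-group test on count data: counts are normalized by
#' \code{\link{medianRatioFactors}}; the per-gene effect is
#' \code{log2((meanTreated + pseudocount) / (meanControl + pseudocount))}
#' on normalized counts; gene-wise negative-binomial dispersions are
#' estimated by method of moments pooled across genes in similar-mean
#' bins; and the Wald statistic divides the log2 fold change by its
#' delta-method standard error, with a two-sided normal p-value.
#'
#' @param counts nonnegative integer matrix (genes x samples) or a
#'   \code{SummarizedExperiment} with a \code{counts} assay and a
#'   \code{condition} column.
#' @param condition factor with two levels, reference (control) first;
#'   taken from \code{colData} when \code{counts} is a
#'   \code{SummarizedExperiment}. At least 2 samples per level.
#' @param pseudocount added to both arm means for fold-change stability on
#'   zeros (default 1 normalized count).
#' @return a \code{\link[S4Vectors]{DataFrame}} with per-gene columns
#'   \code{baseMean}, \code{log2fc}, \code{se}, \code{stat}, \code{p}.
#' @seealso \code{\link{degTable}} for BH adjustment and up/down calls.
#' @export
nbWaldTest <- function(counts, condition = NULL, pseudocount = 1) {
    if (is(counts, "SummarizedExperiment")) {
        if (is.null(condition)) condition <- counts$condition
        counts <- assay(counts, "counts")
    }
    counts <- as.matrix(counts)
    condition <- droplevels(as.factor(condition))
    if (nlevels(condition) != 2L)
        stop("condition must have exactly two levels")
    if (any(table(condition) < 2L))
        stop("each condition needs at least 2 replicates")
    sf <- medianRatioFactors(counts)
    norm <- sweep(counts, 2, sf, "/")
    lev <- levels(condition)
    ctrl <- condition == lev[1]; trt <- condition == lev[2]
    mC <- rowMeans(norm[, ctrl, drop = FALSE])
    mT <- rowMeans(norm[, trt, drop = FALSE])
    log2fc <- log2((mT + pseudocount) / (mC + pseudocount))
    disp <- .binnedDispersion(norm, condition)
    nC <- sum(ctrl); nT <- sum(trt)
    varMeanC <- (mC + disp * mC^2) / nC
    varMeanT <- (mT + disp * mT^2) / nT
    se <- sqrt(varMeanT / (mT + pseudocount)^2 +
               varMeanC / (mC + pseudocount)^2) / log(2)
    stat <- ifelse(se > 0, log2fc / se, 0)
    p <- ifelse(se > 0, 2 * pnorm(-abs(stat)), 1)
    DataFrame(baseMean = (mC + mT) / 2, log2fc = log2fc, se = se,
              stat = stat, p = p, row.names = rownames(counts))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; values are monotone in rank
#' and capped at 1.
#'
#' @param pvals numeric p-values in [0, 1].
#' @return adjusted p-values of the same length.
#' @export
bhAdjust <- function(pvals) {
    if (anyNA(pvals) || any(pvals < 0 | pvals > 1))
        stop("p-values must lie in [0, 1]")
    p.adjust(pvals, method = "BH")
}

#' Differential-expression table with calls
#'
#' Runs \code{\link{nbWaldTest}}, adjusts p-values with
#' \code{\link{bhAdjust}}, and labels each gene \code{up} (log2FC >=
#' \code{lfc} and adjusted p <= \code{alpha}), \code{down} (log2FC <=
#' -\code{lfc}), or \code{ns}. Thresholds default to the conventional
#' |log2FC| >= 1 at FDR 0.05; both boundaries are inclusive.
#'
#' @inheritParams nbWaldTest
#' @param lfc log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return the \code{nbWaldTest} table plus \code{padj} and \code{call}.
#' @export
degTable <- function(counts, condition = NULL, pseudocount = 1,
                     lfc = 1, alpha = 0.05) {
    res <- nbWaldTest(counts, condition, pseudocount)
    res$padj <- bhAdjust(res$p)
    res$call <- ifelse(res$padj <= alpha & res$log2fc >= lfc, "up",
                ifelse(res$padj <= alpha & res$log2fc <= -lfc, "down",
                       "ns"))
    res
}

#' Call differentially expressed genes
#'
#' Applies the inclusive thresholds to a result table: up-regulated genes
#' satisfy log2FC >= \code{lfc} and adjusted p <= \code{alpha};
#' down-regulated genes are symmetric with log2FC <= -\code{lfc}.
#'
#' @param result a table with columns \code{log2fc} and \code{padj} and
#'   gene rownames (e.g. from \code{\link{degTable}}).
#' @inheritParams degTable
#' @return list with character vectors \code{up} and \code{down}.
#' @export
callDegs <- function(result, lfc = 1, alpha = 0.05) {
    if (is.null(result$padj)) stop("result must contain a padj column")
    genes <- rownames(result)
    list(up = genes[result$log2fc >= lfc & result$padj <= alpha],
         down = genes[result$log2fc <= -lfc & result$padj <= alpha])
}

#' Fragments per kilobase per million mapped reads
#'
#' \code{fpkm = count * 1e9 / (length * librarySize)}.
#'
#' @param counts count matrix or vector (genes x samples).
#' @param lengthsBp positive gene lengths in bp (recycled down rows).
#' @param librarySizes positive per-sample library sizes (recycled across
#'   columns).
#' @return FPKM values with the shape of \code{counts}.
#' @export
fpkm <- function(counts, lengthsBp, librarySizes) {
    if (any(lengthsBp <= 0)) stop("gene lengths must be positive")
    if (any(librarySizes <= 0)) stop("library sizes must be positive")
    if (is.matrix(counts)) {
        sweep(sweep(counts * 1e9, 1, lengthsBp, "/"), 2, librarySizes, "/")
    } else {
        counts * 1e9 / (lengthsBp * librarySizes)
    }
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' Fold change of a target transcript in treated vs control samples, each
#' normalized to a reference gene:
#' \code{2^-((ctTargetTreated - ctRefTreated) -
#' (ctTargetControl - ctRefControl))}.
#'
#' @param ctTargetTreated,ctRefTreated,ctRefControl,ctTargetControl finite
#'   Ct values (vectors are combined element-wise).
#' @return fold change(s).
#' @examples
#' ddctFoldChange(20, 15, 18, 15)  # 0.25
#' @export
ddctFoldChange <- function(ctTargetTreated, ctRefTreated,
                           ctTargetControl, ctRefControl) {
    ddct <- (ctTargetTreated - ctRefTreated) -
        (ctTargetControl - ctRefControl)
    2^(-ddct)
}
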