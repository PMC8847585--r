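# Promoter-window quantification of interval signal tracks.

# Length-weighted mean of track values over each window; bases not covered
# by the track count as zero signal. Windows and track are GRanges; the
# track carries a `score` column.
.trackWindowMean <- function(track, windows) {
    res <- numeric(length(windows))
    if (length(windows) == 0L) return(res)
    # seqlevels may legitimately differ (e.g. a mark profiled on a
    # subset of chromosomes); the callers warn about affected genes
    hits <- suppressWarnings(
        findOverlaps(windows, track, ignore.strand = TRUE))
    if (length(hits)) {
        ov <- pintersect(windows[queryHits(hits)],
                         track[subjectHits(hits)], ignore.strand = TRUE)
        contrib <- width(ov) * track$score[subjectHits(hits)]
        sums <- tapply(contrib, queryHits(hits), sum)
        res[as.integer(names(sums))] <- as.numeric(sums)
    }
    res / width(windows)
}

# Promoter windows (TSS +/- windowBp, strand-aware, clipped to chromosome
# bounds). Uses the BED-compatible convention: the TSS of a minus-strand
# gene is its rightmost base.
.promoterWindows <- function(annotation, windowBp) {
    if (windowBp <= 0) stop("window_bp must be positive")
    prom <- promoters(annotation, upstream = as.integer(windowBp),
                      downstream = as.integer(windowBp))
    suppressWarnings(trim(prom))
}

#' Per-gene promoter signal from an interval track
#'
#' Computes, for every gene, the length-weighted mean track value over the
#' strand-aware promoter window TSS +/- \code{windowBp} (clipped to
#' chromosome bounds when sequence lengths are known). Bases without track
#' coverage contribute zero signal; the denominator is always the clipped
#' window length, so values from spike-in-scaled tracks remain
#' depth-comparable across samples. Genes on chromosomes absent from the
#' track receive signal 0 with a warning.
#'
#' @param track \code{GRanges} with a numeric \code{score} column; sorted,
#'   non-overlapping records per chromosome (bedGraph semantics).
#' @param annotation named \code{GRanges} of gene models.
#' @param windowBp half-width of the promoter window in bp (default 3000,
#'   matching the composite-profile range of -3 kb to +3 kb).
#' @return named numeric vector of per-gene mean signal.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10000),
#'                              score = 2)
#' genes <- GenomicRanges::GRanges("chr1",
#'     IRanges::IRanges(5000, 6000), strand = "+")
#' names(genes) <- "g1"
#' promoterSignal(gr, genes, windowBp = 1000)  # g1 = 2
#' @export
promoterSignal <- function(track, annotation, windowBp = 3000) {
    windows <- .promoterWindows(annotation, windowBp)
    missing <- setdiff(unique(as.character(seqnames(annotation))),
                       unique(as.character(seqnames(track))))
    if (length(missing))
        warning("chromosome(s) absent from track, genes there get 0: ",
                paste(missing, collapse = ", "))
    setNames(.trackWindowMean(track, windows), names(annotation))
}

#' Composite (metagene) TSS profile
#'
#' Averages track signal over genes in \code{nBins} equal bins spanning
#' TSS +/- \code{flank}. Each gene contributes in transcriptional
#' orientation: bins of minus-strand genes are reversed before averaging,
#' so the profile runs 5' to 3' across the TSS for every gene.
#'
#' @param track \code{GRanges} signal track with a \code{score} column.
#' @param annotation named \code{GRanges} of gene models (non-empty).
#' @param flank half-width in bp (default 3000).
#' @param nBins even number of bins (default 120, i.e. 50-bp bins).
#' @return a \code{data.frame} with columns \code{offset} (bin center
#'   relative to the TSS, bp) and \code{mean} (mean signal), with
#'   attribute \code{nGenes}.
#' @export
metageneProfile <- function(track, annotation, flank = 3000, nBins = 120) {
    if (length(annotation) == 0L) stop("empty annotation")
    if (flank <= 0) stop("flank must be positive")
    nBins <- as.integer(nBins)
    if (nBins < 2L || nBins %% 2L != 0L) stop("nBins must be even and >= 2")
    windows <- .promoterWindows(annotation, flank)
    binW <- 2 * flank / nBins
    nGenes <- length(windows)
    # per-gene bins laid left-to-right in genome coordinates
    binStart <- rep(start(windows), each = nBins) +
        as.integer(round(rep(seq_len(nBins) - 1L, nGenes) * binW))
    binEnd <- rep(start(windows), each = nBins) +
        as.integer(round(rep(seq_len(nBins), nGenes) * binW)) - 1L
    bins <- GRanges(rep(as.character(seqnames(windows)), each = nBins),
                    IRanges(start = binStart, end = binEnd))
    vals <- matrix(.trackWindowMean(track, bins),
                   nrow = nGenes, ncol = nBins, byrow = TRUE)
    minus <- as.character(strand(annotation)) == "-"
    vals[minus, ] <- vals[minus, nBins:1, drop = FALSE]
    offsets <- -flank + (seq_len(nBins) - 0.5) * binW
    out <- data.frame(offset = offsets, mean = colMeans(vals))
    attr(out, "nGenes") <- nGenes
    out
}

#' Promoter CpG methylation level per gene
#'
#' Pools CpG read counts over each gene's promoter window and returns the
#' pooled beta value sum(methylated)/sum(total). Genes whose window
#' contains no CpG site get \code{NA} and are reported in the
#' \code{missing} attribute (and a warning).
#'
#' @param cpg \code{GRanges} of CpG sites with integer columns \code{meth}
#'   and \code{total} (\code{meth <= total} at every site), or a
#'   data.frame with columns \code{chrom}, \code{pos0} (0-based),
#'   \code{meth}, \code{total}.
#' @param annotation named \code{GRanges} of gene models.
#' @param windowBp promoter half-width in bp (default 3000).
#' @return named numeric vector of beta values in [0, 1], \code{NA} where
#'   no CpG falls in the window; attribute \code{missing} lists such genes.
#' @export
methylationLevel <- function(cpg, annotation, windowBp = 3000) {
    if (is.data.frame(cpg)) {
        cpg <- GRanges(cpg$chrom,
                       IRanges(start = cpg$pos0 + 1L, width = 1L),
                       meth = cpg$meth, total = cpg$total)
    }
    bad <- which(cpg$meth > cpg$total)
    if (length(bad))
        stop("methylated count exceeds total at site(s): ",
             paste0(as.character(seqnames(cpg))[bad[1]], ":",
                    start(cpg)[bad[1]] - 1L),
             if (length(bad) > 1) paste0(" (and ", length(bad) - 1, " more)"))
    windows <- .promoterWindows(annotation, windowBp)
    hits <- findOverlaps(windows, cpg, ignore.strand = TRUE)
    meth <- total <- numeric(length(windows))
    if (length(hits)) {
        ms <- tapply(cpg$meth[subjectHits(hits)], queryHits(hits), sum)
        ts <- tapply(cpg$total[subjectHits(hits)], queryHits(hits), sum)
        meth[as.integer(names(ms))] <- as.numeric(ms)
        total[as.integer(names(ts))] <- as.numeric(ts)
    }
    beta <- ifelse(total > 0, meth / total, NA_real_)
    names(beta) <- names(annotation)
    missing <- names(annotation)[total == 0]
    if (length(missing))
        warning(length(missing), " gene(s) with no CpG in the promoter ",
                "window: ", paste(utils::head(missing, 5), collapse = ", "),
                if (length(missing) > 5) " ...")
    attr(beta, "missing") <- missing
    beta
}
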