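# Shared fixtures: small configurations and hand-built tracks.

smallConfig <- function(seed = 1, ...) {
    synthConfig(nGenes = 300, cohortN = 100, seed = seed, ...)
}

# a flat signal track covering [1, len] on one chromosome
constantTrack <- function(value, chrom = "chr1", len = 2e4) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(1, len), score = value)
}

# single plus-strand gene with TSS at `tss0` (0-based)
singleGene <- function(tss0 = 10000, width = 2000, strand = "+",
                       chrom = "chr1", chromLen = 1e5) {
    if (strand == "+") {
        gr <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(tss0 + 1, tss0 + width),
            strand = strand)
    } else {
        gr <- GenomicRanges::GRanges(
            chrom, IRanges::IRanges(tss0 + 1 - width + 1, tss0 + 1),
            strand = strand)
    }
    GenomeInfoDb::seqlengths(gr) <- stats::setNames(chromLen, chrom)
    names(gr) <- "g1"
    gr
}

# brute-force per-base-pair oracle for promoter window means:
# expand the track to a per-base vector and average over the clipped
# window, counting uncovered bases as zero
bruteForceWindowMean <- function(track, gene, windowBp, chromLen) {
    sig <- numeric(chromLen)
    for (i in seq_along(track)) {
        idx <- GenomicRanges::start(track)[i]:GenomicRanges::end(track)[i]
        sig[idx[idx >= 1 & idx <= chromLen]] <- track$score[i]
    }
    tss0 <- if (as.character(GenomicRanges::strand(gene)) == "+")
        GenomicRanges::start(gene) - 1L else GenomicRanges::end(gene) - 1L
    if (as.character(GenomicRanges::strand(gene)) == "+") {
        lo0 <- tss0 - windowBp; hi0 <- tss0 + windowBp - 1L
    } else {
        lo0 <- tss0 - windowBp + 1L; hi0 <- tss0 + windowBp
    }
    lo <- max(lo0 + 1L, 1L); hi <- min(hi0 + 1L, chromLen)
    mean(sig[lo:hi])
}
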