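#' @importFrom GenomicRanges GRanges mcols mcols<- strand start end width
#'   findOverlaps pintersect promoters trim
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqnames seqlengths seqlengths<- seqlevels
#' @importFrom S4Vectors queryHits subjectHits metadata metadata<- DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom stats rnorm rbinom rpois rnbinom runif median quantile
#'   setNames sd complete.cases plogis qlogis
NULL

# Archetype promoter profiles: mark levels (arbitrary depth-normalized
# units) and CpG methylation beta. prc2_target is bivalent: high H3K27me3
# with moderate H3K4me3 and closed chromatin.
.ARCHETYPE_PROFILE <- rbind(
    baseline    = c(h3k27me3 = 1.0, h3k4me3 = 3.5, atac = 4.5, meth = 0.45),
    methylated  = c(h3k27me3 = 1.0, h3k4me3 = 0.8, atac = 0.8, meth = 0.85),
    quiescent   = c(h3k27me3 = 0.5, h3k4me3 = 0.3, atac = 0.3, meth = 0.05),
    active      = c(h3k27me3 = 1.0, h3k4me3 = 8.0, atac = 8.0, meth = 0.10),
    prc2_target = c(h3k27me3 = 8.0, h3k4me3 = 4.0, atac = 1.5, meth = 0.15)
)

.PROMOTER_FLANK <- 3000L   # bp painted around each TSS
.TRACK_BIN <- 50L          # bedGraph bin width (bp)

# Deterministic sub-seed for a named stream, derived from the master seed.
# Horner hash over UTF-8 codes; all intermediates < 2^53 so doubles are
# exact, result kept below 2^31 for set.seed().
.subSeed <- function(seed, name) {
    h <- 7
    for (code in utf8ToInt(name)) h <- (h * 131 + code) %% 2147483629
    as.integer((h + as.numeric(seed)) %% 2147483629)
}

.withSeed <- function(seed, expr) {
    old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
    on.exit({
        if (is.null(old)) {
            if (exists(".Random.seed", globalenv()))
                rm(".Random.seed", envir = globalenv())
        } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
    expr
}

#' Build a synthetic-study configuration
#'
#' Returns a validated \code{\linkS4class{SynthConfig}}. Defaults describe
#' the package's reference benchmark: 2000 genes in five epigenetic
#' archetypes, triplicate control/treated RNA libraries with
#' negative-binomial counts, a +2 log2FC treatment effect on the
#' PRC2-target archetype, and a 498-sample validation cohort whose marker
#' gene anti-correlates (r = -0.8) with PRC2-target expression.
#'
#' @param nGenes number of genes.
#' @param chromSizes named vector of chromosome lengths (bp).
#' @param archetypeFractions named proportions over
#'   \code{baseline, methylated, quiescent, active, prc2_target}.
#' @param effectLog2FC treatment effect (log2FC) on the PRC2-target
#'   archetype.
#' @param nbDispersion negative-binomial dispersion.
#' @param meanCount mean baseline count.
#' @param nReplicates replicates per arm.
#' @param spikeinDepths expected spike-in depths per library (recycled).
#' @param cohortN cohort size.
#' @param cohortCor marker-vs-PRC2-target correlation target.
#' @param signalNoise lognormal signal noise (sdlog); 0 = noise-free.
#' @param seed master seed.
#' @return a \code{SynthConfig}.
#' @examples
#' cfg <- synthConfig(nGenes = 100, seed = 1)
#' @export
synthConfig <- function(nGenes = 2000,
                        chromSizes = c(chrS1 = 6e6, chrS2 = 6e6,
                                       chrS3 = 6e6, chrS4 = 6e6),
                        archetypeFractions = c(baseline = 0.35,
                                               methylated = 0.15,
                                               quiescent = 0.15,
                                               active = 0.20,
                                               prc2_target = 0.15),
                        effectLog2FC = 2,
                        nbDispersion = 0.05,
                        meanCount = 200,
                        nReplicates = 3,
                        spikeinDepths = c(100000, 90000, 50000, 45000),
                        cohortN = 498,
                        cohortCor = -0.8,
                        signalNoise = 0.3,
                        seed = 42) {
    new("SynthConfig",
        nGenes = as.integer(nGenes),
        chromSizes = chromSizes,
        archetypeFractions = archetypeFractions,
        effectLog2FC = effectLog2FC,
        nbDispersion = nbDispersion,
        meanCount = meanCount,
        nReplicates = as.integer(nReplicates),
        spikeinDepths = spikeinDepths,
        cohortN = as.integer(cohortN),
        cohortCor = cohortCor,
        signalNoise = signalNoise,
        seed = as.integer(seed))
}

#' Simulate gene models with ground-truth archetypes
#'
#' Places \code{nGenes} non-overlapping genes (with at least 3 kb clear on
#' each side, so promoter windows never collide) on the configured
#' chromosomes, assigns strands at random, and attaches the ground-truth
#' archetype label to \code{mcols()$archetype}. Coordinates follow the
#' usual 1-based \code{GRanges} convention and export losslessly to
#' 0-based half-open BED.
#'
#' @param config a \code{\linkS4class{SynthConfig}}.
#' @return a named \code{GRanges} with seqlengths set and metadata columns
#'   \code{archetype} and \code{gene_id}.
#' @examples
#' genes <- simulateGenes(synthConfig(nGenes = 50, seed = 1))
#' @export
simulateGenes <- function(config) {
    stopifnot(is(config, "SynthConfig"))
    nGenes <- config@nGenes
    sizes <- config@chromSizes
    if (nGenes == 0L) {
        gr <- GRanges(seqlengths = sizes)
        names(gr) <- character()
        gr$archetype <- factor(character(), levels = .ARCHETYPES)
        gr$gene_id <- character()
        return(gr)
    }
    .withSeed(.subSeed(config@seed, "genes"), {
        maxGeneLen <- 3000L
        slotMin <- maxGeneLen + 2L * .PROMOTER_FLANK + 2L
        # genes per chromosome, proportional to length
        alloc <- floor(nGenes * sizes / sum(sizes))
        rem <- nGenes - sum(alloc)
        if (rem > 0)
            alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1
        chrom <- character(0); gstart <- integer(0); glen <- integer(0)
        for (chr in names(sizes)) {
            nc <- alloc[[chr]]
            if (nc == 0) next
            slotW <- floor(sizes[[chr]] / nc)
            if (slotW < slotMin)
                stop("cannot place ", nc, " genes with 3 kb flanks on ",
                     chr, " (length ", sizes[[chr]], ")")
            len <- as.integer(round(runif(nc, 1000, maxGeneLen)))
            jitterMax <- slotW - len - 2L * .PROMOTER_FLANK
            jit <- as.integer(floor(runif(nc, 0, jitterMax)))
            chrom <- c(chrom, rep(chr, nc))
            gstart <- c(gstart,
                        as.integer((seq_len(nc) - 1L) * slotW +
                                   .PROMOTER_FLANK + 1L + jit))
            glen <- c(glen, len)
        }
        strand <- sample(c("+", "-"), nGenes, replace = TRUE)
        # archetype assignment: deterministic counts from fractions,
        # then a seeded shuffle over genes
        frac <- config@archetypeFractions[.ARCHETYPES]
        counts <- floor(frac * nGenes)
        short <- nGenes - sum(counts)
        if (short > 0) {
            extra <- order(frac * nGenes - counts, decreasing = TRUE)
            counts[extra[seq_len(short)]] <- counts[extra[seq_len(short)]] + 1
        }
        labels <- sample(rep(.ARCHETYPES, times = counts))
        ids <- sprintf("gene%04d", seq_len(nGenes))
        gr <- GRanges(chrom, IRanges(start = gstart, width = glen),
                      strand = strand, seqlengths = sizes)
        names(gr) <- ids
        gr$archetype <- factor(labels, levels = .ARCHETYPES)
        gr$gene_id <- ids
        sort(gr, ignore.strand = TRUE)
    })
}

# lognormal multiplicative noise; exact archetype mean when sdlog = 0
.noisy <- function(mu, n, sdlog) {
    if (sdlog == 0) rep(mu, n) else mu * exp(rnorm(n, 0, sdlog))
}

#' Simulate promoter chromatin tracks and CpG methylation
#'
#' Paints each gene's promoter window (TSS +/- 3 kb) with 50-bp bedGraph
#' bins at its archetype's mark level (H3K27me3, H3K4me3, ATAC), with
#' per-gene and per-bin lognormal noise, and simulates CpG sites in the
#' same windows with binomial methylated/total read counts around the
#' archetype's methylation beta (logit-normal gene-level noise). With
#' \code{signalNoise = 0} every promoter bin equals the archetype mean
#' exactly. Tracks are sorted and non-overlapping.
#'
#' @param genes gene models from \code{\link{simulateGenes}}.
#' @param truth named archetype labels per gene (defaults to the
#'   \code{archetype} column of \code{genes}).
#' @param config the \code{SynthConfig}.
#' @return list with \code{tracks} (named list of \code{GRanges} with a
#'   \code{score} column, one per mark) and \code{cpg} (\code{GRanges}
#'   with \code{meth} and \code{total}).
#' @export
simulateMultiOmics <- function(genes, truth = NULL, config) {
    stopifnot(is(config, "SynthConfig"))
    if (is.null(truth))
        truth <- setNames(as.character(genes$archetype), names(genes))
    if (!all(names(genes) %in% names(truth)))
        stop("every annotated gene needs a ground-truth label")
    truth <- truth[names(genes)]
    bad <- setdiff(unique(truth), .ARCHETYPES)
    if (length(bad))
        stop("unknown archetype label(s): ", paste(bad, collapse = ", "))
    nGenes <- length(genes)
    prom <- promoters(genes, upstream = .PROMOTER_FLANK,
                      downstream = .PROMOTER_FLANK)
    nBins <- as.integer(2L * .PROMOTER_FLANK / .TRACK_BIN)
    sn <- config@signalNoise

    tracks <- list()
    for (mark in c("h3k27me3", "h3k4me3", "atac")) {
        scores <- .withSeed(.subSeed(config@seed, paste0("track_", mark)), {
            mu <- unname(.ARCHETYPE_PROFILE[truth, mark])
            geneLevel <- if (sn == 0) mu else mu * exp(rnorm(nGenes, 0, sn))
            binNoise <- if (sn == 0) 1 else
                exp(rnorm(nGenes * nBins, 0, sn / 2))
            rep(geneLevel, each = nBins) * binNoise
        })
        if (nGenes == 0L) {
            tracks[[mark]] <- GRanges(seqlengths = config@chromSizes,
                                      score = numeric())
            next
        }
        binStart <- rep(start(prom), each = nBins) +
            rep(seq_len(nBins) - 1L, nGenes) * .TRACK_BIN
        gr <- GRanges(rep(as.character(seqnames(prom)), each = nBins),
                      IRanges(start = binStart, width = .TRACK_BIN),
                      score = scores, seqlengths = config@chromSizes)
        tracks[[mark]] <- sort(gr)
    }

    cpg <- .withSeed(.subSeed(config@seed, "methylation"), {
        sitesPerGene <- as.integer(2L * .PROMOTER_FLANK / 75L)
        mu <- unname(.ARCHETYPE_PROFILE[truth, "meth"])
        beta <- if (sn == 0) mu else plogis(qlogis(mu) + rnorm(nGenes, 0, sn))
        if (nGenes == 0L) {
            GRanges(seqlengths = config@chromSizes,
                    meth = integer(), total = integer())
        } else {
            pos <- rep(start(prom), each = sitesPerGene) +
                rep(seq_len(sitesPerGene) - 1L, nGenes) * 75L
            total <- rpois(nGenes * sitesPerGene, 20) + 1L
            meth <- rbinom(nGenes * sitesPerGene, total,
                           rep(beta, each = sitesPerGene))
            gr <- GRanges(rep(as.character(seqnames(prom)),
                              each = sitesPerGene),
                          IRanges(start = pos, width = 1L),
                          meth = meth, total = total,
                          seqlengths = config@chromSizes)
            sort(gr)
        }
    })
    list(tracks = tracks, cpg = cpg)
}

#' Simulate control/treated RNA count matrices with spike-in libraries
#'
#' Draws negative-binomial counts for \code{nReplicates} control and
#' treated libraries. Per-gene baseline means are lognormal around
#' \code{meanCount}; the treated mean of \code{prc2_target} genes is
#' multiplied by \code{2^effectLog2FC}, all other archetypes are null.
#' Spike-in library sizes are Poisson around the configured depths
#' (recycled over samples).
#'
#' @inheritParams simulateMultiOmics
#' @return a \code{SummarizedExperiment} (assay \code{counts}) with
#'   \code{colData} column \code{condition} and a
#'   \code{\linkS4class{SpikeInStats}} in \code{metadata()$spikein}.
#' @export
simulateCounts <- function(genes, truth = NULL, config) {
    stopifnot(is(config, "SynthConfig"))
    if (config@nReplicates < 2L)
        stop("need at least 2 replicates per arm")
    if (config@nbDispersion < 0 || config@meanCount <= 0)
        stop("nbDispersion must be >= 0 and meanCount > 0")
    if (is.null(truth))
        truth <- setNames(as.character(genes$archetype), names(genes))
    truth <- truth[names(genes)]
    nGenes <- length(genes)
    nRep <- config@nReplicates
    .withSeed(.subSeed(config@seed, "counts"), {
        baseMu <- config@meanCount * exp(rnorm(nGenes, 0, 0.7))
        fcMult <- ifelse(truth == "prc2_target",
                         2 ^ config@effectLog2FC, 1)
        mus <- cbind(matrix(rep(baseMu, nRep), ncol = nRep),
                     matrix(rep(baseMu * fcMult, nRep), ncol = nRep))
        counts <- if (config@nbDispersion == 0)
            matrix(rpois(length(mus), mus), nrow = nGenes)
        else
            matrix(rnbinom(length(mus), mu = mus,
                           size = 1 / config@nbDispersion), nrow = nGenes)
        sampleIds <- c(sprintf("ctrl_%d", seq_len(nRep)),
                       sprintf("trt_%d", seq_len(nRep)))
        dimnames(counts) <- list(names(genes), sampleIds)
        depths <- rep_len(config@spikeinDepths, 2L * nRep)
        umd <- rpois(2L * nRep, depths)
        stats <- spikeInStats(sampleIds, umd, colSums(counts))
        se <- SummarizedExperiment(
            assays = list(counts = counts),
            colData = DataFrame(
                condition = factor(rep(c("control", "treated"),
                                       each = nRep),
                                   levels = c("control", "treated")),
                row.names = sampleIds))
        metadata(se)$spikein <- stats
        se
    })
}

#' Simulate a validation cohort with an anti-correlated marker gene
#'
#' Generates a samples x genes log2(RPM) expression matrix in which a
#' designated marker gene ("EZH2", an EZH2 analog) is driven by a latent
#' repressor-activity factor shared, with opposite sign, by the
#' \code{prc2_target} genes, so that marker expression anti-correlates with
#' mean PRC2-target expression at the configured strength.
#'
#' @param truth named archetype labels per gene.
#' @param config the \code{SynthConfig}.
#' @return a \code{\linkS4class{CohortMatrix}}.
#' @export
simulateCohort <- function(truth, config) {
    stopifnot(is(config, "SynthConfig"))
    n <- config@cohortN
    if (n < 8L) stop("cohortN must be >= 8 for quartile stratification")
    geneIds <- names(truth)
    .withSeed(.subSeed(config@seed, "cohort"), {
        u <- rnorm(n)                      # latent PRC2-activity-low factor
        r <- config@cohortCor
        marker <- 4 + r * u + sqrt(max(0, 1 - r^2)) * rnorm(n)
        nGenes <- length(geneIds)
        baseMu <- rnorm(nGenes, 4, 1)
        loading <- ifelse(truth == "prc2_target", 1.5, 0)
        expr <- matrix(rep(baseMu, each = n), nrow = n) +
            outer(u, loading) + matrix(rnorm(n * nGenes, 0, 0.5), nrow = n)
        colnames(expr) <- geneIds
        expr <- cbind(expr, EZH2 = marker)
        rownames(expr) <- sprintf("sample%03d", seq_len(n))
        new("CohortMatrix", expr = expr, marker = "EZH2")
    })
}

#' Simulate a complete multi-omics study
#'
#' Runs \code{\link{simulateGenes}}, \code{\link{simulateMultiOmics}},
#' \code{\link{simulateCounts}} and \code{\link{simulateCohort}} under one
#' configuration and bundles the results. Each component draws from its
#' own named sub-stream of the master seed, so results do not depend on
#' the order in which generators are invoked.
#'
#' @param config a \code{\linkS4class{SynthConfig}}.
#' @return a \code{\linkS4class{PrcSimulation}}.
#' @examples
#' sim <- simulateStudy(synthConfig(nGenes = 100, cohortN = 50, seed = 7))
#' sim
#' @export
simulateStudy <- function(config = synthConfig()) {
    genes <- simulateGenes(config)
    truth <- setNames(as.character(genes$archetype), names(genes))
    omics <- simulateMultiOmics(genes, truth, config)
    counts <- simulateCounts(genes, truth, config)
    cohort <- simulateCohort(truth, config)
    new("PrcSimulation", genes = genes, tracks = omics$tracks,
        cpg = omics$cpg, counts = counts, cohort = cohort,
        config = config)
}
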