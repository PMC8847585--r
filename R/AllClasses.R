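#' @import methods
NULL

#' Configuration for the synthetic multi-omics study generator
#'
#' A validated parameter object describing the simulated study: number of
#' genes, chromosome sizes, the mixing proportions of the five epigenetic
#' gene archetypes, the treatment effect on the PRC2-target archetype,
#' negative-binomial count parameters, spike-in library depths, the
#' validation-cohort size and marker correlation, and the master seed.
#'
#' Archetypes are \code{baseline}, \code{methylated}, \code{quiescent},
#' \code{active} and \code{prc2_target}; the last carries high promoter
#' H3K27me3 with moderate H3K4me3 (a bivalent profile) and is up-regulated
#' by \code{effectLog2FC} under treatment.
#'
#' @slot nGenes number of genes to simulate.
#' @slot chromSizes named integer-like vector of chromosome lengths (bp).
#' @slot archetypeFractions named proportions over the five archetypes,
#'   summing to 1.
#' @slot effectLog2FC mean treatment-induced log2 fold change of the
#'   \code{prc2_target} archetype.
#' @slot nbDispersion negative-binomial dispersion of simulated counts.
#' @slot meanCount mean baseline expression count.
#' @slot nReplicates replicates per treatment arm.
#' @slot spikeinDepths expected spike-in (exogenous genome) read depths,
#'   recycled over samples.
#' @slot cohortN number of samples in the validation cohort.
#' @slot cohortCor target Pearson correlation between the cohort marker
#'   gene and the mean expression of \code{prc2_target} genes (negative
#'   for an EZH2-like repressor).
#' @slot signalNoise lognormal noise (sdlog) applied to promoter signal
#'   levels and, on the logit scale, to methylation; 0 gives noise-free
#'   archetype means.
#' @slot seed master seed from which all named sub-streams are derived.
#' @export
setClass("SynthConfig", representation(
    nGenes = "integer",
    chromSizes = "numeric",
    archetypeFractions = "numeric",
    effectLog2FC = "numeric",
    nbDispersion = "numeric",
    meanCount = "numeric",
    nReplicates = "integer",
    spikeinDepths = "numeric",
    cohortN = "integer",
    cohortCor = "numeric",
    signalNoise = "numeric",
    seed = "integer"
))

.ARCHETYPES <- c("baseline", "methylated", "quiescent", "active",
                 "prc2_target")

setValidity("SynthConfig", function(object) {
    msg <- character()
    if (length(object@nGenes) != 1L || object@nGenes < 0L)
        msg <- c(msg, "nGenes must be a single nonnegative integer")
    if (is.null(names(object@chromSizes)) || any(object@chromSizes <= 0))
        msg <- c(msg, "chromSizes must be a named vector of positive lengths")
    af <- object@archetypeFractions
    if (!setequal(names(af), .ARCHETYPES))
        msg <- c(msg, paste("archetypeFractions must be named by:",
                            paste(.ARCHETYPES, collapse = ", ")))
    if (abs(sum(af) - 1) > 1e-9)
        msg <- c(msg, "archetypeFractions must sum to 1 (within 1e-9)")
    if (any(af < 0)) msg <- c(msg, "archetypeFractions must be nonnegative")
    if (object@nbDispersion < 0)
        msg <- c(msg, "nbDispersion must be nonnegative")
    if (object@meanCount <= 0) msg <- c(msg, "meanCount must be positive")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (any(object@spikeinDepths <= 0))
        msg <- c(msg, "spikeinDepths must be positive")
    if (object@cohortN < 0L) msg <- c(msg, "cohortN must be nonnegative")
    if (abs(object@cohortCor) > 1)
        msg <- c(msg, "cohortCor must lie in [-1, 1]")
    if (object@signalNoise < 0) msg <- c(msg, "signalNoise must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Per-sample spike-in library statistics
#'
#' Holds, for each sequencing library, the number of reads uniquely matched
#' to the exogenous spike-in genome after duplicate removal (\code{umd}),
#' the reads matched to the target genome before scaling (\code{oh}), the
#' derived standardization factor \code{sf = min(umd)/umd}, and the
#' normalized target count \code{nh = sf * oh}. The sample with the
#' smallest spike-in library has \code{sf = 1}; all other libraries are
#' scaled down to it, so that global loss of a chromatin mark remains
#' visible after normalization.
#'
#' @slot sampleId character sample identifiers.
#' @slot umd spike-in matched read counts (positive).
#' @slot oh target-genome matched read counts before scaling.
#' @slot sf standardization factors in (0, 1].
#' @slot nh normalized target counts.
#' @export
setClass("SpikeInStats", representation(
    sampleId = "character",
    umd = "numeric",
    oh = "numeric",
    sf = "numeric",
    nh = "numeric"
))

setValidity("SpikeInStats", function(object) {
    n <- length(object@sampleId)
    if (length(object@umd) != n || length(object@oh) != n ||
        length(object@sf) != n || length(object@nh) != n)
        return("all slots must have equal length")
    if (n == 0L) return(TRUE)
    if (any(object@umd <= 0)) return("umd counts must be positive")
    if (any(object@oh < 0)) return("oh counts must be nonnegative")
    if (max(abs(object@sf - min(object@umd) / object@umd)) > 1e-8)
        return("sf must equal min(umd)/umd")
    if (abs(max(object@sf) - 1) > 1e-12)
        return("the sample with minimal umd must have sf = 1")
    if (max(abs(object@nh - object@sf * object@oh)) > 1e-6)
        return("nh must equal sf * oh")
    TRUE
})

#' Per-gene multi-omic feature matrix for epigenetic typing
#'
#' Rows are genes; the clustering columns are expression log2 fold change,
#' promoter DNA-methylation beta, H3K4me3 promoter signal and ATAC promoter
#' signal. Promoter H3K27me3 is deliberately held out of clustering and
#' kept in a separate slot: it is used only afterwards, to identify which
#' cluster is the PRC2-target (H3K27me3-high) type. Genes with any missing
#' feature are dropped at construction and recorded in \code{dropped}.
#'
#' @slot features numeric matrix, genes x 4 clustering features.
#' @slot heldout named numeric, promoter H3K27me3 per gene.
#' @slot dropped gene ids removed for missing values.
#' @export
setClass("EpitypeFeatures", representation(
    features = "matrix",
    heldout = "numeric",
    dropped = "character"
))

.FEATURE_COLS <- c("expr_log2fc", "methylation", "h3k4me3", "atac")

setValidity("EpitypeFeatures", function(object) {
    f <- object@features
    if (!identical(colnames(f), .FEATURE_COLS))
        return(paste("feature columns must be:",
                     paste(.FEATURE_COLS, collapse = ", ")))
    if (is.null(rownames(f))) return("features must have gene rownames")
    if (anyNA(f)) return("features must contain no missing values")
    if (!identical(names(object@heldout), rownames(f)))
        return("heldout H3K27me3 must be named identically to feature rows")
    if (anyNA(object@heldout)) return("heldout values must not be missing")
    TRUE
})

#' Fitted k-means epigenetic typing model
#'
#' A k-means solution in z-scored feature space, together with the
#' silhouette model-selection table (when produced by \code{\link{selectK}})
#' and the semantic type map (when produced by \code{\link{assignTypes}}).
#' Inertia is the total within-cluster sum of squared distances.
#'
#' @slot k number of clusters.
#' @slot centers k x features centroid matrix in z-space.
#' @slot cluster named integer cluster assignment per gene.
#' @slot inertia total within-cluster sum of squares.
#' @slot trace inertia after each Lloyd iteration of the winning restart.
#' @slot nInit number of k-means++ restarts.
#' @slot seed RNG seed used for initialization.
#' @slot silhouette data.frame with columns k, silhouette, inertia
#'   (empty unless model selection was run).
#' @slot typeMap named character mapping cluster index to semantic label
#'   (empty until \code{assignTypes} is called).
#' @export
setClass("EpitypeModel", representation(
    k = "integer",
    centers = "matrix",
    cluster = "integer",
    inertia = "numeric",
    trace = "numeric",
    nInit = "integer",
    seed = "integer",
    silhouette = "data.frame",
    typeMap = "character"
))

setValidity("EpitypeModel", function(object) {
    if (nrow(object@centers) != object@k)
        return("centers must have k rows")
    if (is.null(names(object@cluster)))
        return("cluster assignments must be named by gene")
    if (any(object@cluster < 1L) || any(object@cluster > object@k))
        return("cluster indices must lie in 1..k")
    if (object@inertia < 0) return("inertia must be nonnegative")
    if (length(object@typeMap) &&
        sum(object@typeMap == "prc2_target") != 1L)
        return("exactly one cluster must be labeled prc2_target")
    TRUE
})

#' Gene signature from the type/DEG overlap
#'
#' The PRC2-target signature is the intersection of the genes assigned to
#' the H3K27me3-high type with the up-regulated differentially expressed
#' genes; counts record the Venn sizes (|A|, |B|, |A n B|).
#'
#' @slot typeGenes genes of the PRC2-target type.
#' @slot upDegs up-regulated DEGs.
#' @slot signature sorted intersection of the two.
#' @slot counts named integer vector (nType, nUp, nOverlap).
#' @export
setClass("SignatureResult", representation(
    typeGenes = "character",
    upDegs = "character",
    signature = "character",
    counts = "integer"
))

setValidity("SignatureResult", function(object) {
    if (!all(object@signature %in% object@typeGenes) ||
        !all(object@signature %in% object@upDegs))
        return("signature must be contained in both input lists")
    cnt <- object@counts
    if (!identical(names(cnt), c("nType", "nUp", "nOverlap")))
        return("counts must be named nType, nUp, nOverlap")
    if (cnt[["nType"]] != length(object@typeGenes) ||
        cnt[["nUp"]] != length(object@upDegs) ||
        cnt[["nOverlap"]] != length(object@signature))
        return("counts inconsistent with gene lists")
    TRUE
})

#' Cohort expression matrix with a designated marker gene
#'
#' Samples x genes expression on the log2(RPM) scale, plus the id of the
#' marker (regulator) gene used for quartile stratification.
#'
#' @slot expr numeric matrix, samples x genes, log2(RPM).
#' @slot marker marker gene id, present among the columns.
#' @export
setClass("CohortMatrix", representation(
    expr = "matrix",
    marker = "character"
))

setValidity("CohortMatrix", function(object) {
    if (is.null(rownames(object@expr)) || is.null(colnames(object@expr)))
        return("expr must have sample rownames and gene colnames")
    if (anyDuplicated(rownames(object@expr)))
        return("duplicate sample ids")
    if (anyDuplicated(colnames(object@expr)))
        return("duplicate gene ids")
    if (length(object@marker) != 1L ||
        !(object@marker %in% colnames(object@expr)))
        return("marker gene must be one of the expression columns")
    TRUE
})

#' Low/high quartile stratification of cohort samples
#'
#' Samples whose marker expression is at or below the 25th-percentile value
#' form the low group; those at or above the 75th-percentile value form the
#' high group (tie-inclusive, so group sizes can exceed n/4 exactly as in
#' tied real cohorts). Bounds record the two percentile values used.
#'
#' @slot marker marker gene id.
#' @slot lowIds sample ids of the low-marker group.
#' @slot highIds sample ids of the high-marker group.
#' @slot bounds numeric length 2: the 25th and 75th percentile values.
#' @export
setClass("QuartileSplit", representation(
    marker = "character",
    lowIds = "character",
    highIds = "character",
    bounds = "numeric"
))

setValidity("QuartileSplit", function(object) {
    if (length(intersect(object@lowIds, object@highIds)))
        return("low and high groups must be disjoint")
    if (length(object@lowIds) < 2L || length(object@highIds) < 2L)
        return("each group must contain at least 2 samples")
    if (length(object@bounds) != 2L || object@bounds[1] > object@bounds[2])
        return("bounds must be (q25, q75) with q25 <= q75")
    TRUE
})

#' A complete simulated multi-omics study
#'
#' Container returned by \code{\link{simulateStudy}}: gene models with
#' ground-truth archetypes, per-mark promoter signal tracks, a CpG
#' methylation table, treated/control RNA count matrices with spike-in
#' library statistics, and a validation cohort.
#'
#' @slot genes \code{GRanges} gene models; \code{mcols()$archetype} holds
#'   the ground-truth label.
#' @slot tracks named list of \code{GRanges} signal tracks
#'   (h3k27me3, h3k4me3, atac), each with a \code{score} column.
#' @slot cpg \code{GRanges} of CpG sites with \code{meth} and \code{total}
#'   read counts.
#' @slot counts \code{SummarizedExperiment} of RNA counts with a
#'   \code{condition} column (control/treated) and spike-in library
#'   statistics in its metadata.
#' @slot cohort \code{CohortMatrix} validation cohort.
#' @slot config the \code{SynthConfig} used.
#' @export
setClass("PrcSimulation", representation(
    genes = "GRanges",
    tracks = "list",
    cpg = "GRanges",
    counts = "SummarizedExperiment",
    cohort = "CohortMatrix",
    config = "SynthConfig"
))
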