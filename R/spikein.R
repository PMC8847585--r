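#' Spike-in standardization factors
#'
#' Computes the per-sample standardization factor from exogenous spike-in
#' read counts: each library's factor is the smallest spike-in count over
#' all samples divided by that library's own spike-in count,
#' \deqn{SF_i = \min(UMD_1, \ldots, UMD_n) / UMD_i,}
#' so the sample with the fewest spike-in reads keeps factor 1 and all
#' others are scaled down to it. Applying these factors equalizes the
#' spike-in-implied depth across libraries while preserving genuine global
#' differences in the target-genome signal (e.g. genome-wide H3K27me3 loss
#' after PRC2 inhibition).
#'
#' @param umd positive integer vector of spike-in matched read counts
#'   (unique reads matched to the exogenous genome, duplicates removed).
#' @return numeric vector of factors in (0, 1], with \code{max(sf) == 1}.
#' @examples
#' spikeInFactors(c(1000, 2000, 4000))  # 1.0 0.5 0.25
#' @export
spikeInFactors <- function(umd) {
    if (length(umd) == 0L) stop("no spike-in counts supplied")
    if (anyNA(umd) || any(umd <= 0))
        stop("spike-in counts must all be positive; scaling is undefined ",
             "for zero or negative counts")
    min(umd) / umd
}

#' Apply spike-in factors to target-genome counts
#'
#' Element-wise normalization \code{nh = sf * oh}; used for whole-library
#' read totals as well as per-gene or per-bin counts of the same sample.
#'
#' @param oh nonnegative target-genome counts.
#' @param sf factors from \code{\link{spikeInFactors}}, same length.
#' @return normalized counts.
#' @export
applySpikeIn <- function(oh, sf) {
    if (length(oh) != length(sf))
        stop("oh and sf must have the same length")
    if (anyNA(oh) || any(oh < 0)) stop("oh counts must be nonnegative")
    sf * oh
}

#' Construct per-sample spike-in library statistics
#'
#' Convenience constructor deriving factors and normalized counts from raw
#' spike-in and target-genome read counts.
#'
#' @param sampleId sample identifiers.
#' @param umd spike-in matched read counts (positive).
#' @param oh target-genome matched read counts.
#' @return a \code{\linkS4class{SpikeInStats}}.
#' @examples
#' spikeInStats(c("a", "b"), umd = c(1000, 2000), oh = c(5e6, 8e6))
#' @export
spikeInStats <- function(sampleId, umd, oh) {
    sf <- spikeInFactors(umd)
    new("SpikeInStats", sampleId = as.character(sampleId),
        umd = as.numeric(umd), oh = as.numeric(oh),
        sf = sf, nh = applySpikeIn(oh, sf))
}
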