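#' Quantify a simulated study into the clustering feature matrix
#'
#' Convenience wrapper running the quantification and differential-
#' expression stages on a \code{\linkS4class{PrcSimulation}}: promoter
#' signal for each mark, promoter methylation, and the NB Wald DE table,
#' assembled into an \code{\linkS4class{EpitypeFeatures}} (H3K27me3 held
#' out).
#'
#' @param sim a \code{\linkS4class{PrcSimulation}}.
#' @param windowBp promoter half-width (default 3000).
#' @param pseudocount DE pseudocount (default 1).
#' @param lfc,alpha DEG thresholds (defaults 1, 0.05).
#' @return list with \code{features} (\code{EpitypeFeatures}),
#'   \code{deg} (DE table), \code{degCalls} (up/down lists),
#'   \code{signal} (per-mark promoter signal) and \code{meth}.
#' @export
studyFeatures <- function(sim, windowBp = 3000, pseudocount = 1,
                          lfc = 1, alpha = 0.05) {
    signal <- lapply(sim@tracks, promoterSignal, annotation = sim@genes,
                     windowBp = windowBp)
    meth <- suppressWarnings(
        methylationLevel(sim@cpg, sim@genes, windowBp))
    deg <- degTable(sim@counts, pseudocount = pseudocount,
                    lfc = lfc, alpha = alpha)
    features <- suppressMessages(buildFeatureMatrix(
        log2fc = stats::setNames(deg$log2fc, rownames(deg)),
        methylation = meth,
        h3k4me3 = signal$h3k4me3,
        atac = signal$atac,
        h3k27me3 = signal$h3k27me3))
    list(features = features, deg = deg,
         degCalls = callDegs(deg, lfc, alpha),
         signal = signal, meth = meth)
}
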