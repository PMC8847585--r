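# Accessors and show methods for the package's S4 containers.

#' @rdname SpikeInStats-class
#' @export
setMethod("scaleFactors", "SpikeInStats", function(object) {
    stats::setNames(object@sf, object@sampleId)
})

#' @rdname SpikeInStats-class
#' @export
setMethod("normalizedCounts", "SpikeInStats", function(object) {
    stats::setNames(object@nh, object@sampleId)
})

#' Tabulate spike-in statistics
#'
#' @param x a \code{SpikeInStats}.
#' @param ... unused.
#' @return a \code{data.frame} with one row per sample.
#' @export
as.data.frame.SpikeInStats <- function(x, ...) {
    data.frame(sample_id = x@sampleId, umd = x@umd, oh = x@oh,
               sf = x@sf, nh = x@nh, row.names = NULL)
}

setMethod("show", "SpikeInStats", function(object) {
    cat("SpikeInStats with", length(object@sampleId), "samples\n")
    print(as.data.frame.SpikeInStats(object))
})

#' @rdname EpitypeModel-class
#' @export
setMethod("clusterAssignments", "EpitypeModel",
          function(object) object@cluster)

#' @rdname EpitypeModel-class
#' @export
setMethod("typeMap", "EpitypeModel", function(object) object@typeMap)

#' @rdname EpitypeModel-class
#' @export
setMethod("silhouetteTable", "EpitypeModel",
          function(object) object@silhouette)

setMethod("show", "EpitypeModel", function(object) {
    cat("EpitypeModel: k =", object@k, "over",
        length(object@cluster), "genes; inertia =",
        format(object@inertia, digits = 6), "\n")
    tab <- table(object@cluster)
    lab <- if (length(object@typeMap))
        paste0(names(tab), " (", object@typeMap[names(tab)], ")")
    else names(tab)
    cat("cluster sizes:\n")
    print(stats::setNames(as.integer(tab), lab))
    if (nrow(object@silhouette)) {
        best <- object@silhouette$k[which.max(object@silhouette$silhouette)]
        cat("model selection: mean silhouette maximized at k =", best, "\n")
    }
})

#' @rdname SignatureResult-class
#' @export
setMethod("signatureGenes", "SignatureResult",
          function(object) object@signature)

#' @rdname SignatureResult-class
#' @export
setMethod("vennCounts", "SignatureResult", function(object) object@counts)

setMethod("show", "SignatureResult", function(object) {
    cnt <- object@counts
    cat("SignatureResult: |type| =", cnt[["nType"]],
        "|up-DEGs| =", cnt[["nUp"]],
        "|signature| =", cnt[["nOverlap"]], "\n")
})

#' @rdname CohortMatrix-class
#' @export
setMethod("cohortExpr", "CohortMatrix", function(object) object@expr)

#' @rdname CohortMatrix-class
#' @export
setMethod("markerGene", "CohortMatrix", function(object) object@marker)

setMethod("show", "CohortMatrix", function(object) {
    cat("CohortMatrix:", nrow(object@expr), "samples x",
        ncol(object@expr), "genes (log2 RPM); marker =",
        object@marker, "\n")
})

#' @rdname QuartileSplit-class
#' @export
setMethod("lowGroup", "QuartileSplit", function(object) object@lowIds)

#' @rdname QuartileSplit-class
#' @export
setMethod("highGroup", "QuartileSplit", function(object) object@highIds)

setMethod("show", "QuartileSplit", function(object) {
    cat("QuartileSplit on", object@marker, ":",
        length(object@lowIds), "low /", length(object@highIds),
        "high samples; bounds = [",
        format(object@bounds[1], digits = 4), ",",
        format(object@bounds[2], digits = 4), "]\n")
})

#' @rdname PrcSimulation-class
#' @export
setMethod("archetypeTruth", "PrcSimulation", function(object) {
    truth <- as.character(object@genes$archetype)
    stats::setNames(truth, names(object@genes))
})

setMethod("show", "PrcSimulation", function(object) {
    cat("PrcSimulation:", length(object@genes), "genes on",
        length(unique(as.character(
            GenomeInfoDb::seqnames(object@genes)))), "chromosomes\n")
    cat("archetypes:\n")
    print(table(as.character(object@genes$archetype)))
    cat("tracks:", paste(names(object@tracks), collapse = ", "), "|",
        length(object@cpg), "CpG sites |",
        ncol(object@counts), "RNA libraries |",
        nrow(object@cohort@expr), "cohort samples\n")
})
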