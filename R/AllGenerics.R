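#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' @rdname SpikeInStats-class
#' @param object a \code{SpikeInStats}.
#' @export
setGeneric("scaleFactors", function(object) standardGeneric("scaleFactors"))

#' @rdname SpikeInStats-class
#' @export
setGeneric("normalizedCounts",
           function(object) standardGeneric("normalizedCounts"))

#' @rdname EpitypeModel-class
#' @param object an \code{EpitypeModel}.
#' @export
setGeneric("clusterAssignments",
           function(object) standardGeneric("clusterAssignments"))

#' @rdname EpitypeModel-class
#' @export
setGeneric("typeMap", function(object) standardGeneric("typeMap"))

#' @rdname EpitypeModel-class
#' @export
setGeneric("silhouetteTable",
           function(object) standardGeneric("silhouetteTable"))

#' @rdname SignatureResult-class
#' @param object a \code{SignatureResult}.
#' @export
setGeneric("signatureGenes",
           function(object) standardGeneric("signatureGenes"))

#' @rdname SignatureResult-class
#' @export
setGeneric("vennCounts", function(object) standardGeneric("vennCounts"))

#' @rdname CohortMatrix-class
#' @param object a \code{CohortMatrix}.
#' @export
setGeneric("cohortExpr", function(object) standardGeneric("cohortExpr"))

#' @rdname CohortMatrix-class
#' @export
setGeneric("markerGene", function(object) standardGeneric("markerGene"))

#' @rdname QuartileSplit-class
#' @param object a \code{QuartileSplit}.
#' @export
setGeneric("lowGroup", function(object) standardGeneric("lowGroup"))

#' @rdname QuartileSplit-class
#' @export
setGeneric("highGroup", function(object) standardGeneric("highGroup"))

#' @rdname PrcSimulation-class
#' @param object a \code{PrcSimulation}.
#' @export
setGeneric("archetypeTruth",
           function(object) standardGeneric("archetypeTruth"))
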