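# Accessor generics and methods; slot access stays internal.

#' @rdname PSSM-class
#' @param object,x a package object.
#' @export
setGeneric("pssmCounts", function(object) standardGeneric("pssmCounts"))
#' @rdname PSSM-class
#' @export
setMethod("pssmCounts", "PSSM", function(object) object@counts)

#' @rdname PSSM-class
#' @export
setGeneric("pssmWidth", function(object) standardGeneric("pssmWidth"))
#' @rdname PSSM-class
#' @export
setMethod("pssmWidth", "PSSM", function(object) ncol(object@counts))

#' @rdname PSSM-class
#' @export
setGeneric("matrixId", function(object) standardGeneric("matrixId"))
#' @rdname PSSM-class
#' @export
setMethod("matrixId", "PSSM", function(object) object@matrixId)

#' @rdname PSSM-class
#' @export
setGeneric("sourceGene", function(object) standardGeneric("sourceGene"))
#' @rdname PSSM-class
#' @export
setMethod("sourceGene", "PSSM", function(object) object@sourceGene)

#' @rdname PSSM-class
#' @export
setGeneric("pssmBackground", function(object) standardGeneric("pssmBackground"))
#' @rdname PSSM-class
#' @export
setMethod("pssmBackground", "PSSM", function(object) object@background)

#' Consensus sequence of a PSSM (most frequent base per column)
#' @param object a [PSSM-class].
#' @return character(1) consensus string.
#' @export
pssmConsensus <- function(object) {
  pr <- probMatrix(object)
  paste(DNA_BASES4[apply(pr, 2, which.max)], collapse = "")
}

# SyntheticWorld accessors ---------------------------------------------------

#' @rdname SyntheticWorld-class
#' @param object a [SyntheticWorld-class].
#' @export
setGeneric("worldGenes", function(object) standardGeneric("worldGenes"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldGenes", "SyntheticWorld", function(object) object@genes)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldPromoters", function(object) standardGeneric("worldPromoters"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldPromoters", "SyntheticWorld", function(object) object@promoters)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldTfs", function(object) standardGeneric("worldTfs"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldTfs", "SyntheticWorld", function(object) object@tfSet)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("truthNetwork", function(object) standardGeneric("truthNetwork"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("truthNetwork", "SyntheticWorld", function(object) object@truthNetwork)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("plantedSites", function(object) standardGeneric("plantedSites"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("plantedSites", "SyntheticWorld", function(object) object@plantedSites)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldMatrices", function(object) standardGeneric("worldMatrices"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldMatrices", "SyntheticWorld", function(object) object@matrices)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldMotifProbs", function(object) standardGeneric("worldMotifProbs"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldMotifProbs", "SyntheticWorld", function(object) object@motifProbs)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldProfiles", function(object) standardGeneric("worldProfiles"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldProfiles", "SyntheticWorld", function(object) object@profiles)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldKoMap", function(object) standardGeneric("worldKoMap"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldKoMap", "SyntheticWorld", function(object) object@koMap)

#' @rdname SyntheticWorld-class
#' @export
setGeneric("worldKoPathways", function(object) standardGeneric("worldKoPathways"))
#' @rdname SyntheticWorld-class
#' @export
setMethod("worldKoPathways", "SyntheticWorld", function(object) object@koPathways)

# RegNetwork accessors -------------------------------------------------------

#' @rdname RegNetwork-class
#' @param object a [RegNetwork-class].
#' @export
setGeneric("regEdges", function(object) standardGeneric("regEdges"))
#' @rdname RegNetwork-class
#' @export
setMethod("regEdges", "RegNetwork", function(object) object@edges)

#' @rdname RegNetwork-class
#' @export
setGeneric("regNodes", function(object) standardGeneric("regNodes"))
#' @rdname RegNetwork-class
#' @export
setMethod("regNodes", "RegNetwork", function(object)
  igraph::V(object@graph)$name)

#' @rdname RegNetwork-class
#' @export
setGeneric("regulators", function(object) standardGeneric("regulators"))
#' @rdname RegNetwork-class
#' @export
setMethod("regulators", "RegNetwork", function(object) {
  v <- igraph::V(object@graph)
  v$name[v$isRegulator]
})

#' @rdname RegNetwork-class
#' @export
setGeneric("regGraph", function(object) standardGeneric("regGraph"))
#' @rdname RegNetwork-class
#' @export
setMethod("regGraph", "RegNetwork", function(object) object@graph)

#' @rdname RegNetwork-class
#' @export
setGeneric("netCondition", function(object) standardGeneric("netCondition"))
#' @rdname RegNetwork-class
#' @export
setMethod("netCondition", "RegNetwork", function(object) object@condition)

# HierarchyResult accessors --------------------------------------------------

#' @rdname HierarchyResult-class
#' @param object a [HierarchyResult-class].
#' @export
setGeneric("hierLayers", function(object) standardGeneric("hierLayers"))
#' @rdname HierarchyResult-class
#' @export
setMethod("hierLayers", "HierarchyResult", function(object) object@layers)

#' @rdname HierarchyResult-class
#' @export
setGeneric("bottomUpFraction", function(object) standardGeneric("bottomUpFraction"))
#' @rdname HierarchyResult-class
#' @export
setMethod("bottomUpFraction", "HierarchyResult",
          function(object) object@bottomUpFraction)

#' @rdname HierarchyResult-class
#' @export
setGeneric("removedBottomUp", function(object) standardGeneric("removedBottomUp"))
#' @rdname HierarchyResult-class
#' @export
setMethod("removedBottomUp", "HierarchyResult",
          function(object) object@removedBottomUp)

#' @rdname HierarchyResult-class
#' @export
setGeneric("structuralRemoved", function(object) standardGeneric("structuralRemoved"))
#' @rdname HierarchyResult-class
#' @export
setMethod("structuralRemoved", "HierarchyResult",
          function(object) object@structuralRemoved)

#' @rdname HierarchyResult-class
#' @export
setGeneric("retainedEdges", function(object) standardGeneric("retainedEdges"))
#' @rdname HierarchyResult-class
#' @export
setMethod("retainedEdges", "HierarchyResult", function(object) object@edges)

#' @rdname HierarchyResult-class
#' @export
setGeneric("isolatedRegulators", function(object) standardGeneric("isolatedRegulators"))
#' @rdname HierarchyResult-class
#' @export
setMethod("isolatedRegulators", "HierarchyResult",
          function(object) object@isolated)
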