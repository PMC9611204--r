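#' @import methods
#' @importFrom stats setNames
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Position-specific scoring matrix with identifier and background model
#'
#' A `PSSM` holds the per-position base counts of one DNA motif together
#' with the locus tag of the gene the motif was discovered for, the matrix
#' identifier of the form `<gene>_m<k>` (a gene carries one to five
#' matrices), the background base composition and the pseudocount used to
#' regularise the probability and log-odds forms.
#'
#' @slot matrixId character, `<gene>_m<k>` identifier.
#' @slot sourceGene character, locus tag of the gene the matrix belongs to.
#' @slot counts 4 x w numeric matrix of non-negative base counts,
#'   rows named A, C, G, T.
#' @slot background numeric(4) background base probabilities summing to 1.
#' @slot pseudocount positive numeric(1), distributed across bases in
#'   proportion to the background.
#' @exportClass PSSM
setClass("PSSM",
  representation(
    matrixId    = "character",
    sourceGene  = "character",
    counts      = "matrix",
    background  = "numeric",
    pseudocount = "numeric"
  )
)

setValidity("PSSM", function(object) {
  msg <- character()
  cn <- object@counts
  if (!is.numeric(cn) || nrow(cn) != 4L)
    msg <- c(msg, "counts must be a numeric 4 x w matrix")
  if (is.numeric(cn) && nrow(cn) == 4L) {
    if (ncol(cn) < 1L) msg <- c(msg, "counts must have at least one column")
    if (any(cn < 0)) msg <- c(msg, "counts must be non-negative")
    if (!identical(rownames(cn), DNA_BASES4))
      msg <- c(msg, "counts rows must be named A, C, G, T")
  }
  if (length(object@background) != 4L || any(object@background < 0) ||
      abs(sum(object@background) - 1) > 1e-9)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (length(msg) == 0L) {
    # every column must have positive total mass after pseudocount addition
    tot <- colSums(object@counts) + object@pseudocount
    if (any(tot <= 0)) msg <- c(msg, "column totals must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PSSM
#'
#' @param counts 4 x w matrix of base counts (rows A, C, G, T; row names
#'   optional, assigned in that order if missing).
#' @param matrixId matrix identifier `<gene>_m<k>`. If missing it is
#'   derived from `sourceGene` as `<sourceGene>_m1`.
#' @param sourceGene locus tag of the owning gene. If missing it is parsed
#'   from `matrixId`.
#' @param background background base probabilities (default uniform).
#' @param pseudocount total pseudocount, spread over bases proportionally to
#'   the background (default 1).
#' @return A [PSSM-class] object.
#' @examples
#' m <- PSSM(matrix(c(8, 0, 0, 0, 0, 8, 0, 0), nrow = 4), matrixId = "G001_m1")
#' pssmWidth(m)
#' @export
PSSM <- function(counts, matrixId = NULL, sourceGene = NULL,
                 background = rep(0.25, 4), pseudocount = 1) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- DNA_BASES4
  if (is.null(matrixId)) {
    if (is.null(sourceGene))
      stop("one of 'matrixId' or 'sourceGene' is required")
    matrixId <- paste0(sourceGene, "_m1")
  }
  if (is.null(sourceGene)) sourceGene <- parseMatrixId(matrixId)$gene
  new("PSSM",
      matrixId = matrixId, sourceGene = sourceGene, counts = counts,
      background = setNames(as.numeric(background), DNA_BASES4),
      pseudocount = as.numeric(pseudocount))
}

#' Synthetic test world with planted ground truth
#'
#' Container for a self-contained simulated data set: promoters, per-gene
#' motif matrices, a planted TF-to-target truth network, planted motif
#' sites, condition protein profiles and KEGG Orthology annotations.
#' Produced by [generateWorld()] and extended by [generateProfiles()] and
#' [generateKoMap()].
#'
#' @slot genes character vector of locus tags.
#' @slot promoters [Biostrings::DNAStringSet] of upstream regions, one per
#'   gene, names are locus tags.
#' @slot tfSet character, locus tags flagged as transcription factors.
#' @slot truthNetwork data.frame with columns `tf`, `target`: the planted
#'   regulatory relations (including TF self-pairs).
#' @slot plantedSites data.frame with columns `tf`, `target`, `strand`,
#'   `start`, `end`, `site`: every implanted motif occurrence.
#' @slot matrices named list (by gene) of lists of [PSSM-class] objects.
#' @slot motifProbs named list of the generating 4 x w probability matrices.
#' @slot profiles named list (by condition) of lists with elements `loci`
#'   and `tfs`.
#' @slot koMap data.frame with columns `locus`, `ko`.
#' @slot koPathways data.frame with columns `ko`, `pathway`.
#' @slot background numeric(4) background base probabilities.
#' @slot seed integer seed the world was generated under.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(
    genes        = "character",
    promoters    = "ANY",
    tfSet        = "character",
    truthNetwork = "data.frame",
    plantedSites = "data.frame",
    matrices     = "list",
    motifProbs   = "list",
    profiles     = "list",
    koMap        = "data.frame",
    koPathways   = "data.frame",
    background   = "numeric",
    seed         = "integer"
  )
)

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  if (length(object@genes) < 2L) msg <- c(msg, "need at least two genes")
  if (!all(object@tfSet %in% object@genes))
    msg <- c(msg, "tfSet must be a subset of genes")
  if (nrow(object@truthNetwork) &&
      !all(object@truthNetwork$tf %in% object@tfSet))
    msg <- c(msg, "truth network regulators must be in tfSet")
  nmat <- lengths(object@matrices)
  if (length(nmat) && (any(nmat < 1L) || any(nmat > 5L)))
    msg <- c(msg, "every gene must carry between one and five matrices")
  for (cond in names(object@profiles)) {
    pr <- object@profiles[[cond]]
    if (!all(pr$tfs %in% pr$loci)) {
      msg <- c(msg, sprintf("profile '%s': TF loci must be within its loci", cond))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Directed transcription-factor to target network with per-edge best sites
#'
#' The result of [buildNetwork()]: a directed graph over profile loci where
#' an edge tf -> target records the single most stringent motif site (over
#' all of the TF's matrices and promoter windows, both strands) found in the
#' target's upstream region. Nodes not participating in any edge are
#' removed.
#'
#' @slot condition character label of the profile the network was built for.
#' @slot graph an [igraph::igraph] directed graph; vertex attribute
#'   `isRegulator` flags transcription factors.
#' @slot edges data.frame of edge evidence, one row per relation with
#'   columns `tf`, `target`, `matrix_id`, `strand`, `start`, `end`, `site`,
#'   `weight`, `p_value`, `significance`, `tier`.
#' @slot provenance `"step1"` or `"step3"`.
#' @exportClass RegNetwork
setClass("RegNetwork",
  representation(
    condition  = "character",
    graph      = "ANY",
    edges      = "data.frame",
    provenance = "character"
  )
)

setValidity("RegNetwork", function(object) {
  msg <- character()
  ed <- object@edges
  need <- c("tf", "target", "matrix_id", "strand", "start", "end", "site",
            "weight", "p_value", "significance", "tier")
  if (!all(need %in% names(ed)))
    msg <- c(msg, paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(ed) && any(ed$p_value > 9.9e-4 + 1e-15))
    msg <- c(msg, "edge p-values must not exceed 9.9e-4")
  if (!object@provenance %in% c("step1", "step3"))
    msg <- c(msg, "provenance must be 'step1' or 'step3'")
  if (length(msg)) msg else TRUE
})

#' Regulatory hierarchy decomposition result
#'
#' Produced by [hierarchyDecompose()]: the layered hierarchy of regulators
#' after removing structural genes (out-connectivity zero) and bottom-up
#' edges, together with everything needed to reconstruct the input network.
#'
#' @slot layers list of character vectors, layer 1 on top; every node in a
#'   layer only regulates nodes in strictly lower layers.
#' @slot removedBottomUp data.frame (`from`, `to`) of bottom-up edges
#'   removed before layering.
#' @slot bottomUpFraction fraction of classified edges that were bottom-up.
#' @slot structuralRemoved character, structural genes stripped first.
#' @slot isolated character, regulators left with no edges after removals;
#'   placed in the bottom layer.
#' @slot edges data.frame (`from`, `to`) of retained top-down edges.
#' @exportClass HierarchyResult
setClass("HierarchyResult",
  representation(
    layers            = "list",
    removedBottomUp   = "data.frame",
    bottomUpFraction  = "numeric",
    structuralRemoved = "character",
    isolated          = "character",
    edges             = "data.frame"
  )
)

setMethod("show", "PSSM", function(object) {
  cat(sprintf("PSSM %s (gene %s), width %d, pseudocount %g\n",
              object@matrixId, object@sourceGene, ncol(object@counts),
              object@pseudocount))
  cat("consensus:", pssmConsensus(object), "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d genes (%d TFs), promoter length %d, seed %d\n",
    length(object@genes), length(object@tfSet),
    if (length(object@promoters)) Biostrings::width(object@promoters)[1] else 0L,
    object@seed))
  cat(sprintf("  truth network: %d relations; planted sites: %d\n",
              nrow(object@truthNetwork), nrow(object@plantedSites)))
  if (length(object@profiles))
    cat("  profiles:", paste(sprintf("%s (%d loci, %d TFs)",
        names(object@profiles),
        vapply(object@profiles, function(p) length(p$loci), 1L),
        vapply(object@profiles, function(p) length(p$tfs), 1L)),
        collapse = ", "), "\n")
  if (nrow(object@koMap))
    cat(sprintf("  KO map: %d loci, %d KOs\n", nrow(object@koMap),
                length(unique(object@koMap$ko))))
})

setMethod("show", "RegNetwork", function(object) {
  cat(sprintf("RegNetwork [%s, %s]: %d nodes (%d regulators), %d edges\n",
              object@condition, object@provenance,
              igraph::vcount(object@graph),
              sum(igraph::V(object@graph)$isRegulator),
              nrow(object@edges)))
})

setMethod("show", "HierarchyResult", function(object) {
  cat(sprintf(
    "HierarchyResult: %d layers, %d structural genes removed, %.1f%% bottom-up edges\n",
    length(object@layers), length(object@structuralRemoved),
    100 * object@bottomUpFraction))
  for (i in seq_along(object@layers))
    cat(sprintf("  layer %d: %s\n", i,
                paste(object@layers[[i]], collapse = " ")))
})
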