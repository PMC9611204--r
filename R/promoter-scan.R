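# Promoter scanning: window scores on both strands, exact p-values from the
# score lattice, stringency tiers, and the "auto" most-stringent selection.

TIER_LEVELS <- c("high", "medium", "low", "none")

#' Classify a site p-value into a stringency tier
#'
#' Tiers follow the printed p-value bands: low stringency covers 1.0e-4 to
#' 9.9e-4, medium 1.0e-5 to 9.9e-5, and high runs from 9.9e-6 downwards.
#' The printed two-significant-figure endpoints leave gaps (e.g. 9.95e-5),
#' so the implemented intervals are the enclosing half-open decades:
#' low = \[1e-4, 1e-3), medium = \[1e-5, 1e-4), high = (0, 1e-5).
#' Anything at or above 1e-3 is `"none"`.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return character vector: `"low"`, `"medium"`, `"high"` or `"none"`.
#' @examples
#' classifyTier(c(5e-5, 2e-4, 1e-7, 0.5))
#' @export
classifyTier <- function(p) {
  if (any(p <= 0)) stop("p-values must be strictly positive")
  out <- rep("none", length(p))
  out[p < 1e-3] <- "low"
  out[p < 1e-4] <- "medium"
  out[p < 1e-5] <- "high"
  out
}

.emptyHits <- function() {
  data.frame(matrix_id = character(), tf = character(), target = character(),
             strand = character(), start = integer(), end = integer(),
             site = character(), weight = numeric(), p_value = numeric(),
             significance = numeric(), tier = character(),
             stringsAsFactors = FALSE)
}

#' Scan one promoter with one PSSM on both strands
#'
#' Every window of motif width on the direct and reverse strand is scored;
#' windows whose exact single-strand p-value is at most `maxP` are returned,
#' sorted by increasing p-value. Coordinates are 1-based inclusive on the
#' forward strand of the upstream region regardless of the hit strand; the
#' `site` string is the motif-oriented sequence (reverse-complemented for
#' strand `"R"`).
#'
#' @param pssm a [PSSM-class].
#' @param promoter character(1) or [Biostrings::DNAString] upstream region,
#'   at least as long as the motif.
#' @param maxP p-value cutoff (default 9.9e-4, the low-stringency bound).
#' @param targetGene locus tag to record on each hit (defaults to the
#'   promoter's name attribute, if any).
#' @param granularity score lattice cell size in bits.
#' @param dist optional precomputed [scoreDistribution()] for `pssm`.
#' @return data.frame of site hits with columns `matrix_id`, `tf`, `target`,
#'   `strand`, `start`, `end`, `site`, `weight`, `p_value`, `significance`,
#'   `tier`.
#' @export
scanPromoter <- function(pssm, promoter, maxP = 9.9e-4, targetGene = NULL,
                         granularity = 0.01, dist = NULL) {
  if (is.null(targetGene))
    targetGene <- if (!is.null(names(promoter))) names(promoter)[1] else NA_character_
  promoter <- as.character(promoter)
  idx <- .encodeSeq(promoter)
  w <- pssmWidth(pssm)
  L <- length(idx)
  if (L < w)
    stop(sprintf("promoter length %d is shorter than matrix width %d", L, w))
  if (is.null(dist)) dist <- scoreDistribution(pssm, granularity)
  lo <- logOdds(pssm)
  ints <- dist$ints
  nwin <- L - w + 1L
  # window index matrix: row i = positions i .. i+w-1
  win <- outer(seq_len(nwin), 0:(w - 1L), "+")
  base <- matrix(idx[win], nrow = nwin)
  colIdx <- matrix(rep(seq_len(w), each = nwin), nrow = nwin)
  scoreD <- rowSums(matrix(lo[cbind(as.vector(base), as.vector(colIdx))], nrow = nwin))
  intD   <- rowSums(matrix(ints[cbind(as.vector(base), as.vector(colIdx))], nrow = nwin))
  # reverse strand: score the reverse complement of each window, i.e. the
  # column-reversed complemented matrix applied to the forward window
  loR <- lo[4:1, w:1, drop = FALSE]
  intsR <- ints[4:1, w:1, drop = FALSE]
  scoreR <- rowSums(matrix(loR[cbind(as.vector(base), as.vector(colIdx))], nrow = nwin))
  intR   <- rowSums(matrix(intsR[cbind(as.vector(base), as.vector(colIdx))], nrow = nwin))
  pD <- .tailAtInt(dist, intD)
  pR <- .tailAtInt(dist, intR)
  hitD <- which(pD <= maxP & pD > 0)
  hitR <- which(pR <= maxP & pR > 0)
  siteAt <- function(i) substr(promoter, i, i + w - 1L)
  res <- rbind(
    if (length(hitD)) data.frame(
      matrix_id = pssm@matrixId, tf = pssm@sourceGene, target = targetGene,
      strand = "D", start = hitD, end = hitD + w - 1L,
      site = vapply(hitD, siteAt, ""),
      weight = scoreD[hitD], p_value = pD[hitD],
      significance = -log10(pD[hitD]),
      tier = classifyTier(pD[hitD]), stringsAsFactors = FALSE),
    if (length(hitR)) data.frame(
      matrix_id = pssm@matrixId, tf = pssm@sourceGene, target = targetGene,
      strand = "R", start = hitR, end = hitR + w - 1L,
      site = vapply(vapply(hitR, siteAt, ""), revComp, ""),
      weight = scoreR[hitR], p_value = pR[hitR],
      significance = -log10(pR[hitR]),
      tier = classifyTier(pR[hitR]), stringsAsFactors = FALSE)
  )
  if (is.null(res)) return(.emptyHits())
  res[order(res$p_value, res$start, match(res$strand, c("D", "R"))), ,
      drop = FALSE]
}

#' Keep the most stringent hit per (TF, target) relation
#'
#' Mirrors the "auto" selection: among all windows of all of a TF's
#' matrices in a target's promoter, the relation is represented by the hit
#' with the lowest p-value (searching from the strictest data down). Ties
#' are broken by smaller start, strand `"D"` first, then lower matrix
#' index.
#'
#' @param hits data.frame of site hits as returned by [scanPromoter()],
#'   possibly covering several (tf, target) pairs.
#' @return data.frame with one row per (tf, target) pair.
#' @export
autoSelect <- function(hits) {
  if (nrow(hits) == 0L) return(.emptyHits())
  mIdx <- parseMatrixId(hits$matrix_id)$index
  o <- order(hits$tf, hits$target, hits$p_value, hits$start,
             match(hits$strand, c("D", "R")), mIdx)
  hits <- hits[o, , drop = FALSE]
  keep <- !duplicated(paste(hits$tf, hits$target, sep = "\r"))
  res <- hits[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Scan all matrices of the given TFs against the promoters of the given
# target loci; returns the full hit table (no auto selection).
scanProfileHits <- function(tfs, targets, promoters, matrices,
                            maxP = 9.9e-4, granularity = 0.01) {
  proms <- as.character(promoters)
  if (is.null(names(proms))) names(proms) <- names(promoters)
  out <- vector("list", 0L)
  for (tf in tfs) {
    for (pssm in matrices[[tf]]) {
      dist <- scoreDistribution(pssm, granularity)
      for (tg in targets) {
        h <- scanPromoter(pssm, proms[[tg]], maxP = maxP, targetGene = tg,
                          granularity = granularity, dist = dist)
        if (nrow(h)) out[[length(out) + 1L]] <- h
      }
    }
  }
  if (!length(out)) return(.emptyHits())
  do.call(rbind, out)
}
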