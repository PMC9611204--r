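# Motif matrix clustering and the clustered-TF filter: group the matrices
# of profile genes by alignment correlation and keep only clusters that
# contain at least one transcription-factor matrix.

# Flatten the aligned cells of two probability matrices for one offset.
# B is laid over A starting at column offset+1 (offset may be negative).
.alignedCells <- function(pa, pb, offset) {
  wa <- ncol(pa); wb <- ncol(pb)
  aFrom <- max(1L, offset + 1L)
  aTo <- min(wa, offset + wb)
  if (aTo < aFrom) return(NULL)
  bCols <- (aFrom:aTo) - offset
  list(a = as.vector(pa[, aFrom:aTo, drop = FALSE]),
       b = as.vector(pb[, bCols, drop = FALSE]),
       overlap = aTo - aFrom + 1L)
}

#' Best ungapped alignment correlation between two motif matrices
#'
#' Slides one probability matrix along the other over all ungapped offsets
#' and both orientations (direct and reverse complement) and reports the
#' alignment maximising the Pearson correlation of the aligned cells.
#' `ncor` is the width-normalised correlation,
#' `cor * overlap / max(width_a, width_b)`, which penalises short chance
#' alignments. Alignments shorter than `minOverlap` columns are not
#' considered: with informative columns, a handful of coincidentally
#' matching consensus positions is otherwise enough to reach high `cor`.
#'
#' @param a,b [PSSM-class] objects of width at least 2.
#' @param minOverlap minimum aligned columns; default
#'   `max(5, ceiling(2/3 * min(width)))` (capped at the smaller width).
#' @return list with `cor`, `ncor`, `offset` (columns of `b`'s start
#'   relative to `a`'s, 0 = aligned starts) and `orientation`
#'   (`"D"` or `"R"`).
#' @export
matrixSimilarity <- function(a, b, minOverlap = NULL) {
  wa <- pssmWidth(a); wb <- pssmWidth(b)
  if (wa < 2L || wb < 2L) stop("matrices must have width at least 2")
  if (is.null(minOverlap))
    minOverlap <- max(5L, ceiling(2 / 3 * min(wa, wb)))
  minOverlap <- min(minOverlap, wa, wb)
  pa <- probMatrix(a)
  pb <- probMatrix(b)
  pbR <- pb[4:1, ncol(pb):1, drop = FALSE]
  best <- list(cor = -Inf, ncor = -Inf, offset = 0L, orientation = "D")
  wmax <- max(wa, wb)
  for (orient in c("D", "R")) {
    pbo <- if (orient == "D") pb else pbR
    for (off in (minOverlap - wb):(wa - minOverlap)) {
      al <- .alignedCells(pa, pbo, off)
      if (is.null(al) || al$overlap < minOverlap) next
      if (stats::sd(al$a) == 0 || stats::sd(al$b) == 0) next
      r <- stats::cor(al$a, al$b)
      nr <- r * al$overlap / wmax
      better <- (r > best$cor + 1e-12) ||
        (abs(r - best$cor) <= 1e-12 && nr > best$ncor + 1e-12) ||
        (abs(r - best$cor) <= 1e-12 && abs(nr - best$ncor) <= 1e-12 &&
           orient == "D" && best$orientation == "R") ||
        (abs(r - best$cor) <= 1e-12 && abs(nr - best$ncor) <= 1e-12 &&
           orient == best$orientation && abs(off) < abs(best$offset))
      if (better)
        best <- list(cor = r, ncor = nr, offset = off, orientation = orient)
    }
  }
  if (!is.finite(best$cor))
    stop("no admissible alignment between the two matrices")
  best
}

#' Agglomerative clustering of motif matrices
#'
#' Average-linkage agglomeration on the (1 - cor) alignment distance.
#' Merging proceeds greedily from the most correlated pair and stops where
#' any further merge would drop the average `cor` below `corMin` or the
#' average `ncor` below `ncorMin` (the tree is cut where merging would
#' violate either threshold). Singleton clusters and clusters whose members
#' all come from one gene are discarded.
#'
#' @param matrices list of [PSSM-class] objects (all matrices of the
#'   profile genes of one condition).
#' @param corMin minimum average alignment correlation within a cluster
#'   (default 0.6).
#' @param ncorMin minimum average width-normalised correlation
#'   (default 0.4).
#' @param tfSet character vector of transcription-factor locus tags, used
#'   to annotate clusters.
#' @return list of clusters, each a list with `clusterId`, `members`
#'   (matrix ids), `memberGenes`, `containsTf`, `clusteredTfs`. The full
#'   membership table (including discarded matrices) is attached as
#'   attribute `"assignments"`.
#' @export
clusterMatrices <- function(matrices, corMin = 0.6, ncorMin = 0.4,
                            tfSet = character()) {
  n <- length(matrices)
  if (n < 1L) stop("at least one matrix is required")
  ids <- vapply(matrices, matrixId, "")
  genes <- vapply(matrices, sourceGene, "")
  if (n == 1L) {
    S <- matrix(1, 1, 1)
    N <- matrix(1, 1, 1)
  } else {
    S <- diag(n); N <- diag(n)
    for (i in 1:(n - 1L)) {
      for (j in (i + 1L):n) {
        sim <- tryCatch(matrixSimilarity(matrices[[i]], matrices[[j]]),
                        error = function(e) list(cor = -1, ncor = -1))
        S[i, j] <- S[j, i] <- sim$cor
        N[i, j] <- N[j, i] <- sim$ncor
      }
    }
  }
  # greedy average-linkage agglomeration gated by both thresholds
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  Sw <- S; Nw <- N
  diag(Sw) <- -Inf
  repeat {
    Sw[!active, ] <- -Inf; Sw[, !active] <- -Inf
    cand <- Sw >= corMin & Nw >= ncorMin
    cand[!active, ] <- FALSE; cand[, !active] <- FALSE
    if (!any(cand)) break
    Smask <- ifelse(cand, Sw, -Inf)
    k <- arrayInd(which.max(Smask), dim(Smask))
    i <- min(k); j <- max(k)
    # merge j into i, average linkage weighted by cluster sizes
    wi <- sizes[i]; wj <- sizes[j]
    newS <- (wi * Sw[i, ] + wj * Sw[j, ]) / (wi + wj)
    newN <- (wi * Nw[i, ] + wj * Nw[j, ]) / (wi + wj)
    Sw[i, ] <- newS; Sw[, i] <- newS
    Nw[i, ] <- newN; Nw[, i] <- newN
    Sw[i, i] <- -Inf
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- wi + wj
    active[j] <- FALSE
  }
  clusters <- members[active]
  # retained: at least two distinct source genes
  out <- list()
  assign <- data.frame(cluster_id = rep(NA_character_, n),
                       matrix_id = ids, gene = genes,
                       stringsAsFactors = FALSE)
  cid <- 0L
  for (cl in clusters) {
    gs <- unique(genes[cl])
    if (length(cl) < 2L || length(gs) < 2L) next
    cid <- cid + 1L
    label <- sprintf("cluster_%d", cid)
    tfsIn <- intersect(gs, tfSet)
    out[[cid]] <- list(clusterId = label,
                       members = ids[cl],
                       memberGenes = gs,
                       containsTf = length(tfsIn) > 0L,
                       clusteredTfs = tfsIn)
    assign$cluster_id[cl] <- label
  }
  attr(out, "assignments") <- assign
  out
}

#' Retain genes whose matrices share a cluster with a TF matrix
#'
#' The clustered-TF filter: only clusters containing at least one
#' transcription-factor matrix are kept, and the retained gene set is the
#' union of the member genes of those clusters. This purges genes whose
#' motif matrices resemble no co-expressed regulator's motif, i.e. likely
#' false-positive relations.
#'
#' @param clusters result of [clusterMatrices()].
#' @param tfSet character vector of regulator locus tags.
#' @return list with `genes` (retained locus tags) and `table`, a
#'   data.frame in `clusters_motif_names.tab` shape with columns
#'   `cluster_id`, `matrix_id`, `gene` and `Clustered-TF` (comma-separated
#'   TFs of the cluster, empty for TF-less clusters).
#' @export
clusteredTfFilter <- function(clusters, tfSet) {
  rows <- list()
  genes <- character()
  for (cl in clusters) {
    tfsIn <- intersect(cl$memberGenes, tfSet)
    keep <- length(tfsIn) > 0L
    if (keep) genes <- union(genes, cl$memberGenes)
    rows[[length(rows) + 1L]] <- data.frame(
      cluster_id = cl$clusterId,
      matrix_id = cl$members,
      gene = parseMatrixId(cl$members)$gene,
      `Clustered-TF` = if (keep) paste(tfsIn, collapse = ",") else "",
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster_id = character(), matrix_id = character(),
               gene = character(), `Clustered-TF` = character(),
               check.names = FALSE, stringsAsFactors = FALSE)
  list(genes = sort(genes), table = tab)
}

#' Write a clusters_motif_names-style TSV
#'
#' @param filterResult result of [clusteredTfFilter()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeClusterTable <- function(filterResult, path) {
  utils::write.table(filterResult$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
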