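# Motif-matrix core: probability / log-odds forms, sequence scoring and the
# exact score-distribution engine behind site p-values.

#' Parse a matrix identifier of the form `<gene>_m<k>`
#'
#' Matrix identifiers name the owning gene and the matrix index, e.g.
#' `RHE_RS13345_m5` is matrix number 5 of the transcription factor
#' RHE_RS13345. The gene part may itself contain underscores; the final
#' `_m<k>` suffix (k between 1 and 5) is the index.
#'
#' @param matrixId character vector of identifiers.
#' @return data.frame with columns `gene` and `index`.
#' @examples
#' parseMatrixId("RHE_RS13345_m5")
#' @export
parseMatrixId <- function(matrixId) {
  ok <- grepl("^.+_m[1-5]$", matrixId)
  if (!all(ok))
    stop("malformed matrix identifier(s): ",
         paste(matrixId[!ok], collapse = ", "))
  gene <- sub("_m[1-5]$", "", matrixId)
  idx <- as.integer(sub("^.*_m([1-5])$", "\\1", matrixId))
  data.frame(gene = gene, index = idx, stringsAsFactors = FALSE)
}

#' Column probability form of a PSSM
#'
#' The total pseudocount is distributed over the four bases in proportion
#' to the background, then each column is normalised to sum to one.
#'
#' @param pssm a [PSSM-class].
#' @return 4 x w numeric matrix of column probabilities.
#' @export
probMatrix <- function(pssm) {
  cn <- pssm@counts + pssm@pseudocount * pssm@background
  sweep(cn, 2, colSums(cn), "/")
}

#' Log-odds (weight) form of a PSSM
#'
#' Entry (b, j) is `log2(p(b, j) / background(b))` where `p` is the
#' pseudocount-regularised column probability. The sum of entries along a
#' candidate site is its weight in bits.
#'
#' @param pssm a [PSSM-class].
#' @return 4 x w numeric matrix of log2 odds.
#' @export
logOdds <- function(pssm) {
  if (any(pssm@background <= 0))
    stop("background probabilities must all be positive")
  log2(probMatrix(pssm) / pssm@background)
}

# Encode an ACGT string as integer row indices 1..4; error on anything else.
.encodeSeq <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1]]
  idx <- match(v, DNA_BASES4)
  if (anyNA(idx)) stop("sequence contains non-ACGT letters: ", seq)
  idx
}

.revcompIdx <- function(idx) rev(5L - idx)

#' Reverse complement of a DNA string
#' @param seq character(1) over ACGT.
#' @return character(1) reverse complement.
#' @export
revComp <- function(seq) {
  paste(DNA_BASES4[.revcompIdx(.encodeSeq(seq))], collapse = "")
}

#' Score one sequence of motif width against a PSSM
#'
#' Sums the log-odds entries along the sequence; strand `"R"` scores the
#' reverse complement of `seq` (equivalently, the site read on the reverse
#' strand).
#'
#' @param pssm a [PSSM-class].
#' @param seq character(1) DNA string of exactly the motif width.
#' @param strand `"D"` (direct) or `"R"` (reverse).
#' @return numeric(1) weight in bits.
#' @export
scoreSequence <- function(pssm, seq, strand = c("D", "R")) {
  strand <- match.arg(strand)
  idx <- .encodeSeq(seq)
  w <- pssmWidth(pssm)
  if (length(idx) != w)
    stop(sprintf("sequence length %d does not match matrix width %d",
                 length(idx), w))
  if (strand == "R") idx <- .revcompIdx(idx)
  lo <- logOdds(pssm)
  sum(lo[cbind(idx, seq_len(w))])
}

#' Exact distribution of PSSM scores under the background model
#'
#' Computes, by column-wise dynamic programming over a discretized score
#' lattice, the distribution of the weight of a random sequence of motif
#' width drawn i.i.d. from the background (single strand). Log-odds entries
#' are rounded to the nearest multiple of `granularity` bits, so any
#' discretized score differs from the true score by at most
#' `w * granularity / 2`.
#'
#' @param pssm a [PSSM-class].
#' @param granularity lattice cell size in bits (default 0.01).
#' @return list with elements `grid` (ordered achievable discretized
#'   weights, in bits), `prob` (their probabilities) and `tail`
#'   (`tail[i] = P(score >= grid[i])`), plus `granularity`, `offset` and the
#'   integer-rounded matrix `ints` used for lattice lookups.
#' @export
scoreDistribution <- function(pssm, granularity = 0.01) {
  stopifnot(granularity > 0)
  lo <- logOdds(pssm)
  ints <- matrix(as.integer(round(lo / granularity)), nrow = 4,
                 dimnames = dimnames(lo))
  w <- ncol(ints)
  lows <- apply(ints, 2, min)
  highs <- apply(ints, 2, max)
  lo0 <- sum(lows)
  n <- sum(highs) - lo0 + 1L
  # prob[k] = P(discretized sum == lo0 + k - 1)
  prob <- numeric(n)
  prob[1L] <- 1
  filled <- 1L
  bg <- pssm@background
  for (j in seq_len(w)) {
    span <- highs[j] - lows[j]
    nxt <- numeric(min(n, filled + span))
    for (b in 1:4) {
      sh <- ints[b, j] - lows[j]
      nxt[seq_len(filled) + sh] <- nxt[seq_len(filled) + sh] +
        bg[b] * prob[seq_len(filled)]
    }
    filled <- length(nxt)
    prob[seq_len(filled)] <- nxt
    if (filled < n) prob[(filled + 1L):n] <- 0
  }
  prob <- prob[seq_len(filled)]
  tail <- rev(cumsum(rev(prob)))
  keep <- prob > 0
  list(grid = (lo0 + which(keep) - 1L) * granularity,
       prob = prob[keep],
       tail = tail[keep],
       granularity = granularity,
       offset = lo0,
       ints = ints)
}

# Tail probability at a given discretized integer score, from a
# scoreDistribution() result. Exact on the lattice.
.tailAtInt <- function(dist, sInt) {
  grid <- round(dist$grid / dist$granularity)
  i <- findInterval(sInt - 0.5, grid) + 1L
  ifelse(i > length(grid), 0, dist$tail[pmax(i, 1L)])
}

#' Exact p-value of a PSSM score threshold
#'
#' `P(score >= threshold)` for a random background sequence of motif width,
#' single strand, from the discretized exact score distribution. Rounding
#' can move a discretized score up to `w * granularity / 2` below its true
#' value, so thresholds are matched to the lattice with that tolerance:
#' achievable scores are never lost to rounding.
#'
#' @param pssm a [PSSM-class].
#' @param threshold weight threshold in bits; `-Inf` gives 1.
#' @param granularity lattice cell size in bits.
#' @param dist optional precomputed [scoreDistribution()] result.
#' @return numeric(1) tail probability in (0, 1].
#' @export
exactPvalue <- function(pssm, threshold, granularity = 0.01, dist = NULL) {
  if (!is.finite(threshold) && threshold > 0) return(0)
  if (threshold == -Inf) return(1)
  if (is.null(dist)) dist <- scoreDistribution(pssm, granularity)
  g <- dist$granularity
  tol <- pssmWidth(pssm) * g / 2
  i <- findInterval(threshold - tol - 1e-12, dist$grid) + 1L
  if (i > length(dist$grid)) return(0)
  dist$tail[i]
}

#' Significance of a site p-value
#'
#' Defined as `-log10(p)`: the number of decades of stringency of a motif
#' site.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return numeric vector, `-log10(p)`.
#' @examples
#' significance(c(1, 1e-6, 5e-5))
#' @export
significance <- function(p) {
  if (any(p <= 0)) stop("p-values must be strictly positive")
  if (any(p > 1)) stop("p-values must not exceed 1")
  -log10(p)
}
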