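# Shared fixtures: toy matrices, small worlds and independent oracles.

toyPssm <- function(counts, id = "G001_m1", bg = rep(0.25, 4), pc = 1) {
  PSSM(matrix(counts, nrow = 4, dimnames = list(c("A", "C", "G", "T"), NULL)),
       matrixId = id, background = bg, pseudocount = pc)
}

# A near-consensus matrix for the given DNA word (strong counts on the
# word's bases).
wordPssm <- function(word, id = "G001_m1", depth = 20) {
  idx <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  cn <- matrix(0, nrow = 4, ncol = length(idx),
               dimnames = list(c("A", "C", "G", "T"), NULL))
  cn[cbind(idx, seq_along(idx))] <- depth
  PSSM(cn, matrixId = id)
}

randomPssm <- function(width, id = "G001_m1", depth = 20) {
  cn <- matrix(rmultinom(width, depth, rep(0.25, 4)), nrow = 4,
               dimnames = list(c("A", "C", "G", "T"), NULL))
  PSSM(cn, matrixId = id)
}

# Exhaustive single-strand p-value oracle: enumerate all 4^w sequences,
# score them with the real-valued log-odds and sum background
# probabilities of those at or above the threshold.
enumeratePvalue <- function(pssm, threshold) {
  lo <- logOdds(pssm)
  w <- ncol(lo)
  bg <- pssmBackground(pssm)
  seqs <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- rowSums(matrix(lo[cbind(as.vector(seqs),
                                    rep(seq_len(w), each = nrow(seqs)))],
                           nrow = nrow(seqs)))
  probs <- apply(seqs, 1, function(s) prod(bg[s]))
  list(p = sum(probs[scores >= threshold]), scores = scores, probs = probs)
}

# Brute-force triad census over all node triples of a directed graph.
bruteTriads <- function(g) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE)) > 0
  diag(A) <- FALSE
  n <- nrow(A)
  ffl <- 0L; cffl <- 0L; fbl3 <- 0L
  if (n >= 3) {
    tri <- utils::combn(n, 3)
    for (t in seq_len(ncol(tri))) {
      i <- tri[1, t]; j <- tri[2, t]; k <- tri[3, t]
      e <- c(A[i, j], A[j, i], A[i, k], A[k, i], A[j, k], A[k, j])
      cyc <- (e[1] && e[5] && e[4]) || (e[3] && e[6] && e[2])
      if (cyc) { fbl3 <- fbl3 + 1L; next }
      isFfl <- (e[1] && e[5] && e[3]) || (e[3] && e[6] && e[1]) ||
        (e[2] && e[3] && e[5]) || (e[5] && e[4] && e[2]) ||
        (e[4] && e[1] && e[6]) || (e[6] && e[2] && e[4])
      if (isFfl) {
        ffl <- ffl + 1L
        if (sum(e) > 3L) cffl <- cffl + 1L
      }
    }
  }
  list(ffl = ffl, complex_ffl = cffl, fbl3 = fbl3)
}

# Small world shared by several test files (memoised per session).
smallWorld <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- generateWorld(nGenes = 40, nTfs = 5, promoterLen = 150, seed = 3)
      w <- generateProfiles(w, overlap = 0.6)
      w <- generateKoMap(w, nMultiplicityGroups = 3)
      cache <<- w
    }
    cache
  }
})
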