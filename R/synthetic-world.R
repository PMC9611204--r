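# Synthetic test worlds: promoters with implanted motif sites, per-gene
# motif matrices (including near-duplicate copies of regulator motifs),
# planted regulons, condition profiles and KO annotations, all with full
# ground truth and bit-for-bit reproducibility under a single seed.

.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Dominant-base probability achieving a column information content of `ic`
# bits against a uniform background (2 - H(column) = ic).
.domProbForIC <- function(ic) {
  f <- function(x) {
    h <- -x * log2(x) - (1 - x) * log2((1 - x) / 3)
    (2 - h) - ic
  }
  stats::uniroot(f, c(0.2500001, 1 - 1e-9), tol = 1e-10)$root
}

# Random column-probability matrix with per-column information content
# close to `siteStrength` bits.
.randomMotifProbs <- function(width, siteStrength) {
  pDom <- .domProbForIC(min(siteStrength, 1.99))
  pr <- matrix((1 - pDom) / 3, nrow = 4, ncol = width,
               dimnames = list(DNA_BASES4, NULL))
  dom <- sample.int(4, width, replace = TRUE)
  pr[cbind(dom, seq_len(width))] <- pDom
  pr
}

# Multinomial count matrix observed from `depth` sites of a probability
# matrix.
.sampleCounts <- function(probs, depth = 20L) {
  cnt <- apply(probs, 2, function(p) stats::rmultinom(1, depth, p))
  rownames(cnt) <- DNA_BASES4
  cnt
}

# Dirichlet-perturbed copy of a probability matrix (concentration controls
# how close the copy stays to the original).
.perturbProbs <- function(probs, concentration = 60) {
  pr <- apply(probs, 2, function(p) {
    g <- stats::rgamma(4, shape = p * concentration + 0.05)
    g / sum(g)
  })
  rownames(pr) <- DNA_BASES4
  pr
}

# Sample one site (base indices) from a probability matrix.
.sampleSite <- function(probs) {
  apply(probs, 2, function(p) sample.int(4, 1, prob = p))
}

# Truncated Zipf sampler on 1..kmax with exponent alpha.
.rzipf <- function(n, alpha, kmax) {
  k <- seq_len(max(kmax, 1L))
  p <- k^(-alpha)
  sample(k, n, replace = TRUE, prob = p / sum(p))
}

#' Generate a synthetic regulatory test world
#'
#' Builds a self-contained world with known ground truth: upstream
#' promoter regions of fixed length (i.i.d. background composition), a set
#' of regulator genes with informative motifs, regulons with heavy-tailed
#' sizes (to induce hubs), motif sites sampled from each regulator's
#' probability matrix and implanted on a uniformly chosen strand, a
#' self-site for every gene in its own promoter (mirroring motif resources
#' built on self-recognition), and one to five count matrices per gene.
#' A target gene additionally carries a Dirichlet-perturbed copy of each
#' regulator motif planted in its promoter, so matrix clustering sees
#' realistic near-duplicates.
#'
#' @param nGenes number of genes (>= 2).
#' @param nTfs number of regulators, `1 <= nTfs < nGenes`.
#' @param promoterLen upstream region length in bp (default 250); must be
#'   at least twice the maximum motif width.
#' @param regulonExponent heavy-tail (Zipf) exponent for regulon sizes
#'   (default 1.5); sizes are truncated at `nGenes / 4`.
#' @param siteStrength target per-column information content of the
#'   planted motifs, in bits (default 1.8; conserved dyad-derived motifs
#'   are close to consensus).
#' @param motifWidth central motif width in bp (default 12); per-gene
#'   widths vary by +/- 2.
#' @param gc background G+C fraction (default 0.5, i.e. uniform).
#' @param matrixDepth number of sites behind each count matrix column
#'   (default 20).
#' @param seed integer seed; the whole world is a deterministic function
#'   of it.
#' @return a [SyntheticWorld-class] (profiles and KO tables empty until
#'   [generateProfiles()] / [generateKoMap()] are applied).
#' @examples
#' w <- generateWorld(nGenes = 10, nTfs = 2, promoterLen = 100, seed = 7)
#' w
#' @export
generateWorld <- function(nGenes, nTfs, promoterLen = 250,
                          regulonExponent = 1.5, siteStrength = 1.8,
                          motifWidth = 12, gc = 0.5, matrixDepth = 20L,
                          seed = 1L) {
  if (nTfs < 1L || nTfs >= nGenes)
    stop("need 1 <= nTfs < nGenes")
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  wMax <- motifWidth + 2L
  if (promoterLen < 2L * wMax)
    stop("promoterLen must be at least twice the maximum motif width")
  seed <- as.integer(seed)
  digits <- max(3L, nchar(as.character(nGenes)))
  genes <- sprintf(paste0("G%0", digits, "d"), seq_len(nGenes))
  tfSet <- genes[seq_len(nTfs)]
  bg <- setNames(c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2), DNA_BASES4)

  .withSeed(seed, {
    widths <- setNames(sample(motifWidth + c(-2L, 0L, 2L), nGenes,
                              replace = TRUE), genes)
    motifProbs <- setNames(lapply(genes, function(g)
      .randomMotifProbs(widths[[g]], siteStrength)), genes)

    # planted regulons with heavy-tailed sizes
    kmax <- max(1L, floor(nGenes / 4))
    sizes <- .rzipf(nTfs, regulonExponent, kmax)
    truth <- list()
    for (i in seq_len(nTfs)) {
      tf <- tfSet[i]
      targets <- sample(setdiff(genes, tf), sizes[i])
      truth[[i]] <- data.frame(tf = tf, target = targets,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    # every gene recognises a site in its own promoter; for TFs that is a
    # genuine self-regulation, part of the truth network
    truth <- rbind(truth, data.frame(tf = tfSet, target = tfSet,
                                     stringsAsFactors = FALSE))
    truth <- truth[order(truth$tf, truth$target), , drop = FALSE]
    rownames(truth) <- NULL

    # background promoters
    promChar <- vapply(genes, function(g)
      paste(sample(DNA_BASES4, promoterLen, replace = TRUE, prob = bg),
            collapse = ""), "")

    # implant sites: self-site for every gene, then regulon sites;
    # non-overlapping placement where possible
    occupied <- setNames(vector("list", nGenes), genes)
    planted <- list()
    implant <- function(tf, target) {
      w <- ncol(motifProbs[[tf]])
      idx <- .sampleSite(motifProbs[[tf]])
      strand <- sample(c("D", "R"), 1L)
      fwd <- if (strand == "D") idx else .revcompIdx(idx)
      starts <- seq_len(promoterLen - w + 1L)
      for (iv in occupied[[target]])
        starts <- starts[starts > iv[2] | starts + w - 1L < iv[1]]
      if (!length(starts)) starts <- seq_len(promoterLen - w + 1L)
      s <- if (length(starts) == 1L) starts else sample(starts, 1L)
      e <- s + w - 1L
      str <- promChar[[target]]
      substr(str, s, e) <- paste(DNA_BASES4[fwd], collapse = "")
      promChar[[target]] <<- str
      occupied[[target]] <<- c(occupied[[target]], list(c(s, e)))
      planted[[length(planted) + 1L]] <<- data.frame(
        tf = tf, target = target, strand = strand, start = s, end = e,
        site = paste(DNA_BASES4[idx], collapse = ""),
        stringsAsFactors = FALSE)
    }
    for (g in genes) implant(g, g)
    reg <- truth[truth$tf != truth$target, , drop = FALSE]
    for (k in seq_len(nrow(reg))) implant(reg$tf[k], reg$target[k])
    plantedSites <- do.call(rbind, planted)

    # one to five count matrices per gene: the gene's own motif first, then
    # perturbed copies of the motifs of its regulators, then optional
    # perturbed self-copies
    regsOf <- split(reg$tf, reg$target)
    matrices <- setNames(vector("list", nGenes), genes)
    for (g in genes) {
      probsList <- list(motifProbs[[g]])
      for (tf in utils::head(regsOf[[g]], 4L))
        probsList[[length(probsList) + 1L]] <- .perturbProbs(motifProbs[[tf]])
      if (length(probsList) < 5L && stats::runif(1) < 0.3)
        probsList[[length(probsList) + 1L]] <- .perturbProbs(motifProbs[[g]])
      probsList <- utils::head(probsList, 5L)
      matrices[[g]] <- lapply(seq_along(probsList), function(k)
        PSSM(.sampleCounts(probsList[[k]], matrixDepth),
             matrixId = sprintf("%s_m%d", g, k), sourceGene = g,
             background = bg))
    }

    proms <- Biostrings::DNAStringSet(promChar)
    names(proms) <- genes
    new("SyntheticWorld",
        genes = genes, promoters = proms, tfSet = tfSet,
        truthNetwork = truth, plantedSites = plantedSites,
        matrices = matrices, motifProbs = motifProbs,
        profiles = list(), koMap = data.frame(), koPathways = data.frame(),
        background = bg, seed = seed)
  })
}

#' Assign condition protein profiles to a world
#'
#' Each non-regulator locus is either shared by all conditions (with
#' probability `overlap`) or assigned to exactly one condition uniformly;
#' regulators enter every condition independently with probability
#' `tfRate`. With two conditions the labels are `"MM"` and `"bacteroid"`.
#'
#' @param world a [SyntheticWorld-class].
#' @param nConditions number of conditions (default 2).
#' @param overlap fraction in \[0, 1\]: expected fraction of loci shared by
#'   all conditions.
#' @param tfRate probability that a regulator is present in a given
#'   condition's profile (default 1).
#' @param seed integer seed (default: the world's seed + 1).
#' @return the world with its `profiles` slot filled.
#' @export
generateProfiles <- function(world, nConditions = 2, overlap = 0.5,
                             tfRate = 1, seed = NULL) {
  if (overlap < 0 || overlap > 1) stop("overlap must be within [0, 1]")
  if (nConditions < 1L) stop("need at least one condition")
  if (is.null(seed)) seed <- world@seed + 1L
  labels <- if (nConditions == 2L) c("MM", "bacteroid") else
    sprintf("C%d", seq_len(nConditions))
  nonTf <- setdiff(world@genes, world@tfSet)
  .withSeed(seed, {
    shared <- nonTf[stats::runif(length(nonTf)) < overlap]
    rest <- setdiff(nonTf, shared)
    assignTo <- sample(seq_len(nConditions), length(rest), replace = TRUE)
    profiles <- setNames(vector("list", nConditions), labels)
    for (i in seq_len(nConditions)) {
      tfs <- world@tfSet[stats::runif(length(world@tfSet)) <= tfRate]
      loci <- sort(c(shared, rest[assignTo == i], tfs))
      profiles[[i]] <- list(loci = loci, tfs = tfs)
    }
    world@profiles <- profiles
    validObject(world)
    world
  })
}

#' Plant KEGG Orthology annotations with known multiplicity groups
#'
#' Assigns KO identifiers to profiled loci such that exactly
#' `nMultiplicityGroups` KOs have non-identical locus sets across
#' conditions (planted isoenzyme multiplicity, disjoint by construction),
#' `nIdentical` KOs carry the identical-locus pattern (the same gene
#' expressed in several conditions, not an isoenzyme), and every other
#' locus receives its own singleton KO. Each planted KO is mapped to one
#' or two pathway labels.
#'
#' @param world a [SyntheticWorld-class] with at least two profiles.
#' @param nMultiplicityGroups number of planted multiplicity KOs.
#' @param nIdentical number of planted identical-locus KOs (default 2).
#' @param seed integer seed (default: the world's seed + 2).
#' @return the world with `koMap` and `koPathways` filled.
#' @export
generateKoMap <- function(world, nMultiplicityGroups, nIdentical = 2,
                          seed = NULL) {
  if (length(world@profiles) < 2L)
    stop("generateProfiles() must be applied first, with >= 2 conditions")
  if (is.null(seed)) seed <- world@seed + 2L
  conds <- names(world@profiles)
  lociBy <- lapply(world@profiles, `[[`, "loci")
  inAll <- Reduce(intersect, lociBy)
  exclusive <- lapply(seq_along(conds), function(i)
    setdiff(lociBy[[i]], unlist(lociBy[-i])))
  if (any(vapply(exclusive, length, 1L) < nMultiplicityGroups))
    stop("not enough condition-exclusive loci to host the requested groups")
  if (length(inAll) < nIdentical)
    stop("not enough shared loci to host the identical-locus KOs")
  .withSeed(seed, {
    koRows <- list()
    pwRows <- list()
    used <- character()
    for (k in seq_len(nMultiplicityGroups)) {
      ko <- sprintf("K%05d", k)
      for (i in seq_along(conds)) {
        pool <- setdiff(exclusive[[i]], used)
        loci <- sample(pool, min(length(pool), sample(1:2, 1L)))
        used <- c(used, loci)
        koRows[[length(koRows) + 1L]] <- data.frame(
          locus = loci, ko = ko, stringsAsFactors = FALSE)
      }
      pws <- sprintf("map%04d", sample.int(max(4L, 2L * nMultiplicityGroups),
                                           sample(1:2, 1L)))
      pwRows[[length(pwRows) + 1L]] <- data.frame(
        ko = ko, pathway = unique(pws), stringsAsFactors = FALSE)
    }
    idPool <- setdiff(inAll, used)
    idLoci <- if (nIdentical > 0L) sample(idPool, nIdentical) else character()
    for (k in seq_len(nIdentical)) {
      ko <- sprintf("K9%04d", k)
      koRows[[length(koRows) + 1L]] <- data.frame(
        locus = idLoci[k], ko = ko, stringsAsFactors = FALSE)
      used <- c(used, idLoci[k])
      pwRows[[length(pwRows) + 1L]] <- data.frame(
        ko = ko, pathway = sprintf("map%04d", sample.int(99, 1L) + 1000L),
        stringsAsFactors = FALSE)
    }
    # remaining profiled loci: singleton KOs (no multiplicity)
    rest <- setdiff(unique(unlist(lociBy)), used)
    if (length(rest)) {
      kos <- sprintf("K8%04d", seq_along(rest))
      koRows[[length(koRows) + 1L]] <- data.frame(
        locus = rest, ko = kos, stringsAsFactors = FALSE)
      pwRows[[length(pwRows) + 1L]] <- data.frame(
        ko = kos, pathway = "map9999", stringsAsFactors = FALSE)
    }
    world@koMap <- do.call(rbind, koRows)
    world@koPathways <- unique(do.call(rbind, pwRows))
    rownames(world@koMap) <- rownames(world@koPathways) <- NULL
    world
  })
}

#' Condition profiles of a world as plain locus-tag lists
#'
#' @param world a [SyntheticWorld-class].
#' @return named list of character vectors (loci per condition).
#' @export
profileLoci <- function(world) {
  lapply(world@profiles, `[[`, "loci")
}
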