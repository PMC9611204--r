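# Three-step network construction: step-1 network from the full profile,
# step-2 clustered-TF gene selection, step-3 rebuilt network on the
# retained genes; plus regulon extraction and the per-decade p-value
# histogram used to compare step-1 and step-3 stringency.

#' Build a regulatory network from one condition profile
#'
#' Scans the upstream region of every profile locus with every matrix of
#' every co-expressed regulator (self-pairs included: the motif resources
#' this emulates are built on self-recognition, so a TF may hit its own
#' promoter), keeps windows with exact p-value at most `maxP`, and retains
#' one relation per (TF, target) pair: the most stringent hit (the "auto"
#' selection). Genes with no incoming or outgoing relation are removed,
#' as are TFs whose matrices hit no upstream region.
#'
#' @param profile list with elements `loci` (profiled locus tags) and
#'   `tfs` (the regulator subset), or a condition name to take from
#'   `world`-style profiles.
#' @param promoters named [Biostrings::DNAStringSet] (or named character
#'   vector) of upstream regions covering the profile loci.
#' @param matrices named list (by gene) of lists of [PSSM-class] objects.
#' @param maxP site p-value cutoff (default 9.9e-4).
#' @param condition label stored on the network (default `"condition"`).
#' @param granularity score lattice cell size in bits.
#' @param provenance `"step1"` (default) or `"step3"`.
#' @return a [RegNetwork-class].
#' @export
buildNetwork <- function(profile, promoters, matrices, maxP = 9.9e-4,
                         condition = "condition", granularity = 0.01,
                         provenance = "step1") {
  if (!length(profile$loci)) stop("empty profile")
  loci <- intersect(profile$loci, names(promoters))
  tfs <- intersect(profile$tfs, names(matrices))
  hits <- scanProfileHits(tfs, loci, promoters, matrices,
                          maxP = maxP, granularity = granularity)
  edges <- autoSelect(hits)
  nodes <- union(edges$tf, edges$target)
  g <- igraph::graph_from_data_frame(
    edges[, c("tf", "target")], directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::V(g)$isRegulator <- igraph::V(g)$name %in% tfs
  new("RegNetwork", condition = condition, graph = g, edges = edges,
      provenance = provenance)
}

#' Three-step network construction with the clustered-TF filter
#'
#' Step 1 builds a network from the full profile. Step 2 clusters the
#' motif matrices of the step-1 genes and keeps only the genes whose
#' matrices share a cluster with a regulator matrix (the clustered-TF
#' filter, run once per condition). Step 3 rebuilds the network exactly as
#' in step 1 but restricted to the retained genes.
#'
#' @inheritParams buildNetwork
#' @param corMin,ncorMin clustering thresholds, see [clusterMatrices()].
#' @return list with elements `step1` ([RegNetwork-class]), `clusters`
#'   (from [clusterMatrices()]), `retained` (the clustered-TF gene set),
#'   `filter` (the [clusteredTfFilter()] result) and `step3`
#'   ([RegNetwork-class]).
#' @export
threeStep <- function(profile, promoters, matrices, maxP = 9.9e-4,
                      condition = "condition", granularity = 0.01,
                      corMin = 0.6, ncorMin = 0.4) {
  step1 <- buildNetwork(profile, promoters, matrices, maxP = maxP,
                        condition = condition, granularity = granularity)
  genes1 <- regNodes(step1)
  mats <- unlist(lapply(matrices[intersect(genes1, names(matrices))],
                        identity), recursive = FALSE)
  clusters <- clusterMatrices(unname(mats), corMin = corMin,
                              ncorMin = ncorMin, tfSet = profile$tfs)
  filt <- clusteredTfFilter(clusters, profile$tfs)
  retained <- intersect(filt$genes, genes1)
  profile3 <- list(loci = intersect(profile$loci, retained),
                   tfs = intersect(profile$tfs, retained))
  step3 <- if (length(profile3$loci))
    buildNetwork(profile3, promoters, matrices, maxP = maxP,
                 condition = condition, granularity = granularity,
                 provenance = "step3")
  else
    new("RegNetwork", condition = condition,
        graph = igraph::make_empty_graph(directed = TRUE),
        edges = .emptyHits(), provenance = "step3")
  list(step1 = step1, clusters = clusters, retained = retained,
       filter = filt, step3 = step3)
}

#' Interactions per p-value decade
#'
#' Bins the per-edge p-values of a network into decades from 1e-3 down to
#' 1e-20 (everything below 1e-20 is lumped into the last bin); counts sum
#' to the edge count. Comparing the step-1 and step-3 histograms shows the
#' enrichment of high-stringency interactions after the clustered-TF
#' filter.
#'
#' @param net a [RegNetwork-class] with at least one edge.
#' @return named integer vector; names are the decade upper bounds
#'   (`"1e-04"` counts p in \[1e-4, 1e-3), and so on).
#' @export
pvalueRangeHistogram <- function(net) {
  p <- regEdges(net)$p_value
  if (!length(p)) stop("network has no edges")
  dec <- pmax(pmin(floor(log10(p)), -4), -20)
  counts <- table(factor(dec, levels = -4:-20))
  stats::setNames(as.integer(counts), sprintf("1e%03d", -4:-20))
}

#' Fraction of edges at a given stringency tier
#'
#' @param net a [RegNetwork-class].
#' @param tier `"high"`, `"medium"` or `"low"`.
#' @return numeric(1) fraction of edges in the tier.
#' @export
tierFraction <- function(net, tier = "high") {
  ed <- regEdges(net)
  if (!nrow(ed)) return(NaN)
  mean(ed$tier == tier)
}

#' Extract regulons from a network
#'
#' @param net a [RegNetwork-class].
#' @return named list: for each regulator, the character vector of its
#'   targets.
#' @export
extractRegulons <- function(net) {
  ed <- regEdges(net)
  if (!nrow(ed)) return(structure(list(), names = character()))
  lapply(split(ed$target, ed$tf), unique)
}

#' Precision and recall of a network against a planted truth
#'
#' Both sets are restricted to relations whose regulator and target lie in
#' `universe` (typically the scanned profile loci), so the comparison only
#' covers relations the scan could have produced.
#'
#' @param net a [RegNetwork-class].
#' @param truth data.frame with columns `tf` and `target`.
#' @param universe optional character vector of loci to restrict to.
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
networkAccuracy <- function(net, truth, universe = NULL) {
  ed <- regEdges(net)
  pred <- paste(ed$tf, ed$target, sep = "->")
  tr <- truth
  if (!is.null(universe))
    tr <- tr[tr$tf %in% universe & tr$target %in% universe, , drop = FALSE]
  tru <- paste(tr$tf, tr$target, sep = "->")
  tp <- length(intersect(pred, tru))
  list(precision = if (length(pred)) tp / length(pred) else NaN,
       recall = if (length(tru)) tp / length(tru) else NaN,
       tp = tp, fp = length(pred) - tp, fn = length(tru) - tp)
}
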