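# Readers and writers: FASTA promoters, TRANSFAC count matrices, TSV
# profile / KO / network tables, GML export, YAML run configuration.
# All tables carry headers; coordinates are 1-based inclusive.

#' Read and write promoter FASTA files
#'
#' Record ids are bare locus tags; the description field is free-form.
#'
#' @param path file path.
#' @return [Biostrings::DNAStringSet], names are locus tags.
#' @export
readPromoters <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname readPromoters
#' @param promoters named [Biostrings::DNAStringSet] or character vector.
#' @export
writePromoters <- function(promoters, path) {
  if (!is(promoters, "DNAStringSet"))
    promoters <- Biostrings::DNAStringSet(promoters)
  Biostrings::writeXStringSet(promoters, path)
  invisible(path)
}

#' Read a TRANSFAC-format matrix file
#'
#' Accepts the common dialect: `ID` line with the matrix identifier,
#' optional `BF` line with the source gene, a `P0` (or `PO`) header naming
#' the base order, numbered per-position count rows (integer or real) and
#' `//` record separators.
#'
#' @param path file path.
#' @param background background probabilities for the resulting matrices.
#' @param pseudocount pseudocount for the resulting matrices.
#' @return named list of [PSSM-class] objects (by matrix id).
#' @export
readTransfacSet <- function(path, background = rep(0.25, 4),
                            pseudocount = 1) {
  lines <- readLines(path)
  out <- list()
  id <- NULL; bf <- NULL; rows <- list(); lineNo <- 0L
  flush <- function() {
    if (is.null(id)) return()
    if (!length(rows))
      stop(sprintf("%s: matrix '%s' has no count rows", path, id))
    cn <- t(do.call(rbind, rows))
    rownames(cn) <- DNA_BASES4
    out[[id]] <<- PSSM(cn, matrixId = id,
                       sourceGene = if (is.null(bf))
                         parseMatrixId(id)$gene else bf,
                       background = background, pseudocount = pseudocount)
    id <<- NULL; bf <<- NULL; rows <<- list()
  }
  for (ln in lines) {
    lineNo <- lineNo + 1L
    ln <- trimws(ln)
    if (ln == "" || grepl("^XX", ln)) next
    if (grepl("^//", ln)) { flush(); next }
    if (grepl("^ID\\s", ln)) { id <- sub("^ID\\s+", "", ln); next }
    if (grepl("^BF\\s", ln)) { bf <- sub("^BF\\s+", "", ln); next }
    if (grepl("^P[0O]\\s", ln)) next
    if (grepl("^[0-9]+\\s", ln)) {
      vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]][2:5]))
      if (anyNA(vals))
        stop(sprintf("%s line %d: malformed count row '%s'", path, lineNo, ln))
      rows[[length(rows) + 1L]] <- vals
    }
  }
  flush()
  out
}

#' Write PSSMs as a TRANSFAC-format matrix file
#'
#' @param pssms list of [PSSM-class] objects.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTransfacSet <- function(pssms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  fmtNum <- function(v) {
    ifelse(v == round(v), format(as.integer(round(v))), format(v))
  }
  for (p in pssms) {
    writeLines(c(sprintf("ID %s", matrixId(p)),
                 sprintf("BF %s", sourceGene(p)),
                 "P0 A C G T"), con)
    cn <- pssmCounts(p)
    for (j in seq_len(ncol(cn)))
      writeLines(sprintf("%02d %s", j, paste(fmtNum(cn[, j]), collapse = " ")),
                 con)
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read and write condition profile tables
#'
#' Tab-separated with header columns `condition`, `locus`, `is_tf`.
#'
#' @param path file path.
#' @return named list (by condition) of lists with `loci` and `tfs`.
#' @export
readProfileTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(tab, tab$condition), function(d)
    list(loci = sort(d$locus), tfs = sort(d$locus[as.logical(d$is_tf)])))
}

#' @rdname readProfileTable
#' @param profiles named list of lists with `loci` and `tfs`.
#' @export
writeProfileTable <- function(profiles, path) {
  rows <- lapply(names(profiles), function(cond) {
    p <- profiles[[cond]]
    data.frame(condition = cond, locus = p$loci,
               is_tf = as.integer(p$loci %in% p$tfs),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read two-column locus-to-KO and KO-to-pathway tables
#'
#' blastKOALA-style exports: tab-separated, with or without a header.
#'
#' @param path file path.
#' @return data.frame with columns `locus`, `ko` (or `ko`, `pathway`).
#' @export
readKoMap <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           header = .hasHeader(path, c("locus", "ko")))
  names(tab)[1:2] <- c("locus", "ko")
  tab[, c("locus", "ko")]
}

#' @rdname readKoMap
#' @export
readKoPathways <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           header = .hasHeader(path, c("ko", "pathway")))
  names(tab)[1:2] <- c("ko", "pathway")
  tab[, c("ko", "pathway")]
}

.hasHeader <- function(path, expected) {
  first <- tolower(strsplit(readLines(path, n = 1L), "\t")[[1]])
  any(expected %in% first)
}

NETWORK_COLUMNS <- c("Condition", "Locus tag", "K number", "Upstream_region",
                     "Matrix_ID", "Chain", "End_motif", "Start_motif",
                     "Site", "Weight", "p-value", "Significance")

#' Write a network as a 12-column relation table
#'
#' One row per TF gene-target relation with the columns Condition,
#' Locus tag, K number, Upstream_region, Matrix_ID, Chain, End_motif,
#' Start_motif, Site, Weight, p-value and Significance, ordered by
#' decreasing p-value. `Locus tag` and `Upstream_region` both name the
#' target gene (the scanned region is the target's upstream region);
#' `Matrix_ID` carries the regulator and its winning matrix index.
#'
#' @param net a [RegNetwork-class].
#' @param path output TSV path.
#' @param koMap optional data.frame (`locus`, `ko`) to fill the K-number
#'   column (empty otherwise).
#' @return the path, invisibly.
#' @export
writeNetworkTsv <- function(net, path, koMap = NULL) {
  ed <- regEdges(net)
  kn <- if (!is.null(koMap))
    koMap$ko[match(ed$target, koMap$locus)] else rep(NA_character_, nrow(ed))
  kn[is.na(kn)] <- ""
  tab <- data.frame(
    Condition = rep(netCondition(net), nrow(ed)),
    `Locus tag` = ed$target, `K number` = kn,
    Upstream_region = ed$target, Matrix_ID = ed$matrix_id,
    Chain = ed$strand, End_motif = ed$end, Start_motif = ed$start,
    Site = ed$site, Weight = ed$weight, `p-value` = ed$p_value,
    Significance = ed$significance,
    check.names = FALSE, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$`p-value`), , drop = FALSE]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column relation table back into a network
#'
#' @param path TSV written by [writeNetworkTsv()].
#' @param tfSet optional regulator set; defaults to the regulators named
#'   in Matrix_ID.
#' @param provenance provenance label for the rebuilt network.
#' @return a [RegNetwork-class].
#' @export
readNetworkTsv <- function(path, tfSet = NULL, provenance = "step1") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  missing <- setdiff(NETWORK_COLUMNS, names(tab))
  if (length(missing))
    stop(sprintf("%s: missing network columns: %s", path,
                 paste(missing, collapse = ", ")))
  parsed <- parseMatrixId(tab$Matrix_ID)
  ed <- data.frame(
    matrix_id = tab$Matrix_ID, tf = parsed$gene,
    target = tab$`Locus tag`, strand = tab$Chain,
    start = as.integer(tab$Start_motif), end = as.integer(tab$End_motif),
    site = tab$Site, weight = tab$Weight, p_value = tab$`p-value`,
    significance = tab$Significance,
    tier = classifyTier(tab$`p-value`), stringsAsFactors = FALSE)
  ed <- ed[order(ed$tf, ed$target), , drop = FALSE]
  rownames(ed) <- NULL
  if (is.null(tfSet)) tfSet <- unique(ed$tf)
  nodes <- union(ed$tf, ed$target)
  g <- igraph::graph_from_data_frame(
    ed[, c("tf", "target")], directed = TRUE,
    vertices = data.frame(name = nodes))
  igraph::V(g)$isRegulator <- igraph::V(g)$name %in% tfSet
  new("RegNetwork",
      condition = if (nrow(tab)) as.character(tab$Condition[1]) else "condition",
      graph = g, edges = ed, provenance = provenance)
}

#' Export a network as GML
#'
#' @param net a [RegNetwork-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
exportNetworkGml <- function(net, path) {
  g <- regGraph(net)
  # GML has no boolean type; store the regulator flag as 0/1
  igraph::V(g)$isRegulator <- as.integer(igraph::V(g)$isRegulator)
  igraph::write_graph(g, path, format = "gml")
  invisible(path)
}

#' Write a synthetic world to its external file formats
#'
#' Promoters as FASTA, matrices as TRANSFAC, profiles / truth network /
#' KO tables as TSV — the same writers used throughout the package.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePromoters(worldPromoters(world), file.path(dir, "promoters.fasta"))
  writeTransfacSet(unlist(worldMatrices(world), recursive = FALSE),
                   file.path(dir, "matrices.transfac"))
  utils::write.table(truthNetwork(world), file.path(dir, "truth_network.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(worldProfiles(world)))
    writeProfileTable(worldProfiles(world), file.path(dir, "profiles.tsv"))
  if (nrow(worldKoMap(world)))
    utils::write.table(worldKoMap(world), file.path(dir, "ko_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(worldKoPathways(world)))
    utils::write.table(worldKoPathways(world),
                       file.path(dir, "ko_pathways.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a written world back
#'
#' Returns the external-format content (promoters, matrices, profiles,
#' truth network, KO tables); generator-internal ground truth that has no
#' file representation (probability matrices, planted site list) is not
#' recovered.
#'
#' @param dir directory written by [writeWorld()].
#' @return list with `promoters`, `matrices` (per-gene lists of
#'   [PSSM-class]), `truthNetwork`, `profiles`, `koMap`, `koPathways`.
#' @export
readWorld <- function(dir) {
  mats <- readTransfacSet(file.path(dir, "matrices.transfac"))
  byGene <- split(mats, vapply(mats, sourceGene, ""))
  byGene <- lapply(byGene, unname)
  prof <- if (file.exists(file.path(dir, "profiles.tsv")))
    readProfileTable(file.path(dir, "profiles.tsv")) else list()
  koMap <- if (file.exists(file.path(dir, "ko_map.tsv")))
    readKoMap(file.path(dir, "ko_map.tsv")) else data.frame()
  koPw <- if (file.exists(file.path(dir, "ko_pathways.tsv")))
    readKoPathways(file.path(dir, "ko_pathways.tsv")) else data.frame()
  list(promoters = readPromoters(file.path(dir, "promoters.fasta")),
       matrices = byGene,
       truthNetwork = utils::read.delim(file.path(dir, "truth_network.tsv"),
                                        stringsAsFactors = FALSE),
       profiles = prof, koMap = koMap, koPathways = koPw)
}

#' Run configuration
#'
#' A serialisable record of every input path and threshold of a run; a
#' config plus its seed reproduces all outputs bit for bit.
#'
#' @param promotersFasta,matricesTransfac,profilesTsv,koMapTsv,koPathwaysTsv
#'   input file paths.
#' @param maxP scan p-value cutoff.
#' @param granularity score lattice cell in bits.
#' @param corMin,ncorMin matrix-clustering thresholds.
#' @param erReps Erdos-Renyi ensemble size.
#' @param seed integer seed.
#' @param outputDir output directory.
#' @return named list of class `proTRNConfig`.
#' @export
runConfig <- function(promotersFasta = NULL, matricesTransfac = NULL,
                      profilesTsv = NULL, koMapTsv = NULL,
                      koPathwaysTsv = NULL, maxP = 9.9e-4,
                      granularity = 0.01, corMin = 0.6, ncorMin = 0.4,
                      erReps = 1000, seed = 1L, outputDir = ".") {
  structure(list(
    promoters_fasta = promotersFasta, matrices_transfac = matricesTransfac,
    profiles_tsv = profilesTsv, ko_map_tsv = koMapTsv,
    ko_pathways_tsv = koPathwaysTsv, max_p = maxP,
    granularity = granularity, cor_min = corMin, ncor_min = ncorMin,
    er_reps = erReps, seed = as.integer(seed), output_dir = outputDir),
    class = "proTRNConfig")
}

#' @rdname runConfig
#' @param config a `proTRNConfig`.
#' @param path YAML file path.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(runConfig, list(
    promotersFasta = cfg$promoters_fasta,
    matricesTransfac = cfg$matrices_transfac,
    profilesTsv = cfg$profiles_tsv, koMapTsv = cfg$ko_map_tsv,
    koPathwaysTsv = cfg$ko_pathways_tsv, maxP = cfg$max_p,
    granularity = cfg$granularity, corMin = cfg$cor_min,
    ncorMin = cfg$ncor_min, erReps = cfg$er_reps, seed = cfg$seed,
    outputDir = cfg$output_dir))
}
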