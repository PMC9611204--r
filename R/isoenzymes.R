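# Isoenzyme multiplicity from KEGG Orthology: a K number expressed through
# different loci in different conditions marks condition-specific
# isoenzymes; the same locus in every condition is a shared gene.

#' Detect condition-specific isoenzyme multiplicity
#'
#' Groups profiled loci by K number and classifies every KO observed in at
#' least two conditions: `identical` when the per-condition locus sets are
#' equal (a shared gene, not an isoenzyme), `disjoint` when no locus is
#' shared between conditions, `overlapping` otherwise. KOs seen in a
#' single condition are classified `single-condition` and reported
#' separately. Multiplicity (isoenzymes) means class `disjoint` or
#' `overlapping`. Loci without a KO mapping are skipped with a message; a
#' locus annotated with several KOs joins one group per KO.
#'
#' @param profiles named list of character vectors: the loci of each
#'   condition (a [SyntheticWorld-class] is also accepted).
#' @param koMap data.frame with columns `locus` and `ko`.
#' @return data.frame sorted by KO with columns `ko`,
#'   `multiplicity_class`, `n_conditions`, `n_loci` and a list-column
#'   `loci_by_condition` (named list of per-condition locus vectors).
#' @export
detectIsoenzymes <- function(profiles, koMap) {
  if (is(profiles, "SyntheticWorld")) profiles <- profileLoci(profiles)
  if (!length(profiles) || !sum(lengths(profiles)))
    stop("empty profiles")
  conds <- names(profiles)
  rows <- list()
  allLoci <- unique(unlist(profiles))
  unmapped <- setdiff(allLoci, koMap$locus)
  if (length(unmapped))
    message(length(unmapped), " profiled loci without KO mapping skipped")
  kos <- sort(unique(koMap$ko[koMap$locus %in% allLoci]))
  for (ko in kos) {
    koLoci <- koMap$locus[koMap$ko == ko]
    sets <- lapply(profiles, function(l) sort(intersect(l, koLoci)))
    nonEmpty <- sets[lengths(sets) > 0]
    if (!length(nonEmpty)) next
    cls <- if (length(nonEmpty) < 2L) {
      "single-condition"
    } else if (all(vapply(nonEmpty, identical, TRUE, y = nonEmpty[[1]]))) {
      "identical"
    } else {
      inter <- Reduce(intersect, nonEmpty)
      if (length(inter) == 0L) "disjoint" else "overlapping"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      ko = ko, multiplicity_class = cls,
      n_conditions = length(nonEmpty),
      n_loci = length(unique(unlist(nonEmpty))),
      stringsAsFactors = FALSE)
    rows[[length(rows)]]$loci_by_condition <- list(sets)
  }
  if (!length(rows))
    return(data.frame(ko = character(), multiplicity_class = character(),
                      n_conditions = integer(), n_loci = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiplicity (isoenzyme) groups of a detection result
#'
#' Two counts are reported because the counting rule for partially
#' overlapping locus sets is a judgement call: the inclusive count treats
#' `disjoint` and `overlapping` KOs as isoenzymes, the strict count only
#' `disjoint` ones.
#'
#' @param groups result of [detectIsoenzymes()].
#' @return list with `inclusive`, `strict` (counts) and `groups` (the
#'   subset of rows with multiplicity).
#' @export
multiplicityCounts <- function(groups) {
  multi <- groups[groups$multiplicity_class %in%
                    c("disjoint", "overlapping"), , drop = FALSE]
  list(inclusive = nrow(multi),
       strict = sum(groups$multiplicity_class == "disjoint"),
       groups = multi)
}

#' Distinct pathways covered by isoenzyme groups
#'
#' @param groups result of [detectIsoenzymes()]; only rows with
#'   multiplicity (`disjoint` / `overlapping`) contribute.
#' @param koPathways data.frame with columns `ko` and `pathway`.
#' @return list with `count` (distinct pathway labels) and `table`
#'   (data.frame pathway x KO membership).
#' @export
pathwayCoverage <- function(groups, koPathways) {
  multi <- groups[groups$multiplicity_class %in%
                    c("disjoint", "overlapping"), , drop = FALSE]
  pw <- koPathways[koPathways$ko %in% multi$ko, , drop = FALSE]
  missing <- setdiff(multi$ko, koPathways$ko)
  if (length(missing))
    message(length(missing), " KO(s) without pathway annotation contribute 0")
  tab <- unique(pw[order(pw$pathway, pw$ko), c("pathway", "ko")])
  rownames(tab) <- NULL
  list(count = length(unique(pw$pathway)), table = tab)
}

#' Read a K-number multiplicity table
#'
#' Reads a curated table with one row per (K number, condition, locus) —
#' such as the packaged *Rhizobium etli* CFN42 minimal-medium / bacteroid
#' table shipped under `extdata` — into the inputs of
#' [detectIsoenzymes()].
#'
#' @param path TSV with columns `K number`, `Physiological condition`,
#'   `Locus tag` and optionally `Annotation`.
#' @return list with `profiles` (per-condition locus vectors), `koMap`
#'   (`locus`, `ko`) and `annotations` (named by locus).
#' @examples
#' tab <- system.file("extdata", "retli_isoenzymes_table.tsv",
#'                    package = "proTRN")
#' fx <- readIsoenzymeTable(tab)
#' groups <- detectIsoenzymes(fx$profiles, fx$koMap)
#' @export
readIsoenzymeTable <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("K number", "Physiological condition", "Locus tag")
  if (!all(need %in% names(tab)))
    stop(sprintf("%s: expected columns %s", path,
                 paste(need, collapse = ", ")))
  profiles <- lapply(split(tab, tab$`Physiological condition`),
                     function(d) sort(unique(d$`Locus tag`)))
  koMap <- unique(data.frame(locus = tab$`Locus tag`,
                             ko = tab$`K number`,
                             stringsAsFactors = FALSE))
  ann <- if ("Annotation" %in% names(tab))
    setNames(tab$Annotation, tab$`Locus tag`) else NULL
  list(profiles = profiles, koMap = koMap, annotations = ann)
}

#' Regulators of isoenzyme groups across conditions
#'
#' For every multiplicity group and condition, collects the regulators
#' (with winning matrix index and p-value) inferred for each member locus
#' in that condition's network. A group is flagged differentially
#' regulated when the regulator sets differ between conditions; member
#' loci with no inferred regulator are listed as uncovered.
#'
#' @param groups result of [detectIsoenzymes()].
#' @param nets named list of [RegNetwork-class], one per condition (names
#'   must match the profile conditions).
#' @return data.frame with one row per multiplicity group: `ko`,
#'   `differential` (logical), `regulators_by_condition` (list-column of
#'   named lists of data.frames with `tf`, `matrix_id`, `p_value`),
#'   `uncovered` (list-column of loci with no regulator).
#' @export
differentialRegulators <- function(groups, nets) {
  multi <- groups[groups$multiplicity_class %in%
                    c("disjoint", "overlapping"), , drop = FALSE]
  out <- vector("list", nrow(multi))
  for (r in seq_len(nrow(multi))) {
    sets <- multi$loci_by_condition[[r]]
    regsBy <- list()
    tfSets <- list()
    uncovered <- character()
    for (cond in names(sets)) {
      loci <- sets[[cond]]
      if (!length(loci) || is.null(nets[[cond]])) next
      ed <- regEdges(nets[[cond]])
      sel <- ed[ed$target %in% loci, c("tf", "matrix_id", "p_value"),
                drop = FALSE]
      regsBy[[cond]] <- sel
      tfSets[[cond]] <- sort(unique(sel$tf))
      uncovered <- c(uncovered, setdiff(loci, sel$target))
    }
    differential <- length(tfSets) >= 2L &&
      !all(vapply(tfSets, identical, TRUE, y = tfSets[[1]]))
    row <- data.frame(ko = multi$ko[r], differential = differential,
                      stringsAsFactors = FALSE)
    row$regulators_by_condition <- list(regsBy)
    row$uncovered <- list(unique(uncovered))
    out[[r]] <- row
  }
  if (!length(out))
    return(data.frame(ko = character(), differential = logical()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write a K-number multiplicity table
#'
#' One row per (K number, condition, locus), the shape of a curated
#' isoenzyme table, with an optional annotation column.
#'
#' @param groups result of [detectIsoenzymes()].
#' @param path output TSV path.
#' @param annotations optional named character vector by locus.
#' @return the path, invisibly.
#' @export
writeIsoenzymeTable <- function(groups, path, annotations = NULL) {
  rows <- list()
  for (r in seq_len(nrow(groups))) {
    sets <- groups$loci_by_condition[[r]]
    for (cond in names(sets)) {
      for (locus in sets[[cond]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          `K number` = groups$ko[r], `Physiological condition` = cond,
          `Locus tag` = locus,
          Annotation = if (!is.null(annotations) &&
                           locus %in% names(annotations))
            annotations[[locus]] else "",
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
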