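# Hierarchy decomposition: strip structural genes, classify edges by
# out-connectivity, remove bottom-up edges and layer the remaining DAG.

#' Remove structural genes from a network
#'
#' Structural genes are nodes with out-connectivity zero (they regulate
#' nothing); they and their incident edges are removed in a single pass
#' (not iterated, since iterating would change the out-connectivities the
#' later classification relies on).
#'
#' @param net a [RegNetwork-class] or directed [igraph::igraph].
#' @return list with `graph` (the reduced [igraph::igraph]) and
#'   `structural` (removed locus tags).
#' @export
stripStructural <- function(net) {
  g <- .asIgraph(net)
  kout <- igraph::degree(g, mode = "out", loops = TRUE)
  structural <- igraph::V(g)$name[kout == 0]
  list(graph = igraph::delete_vertices(g, structural),
       structural = structural)
}

#' Classify edges as top-down or bottom-up
#'
#' An edge (a, b) is top-down iff the out-connectivity of a strictly
#' exceeds that of b; ties and inversions are bottom-up (the "otherwise"
#' branch). A self-loop is always a tie, hence always bottom-up.
#' Out-connectivities are computed on the graph as given (normally the
#' structural-stripped graph).
#'
#' @param graph a directed [igraph::igraph] with named vertices.
#' @return list of data.frames `topDown` and `bottomUp`, columns `from`,
#'   `to`.
#' @export
classifyEdges <- function(graph) {
  ed <- igraph::as_data_frame(graph, what = "edges")
  if (nrow(ed) == 0L) {
    empty <- data.frame(from = character(), to = character(),
                        stringsAsFactors = FALSE)
    return(list(topDown = empty, bottomUp = empty))
  }
  kout <- igraph::degree(graph, mode = "out", loops = TRUE)
  td <- kout[ed$from] > kout[ed$to]
  list(topDown = ed[td, c("from", "to"), drop = FALSE],
       bottomUp = ed[!td, c("from", "to"), drop = FALSE])
}

#' Decompose a regulatory network into hierarchy layers
#'
#' Strips structural genes, removes all bottom-up edges (which eliminates
#' every feedback circuit, leaving a DAG), and applies layered topological
#' sorting: layer 1 holds the roots (in-degree 0), and every other node
#' sits one layer below its deepest regulator, so each node can only
#' regulate nodes in strictly lower layers. Regulators left without any
#' retained edge are placed in the bottom layer and reported in
#' `isolatedRegulators()`. Adding the removed bottom-up edges and the
#' structural genes back reconstructs the original network exactly.
#'
#' @param net a [RegNetwork-class] or directed [igraph::igraph] with named
#'   vertices.
#' @return a [HierarchyResult-class].
#' @examples
#' g <- igraph::graph_from_literal(A -+ B, A -+ C, B -+ C)
#' hierarchyDecompose(g)
#' @export
hierarchyDecompose <- function(net) {
  g0 <- .asIgraph(net)
  st <- stripStructural(g0)
  g <- st$graph
  cls <- classifyEdges(g)
  dag <- igraph::graph_from_data_frame(
    cls$topDown, directed = TRUE,
    vertices = data.frame(name = igraph::V(g)$name))
  if (!igraph::is_dag(dag))
    stop("internal error: residual cycle after bottom-up edge removal")
  deg <- igraph::degree(dag, mode = "all")
  isolated <- igraph::V(dag)$name[deg == 0]
  core <- igraph::delete_vertices(dag, isolated)
  layers <- list()
  if (igraph::vcount(core) > 0) {
    # longest path from the roots: peel in-degree-0 nodes repeatedly
    depth <- rep(1L, igraph::vcount(core))
    names(depth) <- igraph::V(core)$name
    topo <- igraph::V(core)$name[igraph::topo_sort(core, mode = "out")]
    for (v in topo) {
      preds <- igraph::V(core)$name[
        igraph::neighbors(core, v, mode = "in")]
      if (length(preds)) depth[v] <- max(depth[preds]) + 1L
    }
    for (d in sort(unique(depth)))
      layers[[length(layers) + 1L]] <- sort(names(depth)[depth == d])
  }
  if (length(isolated)) {
    if (length(layers) == 0L) layers <- list(sort(isolated))
    else layers[[length(layers)]] <- sort(c(layers[[length(layers)]],
                                            isolated))
  }
  nClass <- nrow(cls$topDown) + nrow(cls$bottomUp)
  new("HierarchyResult",
      layers = layers,
      removedBottomUp = cls$bottomUp,
      bottomUpFraction = if (nClass) nrow(cls$bottomUp) / nClass else NaN,
      structuralRemoved = st$structural,
      isolated = isolated,
      edges = cls$topDown)
}

#' Indented text report of a hierarchy
#'
#' @param hier a [HierarchyResult-class].
#' @param annotations optional named character vector (e.g. TF family
#'   labels) appended to node names.
#' @return character vector of report lines, invisibly printed.
#' @export
hierarchyReport <- function(hier, annotations = NULL) {
  lines <- character()
  for (i in seq_along(hier@layers)) {
    lines <- c(lines, sprintf("Layer %d:", i))
    for (v in hier@layers[[i]]) {
      ann <- if (!is.null(annotations) && v %in% names(annotations))
        sprintf(" (%s)", annotations[[v]]) else ""
      lines <- c(lines, sprintf("  %s%s", v, ann))
    }
  }
  lines
}

#' Export a hierarchy as JSON
#'
#' @param hier a [HierarchyResult-class].
#' @param path output file path.
#' @param annotations optional named character vector passed through as
#'   node metadata.
#' @return the path, invisibly.
#' @export
writeHierarchyJson <- function(hier, path, annotations = NULL) {
  obj <- list(
    layers = lapply(hier@layers, function(l) {
      if (is.null(annotations)) as.list(l)
      else lapply(l, function(v) list(
        locus = v,
        annotation = if (v %in% names(annotations)) annotations[[v]] else NULL))
    }),
    bottom_up_fraction = hier@bottomUpFraction,
    removed_bottom_up = hier@removedBottomUp,
    structural_removed = hier@structuralRemoved,
    isolated_regulators = hier@isolated)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
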