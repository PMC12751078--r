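#' Build the conserved-PPI graph
#'
#' Nodes are ortholog-group IDs; edges are exactly the group pairs with span
#' at or above `min_span`, annotated with span, a solved flag from the
#' structure index, and the sorted PDB IDs. Self-loops (homo-oligomer group
#' pairs) are kept. Multi-edges cannot arise because spans are already
#' collapsed per group pair.
#'
#' @param spans A `ppi_spans` object.
#' @param index A `structure_index`.
#' @param min_span Minimum span for inclusion (default 5, the "observed in
#'   at least five species" convention).
#' @return An igraph object with edge attributes `span` (integer), `solved`
#'   (logical) and `pdb_ids` (semicolon-joined string).
#' @export
build_graph <- function(spans, index, min_span = 5L) {
  stopifnot(inherits(spans, "ppi_spans"), inherits(index, "structure_index"),
            min_span >= 1L)
  sel <- spans$span >= min_span
  ga <- spans$group_a[sel]; gb <- spans$group_b[sel]
  key <- paste(ga, gb, sep = "\t")
  solved <- key %in% index$solved
  pdb <- vapply(key, function(k) {
    ids <- index$evidence[[k]]
    if (is.null(ids)) "" else paste(sort(ids), collapse = ";")
  }, "", USE.NAMES = FALSE)
  nodes <- sort(unique(c(ga, gb)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (length(ga)) {
    g <- igraph::add_edges(g, rbind(match(ga, nodes), match(gb, nodes)),
                           span = as.integer(spans$span[sel]),
                           solved = solved, pdb_ids = pdb)
  }
  g
}

#' Largest connected components of the conserved graph
#'
#' Components ranked by node count descending, ties broken by edge count
#' descending (self-loops count as one edge), then by smallest node ID.
#' Self-loops never merge distinct nodes.
#'
#' @param graph igraph object from [build_graph()].
#' @param k Number of components to return (k <= 0 is an error).
#' @return List of igraph subgraphs, largest first (at most `k`).
#' @export
components_ranked <- function(graph, k = 10L) {
  if (k <= 0L) stop("k must be positive")
  comp <- igraph::components(graph)
  if (comp$no == 0L) return(list())
  subs <- lapply(seq_len(comp$no), function(i) {
    igraph::induced_subgraph(graph, which(comp$membership == i))
  })
  nsize <- vapply(subs, function(s) as.integer(igraph::vcount(s)), 0L)
  esize <- vapply(subs, igraph::ecount, 0)
  minid <- vapply(subs, function(s) min(igraph::V(s)$name), "")
  ord <- order(-nsize, -esize, minid)
  subs[ord][seq_len(min(k, length(subs)))]
}

#' Solved/unsolved edge counts of a component
#'
#' The quantity behind the two edge colours of the conserved-network
#' figures: structurally solved (with PDB IDs) versus unsolved PPIs.
#'
#' @param component igraph object with a logical `solved` edge attribute.
#' @return Named integer vector `c(n_solved =, n_unsolved =)` summing to the
#'   edge count.
#' @export
edge_color_summary <- function(component) {
  if (igraph::ecount(component) == 0L) {
    return(c(n_solved = 0L, n_unsolved = 0L))
  }
  s <- igraph::E(component)$solved
  c(n_solved = sum(s), n_unsolved = sum(!s))
}

#' Export a conserved graph
#'
#' `edge-tsv` writes columns (group_a, group_b, span, solved{0,1}, pdb_ids)
#' and round-trips through [import_graph_tsv()]; `graphml` writes
#' igraph-flavoured GraphML (solved encoded as 0/1).
#'
#' @param graph igraph object from [build_graph()].
#' @param path Output path.
#' @param format One of "edge-tsv", "graphml".
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("edge-tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g2 <- graph
    if (igraph::ecount(g2) > 0L) {
      igraph::E(g2)$solved <- as.integer(igraph::E(g2)$solved)
    }
    igraph::write_graph(g2, path, format = "graphml")
    return(invisible(path))
  }
  el <- igraph::as_edgelist(graph)
  df <- data.frame(
    group_a = pmin(el[, 1L], el[, 2L]),
    group_b = pmax(el[, 1L], el[, 2L]),
    span = if (igraph::ecount(graph)) igraph::E(graph)$span else integer(),
    solved = if (igraph::ecount(graph)) as.integer(igraph::E(graph)$solved) else integer(),
    pdb_ids = if (igraph::ecount(graph)) igraph::E(graph)$pdb_ids else character(),
    stringsAsFactors = FALSE)
  df <- df[order(df$group_a, df$group_b), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Import a conserved graph from edge-list TSV
#' @param path Path written by [export_graph()] with format "edge-tsv".
#' @return igraph object with span/solved/pdb_ids edge attributes.
#' @export
import_graph_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "character", "integer",
                                         "integer", "character"),
                          quote = "", comment.char = "")
  nodes <- sort(unique(c(df$group_a, df$group_b)))
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(nodes), name = nodes)
  if (nrow(df)) {
    g <- igraph::add_edges(g, rbind(match(df$group_a, nodes),
                                    match(df$group_b, nodes)),
                           span = df$span, solved = df$solved == 1L,
                           pdb_ids = ifelse(is.na(df$pdb_ids), "", df$pdb_ids))
  }
  g
}
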