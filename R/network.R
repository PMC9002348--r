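#' Article-concept bipartite incidence structure
#'
#' The semantic networks are projections of a two-mode structure: articles
#' on one side, concept labels on the other, with a membership whenever a
#' record carries an entity with that label. Duplicate identical labels
#' within one record collapse to a single membership.
#'
#' @param corpus a `corpus` object.
#' @param mode label mode passed to [mesh_label()]: `"distinct"` (default,
#'   asterisked and qualified variants are separate concepts) or `"merged"`.
#' @return An object of class `bipartite_graph`: list with `pmids`,
#'   `labels` and `memberships` (data frame `pmid`, `label`).
#' @export
build_bipartite <- function(corpus, mode = c("distinct", "merged")) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "corpus"))
  mem <- lapply(corpus$records, function(r) {
    labs <- unique(mesh_label(r$entities, mode))
    if (!length(labs)) return(NULL)
    data.frame(pmid = r$pmid, label = labs, stringsAsFactors = FALSE)
  })
  mem <- do.call(rbind, c(mem, list(
    data.frame(pmid = integer(), label = character(),
               stringsAsFactors = FALSE))))
  rownames(mem) <- NULL
  structure(
    list(pmids = vapply(corpus$records, function(r) r$pmid, integer(1)),
         labels = sort(unique(mem$label), method = "radix"),
         memberships = mem,
         mode = mode),
    class = "bipartite_graph"
  )
}

#' @exportS3Method base::print
print.bipartite_graph <- function(x, ...) {
  cat(sprintf(
    "<bipartite_graph> %d article(s) x %d concept label(s), %d membership(s) [%s mode]\n",
    length(x$pmids), length(x$labels), nrow(x$memberships), x$mode))
  invisible(x)
}

empty_weighted_graph <- function() {
  g <- igraph::make_empty_graph(0, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = character())
  igraph::set_edge_attr(g, "weight", value = numeric())
}

# Sparse 0/1 incidence matrix, articles x labels.
incidence_matrix <- function(bip) {
  pmids <- sort(unique(bip$memberships$pmid))
  labels <- bip$labels
  Matrix::sparseMatrix(
    i = match(bip$memberships$pmid, pmids),
    j = match(bip$memberships$label, labels),
    x = 1,
    dims = c(length(pmids), length(labels)),
    dimnames = list(as.character(pmids), labels)
  )
}

#' Project the bipartite structure onto concepts: the semantic network
#'
#' Two concepts are linked whenever they are annotated on the same article;
#' the edge weight is the number of co-annotating articles. Computed as the
#' off-diagonal of the sparse cross-product of the incidence matrix. The
#' result is an undirected, weighted, simple igraph graph whose vertex names
#' are the concept labels; labels that never co-occur with another remain as
#' isolated vertices.
#'
#' @param bip a `bipartite_graph`.
#' @return An igraph graph with a `weight` edge attribute.
#' @export
project_concepts <- function(bip) {
  stopifnot(inherits(bip, "bipartite_graph"))
  M <- incidence_matrix(bip)
  g <- if (ncol(M) == 0L) {
    empty_weighted_graph()
  } else {
    cooc <- Matrix::crossprod(M)         # labels x labels, diag = label usage
    igraph::graph_from_adjacency_matrix(
      cooc, mode = "undirected", weighted = TRUE, diag = FALSE)
  }
  g <- igraph::set_graph_attr(g, "projection", "concept")
  igraph::set_graph_attr(g, "label_mode", bip$mode)
}

#' Project the bipartite structure onto articles
#'
#' The dual projection: articles are linked when they share concept labels,
#' with weight equal to the number of shared labels (the more terms shared,
#' the stronger the link). Vertex names are PMIDs as character.
#'
#' @param bip a `bipartite_graph`.
#' @return An igraph graph with a `weight` edge attribute.
#' @export
project_articles <- function(bip) {
  stopifnot(inherits(bip, "bipartite_graph"))
  M <- incidence_matrix(bip)
  g <- if (nrow(M) == 0L) {
    empty_weighted_graph()
  } else {
    shared <- Matrix::tcrossprod(M)      # articles x articles
    igraph::graph_from_adjacency_matrix(
      shared, mode = "undirected", weighted = TRUE, diag = FALSE)
  }
  g <- igraph::set_graph_attr(g, "projection", "article")
  igraph::set_graph_attr(g, "label_mode", bip$mode)
}

#' Export a weighted edge list
#'
#' Writes the network as a three-column tab-separated table
#' (`source`, `target`, `weight`), the exchange format used for the
#' supplementary edge lists of co-word studies and accepted by Cytoscape.
#'
#' @param net an igraph graph with a `weight` edge attribute.
#' @param file path to write to; when `NULL` the data frame is returned.
#' @return The edge-list data frame, invisibly when written to a file.
#' @export
write_edge_list <- function(net, file = NULL) {
  stopifnot(igraph::is_igraph(net))
  el <- igraph::as_edgelist(net)
  df <- data.frame(
    source = el[, 1L], target = el[, 2L],
    weight = if (igraph::ecount(net)) igraph::E(net)$weight else numeric(),
    stringsAsFactors = FALSE)
  if (is.null(file)) return(df)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export a network as GraphML
#'
#' @param net an igraph graph.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_graphml <- function(net, file) {
  stopifnot(igraph::is_igraph(net))
  igraph::write_graph(net, file, format = "graphml")
  invisible(file)
}

#' Drop edges below a minimum co-occurrence weight
#'
#' @param net an igraph graph with a `weight` edge attribute.
#' @param min_weight smallest weight to keep (default 1 keeps everything).
#' @return The filtered graph; vertices are retained even if isolated.
#' @export
filter_min_weight <- function(net, min_weight = 1) {
  stopifnot(igraph::is_igraph(net), min_weight >= 1)
  if (igraph::ecount(net) == 0L || min_weight <= 1) return(net)
  igraph::delete_edges(net, igraph::E(net)[igraph::E(net)$weight < min_weight])
}
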