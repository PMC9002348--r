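#' Per-node and global topology statistics
#'
#' Computes, for every concept in a semantic network: the unweighted degree
#' `k` (number of adjacent concepts — the published connectivity values),
#' the rank `R` (1 for the most connected concept, 2 for the second, and so
#' on; ties broken by ascending label so ranking is deterministic and
#' independent of node order), the strength (sum of incident co-occurrence
#' weights), betweenness and closeness centrality on the unweighted graph,
#' and the local clustering coefficient. On disconnected graphs closeness
#' is computed within each node's component and scaled by the component's
#' share of the graph (the Wasserman–Faust correction); an isolated node
#' has closeness 0.
#'
#' Global statistics cover node and edge counts, density
#' `2|E| / (|V|(|V|-1))`, the number of connected components, the mean
#' clustering coefficient and the exact-integer degree histogram.
#'
#' @param net an igraph semantic network with at least one vertex.
#' @return An object of class `topology_report`: list with `nodes` (data
#'   frame `label`, `k`, `R`, `strength`, `betweenness`, `closeness`,
#'   `clustering`, sorted by `R`) and `global` (list).
#' @export
compute_node_stats <- function(net) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  if (n == 0L) stop("empty network: no nodes to rank", call. = FALSE)
  labels <- igraph::V(net)$name
  if (is.null(labels)) labels <- as.character(seq_len(n))
  k <- as.integer(igraph::degree(net))
  strength <- if (is.null(igraph::E(net)$weight)) k else
    as.integer(round(igraph::strength(net, weights = igraph::E(net)$weight)))
  btw <- igraph::betweenness(net, weights = NA)
  cls <- closeness_wf(net)
  clu <- igraph::transitivity(net, type = "local", isolates = "zero")
  ord <- order(-k, labels, method = "radix")
  R <- integer(n)
  R[ord] <- seq_len(n)
  nodes <- data.frame(
    label = labels, k = k, R = R, strength = strength,
    betweenness = btw, closeness = cls, clustering = clu,
    stringsAsFactors = FALSE)
  nodes <- nodes[ord, , drop = FALSE]
  rownames(nodes) <- NULL
  m <- igraph::ecount(net)
  hist <- table(factor(k, levels = sort(unique(k))))
  global <- list(
    nodes = n,
    edges = m,
    density = if (n >= 2L) 2 * m / (n * (n - 1)) else NA_real_,
    components = igraph::count_components(net),
    mean_clustering = mean(clu),
    degree_distribution = data.frame(
      k = as.integer(names(hist)), count = as.integer(hist))
  )
  structure(list(nodes = nodes, global = global),
            class = "topology_report")
}

# Closeness with the Wasserman-Faust correction for disconnected graphs:
# within-component closeness scaled by (component size - 1)/(n - 1).
closeness_wf <- function(net) {
  n <- igraph::vcount(net)
  if (n == 1L) return(0)
  comp <- igraph::components(net)
  out <- numeric(n)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    nc <- length(idx)
    if (nc == 1L) {
      out[idx] <- 0
      next
    }
    d <- igraph::distances(net, v = idx, to = idx, weights = NA)
    tot <- rowSums(d)
    out[idx] <- ((nc - 1) / (n - 1)) * ((nc - 1) / tot)
  }
  out
}

#' @exportS3Method base::print
print.topology_report <- function(x, ...) {
  g <- x$global
  cat(sprintf(
    "<topology_report> %d node(s), %d edge(s), density %.4g, %d component(s)\n",
    g$nodes, g$edges, g$density, g$components))
  cat("top of ranking:\n")
  print(utils::head(x$nodes, 5L))
  invisible(x)
}

#' The most connected concepts of a network
#'
#' Returns the first `n` rows of the degree ranking, the "Top-N" listing
#' conventional in co-word studies.
#'
#' @param report a `topology_report`.
#' @param n number of entries (default 20); when larger than the node count
#'   all nodes are returned.
#' @return Data frame of node statistics, rank 1 first.
#' @export
top_ranked <- function(report, n = 20L) {
  stopifnot(inherits(report, "topology_report"), n >= 1L)
  utils::head(report$nodes, min(as.integer(n), nrow(report$nodes)))
}

#' Core-periphery partition by degree quantile
#'
#' Well-connected nodes form the core of a semantic network, sparsely
#' connected nodes its periphery. Here the core is the set of nodes whose
#' degree reaches the upper `quantile` tail of the empirical degree
#' distribution (threshold at the `1 - quantile` quantile).
#'
#' @param report a `topology_report`.
#' @param quantile fraction of the degree distribution regarded as core;
#'   strictly between 0 and 1.
#' @return Named character vector mapping every label to `"core"` or
#'   `"periphery"`.
#' @export
core_periphery <- function(report, quantile = 0.1) {
  stopifnot(inherits(report, "topology_report"))
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile >= 1) {
    stop("quantile must lie strictly between 0 and 1", call. = FALSE)
  }
  thr <- stats::quantile(report$nodes$k, probs = 1 - quantile,
                         names = FALSE, type = 7)
  out <- ifelse(report$nodes$k >= thr, "core", "periphery")
  names(out) <- report$nodes$label
  out
}

#' Export a topology report
#'
#' Writes the per-node table as CSV and the global statistics as JSON, the
#' "network statistics" companion to the edge-list exports.
#'
#' @param report a `topology_report`.
#' @param csv_file path for the per-node CSV.
#' @param json_file path for the global-statistics JSON.
#' @return Invisibly, the report.
#' @export
write_topology_report <- function(report, csv_file, json_file) {
  stopifnot(inherits(report, "topology_report"))
  utils::write.csv(report$nodes, csv_file, row.names = FALSE)
  glob <- report$global
  glob$degree_distribution <- NULL
  glob$degree_histogram <- stats::setNames(
    as.list(report$global$degree_distribution$count),
    report$global$degree_distribution$k)
  jsonlite::write_json(glob, json_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
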