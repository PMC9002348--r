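#' Extract a seed-plus-first-neighbour induced subnetwork
#'
#' The thematic subnetworks of a semantic network are built from a set of
#' seed concepts together with every concept within graph distance `radius`
#' of a seed (first neighbours, by default). The subnetwork is the
#' *induced* subgraph on that node set: every parent edge whose endpoints
#' are both retained is kept, with its weight — not just the edges incident
#' to a seed — so the dense interconnection among a theme's neighbours is
#' preserved.
#'
#' @param net an igraph semantic network with named vertices.
#' @param seeds character vector of seed labels; every seed must exist in
#'   `net` (an unknown seed raises an error that suggests the closest
#'   labels by edit distance).
#' @param radius neighbourhood radius (default 1, the first neighbours).
#' @param include_major_variants when `TRUE`, each seed additionally pulls
#'   in its major-topic twin (`"*Culture"` for `"Culture"` and vice versa)
#'   when that label exists in the network.
#' @return The induced igraph subgraph.
#' @export
extract_subnetwork <- function(net, seeds, radius = 1L,
                               include_major_variants = FALSE) {
  stopifnot(igraph::is_igraph(net), length(seeds) >= 1L, radius >= 1L)
  seeds <- unique(as.character(seeds))
  labels <- igraph::V(net)$name
  missing <- setdiff(seeds, labels)
  if (length(missing)) {
    hints <- vapply(missing, function(m) {
      d <- utils::adist(m, labels)[1L, ]
      paste(labels[order(d)][seq_len(min(3L, length(labels)))],
            collapse = ", ")
    }, character(1))
    stop("seed label(s) not in network: ",
         paste(sprintf("%s (did you mean: %s?)",
                       sQuote(missing), hints), collapse = "; "),
         call. = FALSE)
  }
  if (include_major_variants) {
    twins <- ifelse(startsWith(seeds, "*"),
                    sub("^\\*", "", seeds), paste0("*", seeds))
    seeds <- unique(c(seeds, intersect(twins, labels)))
  }
  hoods <- igraph::ego(net, order = radius, nodes = seeds)
  keep <- unique(unlist(lapply(hoods, as.integer)))
  igraph::induced_subgraph(net, keep)
}

#' Node and edge counts of a subnetwork
#'
#' @param sub an igraph graph.
#' @return Named integer vector `c(nodes = , edges = )`.
#' @export
subnetwork_summary <- function(sub) {
  stopifnot(igraph::is_igraph(sub))
  c(nodes = igraph::vcount(sub), edges = igraph::ecount(sub))
}
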