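#' Run the full literature-mining pipeline
#'
#' Orchestrates the staged analysis end to end: read (or generate) MEDLINE
#' records, apply the selection criteria, build the bipartite incidence and
#' its concept projection (the semantic network), compute topology
#' statistics, extract any requested seed subnetworks, and tally
#' publications by year and country. Every artifact is written under
#' `out_dir` and listed, with its MD5 content hash, in `manifest.csv`, so
#' two runs on the same inputs can be compared file by file.
#'
#' Exactly one corpus source must be given: `input` (paths to MEDLINE text
#' files) or `params` (a [generator_params] for a synthetic corpus).
#'
#' @param input character vector of MEDLINE text files, or `NULL`.
#' @param params a [generator_params] object, or `NULL`.
#' @param out_dir directory for artifacts (created if needed).
#' @param label_mode `"distinct"` or `"merged"` concept labels.
#' @param min_weight minimum co-occurrence weight to keep (default 1).
#' @param subnets optional named list of seed specifications; each element
#'   is a list with `seeds` (character) and optional `radius` and
#'   `include_major_variants`. Names become file stems.
#' @param blocklist optional integer vector (or path to a one-column text
#'   file) of PMIDs to exclude as manually curated.
#' @param article_projection also export the article-article projection.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `corpus`, `network`, `report`, `tallies`,
#'   `subnets` and the `manifest` data frame.
#' @export
run_pipeline <- function(input = NULL, params = NULL,
                         out_dir = "semnet-out",
                         label_mode = c("distinct", "merged"),
                         min_weight = 1,
                         subnets = NULL,
                         blocklist = NULL,
                         article_projection = FALSE,
                         quiet = FALSE) {
  label_mode <- match.arg(label_mode)
  if (is.null(input) == is.null(params)) {
    stop("exactly one corpus source required: `input` files or ",
         "generator `params`", call. = FALSE)
  }
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  put <- function(name) {
    path <- file.path(out_dir, name)
    artifacts[[length(artifacts) + 1L]] <<- path
    path
  }

  if (!is.null(input)) {
    missing <- input[!file.exists(input)]
    if (length(missing)) {
      stop("stage read: input file(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    parsed <- lapply(input, parse_medline)
    records <- unlist(lapply(parsed, function(p) {
      lapply(p$records, as_bib_record)
    }), recursive = FALSE)
    issues <- do.call(rbind, lapply(parsed, `[[`, "issues"))
    if (nrow(issues)) {
      utils::write.csv(issues, put("parse_issues.csv"), row.names = FALSE)
    }
    say("stage read: %d record(s) from %d file(s), %d parse issue(s)",
        length(records), length(input), nrow(issues))
  } else {
    records <- generate_corpus(params)
    say("stage simulate: %d record(s), seed %d",
        length(records), params$seed)
  }

  if (is.character(blocklist) && length(blocklist) == 1L &&
      file.exists(blocklist)) {
    blocklist <- as.integer(readLines(blocklist, warn = FALSE))
  }
  corpus <- apply_selection_criteria(records, blocklist = blocklist)
  utils::write.csv(corpus$exclusions, put("exclusions.csv"),
                   row.names = FALSE)
  say("stage filter: %d kept, %d excluded (%s)",
      length(corpus$records), nrow(corpus$exclusions),
      if (nrow(corpus$exclusions) == 0L) "none" else
        paste(sprintf("%s=%d", names(table(corpus$exclusions$reason)),
                      as.integer(table(corpus$exclusions$reason))),
              collapse = ", "))

  bip <- build_bipartite(corpus, mode = label_mode)
  net <- filter_min_weight(project_concepts(bip), min_weight)
  say("stage build: %d concept node(s), %d edge(s)",
      igraph::vcount(net), igraph::ecount(net))
  write_edge_list(net, put("concept_edges.tsv"))
  write_graphml(net, put("concept_network.graphml"))
  if (article_projection) {
    anet <- filter_min_weight(project_articles(bip), min_weight)
    write_edge_list(anet, put("article_edges.tsv"))
    write_graphml(anet, put("article_network.graphml"))
  }

  report <- compute_node_stats(net)
  write_topology_report(report, put("node_stats.csv"),
                        put("global_stats.json"))
  say("stage stats: density %.4g, %d component(s)",
      report$global$density, report$global$components)

  sub_results <- list()
  for (nm in names(subnets)) {
    sp <- subnets[[nm]]
    sub <- extract_subnetwork(
      net, seeds = sp$seeds, radius = sp$radius %||% 1L,
      include_major_variants = isTRUE(sp$include_major_variants))
    cnt <- subnetwork_summary(sub)
    say("stage subnet [%s]: %d node(s), %d edge(s)",
        nm, cnt[["nodes"]], cnt[["edges"]])
    write_edge_list(sub, put(paste0("subnet_", nm, "_edges.tsv")))
    write_graphml(sub, put(paste0("subnet_", nm, ".graphml")))
    sub_results[[nm]] <- sub
  }

  yearly <- tally_by_year(corpus)
  utils::write.csv(yearly, put("tally_year.csv"), row.names = FALSE)
  country <- tally_by_country(corpus)
  utils::write.csv(country, put("tally_country.csv"), row.names = FALSE)
  say("stage tally: %d year bucket(s), %d country bucket(s)",
      nrow(yearly), nrow(country))

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    bytes = unname(file.size(artifacts)),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)

  invisible(list(corpus = corpus, network = net, report = report,
                 tallies = list(year = yearly, country = country),
                 subnets = sub_results, manifest = manifest))
}
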