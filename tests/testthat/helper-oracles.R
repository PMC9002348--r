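# Brute-force oracles and small fixtures shared across the suite.
# The oracles deliberately use a different computational route
# (explicit pair enumeration) than the package's sparse cross-products.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical named weight vector for an undirected weighted graph:
# names are "a||b" with the endpoint pair byte-sorted, values are weights.
edge_weights <- function(net) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0L) return(stats::setNames(numeric(), character()))
  keys <- apply(el, 1L, function(p) {
    paste(sort(p, method = "radix"), collapse = "||")
  })
  w <- stats::setNames(as.numeric(igraph::E(net)$weight), keys)
  storage.mode(w) <- "double"
  w[order(names(w), method = "radix")]
}

# Concept co-occurrence weights by looping over every article and every
# label pair it carries.
oracle_concept_weights <- function(corpus, mode = "distinct") {
  counts <- list()
  for (rec in corpus$records) {
    labs <- sort(unique(mesh_label(rec$entities, mode)), method = "radix")
    if (length(labs) < 2L) next
    for (i in seq_len(length(labs) - 1L)) {
      for (j in (i + 1L):length(labs)) {
        key <- paste(labs[i], labs[j], sep = "||")
        counts[[key]] <- (counts[[key]] %||% 0) + 1
      }
    }
  }
  w <- unlist(counts) %||% stats::setNames(numeric(), character())
  storage.mode(w) <- "double"
  w[order(names(w), method = "radix")]
}

# Article similarity weights by looping over every article pair.
oracle_article_weights <- function(corpus, mode = "distinct") {
  labs <- lapply(corpus$records, function(r) unique(mesh_label(r$entities, mode)))
  pmids <- vapply(corpus$records, function(r) r$pmid, integer(1))
  counts <- list()
  n <- length(labs)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        shared <- length(intersect(labs[[i]], labs[[j]]))
        if (shared > 0L) {
          key <- paste(sort(as.character(c(pmids[i], pmids[j])),
                            method = "radix"), collapse = "||")
          counts[[key]] <- shared
        }
      }
    }
  }
  w <- unlist(counts) %||% stats::setNames(numeric(), character())
  storage.mode(w) <- "double"
  w[order(names(w), method = "radix")]
}

# Sum over articles of choose(t_a, 2), t_a = distinct labels on article a.
pairs_per_article_total <- function(corpus, mode = "distinct") {
  sum(vapply(corpus$records, function(r) {
    t_a <- length(unique(mesh_label(r$entities, mode)))
    choose(t_a, 2)
  }, numeric(1)))
}

# A small random corpus for property tests.
small_corpus <- function(seed, n_max = 50L, vocab_max = 40L) {
  with_seed_local(seed, {
    n <- sample(5:n_max, 1L)
    vocab <- sample(10:vocab_max, 1L)
  })
  params <- generator_params(
    n_records = n, vocab_size = vocab, terms_per_record = 5,
    universal_prob = 0.9, seed = seed)
  apply_selection_criteria(generate_corpus(params))
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

# Random weighted graph for topology/subnet property tests.
random_network <- function(seed, n_max = 30L) {
  with_seed_local(seed, {
    n <- sample(5:n_max, 1L)
    g <- igraph::sample_gnp(n, p = stats::runif(1, 0.1, 0.5))
    igraph::V(g)$name <- sprintf("Node %03d", sample(n))
    if (igraph::ecount(g) > 0L) {
      igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
    } else {
      g <- igraph::set_edge_attr(g, "weight", value = numeric())
    }
    g
  })
}
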