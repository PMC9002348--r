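#' Parameters for the synthetic MEDLINE corpus generator
#'
#' The generator emulates the statistical structure of a MeSH-annotated
#' PubMed search result: a near-universal check tag (the `Humans` analogue,
#' present on almost every human-health record), a heavy-tailed (Zipf)
#' popularity law over the remaining descriptors, a small per-record
#' annotation count, per-annotation major-topic flags and optional
#' qualifiers, publication years over a fixed window and affiliation
#' strings that end in a country name drawn from a skewed country mix.
#'
#' Defaults mirror a health-equity literature corpus: 950 records over
#' 2014–2021, ~12 annotations per record, `Humans` on 98% of records, a
#' Zipf exponent of 1.2 over a 300-descriptor vocabulary, and publication
#' output concentrated in the United States, Canada, Australia and the
#' United Kingdom.
#'
#' @param n_records number of records to generate.
#' @param vocab_size number of distinct non-universal descriptors.
#' @param zipf_exponent exponent `s` of the descriptor popularity law
#'   (probability of rank-`i` descriptor proportional to `i^-s`).
#' @param universal_prob probability that a record carries the universal
#'   `Humans` tag.
#' @param terms_per_record mean of the (zero-truncated Poisson) number of
#'   non-universal annotations per record; must be at least 1 and no larger
#'   than `vocab_size + 1`.
#' @param major_prob per-annotation probability of the major-topic flag.
#' @param qualifier_prob per-annotation probability of carrying a qualifier.
#' @param qualifier_vocab character vector of subheading texts to draw from.
#' @param year_range inclusive integer pair of publication years.
#' @param country_weights named non-negative vector (names are ISO-3 codes
#'   present in [default_gazetteer()]); records sample their affiliation
#'   country proportionally.
#' @param seed integer seed; identical parameters and seed give a
#'   byte-identical corpus (R's default Mersenne-Twister stream).
#' @return A validated `generator_params` list.
#' @export
generator_params <- function(n_records = 950L,
                             vocab_size = 300L,
                             zipf_exponent = 1.2,
                             universal_prob = 0.98,
                             terms_per_record = 12,
                             major_prob = 0.3,
                             qualifier_prob = 0.2,
                             qualifier_vocab = c(
                               "organization & administration", "education",
                               "ethnology", "psychology", "standards",
                               "epidemiology", "methods", "trends"),
                             year_range = c(2014L, 2021L),
                             country_weights = c(
                               USA = 40, CAN = 12, AUS = 9, GBR = 9,
                               BRA = 4, CHE = 3, DEU = 3, SWE = 2, FRA = 2,
                               MEX = 2, ESP = 2, IND = 2, NLD = 2, COL = 1,
                               NOR = 1, DNK = 1, KEN = 1, CHN = 1, ITA = 1,
                               ARG = 1),
                             seed = 1L) {
  p <- list(n_records = as.integer(n_records),
            vocab_size = as.integer(vocab_size),
            zipf_exponent = zipf_exponent,
            universal_prob = universal_prob,
            terms_per_record = terms_per_record,
            major_prob = major_prob,
            qualifier_prob = qualifier_prob,
            qualifier_vocab = as.character(qualifier_vocab),
            year_range = as.integer(year_range),
            country_weights = country_weights,
            seed = as.integer(seed))
  stopifnot(p$n_records >= 1L, p$vocab_size >= 1L, p$zipf_exponent > 0)
  for (nm in c("universal_prob", "major_prob", "qualifier_prob")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) {
      stop(nm, " must lie in [0, 1]", call. = FALSE)
    }
  }
  if (length(p$year_range) != 2L || p$year_range[1L] > p$year_range[2L]) {
    stop("year_range must be an ordered pair of years", call. = FALSE)
  }
  if (is.null(names(p$country_weights)) || all(p$country_weights <= 0)) {
    stop("country_weights must be a named vector with positive mass",
         call. = FALSE)
  }
  if (p$terms_per_record < 1 || p$terms_per_record > p$vocab_size + 1) {
    stop("terms_per_record must lie in [1, vocab_size + 1]", call. = FALSE)
  }
  structure(p, class = "generator_params")
}

# lambda of the zero-truncated Poisson whose truncated mean equals m.
ztp_lambda <- function(m) {
  if (m <= 1 + 1e-9) return(1e-9)
  stats::uniroot(function(l) l / (1 - exp(-l)) - m,
                 lower = 1e-9, upper = m, tol = 1e-10)$root
}

rztpois <- function(n, lambda) {
  out <- stats::rpois(n, lambda)
  while (any(out == 0L)) {
    z <- out == 0L
    out[z] <- stats::rpois(sum(z), lambda)
  }
  out
}

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_rng_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic MEDLINE-like corpus
#'
#' Draws `n_records` bibliographic records under the statistical model of
#' [generator_params()]. Each record receives a distinct PMID, a non-empty
#' title, a publication year uniform over the year range, one affiliation
#' string ending in a sampled country name, and `k >= 1` distinct MeSH
#' entities: descriptors drawn without replacement under the Zipf
#' popularity law, the universal `Humans` tag added with probability
#' `universal_prob`, and per-annotation major flags and qualifiers (the
#' asterisk is printed on the qualifier when both are present).
#'
#' Optional corruption injects, deterministically and on disjoint record
#' sets, `floor(rate * n)` violations of each kind — extra records reusing
#' an existing PMID (`duplicate`), records stripped of their MeSH
#' annotations (`no_mesh`) and records stripped of their title
#' (`no_title`) — so downstream exclusion accounting can be checked against
#' exact injected counts, returned in the `"injected"` attribute.
#'
#' @param params a [generator_params] object.
#' @param corrupt optional list with any of `duplicate`, `no_mesh`,
#'   `no_title` rates in `[0, 1)`.
#' @return List of [bib_record] objects with attribute `injected` (named
#'   integer vector of injected violation counts).
#' @export
generate_corpus <- function(params = generator_params(), corrupt = NULL) {
  stopifnot(inherits(params, "generator_params"))
  with_rng_seed(params$seed, {
    n <- params$n_records
    vocab <- sprintf("Concept %03d", seq_len(params$vocab_size))
    zipf_p <- seq_len(params$vocab_size)^(-params$zipf_exponent)
    zipf_p <- zipf_p / sum(zipf_p)
    lambda <- ztp_lambda(params$terms_per_record)
    gaz <- default_gazetteer()
    canon <- gaz[gaz$canonical == 1L, ]
    cnames <- stats::setNames(canon$variant, canon$iso3)
    iso <- names(params$country_weights)
    unknown_iso <- setdiff(iso, names(cnames))
    if (length(unknown_iso)) {
      stop("country_weights codes not in gazetteer: ",
           paste(unknown_iso, collapse = ", "), call. = FALSE)
    }
    records <- vector("list", n)
    for (i in seq_len(n)) {
      k <- min(rztpois(1L, lambda), params$vocab_size)
      desc <- sample(vocab, k, prob = zipf_p)
      major <- stats::runif(k) < params$major_prob
      has_q <- stats::runif(k) < params$qualifier_prob &
        length(params$qualifier_vocab) > 0L
      qual <- ifelse(has_q,
                     sample(params$qualifier_vocab, k, replace = TRUE),
                     NA_character_)
      ent <- mesh_entities(
        descriptor = desc, qualifier = qual, major = major,
        major_on_qualifier = major & has_q)
      if (stats::runif(1L) < params$universal_prob) {
        ent <- rbind(mesh_entities("Humans"), ent)
        class(ent) <- c("mesh_entities", "data.frame")
      }
      country <- sample(iso, 1L, prob = params$country_weights)
      records[[i]] <- bib_record(
        pmid = 1000000L + i,
        title = sprintf(
          "Synthetic study %d of equity-related concepts in a simulated health literature corpus",
          i),
        entities = ent,
        year = sample(seq(params$year_range[1L], params$year_range[2L]), 1L),
        affiliations = sprintf(
          "Department of Health Research, University %d, City %d, %s.",
          i %% 50L + 1L, i %% 20L + 1L, cnames[[country]]),
        language = "eng")
    }
    injected <- c(duplicate = 0L, no_mesh = 0L, no_title = 0L)
    if (!is.null(corrupt)) {
      n_nm <- floor((corrupt$no_mesh %||% 0) * n)
      n_nt <- floor((corrupt$no_title %||% 0) * n)
      n_dup <- floor((corrupt$duplicate %||% 0) * n)
      stopifnot(n_nm + n_nt <= n)
      hit <- sample(n, n_nm + n_nt)
      for (i in hit[seq_len(n_nm)]) {
        records[[i]]$entities <- mesh_entities()
      }
      for (i in hit[n_nm + seq_len(n_nt)]) {
        records[[i]]$title <- NA_character_
      }
      if (n_dup > 0L) {
        src <- sample(n, n_dup, replace = FALSE)
        records <- c(records, records[src])
      }
      injected <- c(duplicate = n_dup, no_mesh = n_nm, no_title = n_nt)
    }
    attr(records, "injected") <- injected
    records
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a generated corpus as MEDLINE plain text
#'
#' @param records list of [bib_record] objects (e.g. from
#'   [generate_corpus()]).
#' @param file optional output path.
#' @return MEDLINE text, invisibly when written to a file.
#' @export
records_to_medline <- function(records, file = NULL) {
  write_medline(lapply(records, as_raw_record), file = file)
}

#' The four-article worked example corpus
#'
#' A tiny fixed corpus used throughout the documentation and tests:
#' articles 1–4 annotated with subsets of `Humans` (H), `Health Equity`
#' (E), `Vulnerable Populations` (V), `Culture` (C) and `Trust` (T) —
#' A1 = \{H, E, V\}, A2 = \{H, E, C\}, A3 = \{H, V\}, A4 = \{H, C, T\} —
#' all published in 2020 from Mexico. Its concept projection has 5 nodes
#' and 7 edges and is small enough to verify by hand.
#'
#' @return `toy_corpus_records()`: the list of four [bib_record]s;
#'   `toy_corpus()`: the same records as a filtered `corpus` (the exclusion
#'   log is empty).
#' @export
toy_corpus_records <- function() {
  sets <- list(
    c("Humans", "Health Equity", "Vulnerable Populations"),
    c("Humans", "Health Equity", "Culture"),
    c("Humans", "Vulnerable Populations"),
    c("Humans", "Culture", "Trust"))
  lapply(seq_along(sets), function(i) {
    bib_record(
      pmid = i,
      title = paste0("T", i),
      entities = mesh_entities(descriptor = sets[[i]]),
      year = 2020L,
      affiliations = "Instituto Nacional de Salud, Mexico City, Mexico.",
      language = "eng")
  })
}

#' @rdname toy_corpus_records
#' @export
toy_corpus <- function() {
  apply_selection_criteria(toy_corpus_records())
}
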