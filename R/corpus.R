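#' Assemble the analysis corpus with exact exclusion accounting
#'
#' Applies the corpus selection criteria in a fixed, deterministic order:
#' a record whose PMID has already been seen is a `duplicate` (the first
#' occurrence is kept); a record with no MeSH annotation is `no-mesh`; a
#' record without a title is `no-title`. A record failing several criteria
#' is logged once, under the first matching reason in that order. An
#' optional PMID blocklist supports manual relevance curation, which cannot
#' be automated from the record content; blocklisted records are logged
#' under reason `blocklist` (checked after the automatic criteria).
#'
#' Accounting is exact: `length(records) == length(corpus) + nrow(exclusions)`.
#'
#' @param records list of [bib_record] objects, in input order.
#' @param blocklist optional integer vector of PMIDs to exclude as
#'   manually-curated irrelevant.
#' @return An object of class `corpus`: list with `records` (the kept
#'   records) and `exclusions` (data frame `pmid`, `reason`, `detail`).
#' @examples
#' corp <- apply_selection_criteria(toy_corpus_records())
#' length(corp$records)
#' @export
apply_selection_criteria <- function(records, blocklist = NULL) {
  stopifnot(is.list(records))
  seen <- new.env(parent = emptyenv())
  kept <- vector("list", length(records))
  n_kept <- 0L
  excl <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    stopifnot(inherits(rec, "bib_record"))
    key <- as.character(rec$pmid)
    reason <- NULL; detail <- ""
    if (!is.null(seen[[key]])) {
      reason <- "duplicate"
      detail <- sprintf("pmid first seen at input position %d", seen[[key]])
    } else {
      seen[[key]] <- i
      if (nrow(rec$entities) == 0L) {
        reason <- "no-mesh"; detail <- "record carries no MeSH annotation"
      } else if (is.na(rec$title) || !nzchar(rec$title)) {
        reason <- "no-title"; detail <- "record has no title"
      } else if (rec$pmid %in% blocklist) {
        reason <- "blocklist"; detail <- "pmid on user-supplied blocklist"
      }
    }
    if (is.null(reason)) {
      n_kept <- n_kept + 1L
      kept[[n_kept]] <- rec
    } else {
      excl[[length(excl) + 1L]] <- data.frame(
        pmid = rec$pmid, reason = reason, detail = detail,
        stringsAsFactors = FALSE)
    }
  }
  structure(
    list(
      records = kept[seq_len(n_kept)],
      exclusions = if (length(excl)) do.call(rbind, excl) else
        data.frame(pmid = integer(), reason = character(),
                   detail = character(), stringsAsFactors = FALSE)
    ),
    class = "corpus"
  )
}

#' @exportS3Method base::print
print.corpus <- function(x, ...) {
  cat(sprintf("<corpus> %d record(s) kept, %d excluded\n",
              length(x$records), nrow(x$exclusions)))
  if (nrow(x$exclusions)) {
    tab <- table(x$exclusions$reason)
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.corpus <- function(x) length(x$records)

#' Publications per year
#'
#' Counts corpus records by publication year; records without a year are
#' reported under an explicit `"unknown"` bucket so the counts always sum to
#' the corpus size.
#'
#' @param corpus a `corpus` object.
#' @return Data frame with columns `year` (character; ascending years, then
#'   `"unknown"` when present) and `count`.
#' @export
tally_by_year <- function(corpus) {
  stopifnot(inherits(corpus, "corpus"))
  years <- vapply(corpus$records, function(r) r$year, integer(1))
  known <- sort(table(years[!is.na(years)]))
  out <- data.frame(year = names(known), count = as.integer(known),
                    stringsAsFactors = FALSE)
  out <- out[order(as.integer(out$year)), , drop = FALSE]
  n_unknown <- sum(is.na(years))
  if (n_unknown > 0L) {
    out <- rbind(out, data.frame(year = "unknown", count = n_unknown,
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Publications per country of first affiliation
#'
#' Assigns each record at most one country: the first affiliation string is
#' split on commas and its segments are scanned right to left (country names
#' conventionally close an affiliation) for a gazetteer match; matching is
#' case-insensitive after trimming trailing punctuation. Records with no
#' affiliation or no match are counted under `"UNK"`.
#'
#' @param corpus a `corpus` object.
#' @param gazetteer data frame mapping country-name variants to ISO-3 codes,
#'   columns `variant` and `iso3`; defaults to [default_gazetteer()].
#' @return Data frame with columns `iso3` and `count`, sorted by descending
#'   count then code; counts sum to the corpus size.
#' @export
tally_by_country <- function(corpus, gazetteer = default_gazetteer()) {
  stopifnot(inherits(corpus, "corpus"))
  stopifnot(nrow(gazetteer) > 0L,
            all(c("variant", "iso3") %in% names(gazetteer)))
  lookup <- gazetteer$iso3
  names(lookup) <- tolower(trimws(gazetteer$variant))
  codes <- vapply(corpus$records, function(r) {
    if (!length(r$affiliations)) return("UNK")
    segs <- strsplit(r$affiliations[[1L]], ",", fixed = TRUE)[[1L]]
    segs <- tolower(gsub("[.;[:space:]]+$", "", trimws(segs)))
    for (s in rev(segs)) {
      if (!is.na(lookup[s])) return(unname(lookup[s]))
    }
    "UNK"
  }, character(1))
  tab <- table(codes)
  out <- data.frame(iso3 = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$iso3, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Built-in country gazetteer
#'
#' Common English country-name variants (including abbreviations such as
#' `"USA"` and `"UK"`) mapped to ISO-3 codes, shipped as a plain-text table.
#' The `canonical` column marks the display name used by the synthetic
#' corpus generator.
#'
#' @return Data frame with columns `iso3`, `variant`, `canonical`.
#' @export
default_gazetteer <- function() {
  path <- system.file("extdata", "country_gazetteer.csv",
                      package = "semnetmine", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
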