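#' Bibliographic record
#'
#' One curated MEDLINE entry: the PMID identifier, title, parsed MeSH
#' entities, publication year, affiliation strings and language, plus a
#' passthrough list for tags the pipeline does not interpret.
#'
#' @param pmid positive integer identifier.
#' @param title title string, or `NA` when the record has none (such records
#'   are excluded downstream by [apply_selection_criteria()]).
#' @param entities a [mesh_entities] data frame (possibly empty).
#' @param year integer calendar year or `NA`.
#' @param affiliations character vector of affiliation strings.
#' @param language language code (e.g. `"eng"`) or `NA`.
#' @param extra named list of uninterpreted tag values.
#' @return An object of class `bib_record`.
#' @export
bib_record <- function(pmid, title = NA_character_,
                       entities = mesh_entities(), year = NA_integer_,
                       affiliations = character(),
                       language = NA_character_, extra = list()) {
  pmid <- as.integer(pmid)
  if (length(pmid) != 1L || is.na(pmid) || pmid <= 0L) {
    stop("pmid must be a single positive integer", call. = FALSE)
  }
  validate_mesh_entities(entities)
  structure(
    list(pmid = pmid,
         title = as.character(title)[1L],
         entities = entities,
         year = as.integer(year)[1L],
         affiliations = as.character(affiliations),
         language = as.character(language)[1L],
         extra = extra),
    class = "bib_record"
  )
}

#' @exportS3Method base::print
print.bib_record <- function(x, ...) {
  cat(sprintf("<bib_record> PMID %d%s | %d MeSH entit%s | year %s\n",
              x$pmid,
              if (is.na(x$title)) " (untitled)" else "",
              nrow(x$entities), if (nrow(x$entities) == 1L) "y" else "ies",
              if (is.na(x$year)) "unknown" else x$year))
  invisible(x)
}
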