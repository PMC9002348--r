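#' MeSH annotation entities
#'
#' A MeSH annotation on a MEDLINE record is a descriptor, optionally refined
#' by a qualifier (subheading) attached with `/`, and optionally flagged as a
#' major topic of the article by a leading asterisk (printed either on the
#' descriptor, `*Descriptor`, or on the qualifier, `Descriptor/*qualifier`).
#' Following common practice in co-word analyses of MEDLINE, the asterisked
#' form and the descriptor/qualifier combinations are treated as concepts
#' distinct from the bare descriptor.
#'
#' Entities are stored as a data frame with one row per annotation and
#' columns `descriptor` (character), `qualifier` (character, `NA` when
#' absent), `major` (logical) and `major_on_qualifier` (logical; records on
#' which side of the `/` the asterisk was printed, so labels round-trip
#' exactly).
#'
#' @param descriptor character vector of descriptor texts (no `*`, no `/`).
#' @param qualifier character vector of qualifier texts or `NA`.
#' @param major logical vector, major-topic flag.
#' @param major_on_qualifier logical vector; `TRUE` when the asterisk sits on
#'   the qualifier. Must be `FALSE` where `major` is `FALSE` or `qualifier`
#'   is absent.
#' @return A `mesh_entities` data frame.
#' @export
mesh_entities <- function(descriptor = character(),
                          qualifier = NA_character_,
                          major = FALSE,
                          major_on_qualifier = FALSE) {
  n <- length(descriptor)
  ent <- data.frame(
    descriptor = as.character(descriptor),
    qualifier = rep_len(as.character(qualifier), n),
    major = rep_len(as.logical(major), n),
    major_on_qualifier = rep_len(as.logical(major_on_qualifier), n),
    stringsAsFactors = FALSE
  )
  validate_mesh_entities(ent)
  class(ent) <- c("mesh_entities", "data.frame")
  ent
}

validate_mesh_entities <- function(ent) {
  stopifnot(is.data.frame(ent))
  if (nrow(ent) == 0L) return(invisible(ent))
  bad <- !nzchar(ent$descriptor) | is.na(ent$descriptor)
  if (any(bad)) stop("mesh entity with empty descriptor", call. = FALSE)
  if (any(grepl("[/*]", ent$descriptor))) {
    stop("descriptor must not contain '/' or '*'", call. = FALSE)
  }
  q <- ent$qualifier[!is.na(ent$qualifier)]
  if (any(!nzchar(q)) || any(grepl("[/*]", q))) {
    stop("qualifier must be non-empty and free of '/' and '*'", call. = FALSE)
  }
  if (any(ent$major_on_qualifier & (is.na(ent$qualifier) | !ent$major))) {
    stop("major_on_qualifier requires major = TRUE and a qualifier",
         call. = FALSE)
  }
  invisible(ent)
}

#' Parse raw MH field values into MeSH entities
#'
#' Accepts the four printed forms `D`, `*D`, `D/Q` and `D/*Q` (and the rarer
#' `*D/Q`); whitespace is trimmed, capitalisation is preserved verbatim.
#'
#' @param raw character vector of MH field values, e.g.
#'   `"Health Equity/*organization & administration"`.
#' @return A [mesh_entities] data frame with one row per input value.
#' @examples
#' parse_mesh_field(c("Humans", "*Vulnerable Populations",
#'                    "Health Equity/*organization & administration"))
#' @export
parse_mesh_field <- function(raw) {
  raw <- trimws(as.character(raw))
  if (any(!nzchar(raw))) stop("empty MH field value", call. = FALSE)
  parts <- strsplit(raw, "/", fixed = TRUE)
  n_slash <- lengths(parts) - 1L
  if (any(n_slash > 1L)) {
    stop("MH value with more than one '/': ",
         paste(sQuote(raw[n_slash > 1L]), collapse = ", "), call. = FALSE)
  }
  desc <- trimws(vapply(parts, `[`, "", 1L))
  qual <- trimws(vapply(parts, function(p) {
    if (length(p) > 1L) p[[2L]] else NA_character_
  }, ""))
  major_desc <- startsWith(desc, "*")
  major_qual <- !is.na(qual) & startsWith(ifelse(is.na(qual), "", qual), "*")
  desc <- sub("^\\*", "", desc)
  qual <- sub("^\\*", "", qual)
  if (any(major_desc & major_qual)) {
    stop("MH value with asterisk on both descriptor and qualifier: ",
         paste(sQuote(raw[major_desc & major_qual]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(desc))) {
    stop("MH value with empty descriptor: ",
         paste(sQuote(raw[!nzchar(desc)]), collapse = ", "), call. = FALSE)
  }
  mesh_entities(
    descriptor = desc,
    qualifier = ifelse(is.na(qual) | !nzchar(qual), NA_character_, qual),
    major = major_desc | major_qual,
    major_on_qualifier = major_qual
  )
}

#' Node labels for MeSH entities
#'
#' Under the default `"distinct"` mode each printed MeSH variant is its own
#' concept: the major-topic asterisk is rendered back at its original
#' position and the qualifier is attached with `/`, so `*Health Equity` and
#' `Health Equity` are different node labels. Under `"merged"` mode the major
#' flag and qualifier are dropped, collapsing all variants onto the bare
#' descriptor.
#'
#' `parse_mesh_field()` is the exact inverse of `"distinct"` labels.
#'
#' @param entities a [mesh_entities] data frame.
#' @param mode `"distinct"` (default) or `"merged"`.
#' @return Character vector of labels, one per entity.
#' @export
mesh_label <- function(entities, mode = c("distinct", "merged")) {
  mode <- match.arg(mode)
  validate_mesh_entities(entities)
  if (nrow(entities) == 0L) return(character())
  if (mode == "merged") return(entities$descriptor)
  star_d <- ifelse(entities$major & !entities$major_on_qualifier, "*", "")
  qual <- ifelse(
    is.na(entities$qualifier), "",
    paste0("/", ifelse(entities$major_on_qualifier, "*", ""),
           entities$qualifier)
  )
  paste0(star_d, entities$descriptor, qual)
}
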