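#' Parse plain-text MEDLINE records
#'
#' Reads the tag-based "PubMed format" export: each record is a
#' blank-line-separated block of `TAG - value` lines, the tag padded to four
#' characters; values continue on lines indented by five or more spaces and
#' are re-joined with single spaces. Field order is preserved and every
#' non-blank input line is attributed to exactly one field value, so parsing
#' is lossless.
#'
#' Blocks without a `PMID` tag and lines that are neither a tag line nor a
#' continuation are not dropped silently: they are reported in the
#' line-addressed `issues` table of the result.
#'
#' @param file path to a MEDLINE text file (UTF-8; undecodable bytes are
#'   replaced and logged as issues).
#' @param text alternatively, the record text itself: a single string with
#'   embedded newlines or a character vector of lines.
#' @return An object of class `medline_records`: a list with elements
#'   `records` (list of raw records, each a data frame with columns `tag`,
#'   `value`, `n_lines`) and `issues` (data frame with columns `line`,
#'   `message`).
#' @seealso [write_medline()], [as_bib_record()]
#' @export
parse_medline <- function(file = NULL, text = NULL) {
  if (is.null(text) == is.null(file)) {
    stop("supply exactly one of `file` or `text`", call. = FALSE)
  }
  if (!is.null(file)) {
    text <- readLines(file, warn = FALSE, encoding = "UTF-8")
  }
  lines <- if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }

  issues <- list()
  note <- function(line, msg) {
    issues[[length(issues) + 1L]] <<- data.frame(
      line = line, message = msg, stringsAsFactors = FALSE)
  }

  fixed <- iconv(lines, from = "UTF-8", to = "UTF-8", sub = "�")
  repl <- which(is.na(lines) | fixed != lines)
  for (i in repl) note(i, "undecodable bytes replaced")
  lines <- ifelse(is.na(fixed), "�", fixed)

  records <- list()
  tag <- character(); value <- character(); n_lines <- integer()
  block_lines <- 0L

  flush_block <- function(end_line) {
    if (block_lines == 0L) return(invisible())
    rec <- data.frame(tag = tag, value = value, n_lines = n_lines,
                      stringsAsFactors = FALSE)
    if (any(rec$tag == "PMID")) {
      records[[length(records) + 1L]] <<- rec
    } else {
      note(end_line, sprintf(
        "block with no PMID tag (%d field value(s)) skipped", nrow(rec)))
    }
    tag <<- character(); value <<- character(); n_lines <<- integer()
    block_lines <<- 0L
  }

  is_tag_line <- function(ln) {
    nchar(ln) >= 6L && substr(ln, 5L, 6L) == "- " &&
      grepl("^[A-Z0-9]{1,4} {0,3}$", substr(ln, 1L, 4L))
  }

  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) {
      flush_block(i - 1L)
      next
    }
    if (is_tag_line(ln)) {
      tag[length(tag) + 1L] <- trimws(substr(ln, 1L, 4L))
      value[length(value) + 1L] <- substr(ln, 7L, nchar(ln))
      n_lines[length(n_lines) + 1L] <- 1L
      block_lines <- block_lines + 1L
    } else if (grepl("^ {5,}", ln) && length(value) > 0L) {
      k <- length(value)
      value[k] <- paste(value[k], trimws(ln, "left"))
      n_lines[k] <- n_lines[k] + 1L
      block_lines <- block_lines + 1L
    } else {
      note(i, paste0("malformed line (no tag separator, not a ",
                     "continuation): ", substr(ln, 1L, 60L)))
      block_lines <- block_lines + 1L
    }
  }
  flush_block(length(lines))

  structure(
    list(
      records = records,
      issues = if (length(issues)) do.call(rbind, issues) else
        data.frame(line = integer(), message = character(),
                   stringsAsFactors = FALSE)
    ),
    class = "medline_records"
  )
}

#' @exportS3Method base::print
print.medline_records <- function(x, ...) {
  cat(sprintf("<medline_records> %d record(s), %d parse issue(s)\n",
              length(x$records), nrow(x$issues)))
  invisible(x)
}

#' Write records back to MEDLINE plain text
#'
#' The inverse of [parse_medline()]: values longer than the wrap width are
#' broken at single spaces onto continuation lines indented six spaces, so
#' `parse_medline(text = write_medline(x))` reproduces `x` exactly.
#'
#' @param records a `medline_records` object or a bare list of raw-record
#'   data frames (`tag`, `value` columns).
#' @param file optional path; when given the text is written there.
#' @param width wrap width in columns (default 80, the conventional export
#'   width; round-tripping does not depend on it).
#' @return Invisibly (when `file` is given) or visibly, a single string of
#'   MEDLINE text.
#' @export
write_medline <- function(records, file = NULL, width = 80L) {
  if (inherits(records, "medline_records")) records <- records$records
  out <- character()
  for (rec in records) {
    if (any(grepl("\n", rec$value, fixed = TRUE))) {
      stop("field value contains a newline; normalise before writing",
           call. = FALSE)
    }
    for (j in seq_len(nrow(rec))) {
      head_prefix <- paste0(formatC(rec$tag[[j]], width = -4L), "- ")
      out <- c(out, wrap_field(rec$value[[j]], head_prefix, width))
    }
    out <- c(out, "")
  }
  txt <- if (length(out)) paste0(paste(out, collapse = "\n"), "\n") else ""
  if (!is.null(file)) {
    writeLines(txt, file, sep = "")
    return(invisible(txt))
  }
  txt
}

# Break a value at single-space positions only, so rejoining continuation
# lines with one space restores the text byte-for-byte. A chunk with no
# usable break point is emitted over-width rather than split mid-word.
wrap_field <- function(value, head_prefix, width) {
  cont_prefix <- strrep(" ", 6L)
  avail_head <- max(width - nchar(head_prefix), 1L)
  avail_cont <- max(width - 6L, 1L)
  chunks <- character()
  rest <- value
  avail <- avail_head
  while (nchar(rest) > avail) {
    chars <- strsplit(rest, "", fixed = TRUE)[[1L]]
    sp <- which(chars == " ")
    # single spaces only: neither neighbour is a space, and the break must
    # not strand leading whitespace on the continuation line
    ok <- sp[sp > 1L & sp < length(chars) &
               chars[sp - 1L] != " " & chars[sp + 1L] != " "]
    ok <- ok[ok <= avail + 1L]
    if (!length(ok)) break
    cut <- max(ok)
    chunks <- c(chunks, substr(rest, 1L, cut - 1L))
    rest <- substr(rest, cut + 1L, nchar(rest))
    avail <- avail_cont
  }
  chunks <- c(chunks, rest)
  paste0(c(head_prefix, rep(cont_prefix, length(chunks) - 1L)), chunks)
}

#' Convert a raw MEDLINE record to a bibliographic record
#'
#' Maps `PMID` to the integer identifier, `TI` to the title, `MH` values to
#' parsed MeSH entities, `DP` to the publication year (first four-digit
#' token; an unparseable date yields an absent year, not an error), `AD` to
#' affiliation strings and `LA` to the language. All other tags are kept in
#' a passthrough list.
#'
#' @param raw one raw record (a data frame with `tag` and `value` columns) as
#'   produced by [parse_medline()].
#' @return A `bib_record` object.
#' @export
as_bib_record <- function(raw) {
  vals <- function(tg) raw$value[raw$tag == tg]
  pmid_raw <- vals("PMID")
  if (!length(pmid_raw)) stop("record has no PMID field", call. = FALSE)
  if (!grepl("^[0-9]+$", trimws(pmid_raw[[1L]]))) {
    stop("non-numeric PMID: ", sQuote(pmid_raw[[1L]]), call. = FALSE)
  }
  dp <- vals("DP")
  year <- NA_integer_
  if (length(dp)) {
    m <- regmatches(dp[[1L]], regexpr("\\b[0-9]{4}\\b", dp[[1L]]))
    if (length(m)) year <- as.integer(m)
  }
  ti <- vals("TI")
  la <- vals("LA")
  known <- c("PMID", "TI", "MH", "DP", "AD", "LA")
  extra_idx <- which(!(raw$tag %in% known))
  extra <- split(raw$value[extra_idx], raw$tag[extra_idx])
  bib_record(
    pmid = as.integer(trimws(pmid_raw[[1L]])),
    title = if (length(ti)) ti[[1L]] else NA_character_,
    entities = parse_mesh_field_safe(vals("MH")),
    year = year,
    affiliations = vals("AD"),
    language = if (length(la)) la[[1L]] else NA_character_,
    extra = extra
  )
}

parse_mesh_field_safe <- function(mh) {
  if (!length(mh)) return(mesh_entities())
  parse_mesh_field(mh)
}

#' Convert a bibliographic record back to a raw MEDLINE record
#'
#' Inverse of [as_bib_record()] up to field ordering: emits `PMID`, `TI`,
#' `DP`, `LA`, `AD`, `MH` (as `"distinct"` labels) and any passthrough tags.
#'
#' @param record a `bib_record`.
#' @return A raw-record data frame consumable by [write_medline()].
#' @export
as_raw_record <- function(record) {
  stopifnot(inherits(record, "bib_record"))
  tg <- "PMID"; vl <- as.character(record$pmid)
  add <- function(tag, values) {
    values <- values[!is.na(values)]
    if (length(values)) {
      tg <<- c(tg, rep(tag, length(values)))
      vl <<- c(vl, values)
    }
  }
  add("TI", record$title)
  add("DP", if (is.na(record$year)) NA_character_ else
    as.character(record$year))
  add("LA", record$language)
  add("AD", record$affiliations)
  if (nrow(record$entities)) add("MH", mesh_label(record$entities))
  for (tag in names(record$extra)) add(tag, record$extra[[tag]])
  data.frame(tag = tg, value = vl, n_lines = NA_integer_,
             stringsAsFactors = FALSE)
}
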