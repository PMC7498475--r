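#' Segmentation of extracted full text into excluded and searchable regions
#'
#' Keyword scoring deliberately ignores the title/author/affiliation block,
#' the abstract, the acknowledgements and the literature-cited section, so
#' that e.g. an author affiliated with an "ecology institute" does not set
#' the ecology flag. `segment()` partitions the raw text into labelled,
#' contiguous character spans; `searchable_body()` concatenates the body
#' spans and repairs line-break artifacts before matching.
#'
#' Heading detection is line-anchored, case-insensitive and tolerant of
#' trailing punctuation and numerals ("References 7." still opens the
#' reference section). Synonym lists and the front-matter fallback fraction
#' are configurable via [seg_config()].
#'
#' @name segmenter
NULL

#' Segmentation configuration
#'
#' @param abstract_headings,body_headings,ack_headings,ref_headings character
#'   vectors of heading synonyms, matched case-insensitively as whole heading
#'   lines (trailing punctuation/digits allowed).
#' @param front_matter_fraction fraction of characters treated as front matter
#'   when a document carries no abstract or introduction heading at all.
#' @return a named list used by [segment()].
#' @export
seg_config <- function(abstract_headings = c("abstract", "summary"),
                       body_headings = c("introduction"),
                       ack_headings = c("acknowledgements", "acknowledgments",
                                        "acknowledgement", "acknowledgment"),
                       ref_headings = c("references", "literature cited",
                                        "bibliography"),
                       front_matter_fraction = 0.10) {
  stopifnot(front_matter_fraction > 0, front_matter_fraction < 1)
  list(abstract_headings = abstract_headings,
       body_headings = body_headings,
       ack_headings = ack_headings,
       ref_headings = ref_headings,
       front_matter_fraction = front_matter_fraction)
}

#' Join words hyphenated across line breaks and flatten remaining breaks
#'
#' PDF text extraction splits words across lines ("co-\nordinates"). Fragments
#' are rejoined when an alphabetic character precedes the hyphen-newline and
#' an alphabetic character follows; every remaining line break becomes a
#' single space. The operation is idempotent.
#'
#' @param text character scalar.
#' @return repaired character scalar without line breaks.
#' @export
#' @examples
#' repair_hyphenation("GIS/GPS co-\nordinates were provided")
repair_hyphenation <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  out <- stringr::str_replace_all(text, "(\\p{L})-\\r?\\n(\\p{L})", "\\1\\2")
  stringr::str_replace_all(out, "\\r?\\n", " ")
}

# regex for "this whole line is the heading <kw>", trailing punct/digits ok
heading_rx <- function(keywords) {
  alts <- paste(
    vapply(keywords, function(k) {
      stringr::str_replace_all(stringr::str_escape(k), "\\s+", "\\\\s+")
    }, character(1)),
    collapse = "|")
  stringr::regex(sprintf("^\\s*(?:%s)\\s*[[:punct:][:digit:]]*\\s*$", alts),
                 ignore_case = TRUE)
}

#' Partition raw text into labelled section spans
#'
#' Spans use 0-based, end-exclusive character offsets, are sorted, disjoint,
#' and jointly cover the whole text. The span opened by a heading starts at
#' that heading line. When neither an abstract nor an introduction heading is
#' found, the first `front_matter_fraction` of characters (capped at the first
#' occurrence of an introduction keyword, if any) is treated as front matter
#' and a warning is logged.
#'
#' @param raw_text character scalar, non-empty.
#' @param config list from [seg_config()].
#' @return a tibble with columns `label` (front_matter/abstract/body/
#'   acknowledgements/references), `start`, `end`.
#' @export
segment <- function(raw_text, config = seg_config()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1, nchar(raw_text) > 0)
  n <- nchar(raw_text)

  # line table with absolute start offsets (0-based)
  lines <- stringr::str_split(raw_text, "(?<=\n)")[[1]]
  starts <- cumsum(c(0L, nchar(lines)))[seq_along(lines)]
  bare <- stringr::str_remove(lines, "\\r?\\n$")

  first_at <- function(keywords, from = 0L) {
    hit <- which(stringr::str_detect(bare, heading_rx(keywords)) & starts >= from)
    if (length(hit) == 0) NA_integer_ else starts[hit[1]]
  }
  last_at <- function(keywords) {
    hit <- which(stringr::str_detect(bare, heading_rx(keywords)))
    if (length(hit) == 0) NA_integer_ else starts[hit[length(hit)]]
  }

  abs_start <- first_at(config$abstract_headings)
  intro_start <- first_at(config$body_headings,
                          from = if (is.na(abs_start)) 0L else abs_start)
  ack_start <- first_at(config$ack_headings)
  ref_start <- last_at(config$ref_headings)
  # a references heading before the acknowledgements is some stray match;
  # keep only orderings that can close the document
  if (!is.na(ref_start) && !is.na(ack_start) && ref_start < ack_start)
    ack_start <- NA_integer_

  if (is.na(abs_start) && is.na(intro_start)) {
    ta_warn("no abstract/introduction heading found; front matter set to first %d%% of characters",
            round(100 * config$front_matter_fraction))
    fm_end <- max(1L, as.integer(floor(n * config$front_matter_fraction)))
    intro_word <- stringr::str_locate(
      raw_text, stringr::regex("introduction", ignore_case = TRUE))[1, "start"]
    if (!is.na(intro_word)) fm_end <- min(fm_end, as.integer(intro_word) - 1L)
    cuts <- tibble::tibble(label = "front_matter", start = 0L, end = fm_end)
    body_start <- fm_end
  } else if (!is.na(abs_start)) {
    body_start <- if (!is.na(intro_start)) intro_start else
      min(c(ack_start, ref_start, n), na.rm = TRUE)
    cuts <- tibble::tibble(
      label = c("front_matter", "abstract"),
      start = c(0L, abs_start),
      end = c(abs_start, body_start))
    cuts <- cuts[cuts$start < cuts$end, ]
  } else {
    cuts <- tibble::tibble(label = "front_matter", start = 0L, end = intro_start)
    cuts <- cuts[cuts$start < cuts$end, ]
    body_start <- intro_start
  }

  tail_cuts <- tibble::tibble(label = character(), start = integer(), end = integer())
  pos <- n
  if (!is.na(ref_start) && ref_start >= body_start) {
    tail_cuts <- tibble::tibble(label = "references", start = ref_start, end = n)
    pos <- ref_start
  } else if (is.na(ref_start)) {
    ta_warn("no references heading found")
  }
  if (!is.na(ack_start) && ack_start >= body_start && ack_start < pos) {
    tail_cuts <- dplyr::bind_rows(
      tibble::tibble(label = "acknowledgements", start = ack_start, end = pos),
      tail_cuts)
    pos <- ack_start
  }

  body <- tibble::tibble(label = "body",
                         start = as.integer(body_start),
                         end = as.integer(pos))
  spans <- dplyr::bind_rows(cuts, body[body$start < body$end, ], tail_cuts)
  spans$start <- as.integer(spans$start)
  spans$end <- as.integer(spans$end)
  spans <- spans[order(spans$start), ]
  stopifnot(spans$start[1] == 0L, spans$end[nrow(spans)] == n,
            all(spans$start < spans$end),
            all(spans$end[-nrow(spans)] == spans$start[-1]))
  spans
}

# substring by 0-based [start, end) span
span_text <- function(raw_text, spans, label) {
  sel <- spans[spans$label == label, , drop = FALSE]
  paste(substring(raw_text, sel$start + 1L, sel$end), collapse = "")
}

#' Extract the searchable body of a document
#'
#' Concatenates the body spans of [segment()] and applies
#' [repair_hyphenation()]. Deterministic: identical input gives identical
#' output.
#'
#' @inheritParams segment
#' @return character scalar (possibly empty).
#' @export
searchable_body <- function(raw_text, config = seg_config()) {
  if (nchar(raw_text) == 0) return("")
  spans <- segment(raw_text, config)
  repair_hyphenation(span_text(raw_text, spans, "body"))
}
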