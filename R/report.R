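#' Reporting and end-to-end entry points
#'
#' `audit_corpus()` runs the full pipeline (load, segment, score, summarize)
#' and writes the scorecard matrix plus summary files; `lint_document()`
#' checks a single manuscript against the automated checklist and reports
#' evidence for each check; `render_summary()` lays out a corpus summary as
#' a fixed-width text table. A thin command-line wrapper over these
#' functions ships at `system.file("cli", "taxaudit.R", package =
#' "taxaudit")` with subcommands `audit`, `lint`, `simulate` and
#' `lexicon-dump`.
#'
#' @name cli_report
NULL

#' Audit a corpus end to end
#'
#' Loads documents and sidecars, scores every paper, summarizes, and writes
#' `scorecards.csv`, `summary.json`, `summary.csv` and `summary.txt` into
#' `out_dir`. On any error partial outputs are removed.
#'
#' @param text_dir directory of per-paper `.txt` files.
#' @param metadata_path paper-table CSV.
#' @param authors_path optional author CSV.
#' @param annotations_path optional manual-annotation CSV.
#' @param lex a `taxaudit_lexicon`.
#' @param out_dir output directory (created if needed).
#' @param places decimal places for percentage cells.
#' @return the `corpus_summary`, invisibly.
#' @export
audit_corpus <- function(text_dir, metadata_path, authors_path = NULL,
                         annotations_path = NULL, lex = default_lexicon(),
                         out_dir, places = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- file.path(out_dir, c("scorecards.csv", "summary.json",
                                  "summary.csv", "summary.txt"))
  ok <- FALSE
  on.exit(if (!ok) unlink(outputs), add = TRUE)

  corpus <- load_corpus(text_dir, metadata_path, authors_path)
  ann <- if (is.null(annotations_path)) NULL else
    load_annotations(annotations_path)
  matrix <- score_corpus(corpus$documents, lex, ann)
  summary <- summarize_corpus(matrix, authors = corpus$authors, lex = lex,
                              places = places)
  write_scorecards(matrix, outputs[1])
  write_summary(summary, json_path = outputs[2], csv_path = outputs[3])
  writeLines(render_summary(summary), outputs[4])
  ta_log("audit complete: %d papers -> %s", nrow(matrix), out_dir)
  ok <- TRUE
  invisible(summary)
}

#' Lint a single manuscript for completeness
#'
#' Scores the searchable body of one text file against every automated group
#' and reports, per check, whether it is present together with the first
#' piece of matching evidence quoted verbatim. Manual features are reported
#' as `not_assessed`. The completeness score is the fraction of automated
#' checks present.
#'
#' @param path text file to lint.
#' @param lex a `taxaudit_lexicon`.
#' @param snippet_width characters of context around the first match.
#' @return a `lint_report`: tibble of `check`, `status`, `evidence` plus a
#'   `score` attribute in `[0, 1]`.
#' @export
lint_document <- function(path, lex = default_lexicon(), snippet_width = 40) {
  if (!file.exists(path)) stop("cannot read '", path, "'")
  text <- rawToChar(readBin(path, "raw", file.size(path)))
  Encoding(text) <- "UTF-8"
  body <- searchable_body(text)
  auto <- automated_groups(lex)
  rows <- lapply(auto, function(nm) {
    m <- match_group(body, lex$groups[[nm]])
    snippet <- ""
    if (m$flag) {
      off <- m$evidence$offset[1]
      end <- off + nchar(m$evidence$matched_term[1])
      snippet <- stringr::str_sub(body, max(1, off + 1 - snippet_width),
                                  min(nchar(body), end + snippet_width))
    }
    tibble::tibble(check = nm,
                   status = if (m$flag) "present" else "absent",
                   evidence = snippet)
  })
  manual <- names(lex$groups)[vapply(lex$groups,
                                     function(g) g$category == "manual",
                                     logical(1))]
  rows <- c(rows, lapply(manual, function(nm)
    tibble::tibble(check = nm, status = "not_assessed", evidence = "")))
  report <- dplyr::bind_rows(rows)
  score <- mean(report$status[report$check %in% auto] == "present")
  structure(report, score = score, class = c("lint_report", class(report)))
}

#' @export
print.lint_report <- function(x, ...) {
  cat(sprintf("Completeness score: %.2f (%d/%d automated checks present)\n\n",
              attr(x, "score"),
              sum(x$status == "present"), sum(x$status != "not_assessed")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("%-12s %s", x$status[i], x$check[i]))
    if (nzchar(x$evidence[i])) cat(sprintf('  "...%s..."', x$evidence[i]))
    cat("\n")
  }
  invisible(x)
}

#' Render a corpus summary as a fixed-width text table
#'
#' Parameter rows, one percentage column per year plus the pooled column and
#' the trend label; undefined cells are blank. Average rows follow in a
#' second block.
#'
#' @param summary a `corpus_summary`.
#' @return character vector of table lines.
#' @export
render_summary <- function(summary) {
  wide <- summary_wide(summary)
  strata <- c(as.character(summary$years), "all")
  fmtn <- function(x) ifelse(is.na(x), "",
                             formatC(x, format = "f",
                                     digits = summary$places))
  header <- c(sprintf("%-28s", "Parameter"),
              sprintf("%9s", strata), sprintf("  %-9s", "Trend"))
  lines <- paste(header, collapse = "")
  for (i in seq_len(nrow(wide))) {
    cells <- vapply(strata, function(s) sprintf("%9s", fmtn(wide[[s]][i])),
                    character(1))
    lines <- c(lines, paste0(sprintf("%-28s", wide$parameter[i]),
                             paste(cells, collapse = ""),
                             sprintf("  %-9s", wide$trend[i])))
  }
  if (nrow(summary$averages) > 0) {
    lines <- c(lines, "", paste0(sprintf("%-28s", "Average"),
                                 paste(sprintf("%9s", strata), collapse = "")))
    for (p in unique(summary$averages$parameter)) {
      av <- summary$averages[summary$averages$parameter == p, ]
      cells <- vapply(strata, function(s) {
        v <- av$mean[av$stratum == s]
        sprintf("%9s", if (length(v) == 0 || is.na(v)) "" else
          formatC(v, format = "f", digits = 2))
      }, character(1))
      lines <- c(lines, paste0(sprintf("%-28s", p),
                               paste(cells, collapse = "")))
    }
  }
  lines
}
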