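#' Per-paper scorecards
#'
#' A scorecard row combines three channels that are kept strictly separate:
#' automated keyword flags (never missing — absence of a match is `FALSE`),
#' manual annotations (tri-state; never back-filled from text), and derived
#' composite flags that are pure functions of the other two. A composite is
#' missing exactly when one of its manual constituents is missing.
#'
#' @name scorer
NULL

#' Derived composite flags
#'
#' Computes, from one scorecard row:
#' * `map_without_gps` — a map is shown but no GIS/GPS coordinates are given;
#' * `neither_gps_nor_map` — the type locality is localized by neither;
#' * `complete_classification` — phylum, order and family flags all set;
#' * `ecology_silent` — none of the ecology-related groups
#'   (`ecology_term`, `ecological_association`, `ecological_mode`) matched;
#' * `dna_without_tree` — molecular data used but no phylogenetic tree shown.
#'
#' @param automated named logical vector of automated flags (non-missing).
#' @param manual named logical vector of manual flags (tri-state).
#' @return named logical vector of the five composites (tri-state).
#' @export
derive_composites <- function(automated, manual) {
  # a lexicon may omit a constituent group entirely; the composite is then
  # undefined, mirroring the missing-manual-annotation case
  av <- function(nm) if (nm %in% names(automated)) automated[[nm]] else NA
  mv <- function(nm) if (nm %in% names(manual)) manual[[nm]] else NA
  and3 <- function(...) { v <- c(...); if (anyNA(v)) NA else all(v) }
  or3 <- function(...) { v <- c(...); if (any(v %in% TRUE)) TRUE else
    if (anyNA(v)) NA else FALSE }
  gps <- av("gis_gps")
  eco <- or3(av("ecology_term"), av("ecological_association"),
             av("ecological_mode"))
  map <- mv("map_used")
  tree <- mv("tree_shown")
  c(map_without_gps = and3(!gps, map),
    neither_gps_nor_map = and3(!gps, !map),
    complete_classification = and3(av("phylum_classification"),
                                   av("order_classification"),
                                   av("family_classification")),
    ecology_silent = and3(!eco),
    dna_without_tree = and3(av("molecular_data_used"), !tree))
}

empty_manual <- function() {
  stats::setNames(rep(NA, length(manual_features())), manual_features())
}

# one annotation tibble row -> named tri-state vector over manual_features()
annotations_to_vector <- function(ann_row) {
  out <- empty_manual()
  for (f in intersect(manual_features(), names(ann_row)))
    out[[f]] <- ann_row[[f]]
  out
}

#' Score a single document
#'
#' @param doc one-row tibble (or list) with `paper_id`, `year`, `discipline`,
#'   and `body` (already segmented searchable text).
#' @param lex a `taxaudit_lexicon`.
#' @param ann one-row annotations tibble for this paper, or `NULL` when the
#'   paper was not manually scored.
#' @return a one-row scorecard tibble: identifiers, automated flags in
#'   lexicon order, manual flags, derived flags, `pages`,
#'   `n_data_visualizations`.
#' @export
score_paper <- function(doc, lex = default_lexicon(), ann = NULL) {
  automated <- score_groups(doc$body, lex)
  manual <- if (is.null(ann)) empty_manual() else annotations_to_vector(ann)
  derived <- derive_composites(automated, manual)
  pages <- if (!is.null(ann) && "pages" %in% names(ann)) ann$pages else NA_integer_
  nviz <- if (!is.null(ann) && "n_data_visualizations" %in% names(ann))
    ann$n_data_visualizations else NA_integer_
  dplyr::bind_cols(
    tibble::tibble(paper_id = doc$paper_id, year = as.integer(doc$year),
                   discipline = doc$discipline),
    tibble::as_tibble(as.list(automated)),
    tibble::as_tibble(as.list(manual)),
    tibble::as_tibble(as.list(derived)),
    tibble::tibble(pages = as.integer(pages),
                   n_data_visualizations = as.integer(nviz)))
}

#' Score a whole corpus into a scorecard matrix
#'
#' @param documents document tibble from [load_corpus()].
#' @param lex a `taxaudit_lexicon`.
#' @param annotations annotations tibble from [load_annotations()], or `NULL`.
#' @return scorecard tibble, one row per paper, ordered by `paper_id`; the
#'   column set is identical across rows and documented in [write_scorecards()].
#' @export
score_corpus <- function(documents, lex = default_lexicon(), annotations = NULL) {
  if (nrow(documents) == 0) {
    empty <- score_paper(list(paper_id = "x", year = 2000L, discipline = "",
                              body = ""), lex)
    return(empty[0, ])
  }
  rows <- lapply(seq_len(nrow(documents)), function(i) {
    doc <- documents[i, ]
    ann <- NULL
    if (!is.null(annotations)) {
      hit <- annotations[annotations$paper_id == doc$paper_id, ]
      if (nrow(hit) == 1) ann <- hit
    }
    tryCatch(score_paper(doc, lex, ann),
             error = function(e) stop("while scoring paper '", doc$paper_id,
                                      "': ", conditionMessage(e), call. = FALSE))
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$paper_id), ]
  ta_log("scored %d papers against lexicon %s", nrow(out), lex$version)
  out
}
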