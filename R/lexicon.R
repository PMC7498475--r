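#' Keyword lexicons: parameter groups and their match patterns
#'
#' A lexicon is an ordered set of named parameter groups. An *automated*
#' group carries patterns and is evaluated against the searchable body of a
#' document; a *manual* group carries no patterns and is filled from human
#' annotations. Pattern syntax (all matching is case-insensitive and happens
#' after hyphenation repair, so phrases tolerate line breaks):
#'
#' * `"ecolog*"` — stem: matches any word *starting* with `ecolog`
#'   ("ecology", "ecological"), never mid-word ("gynecology" does not match);
#' * `"host"` — exact word, bounded on both sides;
#' * `"culture collection"` — multiword phrase, whitespace-tolerant;
#' * entries under `regex:` — raw regular expressions (used for coordinate
#'   notations and taxonomic name suffixes such as `-aceae`).
#'
#' @name lexicon
NULL

#' Construct a parameter group
#'
#' @param name group name, unique within a lexicon.
#' @param category `"automated"` (pattern-scored), `"manual"` (annotated by a
#'   human reader) or `"derived"` (computed composite).
#' @param patterns character vector of stems (`"foo*"`), words and phrases.
#' @param regex character vector of raw regular expressions.
#' @return an object of class `parameter_group`.
#' @export
parameter_group <- function(name, category = c("automated", "manual", "derived"),
                            patterns = character(), regex = character()) {
  category <- match.arg(category)
  if (category == "automated" && length(patterns) + length(regex) == 0)
    stop("automated group '", name, "' must carry at least one pattern")
  if (category != "automated" && length(patterns) + length(regex) > 0)
    stop("group '", name, "' is ", category, " and may not carry patterns")
  compiled <- lapply(regex, function(rx) {
    tryCatch(stringr::regex(rx, ignore_case = TRUE),
             error = function(e) stop("malformed pattern in group '", name,
                                      "': ", rx, call. = FALSE))
  })
  # fail fast on an uncompilable regex
  for (rx in compiled) tryCatch(stringr::str_detect("", rx),
    error = function(e) stop("malformed pattern in group '", name, "': ",
                             conditionMessage(e), call. = FALSE))
  structure(list(name = name, category = category, patterns = patterns,
                 regex = regex,
                 compiled = c(lapply(patterns, compile_pattern), compiled)),
            class = "parameter_group")
}

# one stem/word/phrase -> a case-insensitive stringr regex
compile_pattern <- function(pattern) {
  stem <- stringr::str_ends(pattern, stringr::fixed("*"))
  core <- if (stem) stringr::str_sub(pattern, 1, -2) else pattern
  esc <- stringr::str_replace_all(stringr::str_escape(core), "\\s+", "\\\\s+")
  lead <- if (stringr::str_detect(core, "^[\\p{L}\\p{N}]")) "\\b" else ""
  trail <- if (!stem && stringr::str_detect(core, "[\\p{L}\\p{N}]$")) "\\b" else ""
  stringr::regex(paste0(lead, esc, trail), ignore_case = TRUE)
}

#' Build a lexicon from parameter groups
#'
#' @param groups list of [parameter_group()] objects.
#' @param version free-form version string recorded in outputs.
#' @return an object of class `taxaudit_lexicon`.
#' @export
lexicon <- function(groups, version = "custom") {
  nm <- vapply(groups, function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate group name: ", nm[duplicated(nm)][1])
  if (!any(vapply(groups, function(g) g$category == "automated", logical(1))))
    stop("the automated lexicon may not be empty")
  structure(list(groups = stats::setNames(groups, nm), version = version),
            class = "taxaudit_lexicon")
}

#' @export
print.taxaudit_lexicon <- function(x, ...) {
  cat(sprintf("<taxaudit_lexicon %s: %d groups (%d automated)>\n", x$version,
              length(x$groups), length(automated_groups(x))))
  invisible(x)
}

#' Names of the automated groups of a lexicon, in order
#' @param lex a `taxaudit_lexicon`.
#' @return character vector.
#' @export
automated_groups <- function(lex) {
  names(lex$groups)[vapply(lex$groups, function(g) g$category == "automated",
                           logical(1))]
}

#' The built-in default lexicon
#'
#' Twenty-three automated parameter groups covering ecology, geography,
#' taxonomy, molecular data and data availability, plus the thirteen manual
#' features scored by a human reader. The original query dictionary behind
#' the published prevalence table is not public, so these defaults are
#' authored from the table's own column definitions (e.g. climate zone =
#' words such as "temperate" or "tropical"; collection = variations of
#' "herbarium"/"fungarium"/"museum"/"culture collection") and every group is
#' overridable through a lexicon YAML file. The ecology-related set spread
#' over the `ecology_term`, `ecological_association` and `ecological_mode`
#' groups holds ~20 terms. Classification groups match both explicit rank
#' words and rank-typical name suffixes (`-mycota`, `-ales`, `-aceae`), since
#' a family name alone satisfies "whether a family name was provided".
#'
#' @return a `taxaudit_lexicon`.
#' @export
default_lexicon <- function() {
  g <- function(...) parameter_group(...)
  auto <- list(
    g("altitude", "automated", c("altitud*", "elevation*", "a.s.l.")),
    g("biodiversity", "automated", c("biodivers*")),
    g("climate", "automated", c("climat*")),
    g("climate_zone", "automated",
      c("temperate", "tropical", "subtropical", "boreal", "arctic",
        "subarctic", "alpine", "mediterranean", "semi-arid")),
    g("collection", "automated",
      c("herbari*", "fungari*", "museum*", "culture collection")),
    g("distribution", "automated", c("distribut*", "geograph*")),
    g("ecological_association", "automated",
      c("host", "hosts", "substrate*", "habitat*", "partner*",
        "growing on", "on dead", "branch of", "associated with",
        "isolated from")),
    g("ecological_mode", "automated",
      c("saprotroph*", "saprob*", "parasit*", "pathogen*", "symbio*",
        "mycorrhiz*", "endophyt*", "mutualis*", "lichen*",
        "nutritional mode")),
    g("ecology_term", "automated", c("ecolog*")),
    g("family_classification", "automated", c("family", "families"),
      regex = "\\b\\p{L}{4,}aceae\\b"),
    g("gis_gps", "automated",
      c("gps", "gis", "coordinate*", "co-ordinate*"),
      regex = c("[0-9]{1,3}\\s?°\\s?[0-9]{1,2}[0-9.\\s'′″\"]*[NSEW]\\b",
                "-?\\b[0-9]{1,2}\\.[0-9]{4,}\\b[,;]?\\s+-?[0-9]{1,3}\\.[0-9]{4,}\\b")),
    g("index_fungorum", "automated", c("index fungorum", "indexfungorum")),
    g("locality_term", "automated", c("localit*")),
    g("molecular_availability", "automated", c("treebase", "dryad")),
    g("molecular_search", "automated", c("blast")),
    g("molecular_database", "automated", c("genbank", "embl", "ddbj", "insdc")),
    g("molecular_data_used", "automated", c("dna", "pcr", "sequenc*")),
    g("mycobank", "automated", c("mycobank")),
    g("order_classification", "automated", c("order", "orders"),
      regex = "\\b\\p{L}{4,}ales\\b"),
    g("phylum_classification", "automated", c("phylum", "phyla"),
      regex = "\\b\\p{L}{3,}mycota\\b"),
    g("societal", "automated",
      c("agricultur*", "forestry", "biotechnolog*", "medicin*", "medical",
        "pharmaceutic*")),
    g("supplementary_data", "automated", c("supplement*", "additional file")),
    g("threatened", "automated", c("threatened", "endangered", "red list",
                                   "iucn")))
  man <- lapply(manual_features(), function(f) g(f, "manual"))
  lexicon(c(auto, man), version = "builtin-1")
}

#' Manual feature names, in reporting order
#' @return character vector of the thirteen manually scored features.
#' @export
manual_features <- function() {
  c("color_photo", "key_provided", "discussion_section", "electron_microscopy",
    "culture_shown", "macro_scale_bar", "line_drawing", "map_used",
    "open_access", "tree_shown", "context_photo", "micro_photo", "spore_print")
}

#' Names of the derived composite flags, in reporting order
#' @return character vector.
#' @export
derived_flags <- function() {
  c("map_without_gps", "neither_gps_nor_map", "complete_classification",
    "ecology_silent", "dna_without_tree")
}

#' Load a lexicon from a YAML file
#'
#' The file holds `version:` and a `groups:` list of
#' `{name, category, patterns: [...], regex: [...]}` entries. With `path`
#' omitted the built-in [default_lexicon()] is returned.
#'
#' @param path path to a lexicon YAML file, or `NULL` for the default.
#' @return a `taxaudit_lexicon`.
#' @export
load_lexicon <- function(path = NULL) {
  if (is.null(path)) return(default_lexicon())
  raw <- yaml::read_yaml(path)
  if (is.null(raw$groups) || length(raw$groups) == 0)
    stop("lexicon file '", path, "' defines no groups")
  groups <- lapply(raw$groups, function(gr) {
    if (is.null(gr$name)) stop("lexicon group without a name in ", path)
    parameter_group(gr$name,
                    category = if (is.null(gr$category)) "automated" else gr$category,
                    patterns = as.character(unlist(gr$patterns)),
                    regex = as.character(unlist(gr$regex)))
  })
  lexicon(groups, version = if (is.null(raw$version)) "file" else raw$version)
}

#' Serialize a lexicon to YAML
#'
#' `load_lexicon(lexicon_dump(lex, f))` reproduces `lex` (normalized field
#' order). Used by the command-line `lexicon dump` subcommand to surface the
#' active defaults.
#'
#' @param lex a `taxaudit_lexicon`.
#' @param path output file; `NULL` returns the YAML text instead.
#' @return the YAML string, invisibly when written to a file.
#' @export
lexicon_dump <- function(lex, path = NULL) {
  obj <- list(version = lex$version,
              groups = unname(lapply(lex$groups, function(g) {
                out <- list(name = g$name, category = g$category)
                if (length(g$patterns)) out$patterns <- as.list(g$patterns)
                if (length(g$regex)) out$regex <- as.list(g$regex)
                out
              })))
  txt <- yaml::as.yaml(obj)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Match one parameter group against a searchable body
#'
#' @param body character scalar (output of [searchable_body()]).
#' @param group a [parameter_group()] with category `"automated"`.
#' @return a list with `flag` (logical) and `evidence`, a tibble of
#'   `group`, `matched_term`, `offset` (0-based offset into `body`).
#' @export
match_group <- function(body, group) {
  stopifnot(inherits(group, "parameter_group"))
  if (group$category != "automated")
    stop("group '", group$name, "' is not automated")
  ev <- list()
  for (rx in group$compiled) {
    loc <- stringr::str_locate_all(body, rx)[[1]]
    if (nrow(loc) > 0)
      ev[[length(ev) + 1]] <- tibble::tibble(
        group = group$name,
        matched_term = stringr::str_sub(body, loc[, 1], loc[, 2]),
        offset = as.integer(loc[, 1] - 1L))
  }
  evidence <- if (length(ev)) {
    all_ev <- dplyr::bind_rows(ev)
    all_ev[order(all_ev$offset), ]
  } else {
    tibble::tibble(group = character(), matched_term = character(),
                   offset = integer())
  }
  list(flag = nrow(evidence) > 0, evidence = evidence)
}

#' Score every automated group of a lexicon against a body
#'
#' @param body character scalar.
#' @param lex a `taxaudit_lexicon`.
#' @return named logical vector, one non-missing flag per automated group.
#' @export
score_groups <- function(body, lex = default_lexicon()) {
  auto <- automated_groups(lex)
  vapply(auto, function(nm) match_group(body, lex$groups[[nm]])$flag,
         logical(1))
}
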