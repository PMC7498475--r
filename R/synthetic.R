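#' Synthetic species-description corpora with planted ground truth
#'
#' Generates seeded, fully synthetic species-description documents (title /
#' author block / abstract / body / acknowledgements / references), author
#' metadata and manual-annotation tables whose true flag values are known by
#' construction. For every parameter group drawn true, at least one pattern
#' phrase from the active lexicon is embedded in the body inside a
#' natural-language sentence; decoy keyword sentences are planted only in
#' the excluded blocks. Each document is verified at generation time by
#' running the segmenter and lexicon engine, so the ground truth is
#' consistent with the emitted text by construction.
#'
#' @name synthetic_corpus
NULL

# default planting probabilities: overall prevalence of each automated group
default_planting <- function() {
  c(altitude = .1686, biodiversity = .2325, climate = .1367,
    climate_zone = .8915, collection = .8459, distribution = .8277,
    ecological_association = .8815, ecological_mode = .7539,
    ecology_term = .4202, family_classification = .7539, gis_gps = .0447,
    index_fungorum = .1112, locality_term = .3564,
    molecular_availability = .5378, molecular_search = .3546,
    molecular_database = .8569, molecular_data_used = .9079,
    mycobank = .8806, order_classification = .6481,
    phylum_classification = .3191, societal = .5360,
    supplementary_data = .2443, threatened = .0237)
}

default_manual_planting <- function() {
  c(color_photo = .7302, key_provided = .2452, discussion_section = .7758,
    electron_microscopy = .2489, culture_shown = .2516,
    macro_scale_bar = .6334, line_drawing = .4266, map_used = .0638,
    open_access = .7785, tree_shown = .8459, context_photo = .6226,
    micro_photo = .7420, spore_print = .0009)
}

# per-year corpus weights: anchored at the published yearly denominators
# (71 papers in 2009, 110 in 2013, 114 in 2018), linearly interpolated
default_year_weights <- function() {
  w <- stats::setNames(c(71, 80.75, 90.5, 100.25, 110,
                         110.8, 111.6, 112.4, 113.2, 114), 2009:2018)
  w / sum(w)
}

#' Specification of a synthetic corpus
#'
#' Defaults emulate the study conditions of the audited corpus: 1,097
#' papers over 2009-2018, per-group planting probabilities equal to the
#' overall prevalence column of the published table, 29.8% female authors,
#' a zero-truncated Poisson co-author count with mean 4.4, and mean academic
#' ages of 18.11 (first author) and 27.99 (last author).
#'
#' @param n_papers number of papers to generate.
#' @param years candidate publication years.
#' @param year_weights sampling weights over `years` (normalized internally).
#' @param planting named per-group probability of planting an automated flag;
#'   names must be automated groups of the lexicon used at generation time.
#' @param manual_planting named per-feature probability of a true manual flag.
#' @param decoy_rate probability that a paper receives decoy keyword
#'   sentences in its excluded sections.
#' @param female_prob per-author probability of the `female` gender label.
#' @param unknown_gender_prob per-author probability of the `unknown` label.
#' @param coauthor_mean mean of the zero-truncated Poisson co-author count.
#' @param age_first_mean,age_last_mean,age_middle_mean mean academic ages
#'   (years) of first, last and intermediate authors.
#' @param age_missing_rate probability an author's publication-year span is
#'   unresolved (missing).
#' @param annotation_missing_rate probability a manual flag is left blank.
#' @param pages_mean,pages_sd,n_viz_mean page-count and
#'   data-visualization-count distributions.
#' @param discipline discipline label stamped on every paper.
#' @param hyphen_breaks also split some long body words across lines with a
#'   trailing hyphen, emulating PDF extraction artifacts.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   output.
#' @return a `corpus_spec` list.
#' @export
corpus_spec <- function(n_papers = 1097,
                        years = 2009:2018,
                        year_weights = default_year_weights(),
                        planting = default_planting(),
                        manual_planting = default_manual_planting(),
                        decoy_rate = 0.25,
                        female_prob = 0.298,
                        unknown_gender_prob = 0.15,
                        coauthor_mean = 4.4,
                        age_first_mean = 18.11,
                        age_last_mean = 27.99,
                        age_middle_mean = 22,
                        age_missing_rate = 0.10,
                        annotation_missing_rate = 0.10,
                        pages_mean = 10.88, pages_sd = 3.5,
                        n_viz_mean = 0.17,
                        discipline = "mycology",
                        hyphen_breaks = FALSE,
                        seed = 1L) {
  stopifnot(n_papers >= 0, length(years) == length(year_weights),
            all(planting >= 0 & planting <= 1),
            all(manual_planting >= 0 & manual_planting <= 1),
            decoy_rate >= 0, decoy_rate <= 1,
            female_prob + unknown_gender_prob <= 1)
  structure(as.list(environment()), class = "corpus_spec")
}

# zero-truncated Poisson with a given (truncated) mean
rztpois <- function(n, mean) {
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           c(1e-6, mean + 10))$root
  out <- stats::rpois(n, lambda)
  while (any(out == 0)) out[out == 0] <- stats::rpois(sum(out == 0), lambda)
  out
}

load_templates <- function() {
  yaml::read_yaml(system.file("extdata", "templates.yaml",
                              package = "taxaudit"))
}

surname_pool <- function() {
  c("Lindgren", "Tanaka", "Silva", "Novak", "Okafor", "Petrov", "Muller",
    "Rossi", "Chen", "Haugen", "Kowalski", "Dubois", "Santos", "Kim",
    "Andersson", "Moreau", "Costa", "Vargas", "Iversen", "Nagy")
}

country_table <- function() {
  tibble::tibble(
    country = c("Sweden", "Germany", "France", "China", "Japan", "India",
                "USA", "Canada", "Mexico", "Brazil", "Argentina", "Chile",
                "Nigeria", "Kenya", "South Africa", "Australia",
                "New Zealand", "Fiji"),
    continent = rep(c("Europe", "Asia", "North America", "South America",
                      "Africa", "Oceania"), each = 3))
}

# nested continent <= country <= department <= author counts for one paper
draw_affiliations <- function(n_auth) {
  ct <- country_table()
  n_cont <- min(1L + stats::rbinom(1, max(n_auth - 1L, 0L), 0.132),
                length(unique(ct$continent)), n_auth)
  n_ctry <- min(n_cont + stats::rbinom(1, max(n_auth - n_cont, 0L), 0.136),
                n_auth)
  n_dept <- min(n_ctry + stats::rbinom(1, max(n_auth - n_ctry, 0L), 0.443),
                n_auth)
  conts <- sample(unique(ct$continent), n_cont)
  # one country per chosen continent first, extras drawn within them
  ctrys <- vapply(conts, function(cc) sample(ct$country[ct$continent == cc], 1),
                  character(1))
  while (length(ctrys) < n_ctry) {
    cand <- setdiff(ct$country[ct$continent %in% conts], ctrys)
    if (length(cand) == 0) break
    ctrys <- c(ctrys, sample(cand, 1))
  }
  n_ctry <- length(ctrys)
  dept_ctry <- c(seq_len(n_ctry), sample(seq_len(n_ctry), n_dept - n_ctry,
                                         replace = TRUE))
  depts <- sprintf("Department of Organismal Biology %d, University %d",
                   seq_len(n_dept), seq_len(n_dept))
  auth_dept <- c(seq_len(n_dept), sample(seq_len(n_dept),
                                         n_auth - n_dept, replace = TRUE))
  tibble::tibble(
    department = depts[auth_dept],
    country = ctrys[dept_ctry[auth_dept]],
    continent = ct$continent[match(ctrys[dept_ctry[auth_dept]], ct$country)])
}

wrap_text <- function(sentences, width = 78) {
  paste(strwrap(paste(sentences, collapse = " "), width = width),
        collapse = "\n")
}

# assemble one document's text from its planted flags; decoy_groups get
# their keyword sentences copied into the excluded blocks only
build_document <- function(flags, templates, decoy_groups, authors,
                           hyphen_breaks = FALSE) {
  tpl <- templates
  title <- sprintf(sample(tpl$titles, 1), sample(tpl$genera, 1),
                   sample(tpl$places, 1))
  planted <- names(flags)[flags]
  group_sents <- vapply(planted, function(g)
    sample(unlist(tpl$groups[[g]]), 1), character(1))
  filler <- sample(unlist(tpl$filler), sample(4:7, 1), replace = FALSE)
  body_sents <- sample(c(group_sents, filler))

  decoy_sents <- vapply(decoy_groups, function(g)
    sample(unlist(tpl$groups[[g]]), 1), character(1))
  n_dec <- length(decoy_sents)
  dec_abs <- decoy_sents[seq_len(n_dec) %% 3 == 1]
  dec_ack <- decoy_sents[seq_len(n_dec) %% 3 == 2]
  dec_ref <- decoy_sents[seq_len(n_dec) %% 3 == 0]

  body_text <- wrap_text(body_sents)
  if (hyphen_breaks) body_text <- inject_hyphen_breaks(body_text)

  paste(
    title,
    paste(authors$name, collapse = ", "),
    paste(unique(authors$department), collapse = "; "),
    "Abstract",
    wrap_text(c(sample(unlist(tpl$abstract), 2), dec_abs)),
    "Introduction",
    body_text,
    "Acknowledgements",
    wrap_text(c(sample(unlist(tpl$acknowledgements), 2), dec_ack)),
    "References",
    paste(c(sample(unlist(tpl$references), 2), dec_ref), collapse = "\n"),
    sep = "\n")
}

# split a few long alphabetic words across lines ("supple-\nmentary")
inject_hyphen_breaks <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  for (i in seq_along(lines)) {
    if (i %% 3 != 0) next
    words <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    long <- which(nchar(words) >= 8 & grepl("^[A-Za-z]+$", words))
    if (length(long) == 0) next
    w <- long[1]
    cut <- nchar(words[w]) %/% 2
    words[w] <- paste0(substr(words[w], 1, cut), "-\n",
                       substr(words[w], cut + 1, nchar(words[w])))
    lines[i] <- paste(words, collapse = " ")
  }
  paste(lines, collapse = "\n")
}

#' Plant keyword sentences for a flag map into a document
#'
#' Builds a document whose searchable body matches exactly the given flags
#' under `lex`, verifying by scoring and regenerating on accidental
#' collision (at most `max_attempts` times).
#'
#' @param flags named logical vector over the automated groups of `lex`.
#' @param lex lexicon used for planting and verification.
#' @param decoy_groups group names whose keyword sentences are planted only
#'   in excluded sections.
#' @param authors author tibble for the byline (defaults to a stub).
#' @param templates sentence bank (defaults to the packaged bank).
#' @param hyphen_breaks emulate hyphenated line breaks.
#' @param max_attempts regeneration budget before failing.
#' @return document text (character scalar).
#' @export
plant_features <- function(flags, lex = default_lexicon(),
                           decoy_groups = character(),
                           authors = NULL, templates = NULL,
                           hyphen_breaks = FALSE, max_attempts = 10) {
  if (is.null(templates)) templates <- load_templates()
  if (is.null(authors))
    authors <- tibble::tibble(name = "A. Author",
                              department = "Department of Biology")
  missing_tpl <- setdiff(names(flags)[flags], names(templates$groups))
  if (length(missing_tpl))
    stop("no sentence template for group(s): ",
         paste(missing_tpl, collapse = ", "))
  for (attempt in seq_len(max_attempts)) {
    text <- build_document(flags, templates, decoy_groups, authors,
                           hyphen_breaks)
    got <- score_groups(searchable_body(text), lex)
    if (identical(got[names(flags)], flags)) return(text)
  }
  bad <- names(flags)[got[names(flags)] != flags]
  stop("could not realize planted flags after ", max_attempts,
       " attempts; colliding group(s): ", paste(bad, collapse = ", "))
}

#' Generate a synthetic corpus
#'
#' @param spec a [corpus_spec()].
#' @param lex lexicon used to plant and verify keyword sentences.
#' @return a `synthetic_corpus` list: `documents` (tibble paper_id, year,
#'   journal, discipline, text), `papers`/`authors`/`annotations` metadata
#'   tibbles, and `truth` — the ground-truth scorecard (automated flags as
#'   planted, manual flags as emitted after missingness, derived-flag
#'   expectations).
#' @export
generate_corpus <- function(spec = corpus_spec(), lex = default_lexicon()) {
  stopifnot(inherits(spec, "corpus_spec"))
  auto <- automated_groups(lex)
  unknown <- setdiff(names(spec$planting), auto)
  if (length(unknown))
    stop("planting probability for group(s) absent from lexicon: ",
         paste(unknown, collapse = ", "))
  templates <- load_templates()
  set.seed(spec$seed)

  n <- spec$n_papers
  journals <- c("Mycologia", "Fungal Biology", "Mycoscience",
                "Mycological Progress", "Studies in Mycology")
  if (n == 0) {
    empty_truth <- score_corpus(tibble::tibble(paper_id = character(),
                                               year = integer(),
                                               journal = character(),
                                               discipline = character(),
                                               raw_text = character(),
                                               body = character()), lex)
    return(structure(list(
      documents = tibble::tibble(paper_id = character(), year = integer(),
                                 journal = character(),
                                 discipline = character(), text = character()),
      papers = tibble::tibble(paper_id = character(), year = character(),
                              journal = character(), discipline = character()),
      authors = tibble::tibble(), annotations = tibble::tibble(),
      truth = empty_truth, spec = spec), class = "synthetic_corpus"))
  }

  ids <- sprintf("P%04d", seq_len(n))
  years <- spec$years[sample.int(length(spec$years), n, replace = TRUE,
                                 prob = spec$year_weights / sum(spec$year_weights))]
  journal <- sample(journals, n, replace = TRUE)

  n_auth <- rztpois(n, spec$coauthor_mean)
  surnames <- surname_pool()

  docs <- vector("list", n)
  authors_l <- vector("list", n)
  ann_l <- vector("list", n)
  truth_l <- vector("list", n)

  plant_names <- names(spec$planting)
  man_names <- names(spec$manual_planting)

  for (i in seq_len(n)) {
    k <- n_auth[i]
    aff <- draw_affiliations(k)
    # female_prob is conditional on the gender being resolvable, so the
    # female share among fully-resolved papers matches the planted rate
    gender <- ifelse(stats::runif(k) < spec$unknown_gender_prob, "unknown",
                     ifelse(stats::runif(k) < spec$female_prob,
                            "female", "male"))
    age_mean <- c(spec$age_first_mean,
                  rep(spec$age_middle_mean, max(k - 2, 0)),
                  if (k > 1) spec$age_last_mean)
    age <- stats::rpois(k, age_mean)
    newest <- years[i] - stats::rpois(k, 0.5)
    oldest <- newest - age
    miss <- stats::runif(k) < spec$age_missing_rate
    oldest[miss] <- NA_integer_
    newest[miss] <- NA_integer_
    auth <- tibble::tibble(
      paper_id = ids[i], position = seq_len(k),
      name = paste0(sample(LETTERS, k, replace = TRUE), ". ",
                    sample(surnames, k, replace = TRUE)),
      gender = gender,
      department = aff$department, country = aff$country,
      continent = aff$continent,
      oldest_pub_year = as.integer(oldest),
      newest_pub_year = as.integer(newest))
    authors_l[[i]] <- auth

    flags <- stats::setNames(stats::runif(length(plant_names)) <
                               spec$planting[plant_names], plant_names)
    full_flags <- stats::setNames(rep(FALSE, length(auto)), auto)
    full_flags[names(flags)] <- flags
    decoys <- character()
    if (stats::runif(1) < spec$decoy_rate) {
      pool <- intersect(names(templates$groups), auto)
      decoys <- sample(pool, min(sample(1:3, 1), length(pool)))
    }
    text <- plant_features(full_flags, lex, decoy_groups = decoys,
                           authors = auth, templates = templates,
                           hyphen_breaks = spec$hyphen_breaks)
    docs[[i]] <- tibble::tibble(paper_id = ids[i], year = years[i],
                                journal = journal[i],
                                discipline = spec$discipline, text = text)

    man <- stats::setNames(stats::runif(length(man_names)) <
                             spec$manual_planting[man_names], man_names)
    man[stats::runif(length(man)) < spec$annotation_missing_rate] <- NA
    pages <- max(2L, as.integer(round(stats::rnorm(1, spec$pages_mean,
                                                   spec$pages_sd))))
    nviz <- stats::rpois(1, spec$n_viz_mean)
    ann_l[[i]] <- dplyr::bind_cols(
      tibble::tibble(paper_id = ids[i]),
      tibble::as_tibble(as.list(man)),
      tibble::tibble(pages = pages, n_data_visualizations = nviz))

    derived <- derive_composites(full_flags, man)
    truth_l[[i]] <- dplyr::bind_cols(
      tibble::tibble(paper_id = ids[i], year = years[i],
                     discipline = spec$discipline),
      tibble::as_tibble(as.list(full_flags)),
      tibble::as_tibble(as.list(man)),
      tibble::as_tibble(as.list(derived)),
      tibble::tibble(pages = pages, n_data_visualizations = nviz))
  }

  documents <- dplyr::bind_rows(docs)
  ta_log("generated %d synthetic papers (seed %d)", n, spec$seed)
  structure(list(
    documents = documents,
    papers = tibble::tibble(paper_id = ids, year = as.character(years),
                            journal = journal, discipline = spec$discipline),
    authors = dplyr::bind_rows(authors_l),
    annotations = dplyr::bind_rows(ann_l),
    truth = dplyr::bind_rows(truth_l),
    spec = spec), class = "synthetic_corpus")
}

#' Write a synthetic corpus to disk
#'
#' Emits `texts/<paper_id>.txt`, `papers.csv`, `authors.csv`,
#' `annotations.csv` and `ground_truth.csv` under `out_dir`, in the formats
#' [load_corpus()] and [load_annotations()] read back.
#'
#' @param corpus a `synthetic_corpus` from [generate_corpus()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_corpus <- function(corpus, out_dir) {
  stopifnot(inherits(corpus, "synthetic_corpus"))
  text_dir <- file.path(out_dir, "texts")
  dir.create(text_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(corpus$documents))) {
    con <- file(file.path(text_dir,
                          paste0(corpus$documents$paper_id[i], ".txt")),
                "wb")
    writeBin(charToRaw(enc2utf8(corpus$documents$text[i])), con)
    close(con)
  }
  csv <- function(df, name) {
    out <- df
    for (col in names(out))
      if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
    utils::write.csv(as.data.frame(out), file.path(out_dir, name),
                     row.names = FALSE, na = "")
  }
  csv(corpus$papers, "papers.csv")
  csv(corpus$authors, "authors.csv")
  csv(corpus$annotations, "annotations.csv")
  csv(corpus$truth, "ground_truth.csv")
  invisible(out_dir)
}

#' Generate and write a synthetic corpus in one step
#'
#' @param out_dir output directory.
#' @param spec a [corpus_spec()]; `seed` overrides the spec seed if given.
#' @param seed optional integer overriding `spec$seed`.
#' @param lex lexicon for planting.
#' @return the generated `synthetic_corpus`, invisibly.
#' @export
simulate_corpus <- function(out_dir, spec = corpus_spec(), seed = NULL,
                            lex = default_lexicon()) {
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  corpus <- generate_corpus(spec, lex)
  write_corpus(corpus, out_dir)
  invisible(corpus)
}
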