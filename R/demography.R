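#' Authorship demography
#'
#' Gender composition, academic age and collaboration breadth are computed
#' from ingested metadata labels, never inferred from names or looked up
#' online. Gender-composition percentages use only papers whose author list
#' is fully gender-resolved; the lead-author percentage uses every paper
#' whose first author's gender is known.
#'
#' @name demography
NULL

#' Academic age of an author
#'
#' Span in years between the oldest and the most recent publication,
#' oriented so that the result is non-negative; missing when either year is
#' missing.
#'
#' @param oldest_pub_year,newest_pub_year integers or `NA`.
#' @return integer or `NA`.
#' @export
academic_age <- function(oldest_pub_year, newest_pub_year) {
  ifelse(is.na(oldest_pub_year) | is.na(newest_pub_year), NA_integer_,
         as.integer(newest_pub_year) - as.integer(oldest_pub_year))
}

#' Gender-composition statistics
#'
#' @param authors long-format author tibble (`paper_id`, `position`,
#'   `gender` in male/female/unknown, ...).
#' @param places decimal places for the reported percentages.
#' @return list: `pct_female_coauthors` (% female among all authors of
#'   fully-resolved papers), `pct_male_only_papers`, `pct_female_only_papers`
#'   (% of fully-resolved papers), `pct_male_lead` (% of known-lead papers),
#'   with denominators `n_resolved_papers`, `n_authors_resolved`,
#'   `n_lead_known`. Percentages are `NA` when their denominator is zero.
#' @export
gender_stats <- function(authors, places = 1) {
  stopifnot(all(authors$gender %in% c("male", "female", "unknown")))
  by_paper <- split(authors$gender, authors$paper_id)
  resolved <- vapply(by_paper, function(g) !any(g == "unknown"), logical(1))
  res_genders <- unlist(by_paper[resolved], use.names = FALSE)
  n_resolved <- sum(resolved)
  n_auth <- length(res_genders)

  pct <- function(k, n) if (n == 0) NA_real_ else round_half_up(100 * k / n, places)
  only <- function(g, which) all(g == which)

  lead <- authors$gender[authors$position == 1]
  lead_known <- lead[lead != "unknown"]

  list(
    pct_female_coauthors = pct(sum(res_genders == "female"), n_auth),
    pct_male_only_papers = pct(sum(vapply(by_paper[resolved], only, logical(1),
                                          which = "male")), n_resolved),
    pct_female_only_papers = pct(sum(vapply(by_paper[resolved], only, logical(1),
                                            which = "female")), n_resolved),
    pct_male_lead = pct(sum(lead_known == "male"), length(lead_known)),
    n_resolved_papers = n_resolved,
    n_authors_resolved = n_auth,
    n_lead_known = length(lead_known))
}

#' Collaboration breadth statistics
#'
#' Per-paper counts of authors and of distinct departments, countries and
#' continents, and their corpus means.
#'
#' @param authors long-format author tibble.
#' @return list with `per_paper` (tibble: paper_id, n_authors,
#'   n_departments, n_countries, n_continents) and the four means
#'   (`mean_coauthors`, `mean_departments`, `mean_countries`,
#'   `mean_continents`).
#' @export
collaboration_stats <- function(authors) {
  per_paper <- dplyr::bind_rows(lapply(split(authors, authors$paper_id),
    function(a) tibble::tibble(
      paper_id = a$paper_id[1],
      n_authors = nrow(a),
      n_departments = length(unique(a$department)),
      n_countries = length(unique(a$country)),
      n_continents = length(unique(a$continent)))))
  list(per_paper = per_paper,
       mean_coauthors = mean(per_paper$n_authors),
       mean_departments = mean(per_paper$n_departments),
       mean_countries = mean(per_paper$n_countries),
       mean_continents = mean(per_paper$n_continents))
}

#' Full demography summary for a corpus
#'
#' @param matrix scorecard tibble (used for the paper universe).
#' @param authors long-format author tibble.
#' @return list combining [gender_stats()], [collaboration_stats()] means and
#'   mean academic ages of first and last authors (with their denominators).
#' @export
demography_stats <- function(matrix, authors) {
  authors <- authors[authors$paper_id %in% matrix$paper_id, ]
  g <- gender_stats(authors)
  collab <- collaboration_stats(authors)

  age <- academic_age(authors$oldest_pub_year, authors$newest_pub_year)
  is_first <- authors$position == 1
  last_pos <- stats::ave(authors$position, authors$paper_id, FUN = max)
  is_last <- authors$position == last_pos
  first_ages <- age[is_first & !is.na(age)]
  last_ages <- age[is_last & !is.na(age)]

  c(g,
    list(mean_academic_age_first = if (length(first_ages)) mean(first_ages) else NA_real_,
         mean_academic_age_last = if (length(last_ages)) mean(last_ages) else NA_real_,
         n_age_first = length(first_ages),
         n_age_last = length(last_ages),
         mean_coauthors = collab$mean_coauthors,
         mean_departments = collab$mean_departments,
         mean_countries = collab$mean_countries,
         mean_continents = collab$mean_continents,
         n_papers_with_authors = nrow(collab$per_paper)))
}

# averages-block rows (per year and pooled) for the demography quantities
demography_averages <- function(matrix, authors) {
  authors <- authors[authors$paper_id %in% matrix$paper_id, ]
  year_of <- stats::setNames(matrix$year, matrix$paper_id)
  collab <- collaboration_stats(authors)$per_paper
  collab$year <- year_of[collab$paper_id]

  age <- academic_age(authors$oldest_pub_year, authors$newest_pub_year)
  last_pos <- stats::ave(authors$position, authors$paper_id, FUN = max)
  ages <- tibble::tibble(
    paper_id = authors$paper_id,
    year = year_of[authors$paper_id],
    first = ifelse(authors$position == 1, age, NA),
    last = ifelse(authors$position == last_pos, age, NA))

  strata <- c(as.character(sort(unique(matrix$year))), "all")
  cell <- function(p, s, v) {
    v <- v[!is.na(v)]
    if (length(v) == 0)
      return(tibble::tibble(parameter = p, stratum = s, mean = NA_real_,
                            se = NA_real_, n = 0L))
    m <- mean_and_se(v)
    tibble::tibble(parameter = p, stratum = s, mean = m$mean, se = m$se,
                   n = as.integer(m$n))
  }
  pick <- function(df, col, s) if (s == "all") df[[col]] else
    df[[col]][!is.na(df$year) & df$year == as.integer(s)]

  dplyr::bind_rows(lapply(strata, function(s) dplyr::bind_rows(
    cell("academic_age_last", s, pick(ages, "last", s)),
    cell("academic_age_first", s, pick(ages, "first", s)),
    cell("coauthors", s, pick(collab, "n_authors", s)),
    cell("coauthor_continents", s, pick(collab, "n_continents", s)),
    cell("coauthor_countries", s, pick(collab, "n_countries", s)),
    cell("coauthor_departments", s, pick(collab, "n_departments", s)))))
}
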