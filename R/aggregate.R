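#' Prevalence tables, trends and averages
#'
#' The summary layer turns a scorecard matrix into the per-year and overall
#' prevalence table: for every parameter, a numerator `k` (papers with the
#' flag set), a denominator `n` (papers with a non-missing flag — manual
#' features scored for only a subset of papers get subset denominators), and
#' a half-up rounded percentage. Yearly series additionally receive a trend
#' label and the averages block carries means with standard errors.
#'
#' @name aggregator
NULL

#' Prevalence of a tri-state flag vector
#'
#' Missing values are removed from both numerator and denominator. With an
#' empty denominator the cell is undefined (`percent = NA`), not an error.
#'
#' @param flags logical vector (tri-state; `NA` = not assessed).
#' @param places decimal places for the half-up rounded percentage (1 or 2).
#' @return one-row tibble: `k`, `n`, `percent`.
#' @export
#' @examples
#' prevalence(c(rep(TRUE, 19), rep(FALSE, 52)))  # 19/71 -> 26.76
prevalence <- function(flags, places = 2) {
  stopifnot(places %in% c(1L, 2L))
  k <- sum(flags, na.rm = TRUE)
  n <- sum(!is.na(flags))
  tibble::tibble(k = as.integer(k), n = as.integer(n),
                 percent = if (n == 0) NA_real_ else
                   round_half_up(100 * k / n, places))
}

#' Mean and standard error
#'
#' Standard error is the sample standard deviation (n - 1 denominator)
#' divided by `sqrt(n)`; with a single observation the SE is undefined.
#'
#' @param values non-empty numeric vector; `NA`s are dropped first.
#' @return list with `mean`, `se` and `n`.
#' @export
mean_and_se <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("mean_and_se() needs at least one value")
  n <- length(values)
  list(mean = mean(values),
       se = if (n == 1) NA_real_ else stats::sd(values) / sqrt(n),
       n = n)
}

#' Classify the direction of a yearly series
#'
#' A declared, configurable replacement for the qualitative trend column of
#' the published table: with the least-squares slope `b` of value on year and
#' the relative span `r = (max - min) / max(|mean|, eps)`, the label is
#' `no_change` when `r < span_threshold`; otherwise `positive` when the
#' Kendall rank correlation of the series with year is `>= tau_threshold`
#' and `b > 0`; `negative` when it is `<= -tau_threshold` and `b < 0`; and
#' `unclear` in every other case.
#'
#' @param yearly named numeric vector, names = years; at least two years.
#' @param span_threshold relative span below which the series is flat.
#' @param tau_threshold Kendall concordance needed for a directional label.
#' @param eps guard against division by zero in the relative span.
#' @return one of `"positive"`, `"negative"`, `"unclear"`, `"no_change"`.
#' @export
classify_trend <- function(yearly, span_threshold = 0.05, tau_threshold = 0.6,
                           eps = 1e-9) {
  yearly <- yearly[!is.na(yearly)]
  if (length(yearly) < 2) stop("classify_trend() needs at least two years")
  years <- as.numeric(names(yearly))
  if (anyNA(years)) stop("yearly series must be named by year")
  vals <- as.numeric(yearly)
  r <- (max(vals) - min(vals)) / max(abs(mean(vals)), eps)
  if (r < span_threshold) return("no_change")
  b <- stats::cov(years, vals) / stats::var(years)
  tau <- suppressWarnings(stats::cor(years, vals, method = "kendall"))
  if (!is.na(tau) && tau >= tau_threshold && b > 0) return("positive")
  if (!is.na(tau) && tau <= -tau_threshold && b < 0) return("negative")
  "unclear"
}

summary_parameters <- function(matrix, lex) {
  c(intersect(automated_groups(lex), names(matrix)),
    intersect(manual_features(), names(matrix)),
    intersect(derived_flags(), names(matrix)))
}

#' Summarize a scorecard matrix into the prevalence/averages table
#'
#' For every parameter the summary holds one prevalence cell per year present
#' in the corpus plus an overall (`"all"`) cell pooled over papers, and a
#' trend label computed from the yearly percentages. The averages block
#' covers `pages` and `n_data_visualizations`; co-author and academic-age
#' averages join it when an author table is supplied.
#'
#' @param matrix scorecard tibble from [score_corpus()].
#' @param authors optional long-format author tibble (see [corpus_io]).
#' @param lex lexicon used for scoring (fixes parameter order).
#' @param places decimal places for percentage cells.
#' @param trend_args list of overrides passed to [classify_trend()].
#' @return object of class `corpus_summary`: list with tibbles `prevalence`
#'   (parameter, stratum, k, n, percent), `trends` (parameter, trend),
#'   `averages` (parameter, stratum, mean, se, n) and, with authors, the
#'   [demography_stats()] list under `$demography`.
#' @export
summarize_corpus <- function(matrix, authors = NULL, lex = default_lexicon(),
                             places = 2, trend_args = list()) {
  params <- summary_parameters(matrix, lex)
  years <- sort(unique(matrix$year))
  strata <- c(as.character(years), "all")

  prev <- dplyr::bind_rows(lapply(params, function(p) {
    cells <- dplyr::bind_rows(lapply(strata, function(s) {
      flags <- if (s == "all") matrix[[p]] else matrix[[p]][matrix$year == as.integer(s)]
      dplyr::bind_cols(tibble::tibble(parameter = p, stratum = s),
                       prevalence(flags, places))
    }))
    cells
  }))

  trends <- dplyr::bind_rows(lapply(params, function(p) {
    cells <- prev[prev$parameter == p & prev$stratum != "all", ]
    series <- stats::setNames(cells$percent, cells$stratum)
    lbl <- if (sum(!is.na(series)) < 2) NA_character_ else
      do.call(classify_trend, c(list(series), trend_args))
    tibble::tibble(parameter = p, trend = lbl)
  }))

  avg_cols <- intersect(c("pages", "n_data_visualizations"), names(matrix))
  averages <- dplyr::bind_rows(lapply(avg_cols, function(p) {
    dplyr::bind_rows(lapply(strata, function(s) {
      v <- if (s == "all") matrix[[p]] else matrix[[p]][matrix$year == as.integer(s)]
      v <- v[!is.na(v)]
      if (length(v) == 0)
        return(tibble::tibble(parameter = p, stratum = s, mean = NA_real_,
                              se = NA_real_, n = 0L))
      m <- mean_and_se(v)
      tibble::tibble(parameter = p, stratum = s, mean = m$mean, se = m$se,
                     n = as.integer(m$n))
    }))
  }))

  out <- list(prevalence = prev, trends = trends, averages = averages,
              years = years, n_papers = nrow(matrix), places = places)
  if (!is.null(authors)) {
    out$demography <- demography_stats(matrix, authors)
    out$averages <- dplyr::bind_rows(out$averages,
                                     demography_averages(matrix, authors))
  }
  structure(out, class = "corpus_summary")
}

#' @export
print.corpus_summary <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' Write a corpus summary as JSON and CSV
#'
#' The JSON nests parameter -> per-year cells, overall cell and trend; the
#' CSV flattens the same cells into a table layout (parameter rows, year
#' columns, trend column).
#'
#' @param summary a `corpus_summary`.
#' @param json_path,csv_path output paths (`NULL` to skip either).
#' @export
write_summary <- function(summary, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    nested <- lapply(split(summary$prevalence, summary$prevalence$parameter),
                     function(cells) {
      per_year <- cells[cells$stratum != "all", ]
      all_cell <- cells[cells$stratum == "all", ]
      trend <- summary$trends$trend[summary$trends$parameter == cells$parameter[1]]
      list(cells = stats::setNames(
             lapply(seq_len(nrow(per_year)), function(i)
               list(k = per_year$k[i], n = per_year$n[i],
                    percent = per_year$percent[i])),
             per_year$stratum),
           all = list(k = all_cell$k, n = all_cell$n,
                      percent = all_cell$percent),
           trend = trend)
    })
    payload <- list(n_papers = summary$n_papers, years = summary$years,
                    parameters = nested,
                    averages = summary$averages,
                    demography = summary$demography)
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    wide <- summary_wide(summary)
    utils::write.csv(as.data.frame(wide), csv_path, row.names = FALSE, na = "")
  }
  invisible(summary)
}

# parameter x (years..., all, trend) percentage table
summary_wide <- function(summary) {
  prev <- summary$prevalence
  params <- unique(prev$parameter)
  strata <- c(as.character(summary$years), "all")
  wide <- tibble::tibble(parameter = params)
  for (s in strata)
    wide[[s]] <- vapply(params, function(p)
      prev$percent[prev$parameter == p & prev$stratum == s][1], numeric(1))
  wide$trend <- vapply(params, function(p) {
    t <- summary$trends$trend[summary$trends$parameter == p]
    if (length(t) == 0 || is.na(t)) "" else t
  }, character(1))
  wide
}
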