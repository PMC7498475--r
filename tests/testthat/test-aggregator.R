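test_that("prevalence cells use half-up rounding and subset denominators", {
  expect_equal(prevalence(c(rep(TRUE, 19), rep(FALSE, 52)))$percent, 26.76)
  expect_equal(prevalence(c(rep(TRUE, 15), rep(FALSE, 95)))$percent, 13.64)
  expect_equal(prevalence(c(rep(TRUE, 22), rep(FALSE, 92)))$percent, 19.30)
  expect_equal(prevalence(c(rep(TRUE, 111), rep(FALSE, 3)))$percent, 97.37)
  expect_equal(prevalence(rep(FALSE, 5))$percent, 0)
  expect_equal(prevalence(c(rep(TRUE, 996), rep(FALSE, 101)),
                          places = 1)$percent, 90.8)
  # missing values leave both k and n
  cell <- prevalence(c(TRUE, NA, FALSE, NA))
  expect_equal(cell$k, 1L)
  expect_equal(cell$n, 2L)
  # all-missing column is undefined, not an error
  expect_true(is.na(prevalence(c(NA, NA))$percent))
  expect_equal(prevalence(rep(TRUE, 7))$percent, 100)
})

test_that("round_half_up rounds .5 away from zero at any precision", {
  expect_equal(round_half_up(2.675, 2), 2.68)  # would be 2.67 under round()
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(13.635, 2), 13.64)
  expect_equal(round_half_up(90.75, 1), 90.8)
  expect_equal(round_half_up(-2.675, 2), -2.68)
})

test_that("mean and standard error follow the n-1 sample convention", {
  m <- mean_and_se(c(4, 4, 4))
  expect_equal(m$mean, 4)
  expect_equal(m$se, 0)
  m <- mean_and_se(1:5)
  expect_equal(m$mean, 3)
  expect_equal(m$se, 0.7071068, tolerance = 1e-6)
  expect_true(is.na(mean_and_se(5)$se))
  expect_error(mean_and_se(numeric()), "at least one")
})

test_that("trend labels: direction needs concordance, flatness wins", {
  expect_equal(classify_trend(c("2009" = 10, "2012" = 20, "2015" = 30)),
               "positive")
  expect_equal(classify_trend(c("2009" = 30, "2012" = 20, "2015" = 10)),
               "negative")
  expect_equal(classify_trend(c("2009" = 4, "2012" = 4, "2015" = 4)),
               "no_change")
  expect_equal(classify_trend(c("2009" = 100, "2012" = 101)), "no_change")
  # published altitude series: big swings, weak concordance -> unclear
  expect_equal(classify_trend(c("2009" = 26.76, "2013" = 13.64,
                                "2018" = 19.30)), "unclear")
  expect_error(classify_trend(c("2009" = 1)), "at least two")
})

test_that("summary cells equal a naive recount of the matrix", {
  corpus <- generate_corpus(corpus_spec(n_papers = 40, seed = 301))
  docs <- tibble::tibble(paper_id = corpus$documents$paper_id,
                         year = corpus$documents$year,
                         journal = corpus$documents$journal,
                         discipline = corpus$documents$discipline,
                         body = vapply(corpus$documents$text, searchable_body,
                                       character(1), USE.NAMES = FALSE))
  mat <- score_corpus(docs, annotations = corpus$annotations)
  s <- summarize_corpus(mat, authors = corpus$authors)
  for (i in seq_len(nrow(s$prevalence))) {
    row <- s$prevalence[i, ]
    rc <- recount_cell(mat, row$parameter, row$stratum)
    expect_equal(row$k, rc$k, label = paste(row$parameter, row$stratum))
    expect_equal(row$n, rc$n)
    expect_equal(row$percent, rc$percent)
  }
  # stratified consistency: overall k is the sum of per-year k
  for (p in unique(s$prevalence$parameter)) {
    cells <- s$prevalence[s$prevalence$parameter == p, ]
    expect_equal(cells$k[cells$stratum == "all"],
                 sum(cells$k[cells$stratum != "all"]))
    expect_true(all(cells$k <= cells$n))
    expect_true(all(is.na(cells$percent) |
                      (cells$percent >= 0 & cells$percent <= 100)))
  }
})

test_that("single-year corpora collapse per-year onto overall cells", {
  corpus <- generate_corpus(corpus_spec(n_papers = 12, years = 2015,
                                        year_weights = 1, seed = 77))
  docs <- tibble::tibble(paper_id = corpus$documents$paper_id,
                         year = corpus$documents$year,
                         journal = corpus$documents$journal,
                         discipline = corpus$documents$discipline,
                         body = vapply(corpus$documents$text, searchable_body,
                                       character(1), USE.NAMES = FALSE))
  mat <- score_corpus(docs, annotations = corpus$annotations)
  s <- summarize_corpus(mat)
  yearly <- s$prevalence[s$prevalence$stratum == "2015", ]
  overall <- s$prevalence[s$prevalence$stratum == "all", ]
  expect_equal(yearly$percent, overall$percent)
  # one year only: no trend can be assigned
  expect_true(all(is.na(s$trends$trend)))
})

test_that("a feature missing for every paper yields an undefined cell", {
  mat <- score_corpus(tibble::tibble(
    paper_id = c("A", "B"), year = c(2010L, 2011L),
    journal = "J", discipline = "mycology",
    raw_text = c("x", "y"), body = c("plain", "text")))
  s <- summarize_corpus(mat)
  cells <- s$prevalence[s$prevalence$parameter == "map_used", ]
  expect_true(all(is.na(cells$percent)))
  expect_true(all(cells$n == 0))
  txt <- render_summary(s)
  expect_false(any(grepl("map_used +[0-9]", txt)))
})
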