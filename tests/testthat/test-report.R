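test_that("audit runs end to end and matches the ground-truth summary", {
  corpus <- generate_corpus(corpus_spec(n_papers = 30, seed = 71))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  out <- file.path(dir, "out")
  s <- audit_corpus(file.path(dir, "texts"), file.path(dir, "papers.csv"),
                    authors_path = file.path(dir, "authors.csv"),
                    annotations_path = file.path(dir, "annotations.csv"),
                    out_dir = out)
  expect_true(all(file.exists(file.path(out, c("scorecards.csv",
                                               "summary.json", "summary.csv",
                                               "summary.txt")))))
  # summary computed from the pipeline equals one computed from ground truth
  truth_summary <- summarize_corpus(corpus$truth)
  for (p in c("ecology_term", "mycobank", "map_used", "dna_without_tree")) {
    got <- s$prevalence[s$prevalence$parameter == p &
                          s$prevalence$stratum == "all", ]
    want <- truth_summary$prevalence[
      truth_summary$prevalence$parameter == p &
        truth_summary$prevalence$stratum == "all", ]
    expect_equal(got$k, want$k, label = p)
    expect_equal(got$percent, want$percent, label = p)
  }
  # rerun is byte-identical
  out2 <- file.path(dir, "out2")
  audit_corpus(file.path(dir, "texts"), file.path(dir, "papers.csv"),
               authors_path = file.path(dir, "authors.csv"),
               annotations_path = file.path(dir, "annotations.csv"),
               out_dir = out2)
  for (f in c("scorecards.csv", "summary.json", "summary.csv", "summary.txt"))
    expect_identical(readLines(file.path(out, f)),
                     readLines(file.path(out2, f)))
})

test_that("audit failure removes partial outputs", {
  dir <- withr::local_tempdir()
  out <- file.path(dir, "out")
  expect_error(audit_corpus(file.path(dir, "nope"),
                            file.path(dir, "missing.csv"), out_dir = out))
  expect_false(any(file.exists(file.path(out, c("scorecards.csv",
                                                "summary.json")))))
})

test_that("lint reports per-check status, evidence, and a completeness score", {
  dir <- withr::local_tempdir()
  # one sentence per automated group, taken from the generator's bank
  full <- plant_features(
    stats::setNames(rep(TRUE, 23), automated_groups(default_lexicon())))
  f <- file.path(dir, "full.txt"); writeLines(full, f)
  rep_full <- lint_document(f)
  expect_equal(attr(rep_full, "score"), 1.0)
  expect_true(all(rep_full$status[rep_full$check %in%
                                    automated_groups(default_lexicon())] ==
                    "present"))

  empty <- file.path(dir, "empty.txt")
  writeLines(c("T", "A", "Introduction", "Nothing of note.", "References",
               "none"), empty)
  rep_empty <- lint_document(empty)
  expect_equal(attr(rep_empty, "score"), 0.0)

  # "deposited in H" evades the collection checklist item
  evasive <- file.path(dir, "evasive.txt")
  writeLines(c("T", "A", "Introduction",
               "The holotype was deposited in H.", "References", "none"),
             evasive)
  rep_ev <- lint_document(evasive)
  coll <- rep_ev[rep_ev$check == "collection", ]
  expect_equal(coll$status, "absent")
  expect_equal(coll$evidence, "")
  # evidence snippets quote the input verbatim
  ev <- rep_full[rep_full$check == "mycobank", ]
  expect_match(ev$evidence, "MycoBank")
  expect_true(grepl(gsub("\\s+", " ", ev$evidence),
                    gsub("\\s+", " ", full), fixed = TRUE))
})

test_that("rendered summary is a fixed-width table with blank undefined cells", {
  corpus <- generate_corpus(corpus_spec(n_papers = 10, seed = 81,
                                        years = c(2009, 2018),
                                        year_weights = c(1, 1)))
  docs <- tibble::tibble(paper_id = corpus$documents$paper_id,
                         year = corpus$documents$year,
                         journal = corpus$documents$journal,
                         discipline = corpus$documents$discipline,
                         body = vapply(corpus$documents$text, searchable_body,
                                       character(1), USE.NAMES = FALSE))
  mat <- score_corpus(docs, annotations = corpus$annotations)
  txt <- render_summary(summarize_corpus(mat, authors = corpus$authors))
  expect_match(txt[1], "Parameter")
  expect_match(txt[1], "2009")
  expect_match(txt[1], "all")
  expect_match(txt[1], "Trend")
  widths <- nchar(txt[seq_len(1 + 23)])
  expect_length(unique(widths), 1)
  # deterministic golden rendering
  txt2 <- render_summary(summarize_corpus(mat, authors = corpus$authors))
  expect_identical(txt, txt2)
})

test_that("the command-line wrapper audits a corpus from a shell", {
  skip_on_os("windows")
  corpus <- generate_corpus(corpus_spec(n_papers = 6, seed = 99))
  dir <- withr::local_tempdir()
  write_corpus(corpus, dir)
  cli <- system.file("cli", "taxaudit.R", package = "taxaudit")
  out <- file.path(dir, "cliout")
  res <- system2(file.path(R.home("bin"), "Rscript"),
                 c(cli, "audit", "--texts", file.path(dir, "texts"),
                   "--metadata", file.path(dir, "papers.csv"),
                   "--authors", file.path(dir, "authors.csv"),
                   "--annotations", file.path(dir, "annotations.csv"),
                   "--out", out, "--quiet"),
                 stdout = TRUE, stderr = TRUE)
  expect_equal(attr(res, "status") %||% 0, 0)
  expect_true(file.exists(file.path(out, "scorecards.csv")))
})
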