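test_that("the default lexicon carries the 23 automated groups", {
  lex <- default_lexicon()
  expect_length(automated_groups(lex), 23)
  expect_true(all(vapply(lex$groups[automated_groups(lex)], function(g)
    length(g$patterns) + length(g$regex) > 0, logical(1))))
  # manual groups carry no patterns
  man <- lex$groups[manual_features()]
  expect_true(all(vapply(man, function(g) length(g$patterns) == 0, logical(1))))
})

test_that("stems respect word starts and matching is case-insensitive", {
  expect_true(score_groups("notes on the ecology")[["ecology_term"]])
  expect_true(score_groups("an ECOLOGICAL remark")[["ecology_term"]])
  expect_false(score_groups("the gynecology ward")[["ecology_term"]])
  expect_true(score_groups("data in TreeBASE")[["molecular_availability"]])
  expect_true(score_groups("tReEbAsE")[["molecular_availability"]])
})

test_that("collection terms need an explicit repository word", {
  expect_true(score_groups("deposited in herbarium H")[["collection"]])
  expect_false(score_groups("deposited in H")[["collection"]])
  expect_true(score_groups("held in a culture\ncollection")[["collection"]])
})

test_that("ecological associations match host/substrate phrasing", {
  flags <- score_groups("found on dead branch of Quercus")
  expect_true(flags[["ecological_association"]])
  expect_true(score_groups("its usual substrate")[["ecological_association"]])
})

test_that("coordinate notations set the GIS/GPS flag", {
  expect_true(score_groups("collected at 59°21'N, 18°04'E")[["gis_gps"]])
  expect_true(score_groups("at 59.123456, 18.654321")[["gis_gps"]])
  expect_true(score_groups(repair_hyphenation(
    "GIS/GPS co-\nordinates were provided"))[["gis_gps"]])
  expect_false(score_groups("measuring 8.5-11.0 x 4.0-5.5 um")[["gis_gps"]])
})

test_that("classification groups accept rank words and name suffixes", {
  expect_true(score_groups("a member of the Physalacriaceae")[["family_classification"]])
  expect_true(score_groups("the family is unknown")[["family_classification"]])
  expect_true(score_groups("belongs to the Agaricales")[["order_classification"]])
  expect_false(score_groups("fairy tales were told")[["order_classification"]])
  expect_true(score_groups("in the Basidiomycota")[["phylum_classification"]])
})

test_that("empty body scores all false; flags are deterministic", {
  flags <- score_groups("")
  expect_length(flags, 23)
  expect_false(any(flags))
  expect_false(anyNA(flags))
  body <- "ecology, MycoBank and GenBank in a temperate forest"
  expect_identical(score_groups(body), score_groups(body))
})

test_that("match evidence points at the matched term", {
  lex <- default_lexicon()
  body <- "The holotype is kept in herbarium H."
  m <- match_group(body, lex$groups[["collection"]])
  expect_true(m$flag)
  off <- m$evidence$offset[1]
  term <- m$evidence$matched_term[1]
  expect_equal(substr(body, off + 1, off + nchar(term)), term)
})

test_that("adding a pattern can only turn flags on (monotonicity)", {
  set.seed(11)
  for (i in 1:20) {
    body <- random_body(25)
    base <- parameter_group("g", "automated", c("ecolog*", "host"))
    wider <- parameter_group("g", "automated", c("ecolog*", "host", "dead"))
    f1 <- match_group(body, base)$flag
    f2 <- match_group(body, wider)$flag
    expect_true(f2 >= f1)
  }
})

test_that("engine agrees with a brute-force word-boundary oracle", {
  lex <- default_lexicon()
  auto <- automated_groups(lex)
  set.seed(13)
  for (i in 1:60) {
    body <- random_body(sample(5:40, 1))
    for (nm in auto) {
      g <- lex$groups[[nm]]
      expect_identical(match_group(body, g)$flag, oracle_group_flag(body, g),
                       label = sprintf("group %s on body '%s'", nm, body))
    }
  }
})

test_that("lexicon YAML round-trips through dump and load", {
  lex <- default_lexicon()
  f <- withr::local_tempfile(fileext = ".yaml")
  lexicon_dump(lex, f)
  back <- load_lexicon(f)
  expect_identical(names(back$groups), names(lex$groups))
  for (nm in names(lex$groups)) {
    expect_identical(back$groups[[nm]]$patterns, lex$groups[[nm]]$patterns)
    expect_identical(back$groups[[nm]]$regex, lex$groups[[nm]]$regex)
    expect_identical(back$groups[[nm]]$category, lex$groups[[nm]]$category)
  }
})

test_that("degenerate lexicons are rejected with a helpful error", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("version: x\ngroups: []", f)
  expect_error(load_lexicon(f), "no groups")
  expect_error(parameter_group("bad", "automated", character()),
               "at least one pattern")
  expect_error(parameter_group("bad", "automated", "x", regex = "(["),
               "malformed pattern")
  expect_error(lexicon(list(parameter_group("m", "manual"))), "may not be empty")
})
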