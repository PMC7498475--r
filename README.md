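# taxaudit

Dictionary-based completeness auditing of taxonomic species descriptions.

When a new species is described, the publication may or may not tell the
reader — human or machine — where the organism sits in the tree of life,
what it does for a living, where it was collected, whether sequence data
exist and where they were deposited. `taxaudit` measures this, corpus-wide:
it scores each paper's full text for the presence of keyword groups covering
ecology, geography, taxonomy, molecular data and data availability, merges
in manually annotated features (colour photos, determination keys, maps,
open access, ...), derives composite indicators, and aggregates everything
into per-year prevalence tables with trend labels plus authorship demography
statistics. It is aimed at biodiversity informaticians and journal editors
who want a reproducible audit of how informative a body of species
descriptions actually is.

## The method

Each paper, available as extracted plain text (e.g. from `pdftotext`), is

1. **segmented**: the title/author/affiliation block, abstract,
   acknowledgements and literature cited are excluded, so that an author at
   an "ecology institute" or a cited paper title cannot set a flag. Line-broken
   words (`co-\nordinates`) are repaired before matching.
2. **scored** against a lexicon of *parameter groups*. Each automated group
   *g* holds patterns (case-insensitive stems `ecolog*`, exact words,
   phrases, and regular expressions for coordinate notations and rank
   suffixes such as *-aceae*); its flag is

   ```
   x_g(paper) = 1  iff  any pattern of g matches the searchable body
   ```

   Manual features are ingested from a tri-state annotation table (true /
   false / not assessed) and never back-filled from text. Composites are
   pure functions of the flags, e.g.
   `neither_gps_nor_map = !gis_gps & !map_used`.
3. **aggregated**: for parameter *g*, year *t*, the prevalence cell is
   *k/n* with `percent = round_half_up(100·k/n)`, where *n* counts papers
   with a non-missing flag. Averages (pages, co-authors, academic ages)
   are reported with standard errors `sd/√n`, and each yearly series gets a
   trend label from its least-squares slope and Kendall concordance.
   Gender composition uses only papers whose author list is fully
   gender-resolved; academic age is `newest_pub_year − oldest_pub_year`.

A seeded synthetic-corpus generator plants keyword sentences (and decoys in
excluded sections) at configurable prevalences with known ground truth, so
the whole pipeline is testable without any copyrighted source PDFs.

## Worked example

```r
library(taxaudit)

# generate a 60-paper corpus with known ground truth, audit it end to end
dir <- tempfile()
corpus <- simulate_corpus(dir, corpus_spec(n_papers = 60, seed = 42))
summary <- audit_corpus(
  file.path(dir, "texts"), file.path(dir, "papers.csv"),
  authors_path     = file.path(dir, "authors.csv"),
  annotations_path = file.path(dir, "annotations.csv"),
  out_dir          = file.path(dir, "out"))

subset(summary$prevalence, parameter == "ecology_term" & stratum == "all")
#> # A tibble: 1 × 5
#>   parameter    stratum     k     n percent
#>   <chr>        <chr>   <int> <int>   <dbl>
#> 1 ecology_term all        19    60   31.67

summary$demography$pct_female_coauthors
#> [1] 30.2
summary$demography$mean_coauthors
#> [1] 4.216667
```

`31.67` means 19 of the 60 papers mention a variant of "ecology" in their
searchable body — here exactly the 19 papers the generator planted it into
(the default planting probability is 0.42). The demography numbers recover
the generator's planted rates (29.8 % female authors, mean 4.4 co-authors)
up to sampling noise. `out/` now holds `scorecards.csv` (one row per paper,
booleans as 1/0, not-assessed as blank), `summary.json`, `summary.csv` and a
fixed-width `summary.txt`.

Single-manuscript lint:

```r
lint_document(file.path(dir, "texts", "P0001.txt"))
#> Completeness score: 0.57 (13/23 automated checks present)
#>
#> present      altitude  "...ections were made between 300 and 800 m altitude. It was found growing on dead wood of ..."
#> absent       biodiversity
#> absent       climate
#> ...
```

A thin command-line wrapper ships at
`system.file("cli", "taxaudit.R", package = "taxaudit")` with subcommands
`audit`, `lint`, `simulate` and `lexicon-dump`.

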