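options(taxaudit.quiet = TRUE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical five-block document used across segmentation tests
fixture_doc <- function() {
  paste("TITLE", "Authors", "Abstract", "X", "Introduction", "Y",
        "Acknowledgements", "Z", "References", "W", sep = "\n")
}

# independent brute-force matcher: lowercase the body, tokenize, and test
# every pattern by substring-at-word-boundary search (stems by token prefix,
# words/phrases by token equality); raw regexes via base grepl
oracle_group_flag <- function(body, group) {
  b <- tolower(gsub("\\s+", " ", body))
  toks <- strsplit(gsub("[^a-z0-9.'°/-]+", " ", b), " ", fixed = TRUE)[[1]]
  toks <- toks[toks != ""]
  stripped <- gsub("^[.'/-]+|[.'/-]+$", "", toks)
  norm <- paste0(" ", gsub("[^a-z0-9]+", " ", b), " ")
  hit <- FALSE
  for (p in group$patterns) {
    if (endsWith(p, "*")) {
      core <- tolower(substr(p, 1, nchar(p) - 1))
      if (any(startsWith(toks, core) | startsWith(stripped, core))) hit <- TRUE
    } else if (grepl("\\s", p)) {
      if (grepl(paste0(" ", gsub("[^a-z0-9]+", " ", tolower(p)), " "),
                norm, fixed = TRUE)) hit <- TRUE
    } else {
      if (any(toks == tolower(p) | stripped == tolower(p))) hit <- TRUE
    }
    if (hit) return(TRUE)
  }
  for (rx in group$regex)
    if (grepl(rx, body, ignore.case = TRUE, perl = TRUE)) return(TRUE)
  FALSE
}

# vocabulary of pattern words, near-misses and neutral filler for random
# bodies in the oracle-equivalence property test
oracle_vocab <- function() {
  c("ecology", "ecological", "gynecology", "host", "hosting", "substrate",
    "temperate", "temperature", "climate", "acclimatized", "blast",
    "blasted", "genbank", "treebase", "mycobank", "family", "families",
    "physalacriaceae", "agaricales", "tales", "rationales", "phylum",
    "basidiomycota", "dna", "pcr", "sequence", "consequence", "herbarium",
    "museum", "locality", "localities", "altitude", "elevation",
    "distribution", "geography", "biodiversity", "supplementary",
    "threatened", "endangered", "gps", "the", "fungus", "was", "found",
    "on", "dead", "wood", "and", "a", "new", "species")
}

random_body <- function(rng_n = 30) {
  paste(sample(oracle_vocab(), rng_n, replace = TRUE), collapse = " ")
}

# tiny on-disk corpus: three hand-authored papers with known flags
write_tiny_corpus <- function(dir) {
  dir.create(file.path(dir, "texts"), recursive = TRUE, showWarnings = FALSE)
  texts <- list(
    T1 = paste("A new Mycena", "A. Author", "Abstract", "New species here.",
               "Introduction",
               "Notes on the ecology are given. Registered in MycoBank.",
               "References", "Smith A (2010) Old record. J Fun 1: 1.",
               sep = "\n"),
    T2 = paste("Another fungus", "B. Author", "Abstract",
               "We thank the ecology institute.", "Introduction",
               "The holotype is deposited in herbarium H.",
               "Acknowledgements", "We thank the ecology institute.",
               "References", "None.", sep = "\n"),
    T3 = paste("Third fungus", "C. Author", "Abstract", "Text.",
               "Introduction", "Nothing informative is said here.",
               "References", "None.", sep = "\n"))
  for (id in names(texts))
    writeLines(texts[[id]], file.path(dir, "texts", paste0(id, ".txt")))
  papers <- data.frame(paper_id = names(texts), year = c(2009, 2009, 2018),
                       journal = "Mycologia", discipline = "mycology")
  write.csv(papers, file.path(dir, "papers.csv"), row.names = FALSE)
  authors <- data.frame(
    paper_id = c("T1", "T1", "T2", "T3"), position = c(1, 2, 1, 1),
    name = c("A. One", "B. Two", "C. Three", "D. Four"),
    gender = c("female", "male", "male", "unknown"),
    department = c("D1", "D2", "D1", "D3"),
    country = c("Sweden", "Sweden", "Japan", "Brazil"),
    continent = c("Europe", "Europe", "Asia", "South America"),
    oldest_pub_year = c(2000, 1990, 2005, NA),
    newest_pub_year = c(2018, 2018, 2009, NA))
  write.csv(authors, file.path(dir, "authors.csv"), row.names = FALSE, na = "")
  ann <- data.frame(paper_id = c("T1", "T2"),
                    color_photo = c("1", "0"),
                    map_used = c("", "1"),
                    tree_shown = c("0", ""),
                    pages = c("10", "7"),
                    n_data_visualizations = c("0", "2"))
  write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  dir
}

# naive one-pass recount of a summary cell, independent of the aggregator
recount_cell <- function(matrix, parameter, stratum, places = 2) {
  rows <- if (stratum == "all") seq_len(nrow(matrix)) else
    which(matrix$year == as.integer(stratum))
  v <- matrix[[parameter]][rows]
  k <- 0L; n <- 0L
  for (x in v) {
    if (is.na(x)) next
    n <- n + 1L
    if (isTRUE(x)) k <- k + 1L
  }
  pct <- if (n == 0) NA_real_ else {
    raw <- 100 * k / n
    floor(raw * 10^places + 0.5 + 1e-9) / 10^places
  }
  list(k = k, n = n, percent = pct)
}
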