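#' Corpus input/output
#'
#' A corpus is a directory of UTF-8 plain-text files (one per paper,
#' `<paper_id>.txt`) plus two CSV sidecars: a paper table
#' (`paper_id, year, journal, discipline`) and a long-format author table
#' (`paper_id, position, name, gender, department, country, continent,
#' oldest_pub_year, newest_pub_year`). Manual annotations live in a third CSV
#' whose boolean cells are tri-state: `1`/`true`, `0`/`false`, or blank for
#' "not assessed". Blank never silently becomes false; denominators downstream
#' exclude missing values.
#'
#' @name corpus_io
NULL

paper_csv_cols <- c("paper_id", "year", "journal", "discipline")
author_csv_cols <- c("paper_id", "position", "name", "gender", "department",
                     "country", "continent", "oldest_pub_year",
                     "newest_pub_year")

# 0-based offset of the first byte at which a raw vector stops being valid
# UTF-8 (only called once whole-string validation has already failed)
first_invalid_utf8 <- function(bytes) {
  b <- as.integer(bytes)
  i <- 1L; n <- length(b)
  while (i <= n) {
    lead <- b[i]
    len <- if (lead < 0x80) 1L else if (lead >= 0xC2 && lead <= 0xDF) 2L else
           if (lead >= 0xE0 && lead <= 0xEF) 3L else
           if (lead >= 0xF0 && lead <= 0xF4) 4L else return(i - 1L)
    if (i + len - 1L > n) return(i - 1L)
    if (len > 1L) {
      cont <- b[(i + 1L):(i + len - 1L)]
      if (any(cont < 0x80 | cont > 0xBF)) return(i - 1L)
    }
    i <- i + len
  }
  n
}

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("file '", path, "' lacks required columns: ",
         paste(missing, collapse = ", "))
  tibble::as_tibble(df)
}

#' Load a document corpus with its metadata sidecars
#'
#' Every metadata row must have a matching `<paper_id>.txt` file; the
#' `body` field of each record is filled by [searchable_body()].
#'
#' @param text_dir directory containing one UTF-8 `.txt` file per paper.
#' @param metadata_path paper-table CSV (see [corpus_io]).
#' @param authors_path optional long-format author CSV; `NULL` loads no
#'   author metadata.
#' @param config segmentation configuration, see [seg_config()].
#' @return a list with `documents` (tibble: paper_id, year, journal,
#'   discipline, raw_text, body) and `authors` (tibble or `NULL`).
#' @export
load_corpus <- function(text_dir, metadata_path, authors_path = NULL,
                        config = seg_config()) {
  meta <- read_csv_checked(metadata_path, paper_csv_cols)
  if (anyDuplicated(meta$paper_id))
    stop("duplicate paper_id in metadata: ",
         paste(unique(meta$paper_id[duplicated(meta$paper_id)]), collapse = ", "))
  bad_year <- !stringr::str_detect(meta$year, "^[0-9]{4}$")
  if (any(bad_year))
    stop("year must be a 4-digit integer; offending paper_id: ",
         paste(meta$paper_id[bad_year], collapse = ", "))
  files <- file.path(text_dir, paste0(meta$paper_id, ".txt"))
  orphan <- !file.exists(files)
  if (any(orphan))
    stop("metadata rows without a text file: ",
         paste(meta$paper_id[orphan], collapse = ", "))

  raw <- vapply(seq_along(files), function(i) {
    txt <- readBin(files[i], "raw", file.size(files[i]))
    out <- rawToChar(txt)
    Encoding(out) <- "UTF-8"
    if (!validUTF8(out))
      stop("undecodable bytes in '", files[i], "' near offset ",
           first_invalid_utf8(txt))
    out
  }, character(1))

  docs <- tibble::tibble(
    paper_id = meta$paper_id,
    year = as.integer(meta$year),
    journal = meta$journal,
    discipline = meta$discipline,
    raw_text = raw,
    body = vapply(raw, searchable_body, character(1), config = config,
                  USE.NAMES = FALSE))

  authors <- NULL
  if (!is.null(authors_path)) {
    authors <- read_csv_checked(authors_path, author_csv_cols)
    authors$position <- as.integer(authors$position)
    authors$oldest_pub_year <- suppressWarnings(as.integer(authors$oldest_pub_year))
    authors$newest_pub_year <- suppressWarnings(as.integer(authors$newest_pub_year))
    unknown <- setdiff(unique(authors$paper_id), meta$paper_id)
    if (length(unknown))
      stop("author rows reference unknown paper_id: ",
           paste(unknown, collapse = ", "))
    both <- !is.na(authors$oldest_pub_year) & !is.na(authors$newest_pub_year)
    if (any(both & authors$oldest_pub_year > authors$newest_pub_year))
      stop("oldest_pub_year exceeds newest_pub_year for some author rows")
  }
  ta_log("loaded %d documents from %s", nrow(docs), text_dir)
  list(documents = docs, authors = authors)
}

parse_tristate <- function(x, path, column) {
  val <- stringr::str_trim(as.character(x))
  truthy <- c("1", "true", "TRUE", "True")
  falsy <- c("0", "false", "FALSE", "False")
  bad <- !(is.na(val) | val == "" | val %in% c(truthy, falsy))
  if (any(bad))
    stop("invalid boolean '", val[which(bad)[1]], "' in column '", column,
         "' row ", which(bad)[1], " of ", path)
  out <- rep(NA, length(val))
  out[val %in% truthy] <- TRUE
  out[val %in% falsy] <- FALSE
  out
}

#' Load a manual-annotation table
#'
#' One row per paper; boolean feature columns are tri-state (`1`/`true`,
#' `0`/`false`, blank = not assessed). Column names outside the known manual
#' features (plus `pages` and `n_data_visualizations`) are rejected unless
#' listed in `extra_columns`.
#'
#' @param path annotations CSV.
#' @param extra_columns additional column names to accept.
#' @return tibble keyed by `paper_id` with tri-state logical feature columns.
#' @export
load_annotations <- function(path, extra_columns = character()) {
  df <- read_csv_checked(path, "paper_id")
  known <- c("paper_id", manual_features(), "pages", "n_data_visualizations",
             extra_columns)
  unknown <- setdiff(names(df), known)
  if (length(unknown))
    stop("unknown annotation columns in ", path, ": ",
         paste(unknown, collapse = ", "), " (declare them via extra_columns)")
  if (anyDuplicated(df$paper_id))
    stop("duplicate paper_id in annotations: ", path)
  for (col in intersect(manual_features(), names(df)))
    df[[col]] <- parse_tristate(df[[col]], path, col)
  for (col in intersect(c("pages", "n_data_visualizations"), names(df)))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  df
}

#' Write a scorecard matrix to CSV
#'
#' Booleans are serialized as `1`/`0` and missing values as blank cells, so
#' the tri-state distinction survives a round trip through
#' [read_scorecards()]. The column order of the matrix is preserved.
#'
#' @param matrix scorecard tibble from [score_corpus()].
#' @param path output CSV path.
#' @export
write_scorecards <- function(matrix, path) {
  out <- matrix
  for (col in names(out))
    if (is.logical(out[[col]])) out[[col]] <- as.integer(out[[col]])
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to '", path, "': ",
                                           conditionMessage(e)))
  on.exit(close(con))
  utils::write.csv(as.data.frame(out), con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read back a scorecard matrix written by [write_scorecards()]
#'
#' @param path scorecards CSV.
#' @return tibble with logical flag columns (blank cells restored as `NA`).
#' @export
read_scorecards <- function(path) {
  df <- read_csv_checked(path, "paper_id")
  flag_cols <- c(intersect(names(df), c(automated_groups(default_lexicon()),
                                        manual_features(), derived_flags())))
  # flag columns beyond the built-in set: any all-0/1/blank column
  extra <- setdiff(names(df), c("paper_id", "year", "journal", "discipline",
                                "pages", "n_data_visualizations", flag_cols))
  for (col in extra)
    if (all(df[[col]] %in% c("", "0", "1", NA))) flag_cols <- c(flag_cols, col)
  for (col in flag_cols) df[[col]] <- parse_tristate(df[[col]], path, col)
  for (col in intersect(c("year", "pages", "n_data_visualizations"), names(df)))
    df[[col]] <- suppressWarnings(as.integer(df[[col]]))
  df
}
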