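#' Build a name corpus from raw records
#'
#' An `inn_corpus` is a tibble with one row per name and columns
#' `raw_name`, `norm_name`, `year`, `list_id` and `word_class`, plus a
#' `provenance` attribute recording where the records came from.
#'
#' `norm_name` is `raw_name` lowercased with surrounding whitespace stripped.
#' A name is classed `"multi"` when it contains whitespace or any
#' non-alphanumeric character (hyphens included); otherwise `"single"`.
#' Digits count as alphanumeric, so a second word such as "131I" makes a name
#' multi-word through its space, not through the digits.
#'
#' Duplicate normalized names are collapsed to their first occurrence (by
#' input order, i.e. earliest publication wins when the input is
#' chronological); a warning lists the dropped duplicates.
#'
#' @param raw_name character vector of names as published.
#' @param year integer vector of publication years (NA allowed).
#' @param list_id optional character vector of Recommended-List labels.
#' @param provenance free-text label (file path or generator description).
#' @return an `inn_corpus` tibble.
#' @export
inn_corpus <- function(raw_name, year = NA_integer_, list_id = NA_character_,
                       provenance = "in-memory") {
  raw_name <- as.character(raw_name)
  keep <- !is.na(raw_name) & trimws(raw_name) != ""
  raw_name <- raw_name[keep]
  year <- vctrs_recycle(year, length(keep))[keep]
  list_id <- vctrs_recycle(list_id, length(keep))[keep]

  norm <- normalize_name(raw_name)
  stopifnot(all(nzchar(norm)))
  out <- tibble::tibble(
    raw_name = raw_name,
    norm_name = norm,
    year = suppressWarnings(as.integer(year)),
    list_id = as.character(list_id),
    word_class = ifelse(grepl("[^[:alnum:]]", raw_name), "multi", "single")
  )
  dup <- duplicated(out$norm_name)
  if (any(dup)) {
    warning(sprintf(
      "dropping %d duplicate name(s), keeping first occurrence: %s",
      sum(dup), paste(unique(out$norm_name[dup]), collapse = ", ")
    ), call. = FALSE)
    out <- out[!dup, ]
  }
  new_corpus(out, provenance)
}

# internal constructor; `x` must already hold the corpus columns
new_corpus <- function(x, provenance) {
  x <- tibble::as_tibble(x)
  structure(x, class = c("inn_corpus", class(x)), provenance = provenance)
}

vctrs_recycle <- function(x, n) {
  if (length(x) == 1L) rep(x, n) else if (length(x) == n) x else
    stop("length mismatch in corpus columns", call. = FALSE)
}

#' Normalize a raw name
#'
#' Lowercase and strip surrounding whitespace. Idempotent.
#' @param x character vector.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(x) tolower(trimws(x))

#' @export
print.inn_corpus <- function(x, ...) {
  cat(sprintf(
    "<inn_corpus> %d names (%d single-word, %d multi-word) — %s\n",
    nrow(x), sum(x$word_class == "single"), sum(x$word_class == "multi"),
    attr(x, "provenance") %||% "?"
  ))
  NextMethod()
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a name corpus from a delimited text file
#'
#' Expects a delimited file with (at least) a name column and a year column;
#' column names and delimiter are configurable. Empty files yield an empty
#' corpus. Rows whose year does not parse raise a record-level error naming
#' the row.
#'
#' @param path file path.
#' @param delim field delimiter (default `","`).
#' @param name_col,year_col,list_col column names (defaults `"name"`,
#'   `"year"`; `list_col` optional, used when present).
#' @return an `inn_corpus`.
#' @export
read_corpus <- function(path, delim = ",", name_col = "name",
                        year_col = "year", list_col = "list_id") {
  stopifnot(file.exists(path))
  df <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                          progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    return(new_corpus(tibble::tibble(
      raw_name = character(), norm_name = character(), year = integer(),
      list_id = character(), word_class = character()
    ), provenance = path))
  }
  for (col in c(name_col, year_col)) {
    if (!col %in% names(df)) {
      stop(sprintf("required column '%s' not found in %s", col, path), call. = FALSE)
    }
  }
  yr_raw <- df[[year_col]]
  yr <- suppressWarnings(as.integer(yr_raw))
  bad <- which(!is.na(yr_raw) & trimws(yr_raw) != "" & is.na(yr))
  if (length(bad)) {
    stop(sprintf("unparseable year %s at data row %d", dQuote(yr_raw[bad[1]]), bad[1]),
         call. = FALSE)
  }
  lid <- if (list_col %in% names(df)) df[[list_col]] else NA_character_
  inn_corpus(df[[name_col]], year = yr, list_id = lid, provenance = path)
}

#' Write a corpus to delimited text
#'
#' Emits `name,year,word_class` (plus `list_id` when any is recorded).
#' @param corpus an `inn_corpus`.
#' @param path output file.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, delim = ",") {
  out <- tibble::tibble(name = corpus$raw_name, year = corpus$year,
                        word_class = corpus$word_class)
  if (any(!is.na(corpus$list_id))) out$list_id <- corpus$list_id
  readr::write_delim(out, path, delim = delim)
  invisible(path)
}

#' Partition a corpus into single-word and multi-word subsets
#'
#' @param corpus an `inn_corpus`.
#' @return list with elements `single` and `multi`, both `inn_corpus`;
#'   their sizes sum to `nrow(corpus)`.
#' @export
partition_corpus <- function(corpus) {
  prov <- attr(corpus, "provenance") %||% "?"
  list(
    single = new_corpus(corpus[corpus$word_class == "single", ],
                        paste0(prov, " [single-word]")),
    multi = new_corpus(corpus[corpus$word_class == "multi", ],
                       paste0(prov, " [multi-word]"))
  )
}

#' Draw a reproducible uniform random subsample
#'
#' Samples `round(fraction * n)` records without replacement. The same seed
#' always yields the same sample.
#'
#' @param corpus an `inn_corpus`.
#' @param fraction proportion in (0, 1].
#' @param seed integer seed.
#' @return an `inn_corpus` subsample.
#' @export
sample_fraction <- function(corpus, fraction, seed) {
  if (!is.numeric(fraction) || length(fraction) != 1 ||
      fraction <= 0 || fraction > 1) {
    stop("`fraction` must be a single value in (0, 1]", call. = FALSE)
  }
  n <- nrow(corpus)
  k <- round(fraction * n)
  idx <- withr::with_seed(as.integer(seed), sample.int(n, k))
  new_corpus(corpus[idx, ],
             sprintf("%s [%.4g sample, seed %d]",
                     attr(corpus, "provenance") %||% "?", fraction, as.integer(seed)))
}
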