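#' @title Prohibited graphs and digraphs
#' @description WHO naming principle 7 asks for "f" instead of "ph", "t"
#'   instead of "th", "e" instead of "ae"/"oe", "i" instead of "y", and for
#'   "h" and "k" to be avoided. These constants define the scan order used
#'   throughout the package: at each offset the two-character patterns are
#'   tried before the single characters, and the scan never overlaps matches,
#'   so the "h" inside a matched "ph"/"th" is not additionally reported while
#'   an "h" elsewhere (e.g. in "chlor") is.
#' @name prohibited-patterns
NULL

PROHIBITED_DIGRAPHS <- c("ph", "th", "ae", "oe")
PROHIBITED_GRAPHS <- c("y", "h", "k")

#' Scan a name for prohibited graphs and digraphs
#'
#' Left-to-right greedy non-overlapping scan. Digraphs (`ph`, `th`, `ae`,
#' `oe`) take precedence over single graphs (`y`, `h`, `k`) at the same
#' offset, and the scan advances past each match.
#'
#' When a stem lexicon is supplied, hits whose span lies entirely inside a
#' matched recommended-stem span (e.g. the `k` of -kacin in amikacin) are
#' marked `exempt = TRUE` but still returned; principle 7 defers to
#' principle 2 when the offending letters belong to a recommended stem.
#'
#' @param name a single normalized (lowercase alphabetic) single-word name.
#' @param lexicon optional `stem_lexicon` used to mark stem-exempt hits.
#' @return tibble with columns `pattern`, `start` (0-based offset), `exempt`.
#' @examples
#' scan_prohibited("chlorpromazine")
#' @export
scan_prohibited <- function(name, lexicon = NULL) {
  stopifnot(length(name) == 1L, is.character(name))
  if (!grepl("^[a-z]+$", name)) {
    stop("`name` must be non-empty lowercase alphabetic", call. = FALSE)
  }
  n <- nchar(name)
  pat <- character()
  start <- integer()
  i <- 1L
  while (i <= n) {
    two <- substr(name, i, i + 1L)
    one <- substr(name, i, i)
    if (i < n && two %in% PROHIBITED_DIGRAPHS) {
      pat <- c(pat, two); start <- c(start, i - 1L); i <- i + 2L
    } else if (one %in% PROHIBITED_GRAPHS) {
      pat <- c(pat, one); start <- c(start, i - 1L); i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  hits <- tibble::tibble(pattern = pat, start = start, exempt = FALSE)
  if (!is.null(lexicon) && nrow(hits)) {
    spans <- match_stems(name, lexicon)
    spans <- spans[!is.na(spans$start), , drop = FALSE]
    if (nrow(spans)) {
      hit_end <- hits$start + nchar(hits$pattern)
      hits$exempt <- vapply(seq_len(nrow(hits)), function(j) {
        any(spans$start <= hits$start[j] & hit_end[j] <= spans$end)
      }, logical(1))
    }
  }
  hits
}

#' Tabulate prohibited (di)graphs across a single-word corpus
#'
#' For each pattern, counts the names containing it at least once and the
#' total number of instances; both a raw total and an exempt-excluded total
#' are reported, since stem-exempt hits may or may not be treated as
#' violations.
#'
#' @param corpus a single-word `inn_corpus`.
#' @param lexicon optional `stem_lexicon` for exemption marking.
#' @return tibble with one row per pattern plus a `total` row; columns
#'   `pattern`, `names_containing`, `total_instances`, `exempt_instances`.
#' @export
digraph_table <- function(corpus, lexicon = NULL) {
  patterns <- c(PROHIBITED_DIGRAPHS, PROHIBITED_GRAPHS)
  hits <- scan_corpus(corpus, lexicon)
  per <- lapply(patterns, function(p) {
    h <- hits[hits$pattern == p, , drop = FALSE]
    tibble::tibble(
      pattern = p,
      names_containing = length(unique(h$name)),
      total_instances = nrow(h),
      exempt_instances = sum(h$exempt)
    )
  })
  per <- dplyr::bind_rows(per)
  total <- tibble::tibble(
    pattern = "total",
    names_containing = length(unique(hits$name)),
    total_instances = nrow(hits),
    exempt_instances = sum(hits$exempt)
  )
  dplyr::bind_rows(per, total)
}

# all hits over a corpus, one row per hit with the bearing name attached
scan_corpus <- function(corpus, lexicon = NULL) {
  out <- lapply(corpus$norm_name, function(nm) {
    h <- scan_prohibited(nm, lexicon)
    if (nrow(h)) h$name <- nm
    h
  })
  res <- dplyr::bind_rows(out)
  if (!nrow(res)) {
    res <- tibble::tibble(pattern = character(), start = integer(),
                          exempt = logical(), name = character())
  }
  res
}

#' Prohibited (di)graph instances per decade of publication
#'
#' Decade is `floor(year / 10) * 10`. Records without a year are excluded
#' with a warning. Bucket counts sum to the `digraph_table()` grand total
#' over the year-bearing records.
#'
#' @inheritParams digraph_table
#' @return tibble with columns `decade`, `instances`.
#' @export
digraphs_by_decade <- function(corpus, lexicon = NULL) {
  corpus <- drop_yearless(corpus)
  if (!nrow(corpus)) {
    return(tibble::tibble(decade = integer(), instances = integer()))
  }
  counts <- vapply(seq_len(nrow(corpus)), function(i) {
    nrow(scan_prohibited(corpus$norm_name[i], lexicon))
  }, integer(1))
  dec <- (corpus$year %/% 10L) * 10L
  agg <- stats::aggregate(counts, by = list(decade = dec), FUN = sum)
  tibble::tibble(decade = agg$decade, instances = as.integer(agg$x))
}

drop_yearless <- function(corpus) {
  miss <- is.na(corpus$year)
  if (any(miss)) {
    warning(sprintf("excluding %d record(s) with missing year", sum(miss)),
            call. = FALSE)
    corpus <- corpus[!miss, ]
  }
  corpus
}

#' Check a multi-word name for isolated elements and hyphens
#'
#' Principle 6 discourages isolated letters or numbers and hyphenated
#' construction. Tokens are the whitespace-delimited words of the raw name.
#'
#' @param name a single raw multi-word (or hyphenated) name.
#' @return tibble of one row with logical columns `has_hyphen`,
#'   `has_isolated_letter`, `has_isolated_number`, `has_alphanumeric_word`.
#' @examples
#' isolated_elements("peginterferon lambda-1a")
#' @export
isolated_elements <- function(name) {
  stopifnot(length(name) == 1L, is.character(name))
  tokens <- strsplit(trimws(name), "[[:space:]]+")[[1]]
  tibble::tibble(
    has_hyphen = grepl("-", name, fixed = TRUE),
    has_isolated_letter = any(grepl("^[A-Za-z]$", tokens)),
    has_isolated_number = any(grepl("^[0-9]$", tokens)),
    has_alphanumeric_word = any(grepl("[A-Za-z]", tokens) & grepl("[0-9]", tokens))
  )
}

#' Isolated-element report for the multi-word subset of a corpus
#'
#' @param corpus an `inn_corpus` (its multi-word rows are analysed).
#' @return tibble with one row per multi-word name and the
#'   [isolated_elements()] flags.
#' @export
isolated_element_report <- function(corpus) {
  multi <- corpus[corpus$word_class == "multi", ]
  if (!nrow(multi)) {
    return(tibble::tibble(name = character(), has_hyphen = logical(),
                          has_isolated_letter = logical(),
                          has_isolated_number = logical(),
                          has_alphanumeric_word = logical()))
  }
  flags <- dplyr::bind_rows(lapply(multi$raw_name, isolated_elements))
  dplyr::bind_cols(tibble::tibble(name = multi$raw_name), flags)
}

#' Word-length statistics for a single-word corpus
#'
#' Character-count summary of the normalized names. The standard deviation is
#' the population SD by default (`sd_type = "sample"` gives the n-1 form).
#' Mode ties break to the smallest value. Outliers are names strictly longer
#' than `outlier_threshold`, listed ascending by length.
#'
#' @param corpus a non-empty single-word `inn_corpus`.
#' @param outlier_threshold integer; names longer than this are outliers.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return list of class `length_stats`: `n`, `mean`, `sd`, `median`, `mode`,
#'   `q1`, `q3`, `outliers` (tibble `name`, `length`).
#' @export
length_stats <- function(corpus, outlier_threshold = 20, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (nrow(corpus) == 0) stop("no statistics: corpus is empty", call. = FALSE)
  len <- nchar(corpus$norm_name)
  n <- length(len)
  sdv <- stats::sd(len)
  if (is.na(sdv)) sdv <- 0
  if (sd_type == "population") sdv <- sdv * sqrt((n - 1) / n)
  tab <- table(len)
  mode_val <- min(as.integer(names(tab)[tab == max(tab)]))
  q <- stats::quantile(len, c(0.25, 0.5, 0.75), names = FALSE)
  out_idx <- which(len > outlier_threshold)
  outliers <- tibble::tibble(name = corpus$norm_name[out_idx],
                             length = len[out_idx])
  outliers <- outliers[order(outliers$length, outliers$name), ]
  structure(list(
    n = n, mean = mean(len), sd = sdv, median = q[2], mode = mode_val,
    q1 = q[1], q3 = q[3], outliers = outliers,
    outlier_threshold = outlier_threshold
  ), class = "length_stats")
}

#' @export
print.length_stats <- function(x, ...) {
  cat(sprintf(
    "Word length over %d names: mean %.2f (SD %.2f), median %g, mode %g, IQR %g-%g\n",
    x$n, x$mean, x$sd, x$median, x$mode, x$q1, x$q3))
  cat(sprintf("%d outlier(s) longer than %d characters\n",
              nrow(x$outliers), x$outlier_threshold))
  invisible(x)
}

#' Mean name length per decade of publication
#'
#' @param corpus an `inn_corpus` with years.
#' @return tibble with columns `decade`, `n`, `mean_length`.
#' @export
length_by_decade <- function(corpus) {
  corpus <- drop_yearless(corpus)
  if (!nrow(corpus)) {
    return(tibble::tibble(decade = integer(), n = integer(), mean_length = double()))
  }
  len <- nchar(corpus$norm_name)
  dec <- (corpus$year %/% 10L) * 10L
  agg <- stats::aggregate(len, by = list(decade = dec),
                          FUN = function(v) c(n = length(v), m = mean(v)))
  tibble::tibble(decade = agg$decade,
                 n = as.integer(agg$x[, "n"]),
                 mean_length = unname(agg$x[, "m"]))
}
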