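#' Load a monoclonal-antibody infix table
#'
#' Monoclonal-antibody names are built as random prefix + target-class infix
#' + source-class infix + the stem "mab". Target infixes carry an optional
#' vowel (kept before consonant-initial sources, dropped before vowel-initial
#' ones); the table stores both the vowel-bearing and bare forms.
#'
#' @param path TSV file; defaults to the table shipped with the package.
#' @return object of class `mab_infix_table`: list with tibbles `sources`
#'   (`spelling`, `meaning`) and `targets` (`spelling`, `bare`, `meaning`).
#' @export
mab_infix_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mab_infixes.tsv", package = "innlint")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        comment = "#", progress = FALSE, show_col_types = FALSE)
  src <- df[df$role == "source", ]
  tgt <- df[df$role == "target", ]
  stopifnot(!anyDuplicated(src$spelling), !anyDuplicated(tgt$spelling))
  structure(list(
    sources = tibble::tibble(spelling = src$spelling, meaning = src$meaning),
    targets = tibble::tibble(spelling = tgt$spelling,
                             bare = ifelse(is.na(tgt$bare), "", tgt$bare),
                             meaning = tgt$meaning)
  ), class = "mab_infix_table")
}

#' @export
print.mab_infix_table <- function(x, ...) {
  cat(sprintf("<mab_infix_table> %d source infixes, %d target infixes\n",
              nrow(x$sources), nrow(x$targets)))
  invisible(x)
}

# names designated before the prefix+target+source+mab convention
MAB_PRE_CONVENTION <- c("muromonab")

#' Decompose a monoclonal-antibody name
#'
#' Parses `name` as prefix + target infix + source infix + "mab" using
#' longest-match at each stage: the source infix is the longest source
#' spelling ending where "mab" begins (so xizu beats zu), and the target
#' infix is the longest target form ending where the source begins, trying
#' the vowel-bearing form before the bare form. The remaining leading
#' letters (at least one) are the random prefix.
#'
#' Failures are values, not errors: a `mab_failure` names the failed stage
#' (`no-mab`, `no-source`, `no-target`, `empty-prefix`) and notes known
#' pre-convention exceptions (muromonab).
#'
#' @param name normalized lowercase alphabetic name.
#' @param table a [mab_infix_table()].
#' @return a `mab_parse` (fields `prefix`, `target`, `source`, `stem`,
#'   `target_meaning`, `source_meaning`) or a `mab_failure` (fields `name`,
#'   `stage`, `note`).
#' @examples
#' parse_mab("trastuzumab", mab_infix_table())
#' @export
parse_mab <- function(name, table) {
  stopifnot(length(name) == 1L, is.character(name))
  if (!grepl("^[a-z]+$", name)) {
    stop("`name` must be lowercase alphabetic", call. = FALSE)
  }
  note <- if (name %in% MAB_PRE_CONVENTION) {
    "pre-convention name; not formed by the prefix+target+source grammar"
  } else {
    NA_character_
  }
  fail <- function(stage) {
    structure(list(name = name, stage = stage, note = note),
              class = "mab_failure")
  }
  if (!endsWith(name, "mab")) return(fail("no-mab"))
  rest <- substr(name, 1L, nchar(name) - 3L)

  src <- table$sources$spelling
  src_hit <- src[endsWith(rest, src)]
  if (!length(src_hit)) return(fail("no-source"))
  source <- src_hit[which.max(nchar(src_hit))]
  rest2 <- substr(rest, 1L, nchar(rest) - nchar(source))

  # vowel-bearing forms first, then bare; within each, longest match
  forms <- rbind(
    data.frame(form = table$targets$spelling, idx = seq_len(nrow(table$targets)),
               vowel = TRUE, stringsAsFactors = FALSE),
    data.frame(form = table$targets$bare, idx = seq_len(nrow(table$targets)),
               vowel = FALSE, stringsAsFactors = FALSE)
  )
  forms <- forms[nzchar(forms$form), ]
  hit <- forms[endsWith(rest2, forms$form), ]
  if (!nrow(hit)) return(fail("no-target"))
  hit <- hit[order(-hit$vowel, -nchar(hit$form)), ]
  target <- hit$form[1]
  tgt_idx <- hit$idx[1]
  prefix <- substr(rest2, 1L, nchar(rest2) - nchar(target))
  if (!nzchar(prefix)) return(fail("empty-prefix"))

  structure(list(
    prefix = prefix, target = target, source = source, stem = "mab",
    target_meaning = table$targets$meaning[tgt_idx],
    source_meaning = table$sources$meaning[match(source, table$sources$spelling)]
  ), class = "mab_parse")
}

#' @export
print.mab_parse <- function(x, ...) {
  cat(sprintf("%s-%s-%s-%s  [target: %s; source: %s]\n",
              x$prefix, x$target, x$source, x$stem,
              x$target_meaning, x$source_meaning))
  invisible(x)
}

#' @export
print.mab_failure <- function(x, ...) {
  cat(sprintf("not parseable as a -mab name (%s): %s\n", x$stage, x$name))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Assemble a monoclonal-antibody name from its parts
#'
#' Inverse of [parse_mab()] whenever the chosen triple is unambiguous under
#' longest-match. Target may be given in either its vowel-bearing or bare
#' form.
#'
#' @param prefix non-empty letter string.
#' @param target a valid target infix spelling (vowel-bearing or bare form).
#' @param source a valid source infix spelling.
#' @param table a [mab_infix_table()].
#' @return the assembled name.
#' @export
assemble_mab <- function(prefix, target, source, table) {
  stopifnot(is.character(prefix), nzchar(prefix), grepl("^[a-z]+$", prefix))
  if (!target %in% c(table$targets$spelling, table$targets$bare)) {
    stop("unknown target infix: ", target, call. = FALSE)
  }
  if (!source %in% table$sources$spelling) {
    stop("unknown source infix: ", source, call. = FALSE)
  }
  paste0(prefix, target, source, "mab")
}

#' Round-trip audit of the infix cross-product
#'
#' Assembles every target x source combination with a fixed prefix and
#' re-parses each name, recording whether the parse recovers the original
#' triple. Cells that re-parse differently are genuinely ambiguous under the
#' grammar (single-letter infixes make this possible) and are returned
#' flagged, not hidden.
#'
#' @param table a [mab_infix_table()].
#' @param prefix prefix used for every cell.
#' @return tibble with columns `target`, `source`, `name`, `ok`,
#'   `parsed_target`, `parsed_source`.
#' @export
mab_roundtrip_audit <- function(table, prefix = "qq") {
  grid <- expand.grid(target = table$targets$spelling,
                      source = table$sources$spelling,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    nm <- assemble_mab(prefix, grid$target[i], grid$source[i], table)
    p <- parse_mab(nm, table)
    ok <- inherits(p, "mab_parse") && p$prefix == prefix &&
      p$target == grid$target[i] && p$source == grid$source[i]
    tibble::tibble(target = grid$target[i], source = grid$source[i], name = nm,
                   ok = ok,
                   parsed_target = if (inherits(p, "mab_parse")) p$target else NA_character_,
                   parsed_source = if (inherits(p, "mab_parse")) p$source else NA_character_)
  })
  dplyr::bind_rows(res)
}
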