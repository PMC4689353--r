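#' Construct a stem lexicon from an entry table
#'
#' A stem lexicon models the hierarchical stem/sub-stem taxonomy used in
#' pharmaceutical nomenclature: each stem has one or more spellings
#' (allomorphs such as -profen/-profene map to one `stem_id`), an affix class
#' (`prefix`, `suffix`, `infix`, or `freefix`), an optional parent (its
#' hyperonym), a pharmacological definition, and optionally position-dependent
#' senses (e.g. fos means one thing as a suffix and another as an infix or
#' prefix).
#'
#' @param entries tibble/data.frame with columns `stem_id`, `spelling`,
#'   `affix_class`, `parent` (NA for root stems), `definition`; optional
#'   logical `requires_parent` (a sub-stem matched only in names where its
#'   hyperonym also matches directly — used for the single-letter monoclonal
#'   antibody infixes, which are meaningless outside -mab names).
#' @param senses optional tibble with columns `stem_id`, `position`
#'   (`prefix`/`suffix`/`infix`), `sense`.
#' @return object of class `stem_lexicon`: list with elements `entries`
#'   (with a computed `depth` column), `senses`, `lint`.
#' @export
stem_lexicon <- function(entries, senses = NULL) {
  entries <- tibble::as_tibble(entries)
  req <- c("stem_id", "spelling", "affix_class", "parent", "definition")
  missing_cols <- setdiff(req, names(entries))
  if (length(missing_cols)) {
    stop("lexicon is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"requires_parent" %in% names(entries)) entries$requires_parent <- FALSE
  entries$requires_parent[is.na(entries$requires_parent)] <- FALSE
  entries$parent[entries$parent %in% c("", "NA")] <- NA_character_

  if (!all(entries$affix_class %in% c("prefix", "suffix", "infix", "freefix"))) {
    stop("affix_class must be prefix/suffix/infix/freefix", call. = FALSE)
  }
  if (!all(grepl("^[a-z]+$", entries$spelling))) {
    stop("every spelling must be non-empty lowercase alphabetic", call. = FALSE)
  }
  key <- paste(entries$stem_id, entries$spelling, entries$affix_class)
  if (anyDuplicated(key)) {
    stop("duplicate stem entry: ", key[duplicated(key)][1], call. = FALSE)
  }
  # one parent per stem_id
  par_map <- unique(entries[, c("stem_id", "parent")])
  if (anyDuplicated(par_map$stem_id)) {
    stop("stem_id with conflicting parents: ",
         par_map$stem_id[duplicated(par_map$stem_id)][1], call. = FALSE)
  }
  parent_of <- stats::setNames(par_map$parent, par_map$stem_id)
  unknown <- setdiff(stats::na.omit(par_map$parent), par_map$stem_id)
  if (length(unknown)) {
    stop("unknown parent stem_id: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  depth_of <- function(id) {
    d <- 0L
    seen <- character()
    while (!is.na(parent_of[[id]])) {
      if (id %in% seen) stop("cycle in parent links at stem ", id, call. = FALSE)
      seen <- c(seen, id)
      id <- parent_of[[id]]
      d <- d + 1L
      if (d > length(parent_of)) stop("cycle in parent links", call. = FALSE)
    }
    d
  }
  depths <- vapply(par_map$stem_id, depth_of, integer(1))
  entries$depth <- unname(depths[match(entries$stem_id, par_map$stem_id)])

  if (is.null(senses)) {
    senses <- tibble::tibble(stem_id = character(), position = character(),
                             sense = character())
  }
  senses <- tibble::as_tibble(senses)

  lex <- structure(list(entries = entries, senses = senses), class = "stem_lexicon")
  lex$lint <- lint_lexicon(lex)
  lex
}

#' @export
print.stem_lexicon <- function(x, ...) {
  cat(sprintf("<stem_lexicon> %d stems, %d spellings, %d root taxa; %d lint flag(s)\n",
              length(unique(x$entries$stem_id)), nrow(x$entries),
              sum(is.na(x$entries$parent[!duplicated(x$entries$stem_id)])),
              nrow(x$lint)))
  invisible(x)
}

stem_ids <- function(lex) unique(lex$entries$stem_id)

stem_parent <- function(lex, id) {
  p <- lex$entries$parent[match(id, lex$entries$stem_id)]
  if (is.na(p)) NULL else p
}

# ancestor chain (excluding the stem itself), nearest first
stem_ancestors <- function(lex, id) {
  out <- character()
  repeat {
    p <- stem_parent(lex, id)
    if (is.null(p)) break
    out <- c(out, p)
    id <- p
  }
  out
}

stem_root <- function(lex, id) {
  anc <- stem_ancestors(lex, id)
  if (length(anc)) anc[length(anc)] else id
}

#' Lint a stem lexicon for confusability hazards
#'
#' Flags (without rejecting):
#' * `single_letter_distinction` — spellings from unrelated taxa one edit
#'   apart (e.g. -fenin vs -fenine, -micin vs -mycin);
#' * `containment` — a suffix-classed sub-stem whose spelling does not end
#'   with its hyperonym's spelling (e.g. -viroc under the freefix vir), so the
#'   hyperonym cannot be read off the end of the name.
#'
#' @param lex a `stem_lexicon`.
#' @return tibble with columns `type`, `stem_a`, `stem_b`, `detail`.
#' @export
lint_lexicon <- function(lex) {
  e <- lex$entries
  flags <- list()
  # cross-taxon near-identical spellings
  n <- nrow(e)
  if (n > 1) {
    roots <- vapply(e$stem_id, function(id) stem_root(lex, id), character(1))
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (e$stem_id[i] == e$stem_id[j]) next
        if (roots[i] == roots[j]) next
        if (abs(nchar(e$spelling[i]) - nchar(e$spelling[j])) > 1) next
        if (levenshtein(e$spelling[i], e$spelling[j]) == 1) {
          flags[[length(flags) + 1]] <- tibble::tibble(
            type = "single_letter_distinction",
            stem_a = e$stem_id[i], stem_b = e$stem_id[j],
            detail = sprintf("'%s' vs '%s'", e$spelling[i], e$spelling[j]))
        }
      }
    }
  }
  # suffix sub-stem not ending in its hyperonym's spelling
  for (i in seq_len(n)) {
    p <- stem_parent(lex, e$stem_id[i])
    if (is.null(p) || e$affix_class[i] != "suffix") next
    psp <- e$spelling[e$stem_id == p]
    if (!any(endsWith(e$spelling[i], psp))) {
      flags[[length(flags) + 1]] <- tibble::tibble(
        type = "containment", stem_a = e$stem_id[i], stem_b = p,
        detail = sprintf("'%s' does not end with any spelling of hyperonym '%s'",
                         e$spelling[i], p))
    }
  }
  if (!length(flags)) {
    return(tibble::tibble(type = character(), stem_a = character(),
                          stem_b = character(), detail = character()))
  }
  dplyr::bind_rows(flags)
}

#' Load a stem lexicon from a TSV file
#'
#' Columns: `stem_id`, `spelling`, `affix_class`, `parent`, `definition`,
#' `position_sense_key`, `position_sense_text`, and optionally
#' `requires_parent`. Spellings are stored without hyphens. Lines starting
#' with `#` are comments.
#'
#' @param path file path.
#' @return a `stem_lexicon`.
#' @export
load_lexicon <- function(path) {
  stopifnot(file.exists(path))
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        comment = "#", progress = FALSE, show_col_types = FALSE)
  if ("requires_parent" %in% names(df)) {
    df$requires_parent <- toupper(df$requires_parent) %in% c("TRUE", "T", "1", "YES")
  }
  has_sense <- !is.na(df$position_sense_key) & df$position_sense_key != ""
  senses <- tibble::tibble(
    stem_id = df$stem_id[has_sense],
    position = df$position_sense_key[has_sense],
    sense = df$position_sense_text[has_sense]
  )
  entries <- unique(df[, intersect(
    c("stem_id", "spelling", "affix_class", "parent", "definition", "requires_parent"),
    names(df))])
  stem_lexicon(entries, senses)
}

#' Write a stem lexicon to TSV
#'
#' Inverse of [load_lexicon()]: `load_lexicon(write_lexicon(lex, f))` yields
#' an identical lexicon.
#'
#' @param lex a `stem_lexicon`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  e <- lex$entries
  out <- tibble::tibble(
    stem_id = e$stem_id, spelling = e$spelling, affix_class = e$affix_class,
    parent = e$parent, definition = e$definition,
    requires_parent = e$requires_parent,
    position_sense_key = NA_character_, position_sense_text = NA_character_
  )
  if (nrow(lex$senses)) {
    # sense rows repeat the stem's first entry columns; load_lexicon collapses
    # the duplicated entry columns back with unique()
    first <- out[!duplicated(out$stem_id), ]
    idx <- match(lex$senses$stem_id, first$stem_id)
    extra <- first[idx, ]
    extra$position_sense_key <- lex$senses$position
    extra$position_sense_text <- lex$senses$sense
    out <- dplyr::bind_rows(out, extra)
  }
  readr::write_tsv(out, path, na = "")
  invisible(path)
}

#' Locate stem occurrences in a name
#'
#' Finds every lexicon spelling in `name` subject to its affix class: a
#' suffix must end the name, a prefix must start it, an infix must be
#' strictly interior, and a freefix may sit anywhere. Spans are 0-based
#' half-open.
#'
#' When a sub-stem matches, its hyperonym chain is also reported as
#' *implied* matches (`implied = TRUE`, no span) even when the hyperonym's
#' spelling does not occur in the name — maraviroc implies the antiviral
#' freefix vir although no terminal "vir" is present. Matches whose span is
#' strictly contained in a longer match from an unrelated taxon ending at the
#' same boundary are reported with `shadowed = TRUE` (e.g. -tide inside
#' -actide); overlapping matches from unrelated taxa are both flagged
#' `ambiguous = TRUE` (e.g. -dipine and -pine in riodipine).
#'
#' @param name a single normalized lowercase alphabetic name.
#' @param lex a `stem_lexicon`.
#' @return tibble ordered most-specific first (depth, then spelling length,
#'   then stem_id): columns `stem_id`, `spelling`, `start`, `end`,
#'   `position`, `depth`, `implied`, `shadowed`, `ambiguous`.
#' @export
match_stems <- function(name, lex) {
  stopifnot(length(name) == 1L, is.character(name))
  if (!grepl("^[a-z]+$", name)) {
    stop("`name` must be non-empty lowercase alphabetic", call. = FALSE)
  }
  e <- lex$entries
  n <- nchar(name)
  rows <- list()
  for (i in seq_len(nrow(e))) {
    sp <- e$spelling[i]
    ls <- nchar(sp)
    if (ls > n) next
    starts <- all_occurrences(name, sp)  # 0-based
    if (!length(starts)) next
    cls <- e$affix_class[i]
    keep <- switch(cls,
      prefix = starts == 0L,
      suffix = starts + ls == n,
      infix = starts > 0L & starts + ls < n,
      freefix = rep(TRUE, length(starts))
    )
    starts <- starts[keep]
    for (s in starts) {
      rows[[length(rows) + 1]] <- list(
        stem_id = e$stem_id[i], spelling = sp, start = s, end = s + ls,
        depth = e$depth[i], requires_parent = e$requires_parent[i])
    }
  }
  if (!length(rows)) return(empty_match())
  m <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))

  # drop gated sub-stems whose hyperonym has no direct match here
  if (any(m$requires_parent)) {
    direct_ids <- unique(m$stem_id[!m$requires_parent])
    ok <- !m$requires_parent |
      vapply(m$stem_id, function(id) {
        p <- stem_parent(lex, id)
        !is.null(p) && p %in% direct_ids
      }, logical(1))
    m <- m[ok, , drop = FALSE]
    if (!nrow(m)) return(empty_match())
  }

  # same stem, nested spans (allomorphs like tiptiline/iptiline): keep longest
  drop <- rep(FALSE, nrow(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i == j || m$stem_id[i] != m$stem_id[j]) next
      if (m$start[j] <= m$start[i] && m$end[i] <= m$end[j] &&
          (m$end[j] - m$start[j]) > (m$end[i] - m$start[i])) drop[i] <- TRUE
    }
  }
  m <- m[!drop, , drop = FALSE]

  m$position <- mapply(function(s, e2) {
    if (s == 0L && e2 == n) "suffix" else if (e2 == n) "suffix"
    else if (s == 0L) "prefix" else "infix"
  }, m$start, m$end)
  # a whole-name prefix-classed match reads as a prefix
  whole <- m$start == 0L & m$end == n
  if (any(whole)) {
    cls <- e$affix_class[match(paste(m$stem_id, m$spelling),
                               paste(e$stem_id, e$spelling))]
    m$position[whole & cls == "prefix"] <- "prefix"
  }

  roots <- vapply(m$stem_id, function(id) stem_root(lex, id), character(1))
  nr <- nrow(m)
  m$shadowed <- FALSE
  m$ambiguous <- FALSE
  for (i in seq_len(nr)) {
    for (j in seq_len(nr)) {
      if (i == j || roots[i] == roots[j]) next
      overlap <- m$start[i] < m$end[j] && m$start[j] < m$end[i]
      if (overlap) {
        m$ambiguous[i] <- TRUE
        contained <- m$start[j] <= m$start[i] && m$end[i] <= m$end[j] &&
          (m$end[j] - m$start[j]) > (m$end[i] - m$start[i])
        if (contained) m$shadowed[i] <- TRUE
      }
    }
  }
  m$implied <- FALSE

  # implied hyperonyms for every direct match
  direct_ids <- unique(m$stem_id)
  implied_ids <- setdiff(unique(unlist(lapply(direct_ids, function(id)
    stem_ancestors(lex, id)))), direct_ids)
  if (length(implied_ids)) {
    imp <- tibble::tibble(
      stem_id = implied_ids, spelling = NA_character_,
      start = NA_integer_, end = NA_integer_,
      depth = e$depth[match(implied_ids, e$stem_id)],
      requires_parent = FALSE,
      position = NA_character_, shadowed = FALSE, ambiguous = FALSE,
      implied = TRUE)
    m <- dplyr::bind_rows(m, imp)
  }
  m$requires_parent <- NULL
  m <- m[order(-m$depth, -ifelse(is.na(m$spelling), 0L, nchar(m$spelling)),
               m$stem_id), ]
  m$start <- as.integer(m$start)
  m$end <- as.integer(m$end)
  tibble::as_tibble(m)
}

empty_match <- function() {
  tibble::tibble(stem_id = character(), spelling = character(),
                 start = integer(), end = integer(), position = character(),
                 depth = integer(), implied = logical(), shadowed = logical(),
                 ambiguous = logical())
}

# 0-based start offsets of all (possibly overlapping) occurrences
all_occurrences <- function(name, sp) {
  out <- integer()
  from <- 1L
  repeat {
    hit <- regexpr(sp, substr(name, from, nchar(name)), fixed = TRUE)
    if (hit == -1L) break
    s <- from + as.integer(hit) - 1L
    out <- c(out, s - 1L)
    from <- s + 1L
  }
  out
}

#' Resolve the position-dependent sense of a stem match
#'
#' Some stems change meaning with their affix position: fos as a suffix is
#' the hyperonym (insecticides/anthelminthics/pesticides, phosphorus
#' derivatives) but as an infix or prefix the sub-stem sense applies. Stems
#' without position senses return their default definition regardless of
#' position (e.g. grel, vir).
#'
#' @param m one row of a [match_stems()] result (or a list with `stem_id`
#'   and `position`).
#' @param lex a `stem_lexicon`.
#' @return the definition text for that stem at that position.
#' @export
resolve_position_sense <- function(m, lex) {
  id <- m$stem_id[1]
  pos <- m$position[1]
  s <- lex$senses
  hit <- which(s$stem_id == id & s$position == pos)
  if (length(hit)) return(s$sense[hit[1]])
  lex$entries$definition[match(id, lex$entries$stem_id)]
}

#' Check whether a name carries its expected stem
#'
#' A name is `compliant` when [match_stems()] finds a *direct* (not merely
#' implied) match of the expected stem; `noncompliant` otherwise. When no
#' expectation is recorded (`NA`), the verdict is `unlisted`. Matches from
#' other taxa overlapping the expected stem are returned as ambiguity notes
#' (riodipine carries -dipine but could be misread under -pine).
#'
#' @param name normalized single-word name.
#' @param expected_stem_id the stem the name is listed under, or NA.
#' @param lex a `stem_lexicon`.
#' @return list of class `compliance_verdict`: `name`, `expected_stem_id`,
#'   `verdict`, `matches` (the full match table), `ambiguous_alternatives`
#'   (stem_ids of unrelated overlapping matches).
#' @export
classify_compliance <- function(name, expected_stem_id, lex) {
  if (!is.na(expected_stem_id) && !expected_stem_id %in% stem_ids(lex)) {
    stop("unknown stem_id: ", expected_stem_id, call. = FALSE)
  }
  m <- match_stems(name, lex)
  if (is.na(expected_stem_id)) {
    verdict <- "unlisted"
    alts <- character()
  } else {
    direct <- m$stem_id[!m$implied]
    verdict <- if (expected_stem_id %in% direct) "compliant" else "noncompliant"
    exp_rows <- which(!m$implied & m$stem_id == expected_stem_id)
    alts <- character()
    if (length(exp_rows)) {
      root_exp <- stem_root(lex, expected_stem_id)
      for (i in seq_len(nrow(m))) {
        if (m$implied[i] || m$stem_id[i] == expected_stem_id) next
        if (stem_root(lex, m$stem_id[i]) == root_exp) next
        overlaps <- any(m$start[i] < m$end[exp_rows] & m$start[exp_rows] < m$end[i])
        if (isTRUE(overlaps)) alts <- c(alts, m$stem_id[i])
      }
    }
  }
  structure(list(name = name, expected_stem_id = expected_stem_id,
                 verdict = verdict, matches = m,
                 ambiguous_alternatives = unique(alts)),
            class = "compliance_verdict")
}

#' @export
print.compliance_verdict <- function(x, ...) {
  cat(sprintf("%s [expected %s]: %s\n", x$name,
              x$expected_stem_id %||% "—", x$verdict))
  if (length(x$ambiguous_alternatives)) {
    cat("  could be misread under:", paste(x$ambiguous_alternatives, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Stembook-noncompliance rate over a sample
#'
#' Fraction of names whose verdict is `noncompliant` or `unlisted` — the
#' names that are missing from the reference listing or do not carry their
#' preferred stem.
#'
#' @param sample data.frame/tibble with columns `name` and
#'   `expected_stem_id` (NA = not listed).
#' @param lex a `stem_lexicon`.
#' @return list: `rate` (proportion in \[0,1\]), `verdicts` (tibble of
#'   per-name verdicts).
#' @export
compliance_rate <- function(sample, lex) {
  sample <- tibble::as_tibble(sample)
  if (!nrow(sample)) stop("empty sample: no compliance rate", call. = FALSE)
  verdicts <- vapply(seq_len(nrow(sample)), function(i) {
    classify_compliance(sample$name[i], sample$expected_stem_id[i], lex)$verdict
  }, character(1))
  out <- tibble::tibble(name = sample$name,
                        expected_stem_id = sample$expected_stem_id,
                        verdict = verdicts)
  list(rate = mean(verdicts != "compliant"), verdicts = out)
}

# stem node set used for stem-sharing: all non-shadowed direct matches plus
# their ancestor chains (shadowed matches like -tide inside -actide do not
# contribute a shared node)
stem_node_set <- function(name, lex) {
  m <- match_stems(name, lex)
  m <- m[!m$implied & !m$shadowed, , drop = FALSE]
  if (!nrow(m)) return(character())
  unique(unlist(lapply(unique(m$stem_id), function(id) c(id, stem_ancestors(lex, id)))))
}
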