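# filler alphabet: consonant/vowel alternation over the letters that cannot
# form a prohibited graph or digraph (no h, k, y, w), so prohibited patterns
# occur in generated names only where injected or inside an embedded stem
SYN_CONSONANTS <- c("b", "c", "d", "f", "g", "j", "l", "m", "n", "p",
                    "q", "r", "s", "t", "v", "x", "z")
SYN_VOWELS <- c("a", "e", "i", "o", "u")

#' Specification for a synthetic name corpus
#'
#' Defaults emulate the empirical shape of the single-word nomenclature:
#' unimodal name lengths with mean 10.5 and SD 1.7 characters, clipped to
#' [4, 25] after rounding.
#'
#' @param n_names number of names to generate.
#' @param length_mean,length_sd name-length distribution in characters.
#' @param stem_prevalence named numeric: stem_id -> proportion of names
#'   assigned that stem (proportions must sum to at most 1).
#' @param noncompliance_rate proportion of stem-assigned names generated
#'   *without* their assigned stem (they keep the assignment on record, like
#'   a name listed under a stem it does not carry).
#' @param digraph_injection named numeric: prohibited pattern -> per-name
#'   injection probability. May instead be a list keyed by decade
#'   (`"1950"` etc.), each element a named numeric, for decade-varying rates.
#' @param decade_weights named numeric: decade -> sampling proportion
#'   (default: all names in the 2000s).
#' @param seed integer seed; generation is fully reproducible.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_names, length_mean = 10.5, length_sd = 1.7,
                           stem_prevalence = numeric(),
                           noncompliance_rate = 0,
                           digraph_injection = numeric(),
                           decade_weights = c("2000" = 1),
                           seed = 1L) {
  stopifnot(n_names >= 0, length_sd >= 0,
            noncompliance_rate >= 0, noncompliance_rate <= 1)
  if (length(stem_prevalence)) {
    stopifnot(!is.null(names(stem_prevalence)),
              all(stem_prevalence >= 0), all(stem_prevalence <= 1))
    if (sum(stem_prevalence) > 1 + 1e-9) {
      stop("stem prevalences must sum to at most 1", call. = FALSE)
    }
  }
  inj_check <- if (is.list(digraph_injection)) digraph_injection else list(digraph_injection)
  for (m in inj_check) {
    if (length(m)) {
      stopifnot(all(names(m) %in% c(PROHIBITED_DIGRAPHS, PROHIBITED_GRAPHS)),
                all(m >= 0), all(m <= 1))
    }
  }
  stopifnot(all(decade_weights >= 0), sum(decade_weights) > 0)
  structure(list(
    n_names = as.integer(n_names), length_mean = length_mean,
    length_sd = length_sd, stem_prevalence = stem_prevalence,
    noncompliance_rate = noncompliance_rate,
    digraph_injection = digraph_injection,
    decade_weights = decade_weights, seed = as.integer(seed)
  ), class = "synthetic_spec")
}

syn_filler <- function(len) {
  if (len == 0L) return("")
  start_c <- sample(c(TRUE, FALSE), 1L)
  chars <- character(len)
  for (i in seq_len(len)) {
    cons <- xor(start_c, i %% 2 == 0)
    chars[i] <- if (cons) sample(SYN_CONSONANTS, 1L) else sample(SYN_VOWELS, 1L)
  }
  paste(chars, collapse = "")
}

# positions (0-based insertion points / span starts) legal for an affix class
syn_place_stem <- function(len_total, len_stem, affix_class) {
  switch(affix_class,
    prefix = 0L,
    suffix = len_total - len_stem,
    infix = sample(seq_len(len_total - len_stem - 1L), 1L),
    freefix = sample(0:(len_total - len_stem), 1L)
  )
}

#' Generate a synthetic name corpus with recorded ground truth
#'
#' Names are lowercase alphabetic, built from a consonant/vowel-alternating
#' filler (over an alphabet that cannot form prohibited patterns) with stems
#' embedded verbatim at positions legal for their affix class, prohibited
#' patterns injected at recorded offsets, and years drawn per decade weight.
#' Noncompliant names record their assigned stem but are guaranteed not to
#' carry it at a legal position.
#'
#' @param spec a [synthetic_spec()].
#' @param lexicon a `stem_lexicon` providing spellings and affix classes for
#'   the stems named in `spec$stem_prevalence`; defaults to the shipped
#'   lexicon.
#' @return list with `corpus` (an `inn_corpus`) and `truth` (list of
#'   tibbles: `names` with per-name `stem_id`/`compliant`/`year`/`decade`,
#'   and `hits` with per-injection `name`/`pattern`/`start`).
#' @export
generate_corpus <- function(spec, lexicon = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(lexicon)) lexicon <- inn_lexicon()
  stems <- names(spec$stem_prevalence)
  unknown <- setdiff(stems, stem_ids(lexicon))
  if (length(unknown)) {
    stop("stem(s) not in lexicon: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  stem_info <- lapply(stems, function(id) {
    rows <- lexicon$entries[lexicon$entries$stem_id == id, ]
    sp <- rows$spelling[which.max(nchar(rows$spelling))]  # canonical allomorph
    cls <- rows$affix_class[which.max(nchar(rows$spelling))]
    need <- nchar(sp) + if (cls == "infix") 2L else 0L
    if (need > 25L) {
      stop(sprintf("stem '%s' cannot fit a name of at most 25 characters", id),
           call. = FALSE)
    }
    list(id = id, spelling = sp, affix_class = cls,
         all_spellings = unique(rows$spelling), min_len = max(4L, need))
  })
  names(stem_info) <- stems

  withr::with_seed(spec$seed, {
    decades <- as.integer(names(spec$decade_weights))
    res_names <- character(spec$n_names)
    res_year <- integer(spec$n_names)
    res_stem <- character(spec$n_names)
    res_comp <- logical(spec$n_names)
    hit_rows <- list()
    seen <- new.env(parent = emptyenv())

    for (i in seq_len(spec$n_names)) {
      decade <- if (length(decades) == 1L) decades else
        sample(decades, 1L, prob = spec$decade_weights)
      year <- decade + sample(0:9, 1L)
      assigned <- NA_character_
      if (length(stems)) {
        u <- stats::runif(1)
        cum <- cumsum(spec$stem_prevalence)
        k <- which(u <= cum)
        if (length(k)) assigned <- stems[k[1]]
      }
      compliant <- !is.na(assigned) && stats::runif(1) >= spec$noncompliance_rate

      inj <- spec$digraph_injection
      if (is.list(inj)) inj <- inj[[as.character(decade)]] %||% numeric()
      # decide this name's injections up front so their length is part of
      # the drawn name length, not added on top of it
      todo <- names(inj)[stats::runif(length(inj)) < unlist(inj)]
      inj_len <- sum(nchar(todo))

      made <- NULL
      for (try in 1:100) {
        len <- as.integer(round(stats::rnorm(1, spec$length_mean, spec$length_sd)))
        len <- max(4L, min(25L, len)) - inj_len
        spans <- list()
        stem_class <- NULL
        if (!is.na(assigned) && compliant) {
          info <- stem_info[[assigned]]
          len <- max(len, info$min_len)
          ls <- nchar(info$spelling)
          pos <- syn_place_stem(len, ls, info$affix_class)
          nm <- paste0(syn_filler(pos), info$spelling, syn_filler(len - pos - ls))
          spans <- list(c(pos, pos + ls))
          stem_class <- info$affix_class
        } else {
          nm <- syn_filler(max(4L, len))
          if (!is.na(assigned)) {
            # noncompliant: must not accidentally carry the assigned stem
            if (syn_carries_stem(nm, stem_info[[assigned]])) next
          }
        }
        # boundary repair: a stem ending/starting with a vowel can abut a
        # filler vowel and create an accidental ae/oe
        nm <- syn_fix_vowel_digraphs(nm, spans)
        hits <- list()
        for (p in todo) {
          ins <- syn_inject(nm, p, spans, stem_class)
          if (is.null(ins)) next
          nm <- ins$name
          spans <- ins$spans
          hits <- lapply(hits, function(h)
            if (h$start >= ins$at) { h$start <- h$start + nchar(p); h } else h)
          hits[[length(hits) + 1]] <- list(pattern = p, start = ins$at)
        }
        if (!exists(nm, envir = seen, inherits = FALSE)) {
          made <- list(name = nm, hits = hits)
          break
        }
      }
      if (is.null(made)) {
        stop("could not generate a collision-free name after 100 tries", call. = FALSE)
      }
      seen[[made$name]] <- TRUE
      res_names[i] <- made$name
      res_year[i] <- year
      res_stem[i] <- assigned
      res_comp[i] <- compliant
      for (h in made$hits) {
        hit_rows[[length(hit_rows) + 1]] <-
          tibble::tibble(name = made$name, pattern = h$pattern, start = h$start)
      }
    }

    corpus <- inn_corpus(res_names, year = res_year,
                         provenance = sprintf("synthetic (seed %d)", spec$seed))
    truth <- list(
      names = tibble::tibble(name = res_names, year = res_year,
                             decade = (res_year %/% 10L) * 10L,
                             stem_id = res_stem, compliant = res_comp),
      hits = if (length(hit_rows)) dplyr::bind_rows(hit_rows) else
        tibble::tibble(name = character(), pattern = character(), start = integer())
    )
    list(corpus = corpus, truth = truth)
  })
}

# does `nm` carry the stem at a position legal for its affix class?
syn_carries_stem <- function(nm, info) {
  n <- nchar(nm)
  for (sp in info$all_spellings) {
    occ <- all_occurrences(nm, sp)
    if (!length(occ)) next
    ls <- nchar(sp)
    ok <- switch(info$affix_class,
      prefix = any(occ == 0L),
      suffix = any(occ + ls == n),
      infix = any(occ > 0L & occ + ls < n),
      freefix = TRUE)
    if (ok) return(TRUE)
  }
  FALSE
}

# replace the filler half of any accidental ae/oe that falls outside the
# protected spans
syn_fix_vowel_digraphs <- function(nm, spans) {
  inside <- function(pos) {
    any(vapply(spans, function(s) pos >= s[1] && pos < s[2], logical(1)))
  }
  repeat {
    hit <- regexpr("ae|oe", nm)
    if (hit == -1L) break
    p0 <- as.integer(hit) - 1L  # 0-based offset of the a/o
    if (length(spans) && inside(p0) && inside(p0 + 1L)) break  # stem-internal, leave
    if (!length(spans) || !inside(p0 + 1L)) {
      substr(nm, p0 + 2L, p0 + 2L) <- "i"   # the e is filler
    } else {
      substr(nm, p0 + 1L, p0 + 1L) <- "u"   # the a/o is filler
    }
  }
  nm
}

# insert pattern `p` at a position outside existing span interiors; a bare
# "h" is never placed directly after t/p (it would merge into th/ph), and an
# embedded stem keeps its affix-legal position (nothing is appended after a
# suffix stem or prepended before a prefix stem)
syn_inject <- function(nm, p, spans, stem_class = NULL) {
  n <- nchar(nm)
  cand <- 0:n
  interior <- unlist(lapply(spans, function(s)
    if (s[2] - s[1] > 1) seq(s[1] + 1L, s[2] - 1L) else integer()))
  cand <- setdiff(cand, interior)
  if (!is.null(stem_class) && length(spans)) {
    if (stem_class == "suffix") cand <- setdiff(cand, n)
    if (stem_class == "prefix") cand <- setdiff(cand, 0L)
  }
  if (p == "h") {
    prevch <- ifelse(cand == 0L, "", substring(nm, cand, cand))
    cand <- cand[!prevch %in% c("t", "p")]
  }
  if (!length(cand)) return(NULL)
  at <- if (length(cand) == 1L) cand else sample(cand, 1L)
  new_nm <- paste0(substr(nm, 1, at), p, substr(nm, at + 1, n))
  lp <- nchar(p)
  spans <- lapply(spans, function(s) if (s[1] >= at) s + lp else s)
  spans[[length(spans) + 1]] <- c(at, at + lp)
  list(name = new_nm, at = at, spans = spans)
}

#' Plant near-miss name pairs at a controlled edit count
#'
#' For each pair, picks a base name from the corpus, applies `k_edits`
#' random single-character edits (insertion, deletion, substitution over the
#' generator alphabet), and appends the variant. Variants colliding with an
#' existing name, or whose true edit distance to the base is zero, are
#' resampled (bounded at 100 retries). The recorded `true_led` is recomputed
#' with [levenshtein()] and may be smaller than `planted_k` when edits
#' partially cancel.
#'
#' @param corpus a non-empty `inn_corpus`.
#' @param k_edits number of random edits per variant (>= 1).
#' @param n_pairs number of pairs to plant.
#' @param seed integer seed.
#' @return list with `corpus` (augmented) and `pairs` (tibble `base`,
#'   `variant`, `planted_k`, `true_led`).
#' @export
plant_near_miss_pairs <- function(corpus, k_edits, n_pairs, seed) {
  stopifnot(k_edits >= 1, nrow(corpus) > 0)
  alphabet <- c(SYN_CONSONANTS, SYN_VOWELS)
  withr::with_seed(as.integer(seed), {
    existing <- new.env(parent = emptyenv())
    for (nm in corpus$norm_name) existing[[nm]] <- TRUE
    base_v <- character(n_pairs); var_v <- character(n_pairs)
    led_v <- integer(n_pairs); year_v <- integer(n_pairs)
    for (i in seq_len(n_pairs)) {
      done <- FALSE
      for (try in 1:100) {
        b <- sample.int(nrow(corpus), 1L)
        base <- corpus$norm_name[b]
        v <- base
        for (e in seq_len(k_edits)) v <- syn_random_edit(v, alphabet)
        if (!nzchar(v) || exists(v, envir = existing, inherits = FALSE)) next
        d <- levenshtein(base, v)
        if (d < 1L) next
        base_v[i] <- base; var_v[i] <- v
        led_v[i] <- d; year_v[i] <- corpus$year[b]
        existing[[v]] <- TRUE
        done <- TRUE
        break
      }
      if (!done) {
        stop("could not plant a collision-free near-miss pair after 100 tries",
             call. = FALSE)
      }
    }
    aug <- inn_corpus(c(corpus$raw_name, var_v), year = c(corpus$year, year_v),
                      provenance = paste0(attr(corpus, "provenance") %||% "?",
                                          " + planted near misses"))
    list(corpus = aug,
         pairs = tibble::tibble(base = base_v, variant = var_v,
                                planted_k = k_edits, true_led = led_v))
  })
}

#' Shipped lexicon augmented with common non-stem endings
#'
#' Real nomenclatures contain frequent terminal letter sequences (-ine,
#' -one, -ide) that are not recommended stems yet make unrelated names look
#' alike. This lexicon adds such endings as pseudo-stems so the generator
#' can plant look-alike families *without* a pharmacological relationship;
#' analysing the result against the plain shipped lexicon then reproduces
#' the characteristic pattern that close pairs are mostly stem-related while
#' distant pairs increasingly share mere letters.
#'
#' @return a `stem_lexicon` for use with [generate_corpus()].
#' @export
lexicon_with_common_endings <- function() {
  e <- inn_lexicon()$entries
  extra <- tibble::tibble(
    stem_id = c("end_ine", "end_one", "end_ide"),
    spelling = c("ine", "one", "ide"),
    affix_class = "suffix", parent = NA_character_,
    definition = "common ending (not a recommended stem)",
    requires_parent = FALSE)
  stem_lexicon(dplyr::bind_rows(e[, names(extra)], extra))
}

syn_random_edit <- function(x, alphabet) {
  n <- nchar(x)
  op <- sample(c("ins", "del", "sub"), 1L)
  if (op == "del" && n <= 1L) op <- "ins"
  if (op == "ins") {
    at <- sample(0:n, 1L)
    paste0(substr(x, 1, at), sample(alphabet, 1L), substr(x, at + 1, n))
  } else if (op == "del") {
    at <- sample(seq_len(n), 1L)
    paste0(substr(x, 1, at - 1L), substr(x, at + 1L, n))
  } else {
    at <- sample(seq_len(n), 1L)
    ch <- sample(alphabet, 1L)
    paste0(substr(x, 1, at - 1L), ch, substr(x, at + 1L, n))
  }
}
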