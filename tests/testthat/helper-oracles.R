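# Independent brute-force oracles used to validate the optimized
# implementations. These deliberately avoid the package's internal code
# paths: the edit-distance oracle is a memo-free recursion, the scanner and
# matcher oracles are plain nested loops.

# exponential, memo-free edit distance by first-character recursion
oracle_led <- function(a, b) {
  if (nchar(a) == 0L) return(nchar(b))
  if (nchar(b) == 0L) return(nchar(a))
  cost <- as.integer(substr(a, 1, 1) != substr(b, 1, 1))
  ta <- substr(a, 2, nchar(a))
  tb <- substr(b, 2, nchar(b))
  min(oracle_led(ta, b) + 1L,
      oracle_led(a, tb) + 1L,
      oracle_led(ta, tb) + cost)
}

# all strings of length 0..max_len over `alphabet`
all_strings <- function(alphabet, max_len) {
  out <- ""
  level <- ""
  for (l in seq_len(max_len)) {
    level <- as.vector(outer(level, alphabet, paste0))
    out <- c(out, level)
  }
  out
}

# left-to-right greedy scan, digraphs before single graphs, no overlap
oracle_scan <- function(name) {
  digraphs <- c("ph", "th", "ae", "oe")
  singles <- c("y", "h", "k")
  pats <- character(); starts <- integer()
  i <- 1L
  n <- nchar(name)
  while (i <= n) {
    matched <- FALSE
    for (d in digraphs) {
      if (i < n && substr(name, i, i + 1L) == d) {
        pats <- c(pats, d); starts <- c(starts, i - 1L)
        i <- i + 2L; matched <- TRUE
        break
      }
    }
    if (!matched) {
      ch <- substr(name, i, i)
      if (ch %in% singles) { pats <- c(pats, ch); starts <- c(starts, i - 1L) }
      i <- i + 1L
    }
  }
  data.frame(pattern = pats, start = starts, stringsAsFactors = FALSE)
}

# try every spelling at every offset, filter by affix rule, gate
# parent-requiring sub-stems, drop same-stem spans nested in a longer one;
# returns the set of direct matches as "stem_id:start:end" keys
oracle_match_keys <- function(name, lex) {
  e <- lex$entries
  n <- nchar(name)
  rows <- list()
  for (r in seq_len(nrow(e))) {
    sp <- e$spelling[r]
    ls <- nchar(sp)
    if (ls > n) next
    for (s in 0:(n - ls)) {
      if (substr(name, s + 1L, s + ls) != sp) next
      ok <- switch(e$affix_class[r],
        prefix = s == 0L,
        suffix = s + ls == n,
        infix = s > 0L && s + ls < n,
        freefix = TRUE)
      if (ok)

        rows[[length(rows) + 1]] <- data.frame(
          stem_id = e$stem_id[r], start = s, end = s + ls,
          requires_parent = e$requires_parent[r],
          parent = ifelse(is.na(e$parent[r]), "", e$parent[r]),
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(character())
  m <- unique(do.call(rbind, rows))
  direct <- unique(m$stem_id[!m$requires_parent])
  m <- m[!m$requires_parent | m$parent %in% direct, , drop = FALSE]
  keep <- rep(TRUE, nrow(m))
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(nrow(m))) {
      if (i == j || m$stem_id[i] != m$stem_id[j]) next
      if (m$start[j] <= m$start[i] && m$end[i] <= m$end[j] &&
          (m$end[j] - m$start[j]) > (m$end[i] - m$start[i])) keep[i] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]
  sort(paste(m$stem_id, m$start, m$end, sep = ":"))
}

# random lowercase strings biased toward the letters that occur in
# prohibited patterns so the scanner oracle gets exercised hard
random_scan_strings <- function(n, max_len = 15, seed = 42) {
  withr::with_seed(seed, {
    alphabet <- c(letters, rep(c("p", "t", "h", "a", "e", "o", "y", "k"), 4))
    vapply(seq_len(n), function(i) {
      len <- sample.int(max_len, 1L)
      paste(sample(alphabet, len, replace = TRUE), collapse = "")
    }, character(1))
  })
}

# small deterministic toy corpus used across corpus/orthography tests
toy_corpus <- function() {
  inn_corpus(
    c("montelukast", "abacavir", "amikacin", "hydrocortisone",
      "chlorpromazine", "nedocromil", "maraviroc",
      "peginterferon lambda-1a", "ioflubenzamide 131I", "epoetin-alfa"),
    year = c(1997, 1995, 1972, 1951, 1957, 1980, 2005, 2010, 2011, 1990),
    provenance = "toy"
  )
}

fixture_lexicon <- function() inn_lexicon()
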