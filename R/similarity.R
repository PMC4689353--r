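#' Levenshtein edit distance
#'
#' Minimum number of single-character insertions, deletions, or
#' substitutions transforming one string into the other (unit costs, no
#' transposition), computed by the classic dynamic program. Symmetric, and
#' bounded by `abs(nchar(a) - nchar(b)) <= d <= max(nchar(a), nchar(b))`.
#'
#' @param a,b character vectors (recycled to common length).
#' @return integer vector of distances.
#' @examples
#' levenshtein("book", "back")
#' levenshtein("mercaptopurine", "mercaptamine")
#' @export
levenshtein <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  vapply(seq_len(n), function(i) {
    led_codes(utf8ToInt(a[i]), utf8ToInt(b[i]))
  }, integer(1))
}

# core DP on integer code vectors; `cap` allows early abandon: when every
# entry of a row exceeds cap the true distance must exceed cap and cap+1L is
# returned (identical to the full DP for all distances <= cap)
led_codes <- function(ai, bi, cap = Inf) {
  la <- length(ai)
  lb <- length(bi)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  if (abs(la - lb) > cap) return(as.integer(cap + 1L))
  prev <- 0:lb
  for (i in seq_len(la)) {
    sub <- prev[1:lb] + (ai[i] != bi)
    cur <- integer(lb + 1L)
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, sub[j])
    }
    if (is.finite(cap) && min(cur) > cap) return(as.integer(cap + 1L))
    prev <- cur
  }
  as.integer(prev[lb + 1L])
}

#' Screen a sample of names against a universe for near misses
#'
#' Computes the Levenshtein edit distance for every (sample, universe) pair
#' of distinct names and retains pairs with distance in `[1, max_led]`.
#' Pairs are stored unordered (name_a < name_b) and deduplicated when the
#' same pair arises from both directions. A pre-filter skips pairs whose
#' length difference already exceeds `max_led`; this is behaviourally
#' identical to the full dynamic program.
#'
#' @param sample,universe single-word `inn_corpus` objects (or character
#'   vectors of normalized names).
#' @param max_led retain pairs with distance at most this (default 4).
#' @return tibble of class `similar_pairs`: columns `name_a`, `name_b`,
#'   `led`, `shares_stem`, `shares_substem` (flags NA until
#'   [annotate_shared_stems()] is applied). Attributes `total_comparisons`
#'   (|sample| x |universe| minus self-pairs), `retained`, `discarded`.
#' @export
screen_pairs <- function(sample, universe, max_led = 4) {
  stopifnot(is.numeric(max_led), max_led >= 1)
  s <- if (inherits(sample, "inn_corpus")) sample$norm_name else as.character(sample)
  u <- if (inherits(universe, "inn_corpus")) universe$norm_name else as.character(universe)
  s_codes <- lapply(s, utf8ToInt)
  u_codes <- lapply(u, utf8ToInt)
  u_len <- nchar(u)

  rows_a <- character(); rows_b <- character(); rows_d <- integer()
  n_self <- 0L
  for (i in seq_along(s)) {
    li <- length(s_codes[[i]])
    cand <- which(abs(u_len - li) <= max_led)
    for (j in cand) {
      if (s[i] == u[j]) { n_self <- n_self + 1L; next }
      d <- led_codes(s_codes[[i]], u_codes[[j]], cap = max_led)
      if (d >= 1L && d <= max_led) {
        if (s[i] < u[j]) { rows_a <- c(rows_a, s[i]); rows_b <- c(rows_b, u[j]) }
        else { rows_a <- c(rows_a, u[j]); rows_b <- c(rows_b, s[i]) }
        rows_d <- c(rows_d, d)
      }
    }
    # identical strings have zero length difference, so every self-pair is
    # inside the band and has been counted above
  }
  out <- tibble::tibble(name_a = rows_a, name_b = rows_b, led = rows_d)
  out <- out[!duplicated(paste(out$name_a, out$name_b)), ]
  out <- out[order(out$led, out$name_a, out$name_b), ]
  out$shares_stem <- NA
  out$shares_substem <- NA
  total <- length(s) * length(u) - n_self
  structure(out, class = c("similar_pairs", class(out)),
            total_comparisons = total, retained = nrow(out),
            discarded = total - nrow(out), max_led = as.integer(max_led))
}

#' Flag stem sharing on screened pairs
#'
#' Two names share a stem when their stem node sets (direct non-shadowed
#' matches plus implied hyperonym chains) intersect at any taxonomy node;
#' they additionally share a sub-stem when the intersection contains a node
#' of depth >= 1. Sharing is decided by taxonomy-node identity, not string
#' equality, so allomorph pairs (indoprofen/diprofene) share a stem, while
#' pairs with common terminal letters but no lexicon-backed common stem
#' (lagatide/giractide) do not.
#'
#' @param pairs a `similar_pairs` tibble from [screen_pairs()].
#' @param lex a `stem_lexicon`.
#' @return `pairs` with `shares_stem` and `shares_substem` filled in.
#' @export
annotate_shared_stems <- function(pairs, lex) {
  nms <- unique(c(pairs$name_a, pairs$name_b))
  sets <- lapply(nms, stem_node_set, lex = lex)
  names(sets) <- nms
  depth_of <- stats::setNames(
    lex$entries$depth[!duplicated(lex$entries$stem_id)],
    lex$entries$stem_id[!duplicated(lex$entries$stem_id)])
  flags <- vapply(seq_len(nrow(pairs)), function(i) {
    common <- intersect(sets[[pairs$name_a[i]]], sets[[pairs$name_b[i]]])
    c(length(common) > 0, any(depth_of[common] >= 1))
  }, logical(2))
  pairs$shares_stem <- flags[1, ]
  pairs$shares_substem <- flags[2, ]
  pairs
}

#' Similarity summary stratified by edit distance
#'
#' Per distance value 1..`max_led`: pair frequency, percentage of pairs
#' sharing a stem, and percentage sharing both a stem and a sub-stem.
#' Empty bins report frequency 0 with NA percentages (rendered as em-dashes
#' by the report writer).
#'
#' @param pairs an annotated `similar_pairs` tibble.
#' @param max_led largest distance bin; defaults to the screen's `max_led`.
#' @return tibble with columns `led`, `frequency`, `pct_sharing_stem`,
#'   `pct_sharing_stem_and_substem`.
#' @export
summarize_pairs <- function(pairs, max_led = NULL) {
  if (is.null(max_led)) max_led <- attr(pairs, "max_led") %||% max(c(pairs$led, 1L))
  res <- lapply(seq_len(max_led), function(d) {
    sub <- pairs[pairs$led == d, , drop = FALSE]
    n <- nrow(sub)
    tibble::tibble(
      led = d, frequency = n,
      pct_sharing_stem = if (n) 100 * mean(sub$shares_stem) else NA_real_,
      pct_sharing_stem_and_substem = if (n) 100 * mean(sub$shares_substem) else NA_real_
    )
  })
  dplyr::bind_rows(res)
}
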