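#' The stem lexicon shipped with the package
#'
#' Encodes the antiasthmatic (-ast), antiviral (vir) and monoclonal-antibody
#' (-mab) stem taxa in full, plus the lone stems and hazard examples used
#' throughout the documentation (allomorph pairs, single-letter-distinct
#' stems, position-dependent fos, homophonic -micin/-mycin). A complete
#' reference stem book can be loaded through the same TSV format with
#' [load_lexicon()].
#'
#' @return a `stem_lexicon`.
#' @export
inn_lexicon <- function() {
  load_lexicon(system.file("extdata", "inn_stem_lexicon.tsv", package = "innlint"))
}

#' Run the full naming-principle audit over a corpus
#'
#' Runs the five audit stages and writes one TSV report per stage (with a
#' JSON mirror) plus a run manifest:
#'
#' 1. isolated elements and hyphenation in multi-word names;
#' 2. prohibited (di)graph table and per-decade counts;
#' 3. word-length statistics, per-decade means and the outlier list;
#' 4. stem matches and (when expectations are supplied) the compliance rate
#'    over a random subsample;
#' 5. edit-distance screening of the subsample against the whole single-word
#'    set, stem-sharing annotation, and the stratified summary.
#'
#' @param corpus an `inn_corpus` or a path readable by [read_corpus()].
#' @param lexicon a `stem_lexicon` (default: the shipped lexicon).
#' @param outdir output directory (created if absent).
#' @param max_led screening threshold (default 4).
#' @param outlier_threshold length-outlier threshold (default 20).
#' @param sample_fraction_q4 fraction of the single-word set sampled for the
#'   stem and similarity stages (default 0.01).
#' @param seed integer seed for the subsample.
#' @param expectations optional tibble (`name`, `expected_stem_id`) for the
#'   compliance stage.
#' @return (invisibly) list with all computed tables and the manifest.
#' @export
run_full_analysis <- function(corpus, lexicon = NULL, outdir,
                              max_led = 4, outlier_threshold = 20,
                              sample_fraction_q4 = 0.01, seed = 1L,
                              expectations = NULL) {
  if (is.character(corpus)) corpus <- read_corpus(corpus)
  if (is.null(lexicon)) lexicon <- inn_lexicon()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "partition"
  result <- tryCatch({
    parts <- partition_corpus(corpus)
    single <- parts$single
    multi <- parts$multi

    stage <- "isolated-elements"
    q1 <- isolated_element_report(corpus)
    write_report(q1, outdir, "q1_isolated_elements")

    stage <- "digraphs"
    q2_table <- digraph_table(single, lexicon)
    q2_decade <- digraphs_by_decade(single, lexicon)
    write_report(q2_table, outdir, "q2_digraph_table")
    write_report(q2_decade, outdir, "q2_digraphs_by_decade")

    stage <- "word-length"
    q3 <- length_stats(single, outlier_threshold = outlier_threshold)
    q3_decade <- length_by_decade(single)
    write_report(tibble::tibble(
      n = q3$n, mean = q3$mean, sd = q3$sd, median = q3$median,
      mode = q3$mode, q1 = q3$q1, q3 = q3$q3
    ), outdir, "q3_length_stats")
    write_report(q3$outliers, outdir, "q3_outliers")
    write_report(q3_decade, outdir, "q3_length_by_decade")

    stage <- "stems"
    subsample <- sample_fraction(single, sample_fraction_q4, seed)
    q4_matches <- dplyr::bind_rows(lapply(subsample$norm_name, function(nm) {
      m <- match_stems(nm, lexicon)
      if (nrow(m)) m$name <- nm
      m
    }))
    write_report(q4_matches, outdir, "q4_stem_matches")
    q4_rate <- NULL
    if (!is.null(expectations)) {
      exp_sub <- expectations[expectations$name %in% subsample$norm_name, ]
      if (nrow(exp_sub)) {
        q4_rate <- compliance_rate(exp_sub, lexicon)
        write_report(q4_rate$verdicts, outdir, "q4_compliance")
      }
    }

    stage <- "similarity"
    pairs <- screen_pairs(subsample, single, max_led = max_led)
    pairs <- annotate_shared_stems(pairs, lexicon)
    q5_summary <- summarize_pairs(pairs, max_led)
    write_report(tibble::as_tibble(pairs), outdir, "q5_similar_pairs")
    write_report(format_summary(q5_summary), outdir, "q5_summary")

    manifest <- list(
      seed = as.integer(seed),
      max_led = max_led,
      outlier_threshold = outlier_threshold,
      sample_fraction = sample_fraction_q4,
      counts = list(
        total = nrow(corpus), single = nrow(single), multi = nrow(multi),
        subsample = nrow(subsample),
        comparisons = attr(pairs, "total_comparisons"),
        pairs_retained = attr(pairs, "retained"),
        pairs_discarded = attr(pairs, "discarded")
      ),
      provenance = attr(corpus, "provenance")
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    list(q1 = q1, q2_table = q2_table, q2_decade = q2_decade,
         q3 = q3, q3_decade = q3_decade, q4_matches = q4_matches,
         q4_rate = q4_rate, pairs = pairs, q5_summary = q5_summary,
         manifest = manifest)
  }, error = function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(result)
}

# TSV report with a JSON mirror; percentages already formatted upstream
write_report <- function(df, outdir, name) {
  readr::write_tsv(tibble::as_tibble(df), file.path(outdir, paste0(name, ".tsv")),
                   na = "")
  jsonlite::write_json(df, file.path(outdir, paste0(name, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null")
  invisible(NULL)
}

# render similarity summary percentages to one decimal, em-dash for empty bins
format_summary <- function(s) {
  fmt <- function(x) ifelse(is.na(x), "—", sprintf("%.1f", x))
  tibble::tibble(
    led = s$led, frequency = s$frequency,
    pct_sharing_stem = fmt(s$pct_sharing_stem),
    pct_sharing_stem_and_substem = fmt(s$pct_sharing_stem_and_substem)
  )
}
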