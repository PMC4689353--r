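test_that("the shipped lexicon loads with the expected taxa and lint flags", {
  lex <- fixture_lexicon()
  e <- lex$entries
  expect_setequal(e$stem_id[e$parent %in% "ast"],
                  c("lukast", "milast", "trodast", "zolast"))
  expect_true("viroc" %in% e$stem_id[e$parent %in% "vir"])

  lint <- lex$lint
  sl <- lint[lint$type == "single_letter_distinction", ]
  expect_true(any(sl$stem_a == "fenin" & sl$stem_b == "fenine" |
                    sl$stem_a == "fenine" & sl$stem_b == "fenin"))
  expect_true(any(sl$stem_a == "micin" & sl$stem_b == "mycin" |
                    sl$stem_a == "mycin" & sl$stem_b == "micin"))
  expect_true(any(lint$type == "containment" & lint$stem_a == "viroc"))
})

test_that("malformed lexicons are rejected at load", {
  base <- tibble::tibble(
    stem_id = "a", spelling = "aaa", affix_class = "suffix",
    parent = NA_character_, definition = "x")
  expect_error(stem_lexicon(dplyr::mutate(base, parent = "a")), "cycle")
  expect_error(stem_lexicon(dplyr::mutate(base, parent = "ghost")), "unknown parent")
  expect_error(stem_lexicon(dplyr::bind_rows(base, base)), "duplicate")
  two <- dplyr::bind_rows(base, tibble::tibble(
    stem_id = "b", spelling = "bbb", affix_class = "suffix",
    parent = "a", definition = "y"))
  cyc <- two
  cyc$parent <- c("b", "a")
  expect_error(stem_lexicon(cyc), "cycle")
  expect_error(stem_lexicon(dplyr::mutate(base, affix_class = "circumfix")),
               "affix_class")
  expect_error(stem_lexicon(dplyr::mutate(base, spelling = "AAA")), "alphabetic")
})

test_that("matching honors affix classes and reports implied hyperonyms", {
  lex <- fixture_lexicon()

  m <- match_stems("montelukast", lex)
  expect_equal(m$stem_id, c("lukast", "ast"))
  expect_equal(m$position, c("suffix", "suffix"))
  expect_equal(m$depth, c(1L, 0L))
  expect_false(any(m$implied))  # ast matches the string directly too

  mv <- match_stems("maraviroc", lex)
  expect_true(all(c("viroc", "vir") %in% mv$stem_id))
  expect_equal(mv$stem_id[1], "viroc")  # most specific first

  # vir as a freefix fires inside a non-antiviral name
  vg <- match_stems("virginiamycin", lex)
  expect_true("vir" %in% vg$stem_id)
  expect_true("mycin" %in% vg$stem_id)

  lone <- match_stems("nedocromil", lex)
  expect_equal(lone$stem_id, "cromil")
  expect_true(is.na(stem_lexicon_parent <- lex$entries$parent[
    lex$entries$stem_id == "cromil"]))

  expect_equal(nrow(match_stems("qqqq", lex)), 0L)
})

test_that("suffix/prefix matches sit at the word edges and sub-stems imply ancestors", {
  lex <- fixture_lexicon()
  gen <- generate_corpus(synthetic_spec(
    n_names = 120, stem_prevalence = c(lukast = 0.4, arte = 0.3), seed = 21))
  for (nm in gen$corpus$norm_name) {
    m <- match_stems(nm, lex)
    direct <- m[!m$implied, , drop = FALSE]
    if (!nrow(m)) next
    n <- nchar(nm)
    e <- lex$entries
    for (i in seq_len(nrow(direct))) {
      cls <- e$affix_class[match(paste(direct$stem_id[i], direct$spelling[i]),
                                 paste(e$stem_id, e$spelling))]
      if (cls == "suffix") expect_equal(direct$end[i], n)
      if (cls == "prefix") expect_equal(direct$start[i], 0L)
      if (cls == "infix") expect_true(direct$start[i] > 0 && direct$end[i] < n)
    }
    # every match at depth > 0 has its full ancestor chain reported
    for (id in m$stem_id[m$depth > 0]) {
      anc <- innlint:::stem_ancestors(lex, id)
      expect_true(all(anc %in% m$stem_id), info = nm)
    }
  }
})

test_that("matcher agrees with the try-every-offset oracle on random names", {
  lex <- fixture_lexicon()
  gen <- generate_corpus(synthetic_spec(
    n_names = 300,
    stem_prevalence = c(lukast = 0.15, mycin = 0.15, vir = 0.1, arte = 0.1,
                        fos = 0.1, mab = 0.1),
    seed = 77))
  for (nm in gen$corpus$norm_name) {
    got <- match_stems(nm, lex)
    got <- got[!got$implied, , drop = FALSE]
    keys <- sort(paste(got$stem_id, got$start, got$end, sep = ":"))
    expect_equal(keys, oracle_match_keys(nm, lex), info = nm)
  }
})

test_that("overlapping unrelated stems are flagged, contained ones shadowed", {
  lex <- fixture_lexicon()
  rio <- match_stems("riodipine", lex)
  expect_setequal(rio$stem_id, c("dipine", "pine"))
  expect_true(all(rio$ambiguous))
  expect_true(rio$shadowed[rio$stem_id == "pine"])
  expect_false(rio$shadowed[rio$stem_id == "dipine"])

  gir <- match_stems("giractide", lex)
  expect_true(gir$shadowed[gir$stem_id == "tide"])
  expect_false(gir$shadowed[gir$stem_id == "actide"])
})

test_that("position-dependent senses resolve by affix position", {
  lex <- fixture_lexicon()
  ur <- match_stems("uredofos", lex)
  expect_equal(ur$position[ur$stem_id == "fos"], "suffix")
  expect_match(resolve_position_sense(ur[ur$stem_id == "fos", ], lex),
               "insecticides")

  bf <- match_stems("benfosformin", lex)
  expect_equal(bf$position[bf$stem_id == "fos"], "infix")
  expect_match(resolve_position_sense(bf[bf$stem_id == "fos", ], lex),
               "other than")

  # grel has no position senses: same meaning as infix or suffix
  g1 <- resolve_position_sense(list(stem_id = "grel", position = "infix"), lex)
  g2 <- resolve_position_sense(list(stem_id = "grel", position = "suffix"), lex)
  expect_equal(g1, g2)
})

test_that("compliance verdicts distinguish compliant, noncompliant and unlisted", {
  lex <- fixture_lexicon()
  expect_equal(classify_compliance("montelukast", "lukast", lex)$verdict, "compliant")
  expect_equal(classify_compliance("clortermine", "orex", lex)$verdict, "noncompliant")

  rio <- classify_compliance("riodipine", "dipine", lex)
  expect_equal(rio$verdict, "compliant")
  expect_true("pine" %in% rio$ambiguous_alternatives)

  expect_equal(classify_compliance("montelukast", NA, lex)$verdict, "unlisted")
  expect_error(classify_compliance("montelukast", "nosuchstem", lex), "unknown stem_id")
})

test_that("the noncompliance rate counts noncompliant and unlisted names", {
  lex <- fixture_lexicon()
  all_ok <- tibble::tibble(
    name = c("montelukast", "maraviroc", "granisetron"),
    expected_stem_id = c("lukast", "viroc", "setron"))
  expect_equal(compliance_rate(all_ok, lex)$rate, 0)

  mixed <- dplyr::bind_rows(all_ok, tibble::tibble(
    name = c("clortermine", "zzzdrug"), expected_stem_id = c("orex", NA)))
  r <- compliance_rate(mixed, lex)
  expect_equal(r$rate, 2 / 5)
  expect_equal(sum(r$verdicts$verdict == "compliant"), 3L)

  expect_error(compliance_rate(all_ok[0, ], lex), "empty")
})

test_that("a lexicon survives a write/load round trip", {
  lex <- fixture_lexicon()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon(lex, f)
  lex2 <- load_lexicon(f)
  ord <- function(e) e[order(e$stem_id, e$spelling, e$affix_class), ]
  expect_equal(ord(lex2$entries), ord(lex$entries))
  sord <- function(s) s[order(s$stem_id, s$position), ]
  expect_equal(sord(lex2$senses), sord(lex$senses))
})
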