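test_that("prohibited scan reproduces the canonical worked examples", {
  h <- scan_prohibited("phthalylsulfathiazole")
  # the three digraphs read off in order, plus the single graph y the name
  # also carries
  expect_equal(h$pattern[h$pattern %in% c("ph", "th", "ae", "oe")],
               c("ph", "th", "th"))
  expect_equal(h$pattern, c("ph", "th", "y", "th"))
  expect_equal(h$start, c(0L, 2L, 6L, 13L))

  expect_equal(sum(scan_prohibited("hydrocortisone")$pattern == "h"), 1L)
  expect_equal(scan_prohibited("hydrocortisone")$start[1], 0L)
  ch <- scan_prohibited("chlorpromazine")
  expect_equal(ch$pattern, "h")
  expect_equal(ch$start, 1L)

  expect_equal(nrow(scan_prohibited("abacavir")), 0L)
  expect_error(scan_prohibited("ioflubenzamide 131i"), "alphabetic")
})

test_that("hits inside a recommended stem are marked exempt but still returned", {
  lex <- fixture_lexicon()
  k <- scan_prohibited("amikacin", lex)
  expect_equal(k$pattern, "k")
  expect_equal(k$start, 3L)
  expect_true(k$exempt)
  # same name without a lexicon: reported, not exempt
  expect_false(scan_prohibited("amikacin")$exempt)
  # the th of a -methasone name is stem-exempt
  m <- scan_prohibited("betamethasone", lex)
  expect_true(m$exempt[m$pattern == "th"])
})

test_that("scanner agrees with a brute-force oracle and hits never overlap", {
  strings <- random_scan_strings(2000, max_len = 15, seed = 99)
  for (s in strings) {
    got <- scan_prohibited(s)
    want <- oracle_scan(s)
    expect_equal(got$pattern, want$pattern, info = s)
    expect_equal(got$start, want$start, info = s)
    if (nrow(got) > 1) {
      ends <- got$start + nchar(got$pattern)
      expect_true(all(got$start[-1] >= ends[-nrow(got)]), info = s)
    }
  }
})

test_that("digraph table counts names and instances and conserves totals", {
  cc <- inn_corpus(c("phthalylsulfathiazole", "abacavir"), year = 1950)
  tab <- digraph_table(cc)
  row <- function(p) tab[tab$pattern == p, ]
  expect_equal(row("ph")$names_containing, 1L)
  expect_equal(row("ph")$total_instances, 1L)
  expect_equal(row("th")$total_instances, 2L)
  expect_equal(row("y")$total_instances, 1L)
  expect_equal(row("total")$total_instances,
               sum(tab$total_instances[tab$pattern != "total"]))
  # conservation against per-name scans
  expect_equal(row("total")$total_instances,
               sum(vapply(cc$norm_name, function(nm) nrow(scan_prohibited(nm)),
                          integer(1))))

  empty <- inn_corpus(character(), provenance = "empty")
  expect_true(all(digraph_table(empty)$total_instances == 0L))
})

test_that("per-decade digraph counts bucket by floor(year/10)*10 and sum to the total", {
  cc <- inn_corpus("phenindione", year = 1956)
  d <- digraphs_by_decade(cc)
  expect_equal(d$decade, 1950L)
  expect_equal(d$instances, 1L)

  toy <- toy_corpus()
  single <- partition_corpus(toy)$single
  d2 <- digraphs_by_decade(single)
  expect_equal(sum(d2$instances),
               digraph_table(single)$total_instances[
                 digraph_table(single)$pattern == "total"])

  noyear <- inn_corpus(c("hydrocortisone", "abacavir"), year = c(NA, 1995))
  expect_warning(d3 <- digraphs_by_decade(noyear), "missing year")
  expect_equal(sum(d3$instances), 0L)
})

test_that("isolated-element flags match the multi-word examples", {
  r <- isolated_elements("peginterferon lambda-1a")
  expect_true(r$has_hyphen)
  expect_true(r$has_alphanumeric_word)
  expect_false(r$has_isolated_letter)
  expect_false(r$has_isolated_number)

  r2 <- isolated_elements("ioflubenzamide 131I")
  expect_false(r2$has_hyphen)
  expect_true(r2$has_alphanumeric_word)

  r3 <- isolated_elements("abc def")
  expect_false(any(unlist(r3)))

  r4 <- isolated_elements("abc d 3")
  expect_true(r4$has_isolated_letter)
  expect_true(r4$has_isolated_number)

  rep <- isolated_element_report(toy_corpus())
  expect_equal(nrow(rep), 3L)
  expect_equal(sum(rep$has_hyphen), 2L)
})

test_that("length statistics match hand-computable cases and order their quantiles", {
  one <- inn_corpus("phenoxymethylpenicillin", year = 1959)
  s <- length_stats(one)
  expect_equal(s$n, 1L)
  expect_equal(s$mean, 23)
  expect_equal(s$outliers$length, 23L)

  two <- inn_corpus(c("abcde", "fghij"), year = 2000)
  s2 <- length_stats(two)
  expect_equal(s2$mean, 5)
  expect_equal(s2$sd, 0)
  expect_equal(s2$median, 5)

  # population vs sample SD on {4, 6}
  uneven <- inn_corpus(c("abcd", "abcdef"), year = 2000)
  expect_equal(length_stats(uneven)$sd, 1)
  expect_equal(length_stats(uneven, sd_type = "sample")$sd, sqrt(2))

  gen <- generate_corpus(synthetic_spec(n_names = 400, seed = 5))
  st <- length_stats(partition_corpus(gen$corpus)$single)
  len <- nchar(gen$corpus$norm_name)
  expect_true(min(len) <= st$q1 && st$q1 <= st$median &&
                st$median <= st$q3 && st$q3 <= max(len))
  expect_true(st$mean >= min(len) && st$mean <= max(len))

  expect_error(length_stats(inn_corpus(character())), "empty")
})

test_that("outliers are the names strictly longer than the threshold, ascending", {
  nine <- inn_corpus(
    c("sulfachlorpyridazine", "succinylsulfathiazole", "methyldihydromorphine",
      "phthalylsulfathiazole", "ethylmethylthiambutene", "phthalylsulfamethizole",
      "sulfamethoxypyridazine", "diiodohydroxyquinoline", "phenoxymethylpenicillin"),
    year = 1955)
  # the threshold is strict, so the 20-character name needs threshold 19 to
  # appear in the outlier list alongside the longer eight
  s19 <- length_stats(nine, outlier_threshold = 19)
  expect_equal(s19$outliers$length, c(20L, 21L, 21L, 21L, 22L, 22L, 22L, 22L, 23L))
  s20 <- length_stats(nine, outlier_threshold = 20)
  expect_equal(nrow(s20$outliers), 8L)
  expect_true(all(s20$outliers$length > 20))
})

test_that("per-decade mean lengths average within buckets", {
  cc <- inn_corpus(c("abcdefghij", "abcdefghijkl", "abcdefgh"),
                   year = c(1961, 1969, 1978))
  d <- length_by_decade(cc)
  expect_equal(d$mean_length[d$decade == 1960], 11)
  expect_equal(d$mean_length[d$decade == 1970], 8)

  single <- inn_corpus("montelukast", year = 1997)
  expect_equal(length_by_decade(single)$mean_length, 11)
})
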