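# innlint

Orthographic and stem-taxonomy auditing of generic drug names.

Look-alike/sound-alike (LASA) confusion between medication names — think
mercaptopurine dispensed for mercaptamine — is one of the most common
classes of medication error. Generic names (International Nonproprietary
Names, INNs) are designated under WHO naming principles that constrain
spelling (no `ph`, `th`, `ae`, `oe`, `y`, `h`, `k`), structure (no isolated
letters/numbers or hyphens, not inconveniently long) and semantics (a shared
*stem* — e.g. -ast for antiasthmatics, with sub-stems like -lukast for
leukotriene receptor antagonists — must signal pharmacological
relationship). The catch is that shared stems make related names look
alike, so the principles compete with each other.

`innlint` is for medication-safety researchers and nomenclature reviewers
who want those checks to be mechanical and reproducible. It provides:

* **Corpus handling** — delimited-text ingestion, normalization,
  single/multi-word partitioning, seeded subsampling.
* **Orthography checks** — a greedy non-overlapping scanner for the
  prohibited graphs and digraphs (with stem-based exemptions, e.g. the `k`
  of amikacin inside -kacin), isolated-element/hyphen flags for multi-word
  names, and word-length statistics with outlier listing.
* **A stem lexicon and matcher** — hierarchical stem/sub-stem taxonomy with
  affix classes (prefix, suffix, infix, freefix), allomorph spellings,
  position-dependent senses (fos), implied hyperonyms by taxonomy link
  (maraviroc → vir), shadowing of letter-overlap pseudo-matches, and
  compliance verdicts.
* **A monoclonal-antibody name grammar** — longest-match decomposition into
  prefix + target infix + source infix + `mab` (tras|tu|zu|mab), with
  structured failures and an exhaustive round-trip audit.
* **Similarity screening** — Levenshtein edit distance
  (d(a,b) = minimum insertions + deletions + substitutions), sample-vs-universe
  screening with exact band pruning, stem-sharing annotation, and summaries
  stratified by distance.
* **A synthetic corpus generator** — names with configurable length
  distribution, planted stem families, controlled noncompliance, recorded
  digraph injections and near-miss pairs, so the whole pipeline is testable
  with known ground truth.

## Worked example

```r
library(innlint)
lex <- inn_lexicon()

match_stems("montelukast", lex)
#> # A tibble: 2 × 9
#>   stem_id spelling start   end depth position shadowed ambiguous implied
#>   <chr>   <chr>    <int> <int> <int> <chr>    <lgl>    <lgl>     <lgl>
#> 1 lukast  lukast       5    11     1 suffix   FALSE    FALSE     FALSE
#> 2 ast     ast          8    11     0 suffix   FALSE    FALSE     FALSE
```

montelukast carries the antiasthmatic stem -ast and, more specifically, the
leukotriene-receptor-antagonist sub-stem -lukast (depth 1 in the taxon);
spans are 0-based half-open offsets into the name.

```r
scan_prohibited("amikacin", lex)
#> # A tibble: 1 × 3
#>   pattern start exempt
#>   <chr>   <int> <lgl>
#> 1 k           3 TRUE
```

The prohibited `k` is reported but marked exempt: it lies inside the
recommended stem -kacin.

```r
parse_mab("trastuzumab", mab_infix_table())
#> tras-tu-zu-mab  [target: tumour; source: humanised]

levenshtein("mercaptopurine", "mercaptamine")
#> [1] 4
```

Screening a synthetic corpus with planted stem families (plus common
non-stem endings such as -ine) reproduces the empirical signature of
stem-driven confusability — the closer two names, the likelier they share a
stem:

```r
gen <- generate_corpus(synthetic_spec(
  n_names = 1200,
  stem_prevalence = c(lukast = 0.1, milast = 0.1, ciclovir = 0.08, setron = 0.08,
                      end_ine = 0.25, end_one = 0.12, end_ide = 0.12),
  seed = 2026), lexicon_with_common_endings())
smp <- sample_fraction(gen$corpus, 0.12, seed = 2027)
pairs <- annotate_shared_stems(screen_pairs(smp, gen$corpus, max_led = 4), lex)
summarize_pairs(pairs, 4)
#> # A tibble: 4 × 4
#>     led frequency pct_sharing_stem pct_sharing_stem_and_substem
#>   <int>     <int>            <dbl>                        <dbl>
#> 1     1        23            100                          100
#> 2     2       233             99.1                         88.4
#> 3     3       868             92.9                         74.9
#> 4     4      1899             78.4                         56.0
```

Pair frequency grows with edit distance while the fraction of pairs whose
resemblance is backed by a real stem falls — distant look-alikes
increasingly share mere letters (the lagatide/giractide trap), close
look-alikes share pharmacology.

`run_full_analysis(corpus, outdir = "reports", seed = 1)` runs all five
audit stages (isolated elements, digraphs, lengths, stems, similarity) and
writes TSV/JSON reports plus a manifest with the seed and stage counts. A
thin command-line wrapper with the same stages ships in `inst/cli/innlint.R`.

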