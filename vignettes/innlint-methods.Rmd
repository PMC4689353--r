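---
title: "Auditing nonproprietary drug names: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing nonproprietary drug names: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(innlint)
```

## What the package models

Generic drug names (International Nonproprietary Names, INNs) are designated
under WHO naming principles that constrain both form and meaning: names
should avoid isolated letters and numbers and hyphens; they should prefer
shallow orthography (`f` for `ph`, `t` for `th`, `e` for `ae`/`oe`, `i` for
`y`, avoiding `h` and `k`); they should not be inconveniently long; they
should carry a *stem* shared with pharmacologically related substances; and
they should not be confusable with existing names. The last two pull in
opposite directions: a shared stem makes related names look alike by
construction. `innlint` implements each of these checks as a testable
operation so that a name corpus can be audited mechanically, and ships a
synthetic corpus generator with recorded ground truth so every stage can be
validated without access to any proprietary or hand-digitized name database.

## Corpus model

A corpus row holds the published spelling, the normalized form (lowercased,
trimmed), a publication year, and a word class. A name is *multi-word* when
it contains whitespace or any non-alphanumeric character; digits are
alphanumeric, so `ioflubenzamide 131I` is multi-word because of its space,
not its digits. Multi-word names are audited for isolated elements and
hyphenation; all other checks run on the single-word set. Duplicate
normalized names collapse to their first occurrence with a warning — the
earliest publication wins when input is chronological, which matches how a
deduplicated reference list is built.

`sample_fraction()` draws `round(fraction * n)` records without replacement
under an explicit seed; every randomized stage of the pipeline records its
seed so a report bundle is byte-reproducible.

## Prohibited graphs and digraphs

The scanner walks the name left to right; at each offset the two-character
patterns (`ph`, `th`, `ae`, `oe`) are tried before the single characters
(`y`, `h`, `k`), and the scan jumps past each match. Hence the `h` inside a
matched `ph`/`th` is never double-counted, while an initial `h`
(hydrocortisone) or the `h` of `chlor` (chlorpromazine) is reported. The
greedy non-overlap rule is a design choice: it reproduces the canonical
reading of phthalylsulfathiazole as ⟨ph, th, th⟩ (the name also carries a
`y`, which the scanner reports as a fourth, single-graph hit). No prohibited
digraph contains `y`, and `ae`/`oe` cannot overlap `ph`/`th`, so no further
tie-breaks are needed.

Because recommended stems themselves contain prohibited letters (the `k` of
-kacin, the `th` of -methasone), a hit whose span lies entirely inside a
matched stem span is marked *exempt* when a lexicon is supplied. Whether
exempt hits should count as violations is a policy question, not a technical
one, so reports carry both the raw and the exempt-excluded totals.

Word-length statistics use the population standard deviation by default
(`sd_type = "sample"` gives the n−1 form; with thousands of names the two
are indistinguishable, and neither convention can be inferred from published
summaries). The mode breaks ties toward the smallest value, for determinism.
Length outliers are *strictly* longer than the threshold (default 20).
Historical lists of "names longer than 20 characters" typically include a
20-character member; reproducing such a list needs threshold 19 under strict
semantics, and the tests do exactly that rather than blurring the rule.

## The stem lexicon

A stem entry has one or more spellings (allomorphs such as -profen/-profene
map to a single stem), an affix class (`prefix`, `suffix`, `infix`,
`freefix`), an optional hyperonym, a pharmacological definition, and
optionally position-dependent senses: fos as a suffix names the
insecticide/anthelminthic hyperonym, while as an infix or prefix it is the
residual sub-stem; grel and vir mean the same thing wherever they sit.

Matching honors the affix class: a suffix must end the name, a prefix must
start it, an infix must be strictly interior, a freefix may sit anywhere.
Three deliberate behaviours:

* **Implied hyperonyms by taxonomy link, not string containment.** A match
  of -viroc reports the antiviral freefix vir as an implied ancestor even
  though no terminal "vir" is present in maraviroc. Containment would get
  this wrong, which is exactly the trap the taxonomy lays for human readers.
* **Shadowing.** A match strictly contained in a longer match from an
  unrelated taxon (-tide inside -actide in giractide; -pine inside -dipine
  in riodipine) is still reported, flagged `shadowed`, but contributes no
  node to stem-sharing sets. Without this, any pair of names ending in the
  same letters would "share a stem" merely by letter overlap.
* **Gated sub-stems.** The single-letter monoclonal-antibody infixes
  (`-a-`, `-o-`, `-u-`, ...) are meaningless outside -mab names and would
  otherwise match in nearly every name; entries can therefore require their
  hyperonym to match directly before they fire.

The lexicon linter flags, without rejecting, cross-taxon spellings one edit
apart (-fenin/-fenine, -micin/-mycin) and suffix sub-stems that do not end
with their hyperonym's spelling (-viroc under vir) — both are real hazards
in the reference taxonomy, and the linter's job is to surface them.

Compliance classification is deliberately conservative: a name is compliant
only when the expected stem matches *directly*; matches from unrelated taxa
overlapping the expected stem are attached as ambiguity notes rather than
adjudicated, because which reading is "correct" is precisely the open
question such names pose.

## The monoclonal-antibody grammar

Antibody names decompose as random prefix + target-class infix +
source-class infix + "mab". Parsing strips "mab", then applies longest match
twice: the source infix ending at the strip point (so xizu beats zu), then
the target infix, trying the vowel-bearing form before the bare form
(toxa before tox) — the vowel is dropped before vowel-initial sources, so
longest-match reproduces the canonical decompositions (tras|tu|zu|mab,
ur|toxa|zu|mab, ote|li|xizu|mab, volo|ci|xi|mab). Failures are structured
values naming the failed stage; muromonab and other pre-convention names are
handled by an explicit exception list rather than by loosening the grammar.
The tumour target infix `tu` is included in the shipped table although some
printed infix lists omit it: the canonical trastuzumab decomposition
requires it, and the table's header records this provenance. An exhaustive
assemble-then-parse audit over the full 9 × 9 infix cross-product verifies
that the grammar round-trips, and flags (rather than hides) any cell where
single-letter infixes make the segmentation ambiguous.

## Edit-distance screening

`levenshtein()` is the classic unit-cost dynamic program — insertions,
deletions, substitutions, no transposition. The tests pin it to a memo-free
recursive oracle (exhaustively for all pairs of strings up to length 3 over
a three-letter alphabet, and on sampled longer pairs — the recursion is
exponential, which is why the exhaustive part stays small) and to
`utils::adist` on 2,000 random pairs, and check the metric axioms on random
triples. Screening a sample against a universe skips pairs whose length
difference already exceeds the threshold; this band filter is provably
equivalent to running the full dynamic program, and the early-abandon cap
inside the DP returns `cap + 1` only when every entry of a row exceeds the
cap, so retained distances are exact. Pairs are stored unordered and
deduplicated; the total comparison count (|sample| × |universe| minus
self-pairs) is reported as metadata so ordered-design counts remain
reconstructable.

Stem sharing on screened pairs is decided by taxonomy-node identity, never
by string equality: allomorph pairs (indoprofen/diprofene) share a node,
while pairs with common terminal letters but no lexicon-backed stem
(lagatide/giractide) do not. Sub-stem sharing requires a common node at
depth ≥ 1 and therefore implies stem sharing.

## The synthetic generator

The generator exists so that every analysis stage can be tested against
known ground truth. It emulates:

* **Length structure** — lengths are a rounded normal (default mean 10.5,
  SD 1.7 characters) clipped to [4, 25]. Rounding adds about
  `sqrt(1/12)` ≈ 0.29 characters of variance in quadrature, i.e. about
  0.02 SD; tests allow for this.
* **Phonotactics** — filler text alternates consonants and vowels over an
  alphabet excluding `h`, `k`, `y`, `w`, so no prohibited pattern can arise
  from filler. Prohibited patterns appear only where injected (at recorded
  offsets) or inside an embedded stem, which makes digraph-rate recovery
  exact. An injected bare `h` is never placed directly after `t`/`p` (it
  would merge into a digraph), insertions never land inside a recorded span,
  and a name's injections are decided before its length is drawn so the
  injected characters are part of the target length, not added on top.
* **Stem families** — each name is assigned at most one stem by the
  configured prevalences and embeds its canonical spelling at an affix-legal
  position; with probability `noncompliance_rate` a name keeps the
  assignment on record but is generated (and verified) not to carry the stem
  — the synthetic analogue of a name listed under a stem it does not use.
  Injections never break an embedded stem's affix position (nothing is
  appended after a suffix stem or prepended before a prefix stem).
* **Near misses** — `plant_near_miss_pairs()` applies k random edits to a
  base name, records the planted k and the recomputed true distance (edits
  may cancel), and guarantees the variant collides with no existing name.
* **Look-alikes without relationship** — `lexicon_with_common_endings()`
  adds frequent non-stem endings (-ine, -one, -ide) as pseudo-stems for
  generation only. Analysing such a corpus against the plain lexicon
  reproduces the characteristic empirical gradient: the closer two names
  are, the more likely their resemblance is stem-driven, because a short
  shared ending buys less similarity than a long shared stem.

What the generator does **not** emulate: realistic letter n-gram statistics,
pronunciation, multi-word names, or the historical decade structure of any
real list (decade weights are uniform dials, not history). Passing tests on
synthetic corpora therefore demonstrates correctness of the *operations*,
not claims about any particular real nomenclature.

## Problem sizes and numerical choices

The test suite and acceptance script run the property suites at sizes chosen
to exercise the code thoroughly while staying quick on one CPU: exhaustive
oracle equivalence for edit distance at string length ≤ 3 (plus sampled
longer pairs and an `adist` cross-check), 10,000-string scanner-oracle
equivalence, 10,000-triple metric-axiom checks, matcher-oracle equivalence
on 800 generated names, parameter recovery at n = 5,000 within 95% binomial
and normal confidence intervals, and similarity stratification on a
1,200-name corpus screened against a 12% subsample. Statistical checks use
fixed seeds; the recovery tolerances are the standard-error bounds implied
by the configured parameters, never tuned constants.

Degenerate inputs are defined, not patched: an empty corpus yields an empty
partition and an all-zero digraph table but refuses length statistics; an
empty screen yields zero-frequency bins whose percentages are undefined and
render as em-dashes; assembling an antibody name from unknown infixes is an
error while failing to parse one is a value.

## Known limitations

* Orthography only: no phonetic similarity, no grapheme-to-phoneme modeling.
* The shipped lexicon is a deliberately small taxonomy fragment; real
  audits should load a complete stem book through the same TSV format.
* Compliance verdicts expose ambiguity instead of resolving it; a
  downstream reviewer decides what "the correct stem" means when several
  match.
* The antibody grammar implements the classic prefix+target+source+mab
  convention; later nomenclature revisions (suffix retirement, new class
  infixes) are out of scope.
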