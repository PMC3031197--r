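---
title: "Profiling journal specialty coverage with MeSH metaterms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling journal specialty coverage with MeSH metaterms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshprofiler)
```

## The model

MEDLINE articles are manually indexed with MeSH headings: descriptor /
qualifier pairs, of which a handful are starred as *major topics* — the
subjects the article is really about. A **metaterm** is a super-concept
standing for a medical specialty or biological science, attached by manual
semantic links to one or more MeSH descriptors or qualifiers. The package's
core operation turns an article's major headings T1…Tn into a ranked
metaterm list M1…Mk in three steps:

1. **Direct links.** A major heading whose descriptor carries a link to a
   metaterm induces it.
2. **Hierarchy closure.** MeSH descriptors sit at tree positions encoded by
   dot-separated tree numbers (`A01.378.800.667.715`); every proper dot
   prefix names an ancestor. A link on a descriptor is inherited downward:
   the descriptor and all of its descendants induce the linked metaterm.
   This is why *Thumb*, five levels below an anatomy-linked root, induces
   *anatomy*, and why *Alcoholism* — which sits in both a
   chemically-induced-disorders tree and a mental-disorders tree — induces
   both *toxicology* and *psychiatry*.
3. **Qualifier links.** When a heading's qualifier is itself starred,
   metaterms linked directly to that qualifier are added. Qualifiers carry
   no hierarchy in this model (their real trees are shallow and links to
   them are rare; our fixture's single qualifier link is synthetic and
   flagged as such).

A metaterm's **support** is the number of major heading lines inducing it;
articles rank metaterms by support descending, ties broken alphabetically
(the upstream ranking rule is unstated; an alphabetical tie-break keeps
results deterministic). Descriptor- and qualifier-derived inductions carry
equal weight — nothing in the source material suggests otherwise.
Metaterms on the exclusion list (methods and laboratory-test specialties
such as *statistics*) are dropped after induction but before ranking, so
diagnostics can still see them.

Implementation note: rather than walking ancestors per heading, the
categorizer materializes the descriptor-to-metaterm closure once
(`metaterm_closure()`) and joins headings against it; a per-heading
brute-force enumeration serves as the independent oracle in the test suite.

## Profiles, rankings, trends

For one journal and one or more pooled years, occurrences are counted per
metaterm and converted to **relative weights**, `count / total × 100`.
Two choices here are genuinely open and therefore configurable:

- **Counting unit** (`unit`): by default a metaterm counts once per article
  in which it is induced (`"article"`); `"heading"` sums support counts
  instead. "Number of occurrences" is ambiguous between the two.
- **Denominator** (`denominator`): by default the total number of metaterm
  occurrences in the journal-year (`"occurrence"`), so weights sum to
  100%. The corpus that motivated this package induced 62,557 metaterms
  from 14,091 articles, and published percentage magnitudes are consistent
  only with occurrence shares — even though the study's stated aim speaks
  of "articles concerning a specialty compared to the total number of
  articles". The `"article"` denominator implements that reading; its
  weights do not sum to 100%.

Ranks run 1, 2, 3… by weight descending, ties alphabetical. Published
per-journal rank columns are not always monotone in their printed
percentages; no ranking rule can reproduce such cells from the weights, so
this package ranks by weight and does not chase them.

The **trend** between a start and end year is
`round((w_end − w_start) / w_start × 100)` as a signed integer percent,
rounded half away from zero to match the printed `+107%` / `−76%` style;
it is undefined (NA) when the start weight is zero. Trends are computed
from stored full-precision weights; recomputing from 2-decimal printed
weights can shift a trend by one point, which is why the bundled
reference table (`journal_trend_weights()`) flags each printed row as
arithmetically self-consistent or not. One published column (JAMA 1997)
duplicates another journal's column verbatim — an apparent typesetting
fault — so several of its printed trends disagree with their own weights;
those rows are flagged `self_consistent = 0` and carried for completeness
only.

Pooling profiles (`pooled_profile()`) sums counts and recomputes weights,
so pooling any partition of a corpus equals profiling it in one pass — a
property the acceptance tests exercise under random partitions.
`top_n_overlap()` intersects top-N metaterm sets across journals (the
"systematically in the first 10" summary).

## The synthetic world

The generator's defaults emulate the corpus the method was built for:

| parameter | default | rationale |
|---|---|---|
| journals | BMJ, JAMA, Lancet, NEJM | the four high-impact general-medicine journals |
| years | 1997, 2002, 2007 | a ten-year window with a midpoint, inside the journals' cited half-life |
| articles per cell | 1,174 | 14,088 total ≈ the 14,091 articles of the study corpus |
| headings per article | 8–12 (uniform) | 141,474 headings / 14,091 articles ≈ 10 |
| major fraction | 0.157 | 22,155 major / 141,474 headings |
| specialties | 6 | desk-scale; one disjoint subtree + one metaterm each |
| tree depth / branching | 3 / 6 | a few hundred descriptors, enough to exercise multi-level closure |

Each article draws a specialty from its journal-year's mixture vector (by
default one flat-Dirichlet draw per cell, emulating differing editorial
emphases), then draws each heading as major with probability
`major_fraction` — major headings uniformly (with replacement) from the
specialty's subtree, the rest from a never-linked noise subtree. Because
noise induces nothing and specialty subtrees are disjoint, an article with
at least one major heading induces exactly its planted metaterm, so under
the default article-unit / occurrence-denominator profile the expected
weight of specialty *s* is exactly `100 × mixture[s]`
(`expected_weights()`): the thinning by articles with no major heading
cancels between numerator and denominator. An `overlap_links` knob makes a
second subtree induce two metaterms (alcoholism-style) for categorizer
tests, but closes off the analytic expectation and is excluded from
recovery oracles.

What the generator does **not** emulate: real MeSH term frequency
distributions (real headings are heavily skewed; ours are uniform within a
subtree), repeated-descriptor conventions (we may draw the same descriptor
twice for one article), qualifier-major headings, editorial drift with
serial correlation across years, or indexing-policy changes. A green
recovery test therefore establishes that the pipeline measures planted
mixtures correctly — not that any particular real-world weight is right.

The curated fixture (`curated_fixture()`) is merged into every toy
thesaurus regardless of seed, so the worked examples (*Thumb* → anatomy;
*Alcoholism* → psychiatry + toxicology) hold in every generated world. Its
links include both the direct descriptor links and the ancestor-chain
links; intermediate descriptors (*Hand*, *Fingers*,
*Substance-Related Disorders*) are reachable only through the closure and
keep the recursive route honestly exercised.

## Numerical and edge-case choices

- Metaterm names are case-insensitive and stored lower-case (source
  material mixes capitalizations).
- A heading is *major* if either its descriptor or its qualifier is
  starred; a starred-qualifier line contributes its descriptor (with
  closure) and its qualifier to induction.
- Records without a PMID or a publication year are skipped and tallied,
  not fatal; unresolvable descriptors yield a warning tally and no
  induction. No deduplication beyond PMID uniqueness is attempted
  (electronic/print dual entries are out of scope).
- Profiles store full-precision weights; 2-decimal rounding happens only
  at the reporting surface. Weight sums are asserted to 100 ± 0.01.
- `trend_percent` uses `sign(x) * floor(|x| + 0.5)` — half away from zero —
  rather than R's banker's rounding.
- Empty cases are defined, not errors: an article with no major headings
  induces nothing; an empty result set profiles to an empty table; ranking
  an empty profile and a zero denominator are errors.

## Limitations

The shipped metaterm table is a small curated extract, not the full
production table of ~104 specialty metaterms (its source is no longer
published); corpus-level published counts (14,091 articles, 22,155 major
terms, 62,557 induced metaterms, 81 specialties) are consequently not
reproducible at desk scale and are covered instead by the property-based
substitutes in `tests/testthat/test-acceptance.R`. Live PubMed retrieval
is deliberately out of scope: the package ingests exported files only.
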