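# meshprofiler

Measure how medical specialties are represented in journals, from the MeSH
indexing of their articles.

Every MEDLINE-indexed article carries MeSH headings — descriptor/qualifier
pairs assigned by NLM indexers, a few of them starred as *major topics*.
`meshprofiler` maps those major headings onto **metaterms**: super-concepts
standing for medical specialties or biological sciences (e.g. *cardiology*,
*psychiatry*), each tied by manual semantic links to one or more MeSH
descriptors or qualifiers. A link placed on a descriptor is inherited by
everything below it in the MeSH tree, so with major terms T1…Tn an article
induces metaterms M1…Mk ranked by how many major headings support each —
e.g. the descriptor *Thumb* (under an anatomy-linked ancestor) induces
*anatomy*, and *Alcoholism* induces both *psychiatry* and *toxicology*.

Aggregated per journal and year, the induced metaterms give each
specialty's **relative weight** — its percent share of all metaterm
occurrences in that journal-year — from which the package builds ranked
distribution tables, cross-journal top-N overlap summaries, and ten-year
trends, `trend = round((w_end − w_start)/w_start × 100)`. It is aimed at
bibliometricians and editors asking questions like "which specialties does
this general-medicine journal actually cover, and how has that shifted?"

## What's in the box

- **MeSH model** — a tabular thesaurus dialect (`read_thesaurus`), ancestor
  queries over dot-separated tree numbers (`mesh_ancestors`), and a
  metaterm link table with an exclusion list for methods/lab-test
  metaterms (`read_link_table`, `linked_metaterms`).
- **MEDLINE I/O** — the plain-text field-tag dialect (`read_medline`,
  `parse_medline_text`, round-tripping `render_medline`) and PubMed XML
  (`read_pubmed_xml`); major-topic asterisks on descriptors or qualifiers
  set the major flags.
- **Categorizer** — `categorize_corpus()` induces ranked metaterms per
  article via a precomputed hierarchy closure (`metaterm_closure`).
- **Profiler** — `journal_year_profile()`, `rank_metaterms()`,
  `pooled_profile()`, `trend_percent()`, `top_n_overlap()`, and
  `build_report()` which writes the whole bundle (`write_report`).
- **Synthetic data** — `generator_config()` / `generate_toy_thesaurus()` /
  `generate_corpus()` plant a known specialty mixture over a toy MeSH tree
  so recovered weights can be checked against `expected_weights()` exactly.
- **Reference data** — `journal_trend_weights()`: published 1997/2002/2007
  specialty weights of BMJ, JAMA, Lancet and NEJM with printed trends.
- A thin CLI at `exec/meshprofiler` (`categorize | profile | trend |
  simulate`, exit codes 0/2/3).

## Worked example

```r
library(meshprofiler)

cf <- curated_fixture()          # small hand-checked MeSH/metaterm extract
corpus <- parse_medline_text(c(
  "PMID- 1", "JT  - Lancet", "DP  - 1997",
  "MH  - *Alcoholism", "MH  - *Mental Disorders", "MH  - *Thumb", ""))
categorize_article(corpus, "1", cf$thesaurus, cf$links)
#> # A tibble: 3 × 2
#>   metaterm   support
#>   <chr>        <int>
#> 1 psychiatry       2
#> 2 anatomy          1
#> 3 toxicology       1
```

Two major headings (*Alcoholism* via its mental-disorders tree, *Mental
Disorders* directly) support *psychiatry*; *anatomy* and *toxicology* are
each supported by one heading; ties are broken alphabetically.

Trends from the bundled reference weights:

```r
ref <- journal_trend_weights()
lg <- ref[ref$journal == "Lancet" & ref$specialty == "Genetics", ]
trend_percent(lg$weight_1997, lg$weight_2007)
#> [1] -76
```

Genetics fell from 3.61% to 0.88% of the Lancet's metaterm occurrences —
a 76% decline over the decade.

A full synthetic analysis:

```r
cfg <- generator_config(seed = 1)        # 4 journals x 3 years x ~1174 articles
toy <- generate_toy_thesaurus(cfg)
report <- build_report(generate_corpus(cfg, toy), toy$thesaurus, toy$links)
report
#> <metaterm_report> 14088 articles, 22460 major headings, 6 metaterms induced (11546 occurrences)
#>   12 journal-year profiles, 4 journals, 24 trend rows
write_report(report, "report")           # CSVs + Markdown tables + run summary
```

## Acceptance script

`scripts/acceptance.R` re-runs the pipeline from scratch against the
installed package: it generates the study-scale synthetic corpus for the
given seed, categorizes and profiles it, recomputes the published trends
from the bundled weight table, and writes the acceptance JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

See `vignettes/journal-specialty-profiling.Rmd` for the model, its
assumptions, and the design decisions.
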