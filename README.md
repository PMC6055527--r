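# crypticsplice

Discovery of splice-site-creating mutations (SCMs) from somatic mutation
tables and spliced RNA-seq alignments.

Most annotation pipelines label a somatic variant by its predicted
protein effect and call it a day. But a "silent" or "missense" mutation
can create a new splice donor or acceptor, rerouting splicing to a
cryptic junction with consequences — truncations, in-frame deletions,
frame shifts — that the conventional label completely misses. The
evidence is sitting in the tumor's own RNA-seq: spliced reads whose
CIGAR `N` gap defines a junction that is absent from the annotation,
private to the mutated sample, and anchored next to the mutation.

`crypticsplice` is a tidyverse-native R package for researchers
integrating DNA and RNA evidence in cancer cohorts. For each mutation it

1. extracts candidate alternative junctions within ±20 bp from the
   sample's spliced alignments (≥ 5 unique fragments, mapping quality
   ≥ Q20),
2. removes annotated (canonical) junctions and HLA loci,
3. quantifies junction usage as the **junction allele fraction**,
   `JAF = alternative-junction fragments / fragments at the locus`
   (default floor 5%), and for splice-in mutations the **spliced-in
   JAF** — the fraction of junction fragments carrying the mutant
   allele,
4. requires the case to stand in the top 5% of a mutation-free control
   cohort's support distribution (nearest-rank 95% threshold, strict),
5. scores reference vs mutant donor 9-mers / acceptor 23-mers with a
   maximum-entropy-style model, `score = log2(P_model / P_background)`
   in bits, and classifies −3 acceptor `aGag`/`agGag` contexts,
6. assigns a review status — `Pass`, `Complex` (more than one surviving
   junction), `NoSupport` — with a complete audit trail, aggregates
   per-gene recurrence and ±5 bp same-junction clusters, and
7. reconstructs the mutant protein implied by a call and enumerates
   novel 8–11-mer neoepitope candidates, optionally gated by an external
   MHC-affinity predictor's table (≤ 500 nM).

A first-class synthetic-fixtures module (`generate_truth_set()`,
`simulate_alignments()`) builds fully self-contained mini-genome worlds
with declared truth — the basis of the package's tests and benchmarks.

## Worked example

A "silent" mutation that creates a de novo donor site, deleting 30
coding nucleotides in frame — high junction support in the case, zero
support across 20 controls:

```r
library(crypticsplice)

w      <- generate_truth_set(n_events = 1, event_types = "donor_del30",
                             true_jaf = 0.5, depth = 164,
                             n_cases = 1, n_controls = 20, seed = 42)
aln    <- simulate_alignments(w, seed = 42)
idx    <- build_junction_index(w$annotation)
models <- splice_models_from_annotation(w$genome, idx)

res <- call_scms(w$mutations, aln[w$samples$cases],
                 aln[w$samples$controls], idx,
                 genome = w$genome, models = models)
res
#> <scm_calls> 1 mutations: 1 Pass, 0 Complex, 0 NoSupport

dplyr::glimpse(tidy(res))   # one row per surviving mutation-junction pair
```

The single `Pass` call reads (selected columns):

| field | value | meaning |
|---|---|---|
| `variant_class` | `silent` | the conventional annotation that missed the event |
| `junction_start`, `junction_end` | 590, 740 | the cryptic intron (0-based half-open) |
| `unique_read_support` | 96 | deduplicated fragments spanning the new junction |
| `locus_depth`, `jaf` | 164, 0.585 | fragments at the locus; junction allele fraction |
| `in_out` | `splice_out` | the mutation is removed within the new intron |
| `control_max` | 0 | no control sample expresses this junction |
| `expression_verdict` | `high` | case count above the control 95% threshold |
| `alt_ref_score` → `alt_mut_score` | −2.86 → −0.05 bits | the mutation strengthens the new donor |
| `review` | `Pass` | exactly one junction survived all filters |

Downstream, the altered protein and its candidate neoepitopes:

```r
tm <- w$transcripts[[w$truth$gene]]
wt <- translate_transcript(w$genome, tm)
mt <- translate_mutant(w$genome, tm,
                       list(start = w$truth$alt_start, end = w$truth$alt_end),
                       w$mutations[1, ])
nchar(wt); nchar(mt)
#> [1] 129
#> [1] 119          # exactly 10 residues deleted in frame
nrow(enumerate_novel_epitopes(mt, wt))
#> [1] 34           # novel 8-11-mers absent from the wild type
```

`autoplot(res)` shows JAF by annotation class, `plot_score_shift(res)`
the reference-vs-mutant score scatter, and `review_and_aggregate(res)`
the per-gene recurrence tables. `tidy()`/`glance()` methods return
tibbles throughout, so results pipe straight into dplyr.

A thin command-line wrapper (`inst/cli/crypticsplice.R`) exposes
`simulate`, `call` and `report` subcommands over files on disk; see its
header for usage.

## Vignette

`vignettes/crypticsplice-methods.Rmd` documents the model and every
numerical convention: coordinate system, the JAF anchor, nearest-rank
thresholds and the strict top-5% rule, the factorized splice-model
format, review rules, what the simulator does and does not emulate, and
known limitations.
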