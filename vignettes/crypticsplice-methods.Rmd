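---
title: "Detecting splice-site-creating mutations with crypticsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting splice-site-creating mutations with crypticsplice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conventional somatic-mutation annotation classifies variants by their
predicted protein effect — missense, silent, nonsense — or flags them as
splice-disrupting when they hit the consensus GT/AG dinucleotides. This
misses a distinct mechanism: a mutation can *create or strengthen* a
splice donor or acceptor where none was used before, rerouting splicing
to a cryptic junction. Such splice-site-creating mutations (SCMs) leave a
direct footprint in RNA-seq: spliced reads whose gap (the CIGAR `N`
operation) ends at a junction absent from the transcript annotation,
appearing only in the sample that carries the mutation.

`crypticsplice` integrates a somatic mutation table with per-sample
spliced alignments to find these events, quantify their usage, score the
underlying sequence change with a maximum-entropy splice-site model, and
enumerate the neoepitopes the altered protein may present.

## The pipeline, step by step

For each mutation in the mutated sample:

1. **Junction discovery.** Every intron observed in the sample's spliced
   alignments is a candidate if its *nearer* boundary lies within
   `window` (default 20 bp) of the mutation and at least `min_reads`
   (default 5) unique fragments with mapping quality at or above
   `min_mapq` (default Q20) support it. 20 bp is the span of the splice
   region around a junction, so a larger window could not attribute a
   junction to the mutation. Support is counted at the *fragment* level:
   a read pair whose two mates both span the junction is one observation.
   Duplicate-marked, secondary and supplementary records never count.
2. **Annotation filtering.** Candidates exactly matching an annotated
   intron (any transcript) are canonical and removed; candidates
   overlapping an HLA gene are removed because mapping in those
   hyper-polymorphic loci is unreliable. Survivors are annotated with the
   nearest canonical intron — preferentially one of the same gene sharing
   a boundary, the classic cryptic-donor/acceptor geometry.
3. **Junction allele fraction (JAF).** The usage of the alternative
   junction is the fraction of fragments at the locus that span it:
   `JAF = alt_junction_fragments / locus_depth`. Events below `jaf_min`
   (default 5%) are filtered.
4. **Control-cohort filtering.** The junction's support is counted, with
   identical rules, in every control sample — samples of the same cohort
   without a mutation in the gene of interest. The case must stand in the
   top 5% of that distribution (strictly above the 95% nearest-rank
   threshold). When no control expresses the junction at all the
   threshold is degenerate and the case passes on the discovery floor
   `min_reads`; this is the typical SCM signature (high case support,
   zero controls positive).
5. **Splice-site scoring.** Reference and mutant k-mers at the
   alternative and nearest canonical boundaries are scored in bits (see
   below), and the relationship is classified: `alt_stronger`,
   `gap_narrowed`, or `no_evidence`.
6. **Review.** Deterministic rules replace by-eye review: exactly one
   surviving junction is a `Pass`; more than one alternatively spliced
   product is `Complex`; none is `NoSupport`, with the first failing
   filter kept in an audit trail so every input mutation is accounted
   for exactly once.

### Coordinate conventions

All internal coordinates are 0-based half-open; MAF positions (1-based)
are converted at the readers. An intron is identified by
`(chrom, first intronic base, last intronic base + 1)`, exactly what a
CIGAR `N` span denotes. The half-open convention makes the
splice-in/splice-out boundary exact: a mutation at `intron.start` is
splice-out (first intronic base), at `intron.start - 1` or `intron.end`
splice-in (flanking exonic bases).

### The JAF denominator

"Reads at the genomic location" needs an anchor. We use the exonic base
immediately adjacent to the junction boundary nearer the mutation, and
count deduplicated fragments that either align a base there or span it
with a gap. Junction-supporting fragments always align flanking bases,
so the numerator is a subset of the denominator and the JAF is the local
exon-usage analogue of an inclusion ratio. Zero depth yields an
undefined JAF and the event is filtered with that reason.

### Spliced-in JAF

For splice-in mutations (retained in the new exon) the association
between mutation and junction is measured as the fraction of
junction-supporting fragments whose alignment covers the mutation with
the alternate allele. When no junction fragment reaches the mutation —
fragments are finite, and the mutation can sit beyond their span — the
quantity is reported as *undefined* rather than zero, since absence of
coverage is not evidence of absence.

## Control-cohort statistics

Control counts are small, zero-inflated integers, so quantiles are taken
without interpolation. The nearest-rank threshold used everywhere is the
left-continuous inverse of the empirical CDF: the smallest member `v` of
the multiset with strictly more than `p·n` elements `≤ v`, i.e.
`sort(x)[floor(p·n) + 1]`. For twenty controls with counts
`{0×18, 3, 9}` this gives `q05 = 0` and `q95 = 9`: the case must beat
every control outside the top 5%. Interpolated quantiles would fabricate
non-integer thresholds between observed counts.

The top-5% rule is strict (`count > q95`): with heavily zero-inflated
controls a non-strict rule would pass cases indistinguishable from
controls. Per-sample expression verdicts partition the outcomes:
`no_expression` when both thresholds and the count are zero, `high`/`low`
outside the 95%/5% thresholds, `average` otherwise.

Control eligibility defaults to *gene level* — any sample with a
mutation in the gene of interest is excluded from the control set — the
stricter of the two plausible readings; `scm_config(control_scope =
"site")` relaxes it to the identical variant.

## Splice-site scoring model

A donor site is scored on a 9-mer (3 exonic + 6 intronic bases), an
acceptor on a 23-mer (20 intronic + 3 exonic). The score is a
log-likelihood ratio in bits:

`score(k) = log2 P_model(k) − log2 P_background(k)`

The model probability factorizes over blocks of positions — each block a
probability table over its sub-k-mer with an exponent of +1 or −1 — so a
fully position-independent model, a full joint table, or a product of
ratios of overlapping sub-models (the maximum-entropy decomposition) are
all expressible in one container and one plain-text file format. The
intronic consensus dinucleotides (donor +1,+2; acceptor −2,−1) are
scored separately from consensus-frequency ratios. Every lookup adds a
pseudocount of 1e-6 so scores stay finite; k-mers containing N are
unscoreable; indel-bearing footprints are flagged unscoreable rather
than scored on shifted sequence, because single-nucleotide events are
the only ones with a well-defined mutant k-mer.

`splice_model_from_sites()` estimates a position-independent model from
the per-position base frequencies of example sites (with a Dirichlet
0.5 smoothing), and `splice_models_from_annotation()` applies it to all
canonical sites of a genome — the standard way to obtain sensible
models for a synthetic world. The file format is open so externally
converted model tables can be dropped in.

A mutation at the −3 position of an alternative acceptor whose −2,−1
read AG is additionally classified against the `aGag`/`agGag` repeat
contexts (capitalised base = mutated position) and the substitution is
labelled as transition or transversion.

## Neoepitope enumeration

The mutant transcript is built by interval arithmetic: the canonical
intron overlapping the alternative one is merged back into the
transcribed region and the alternative intron is subtracted, so a
junction identical to an annotated one reproduces the wild type exactly.
Splice-in substitutions are applied to the exonic sequence. Translation
runs from the annotated start codon to the first in-frame stop —
readthrough is not modelled — so in-frame deletions shorten the protein
with intact flanks and frame shifts produce a novel C-terminus. All
8–11-mer windows of the mutant protein are kept if they do not occur as
substrings of the *same transcript's* wild-type protein (proteome-wide
exclusion is out of scope). Binding affinity is consumed from a
precomputed external predictor table keyed by peptide; peptides at or
below 500 nM are retained, and peptides missing from the table are kept
with unknown affinity rather than silently dropped.

## What the synthetic worlds emulate — and what they do not

`generate_truth_set()` builds mini-genomes of three-exon genes (150 bp
exons, 120 bp introns) with consensus GT..AG boundaries, a stop-free
coding sequence, and an `AGAGAG` acceptor tail so that the −3 acceptor
position has a G consensus — the context the −3 events exploit. Four
event types cover the observed geometries: intronic donor creation
(splice-out), exonic donor strengthening (splice-in), the −3 `aGag`
acceptor shift of exactly 2 nt, and an in-frame donor creation deleting
30 coding nt (10 residues). Decoy mutations sit mid-exon, at least 25 bp
from any junction boundary. `simulate_alignments()` draws error-free
paired-end fragments whose junction choice is Bernoulli with the
declared JAF, so junction counts are exactly binomial around truth;
mapping qualities, duplicate mates spanning the same junction, and
control contamination are configurable knobs.

Passing tests on these worlds demonstrates the counting, filtering and
bookkeeping are correct under known truth. They do not demonstrate
robustness to real-data phenomena the simulator omits: alignment errors
around junctions, multi-mapping in paralogous regions, intron retention,
expression heterogeneity across genes, GC and positional coverage bias,
or aligner-specific soft-clipping — which is why the mapping-quality
floor, the duplicate policy and the control cohort exist in the first
place.

Problem sizes used by the test-suite benchmarks are the package's own
choices: the end-to-end cohort uses 5 cases and 20 controls with 20
injected events (JAF 0.2–0.5, locus depth 100) among 200 decoys; JAF
recovery uses a grid of {0.05, 0.1, 0.25, 0.5, 0.75} at depth 200 with
20 replicates per point; the discovery oracle is checked over 50
independently seeded worlds.

## Numerical and design choices

- **Nearest-rank quantile convention** as above; the degenerate
  all-zero-control case passes on `min_reads`, since "top 5%" is
  undefined on a constant zero distribution.
- **Nearer-boundary window anchoring**: a junction has two ends and the
  ±20 bp window is anchored on the mutation; we measure to the nearer
  boundary, matching the geometry of a mutation creating one of the two
  sites.
- **Fragment-level deduplication everywhere**: "unique reads" means
  unique fragment names; the same rule is used for discovery, depth,
  control counts and spliced-in counts so that ratios are ratios of the
  same unit.
- **Review rules**: `Complex` = more than one surviving junction for the
  mutation; interactive review of homologous-region artefacts is not
  automatable, so highly homologous regions are only flagged by their
  low-mapping-quality fraction, never silently resolved.
- **HLA filtering by gene-symbol prefix** (`^HLA-`), configurable; the
  locus list is annotation-dependent and prefix matching keeps the rule
  transparent.
- **Per-mutation error isolation**: a failure in one mutation is logged
  into the audit trail and the run continues; malformed global inputs
  abort.
- **Determinism**: given fixed inputs and seed, discovery output is
  coordinate-sorted and byte-stable; generators restore the caller's RNG
  state.

## Limitations

Splice-site strength is only one determinant of splice-site choice:
exonic splicing enhancers/silencers, the branch point, the
polypyrimidine tract and RNA-binding proteins are not modelled, so score
deltas are descriptive annotations, not filters. Intron retention and
exitrons produce no `N` span and are invisible to this design. The JAF
of lowly expressed genes is noisy at the default 5% threshold, and
tumor purity is not adjusted for. Binding-affinity prediction is
delegated entirely to an external tool's output table.
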