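---
title: "Identifying single- and dual-TCR T cells: methods and design choices"
author: "dualTCR maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying single- and dual-TCR T cells: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualTCR)
```

# The biological question

Allelic exclusion is supposed to guarantee one TCR per T cell, but it is
incomplete: the TRA locus rearranges on both alleles (and can rearrange
repeatedly on one), and TRB exclusion occasionally fails. The result is a
population of *dual TCR* T cells carrying two functional α chains, two β
chains, or both. Because each receptor confers its own specificity, these
cells matter for tolerance, autoimmunity and immunotherapy, and their
abundance is a quantity of real interest — historically estimated at
1–10%, and substantially higher when measured with paired-chain
single-cell sequencing.

`dualTCR` turns raw single-cell V(D)J contig annotations into that
measurement: a per-sample partition of paired T cells into one single and
four dual pairing classes, with clonal expansion, V/J usage, subset
composition and group-level statistics layered on top.

# The procedure

## Contig quality control

Four exclusion rules are applied to the contig table, in a fixed order:

1. `is_cell = FALSE` — the barcode was not called a cell;
2. `high_confidence = FALSE` — the assembly is unreliable;
3. locus not TRA or TRB — γδ contigs and `Multi`/`None` calls are out of
   scope (the analysis concerns αβ T cells only);
4. `productive` not true — the junction is out of frame, contains a stop,
   or could not be called (`"None"`-style values are treated as
   non-productive for filtering, but kept as a distinct tri-state so the
   two cases remain distinguishable upstream).

Each rule logs its drop count; retained + dropped = input is asserted in
the tests, and the same counts are what the synthetic generator's
labelled noise is checked against. The filter is idempotent.

Boolean parsing accepts the `True/TRUE/true` spellings that different
cellranger versions have emitted. Allele suffixes (`*01`) are stripped
from all gene calls at read time: downstream identity and usage are
gene-level, which is what repertoire usage plots report. Sample identity
is always injected by the caller — per-sample files carry no sample
column, and guessing from barcode suffixes is fragile.

## Chains, cells, and the paired denominator

Surviving contigs are grouped by barcode and collapsed into *distinct
functional chains*. Chain identity is configurable with
`nt` as the default: locus + V gene + J gene + CDR3 nucleotide sequence.
The nucleotide junction separates convergent rearrangements that share
V/J but differ at the junction (which amino-acid identity would merge),
while gene-level identity alone would conflate genuinely different
receptors. The D gene is excluded from the key — frequently uncalled on
TRA, unreliable on TRB, and encoded by the junction anyway — and the C
gene is ignored (whether source pipelines merged same-junction contigs
with different C genes is not recoverable; merging is the conservative
choice). Contigs collapsing to one key have their UMIs summed.

No UMI-dominance filter is applied. Secondary chains are precisely the
object of study, and any threshold for "the real chain" would be an
uncited filter biasing dual calls downward; a `minUmis` option exists but
defaults to 0.

Cells with chains at only one locus are then removed. The retained count
— cells with at least one α *and* one β chain — is the sample's
**paired-cell denominator**; every pairing proportion in the package is a
fraction of it.

## The pairing taxonomy

With `a` distinct α chains and `b` distinct β chains, a paired cell is
classified as: (1,1) single A+B; (1,2) dual A+B1+B2; (2,1) dual B+A1+A2;
(2,2) dual A1+A2+B1+B2; anything with three or more chains at a locus
falls into `OTHERS`. Two conventions deserve note:

* **`OTHERS` counts toward the dual total.** In the published cohort
  table this package ships, the four dual subtype counts only sum to the
  printed dual totals when the residual class is included (e.g. the first
  pre-treatment sample: 41 + 13 + 1 + 1 = 56), so that is the convention
  implemented.
* **Display rounding is half-up to 2 decimals**, the convention of the
  published table. All statistics consume unrounded values; the rounded
  `pct_*` columns are presentation only. Two of the 90 published
  percentage cells are truncations rather than roundings (they differ
  from half-up in the second decimal), which is why reproduction checks
  allow a ±0.01 margin.

## Clonotypes and expansion

Two cells share a clonotype when their chain sets match under the chosen
definition, within one sample and one receptor class. The default,
`full_set`, requires the *entire* chain set to match — for a dual cell,
all three or four chains. This is the strictest reading of "clone size"
for dual cells and the only one that makes a dual clone unambiguous;
`beta_only` (the bulk-repertoire convention) is provided as an
alternative, and the two are contrasted in the tests on a fixture where
they disagree. Clonal expansion is defined as clonotype size ≥ 2, and
expansion is evaluated within a sample, never pooled across a patient's
timepoints. Gene usage counts *chains*, not cells — a two-β cell
contributes two TRBV observations — which is what makes a dual-vs-single
usage comparison well defined; frequencies are normalized within each
(family, class, group) stratum and sum to 1 there.

## Subset integration

Subset labels (naive CD4/CD8, CD4/CD8 central memory, CD4/CD8 effector
memory, Treg) are an *input*: they derive from transcriptome clustering
and reference annotation, which is out of scope here. The join is by
(sample, barcode) with inner-join semantics; unmatched counts on both
sides are reported, unmatched cells stay available to sample-level
analyses, and the seven-label vocabulary is enforced strictly so manifest
typos fail loudly rather than silently creating empty strata.

## Statistics

Welch/Student two-sample t, paired t, Pearson chi-square (no continuity
correction) and one-way ANOVA are implemented directly from their
formulas; tail probabilities go through the regularized incomplete
beta/gamma functions rather than R's distribution wrappers, and R's
`t.test`/`chisq.test`/`oneway.test` serve as independent oracles in the
test suite (agreement to 1e-6 on randomized batteries; the calibration
test additionally checks each test's type-I error lies in [0.04, 0.06]
at α = 0.05 under 10,000 null simulations). Design choices:

* **Welch is the default** for independent comparisons — safer under
  unequal small-sample variances, with Student's pooled variant behind a
  flag.
* **Two-sided p-values throughout**; sidedness is never inferred from the
  direction a hypothesis "should" go.
* **No multiple-testing correction by default**, matching the fixed
  p < 0.05 convention of the analyses this package reproduces;
  Benjamini–Hochberg is available (`adjustPValues`).
* Degenerate inputs (zero-variance differences, empty contingency
  margins, zero within-group variance) raise errors with explicit
  messages rather than returning NaN.

# The synthetic generator

`simulateSample()` draws clonotypes (pairing type from configurable
probabilities; clone size 1 + Geometric(p), default p = 0.9 giving mean
size ≈ 1.11, plus optional planted clones), expands them into cells,
assigns subsets (with an optional dual-specific bias, e.g. a 2× Treg
enrichment), and emits a raw contig table in the 10x CSV layout together
with complete ground truth. CDR3s are generated as amino-acid strings
(Cys start, 10–20 residues) reverse-translated through a static codon
table — cosmetically realistic junctions (TGT/TGC start, length a
multiple of 3, 30–60 nt) with no claim of modelling recombination
biology.

Noise is injected after the clean table is built, each contig violating
exactly one QC rule (non-cell barcode, low-confidence flag, γδ locus,
non-productive junction), plus duplicate contigs (same chain, split
UMIs — absorbed by collapse) and unpaired single-locus cells (removed by
the paired-cell rule). Every row carries a hidden truth label, so QC drop
counts can be asserted *exactly*, not approximately. Identical seeds give
identical output.

The default sample composition — 12.1% dual, split 3.4 / 7.3 / 1.0 / 0.4
across the four dual classes — is the healthy-control composition of the
published cohort; the two-α class dominates, as TRA allelic inclusion
predicts.

**The cohort preset.** `kdCohortPreset()` builds the 15-sample design (6
patients pre- and post-treatment, 3 controls) at the published paired-cell
sizes, with each pre-treatment and control sample's pairing probabilities
taken from its published composition. Post-treatment samples plant a
*uniform* dual-fraction increase of 4.27 percentage points — the published
cohort's mean pre→post shift — rather than each patient's individual
published shift. This is deliberate: the preset's role is to carry a
reliably detectable planted effect for power and end-to-end checks, and
the faithful per-patient values (one patient *decreases*) put the paired
t-test at p ≈ 0.04, too marginal to reject consistently across seeds. The
published per-patient heterogeneity is therefore *not* emulated, and the
preset should not be read as a re-simulation of the study. Post-treatment
samples (except the one patient whose expansion the source did not
observe) also plant two expanded dual clonotypes, and control/post
samples carry a 2×/1.5× Treg bias among dual cells. Acceptance checks run
the preset at 30% of the published sample sizes purely for runtime; the
planted effect is large enough that the downscaling does not affect
power.

**What a green test does and does not establish.** The generator emulates
class mixtures, clone-size laws, usage bias, subset composition and
contig-level contamination. It does not emulate expression data, doublet
transcriptomes, sequencing error in junctions, batch effects, or
inter-sample chain sharing. Ground-truth recovery at zero noise
establishes that the pipeline's bookkeeping is exact — not that it would
be unconfounded on real data (see limitations).

# Numerical and degenerate-input choices

* Half-up rounding is implemented explicitly (R's `round` is
  banker's rounding) and used only for display columns.
* Empty samples (zero paired cells) are an error at summary time, not a
  row of NaNs.
* Empty usage or composition strata yield zero-count rows with absent
  frequencies rather than 0/0.
* Clonotype ids are deterministic (ordered by sample, class, decreasing
  size, then key), so identical inputs give identical tables; collapse
  output is sorted on (sample, barcode, chain key) making all stage
  outputs invariant under input row permutation.
* Derived per-sample seeds are kept below 2^31 − 1.

# Limitations

* **Doublets masquerade as dual cells.** Two cells under one barcode are
  indistinguishable from one dual cell at the repertoire level. The
  upstream workflow this package slots into removes expression-called
  doublets before the contig table is built; the generator exposes a
  `doubletRate` knob (default 0) to study the confounding, but the
  package itself cannot correct it.
* The `OTHERS`-inside-dual convention and the full-set clonotype
  definition are choices among defensible alternatives; both are
  configurable or documented where they bite.
* Total-barcode counts ("cells before pairing") depend on what upstream
  QC counted; this package reports its own total — barcodes with at least
  one functional contig — which need not match any published total
  exactly.
* Gene names are opaque strings: no IMGT validation or normalization is
  attempted, so pseudogene names pass through verbatim.
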