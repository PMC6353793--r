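---
title: "Inter-Organ Clone Tracking of CD8+ T cell repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inter-Organ Clone Tracking of CD8+ T cell repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(tcrioct)
```

## The analysis problem

Antitumor CD8+ T cell responses unfold across organs: clones are primed in
the tumor-draining lymph node (dLN), circulate through peripheral blood
(PBL), and infiltrate the tumor. Bulk TCR sequencing of sorted CD8+ T
cells from each compartment of the same animal yields one clonotype table
per sample — one row per clone with its read count, frequency, CDR3
nucleotide and amino-acid sequence, and IMGT V/D/J segment calls.

`tcrioct` analyzes such tables in three layers:

1. **Preprocessing** — removal of non-functional clones and normalization
   of sequencing coverage across samples;
2. **Single-repertoire structure** — clonality, diversity, rank-quantile
   statistics, V/J usage, rank-frequency distributions;
3. **Inter-Organ Clone Tracking (IOCT)** — identifying clonotypes shared
   among compartments of one mouse, their per-compartment frequencies,
   major/minor pattern classification, public-clone sharing across mice,
   and tracking of named clones of known specificity.

A synthetic study generator produces multi-mouse, multi-compartment data
with planted structure, so every stage of the pipeline can be validated
by parameter recovery without access to sequencing data.

## Clone identity

A clone is a set of TCR reads sharing a V segment, a J segment, and a
CDR3 sequence. Two identity levels are supported:

* **Nucleotide** (`mode = "nt"`, the default): V + J + CDR3 nucleotide
  sequence. Used within a mouse, where reads from the same cell lineage
  share nucleotides.
* **Amino acid** (`mode = "aa"`): V + J + CDR3 amino-acid sequence. Used
  across mice and for named clones, where convergent recombination
  produces synonymous nucleotide variants of the same receptor.

Segment names are compared at IMGT gene level: allele suffixes (`*01`)
are stripped before comparison (configurable). The D segment is carried
through but never participates in identity, since D calls are ambiguous
for many rearrangements and the identity definition above does not
include them. `collapse_by_key()` merges clones sharing a key, summing
counts and frequencies; it is idempotent and conserves totals.

## Preprocessing

**Non-functional filtering.** Clones whose CDR3 amino-acid sequence
contains a stop codon (`*`) or frameshift (`_`) marker carry no surface
receptor and are removed; frequencies of the survivors are recomputed
from surviving read counts. The marker set is configurable.

**Coverage normalization.** Coverage is defined as total reads divided by
the number of sorted starting T cells. Samples are normalized to a common
coverage — 9 reads/cell for TCRβ, 5 for TCRα — by drawing exactly
`round(coverage × cells)` reads (ties to even) *without replacement* from
the sample's read pool, i.e. a multivariate hypergeometric draw in which
each clone contributes `count` indistinguishable reads. This is the
standard semantics of repertoire downsampling tools; a with-replacement
(multinomial) mode exists behind `replace = TRUE`. Filtering precedes
downsampling in the standard pipeline. The two operations commute only in
expectation, not per-realization, which is why the pipeline fixes the
order. A sample whose read pool is smaller than the target triggers an
error carrying the deficit by default; `insufficient = "keep"` returns
the sample unchanged for permissive workflows.

The draw is implemented by sequential conditional univariate
hypergeometric sampling (`stats::rhyper`), which is exact, and is
deterministic given a seed. Unbiasedness — post-downsampling expected
frequencies equal pre-downsampling frequencies — is verified in the test
suite against the closed-form hypergeometric mean and variance over
1,000 seeds.

## Repertoire structure statistics

**Clonality** is 1 − Pielou's evenness:

$$\mathrm{clonality} = 1 + \frac{\sum_{i=1}^{n} p_i \ln p_i}{\ln n}$$

where $p_i$ is the frequency of clone $i$ among $n$ unique clones. It is
0 for a perfectly even repertoire and grows toward 1 as few clones
dominate; being normalized by $\ln n$ it is comparable between samples
with different clone counts. For $n = 1$ the expression is 0/0; the
package defines it as 1 (maximally uneven), documented and tested.
Natural logarithms are used throughout.

**Diversity** is the number of clones with frequency strictly above a
threshold, default 0.01% — a detection-robust count of
non-negligible clones rather than a raw richness estimate. Richness
estimators (Chao, Hill numbers, rarefaction) are deliberately out of
scope.

**Quantile statistics** rank clones by descending frequency and split the
ranks into five equal bins (top 20%, 20–40%, …, 80–100%); bin $k$ covers
ranks $(\lceil n(k-1)/5\rceil, \lceil nk/5\rceil]$. The combined
frequency per bin plus the individual top-5 clone frequencies summarize
how much of the repertoire its largest clones occupy. When 5 does not
divide $n$ the ceil rule makes bin sizes differ by one; in that case the
bin totals need not decrease monotonically (a one-clone bin can hold less
mass than a following two-clone bin), which is why the package asserts
monotonicity only for equal-size bins. Frequency ties at a bin boundary
follow the package's deterministic clone order (descending count, then
lexicographic by CDR3/V/J); no fractional splitting.

## Inter-Organ Clone Tracking

`build_overlap()` takes 2–3 repertoires from distinct compartments of one
mouse and tabulates the clones present in at least `min_compartments` of
them, with each clone's frequency in every compartment. Combined overlap
frequency per compartment is the sum of the overlapping clones'
frequencies *within that compartment's own normalization* — repertoires
are never pooled, because clone frequencies are only meaningful relative
to their own sample and repertoires differ strongly between individual
mice. Three-way overlap (`min_compartments = 3`) is by construction a
subset of every pairwise overlap, an invariant the tests assert. For
plotting, "top overlapping clones" are ranked by their maximum frequency
across compartments; the ranking axis is a package choice and is
configurable by ranking within one compartment via
`overlap_rank_frequency()`.

**Pattern classification.** In a compartment, a *major* clone has
frequency ≥ 0.1% and a *minor* clone < 0.1%; the boundary is inclusive
for major. Each dLN–tumor overlapping clone falls in exactly one of four
patterns (tumor-major/dLN-major, tumor-major/dLN-minor,
tumor-minor/dLN-major, tumor-minor/dLN-minor); `classify_patterns()`
reports the percentage of overlapping clones per pattern, which always
sums to 100.

**Public clones** are clonotypes (amino-acid identity) shared by at least
two mice in the same compartment; `public_clones()` reports, per mouse,
the combined frequency of its clones found in at least one other mouse.
`top_clone_heatmap_data()` lays out each mouse's top-10 clones across all
mice as a log10-frequency matrix with explicit `NA` for absence.

**Named clones.** `track_clone()` returns the summed frequency of all
repertoire clones matching a user-supplied (V, J, CDR3) record — e.g. a
transgenic melanoma-specific receptor — at either identity level;
`compare_tracked()` compares a clone's frequency between treatment groups
with a two-sided unpaired Student's t-test (pooled variance, matching the
study design it emulates; Welch's correction behind a flag). Group
summaries are mean ± SE with SE = SD/√n. The actual CDR3 sequences of
published reference clones are supplied by the user; the package ships
none.

## The synthetic study generator

`scenario_config()` + `generate_study()` emulate a two-group tumor-mouse
study. Per mouse and compartment, a repertoire is a mixture of:

* a **private background** of `n_clones` clones with power-law
  rank-frequency weights, exponent 1.0 in dLN/PBL and 1.5 in the tumor so
  the tumor is the most oligoclonal compartment, as observed in
  tumor-infiltrating repertoires;
* a **mouse-private shared pool** (default 150 clones, Zipf-weighted)
  present in all of that mouse's compartments, with per-compartment total
  weight 3.6% (dLN CD44hi), 10.8% (PBL) and 41.9% (tumor) — the reported
  combined inter-organ overlap frequencies of the control condition the
  generator emulates;
* a **compartment-specific public pool** (default 100 clones) shared by
  every mouse's corresponding compartment, with weights 23.1% (dLN),
  3.3% (PBL) and 48.2% (tumor), matching reported public-clone
  fractions. Public pools are compartment-specific and the shared pool is
  mouse-private because a single pool cannot satisfy both statistics
  simultaneously (the tumor's public fraction exceeds its within-mouse
  overlap fraction);
* two **spike-in clones** with fixed synthetic sequences: a dLN-planted
  clone at 0.6% (control) vs 3.0% (treated) emulating a
  transgene-tracked receptor, and a tumor-planted reactive clone at
  0.49% vs 4.5%. The treated tumor value is capped below the reported
  analogue so that the compartment's planted weights (shared + public +
  spikes) leave a feasible background budget;
* **nonfunctional contamination**: each background clone carries a stop
  or frameshift marker with probability 5%. Planted pool and spike
  clones stay functional so that parameter recovery is exact; the
  generator records the realized per-compartment renormalization factor
  so planted weights remain exactly recoverable after filtering.

The **treatment effect** multiplies the shared-pool size and the shared
pool's dLN weight (default ×5, the magnitude of the reported expansion of
the dLN–tumor overlap under treatment). It acts on the mechanism — more
clones trafficking between dLN and tumor, at higher dLN frequency — so
pipeline detection of the group difference is a genuine recovery test
rather than bookkeeping of a summary statistic.

CDR3s are random in-frame nucleotide strings (C…F/W framing, 8–18
codons) with deterministic translation, so both identity levels are
exercisable; 2% of shared-pool clones are emitted as two synonymous
nucleotide variants to exercise amino-acid collapsing. Read counts are
drawn multinomially at 12 reads/cell (above the ×9 normalization floor);
`sample_reads = FALSE` skips the multinomial stage and yields exact
planted frequencies. All randomness derives from one master seed;
per-mouse streams are sub-seeded so any mouse regenerates independently
and identically.

**What the generator does not emulate:** PCR amplification bias,
sequencing error and read-level quality structure (upstream of clonotype
tables), realistic V(D)J recombination statistics and CDR3 length/motif
distributions, biological correlation between public and
tumor-infiltrating status, and repertoire overlap *between* background
clones of different mice beyond the planted pools. Tests passing on
synthetic data therefore validate the computational pipeline — not the
biological fidelity of any particular dataset.

## Numerical choices

* Clone ordering everywhere: descending count, ties broken
  lexicographically by (CDR3, V, J) — all rankings reproducible across
  platforms.
* Downsampling target: `round(coverage × cells)`, ties to even.
* Frequency conservation in `collapse_by_key()` is exact to 1e-12;
  generated tables sum to 1 within 1e-9.
* Degenerate inputs: empty repertoires are rejected where a statistic is
  undefined (clonality, quantile statistics need ≥ 5 clones,
  all-nonfunctional filtering, empty overlap for pattern percentages)
  with typed conditions rather than `NA`s.
* Group aggregation is always mean ± SE across mice; unequal group sizes
  are handled naturally and per-metric `n` is reported. **No
  multiple-testing correction is applied** — p-values are per-metric
  Student's t-tests, mirroring the single-comparison reporting style of
  the study design this pipeline emulates; interpret accordingly.

## Problem sizes used in validation

The default scenario is 5 + 5 mice × 3 compartments with 4000/3000/1500
background clones and 10000/8000/4000 starting cells (dLN/PBL/tumor).
Pre-sampling recovery of planted counts and weights is exact at this
scale; post-sampling combined overlap frequencies are recovered within
2% relative error on group means. The 100-replicate directional check of
the treatment effect runs on a structurally identical scaled-down
scenario (400/300/200 background clones, 2 mice per group) — sizes
chosen so the whole validation suite runs comfortably on a laptop while
keeping every planted effect far above sampling noise.

## Known limitations

* Diversity and overlap counts depend on sequencing depth even after
  coverage normalization; comparisons are only meaningful between
  samples normalized to the same coverage.
* The clonality convention for n = 1 (value 1) is a boundary definition;
  single-clone samples should be interpreted with care.
* Overlap detection is exact-match by clone key; no CDR3
  sequence-similarity clustering for antigen inference is performed.
* No statistical model of overlap significance is provided; overlap
  counts are descriptive.
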