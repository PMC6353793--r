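# tcrioct — Inter-Organ Clone Tracking for TCR repertoires

`tcrioct` analyzes bulk T cell receptor (TCR) repertoires of CD8+ T
cells sampled from several tissue compartments of the same animal —
tumor-draining lymph node (dLN), peripheral blood (PBL), and tumor — to
follow individual T cell clones through the cancer-immunity cycle. It is
aimed at immunologists working with clonotype tables produced by
standard V(D)J assembly toolchains (one tab-separated table per sample:
read count, frequency, CDR3 nucleotide/amino-acid sequence, IMGT V/D/J
segments).

The package provides:

* **Preprocessing** — removal of non-functional clones (stop codon `*`
  or frameshift `_` in the CDR3) with renormalization, and coverage
  normalization by exact multivariate-hypergeometric downsampling to a
  fixed reads-per-cell coverage (×9 TCRβ, ×5 TCRα).
* **Repertoire statistics** — clonality as 1 − Pielou's evenness,

  clonality = 1 + (Σᵢ pᵢ ln pᵢ) / ln n,

  diversity (number of clones with frequency > 0.01%), rank-quantile
  statistics (combined frequency of the top 20%, 20–40%, … clones and
  the top-5 clones), V/J segment usage, and rank-frequency
  distributions.
* **Inter-Organ Clone Tracking (IOCT)** — tables of clones overlapping
  ≥ 2 (or all 3) compartments of one mouse with per-compartment
  frequencies; combined overlap frequencies; classification of dLN–tumor
  overlapping clones into four major/minor patterns at a 0.1% frequency
  threshold; public-clone fractions across mice (amino-acid identity);
  top-clone sharing matrices; and tracking of named clones by their
  (V, J, CDR3) identity, with group comparison by two-sided unpaired
  Student's t-tests.
* **A synthetic study generator** — multi-mouse, multi-compartment
  clonotype tables with planted shared pools, public pools, spike-in
  clones, nonfunctional contamination and a treatment effect, so the
  entire pipeline is testable by parameter recovery.
* **A pipeline orchestrator** (`run_study()`) and a thin command-line
  wrapper (`inst/cli/tcr-ioct.R`) with subcommands
  `simulate | filter | downsample | stats | overlap | track | run`.

Clone identity follows the field convention: same V segment, J segment
and CDR3 nucleotide sequence (within a mouse), or CDR3 amino-acid
sequence (across mice and for named clones). See the vignette
(`vignettes/inter-organ-clone-tracking.Rmd`) for the full model
description, parameter defaults, and design rationale.

## Worked example

Generate the default synthetic study (5 control + 5 anti-CD4-treated
mice, three compartments each) and run the full pipeline:

```r
library(tcrioct)

cfg    <- scenario_config(seed = 42L)
study  <- generate_study(cfg, file.path(tempdir(), "study"))
report <- run_study(study, run_config(seed = 42L))

gs <- report$group_stats
gs[gs$metric %in% c("dln_tumor_count", "dln_tumor_freq_dln",
                    "dln_tumor_freq_tumor"), ]
```

which prints:

```
   group               metric n         mean           se
    aCD4      dln_tumor_count 5 744.00000000 2.1213203436
    aCD4   dln_tumor_freq_dln 5   0.21625333 0.0007498510
    aCD4 dln_tumor_freq_tumor 5   0.46472222 0.0011698370
 control      dln_tumor_count 5 153.40000000 0.6782329983
 control   dln_tumor_freq_dln 5   0.04464889 0.0006855799
 control dln_tumor_freq_tumor 5   0.42496111 0.0016855321
```

Read: control mice share on average 153 clones between dLN CD44hi and
tumor, occupying ~4.5% of the dLN and ~42% of the tumor repertoire —
only a small fraction of the dLN repertoire participates in the tumor
response, but those clones dominate the tumor. Treated mice share ~744
clones at ~22% of the dLN: the planted treatment effect (a larger
dLN–tumor trafficking pool at higher dLN frequency) is recovered by the
pipeline, with

```r
report$comparisons[report$comparisons$metric == "dln_tumor_count", ]
#>          metric  group1 group2 n1 n2 mean1 mean2      p_value
#> dln_tumor_count control   aCD4  5  5 153.4   744 4.577405e-17
```

`run_study(..., out_dir = "report")` additionally writes the per-sample
statistics, per-mouse overlap tables, group summaries, t-tests, a
machine-readable `summary.json` and a run log.

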