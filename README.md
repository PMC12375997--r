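# lcprofiler

Consensus-matrix profiling of antibody light-chain (LC) repertoires on the
127-position IMGT scaffold.

## What it is for

In systemic AL amyloidosis a patient's monoclonal LC deposits as amyloid
fibrils; in multiple myeloma (MM) clonal LCs circulate at high levels but
rarely form amyloid. Which somatic residue changes tip an LC toward
aggregation is obscured by the diversity of LC sequences: every LC derives
from one germline IGKV/IGLV gene plus a personal set of changes, and what
counts as an unusual residue differs gene by gene. `lcprofiler` is for
researchers comparing monoclonal cohorts (AL, MM) against a polyclonal
repertoire reference, gene by gene, on the fixed IMGT scaffold.

The core objects and statistics:

* **Consensus matrix** — per gene and cohort, the 127 x 21 fractions
  $C_{ps} = n_s(p)/n$ of each residue (gap included as a 21st symbol) at
  each IMGT position; with difference matrices, per-position Gini
  diversity, position-wise Pearson correlation, Euclidean distances and
  hierarchical clustering, and "most-frequent-residue-removed" logo data.
* **Rarity classification** — a residue is *common* when its reference
  fraction is >= 10%, *uncommon* below, *rare* below 1%; per-sequence
  frequency profiles and per-position uncommon-carrier counts follow.
* **Enrichment** — 2x2 carrier tables between cohorts, summarized by the
  corrected proportion ratio
  `R = [(a+0.1)/(n1+0.2)] / [(c+0.1)/(n2+0.2)]`
  with Wald confidence intervals, two-sided p-values, Benjamini–Hochberg
  FDR within families, and a germline-only artifact filter for scans
  against much larger comparators.
* **Patterns** — a grammar for published residue changes (`X86N` gain,
  `ST20X` loss, `R25G`/`K56DE` exact, `P115PP` CDR3 proline insertion,
  `U52` any-uncommon) with gene eligibility derived from germline
  residues, never hard-coded.
* **Synthetic repertoires** — a seeded generator with germline backbones,
  allele polymorphism, position-biased residue changes and planted
  enrichment effects, used to validate calibration and power end to end.

## Worked example

A synthetic IGLV6-57-like analysis: a 20,000-sequence polyclonal reference
carrying an R25/G25 allele polymorphism at 6.6%, and a 150-sequence "AL"
cohort in which the variant allele is enriched (24%) and an eightfold
carrier-rate effect is planted at position 52.

```r
library(lcprofiler)

oas <- simulate_repertoire(oas_cfg)$set     # 20,000 sequences
ref <- build_consensus(oas)
al  <- simulate_repertoire(al_cfg)$set      # 150 sequences

scan <- scan_positions(al, ref, ref, germline,
                       comparison = "AL_vs_OAS", artifact_filter = TRUE)
subset(as.data.frame(scan),
       !excluded & !not_plotted & q < 0.05 & ratio > 1)
```

```
 position region   a  n1    c    n2 ratio ci_low ci_high        q
       25    FR1  46 150 2972 20000  2.07   1.62    2.63  2.7e-07
       52    FR2 104 150 1753 20000  7.91   7.04    8.87 5.9e-268
```

Both planted signals — and nothing else — are called: the allele-driven
enrichment at position 25 (ratio 2.07, close to the planted 24%/6.6%
carrier contrast after somatic noise) and the planted eightfold effect at
52 (estimated 7.91). For a single published contrast, e.g. glycine at
position 25 among IGLV6-57 LCs (33/137 AL carriers vs 5,958/90,110
polyclonal):

```r
tab <- carrier_table(33, 137, 5958, 90110)
signif(corrected_ratio(tab), 3)   # 3.65
wald_test(tab)                    # CI 2.71-4.91, p = 1.59e-17
```

A thin command-line front-end over the same functions is installed at
`inst/cli/lcprofiler` (`build-matrix`, `profile`, `scan`, `patterns`,
`cluster`, `simulate`).

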