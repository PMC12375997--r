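---
title: "Consensus-matrix profiling of antibody light chains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus-matrix profiling of antibody light chains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lcprofiler)
```

## The problem

Systemic AL amyloidosis is caused by a patient's single monoclonal antibody
light chain (LC) depositing as amyloid fibrils. Every patient's LC is
unique: it derives from one germline IGKV/IGLV gene and carries a personal
set of somatic residue changes, typically 5-15 per sequence. Because the
likelihood of each change depends on the germline gene's nucleotide
sequence, "wild-type vs mutant" is a poor frame for LC variation. This
package instead works with *residue frequencies*: for each germline gene, a
consensus matrix built from a large polyclonal repertoire gives the
fraction of sequences carrying each residue at each position, and residues
observed in a monoclonal LC are judged *common* or *uncommon* against that
reference.

All sequences live on the fixed 127-position IMGT scaffold for light
chains, with the gap treated as a first-class 21st symbol: conserved gaps
(e.g. positions 58-64, and 110-113 within CDR3) are genuine states, and
insertions into germline gaps are residue changes like any other.

## The model and statistics

**Consensus matrices.** For a set of $n$ aligned sequences from one gene
and cohort, the consensus matrix $C$ is $127 \times 21$ with
$C_{ps} = (\text{count of symbol } s \text{ at position } p)/n$. Rows sum
to 1 exactly. Cohorts too large to store as sequences (a polyclonal
reference may contain hundreds of thousands of sequences per gene) can be
supplied as a fraction matrix plus $n$; counts are reconstructed by
rounding with validation, which is exact whenever the fractions came from
counts.

**Diversity and comparison.** Per-position residue diversity is summarized
by the Gini coefficient of the 21 fractions. We use the sample-corrected
estimator (the mean-absolute-difference form multiplied by $n/(n-1)$ with
$n = 21$ symbols), because only the corrected form reaches exactly 1 for a
point mass and 0 for the uniform distribution, which are the interpretable
endpoints; the uncorrected form is available as an option. Cohorts are
compared by difference matrices (element-wise subtraction of fractions),
by per-position Pearson correlation of the two 21-entry residue
distributions (rho = 1 means identical distributions; positions where a
distribution is exactly uniform have zero variance and are flagged
undefined rather than given an arbitrary value), and by the Euclidean
(Frobenius) distance over all $127 \times 21$ cells, which feeds
agglomerative hierarchical clustering. Complete linkage is the default --
it is the default of the R `hclust` function and therefore the most likely
convention in prior work -- with average and single linkage available.
Distances are computed over fractions, not counts, since the matrices are
defined as fractions; counts are an option.

**Rarity.** A residue is *common* at a position when its reference
fraction is at least the uncommon cutoff (default 10%), *uncommon* below
it, and *rare* below the rare cutoff (default 1%); a residue never
observed in the reference is rare. The boundary is deliberately
asymmetric: exactly 10% is common. Gaps are classified like any residue,
so a deletion at a normally occupied position registers as uncommon, and a
germline gap is (usually) common for the gap symbol. Per-sequence
*frequency profiles* report, for all 127 positions, the reference fraction
of the residue the query carries -- the least common entries are the
natural candidates for destabilizing changes.

**Enrichment.** Cohorts are compared position-by-position (any uncommon
residue) or pattern-by-pattern (a specific residue change) through 2x2
carrier tables: $a$ of $n_1$ target sequences vs $c$ of $n_2$ comparator
sequences. The headline statistic is the corrected proportion ratio
$$ R = \frac{(a + \delta)/(n_1 + 2\delta)}{(c + \delta)/(n_2 + 2\delta)},
   \qquad \delta = 0.1, $$
with the additive correction applied to each of the four interior cells so
that zero cells never divide by zero. This functional form -- rather than
the textbook cross-product odds ratio, which is provided as an option --
is what reproduces the published worked examples this package regression-
tests against; for the rare-carrier regimes involved the two are nearly
identical, but the proportion-ratio form is what the reported values
follow, so it is the default and is labelled "ratio" throughout. The log
ratio's standard error defaults to the ratio-of-proportions form
$\sqrt{1/a' - 1/n_1' + 1/c' - 1/n_2'}$ on corrected counts (Woolf's
odds-ratio SE is an option), giving Wald confidence intervals
$\exp(\ln R \pm z\,\mathrm{se})$ and two-sided normal p-values. Because
the exact SE convention behind published p-values cannot be pinned down
from their printed precision, this package treats ratios as the
reproducible quantity and p-values as approximate.

**Multiple testing and artifacts.** P-values are adjusted by
Benjamini-Hochberg step-up within families -- one family per gene and
comparison for position scans, one per pattern table otherwise. Two
position classes are removed from the testable family: positions whose
germline residue is a gap (not plotted, following the convention for
per-position scans), and *germline-only artifacts* -- positions with
$R > 1$ where every target sequence carries exactly the germline residue,
a signal generated purely by the comparator's size and diversity. The
artifact rule only ever removes apparent enrichments, never depletions.

**Patterns.** Published residue changes are encoded as a small grammar:
`X37D` (gain of D from any other residue), `ST20X` (loss of a germline S
or T), `R25G`/`K56DE` (exact changes, possibly to a residue set),
`P115PP` (a second proline adjacent to the germline CDR3 proline with at
least one residue inserted into the 110-113 germline gap), and `U52` (any
uncommon residue at the position). Gene eligibility follows the published
convention: gain patterns exclude genes already carrying the gained
residue in germline, loss patterns require it; denominators are derived
from eligibility, never hard-coded. Two gap conventions are documented
and switchable: an observed gap counts as *losing* the germline residue
(a deletion is not the specified residue) but never as *gaining* one.
Adjacency for the proline-insertion rule is judged on occupied scaffold
slots, skipping gaps, because IMGT insertions need not be physically
adjacent in scaffold coordinates.

## The synthetic generator

Real inputs at publication scale (hundreds of monoclonal sequences per
gene; millions of polyclonal sequences) are not redistributable, so the
package ships a seeded generator that emulates their statistical
structure: germline backbones per gene, optional allele polymorphism
(sampled per sequence at configured frequencies, as for the R25/G25
polymorphism), independent per-position somatic residue changes with a
configurable rate profile, and planted enrichment effects with known
truth.

Defaults, chosen once as the study conditions: a mean of 10 residue
changes per sequence spread uniformly over the germline's occupied
positions (the literature range is 5-15), substitution uniform over the
19 non-germline residues with gap (deletion) probability 0.01, and
germline gaps at positions 58-64 and 110-113. A planted effect multiplies
one position's carrier rate by a factor and forces carriers to a single
specified residue, so the uncommon-carrier rate ratio against an
unplanted cohort equals the multiplier by construction -- this matches
the carrier-count statistics the scan measures, rather than perturbing
per-site substitution spectra.

What the generator does *not* emulate -- and therefore what passing tests
do not show about real data: gene- and position-specific hypermutation
spectra (changes here are independent and uniform over replacements),
clonal lineage structure, CDR3 length variation beyond the fixed scaffold,
and sequencing artifacts at the termini. Tests against the generator
validate the statistical machinery (calibration, power, ordering), not
biological conclusions.

Problem sizes used by the validation suite, chosen to mirror the regime
of a per-gene analysis while remaining quick to run: null calibration
uses 200 replicates of a 200-sequence target against a 20,000-sequence
reference; power uses 100 replicates with a tenfold planted effect at the
same sizes; multiplier-ordering uses 100 replicates of multipliers
{2, 5, 10} against 10,000-sequence comparators. Under these conditions
the suite requires a mean false-call proportion at or below 0.05, at
least 95% detection of the tenfold effect, and order-preserving ratio
estimates.

## Numerical and design choices

* IMGT region boundaries are configuration, not data: the defaults
  (FR1 1-26, CDR1 27-38, FR2 39-55, CDR2 56-65, FR3 66-104, CDR3 105-117,
  FR4 118-127) follow the IMGT unique-numbering convention, and every
  region-dependent output records the map used.
* Validation rejects, rather than imputes, any sequence with an ambiguity
  code, a wrong scaffold length, or an over-length CDR3 insertion;
  rejections are data (id + reason), not exceptions, and ingest reports
  always reconcile.
* Sequence-set deduplication is an explicit switch, default off, because
  whether duplicates should be removed per-sample or globally is a
  data-provenance question the package cannot decide.
* Logo data excludes the per-position maximum with an alphabetical
  tie-break (deterministic); remaining heights are raw fractions, so a
  position's letters sum to 1 minus the maximum fraction.
* The confidence level's normal quantile is computed exactly
  (`qnorm(0.975)` = 1.959964), not rounded to 1.96.
* Extreme Wald z-scores can underflow to p = 0; these are kept (BH handles
  zeros) rather than clamped.
* The generator draws sequences in index order from a single seeded
  stream, so increasing the cohort size appends sequences without
  reshuffling earlier ones.

## Known limitations

The package consumes pre-numbered, pre-aligned input; it does not
implement antibody numbering (ANARCI/High-VQuest remain upstream), does
not model nucleotide sequences or constant domains, and emits plot-ready
tables rather than rendered figures. P-values are Wald approximations and
degrade for very small cohorts (the smallest published comparators have
single-digit n); the corrected ratio remains well-defined there, which is
precisely why it is the reproducible quantity. Carrier-rate planting in
the generator caps at probability 1, so very large multipliers on high
base rates saturate.

## A worked example

```{r example, eval = FALSE}
library(lcprofiler)

# synthetic stand-ins for a monoclonal cohort and a polyclonal reference
gl  <- read_germline_fasta("germline.fasta")
ref <- read_consensus_tsv("IGLV6-57_OAS_consensus.tsv")
al  <- read_aligned_fasta("al.fasta", gene = "IGLV6-57", cohort = "AL")$set

# rarity profile of one sequence
prof <- frequency_profile(set_member(al, 1), ref)
head(prof[order(prof$frequency), ])

# per-position enrichment scan with artifact filtering
scan <- scan_positions(al, ref, ref,
                       reference_allele_of(gl, "IGLV6-57"),
                       comparison = "AL_vs_OAS", artifact_filter = TRUE)
subset(scan, q < 0.05 & ratio > 1)

# a published pattern, counted with derived eligibility
pat <- parse_pattern("R25G", gene_scope = "IGLV6-57")
count_pattern(pat, list(al), gl)
```
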