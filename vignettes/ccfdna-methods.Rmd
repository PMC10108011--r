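---
title: "Quantifying colon-derived cfDNA from bisulfite amplicon reads: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying colon-derived cfDNA from bisulfite amplicon reads: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfdna)
```

## The measurement model

Plasma cell-free DNA (cfDNA) is a tissue mixture. A locus that is
unmethylated in colon epithelium and methylated essentially everywhere else
acts as a counting assay for colon-derived molecules: after bisulfite
conversion, each sequenced molecule shows `TG` at a CpG it carried
unmethylated and `CG` at one it carried methylated. A molecule is scored as
colon-derived only when *every* CpG on it is unmethylated — the joint pattern
over 4–8 CpGs is what gives the assay its specificity, since a sporadic
single unmethylated CpG in a background molecule is far more likely than a
fully unmethylated haplotype.

For marker $j$ with $n_j$ accepted molecules of which $u_j$ are fully
unmethylated, the marker fraction is $\hat f_j = u_j / n_j$. With a measured
total cfDNA concentration $c$ (ng/ml) the tissue-derived concentration is

$$\hat{y}_j = \hat f_j \cdot c \cdot 303 \quad \text{[GE/ml]},$$

where 303 converts ng/ml to haploid genome equivalents per ml (one haploid
genome weighs about 3.3 pg; $1000/3.3 \approx 303$). The per-sample c-cfDNA
score is the arithmetic mean of $\hat y_j$ over markers with a defined
fraction. Pooling molecules across markers before taking the fraction would
weight markers by their (technical) read depth; the mean over marker-level
concentrations treats each amplicon as an independent estimate of the same
underlying quantity and is robust to one failed amplicon, whose absence is
reported rather than imputed as zero.

## Read processing choices

**Demultiplexing.** Reads are assigned to the unique barcode within a
Hamming distance of 1 (configurable) of their prefix; a prefix equidistant
from two barcodes is left unassigned — a tie is never guessed, because a
wrong marker assignment corrupts two markers at once.

**Alignment.** Each barcode-trimmed read is aligned end-to-end to the
*unconverted* amplicon reference under match 0, mismatch −6, gap open −5,
gap extend −3, with one asymmetry: read `T` opposite reference `C` scores as
a match. This makes fully converted reads, methylated reads (which retain
`C` at CpGs, a literal match) and everything in between align at their true
error cost, while a read `C` opposite reference `T` stays a mismatch —
C→T conversion happens on the molecule, never in reverse. A read is accepted
when its score is at least $-0.2 \times$ its length (inclusive: the
threshold is an attainable minimum), i.e. roughly one mismatch per 30 bp;
base qualities are never consulted. The scoring constants are configurable;
the defaults express the acceptance threshold in the conventional
end-to-end regime for this assay class.

Because amplicon reads overwhelmingly match the reference length and carry
only substitutions, the implementation evaluates the ungapped end-to-end
score first and invokes the full gapped aligner (Biostrings) only when the
ungapped score misses the threshold or the lengths differ. The acceptance
decision is unchanged by this (the optimal score can only exceed the
ungapped score, so an ungapped pass implies an overall pass); in the rare
case where a gapped alignment would rearrange bases around a CpG despite a
passing ungapped score, the ungapped readout is used — a deliberate
tie-break toward the simpler alignment, consistent with preferring
mismatches over gaps. Duplicate read sequences are collapsed before
alignment and expanded afterwards.

**CpG calls and the ambiguity rule.** At each CpG, `CG` → METHYLATED, `TG` →
UNMETHYLATED; any other dinucleotide, an `N`, a deletion, or an insertion
splitting the two bases → AMBIGUOUS. An AMBIGUOUS call makes the molecule
*not* fully unmethylated but keeps it in the denominator. This is the
conservative closure of the CG/TG rule: uncertainty can reduce, never
inflate, the estimated colon-derived signal. A marker with zero accepted
molecules reports an undefined fraction with a QC flag — never 0, which
would fabricate a negative result.

## The plasma read simulator

`simulate_sample_reads()` draws each molecule's origin (colon with
probability `colon_fraction`), starts colon molecules from the all-CpG
unmethylated template and background molecules from the all-CpG methylated
template, then applies three noise processes:

| parameter | meaning | default |
|---|---|---|
| `conversion_efficiency` | P(unmethylated C → T) | 0.995 |
| `inappropriate_conversion_rate` | P(methylated CpG C → T) | 0.005 |
| `seq_error_rate` | per-base substitution probability | 0.003 |

The defaults are routine figures for bisulfite kits and short-read
sequencers; they are stated here once and used as the simulator's standard
conditions. With substitution error 0 and inappropriate conversion 0, the
expected observed fraction is `colon_fraction × conversion_efficiency^k`
(`k` CpGs): each unconverted CpG on a colon molecule reads as `CG` and
demotes it. The test suite asserts this attenuation law at $n = 50{,}000$
molecules. Sequencing errors are substitutions only by default, which keeps
the acceptance-threshold arithmetic analytic; indels are not part of the
error model (the aligner still handles them when present in real data).
Qualities are written as a constant `I` because the pipeline ignores them.

What the simulator does **not** emulate: PCR duplicates and amplification
bias, UMI structure, fragment-length variation, partially methylated
background haplotypes (available via config extension, not default), and
real per-marker depth profiles. Passing tests therefore validate the
*computational* readout — demultiplexing, alignment, calling, counting,
unit conversion — not the wet-lab assay's analytical sensitivity.

## The cohort simulator

`simulate_cohort()` generates a cohort with the structure the response
analysis assumes. Defaults are the study conditions of a 37-patient
neoadjuvant-chemoradiation cohort: pathCR probability 7/37; TRG 1/2/3 split
11/11/8 among residual-disease patients; W2D1 c-cfDNA medians 8.6 (pathCR)
vs 57.7 (residual) copies/ml; relapse probability 8/30 (residual) and 1/7
(pathCR); an increase from W1D1 to W2D1 with probability 1 given relapse and
7/17 given no relapse; median time to relapse 20 months; follow-up censoring
uniform on 12–38.6 months (median 25.3). Weekly medians beyond W2D1 are free
parameters chosen to show the typical trend — a transient dip in responders,
a slow rise overall — and baseline medians (25 vs 45 copies/ml) encode
"responders lower at baseline" at a plausible scale; neither is a claim
about observed values.

Marginals are log-normal: strictly positive and heavy-tailed, matching the
order-of-magnitude spread between group medians; `log_sd = 1.0` by default.
The relapse coupling acts directly on the analyzed quantity: the increase
indicator is drawn from its conditional probability, and W2D1 is then drawn
from its group's log-normal *truncated* to the side of W1D1 the indicator
demands (exact inverse-CDF sampling). Consequences worth knowing:

- W1D1 values are exactly log-normal; the calibration test (sample median
  within 2% of the configured median at $n = 10{,}000$) is run there.
- The W2D1 marginal is distorted by the truncation whenever the configured
  increase probability differs from the natural probability implied by the
  two medians; medians configured for W2D1 are targets for the *untruncated*
  component, not guaranteed sample medians.
- At `log_sd = 0` every value collapses to its group median and the coupling
  cannot bind; dynamics then follow the median ordering.

## Statistical procedures

The module's contracts are fixed and each implementation is cross-checked in
the tests against a hand-written enumeration oracle:

- **Mann-Whitney U**: exact p by full enumeration when the smaller group has
  ≤ 8 observations and there are no ties; otherwise normal approximation
  with tie and continuity correction. One-sided use is restricted to the
  pre-specified direction "responders lower" in the baseline TRG comparison.
- **Fisher's exact test** (two-sided): sum of hypergeometric probabilities
  not exceeding the observed table's, with a $1 + 10^{-7}$ relative guard
  for floating-point ties; this convention reproduces the canonical
  p = .019 on the 7/7-vs-7/17 increase×relapse table.
- **ROC/AUC**: AUC is the concordance probability with ties counted ½
  (trapezoidal area); the 95% CI uses DeLong by default because it is
  deterministic — a seeded stratified bootstrap is available. The CI is
  clipped to $[0, 1]$ and ordered around the point estimate.
- **Kaplan-Meier / log-rank**: product-limit curves per group; log-rank
  chi-square with $k-1$ df. With no events anywhere the statistic is defined
  as 0 (p = 1) rather than NaN; a single censored subject yields a flat
  curve at 1.
- **Dynamics**: INCREASE iff the W2D1 value strictly exceeds baseline; a tie
  is NO_INCREASE, resolving the undefined case away from the
  negative-prognosis call. Patients missing either timepoint are excluded
  with a logged reason. The subgroup entering the increase×relapse table is
  an explicit argument, since reasonable analyses may restrict it (e.g. to
  residual-disease patients); the default is all classifiable patients.

No multiple-testing correction is applied — the report is a small set of
pre-specified analyses and carries the number of tests performed so a reader
can apply their own adjustment.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open throughout; amplicons are handled in
sequencing orientation only (single-strand assay). Acceptance at the score
threshold is inclusive. Alignment ties prefer mismatches over gaps (via the
ungapped-first evaluation); gap placement inside repeats is aligner-chosen
and CpG calls treat a split dinucleotide as AMBIGUOUS wherever the gap
lands. Empty FASTQ files, zero-molecule configs, zero-dispersion cohorts,
all-censored survival groups and single-class ROC inputs are all either
handled with defined semantics or rejected with a typed error — never
silently coerced.

All simulators consume an explicit integer seed and restore the caller's RNG
state; identical configuration implies byte-identical output files, which
the end-to-end CLI test verifies by hashing report bytes across two runs.

## Problem sizes used in validation

The test suite simulates up to 50,000 molecules per marker for parameter
recovery (spikes 0.001–0.2, 20 seeds each), sweeps every 2×2 table with all
margins ≤ 12 against the hypergeometric oracle, checks AUC against the
pairwise oracle on 100 random instances up to $n = 200$, and calibrates the
type-I error of the W2D1 comparison on 2,000 null cohorts (rejection rate
required in $[0.03, 0.07]$ at $\alpha = .05$). These sizes were chosen so
Monte-Carlo assertions sit at ≥ 3 standard errors from their thresholds.

## Known limitations

- Fixture amplicon sequences are synthetic; marker names are carried for
  interface realism only, and nothing is claimed about the real loci.
- The aligner is amplicon-scale (one reference per read); it is not a
  genome-scale bisulfite aligner.
- The cohort generator couples relapse to a single binary indicator, not to
  a latent tumor-kinetics model; it reproduces the analyzed contingency
  structure, not biological trajectories.
- Group-level statistics on 7-vs-30 samples have the usual small-sample
  caveats; the exact tests are exact, but power statements in the tests are
  regression guards for the simulator's default effect sizes, not clinical
  claims.
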