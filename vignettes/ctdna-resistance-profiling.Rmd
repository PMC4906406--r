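---
title: "Profiling EGFR-TKI resistance from plasma ctDNA: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling EGFR-TKI resistance from plasma ctDNA: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctdnaprof)
library(dplyr)
```

## The problem

Patients with *EGFR*-mutant non-small cell lung cancer who progress on a
third-generation, T790M-selective EGFR inhibitor do so through a
heterogeneous mix of mechanisms: copy-number gains in bypass receptor
kinases (*MET*, *ERBB2*, *EGFR* itself), new activating point mutations
(*PIK3CA*, *KRAS*, second-site *EGFR* mutations), and shifts in the
clonal balance between T790M-mutant and T790M-wild-type tumour cell
populations. Serial plasma sequencing of cell-free DNA (cfDNA) with a
targeted hybrid-capture panel can observe all of these at once — if the
quantitative machinery is careful about the things that make plasma
hard: tumour-derived DNA is a small, varying fraction of total cfDNA,
copy-number signal is diluted accordingly, and a mutation "missing" from
a sample may simply sit below the depth-limited detection floor.

`ctdnaprof` implements that machinery as a set of composable,
tibble-first functions: a depth-based copy-number index with empirically
calibrated detection thresholds, ctDNA-fraction estimation from truncal
or copy-number-corrected driver variant allele fractions (VAFs), the
T790M:activating-mutation clonal ratio with limit-of-detection
censoring, rule-based resistance-mechanism calling with innate/acquired
classification, and an in-silico spike-in benchmark that measures the
copy-number caller's sensitivity and specificity. A synthetic-cohort
generator reproduces the statistical structure these methods assume, so
the whole pipeline is testable end to end without patient data.

## The copy-number index

Per-region capture depth is the raw signal. For each sample, depth in
region $i$ is divided by the sample's selector-wide autosomal median
depth (removing library-size differences) and log2-transformed:

$$\hat d_i = \log_2\left(\frac{\mathrm{depth}_i}{\mathrm{median}_{j \in \mathrm{autosomes}}\,\mathrm{depth}_j}\right).$$

A cohort of healthy-control plasma samples (27 by default) provides, for
every region, a mean $\mu_i$ and standard deviation $\sigma_i$ of
$\hat d_i$, plus a Shapiro–Wilk normality p-value kept as QC metadata
(normality of normalized depths is what justifies a z-statistic
treatment; the QC value is stored, not used to exclude regions by
default). A patient sample's regions are then scored as
$z_i = (\hat d_i - \mu_i)/\sigma_i$, and for a gene $g$ covered by
$n_g$ regions the copy-number index is

$$C_g = \frac{\sum_{i \in g} z_i}{\sqrt{n_g}}.$$

This is an unweighted z-score combination in the style of Stouffer's
method, but the regions of one gene are not assumed independent, so
$C_g$ is *not* treated as a standard normal deviate. Instead each gene's
detection threshold $t_g$ is calibrated empirically: candidate
thresholds are the gene's observed control indices (plus a sentinel just
above the maximum), and $t_g$ is the smallest candidate whose in-control
false-positive rate under the rule $C_g \ge t_g$ is below
$\alpha = 0.05$. With 27 controls this lands on the largest observed
control index (an in-sample false-positive rate of 1/27 ≈ 3.7%). If no
finite candidate qualifies, the sentinel is returned and flagged.
Calibration is in-sample by default (fit and calibrate on the same
controls); refitting the model on the same matrix reproduces $\mu$,
$\sigma$ and $t$ exactly.

Two numerical choices matter here. Regions with zero depth map to an
explicit $-\infty$ sentinel at normalization and are excluded downstream
with a log message — zero is a real measurement and must not silently
become missing. Regions with $\sigma_i = 0$ (possible only in degenerate
cohorts) are excluded rather than floored, since a zero-variance region
makes $z$ undefined; a gene whose regions are all excluded is marked
uncallable. Losses are reported descriptively (the index is signed), but
only gains are ever called significant: thresholds are calibrated for
gains.

## From index to copy number

The linear relative depth of a gene, $r$, is the arithmetic mean over
its regions of $2^{\hat d_i - \mu_i}$ — linear because the underlying
mixture is linear in depth, and referenced to the control mean so that
fixed per-region capture-efficiency differences cancel. A plasma sample
with tumour genome-equivalent fraction $f$ and mean tumour copy number
$\mathrm{CN}$ in the gene satisfies

$$r = (1 - f) + f\,\frac{\mathrm{CN}}{2},$$

so a significant gain is converted to a **normalized copy number** by
inversion:

$$\mathrm{CN} = 2 + \frac{2(r - 1)}{f},$$

clipped below at zero. This is the mean copy number across all cells
contributing DNA to plasma; when the gain is subclonal it underestimates
the level inside the subclone. The conversion is only attempted when the
call is significant and $f$ is available, and samples whose
truncal/activating raw VAF falls below the 2% adequacy gate are marked
*inconclusive*: their copy-number analysis cannot rule a gain in or out.

## ctDNA fraction and the corrected activating VAF

A truncal *TP53* mutation (truncal in this tumour type) anchors the
tumour fraction: under the heterozygous-clonal assumption
$f = \min(1, 2\cdot\mathrm{VAF})$. Both the raw truncal VAF and the
doubled fraction are always reported, because some gates (the 2%
SCNA-adequacy gate) are expressed in raw VAF units; a
`ctdna_fraction_mode` of `"raw_vaf"` is available for workflows that
treat %ctDNA and VAF as synonyms.

Without *TP53*, the *EGFR*-activating mutation stands in — but its VAF
is inflated whenever *EGFR* itself carries a significant gain, because
the amplified allele is over-represented in plasma. The package models
the amplified copies as carrying the activating mutation, under which
the raw VAF is $v = f\,\mathrm{CN}/(2r)$; the heterozygous-equivalent
(corrected) VAF is then $v\,r/\mathrm{CN}$, which doubles back to $f$.
Since $\mathrm{CN}$ itself depends on $f$, the two are solved jointly,
giving the closed form $f = 1 + r(v - 1)$. Without a significant gain
the correction is the identity. The correction's copy configuration is
a declared model assumption — plasma sequencing alone cannot phase the
amplified copies — and it is recorded per sample. T790M is never
copy-number corrected (single-copy assumption).

## The T790M:activating ratio and censoring

The ratio of the T790M VAF to the corrected activating VAF tracks the
share of the tumour carried by the T790M subclone, independent of total
tumour burden. When T790M is undetected in a sample where the
activating mutation is present, its VAF is censored at the lower of:

1. the **limit-of-detection bound**: the smallest VAF $v$ at which at
   least $s$ supporting reads would be observed with 95% probability
   under a binomial model at the sequenced depth of the T790M locus
   (closed form $v = 1 - 0.05^{1/\mathrm{depth}}$ for $s = 1$; monotone
   bisection otherwise; default $s = 2$, reflecting a multi-read
   evidence requirement typical of deep targeted callers — the choice
   of $s$ is configurable since the evidence bar is not uniquely
   determined);
2. the corrected activating VAF itself (equivalent to assuming a ratio
   of 1).

A censored ratio is therefore an upper bound and never exceeds 1.
Patients are grouped at a ratio cut-point of 0.5 — the value an ROC
analysis against partial response recovers on cohorts with separated
low/high ratio groups; the package's `roc_cutpoint()` scans midpoints
between consecutive sorted unique ratios, maximizes Youden's J and
breaks ties toward the smallest candidate, so the result is
deterministic. Trajectory analysis (pretreatment → progression percent
change) requires T790M detectable pretreatment and the activating
mutation at both endpoints, and flags patients whose progression
activating VAF falls below 0.3% as not evaluable: at that level the
ratio change cannot be measured accurately (the floor is configurable).

## Resistance rules and timing

Because every patient in this setting already carries resistance
mechanisms to earlier therapy lines, a putative mechanism of resistance
to the current drug must show *positive selection*: it is called when it
is **emergent** (absent in pretreatment plasma, present at progression)
or **increasing** (its relative abundance — SNV VAF over the truncal
VAF, or normalized copy number for a gain — rises from pretreatment to
progression; any strict increase counts by default, with a fold-change
knob). Two carry-forward cases keep a pre-existing alteration on the
list when progression data cannot exclude it: a pretreatment gain whose
progression copy-number analysis is inconclusive (activating VAF below
the 2% gate), and a pretreatment SNV with no detectable ctDNA at
progression. T790M and the activating mutation themselves are excluded
as candidates (they are the drug's target), as is the truncal anchor.
Copy-number candidates are restricted by default to the receptor-kinase
genes the index is calibrated for (*EGFR*, *ERBB2*, *MET*); this also
bounds the contribution of threshold-level false positives to the call
set. Comparisons use the two endpoints only; intermediate timepoints
are reported descriptively, since trajectories through mid-treatment
nadirs are dominated by tumour-burden changes rather than selection.

Resistance timing splits at a progression-free survival of 3 months
(30.44 days/month): under 3 months is innate, otherwise acquired, with
the exact boundary assigned to acquired. Patients are categorized as
SCNA-only, SCNA+SNV or SNV-only, and the innate/acquired × category
contingency table is tested with the Freeman–Halton extension of
Fisher's exact test, implemented by full enumeration of tables with the
observed margins under the multivariate hypergeometric null
(probability ordering, with a 1e-7 relative tie tolerance guarding
floating-point probability ties). Enumeration is guarded at 10⁷ tables;
beyond that a seeded Monte-Carlo mode samples fixed-margin tables.
Group-level comparisons (best response by rank-sum, progression-free
survival by Kaplan–Meier/log-rank with censoring) delegate to standard
routines.

## The spike-in benchmark

Sensitivity of the copy-number caller is measured by mixing a
pure-tumour depth profile into each healthy-control background at
defined fractions. Both rows are first scaled to their own autosomal
median — a genome-equivalent equalization, so a more deeply sequenced
tumour library does not contribute more genomes than intended — then
mixed linearly and rescaled to the control's original median. This
depth-space construction preserves exactly the quantity the index
consumes (the original experiment mixed raw reads; the equalization
step here is the depth-space interpretation of that protocol's input
adjustment, and externally computed depth matrices from a real spike
experiment can be fed through the same grid runner). The default
dilution series is 0.1–10% over twelve fractions; with 27 backgrounds
that is 324 spiked samples per profile. Specificity comes from scoring
unspiked controls — held-out ones by default, with in-sample scoring
available (in-sample specificity is 26/27 per callable gene by
construction of the threshold).

## What the synthetic generator emulates — and what it does not

The generator reproduces the structure the methods assume:

* **Selector**: ~115 non-overlapping regions over 20 genes by default
  (12 for *EGFR*, 10 for *MET*), laid out at plausible coordinates. The
  background genes matter: an amplified gene must remain a small
  minority of the selector or the selector-wide median normalization
  absorbs part of its own signal. Real panels are larger still, so the
  synthetic selector is conservative in this respect.
* **Control depths**: depth(s, i) = mean_depth × e_i × 2^(σ·ε), with
  per-region capture efficiencies e_i drawn once per configuration
  (log2 sd 0.25) and shared by all samples — normalization must remove
  sample effects, not region effects — and ε standard normal. Defaults:
  27 controls, 5,500× mean depth, σ = 0.10. The magnitude of σ is a
  free parameter of the generator (real control cohorts pin it
  empirically); 0.10 makes a 10× gain detectable at ≥2% ctDNA, the
  regime the methods target.
* **Tumour samples**: gene depth follows the linear mixture above;
  variant alt reads are binomial at the realized locus depth (a
  beta-binomial overdispersion knob exists, default off).
* **Patient series**: named scenarios (T790M-subclone depletion,
  emergent *MET* gain, increasing *PIK3CA* subclone, mixed mechanisms,
  null) with ground-truth labels attached, so rule recovery is
  measurable. The depletion scenario moves the T790M clone fraction
  from ~0.85 to ~0.25 of the tumour, a median ratio drop above 50%.

All randomness flows through one seeded generator; stage-local seeds
are derived deterministically from the global seed and a stage label,
so adding a stage never reshuffles another stage's draws, and identical
seeds give identical outputs byte for byte.

Deliberately **not** modelled: GC-content and mappability bias,
fragment-size structure, sequencing error (so a single alt read is
always real here — detection in synthetic data reduces to alt_reads ≥
1), UMI/duplication structure, correlated region noise, and germline
SNP background beyond what the filtering rules need. Consequently,
passing tests demonstrate that the *computations* are correct and
internally consistent under the declared noise model — not that the
noise model captures every property of real cfDNA. Two practical
corollaries: real control indices are typically overdispersed relative
to the synthetic ones (correlated capture noise), which pushes real
calibrated thresholds higher than synthetic ones; and synthetic
germline filtering is exercised by construction rather than by realistic
SNP contamination.

## Known limitations

* **Threshold sampling variance.** A threshold calibrated as the
  maximum of 27 control indices is an order statistic with substantial
  sampling noise: held-out false-positive rates scatter around the
  design rate (~4–5% on average) with a standard deviation of a few
  percent, and an unlucky control draw yields a permissive threshold.
  This is inherent to the calibration rule at this cohort size; the
  property tests therefore pool replicate calibrations, and specificity
  estimates from any single cohort should be read with binomial *and*
  calibration error in mind.
* **Gains only, gene-level only.** Losses are never called, and the
  index cannot distinguish focal amplification from broader polysomy.
* **Subclonal gains are averaged.** Normalized copy number is a mean
  over contributing cells.
* **False-positive floor in mechanism calls.** With per-gene
  false-positive rates near α, emergent-SCNA precision is bounded by
  the number of candidate genes; the default three-gene restriction
  keeps the expected contamination near one call per ~7 patients.
* **Phasing is out of scope.** Cis/trans relationships between
  second-site mutations are data statements, not computations.

## Problem sizes used by the test-suite and benchmark

The packaged tests run the full spike grid (27 backgrounds × 12
fractions), recover planted copy numbers and tumour fractions over 100
replicate samples, run the depletion scenario as 100 replicate cohorts
of 35 patients, check the index's null distribution on a 3,000-sample
control cohort, and verify the exact test against the reference r×c
implementation on every 2×3 table with total count ≤ 12. These sizes
were chosen to keep Monte-Carlo error well below the margins being
asserted while remaining comfortable to run routinely.
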