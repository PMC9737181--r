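---
title: "Methods: shallow-WGS aneuploidy screening with an ensemble of dosage Z statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shallow-WGS aneuploidy screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuscreen)
```

# The screening problem

Cell-free DNA in maternal plasma is a mixture of maternal and fetal
(placental) fragments. If the fetus carries a trisomy of chromosome $c$ and
the fetal fraction of plasma DNA is $\mathrm{ff}$, the expected share of
reads mapping to $c$ rises by the mixture factor

$$\frac{(1-\mathrm{ff}) \cdot 2 + \mathrm{ff}\cdot 3}{2} = 1 + \mathrm{ff}/2,$$

i.e. a 5% relative increase at a typical 10% fetal fraction — under 0.1
percentage points of absolute dosage shift for chromosome 21. Detecting this
reliably from a shallow (well below 1×) whole-genome sequencing run requires
careful normalization against a euploid reference cohort. `aneuscreen`
fits that normalization and three complementary dosage statistics on the
reference cohort, then combines them in a cross-validated logistic model.

# Preprocessing

Reads are counted into fixed 50 kb bins (BED-convention half-open
intervals; a read belongs to the bin containing its leftmost mapped base).
Only primary, non-duplicate, non-supplementary alignments with mapping
quality at least 30 are counted. Two corrections follow:

**GC correction.** The default method groups autosomal bins into GC strata
of width 0.01 (merging strata with fewer than 50 bins into the stratum of
nearest mean GC, so weights are never estimated from a handful of bins) and
scales each sample's counts in stratum $g$ by
$w_g = \bar{x}_{\text{all}}/\bar{x}_g$. These ratio weights are exactly
reproducible, preserve each sample's grand total, and make the correction
idempotent. A per-sample LOESS alternative (`method = "loess"`, span 0.3)
is provided for cohorts with strongly nonlinear bias. Correction is
per-sample by default — each sample's own GC curve is used, as amplification
bias varies between libraries — with a cohort-level curve available via
`gcScope = "cohort"`. Bins with unknown GC (more than 50% assembly-gap N
bases) are excluded outright.

**χ² variation reduction.** Some bins vary across euploid samples far more
than counting noise allows (mappability artifacts, recurrent CNVs). After
normalizing every reference sample to the cohort mean total, bin $i$ with
cross-sample expectation $e_i$ gets
$\chi^2_i = \sum_s (x_{si}-e_i)^2/e_i$ and the scaled statistic
$q_i = \chi^2_i/(n-1)$. Bins with $q_i$ above the cutoff
$q^\* = \mathrm{qchisq}(0.9999,\, n-1)/(n-1)$ are down-weighted
multiplicatively by $q^\*/q_i$; the same fixed weights are applied to test
samples. The 0.9999 quantile keeps the expected number of false down-weights
near zero for tens of thousands of bins while still catching the strongly
overdispersed ones; the multiplicative rule shrinks rather than discards
information, and weights are by construction in $(0,1]$. Bins with zero
expectation are excluded.

# The three dosage statistics

All three are fitted on the corrected reference counts for target
chromosomes 13, 18 and 21. Sex chromosomes are excluded everywhere (fetal
sex confounds X/Y dosage); sample standard deviations use the $n-1$
denominator throughout.

**STD (standard Z-score).** The chromosomal fraction
$f_c = \sum_{i \in c} x_i / \sum_{i \in \text{autosomes}} x_i$ is
standardized against the reference cohort: $z = (f_c - \mu_c)/\sigma_c$.

**NCV (normalized chromosome value).** The ratio
$R_c = \text{count}(c)/\text{count}(D_c)$ cancels depth exactly and, with a
well-chosen denominator set $D_c$, much of the shared technical variation.
$D_c$ is the subset of non-target autosomes (13, 18 and 21 are never
eligible) of size at most 9 minimizing the reference coefficient of
variation of $R_c$. The default search is greedy forward selection,
stopping when no addition strictly reduces the CV (ties prefer the smaller
set, then the lower-numbered chromosome); exhaustive enumeration over all
subsets is available (`strategy = "exhaustive"`) and serves as the oracle in
the tests. Forward selection is a heuristic: on unstructured toy data with
very few reference samples it can miss the exhaustive optimum, but on
depth-structured data of the kind the statistic is designed for — a shared
per-sample depth factor plus roughly independent per-chromosome noise — the
optimal sets are nested and the two searches agree, which is what the test
fixtures verify.

**WSRB (within-sample reference bin).** For each scored bin $i$ on a target
chromosome, the $k = 100$ bins on non-target autosomes with the most
similar depth-normalized behaviour across the reference cohort (smallest
sum of squared differences between sample-normalized count profiles; ties
broken by genomic order) form its reference set. The within-sample ratio
$t_i = x_i / \sum_{j \in N_i} x_j$ is standardized by the reference mean and
SD of $t_i$, and the per-bin values are Stouffer-combined,
$S = \sum_i z_i/\sqrt{m}$. Because bin-level $z_i$ are mildly positively
correlated — neighbor sets overlap, and bins share GC-stratum correction
noise — the raw $S$ is overdispersed under the null (its SD exceeds 1), so
$S$ is recalibrated against the reference cohort's own Stouffer values:
$z = (S - \mu_S)/\sigma_S$. This final standardization is what keeps the
"z ≥ 3" rule meaningful for all three statistics; it is the same device
modern WGS copy-number callers use for their aggregate statistics. Bins
whose reference ratio SD falls below `sdFloor` are dropped from scoring;
$k$ is capped (with a warning) by the number of available candidate bins.

**Call rule.** A chromosome with $z \ge 3.0$ is called trisomic — the
boundary value itself calls trisomy, while the ensemble's probability rule
below is strict (`p > 0.5`); the two rules deliberately treat their
boundaries differently, following their published wording.

# The logistic ensemble

Each (sample, target chromosome) pair is one decision; a 109-sample study
yields 327 decisions. The three Z values (optionally plus sample-level GC%
and fetal fraction%) enter a binary logistic regression fitted by
iteratively reweighted least squares (convergence when the largest
coefficient update falls below $10^{-8}$, at most 100 iterations). One
pooled model spans the three chromosomes — the Z statistics are already on a
common scale, and pooling triples the effective training size; per-chromosome
labels are available in the feature table if separate models are wanted.

Near-separable feature tables are expected — trisomic Z values sit far from
the euploid cloud — so complete or quasi-separation (non-convergence or a
diverging coefficient norm) is detected and handled by refitting with a tiny
ridge penalty ($10^{-6}$ on the non-intercept coefficients), flagged as
`converged = FALSE` in the returned model. The penalty makes the fit
reproducible without materially moving the decision boundary.

Evaluation is leave-one-out cross-validation with folds defined by sample:
all three chromosome rows of the held-out sample are predicted by a model
fitted on the other samples' rows, preventing within-sample leakage. The
procedure is deterministic. Metrics (accuracy, sensitivity, specificity,
PPV, NPV) are reported from confusion counts, rounded half-up to 3 decimals
in written tables; a metric with a zero denominator is reported as
undefined (`NA`), never as 0. ROC AUC uses the rank (Mann–Whitney) form with
ties counted ½.

# The cohort simulator

`simulateCohort()` generates the data every other module is tested on. Per
bin, GC is drawn from a Beta distribution with mean 0.41, smoothed along the
genome with a 5-bin moving average (GC is locally autocorrelated at the
50 kb scale) and clipped to [0.2, 0.8]. Expected bin rates are proportional
to bin width times a quadratic amplification-efficiency curve peaking at GC
0.41 (amplitude 0.3, floored at 0.1). Counts are negative-binomial with
size 200 (variance/mean ≈ 1.35 at the default depth — shallow-WGS bins are
mildly overdispersed, and the χ² reduction needs heterogeneity to act on);
a random 2% of bins get their size divided by 20 (variance/mean ≈ 8),
emulating recurrent artifact bins. A trisomic test sample has its affected
chromosome's rates lifted by $1+\mathrm{ff}/2$ before renormalization.
Euploid fetal fractions follow Normal(11%, 3.5%) truncated to [1, 25]% —
first-trimester cohorts centre near 11–12%. All randomness flows from one
seed.

Defaults are desk-scale: hg19 autosome lengths divided by 20 (≈ 2,900 bins
of 50 kb) and 200,000 reads per sample, giving the same per-bin depth as a
2-million-read full-genome run; `scaleFactor = 1` with 2,000,000 reads is
the full-scale configuration. Note that chromosome-level signal-to-noise is
governed by total reads, not by per-bin depth: at 200,000 reads the
chromosome-21 fraction has a counting-noise CV near 2%, so a 15%-fetal-
fraction trisomy 21 sits only ≈ 3–4 SD above the euploid mean. The
simulator reproduces that arithmetic faithfully; perfect per-cohort
sensitivity at that depth is not a property of the method and the test suite
documents the achieved operating point rather than asserting one the
physics does not support.

What the simulator does *not* emulate: inter-sample biological variation
beyond fetal fraction (maternal CNVs, confined placental mosaicism),
GC-bias curves that differ between samples, fragment-length effects,
mappability structure, twins, and mosaic trisomies. Passing tests therefore
demonstrate the statistical machinery under controlled noise, not clinical
performance on real cohorts.

# Numerical and design choices

- Coordinates are 0-based half-open on disk (BED) and 1-based inside R
  (GRanges); bin ids `"chrom:start-end"` use the BED convention.
- GC strata assignment depends only on the grid, never on counts, so
  reference and test samples share the same strata deterministically.
- Per-sample normalization before the χ² statistic scales every sample to
  the cohort mean total; the dosage statistics themselves are
  depth-invariant (fractions and ratios), so this target only affects the
  χ² fit.
- The greedy/exhaustive NCV tie-breaks (smaller set, then lexicographic
  chromosome order) make model fits bit-reproducible.
- WSRB neighbor ties are broken by genomic order; a test-sample bin whose
  neighbor-set count is zero is skipped, and a chromosome with no scorable
  bins is an error rather than a silent zero.
- Degenerate inputs fail loudly: zero-SD reference fractions or ratios,
  single-class labels, all-identical reference cohorts, zero autosomal
  totals, and missing BAM indexes are all errors with specific messages.

Problem sizes in the test suite were chosen to keep the default run around
half a minute: toy grids of 10–120 bins for the hand-verifiable oracles, a
100-reference / 60-test desk-scale cohort for null calibration, 50-sample
cohorts for the fetal-fraction trend, and five seeded 30/30 cohorts for the
end-to-end harness.

# Known limitations

- Whole-chromosome dosage only: no segmental CNVs, no microdeletions, no
  sex-chromosome aneuploidies.
- Fetal fraction is an input (metadata or simulator truth), not estimated
  from the counts.
- The WSRB implementation is a faithful re-derivation of the within-sample
  reference-bin idea (squared-distance neighbor search, Stouffer
  aggregation, reference recalibration), not a line-by-line port of any
  particular tool.
- Mosaic trisomies — dosage shifts below the fitted noise floor — are
  missed by construction; this is a limitation of the underlying assay, not
  of the implementation.
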