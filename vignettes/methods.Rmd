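---
title: "Profiling anti-proliferative response to aromatase inhibition: methods and design"
author: "EndoResist authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling anti-proliferative response to aromatase inhibition: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EndoResist)
```

## The problem

In postmenopausal ER+HER2- breast cancer, two weeks of neoadjuvant
aromatase inhibitor (AI) treatment suppresses tumour proliferation in most
patients, measured as the proportional change in the Ki67
immunohistochemistry index between a baseline biopsy and surgery. A
minority of tumours barely respond. EndoResist implements an analysis
pipeline for asking *what distinguishes poor responders*: it selects good
and poor responders from paired Ki67, stratifies poor responders by ESR1
expression, calls intrinsic molecular subtypes with a cross-platform
calibration, scores expression signatures, runs negative-binomial
differential expression, and compares somatic mutations and copy-number
alterations between response groups. Because the motivating cohort data are
access-controlled, the package ships a synthetic-cohort generator with
complete ground truth; every stage is exercised and validated on simulated
data.

## Responder selection

The proportional Ki67 change is `100 * (2wk - baseline) / baseline`.
Eligibility requires ER+, HER2-, paired Ki67 values, and baseline Ki67
strictly above 10% (the strict inequality matters at the boundary and is
tested). Poor responders (PRs) are the eligible patients at or above the
85th linear-interpolation sample quantile of the change (the worst 15% of
anti-proliferative response); ties at the threshold are all included and
the realized fraction reported. Good responders (GRs) are drawn from the
patients below the median change, matched 1:1 to the PR counts within
baseline Ki67 categories so GRs are not biased toward indolent
low-proliferation tumours. Category boundaries are half-open --
[10, 20), [20, 30), [30, 100] -- which avoids double counting; the source
demographics express the same bands without boundary rules. Matching
within category is uniform random under a seed, emulating category
matching without reimplementing any proprietary matcher; when a category's
GR pool is smaller than its PR count the category is under-matched with a
warning. PRs are further stratified at log2 normalized ESR1 counts of 12;
the boundary value 12 is assigned HIGH (the threshold's source states
"above and below" without deciding the boundary). Stromal TILs are
categorized low (< 11), intermediate (11-59) and high (>= 60); 60 goes to
high.

## Intrinsic subtyping and the calibration search

Subtype calls are nearest-centroid: Spearman rank correlation of a
centered sample profile to each of the four centroids (LumA, LumB, HER2e,
Basal) over the shared panel genes, label = argmax, confidence = the
maximum correlation. Rank correlation makes calls invariant to any
strictly monotone per-sample transform; Pearson is available as a switch.
Ties resolve to the fixed subtype order with a tie flag, and constant
profiles are flagged unclassifiable rather than called.

Centering is where cross-platform subtyping lives or dies. The baseline is
whole-cohort gene-level median centering. That baseline silently assumes
the cohort's subtype composition matches the population the centroids were
built from; in an ER+HER2- cohort skewed to ~85% luminal tumours the
per-gene median sits at the luminal profile, and centered luminal samples
collapse toward zero on exactly the genes that distinguish them. The
calibration search fixes this: each iteration draws k (5-15) of the
externally subtyped reference samples, draws a training subset matched to
the composition of their reference calls, sets the per-gene centering
vector to mean(study subset) - mean(training subset), classifies all
reference samples after centering, and records the concordance with the
reference calls. The argmax-concordance centering vector over many
iterations (default 50,000; configurable up to millions) is the
calibration factor applied to the whole cohort. Ties break toward higher
mean assigned-centroid correlation, then the earliest iteration. The
subset means use the arithmetic mean (the search's definition), while the
naive baseline uses the median; both are exported.

Two conventions keep the scales coherent. The training matrix is
gene-median-centered internally before centroids are built and before
subset means are taken -- the standard convention for centroid reference
files -- so the mean-difference centering lands study data on the centroid
scale. And because the same constant per-gene vector added to both study
and training matrices cancels in the centering vector, calibrated calls
are invariant to any such offset (tested). Segment-level coordinates
elsewhere in the package are held as GRanges, 1-based closed -- the
Bioconductor convention, which coincides with the SEG convention, so no
conversion is needed at the boundary.

The k-subset is drawn from the reference samples only: their subtype calls
exist, so composition matching is well defined; drawing from unsubtyped
cohort samples would make the target composition unobservable. The
reported confidence is the maximum Spearman correlation; a published
high-confidence threshold of 0.95 for an assay-specific probability is
exposed as a threshold parameter without asserting the two scales are
equivalent. The inner loop (50,000 iterations x reference samples x
50-gene rank correlations) is compiled C++ driven by R's RNG, so results
reproduce exactly from `set.seed()`.

## Differential expression

`nbWaldTest` is a compact negative-binomial GLM pipeline, deliberately not
a clone of any existing package: per-gene NB GLMs with log link and
size-factor offsets (median-of-ratios size factors, geometric mean 1, with
a positive-counts fallback), gene-wise dispersion by adjusted profile
likelihood (a Cox-Reid-style `-0.5 log det(X'WX)` term offsets the bias
from estimating two means), a parametric trend `a0 + a1/mean` fitted by
robust regression, log-scale shrinkage of gene-wise estimates toward the
trend with fixed weight 0.5 (geometric averaging keeps dispersions
positive and never crosses the trend), and a Wald test on the group
coefficient with Benjamini-Hochberg correction. There is no outlier
handling, independent filtering, or fold-change shrinkage. Validation is
by calibration, not numerical identity to any package: on 10,000 null NB
genes at 20 vs 20 the fraction of p < 0.05 must sit in 0.05 +/- 0.01, and
2% spiked genes at |log2 FC| = 2 (balanced up/down so size factors stay
honest) must be detected at FDR < 0.05 with power > 0.9; fold changes are
additionally cross-checked against an established NB GLM implementation on
true signals. Genes with all-zero counts in one group get a 0.5-count
continuity offset applied to the whole fit (estimate, SE and p), because
the uncorrected Wald statistic is degenerate there; such genes are flagged
`zero_group`.

The expressed-gene filter is a simplified filterByExpr-style rule: CPM at
least `min_count / median library size * 1e6` in at least as many samples
as the smallest group, and total count at least 15.

## Signature scoring

`ssgseaScore` walks the expression ranking of one sample and accumulates
the weighted in-set ECDF (weights rank^alpha, alpha = 0.25 by default,
normalized over the set) minus the uniform out-of-set ECDF; the score is
the sum over all positions. It depends on ranks only. Ties order
deterministically by gene identifier so running sums are reproducible.
`prerankedGsea` uses the weighted Kolmogorov-Smirnov statistic (weight =
|statistic|) with a gene-permutation null; NES = ES / mean(|null ES| of
the same sign) and BH FDR across sets. The HOXB13/IL17BR (H/I) ratio is
the difference of the two genes' log2 normalized values -- the published
assay's proprietary scale is not reproduced, so only the direction of
group differences is comparable, not the magnitudes. Immune deconvolution
gene sets are consumed as GMT collections and scored by ssGSEA; the
curation of those sets is not reimplemented. Covariate-score correlations
(estradiol, TILs) use Spearman with BH across sets after applying the
exclusion rule (estradiol above 130 pmol/L is implausibly premenopausal
and dropped).

## Genomic alterations

Somatic mutations are retained when VAF >= 0.05, alternative reads >= 5,
consequence high or moderate, and population allele frequency below 1e-5
-- conjunctive, order-independent filters with a per-rule removal log.
Burden (TMB) is retained mutations per tumour; group comparison is
Mann-Whitney. Per-gene prevalence comparisons use two-sided Fisher tests
on (mutated, wild-type) x group with BH, skipping genes below 3 mutated
samples to avoid degenerate tables. Copy-number segments are called gain
at log2 ratio >= 0.2 and loss at <= -0.2 (boundary inclusive); the
upstream assay's HMM states are not published, so threshold calls are an
approximation and both thresholds are configurable. Purity/ploidy
correction is deliberately omitted (not described for the motivating
analysis). Calls are binned on a 3-Mbp tiling by majority overlap (exact
ties go neutral; uncovered bins are NA), compared per bin and direction by
Fisher + BH. Chromosomal instability is the fraction of covered genome
with a non-neutral call, invariant to segment splitting. Compound TP53
status requires both a retained TP53 mutation and a loss-called segment
overlapping the TP53 locus (default hg38 chr17:7,668,421-7,687,490,
configurable).

## The synthetic cohort: what it emulates

The generator's defaults are the study conditions the analysis assumes.
Subtype composition is skewed luminal (42/43/8/7% LumA/LumB/HER2e/Basal,
85% luminal) against a balanced training set. Subtype expression signal is
drawn through four latent axes (luminal/ER, proliferation, HER2,
basal-keratin) with per-gene loadings: genes in a module are correlated,
within-subtype heterogeneity is shared across the module (latent sd 0.35),
and LumA/LumB form a proliferation continuum rather than separated point
clouds -- this is what makes naive median centering measurably fallible
under composition skew, as in real data. A per-gene platform offset
(sd 0.8 by default) separates the study from the training scale. ESR1 is a
two-component log2 mixture (low mode 9.5 +/- 0.8, high mode 13.2 +/- 0.5,
10% low by default) defined on the observed study scale, so the ESR1 row
carries no platform offset. Counts are negative binomial with mean
`library factor x 2^(log2 expression)` and dispersion 0.05.

Resistance is Bernoulli with logit = intercept + configured log-odds
effects of low ESR1 (2.0), HER2e (1.0), Basal (1.5), TP53 mutation (0.8)
and the latent immune score (0.5/sd); the intercept is solved numerically
on the realized covariates so the marginal resistant fraction hits its
target (0.15, mirroring the poor-responder selection fraction). No
data-generating model is published for this; this one makes every reported
association reproducible in expectation. Ki67 at two weeks is
`baseline x (1 + pc/100)` clipped to [0, 100], with pc uniform on
(-100, -80) for sensitive and (-48, +184) for resistant tumours, spanning
the published ranges (the published poor-responder "range 48% to 184%"
printed beside a median of -14% is read as -48..+184). Baseline Ki67 is
per-subtype log-normal (medians 18-40%, higher in non-luminal subtypes).
Plasma estradiol is log-normal (median 38 pmol/L, log-sd 0.6) with a
-0.35 log shift in resistant samples; a few draws exceed 130 pmol/L and
exercise the exclusion rule. TILs are zero-inflated Beta on [0, 60] with
the Beta mean coupled to the immune score -- a modelling choice, since only
category boundaries are published. Mutations follow configured ER+-typical
prevalences (PIK3CA 0.35, TP53 0.24, CDH1/KMT2C/GATA3 0.10, MAP3K1 0.09,
plus a background panel totalling ~2.7 mutations/tumour); TP53-mutant
tumours carry 1.5x co-mutations with base rates rescaled so each gene's
marginal prevalence stays at its configured value. The mutation table also
contains artifact rows that deliberately fail exactly one somatic filter.
Copy-number segments partition 22 hg38-like autosomes at random
breakpoints with 6% gain / 6% loss per background segment, plus dedicated
TP53-locus and chr6q segments whose loss/gain probabilities are enriched
in resistant tumours (0.18 to 0.35 and 0.08 to 0.25).

What the generator does *not* emulate: correlation between low ESR1 and
basal subtype (drawn independently for parameter identifiability), read-
level artifacts, isoform structure, batch effects beyond the single
platform shift, tumour purity, and any spatial structure. Passing tests
therefore demonstrate that the algorithms recover known structure under
the stated statistical assumptions -- not that they are robust to every
artefact of real FFPE RNA-seq.

## Problem sizes and numerical choices

The bundled validation runs at desk scale, chosen so the full suite
completes in minutes: calibration parameter recovery uses 20 cohorts of
n = 300 with 59 reference calls at 3% label error and 50,000 search
iterations per cohort (the argmax stabilizes far below millions of
iterations on synthetic data); differential-expression calibration uses
10,000 genes at 20 vs 20; the end-to-end run uses n = 400. Dispersion
optimization is vectorized golden-section search on log dispersion in
[1e-6, 10] to 1e-4; IRLS uses closed-form 2x2 solves with damped steps and
a mean cap at 1e12 for separation. Two-sided Fisher p-values sum
hypergeometric point probabilities <= observed with 1e-7 relative slack.
The Mann-Whitney exact path (n <= 8 per group, no ties) enumerates the U
distribution by the standard recursion; otherwise a tie-corrected normal
approximation with continuity correction is used. Quantiles are
linear-interpolation sample quantiles (type 7).

## Known limitations

The calibration search explores uniformly at random; no early stopping or
importance sampling. The DE module is two-group only -- paired
within-patient modelling of on-treatment change is out of scope. H/I
magnitudes are not comparable to the published index scale. CNA calling
from log2 ratios ignores purity and ploidy. The demographic-table age
category test construction is level-vs-rest; one published age-category
p-value is not reproducible from any obvious 2x2/4x2 construction of the
printed counts and is not asserted anywhere.
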