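---
title: "Methods: quantitative myopathology and multi-omic comparison of nemaline myopathies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative myopathology and multi-omic comparison of nemaline myopathies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

rodomics is a tested re-implementation of the computational core of a
comparative study design for nemaline myopathies: quantitative muscle
morphometry by stereological sampling, label-free proteomic differential
abundance from laser-capture microdissected tissue, signed-rank gene-set
enrichment, immunoglobulin spectral-count comparison, and
proteome–transcriptome integration. Inherited nemaline myopathy (iNM) is a
genetic disorder of the sarcomeric thin filament; sporadic late-onset
nemaline myopathy (SLONM) is an acquired, potentially treatable mimic often
accompanied by a monoclonal gammopathy. Both are defined by nemaline rods —
Z-disc-derived protein aggregates in muscle fibers — so quantitative
criteria that separate the two are clinically valuable.

Patient data cannot be redistributed, so every stage here runs on synthetic
data with planted ground truth. The generators are first-class, tested code:
their role is to make each downstream claim falsifiable (calibration,
recovery, bias), not to reproduce any cohort's numbers.

This vignette records the models, the parameter choices that matter, the
numerical conventions, and the design decisions that were genuinely open.

## Synthetic muscle sections

`generate_section()` builds a fiber map: a rectangular section tiled by
non-overlapping fiber cross-sections. Fiber outlines are the Voronoi cells
of a jittered square grid — computed exactly by clipping each seed point's
neighbourhood with perpendicular-bisector half-planes — then shrunk toward
their centroids to leave endomysial gaps. Jitter is bounded at 30% of the
grid pitch so that all true Voronoi neighbours lie within three pitches,
which makes the neighbourhood clipping exact rather than approximate. The
default pitch of 65–70 µm gives fiber diameters in the tens of micrometres,
the normal adult range.

Per-fiber annotations:

* `has_rods` is Bernoulli with the group's rod prevalence. Defaults (53%
  iNM, 11% SLONM) are group means reported for real cohorts, used here as
  generator settings, not as ground truth to be reproduced.
* Rod-positive fibers are scaled relative to rod-negative ones so that the
  expected diameter ratio equals `size_ratio_by_group` (defaults 1.12 and
  0.60: rod fibers slightly larger in iNM, markedly atrophic in SLONM).
  Because both classes receive the same multiplicative size jitter, the
  ratio of expectations is exact by construction.
* Each rod-positive fiber draws a spatial pattern from the group's mix. Rod
  marks are points: `subsarcolemmal` places them within 15% of the
  equivalent radius from the boundary, `central` within 30% of the
  equivalent radius around the centroid, `diffuse` uniformly. These bands
  are exactly the quantities the classifier inverts, so
  classifier-invertibility is a meaningful test (≥ 95% agreement is asserted
  in the suite; disagreements come only from the 80% majority rule meeting
  finite rod counts).
* Lesion flags (necrotic, regenerating) are Bernoulli per fiber; "atrophic
  fibers filled with rods" are rod-positive fibers additionally shrunk to
  35% size and packed with ≥ 20 rods, at a group-specific rate (rare in
  iNM, common in SLONM).

The per-sample pattern mixes are set so iNM sections show aggregated
(central/subsarcolemmal) rods and SLONM sections predominantly diffuse rods.
Sample-level pattern percentages in real cohorts are reported per biopsy,
not per fiber, so the per-fiber mixes are a modelling choice.

## Synthetic omics

`generate_intensity_matrix()` draws feature baselines
$\mu_i \sim N(\texttt{base\_log2\_mean}, \texttt{base\_log2\_sd})$ and cell
values $x_{ij} = \mu_i + \beta_i\,[j \in \text{group 2}] + \varepsilon_{ij}$
with $\varepsilon_{ij} \sim N(0, \texttt{noise\_sd})$. `noise_sd`
(default 0.5 on the log2 scale) is the replicate-level variation the
per-feature model must overcome; the published parameter set for this kind
of data has no explicit noise term, so the default was chosen as a typical
between-biopsy CV for label-free MS1 intensities.

Missingness is left-censored (MNAR), the regime of label-free MS: a cell is
missing with probability $\operatorname{logit}^{-1}((t - x_{ij})/s)$, a
*soft* threshold (scale $s = 0.5$ log2 units) rather than a hard cut — a
hard cut would make imputation trivially invertible and untestable. The
threshold $t$ is solved numerically so the mean missing probability over the
realized matrix equals `censor_quantile` exactly, which keeps the marginal
missing rate testable at binomial precision.

Planted effects are placed on the *detectable mid-range* of the abundance
distribution: above twice the censoring quantile and below the 90th
percentile of baselines. Both bounds are scientific choices. The lower bound
exists because an effect on a protein censored in every sample of both
groups is not expressed in the measured data at all — no method could
recover it, and its real-data analogue would never appear in a results
table. The upper bound exists because quantile normalization is rank-based:
a strong planted shift that crosses the sparse extreme tail of the
distribution reshuffles top ranks group-specifically and displaces bystander
features by the large inter-order-statistic gaps there. That artifact is a
genuine property of quantile normalization worth knowing about, but it is
not the recovery property the benchmarks measure; keeping planted effects
off the extreme top (where 16-fold-regulated targets are biologically
implausible anyway) separates the two. The count generator applies the same
principle: planted families are drawn from rates above the 20th percentile,
since bottom-rate families sit at the two-unique-peptide presence floor.

`generate_count_table()` draws spectral counts negative-binomially with mean
$r_i T_j$ (family rate × per-sample total) and variance
$\phi \cdot \text{mean}$; $\phi = 1$ degenerates to Poisson exactly. Family
rates are log-normal around $2\times10^{-4}$ of total spectra, giving median
counts near 10 at the default 50 000 spectra per sample.

`generate_paired_omics()` builds a protein arm (with censoring) and a
complete log2 expression arm over one gene universe whose planted sets
intersect in exactly `n_shared_targets` features with concordant directions
— the ground truth for the integration stage.

All generators derive their randomness from one seed; `child_seed()` maps
(seed, component-name) to a fixed 31-bit child seed so any stage can be
re-run in isolation and reproduce the full-pipeline output.

## Stereological morphometry

`plan_sampling()` realizes systematic uniform random sampling: square
counting frames of 100, 200 or 400 µm on a grid with spacing in
[800, 2000] µm and uniform random x/y offsets. The frame size is the
smallest whose expected fiber count (density × area) lies in [4, 20]; the
spacing targets ≈ 25 sites. A fiber is counted when its area centroid falls
in a frame's half-open square $[x, x+s) \times [y, y+s)$ — chosen over
Gundersen forbidden-line counting because centroid-in-half-open-tile is
provably unbiased for centroid-defined sampling and makes exhaustive tiling
(spacing = frame size, zero offset) an exact partition, which the suite
exploits as an equality-with-census test.

"Minimum cross-sectional diameter" is the minimum Feret (caliper) diameter,
computed on the convex hull by rotating calipers; the convex hull makes the
measure robust to boundary concavities of the shrunken polygons, matching
the usual morphometric reading.

`classify_rod_distribution()` calls a fiber subsarcolemmal if ≥ 80% of rod
points lie within 0.15·r~eq~ of the boundary, central if ≥ 80% lie within
0.30·r~eq~ of the centroid, else diffuse; exact ties resolve subsarcolemmal
before central. "Atrophic fibers filled with rods" is operationalized with
two explicit cutoffs — diameter below half the sample's median rod-negative
diameter and ≥ 20 rods — because the real feature is identified visually;
both cutoffs are arguments. A sample reports every pattern carried by at
least 10% of its rod-positive fibers, mirroring the observation that more
than one distribution may be seen per biopsy.

Group comparison uses the two tests named for this kind of data: two-sided
pooled-variance Student t for continuous metrics and chi-square *without*
continuity correction on 2 × 2 presence tables. Zero pooled variance reports
a missing p value rather than a fabricated one. Because mean-of-sample-means
and pooled-fiber proportions genuinely differ (biopsies contribute unequal
fiber counts), summaries expose per-sample values and the comparison works
on sample-level means.

## Label-free differential abundance

The pipeline is imputation → log2 → quantile normalization → per-feature
model, in that order.

*Imputation.* "Bottom five percentiles" is read literally: the donor pool is
the multiset of observed intensities at or below the pooled 5th percentile
(linear-interpolation percentile) of *all* samples, and each missing cell
receives one uniform draw from it. Pooling is matrix-wide, not per sample,
following the description of an overall intensity distribution; a single
imputation realization per run with a recorded seed matches the
single-matrix workflow. The suite asserts the bound (every imputed value ≤
the pooled 5th percentile) and uniformity over the pool on every run.

*Quantile normalization.* Classical: rank r in every sample is replaced by
the across-sample mean of rank-r values; tied values receive the mean of the
reference values at their joint positions. Tie dialects differ between
implementations, so the convention is both documented and cross-checked
against an independent reference implementation in the suite.

*Per-feature model.* Each feature is fit with a Gaussian linear model with a
mean per group against the intercept-only null; the ANOVA contrast yields
$F = t^2$ on (1, n−2) df exactly in the two-group case, so p values come
from the F distribution, not a deviance approximation. log2 fold change is
group 2 minus group 1 on the normalized scale. BH adjustment and the
significance rule — adjusted p < 0.05 **and** |log2FC| > 1, both strict —
are separate, reusable steps. The identical engine is applied to log-scale
transcriptomic matrices (skipping imputation and the log2 step); the
original transcriptomic test statistic is unspecified in the source design,
so the shared Gaussian engine is a documented stand-in for applying the same
thresholds, not a claim about the original analysis.

## Preranked enrichment

Rank scores are $\operatorname{sign}(\log_2 FC) \cdot (-\log_2 p)$. Zero p
values are clamped to a tenth of the smallest positive p so scores stay
finite; clamped features are flagged. Duplicate gene symbols keep the entry
with the largest magnitude; ordering ties break lexicographically so the
ranking is total and deterministic.

The enrichment score is the classical weighted Kolmogorov–Smirnov running
sum: hits advance by $|s|^w / \sum_{set} |s|^w$ (weight 1 by default,
0 for the unweighted statistic), misses retreat by $1/(N - N_{set})$, and ES
is the signed maximum-magnitude deviation. Exact magnitude ties between the
positive and negative extreme (possible because miss steps are rational)
resolve to the positive side, a convention shared by the test oracle. The
null is gene-set permutation — random same-size gene sets — because a
preranked input has no sample labels to permute. NES divides ES by the mean
magnitude of same-sign null scores; the FDR q pools null and observed NES
within each sign class and is forced monotone non-increasing in |NES| (from
the strongest set downward, q can only grow). Selection is q ≤ 0.05,
non-strict. No numerical parity with any specific release of the original
enrichment software is claimed; the engine's contract is the oracle
equivalence of ES, null calibration, and planted-signal recovery that the
suite tests. Curated pathway collections are not bundled (licensing and
versioning); tests and the demo use synthetic GMT files.

## Immunoglobulin spectral counts

Chain families present with ≥ 2 unique peptides in at least one sample are
retained; families present in only one group are flagged
`exclusive_to_group` and reported descriptively rather than tested, since a
rate test against structural zeros answers a different question.

Both tracks share one mean model: counts with a log(total spectra) offset
and a group term. The Poisson track is the likelihood-ratio chi-square on
1 df. The quasi-likelihood track scales the deviance drop by a
Pearson-residual dispersion and refers it to an F distribution. Per-family
dispersions estimated on n − 2 df are noisy, so they are moderated across
families by empirical-Bayes squeezing (`limma::squeezeVar`), with the prior
degrees of freedom added to the F denominator — the quasi-likelihood F-test
in the form the count-omics field uses it. When dispersion is truly 1 the
moderated estimate concentrates at 1 and the two tracks converge; under real
overdispersion the quasi track is systematically the more stringent one, the
ordering the dual-FDR report is designed to show. Whether the original
method used a quasi-Poisson or negative-binomial working model is unknown;
the choice is isolated behind `quasi_likelihood_test()`.

BH is applied within each track separately by the same `adjust_bh()` used
everywhere; the differential call is made on the quasi track, with
Poisson-only passes reported as trend-level.

## Integration

`overlap_targets()` intersects the significant sets of the two arms after
optional protein-to-gene mapping, reports per-target fold changes of both
arms and their direction concordance, and counts the exclusive sides.
Concordance is reported, never used as a membership filter — the overlap is
a descriptive Venn, and discordant overlaps are themselves informative
(e.g. relocalization without expression change).

## Orchestration and reproducibility

`run_all()` validates the whole configuration before any stage runs,
executes generate → morphometry → protein DE → enrichment → counts →
integration with per-stage child seeds, writes every artifact as plain text
with numbers at 10 significant digits (so checksums are stable across
platforms), and finishes with a JSON manifest of outputs and md5 sums.
Running the same configuration twice yields byte-identical outputs; the
suite asserts this on the shipped demo configuration.

## Problem sizes, tolerances, degenerate inputs

The suite exercises: 5000-feature matrices at 10 samples per group for
calibration and recovery (20 seeds; sensitivity and observed FDR measured at
the strict dual threshold); 2000-feature paired designs at effect 4 for
integration recovery (20 seeds); ~2100-fiber sections with 200 random-offset
sampling replicates for estimator bias (3 SE tolerance); 1000 permutations
for planted-set enrichment and 200 for null calibration; 500 families at 20
samples per group for the Poisson/quasi convergence bound. Oracle
equivalences use 1e-10–1e-12 tolerances; the Feret check runs against an
angular-scan oracle refined locally around its minimum because the width
function has a kink there and a fixed 3600-angle grid alone is only accurate
to ~1e-4.

Degenerate inputs have defined behaviour throughout: zero prevalence, zero
censoring and dispersion 1 produce exact corresponding structure; flat
features report F = 0, p = 1 while zero-residual-variance features with
distinct means report a missing p and a flag; all-missing features are
imputed wholesale and flagged; empty count tables and empty overlaps return
empty, well-typed results.

## What the synthetic data does not emulate

Fiber outlines are convex-ish Voronoi cells: no real segmentation noise,
split/merged fibers, freezing artifacts or fascicle architecture. Intensity
noise is homoscedastic Gaussian on the log scale with independent features:
no correlated complexes, batch effects, or peptide-level roll-up structure.
Counts are independent across families; real immunoglobulin variable-region
counts are clonally correlated within a patient. Passing tests therefore
demonstrate that the implementations are correct and calibrated under the
stated models — not that the pipeline's power on real cohorts matches the
synthetic numbers.

## Worked example

```{r, eval = FALSE}
library(rodomics)

cfg <- read_config(system.file("extdata", "demo_config.yaml",
                               package = "rodomics"))
run_all(cfg, out_dir = "demo_out")
# demo_out/ now holds fiber maps (GeoJSON), matrices and design (TSV),
# per-sample morphometry, group comparison, DE tables, enrichment results,
# immunoglobulin dual-FDR table, the overlap report and manifest.json
```
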