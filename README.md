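# rodomics

Quantitative myopathology and multi-omic comparison of nemaline myopathies,
as a reusable, tested R pipeline.

Nemaline myopathies are defined by nemaline rods — aggregates of Z-disc and
thin-filament proteins inside muscle fibers. The inherited form (iNM, e.g.
*ACTA1*/*NEB* mutations) and the sporadic late-onset form (SLONM, acquired,
often with a monoclonal gammopathy) can mimic each other clinically, yet
SLONM may respond to immunotherapy while iNM does not. Distinguishing them
quantitatively — from biopsy morphometry and from molecular profiles of the
rod regions — is the problem this package addresses, for muscle pathologists
and computational biologists who want the analysis machinery without access
to patient data.

The pipeline has six cooperating parts:

* **Synthetic data with planted truth** — fiber maps (Voronoi-cell fiber
  geometry, per-fiber rod annotations and spatial patterns, lesion flags),
  log-normal protein-intensity matrices with intensity-dependent
  left-censored missingness (MNAR), overdispersed spectral-count tables, and
  paired proteome/transcriptome designs with a known shared-target set.
* **Stereological morphometry** — systematic uniform random sampling with
  counting frames (smallest frame of 100/200/400 µm giving 4–20 expected
  fibers per site, spacing in 800–2000 µm, random offsets), minimum Feret
  fiber diameters by rotating calipers, rod-distribution classification
  (subsarcolemmal / central / diffuse), and two-group statistics (pooled
  Student t, chi-square without continuity correction).
* **Label-free differential abundance** — missing values imputed by uniform
  draws from the pooled bottom five percentiles, log2 + quantile
  normalization, then per-protein Gaussian linear models where the ANOVA
  contrast against the null model gives F = t² on (1, n−2) df; BH
  adjustment; significant ⇔ adjusted p < 0.05 and |log2FC| > 1 (strict).
  The same engine applies the thresholds to log-scale expression matrices.
* **Preranked enrichment** — rank score sign(log2FC)·(−log2 p), the weighted
  Kolmogorov–Smirnov running-sum enrichment score, a gene-permutation null,
  NES, and a sign-pooled FDR q with selection at q ≤ 0.05.
* **Immunoglobulin spectral counts** — ≥ 2-unique-peptide presence filter,
  Poisson likelihood-ratio and moderated quasi-likelihood F tests with
  total-spectra offsets, and side-by-side Poisson/quasi FDR tracks (the
  quasi track is the stringent one under overdispersion).
* **Integration** — overlap of significant proteins and genes with
  per-target direction concordance and Venn counts.

A single YAML config drives the whole chain (`run_all()`), all randomness
derives from one seed, and every output is plain text with stable checksums.

## Worked example

Generate an iNM-like section, sample it stereologically, and summarize:

```r
library(rodomics)
cp <- cohort_params()                       # group settings (iNM vs SLONM)
m  <- generate_section(cp, "iNM", seed = 42)
m
#> fiber_map: 2116 fibers (1097 rod+), section 3000 x 3000 um, group iNM
plan <- plan_sampling(m, seed = 1)          # frame 200 um, spacing 800 um
summarize_sample(sample_fibers(m, plan))
#> morphometry_summary: 152 fibers, 53.3% rod+, size ratio 1.12, patterns {central, subsarcolemmal}
```

The sampled estimate (53.3% rod-positive, size ratio 1.12) agrees with the
generator's iNM settings (prevalence 0.53, ratio 1.12) — the stereological
estimator is unbiased, which the test suite verifies over 200 random-offset
replicates.

Paired omics with three planted shared targets, recovered end to end:

```r
p2  <- generate_paired_omics(
  omics_params(n_features = 2000, n_per_group = 10, frac_affected = 0.01,
               effect_log2fc = 4, censor_quantile = 0.1, seed = 42),
  n_shared_targets = 3)
dep <- run_de(p2$proteomics$intensities, p2$proteomics$groups, seed = 2)
der <- run_de(p2$rna$log2, p2$rna$groups, log_transform = FALSE)
overlap_targets(dep, der)
#> overlap_report: 3 common, 17 protein-only, 17 gene-only (0 unmapped)
#>        gene protein_log2fc gene_log2fc concordant
#> 1 GENE00023      -2.487500   -4.287105       TRUE
#> 2 GENE00479       4.076740    3.706594       TRUE
#> 3 GENE01447      -3.095408   -4.062686       TRUE
```

The three recovered targets are exactly the planted shared set
(`p2$shared`), all direction-concordant — the synthetic analogue of finding
a small set of targets common to the proteomic and transcriptomic arms.

The full pipeline on the shipped demo configuration:

```r
cfg <- read_config(system.file("extdata", "demo_config.yaml", package = "rodomics"))
run_all(cfg, out_dir = "demo_out")
```

writes fiber maps (GeoJSON), intensity/count matrices and design files
(TSV), per-sample and group-level morphometry, DE tables, enrichment
results, the dual-FDR immunoglobulin table, the overlap report, and a
`manifest.json` with md5 checksums; re-running the same config reproduces
every byte.

See the methods vignette (`vignettes/rodomics-methods.Rmd`) for the models,
parameter defaults and numerical conventions.

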