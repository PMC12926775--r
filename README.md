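# clusterscan

Detecting short-interval longitudinal cortical atrophy from
**cluster-scanned** structural MRI — many short scans per visit, pooled
statistically so that changes of a few hundredths of a millimetre over 3-6
months become detectable in a single patient.

Single-scan cortical-thickness estimates carry 2-5% measurement error,
about the size of a full year of atrophy in symptomatic AD or FTLD. The
design this package analyses collects up to 32 fast structural scans per
timepoint (2 days × 2 sessions × 8 scans) at baseline, 3 months, and
6 months, and asks — per participant — whether phenotypically vulnerable
("core atrophy") cortex thins faster than spared sensorimotor ("control")
cortex.

The package is aimed at neuroimaging statisticians and methodologists: it
implements the full analysis chain against tidy scan-level thickness
tables (surface reconstruction is upstream and out of scope), plus a
synthetic-data module with known ground truth so every stage is testable
without any MRI download.

## The models in brief

- **W-scores.** Per unit *i*, controls give an OLS fit
  `T = β0 + β1·Age + β2·Sex + ε`; a participant's deviation is
  `W = (T − T̂)/SD_i`. Core ROI: connected clusters of vertices with
  `W < −2` (an explicit size/parcel rule replaces manual curation);
  control ROI: pre/postcentral vertices with `W ≥ −0.25`.
- **Motion QC.** Per TR, rigid head movement is summarized as the RMS
  displacement of a 64-mm solid sphere,
  `sqrt(r²/5 · tr(AᵀA) + ‖Ac + t‖²)` with `A = R − I`; per scan, RMS
  displacement per minute (RMSpm). Scans with RMSpm > 10 mm/min are
  discarded.
- **Atrophy model.** Per participant, REML fit of
  `thickness ~ Timepoint × ROI + RMSpm` with nested random intercepts for
  scans within sessions within days and ROI×Timepoint-stratified residual
  variances; likelihood-ratio choice against a scans-only structure;
  estimated marginal means, Bonferroni-adjusted pairwise (family 6,
  per-test .008) and interaction contrasts (family 3, .017). The REML
  engine is authored in the package and cross-checked against
  `nlme`/`emmeans` in the test suite.
- **Vertex-wise maps** inside the core mask with a singular-fit fallback
  cascade (nested → scans-only → fixed-only), significant where
  `p_main < .05` and `p_pair < .017`.
- **Precision analysis.** Bootstrap percent-deviation curves over 1-32
  scans per timepoint against a 10,000-replicate reference rate, with a
  sustained-diminishing-returns plateau rule (<5% improvement for two
  consecutive steps).

## Worked example

```r
library(clusterscan)

sim <- generate_cluster_dataset(synthetic_truth(), design = c(3, 2, 2, 8), seed = 42)
qc  <- filter_scans(sim$dataset, threshold = 10)

full   <- fit_lme(qc$dataset, random = "nested")
simple <- fit_lme(qc$dataset, random = "scan")
lrt <- lrt_random_structure(full, simple)   # p = 0.109 -> retain "scan"
fit <- if (lrt$retain == "scan") simple else full
fit
#> Linear mixed-effects fit (REML), 190 observations
#>   random: scan | residual strata: roi_timepoint | logLik(REML) = 467.877
#>   variance components (SD, mm): scan = 0.01088
#>   residual SD = 0.01368 mm; stratum weights: core.BL = 1, control.BL = 1.09, ...
```

One scan of 96 exceeded the 10 mm/min motion threshold (hence 190 rows),
and the day/session components were small enough that the scans-only
random structure is retained. Estimated marginal means and core-ROI
contrasts:

```r
estimated_marginal_means(fit)
#>   timepoint     roi   emm       se df lower upper
#> 1        BL    core 1.783 0.003152 92 1.777 1.790
#> 2        M3    core 1.766 0.002852 92 1.760 1.772
#> 3        M6    core 1.739 0.002826 92 1.734 1.745
#> 4        BL control 2.351 0.003333 92 2.344 2.357
#> 5        M3 control 2.353 0.003569 92 2.346 2.360
#> 6        M6 control 2.345 0.003689 92 2.338 2.353

subset(as.data.frame(pairwise_contrasts(fit)), roi == "core")
#>         label  delta   lower  upper     t df p_adjusted
#>       BL - M3 0.0173 0.00884 0.0258  4.06 91   6.20e-04
#>       BL - M6 0.0443 0.03589 0.0527 10.45 91   1.78e-16
#>       M3 - M6 0.0270 0.01905 0.0350  6.74 91   8.62e-09

percent_change(estimated_marginal_means(fit), c("BL", "M6"), "core")
#> [1] -2.5
```

The generating truth was a 0.041-mm (−2.3%) 6-month core decline; the fit
estimates 0.0443 mm with a CI that covers the truth, a significant
core-vs-control interaction over every interval, and −2.5% change. The
precision curve says pooling stops paying off at 13 scans per timepoint:

```r
deviation_curve(scan_values(qc$dataset, "BL", "core"),
                scan_values(qc$dataset, "M6", "core"),
                B = 10000, seed = 42, label = "BL - M6")
#> Precision curve [BL - M6]: reference rate = 0.0449 mm, B = 10000, k = 1..32
#>   plateau at 13 scans/timepoint (mean deviation 11.67%)
```

`run_demo("out", seed = 1)` executes the whole pipeline (simulate →
normative fit → W-scores → ROIs → motion QC → mixed model → vertex-wise
maps → precision curves) and writes CSV/TSV/label/JSON outputs plus a run
manifest; `inst/cli/clusterscan.R` exposes the same stages as a command
line. See the vignette in `vignettes/cluster-scanning-methods.Rmd` for the
models, assumptions, and numerical choices.

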