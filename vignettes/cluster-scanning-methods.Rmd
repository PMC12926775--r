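---
title: "Detecting short-interval cortical atrophy from cluster-scanned MRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting short-interval cortical atrophy from cluster-scanned MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clusterscan)
```

## The problem

Cortical thickness estimated from a single structural MRI scan carries a
measurement error of roughly 2-5%, which is the same order as the annual
atrophy rate in symptomatic Alzheimer's disease or frontotemporal lobar
degeneration. Over a 3- or 6-month interval the true change (a few
hundredths of a millimetre) is therefore invisible to a single
scan-per-visit design. *Cluster scanning* attacks the problem by brute
sampling: many short structural scans per visit (here, up to 32 scans
spread over 2 days, in 2 sessions per day of 8 scans each), pooled
statistically so that the standard error of the visit-level thickness
estimate shrinks enough for short-interval change to become detectable in a
single patient.

This package implements the full analysis chain for such data:

1. **Normative W-score modeling** of baseline thickness against a control
   cohort, giving covariate-adjusted atrophy maps.
2. **Individualized ROI construction**: a participant-specific "core
   atrophy" region (where the disease is already active) and a sensorimotor
   "control" region (expected to be spared).
3. **Motion quality control** from navigator-estimated rigid-body
   transforms.
4. A **mixed-effects atrophy model** per participant, with estimated
   marginal means, pairwise and interaction contrasts.
5. **Vertex-wise change maps** inside the core region with a singular-fit
   fallback cascade.
6. A **bootstrap precision analysis** asking how many scans per visit are
   actually needed.

A synthetic-data module generates all of these inputs with known ground
truth; the package is developed and tested entirely against it.

## W-scores and ROI definition

For each surface unit $i$ (vertex or ROI) the control cohort yields an
ordinary least-squares fit

$$T_{ij} = \beta_0 + \beta_1\,\mathrm{Age}_j + \beta_2\,\mathrm{Sex}_j + \varepsilon_{ij},$$

with sex coded 0 = female, 1 = male. A participant's observed thickness
$T_i$ is then expressed as

$$W_i = \frac{T_i - \hat T_i}{SD_i},$$

where $SD_i$ is the residual standard deviation of unit $i$ in the
controls. $W$ is a z-like score adjusted for age and sex; negative values
mean thinner cortex than expected. We use the unbiased residual-df
denominator $\sqrt{RSS/(n-3)}$ by default because it is the estimator that
is consistent for $\sigma_i$ under the model; the plain $n-1$ sample SD of
the residuals is available as an option (`sd_denom = "n-1"`) since either
reading is defensible and published pipelines do not always state which
they used. Training-cohort W-scores are mean-zero per unit by construction,
and W is invariant to affine rescaling of the age covariate; both are
enforced by tests.

The core-atrophy ROI collects vertices with $W < -2$ (strict inequality).
Published analyses of this kind then curate the thresholded clusters by
hand, keeping those that match the clinical phenotype's vulnerable anatomy.
Manual curation cannot be reproduced by code, so this package replaces it
with an explicit rule — connected components of the thresholded set,
filtered by minimum size and (optionally) by majority parcel — and records
the rule in the mask's provenance. The control ROI starts from the
pre/postcentral parcels (primary sensorimotor cortex, typically spared in
PPA and posterior cortical atrophy) and removes vertices with $W < -0.25$;
a vertex at exactly $W = -0.25$ is kept, matching the strict inequality of
the exclusion rule. ROI mean thickness is the unweighted average over mask
vertices; an area-weighted option exists but is off by default, mirroring
the plain-average convention of the source analyses.

## Motion quality control

Navigator sequences estimate one rigid transform per TR relative to the
scan's first TR. A transform with rotation $R$ and translation $t$ is
summarized as the RMS displacement of all points of a solid 64-mm-radius
sphere centered at the isocenter. Writing $A = R - I$, the closed form is

$$\mathrm{RMS}(R, t) = \sqrt{\tfrac{r^2}{5}\,\mathrm{tr}(A^\top A) + \lVert A c + t\rVert^2},$$

because the second moment of a uniform solid sphere of radius $r$ is
$r^2/5$ per axis. Tests verify this against a Monte-Carlo average over
$4\times10^5$ points to within 0.5%.

The per-scan score, RMS displacement per minute (RMSpm), is by default the
*framewise path length per minute*: the sum over TRs of the RMS
displacement of the relative transform from the previous TR, divided by
scan duration in minutes. The phrase "displacement relative to the first
TR, averaged over the scan, per minute" is also consistent with a second
reading — the mean of per-TR displacements from TR 1 divided by duration —
so both are implemented (`mode = "mean-to-first"`) and the mode is recorded
in the summary. The exclusion rule discards scans with RMSpm strictly
greater than 10 mm/min. Under the synthetic motion distribution (lognormal,
log-mean $\ln 3$, log-sd 0.5) roughly 1% of scans exceed the threshold,
matching the 0-16% discard rates seen in practice.

## The mixed-effects atrophy model

Per participant, ROI-level thickness $y$ is modeled as

$$y = X\beta + Z_d b_d + Z_s b_s + Z_c b_c + \varepsilon,$$

with fixed effects Timepoint (baseline, 3 months, 6 months; baseline
reference), ROI (core reference), their interaction, and the scan's RMSpm
as a covariate of no interest; nested random intercepts for days, sessions
within days, and scans within sessions (the scan — not the scan-by-ROI cell
— is the sampling unit, so a scan's intercept is shared by its core and
control rows); and stratified residual variances
$\varepsilon \sim N(0, \sigma^2 \mathrm{diag}(w^2_{s(i)}))$. The default
stratification is ROI $\times$ Timepoint (six weights, reference weight 1),
the most permissive reading of "heteroscedasticity between ROIs across
timepoints"; ROI-only (two weights) is a configuration option.

Estimation is restricted maximum likelihood, authored in the package:
the marginal covariance is
$V = \sigma^2\left(\sum_l \gamma_l Z_l Z_l^\top + \mathrm{diag}(w^2)\right)$
with relative variances $\gamma_l = \sigma_l^2/\sigma^2$; the profiled
restricted log-likelihood is optimized over $(\log\gamma, \log w)$ with
$\sigma^2$ profiled out, using a PORT local search followed by a
Nelder-Mead polish and up to three jittered restarts. A fit is flagged
*singular* when any relative variance falls below $10^{-6}$. Tests verify
the engine against the closed-form balanced one-way ANOVA estimators (to
$10^{-6}$), against the exact GLS solution at known variance components
(to $10^{-8}$), and against an independent reference implementation
(`nlme::lme` with `varIdent` weights — the software lineage these analyses
come from — agreeing in restricted log-likelihood, coefficients, EMMs and
contrast SEs).

One identifiability subtlety is handled explicitly: when a grouping factor
has only singleton groups (the vertex-level models below have exactly one
observation per scan), its variance rides an exact likelihood ridge with
the residual. Such components are *aliased*: fixed at the most parsimonious
point of the ridge (zero) rather than estimated, and a random structure
that is entirely aliased is reported as singular. This makes the
vertex-level fallback cascade deterministic instead of
optimizer-start-dependent.

Model selection between the nested and scans-only random structures uses a
likelihood-ratio test on the REML fits (valid because the fixed effects are
identical), $2\Delta\ell$ against $\chi^2_2$, retaining the simpler model
when $p > .05$. The boundary-null conservatism of the plain $\chi^2$
reference is known and accepted as the conventional choice.

### Inference

Estimated marginal means fix motion at its sample mean and read off the
Timepoint $\times$ ROI grid. Pairwise timepoint contrasts are coded
reference-minus-later, so positive $\Delta$ is thinning; the family is all
six (3 pairs $\times$ 2 ROIs) and Bonferroni-adjusted p-values are
$\min(1, 6p)$, giving the conventional per-test threshold
$.05/6 = .008$. Interaction contrasts compare core and control declines per
pair (family of 3, threshold $.05/3 = .017$). Percent change is
$100(\mathrm{EMM}_{later} - \mathrm{EMM}_{ref})/\mathrm{EMM}_{ref}$,
rounded to one decimal in report output.

Denominator degrees of freedom follow a containment heuristic over the
grouping hierarchy (each fixed-effect column is assigned to the outermost
level within whose groups it is constant; the level's df is
$m_l - m_{l-1} - p_l$), matching the reference implementation's behaviour
on the designs used here; `residual` ($n-p$) and `normal` (z) methods are
options. EMM intervals use the observation-level df: with the default
design this yields 95% intervals whose empirical coverage of the true cell
means is about 93-95% over 300 simulated datasets (measured in the test
suite), whereas outer-level df overcovers (about 99%). F tests of the
fixed terms default to marginal (Type-III-style) Wald statistics;
sequential tests, which reproduce the reference implementation's ANOVA
table, are available via `type = "sequential"`.

## Vertex-wise cascade

Inside the core mask each vertex is modeled separately with Timepoint +
motion fixed effects (no ROI factor — the analysis runs within a single
mask; pooling both masks into one vertex model would be the alternative
reading, noted but not implemented). Because a vertex contributes one value
per scan, the nested structure is frequently singular; the cascade
therefore tries nested day/session/scan intercepts, then scans-only, then a
fixed-effects-only model, recording a model code (2/1/0) per vertex. A
vertex where all three models fail is reported as an explicit gap, never
zero-filled. A vertex-pair change is significant when the Timepoint main
effect has $p < .05$ *and* the pairwise contrast has $p < .017$; no further
adjustment over vertices is applied (the analysis is explicitly
exploratory).

## Bootstrap precision and the plateau rule

For an interval (say baseline to 6 months) the *reference atrophy rate* is
the mean of $B = 10{,}000$ bootstrap estimates of the thickness difference,
each formed by resampling 32 scans with replacement per timepoint (32 even
when fewer survived QC, resampling from what exists). For each scan count
$k = 1..32$, $B$ fresh bootstrap estimates with $k$ resampled scans give
percent deviations $100\,|\hat\Delta_b - \mathrm{ref}|/\mathrm{ref}$,
summarized by mean and quartiles. Bootstrap estimates are simple means per
timepoint, not mixed-model fits: that is what "bootstrap estimates of
thickness difference" denotes, and it keeps the 320,000 resamples cheap.
The curve requires a reference rate above a small tolerance (default
$10^{-3}$ mm): percent deviation from a near-zero reference is
ill-defined, which is why the analysis targets the declining core ROI.

The *plateau* scan count is the smallest $K$ such that for each of the
last two steps ending at $K$ the reduction in mean deviation is strictly
less than 5% of the immediately preceding value; increases (negative
reductions) also qualify as diminishing returns. The detector is invariant
to uniform rescaling of the curve and is exercised on hand-checkable
sequences in the tests. On synthetic data with the default truth the
plateau lands at 11-14 scans per timepoint, the same range reported for
real cluster-scan data.

## The synthetic-data module

The generator is the package's stand-in for the study design, and its
defaults *are* the study conditions: 3 timepoints $\times$ 2 days $\times$
2 sessions $\times$ 8 scans (32 scans per timepoint, 192 ROI-level rows);
a normative cohort of $n = 25$ controls, age $67.4 \pm 4.8$, 13 men and 12
women; core-ROI cell means 1.780/1.760/1.739 mm (a 0.041-mm 6-month
decline, the published svPPA-like pattern) against a nearly flat control
ROI at about 2.35 mm. Values the source material does not state were fixed
once as follows and not revisited: random-intercept SDs
$\sigma_{day} = \sigma_{session} = 0.004$ mm and $\sigma_{scan} = 0.01$ mm
with residual SDs of 0.012 mm (core) and 0.020 mm (control), chosen so
that single-scan errors are 1-2% of thickness, consistent with the
test-retest literature; a lognormal motion distribution
($\ln 3$, 0.5) whose upper tail produces occasional QC exclusions; and a
small motion slope of $-0.001$ mm per (mm/min), consistent with the mostly
non-significant motion effects in published fits. Thickness is assembled
as cell mean + day + session + scan intercepts (shared across the two ROI
rows of a scan) + centered-motion effect + stratum noise.

Vertex-level data add a baseline map, a per-interval decline map, and
spatially correlated noise produced by repeated neighbour averaging on the
mesh — not a geodesic Gaussian: upstream surface smoothing is out of scope
and only its statistical signature (spatially correlated noise) matters
downstream.

What the generator deliberately does not emulate: image-domain artifacts,
FreeSurfer reconstruction failures, longitudinal template drift,
within-session thickness trends, or spatially structured disease
progression beyond the decline map. Passing tests therefore demonstrate
that the *statistical machinery* is correct under the declared generating
model, not that the upstream image processing of real data is unbiased.

## Problem sizes and numerical choices

Simulation-backed tests use the default design (192 rows per dataset):
parameter recovery averages 200 replicates, confidence-interval coverage
uses 300, and the likelihood-ratio selection checks use 24 null and 10
alternative replicates; bootstrap oracles use $B = 10^5$ against exact
enumeration on 2-3 scans per timepoint. These sizes put Monte-Carlo error
well inside the asserted tolerances (e.g. the recovery check's
$\pm 0.003$ mm tolerance is about 7 Monte-Carlo standard errors at 200
replicates). Degenerate inputs are handled explicitly: zero-residual data
profile to an essentially flat restricted likelihood and are returned with
exact GLS coefficients and a singular flag; non-finite responses are
rejected before optimization; an all-atrophic control parcel is an error
with a diagnostic rather than an empty mask.

## Known limitations

- The manual anatomical curation of core clusters is replaced by an
  explicit size/parcel rule; results on real data will differ from a
  neuroradiologist's selection.
- Containment df are a heuristic; Satterthwaite/Kenward-Roger methods are
  not implemented. No conclusion in the package's outputs depends on the
  df method beyond interval width.
- Random slopes, temporal autocorrelation, and pooled multi-participant
  models are out of scope; the model is fit per participant, as in the
  source design.
- The bootstrap treats scans as exchangeable within timepoint, ignoring
  the day/session nesting that the mixed model accounts for.
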