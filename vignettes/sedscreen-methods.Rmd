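---
title: "Methods: bioactivity-based screening and remediation analysis for contaminated sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioactivity-based screening and remediation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedscreen)
```

## The problem

After a flooding disaster, contaminated sediments are redistributed across an
estuary and onto shore. Deciding where to remediate requires characterizing
hazard quickly, but targeted chemistry (e.g., the 16 EPA priority PAHs) only
covers the *known* contaminants. `sedscreen` implements an analysis pipeline
in which concentration-response screening of sediment extracts in human
cell-based assays provides an integrated measure of bioactivity per sample,
and that measure is carried through spatial statistics, cross-prediction
against chemistry, risk screening, and a comparison of remediation goals set
from chemical risk versus from bioactivity.

Because the pipeline is statistical, the package also contains a first-class
synthetic-data generator that emulates the structure of such a study — a
spatially autocorrelated contamination field, PAH profiles with alkylated
homologs, and logistic concentration-response signals — together with the
planted ground truth, so every stage can be validated by parameter-recovery
tests rather than by eyeballing.

## The synthetic study generator

`study_design()` fixes the study conditions. The defaults describe a
46-sample campaign in three regions (an industrial ship channel `HSC`, an
intermediate lakes area `MCL`, an open bay `GB`), 34 endpoints in five cell
types, and 40 analytes (16 parent PAHs, 21 alkylated homologs, 3 exact
totals), screened on an 8-point 3-fold dilution ladder with 3 replicate
wells and 12 vehicle wells per endpoint.

**Latent contamination field.** Each site carries a latent contamination
score: a zero-mean Gaussian field with exponential covariance
$\exp(-d/\phi)$ ($\phi$ = 20 km by default, sampled exactly by Cholesky
factorization of the distance covariance — exact is affordable at $n \le$ a
few hundred) plus planted regional offsets (2.0, 1.0, 0 log10 units for
HSC, MCL, GB). The offsets produce the ship-channel-to-bay contamination
gradient such studies report. Coordinates are WGS84 lon/lat and all
distances are haversine km.

**Chemistry.** Each parent PAH's log10 concentration is an affine function
of the field (loading 0.10) plus independent noise (sd 0.65 log10 units,
baselines roughly 50–500 ng/g dry weight by compound). Homologs are fixed
fractions of their parents with lognormal jitter (sd 0.1); totals are exact
sums. The small loading relative to the noise is deliberate: it makes
individual analytes carry mostly idiosyncratic variation, so that
bioactivity can recover the *aggregate* burden while remaining a poor
predictor of any single analyte — the asymmetry the analysis is designed to
expose.

**Bioactivity.** Endpoints come in three planted kinds. Chemistry-driven
endpoints respond to an aggregate burden
$b_i = \sum_k w_k \log_{10}(1 + C_{ik}/C^{\mathrm{ref}}_k)$, with weights
spread equally across parent lineages; the transform keeps the burden
positive (so scaling weights up always increases it) and saturates
gracefully. Non-PAH endpoints respond to a latent contaminant score outside
the measured panel, given correlation 0.6 with the standardized field
(co-occurring sources) — these are the "unknowns" that make chemical risk
alone under-protective. Null endpoints emit pure replicate noise.
Log10 EC50 decreases linearly in the driver (slope 5 per unit burden), and
responses follow a logistic in log dilution with Hill slope 1.5, amplitudes
0.5–0.8 relative to vehicle, and Gaussian replicate noise (sd 0.05). The
true POD is recorded analytically as the dilution where the noiseless curve
crosses vehicle mean ± 1 noise sd; curves that never cross within the
tested range are inactive.

The generator emulates: spatial autocorrelation and a regional gradient,
parent/alkylated lineage structure with exact totals, realistic
concentration-response shapes, null endpoints, and partial (not full)
explanation of bioactivity by measured chemistry. It does *not* emulate:
plate-position or batch effects, heteroscedastic or non-Gaussian assay
noise, censored chemistry (non-detects), or measurement error models beyond
lognormal jitter. Recovery tests passing on this generator therefore show
the pipeline's statistical machinery is correct under its stated
assumptions — not that real plate data are this well behaved.

## Concentration-response modeling and PODs

Responses are scaled by the pooled vehicle mean per endpoint (pooling all
vehicle wells; per-plate controls are not modeled). Each sample × endpoint
series is fit with a four-parameter logistic in log10 dilution,

$$f(x) = \mathrm{bottom} + \frac{\mathrm{top} - \mathrm{bottom}}
{1 + 10^{\,h\,(\log_{10}\mathrm{EC}_{50} - \log_{10}x)}},$$

by Levenberg–Marquardt least squares with five EC50 starts spread over the
tested range (ties broken by lower residual sum of squares, then smaller
$|h|$; soft parameter bounds two decades beyond the tested range). The POD
is the smallest tested dilution at which the fitted curve leaves the
vehicle band (control mean ± 1 control SD, SD of wells rather than SEM),
solved from the logistic inverse in closed form with a bisection fallback,
and evaluated continuously rather than only at tested dilutions. Three
conventions matter:

* curves already outside the band at the lowest tested dilution are clamped
  there and flagged `extrapolated_low` (no unbounded extrapolation);
* curves that never leave the band are censored at the highest tested
  dilution;
* before any POD is derived, the logistic must beat a constant model in an
  F-test at level 0.05. An unconstrained 4PL fit to pure replicate noise
  drifts marginally outside the band for a substantial fraction of series;
  requiring the curve to explain the data better than a flat line is the
  standard active-call gate and restores honest censoring for signal-free
  endpoints.

## ToxPi integration

Per endpoint, PODs are inversely scaled to $[0,1]$ on the log10 scale:
score $= (\max \log_{10}\mathrm{POD} - \log_{10}\mathrm{POD}) /
(\max - \min)$ over that endpoint's samples, so 0 marks the weakest
observed bioactivity (highest POD) and 1 the strongest. Censored PODs score
0, as do all samples of an endpoint with zero POD range. Whether scaling
should be per endpoint or over the pooled dataset, and on log or linear
PODs, is genuinely underdetermined; per-endpoint log scaling matches ToxPi
convention and is the default, with both alternatives available
(`scale_pods(scale_on =, by =)`). Slices combine with equal weights by
default into per-cell-type means and an overall weighted mean; rank 1 is the
most bioactive sample. Heatmap ordering uses average-linkage hierarchical
clustering on Euclidean distances.

## Spatial statistics

The Mantel test correlates upper triangles of the geographic distance
matrix and a feature dissimilarity matrix (squared differences for single
features; $1 - \rho_{ij}$ Spearman for the global test). The statistic is
the Pearson correlation of distances (the classical Mantel form), the test
is one-sided (greater), since the spatial-association hypothesis is that
nearby sites are similar, and significance comes from simultaneous
row/column permutations with $p = (1 + \#\{r^* \ge r\})/(B + 1)$, $B =$
10,000 by default. For $n \le 8$ an exhaustive mode enumerates all $n!$
relabelings and returns the exact permutation p-value. Screens over many
features are BH-adjusted within each feature set. At the generator's
default latent loading, the spatial signal in individual analytes is weak
relative to their noise, so Mantel screens on defaults typically find few
or no significant analytes; the permutation test's calibration (type-I
error at nominal level) is what the test suite asserts.

Maps are interpolated by ordinary kriging: values log10-transformed
(concentration-like quantities; identity for scores), method-of-moments
semivariogram at a stated lag size, spherical model fit by weighted least
squares with weights $N_j/h_j^2$, and the OK system solved in covariance
form with the unbiasedness constraint (weights sum to 1 at every node; the
common factorization is reused across the grid). The default lag is the
mean nearest-neighbor distance between sites — the usual nearest-neighbor
rule; a lag specified in degrees (e.g. 0.003) converts at ~111.2 km per
degree. Duplicate coordinates are averaged with a warning to keep the
system nonsingular. The default grid is 100 × 100 over the bounding box
plus a 5% margin.

## Cross-prediction

`loocv_ridge()` predicts every column of one matrix from all columns of the
other with a single shared ridge penalty, under leave-one-out
cross-validation. Standardization uses training-fold statistics only (the
stricter reading that avoids any leakage through the held-out sample), and
held-out predictions return to the original scale via the training fold's
column mean and SD. The penalty grid is 30 log-spaced points on
$[10^{-3}, 10^{3}] \times p$ and is chosen to minimize overall mean-squared
prediction error. PODs enter on the log10 scale with censored values at the
maximum tested dilution; concentrations on the $\log_{10}(x + m/2)$ scale
($m$ = smallest positive value per analyte). Per-feature performance is the
Pearson correlation between cross-validated predictions and observations,
with two-sided p-values and BH adjustment within each prediction direction;
constant predictions (or responses) have no defined correlation and are
flagged degenerate and reported non-significant. Note that under the null,
cross-validated predictions are slightly *negatively* correlated with
held-out observations (shrinkage toward training means), so the two-sided
test is mildly conservative-to-liberal depending on direction; the suite
checks the realized false-positive rate directly.

## Risk screening and remediation goals

Alkylated homologs are summed into their parents (conservative), totals
excluded. For each scenario, $\mathrm{HI} = \sum_i C_i/\mathrm{SL}^{nc}_i$
and $\mathrm{CR} = \sum_i C_i/\mathrm{SL}^{ca}_i$ in cases per million,
with screening levels defined at hazard quotient 1 and $10^{-6}$ risk. The
ratio form is algebraically equivalent to the full intake equations given
SLs defined at those anchors, and keeps all exposure assumptions inside the
parameter table. The shipped table
(`inst/extdata/screening_levels_synthetic.csv`) is synthetic/illustrative —
two scenarios related by a 280-fold exposure-duration ratio
(350 d × 24 h vs 5 d × 6 h) — because authoritative screening levels are
versioned externally; real assessments must supply their own table. The two
scenarios are reported separately, over the parent-summed 16 PAHs.

The traditional remediation factor exploits linearity:
$F_{\mathrm{trad}} = \max(\mathrm{HI}, \mathrm{CR}, 1)$. The
bioactivity-based goal is the dilution at which at most 10% of endpoints
remain active: nominally the type-7 (linearly interpolated) 10th percentile
of the sample's POD pool, censored endpoints entering as $+\infty$ while
staying in the active-fraction denominator. Because an interpolated
percentile can land exactly on the POD whose activation would breach 10%
(for example with 34 endpoints, where at most 3 may be active but the
percentile sits on the 4th order statistic), the goal is capped just below
that POD; this makes the guarantee `fraction_active(goal) <= 0.10` exact
for every sample while changing the goal by a negligible relative amount.
Baseline exposure is the undiluted extract (dilution 1.0), so the
bioactivity factor is $1/\mathrm{goal}$, floored at 1; equality with a goal
counts as compliant. Residuals cross the two criteria: the active fraction
at $1/F_{\mathrm{trad}}$, and $\mathrm{CR}/F_{\mathrm{bio}}$,
$\mathrm{HI}/F_{\mathrm{bio}}$.

## Numerical choices and degenerate inputs

* Flat series return a flat converged fit; non-converged fits censor with a
  quality flag.
* A zero-width vehicle band (SD 0) makes any non-flat curve depart
  immediately; the POD clamps to the lowest tested dilution,
  flagged extrapolated-low.
* Logistic inversion handles band edges beyond an asymptote by returning
  censoring; a bisection fallback (relative tolerance $10^{-6}$) covers
  degenerate inverses.
* Constant features are excluded from Mantel screens and ridge responses
  with warnings; constant fields krige to the constant with zero variance.
* Permutation p-values use the add-one convention, never zero; exhaustive
  enumeration includes the identity.
* All generators accept a seed and restore the caller's RNG state; the
  pipeline derives stage seeds from one master seed, and rerunning with the
  same seed reproduces every CSV byte for byte.

## Interfaces

The exported functions are the interface, designed data-frame-first so
stages chain with the pipe; `run_pipeline()` executes the whole analysis
and writes the stage tables (`pods.csv`, `toxpi.csv`, `mantel.csv`, kriging
grids, `crosspred_*.csv`, `risk.csv`, `remediation.csv`, region summaries)
plus a checksum manifest. A thin command-line wrapper over `run_pipeline()`
ships in `inst/cli/sedscreen.R` for shell use.

## Problem sizes used by the test suite

Unit tests run on a reduced 12-sample design with the same structure.
Whole-pipeline checks use the full default design (46 × 34): one full
curve-fitting recovery run, 50 random curves against a dense-grid
($10^{-4}$ log10 step) crossing oracle, Mantel calibration with 400 null
features at 999 permutations, 30 simulations for cross-prediction
power/size (with the non-PAH driver decoupled so nulls are genuine nulls),
100 simulations each for the prediction-asymmetry, remediation-asymmetry
and ToxPi-recovery properties (these use the generator's analytic true
PODs; the fitted-POD path is validated separately), and a double run of the
full pipeline for byte-level determinism. Simulation counts are chosen so
binomial noise on the asserted rates is small relative to their margins.

## Known limitations

* The POD rule depends on the vehicle SD estimate; few vehicle wells make
  the band itself noisy, which the F-test gate mitigates but does not
  remove.
* Kriging assumes second-order stationarity and an isotropic spherical
  semivariogram; no anisotropy or trend (universal kriging) is modeled.
* The Mantel test's power against smooth large-scale trends is limited;
  a significant result supports spatial association, a null result does
  not exclude it.
* Ridge cross-prediction shares one penalty across all responses; features
  with very different signal-to-noise are all shrunk alike.
* HI/CR screening ignores route partitioning and probabilistic exposure;
  it is a screening-level ratio calculation by design.
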