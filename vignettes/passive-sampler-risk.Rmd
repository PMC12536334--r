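---
title: "Multi-matrix risk assessment with passive samplers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-matrix risk assessment with passive samplers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psdrisk)
library(dplyr)
```

`psdrisk` analyses monitoring campaigns in which the same suite of
contaminants of emerging concern (CECs — pharmaceuticals, pesticides, illicit
drugs and their transformation products) is measured in three matrices of a
freshwater system: grab water samples, multi-sorbent passive sampler disks,
and the tissue of a sentinel benthic invertebrate (an amphipod such as
*Gammarus pulex*). This vignette describes the models the package implements,
the conventions and tunable parameters behind them, and what the synthetic
campaign generator does and does not emulate.

## Units and censoring

Everything downstream depends on two conventions enforced at read time.

Canonical units are: aqueous concentrations in ng/L (water, TWA, PNEC, MEC),
sorbent disk loads in ng/disk, tissue concentrations in ng/g, EC50 in µg/L,
PC~crit~ in mg/L, bioconcentration factors in L/kg, sampling rates in L/day.
Conversions are exact powers of ten held in named constants
(`MG_L_TO_NG_L`, `UG_L_TO_NG_L`, `MG_KG_TO_NG_G`). Two products matter:

* EC50 [µg/L] × BCF [L/kg] = µg/kg, which is *numerically* ng/g — the
  internal EC50 needs no conversion factor;
* PC~crit~ [mg/L] × BCF [L/kg] = mg/kg = µg/g, which is 10^3^ ng/g — the
  effect-unit denominator is multiplied by `MG_KG_TO_NG_G`.

Censoring follows the detected/quantifiable distinction of trace analysis:
`not_detected` observations contribute to no statistic; `detected_below_loq`
observations count towards detection sets but never towards concentration or
risk arithmetic; only `quantified` rows carry values. A value must be present
if and only if a row is quantified — `read_measurements()` and
`validate_measurements()` refuse anything else.

Field and extraction blanks are treated identically (the data cannot
distinguish their consequences): a blank that is *quantified above the
compound's detection limit* in a month removes that compound from that
month's data in all matrices (`apply_blank_exclusion()`), the most
conservative reading of blank-correction practice. Blanks that are merely
detected below the LOQ never trigger exclusion. The operation is idempotent
and logs every removed compound–month pair.

## Sampler kinetics

Passive sampling in the integrative (linear) phase of first-order uptake
accumulates mass at a rate proportional to the dissolved concentration:

$$m(t) = R_s \, C_w \, t,$$

so the time-weighted-average concentration over a deployment of length $t$
is $C_{TWA} = m / (R_s t)$ (`twa_concentration()`), and conversely a known
water concentration implies a theoretical disk load $m = C_w R_s t$
(`theoretical_disk_mass()`). The two are exact inverses; the package never
models the curvilinear approach to equilibrium (no membrane/boundary-layer
terms, no in-situ adjustment of $R_s$ for flow or temperature — a known
limitation of transferring laboratory rates to the field).

Rates are calibrated from laboratory time series at a constant concentration
$C_{lab}$ by ordinary least squares of mass against time,
$R_s = \text{slope} / C_{lab}$ (`calibrate_rs()`). Two deliberate choices:

* **Free intercept.** A small time-zero offset or lag phase should not bias
  the slope; whether published calibrations force the intercept through zero
  is generally unstated, so the free intercept is the default and the rate
  comes from the slope alone.
* **Deterministic linear-window rule.** Saturation shows up at the longest
  deployment time. The series is fitted without its last point; if the last
  point's predictive residual exceeds three residual standard deviations of
  that fit (and at least three points remain), it is dropped, once. A single
  documented pass beats silent judgement, and it leaves genuinely linear
  series untouched.

A non-positive slope flags the estimate invalid (`valid = FALSE`); invalid
rates are unusable downstream, which is how compounds with no usable
calibration on a sorbent naturally drop out of sampler-derived risk
quotients. `twa_agreement()` summarises TWA-vs-grab comparability as signed
differences (TWA − grab); with a single pair the standard deviation is
reported as 0 by convention, documented here, so summaries stay numeric.

## Risk metrics

Three scores are computed per quantifiable compound × matrix × month cell
(replicates averaged), then optionally pooled across months as mean ± sd
(`summarise_risk()`).

**Risk quotient.** $RQ = MEC / PNEC$, classified into four bands that
partition the non-negative line: insignificant $[0, 0.1)$, low $[0.1, 1)$,
medium $[1, 10]$, high $(10, \infty)$. Published band definitions typically
leave the interval closures ambiguous; here lower bounds are inclusive for
low and medium and 10 belongs to medium, so "high" means strictly greater
than 10. The breakpoints are configurable through `risk_thresholds()`.

**Internal toxic units** (pesticides). The tissue concentration is compared
with the internal EC50:

$$TU_{int} = \log_{10}\frac{C_{invert}}{EC50 \times BCF}.$$

Values above −3.0 log units indicate possible adverse effects in
invertebrates; the comparison is strict (−3.0 exactly does not exceed).
Where several BCF estimates exist, the largest is used
(`select_worst_case_bcf()`) so the derived internal threshold is the most
protective.

**Internal effect units** (pharmaceuticals lacking EC50 data). The analogue
built on the predicted critical environmental concentration:

$$EU_{int} = \log_{10}\frac{C_{invert}}{PC_{crit} \times BCF \times 10^3},$$

with the denominator in ng/g. The algebraic form of the denominator is an
open design point: the package defaults to PC~crit~ × BCF (the direct
analogue of the internal EC50) but exposes `eu_form = "pc_crit_only"` in
`risk_thresholds()` for the uninternalised variant; every effect-unit
function and the back-calculation honour the configured form. Effect units
rank compounds — there is no established exceedance threshold for them.

**Sampler-as-organism substitution.** Dividing the contaminant mass on a
sorbent disk by the disk weight (0.0115 g for a 9 mm disk) yields a ng/g
pseudo-concentration (`psd_pseudo_concentration()`) that can stand in for
$C_{invert}$ in both formulas. This treats the accumulative sampler as a
surrogate organism and — crucially — needs no calibrated $R_s$. The
substitution is transparent: if the pseudo-concentration equals the tissue
concentration, the scores are identical.

`risk_table()` assembles all applicable metrics for a campaign: RQ from
water and from sampler TWA (the latter only where a rate exists for that
sorbent), TU for pesticides with EC50 + BCF and EU for pharmaceuticals with
PC~crit~, each from both the tissue and the sampler-as-organism route.
Compounds lacking constants are skipped, not errored, and listed in the
`"skipped"` attribute.

```{r}
compounds <- read_compound_table(
  system.file("extdata", "demo_compounds_synthetic.csv", package = "psdrisk"))
measurements <- read_measurements(
  system.file("extdata", "demo_measurements_synthetic.csv", package = "psdrisk"))
risk <- risk_table(measurements, compounds)
summarise_risk(risk) |> filter(compound_id == "imidacloprid")
```

The bundled demonstration tables combine constants a campaign of this kind
would use (a PNEC of 6.8 ng/L for imidacloprid, PC~crit~ values of
1.4 × 10^−4^ and 6.4 × 10^−6^ mg/L for citalopram and clopidogrel) with
synthetic monthly series; they are labelled `_synthetic` and are fixtures,
not study data.

## Cross-matrix comparison

Occurrence is compared as set algebra first: per matrix (plus `psd_any`, the
union over sorbents), `occurrence_sets()` builds detected and quantified
compound sets, and `venn_counts()` enumerates the seven regions of any three
sets. Quantified ⊆ detected holds by construction, and region counts always
sum to the union's cardinality.

Quantitative profiles are compared on a replicate-by-compound matrix
(`profile_matrix()`), min–max scaled *within each measurement replicate* to
[0, 1] (`minmax_scale()`). Two conventions: censored or absent entries are
zero-filled before scaling — a non-detect is evidence of (near-)absence in
an occurrence profile, not a value missing at random — and constant rows map
to all zeros. Scaling is idempotent.

PCA (`pca_profiles()`) is centred and covariance-based: the data are already
on a common [0, 1] scale, so correlation-PCA would only re-weight compounds
by their residual variances. Component signs are fixed deterministically
(largest-magnitude loading positive), all components are computed, two are
retained for reporting, and the ten compounds with the strongest loadings
across retained components are reported as the drivers of separation.
Hierarchical clustering (`hca_profiles()`) defaults to Euclidean distance
with Ward (`ward.D2`) linkage — the standard pairing for scaled occurrence
profiles — with both configurable; `same_cluster()` answers co-membership
queries at any cut height. `linear_matrix_correlation()` provides the paired
OLS (slope, intercept, R², slope-t p-value) used to ask whether
concentrations in one matrix predict another.

## The proxy model: calibrating sampler against biota effect units

The package's central model treats the sampler-as-organism effect units as a
predictor of the biota effect units. Per sorbent (separate models; no pooled
multi-sorbent model), `eu_calibration()` fits

$$EU_{biota} = \beta_0 + \beta_1 \, EU_{psd} + \varepsilon$$

by OLS on compound × month pairs (`eu_pairs()` builds them from a campaign).
Reported alongside the fit are the signed mean error (predicted − observed;
identically zero in-sample for an intercept-including OLS fit, which is why
in-sample mean errors of order 10^−16^ are expected), its spread, and a
normal-approximation 95% CI (mean ± 1.96 sd/√n).

Because the campaign datasets are small (tens of pairs), validation uses
5-fold cross-validation (`kfold_validate()`): a seeded uniform shuffle into
folds of sizes differing by at most one, each point held out exactly once,
with held-out mean errors reported in log10 effect units and — when
PC~crit~/BCF are available — in back-calculated tissue concentrations via
`predict_internal_concentration()`, the exact inverse of the effect-unit
formula. Stratification by compound is off by default (nothing indicates it
is standard here); the pooled CI uses the normal approximation by default
with a t-based option for small fold counts. All fold assignments derive
from a recorded seed, so reports are reproducible.

`tu_crosscheck()` performs the complementary classification exercise for a
pesticide: log10 toxic units from (a) tissue, (b) water against the
*unadjusted* EC50 (the conventional water-column screen), (c) measured disk
mass via the pseudo-concentration, and (d) a theoretical disk mass
reconstructed from water data via $R_s t$ — reporting which routes agree
with the tissue-based exceedance call at −3.0. This is the scenario in which
water-based screening can miss a risk that both the tissue and the sampler
routes flag.

## The synthetic campaign generator

`generate_campaign()` draws a complete campaign from a seeded configuration
(`campaign_config()`); every observation is reproducible from the seed, and
the returned `truth` object suffices to reconstruct the generation.

The generative model is deliberately the simplest one consistent with the
pipeline's assumptions: monthly water means (optionally with a linear
seasonal trend) with multiplicative log-normal noise; sampler masses
$R_s \times \bar{C}_w \times t$ built on the *realized* (not nominal) water
series, so the TWA relation closes exactly in the noiseless limit; biota
concentrations proportional to realized water through an apparent BCF
(instantaneous proportionality — no toxicokinetic lag, since only the
proportional structure is needed by the proxy model); censoring against
per-matrix LOD/LOQ; and sporadic contaminated blanks.

Defaults describe the study conditions the package targets: six monthly
7-day deployments, three replicates, water means log-spaced across
10–1350 ng/L, log-scale noise of 0.3 (water), 0.1 (sampler) and 0.2
(biota) — values chosen once as realistic for a wastewater-impacted urban
river and not tuned thereafter.

What the generator does **not** emulate, and what passing tests therefore do
not demonstrate about real data: analytical (LC-MS/MS) error structure and
matrix effects; temperature- or flow-dependent uptake in either sampler or
organism; toxicokinetic lag and depuration in biota; organism movement
relative to the static sampler; between-sorbent selectivity differences
beyond a scalar rate.

Three presets (`scenario_presets()`) pin down qualitatively important
regimes: `"wandle_like"` (a 100-compound, six-month campaign in the realistic
concentration range), `"proxy_ideal"` (noiseless, apparent BCF proportional
to uptake rate, so sampler and biota effect units are affinely related and
calibration is exact — the closure case), and `"misclassify"` (a single
pesticide whose tissue toxic unit exceeds −3.0 while its water-based toxic
unit does not, so only the sampler routes classify correctly).

```{r}
camp <- generate_campaign(scenario_presets("proxy_ideal"))
pairs <- eu_pairs(camp$measurements, camp$compounds, sorbent = "hlb")
glance(eu_calibration(pairs$eu_psd, pairs$eu_biota, sorbent = "hlb"))
```

## Numerical choices and degenerate inputs

* Boundary behaviour is pinned by tests: RQ bands at 0.1, 1 and 10; the
  strict TU threshold at −3.0; zero masses and concentrations propagate to
  zero.
* Perfect fits (noiseless closure cases) are legitimate inputs to every OLS
  wrapper; the usual "essentially perfect fit" caveat is suppressed there.
* `calibrate_rs` on a flat or decreasing series returns an invalid estimate
  rather than an error; fewer than three points is an error.
* All randomness flows through explicit seeds (`campaign_config(seed=)`,
  `kfold_validate(seed=)`, `generate_calibration_series(seed=)`); internal
  seeding saves and restores the caller's RNG state.
* Test problem sizes were chosen to exercise the statistics at desk scale:
  the parameter-recovery suites use 500–1000 seeded replicates of 5-point
  calibrations, the campaign closures use the presets above (24–100
  compounds over six months).

## Known limitations

The package computes risk *indices*, not risk: PNEC, EC50, PC~crit~ and BCF
values are inputs, and effect units in particular rank compounds rather than
quantify hazard (PC~crit~ derives from human therapeutic plasma
concentrations, not invertebrate toxicity endpoints). Uncertainty in
calibrated uptake rates is not propagated into the proxy model. No mixture
toxicity, species sensitivity distributions, or equilibrium-phase sampler
models are included.
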