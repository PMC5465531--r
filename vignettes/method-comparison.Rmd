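---
title: "Validating a cardiac-output method: agreement, precision, and trending"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating a cardiac-output method: agreement, precision, and trending}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemotrend)
```

## The problem

Intensive-care clinicians titrate fluids and catecholamines against cardiac
output (CO, L/min). The reference measurement — intermittent thermodilution
through a pulmonary artery catheter (PAC) — is invasive, so non-invasive
estimates such as Doppler transthoracic echocardiography (TTE) are attractive
if they agree with the reference *and* track its changes. Validating a test
method therefore needs four distinct statistical ingredients, all implemented
here:

1. **Measurement**: turning raw quantities into CO.
2. **Precision**: how repeatable each method's own replicates are, and the
   smallest change that exceeds measurement noise (least significant change,
   LSC).
3. **Agreement**: Bland–Altman bias, limits of agreement (LOA) and the
   Critchley percentage error (PE).
4. **Trending**: whether changes in the test method follow changes in the
   reference (four-quadrant concordance, polar-plot statistics, ROC change
   detection).

## Measurement model

The echo CO uses the standard Doppler stroke-volume computation. With
\(\bar d\) the mean of (nominally three) LVOT diameter measurements (cm),
\(\overline{VTI}\) the mean of (nominally five) velocity–time integrals (cm)
and HR the heart rate (bpm):

\[
A_{LVOT} = \pi \left(\bar d / 2\right)^2, \qquad
SV = A_{LVOT}\,\overline{VTI} \ \text{(ml)}, \qquad
CO = SV \times HR / 1000 \ \text{(L/min)}.
\]

Full-precision \(\pi\) is used; clinical worksheets often print the constant
as 3.14, and `pi_const = 3.14` reproduces that display exactly. The reference
CO is the arithmetic mean of (nominally five) thermodilution bolus values.
Other replicate counts are accepted — real data are messy — but are flagged
with a message.

## Precision and least significant change

Per subject, the coefficient of variation (CV) of the replicates is sd/mean
(n − 1 denominator). CVs are pooled across subjects as a root mean square, so
the pooled CV² is the mean within-subject relative variance (arithmetic
pooling is available via `pooling = "mean"`). The precision of the *averaged*
measurement and the LSC are

\[
\text{precision} = 100 \cdot \frac{k \cdot CV_{pooled}}{\sqrt{n}}, \qquad
LSC = \text{precision} \times \sqrt{2},
\]

with \(n\) the replicate count and \(k = 2\) by default (`precision_k = 1.96`
gives the normal-quantile variant). Published validation studies frequently
quote precision/LSC pairs that are not mutually consistent under any single
convention — the two conventions differ by the \(\sqrt2\) and by \(k\) — so
the convention here is explicit and overridable rather than implicit.

## Agreement

Differences are test minus reference. Bias is the mean difference (a median
option exists because clinical reports sometimes quote a "median bias"; it
moves only the bias line, since symmetric limits are only consistent with the
mean construction). LOA are bias ± 1.96·sd of the differences. The percentage
error is

\[
PE = 100 \cdot \frac{1.96\,\sigma_d}{\overline{CO}},
\]

with \(\overline{CO}\) the grand mean of the pairwise means of the two
methods (the reference-method mean is available via `denominator =
"reference"`). PE ≤ 30% is the conventional interchangeability criterion.
Repeated measurements per patient are treated as independent pairs, matching
common practice in this literature; no repeated-measures variance
decomposition is attempted.

## Trending

Changes are second minus first measurement, each method against its own
baseline for percentage changes.

**Four-quadrant**: a pair is excluded when it is inside the open central
square — percentage change below the zone (default 15%) on *both* axes; the
drawn exclusion region in this literature is a square, not a cross, which
settles the "both axes" reading. Concordance is the percentage of included
pairs agreeing in sign; > 90% is good trending.

**Polar plot**: each pair of absolute changes \((\Delta_{ref},
\Delta_{test})\) maps to radius \(|(\Delta_{ref}+\Delta_{test})/2|\) and
angle \(\theta = \operatorname{atan2}(\Delta_{test}, \Delta_{ref}) - 45^\circ\),
so the line of identity becomes the polar axis; points whose mean change is
negative are folded by 180° into the half circle (a concordant decrease lands
on the axis, as it should). Points with mean change magnitude below the
exclusion radius (default 0.5 L/min, boundary included) are excluded. The
radial LOA are mean ± 1.96·sd of the included angles (a percentile option
exists); polar concordance is the fraction of included angles within ±30°.
Good trending is a mean angle within ±5° and radial LOA within ±30°. No
circular statistics beyond mean/sd are used — angles here are tightly
clustered around 0° in any usable method, where linear statistics on angles
are adequate.

Degenerate cases (all points excluded, fewer than two polar points) raise a
classed `hemotrend_degenerate_error` rather than returning NaN, and the
pipeline converts them into explicit `undefined` report entries.

**ROC**: pairs are labelled positive when the reference change exceeds 10%
(strict), scored by the test method's percentage change. The AUC is the
empirical Mann–Whitney area (ties ½); the CI and the test against AUC = 0.5
use the DeLong variance (a stratified bootstrap is available and is the only
consumer of the config seed). The operating point evaluates the strict rule
"test change > 8%". Strict inequalities match the "more than" phrasing used
when such cutoffs are reported.

## The synthetic cohort generator

No patient-level dataset is shipped; the generator emulates the *structure*
such validation studies analyse, so that every statistic can be verified
against known ground truth:

* true CO per patient: normal, mean 6.0 and sd 1.8 L/min, truncated above
  1.5 L/min by rejection (smoothness preserved; a parameterisation rejecting
  more than 1% of draws is refused as misconfigured);
* a multiplicative lognormal-style 24-h change (log-sd 0.15) for the
  re-measured subgroup;
* **two layered noise sources** — this is essential. A per-patient,
  per-timepoint proportional disagreement of each method around true CO
  (sd 7.5%), plus per-replicate noise (CV 9%) within the five boluses and
  five VTI traces. Replicate noise alone, at the 8–9% precision such studies
  report, cannot produce limits of agreement near ±1.5 L/min; the layered
  model reconciles both magnitudes, with defaults calibrated so the emergent
  PE is ≈ 25% and precision ≈ 8%;
* a fixed test-method offset of 0.2 L/min;
* echo raw values back-solved (one anatomical LVOT diameter per patient,
  near 2.0 cm; VTI = SV/area with SV = CO·1000/HR, HR near 100 bpm), so the
  measurement module reconstructs the intended CO up to replicate noise. The
  three diameter entries repeat the drawn diameter: the model places
  replicate noise on VTI traces and boluses only.

Default design shape: 38 patients, 26 with a second timepoint — 64
measurement pairs and 26 change pairs. True CO and HR defaults sit at the
medians typical of mechanically ventilated ICU cohorts (CO ≈ 5.8 L/min,
HR ≈ 100 bpm); distributional information beyond such summaries is not
published, so the shapes (normal, lognormal change) are modelling choices,
not fits.

`expected_summaries()` returns the oracle values implied by the parameters:
bias, sd of differences and PE in closed form from truncated-normal moments
and the layered variances; precision as \(100 k\,cv/\sqrt n\); and the AUC of
the ratio-based change model, which has no tractable closed form, as a
high-precision numeric expectation (large-sample evaluation of the scalar
change model on an isolated RNG stream, independent of the cohort
generator's code path).

### What the generator does and does not emulate

It reproduces the statistical skeleton: paired structure, layered
between-method and within-replicate noise, a calibrated offset, multiplicative
24-h changes. It does **not** model beat-to-beat or ventilator-cycle
dynamics, operator effects, persistent per-patient method disagreement across
timepoints (disagreement is redrawn at each timepoint), or non-normal
disagreement tails. Two consequences matter when reading test results:
passing recovery tests shows the *estimators* are correct under the stated
model, not that any clinical device agrees with any other; and because
disagreement is independent across timepoints, change statistics on
26-pair synthetic cohorts are noisier than the cleanest published clinical
trending results — small-sample runs legitimately show four-quadrant
concordance well below 90% and radial LOA beyond ±30°.

## Numerical and testing choices

* Exclusion zones: open central square (four-quadrant), boundary-inclusive
  radius (polar) — the boundary convention is documented because reports are
  silent on it.
* All thresholds live in `analysis_config()`; the defaults are the shipped
  study profile (15% / 0.5 L/min / ±30° / >10% / >8% / 1.96 / k = 2 / mean
  bias / DeLong).
* Reports echo their full configuration and validate before serialisation;
  re-running the same input and config reproduces the JSON byte for byte.
* Monte-Carlo test sizes: recovery tests use 1000-patient (2000-pair)
  cohorts and a 200 000-draw AUC oracle — large enough that the pre-stated
  tolerances (bias ±0.05 L/min, PE ±2 points, precision ±0.5 points, AUC
  ±0.02) are several standard errors wide, small enough to run in seconds.
  Seeds are fixed constants chosen up front.

## Limitations

* No repeated-measures correction in the Bland–Altman variance; pairs from
  the same patient are treated as independent.
* The DeLong CI emulates, but need not match digit-for-digit, the legacy
  commercial tools used in older reports (whose CI algorithms are not fully
  specified); the CI method is configurable and recorded in the report.
* Percentage changes divide by each method's own baseline; baselines at or
  below zero are excluded with a warning rather than imputed.
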