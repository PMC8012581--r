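---
title: "Continuous mortality-risk prediction for very preterm infants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous mortality-risk prediction for very preterm infants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Mortality among infants born before 32 completed weeks of gestation is
common and often precipitous. Admission-time severity scores such as
CRIB-II summarise an infant's *a priori* risk from fixed perinatal factors
(gestation, birth weight, sex, admission temperature, base excess), but
they are frozen at admission: they cannot see the bradycardia, hypotension
and desaturation that mark a decompensating infant hours before death.
`neoworry` implements a continuous alternative: a classifier that, every
ten seconds, predicts whether an infant will die within the next six
hours, combining the static factors with rolling statistics of the bedside
vital signs.

## The model

Each timepoint $t$ of an infant's stay is a row of 34 features:

* four static factors — gestational age (completed weeks), sex (0/1),
  race (integer code over four categories), birth weight (g);
* for each of five dynamic channels (HR, RR, SpO2, systolic BP, mean BP)
  and each of two trailing windows ($w$ = 5 min and 30 min), three
  statistics — the rolling mean $\bar{x}_{t,w}$, the rolling sample
  standard deviation $s_{t,w}$, and the absolute z-score
  $|x_t - \bar{x}_{t,w}| / s_{t,w}$.

The label is
$y_t = \mathbf{1}\{0 < t_{\text{death}} - t \le 21{,}600\ \text{s}\}$, so a
deceased infant with at least six hours of pre-death data contributes
exactly 2,160 positive rows on the 10-s grid (the death instant itself is
excluded from the record). A random forest (100 trees, depth at most 4 —
selectable by 5-fold infant-level cross-validated grid search over depths
{2, 4, 8, 12} and tree counts {25, 50, 100, 200}) is trained after the
majority class is subsampled to parity, and emits a worry probability (the
fraction of trees voting worry) per timepoint. Per-infant calls take the
majority vote over the final six hours, with the mean worry probability
over that window as the per-infant ROC score; exact ties (possible with
the even count 2,160) resolve to worry, the clinically conservative
choice.

Two comparators are evaluated per infant against the eventual-death
outcome: a logistic regression on the four static factors alone, and the
CRIB-II score thresholded at 11 with ROC swept over its integer totals.

### Channel composition of the 34 features

With four statics, three statistics and two windows, 34 features force
exactly five dynamic channels. Diastolic BP is the channel dropped by
default — systolic and mean BP carry nearly all of its information, and
respiratory rate and mean arterial pressure are the dynamically most
informative signals in this population — but `feature_config()` can
restore it (yielding 40 features). Raw instantaneous values are not
features; only the three rolling statistics enter, which is also what
bounds the influence of transient sensor noise.

## The synthetic cohort generator

Real NICU archives of this kind cannot be shared, so the package ships a
generator whose defaults are calibrated to the demographic profile of a
very-preterm cohort:

* GA discrete on 22–31 completed weeks (discretised normal, location
  27.35, scale 2.4); BW conditionally normal,
  $903 + 120\,(\text{GA} - 27)$ g with SD 152 g, truncated to
  [360, 1520] g.
* Death probability: logistic baseline
  $\mathrm{plogis}(-1.62 - 0.72\,(\text{GA}-27))$ per completed week,
  multiplied by the birth-weight adjustment
  $2\,\mathrm{plogis}(-(bw - m(ga))/260)$, which averages to one within a
  GA stratum while making lighter infants die more often. The closed-form
  marginal (`marginal_mortality()`) is 0.214; large cohorts reproduce
  mean GA ≈ 27 weeks, mean BW ≈ 929 g, and a deceased-group mean BW
  ≈ 700 g.
* Vitals at 1 Hz: each channel is mean-reverting AR(1) noise (reversion
  rate 0.01 s⁻¹) around a GA-dependent set-point (the mean-BP set-point
  follows the clinical rule of thumb MAP ≈ GA), plus a persistent
  per-infant baseline offset (e.g. SD 14 beats/min for HR). The offsets
  matter: without them a channel's absolute level gives decompensation
  away and the forest's per-timepoint accuracy saturates near 1, far from
  the regime this kind of monitoring data actually supports. With them
  the pipeline lands at per-timepoint accuracy ≈ 0.9 and the static
  factors rise to the top of the importance ranking, as they should when
  mortality is GA/BW-driven.
* Decompensation: for deceased infants the channel means ramp linearly
  over the final 12 h to configured end-of-life shifts (HR −20, RR −12,
  SpO2 −8, BP −10/−8/−6), so the 6-h worry window lies wholly inside the
  epoch; survivors have none.
* Blood-pressure sourcing: 40 % of infants carry an arterial line
  (continuous BP); the rest get cuff measurements at uniform random
  intervals between 30 min and 12 h, held at the last observation
  between samples.
* Artifacts: per channel, 2 % of samples become missing and 0.5 % are
  replaced by values outside the viable range, at positions drawn without
  replacement.
* Record durations are uniform on 80–240 h; deaths occur no earlier than
  24 h (configurable) and a deceased record ends at the death time,
  snapped to the 10-s grid so worry-window counts are exact.
* Admission temperature (normal around 36.5 °C, cooler at lower GA) and
  base excess (around −4 mmol/L, more acidotic at lower GA) are emitted
  solely to feed CRIB-II; they are not classifier features.

What the generator does *not* emulate: waveform morphology, circadian and
handling-related structure, disease-specific events (sepsis, IVH),
care-escalation artifacts, or informative missingness. Passing tests
therefore demonstrate the pipeline's arithmetic, calibration and ordering
properties on data with the assumed statistical structure — not clinical
performance on real archives.

## Numerical and design choices

* **Downsampling is decimation** (the instantaneous sample at each 10-s
  tick): the 1-Hz source is already a time-integrated mean, so further
  averaging would double-smooth.
* **Pipeline order**: viable-range filter → split-level mean imputation on
  the 1-Hz series → decimation → features. Imputation means are computed
  separately for the training and testing splits, never across them.
  Cuff-BP hold-last-observation happens at simulation so BP behaves as a
  stepwise 1-Hz series before filtering.
* **Viable ranges are closed intervals** (boundary values kept): HR
  [0, 250], RR [0, 120], SpO2 [0, 100], BP [10, 90].
* **Rolling SD** uses denominator $n-1$ and is defined as 0 for windows
  with fewer than two samples; $|z|$ is 0 wherever the SD is 0. Windows
  shrink to the available history at the start of a record, so the first
  row of every record has SD = 0 and $|z|$ = 0.
* **Worry window is half-open**, $(0, 21{,}600]$ s before death: the only
  convention under which 45 full windows give exactly
  45 × 2,160 = 97,200 positive rows.
* **Cross-validation folds and the train/test split are infant-level**;
  balancing happens inside each training fold only. Grid-search selection
  uses mean held-out accuracy with mean-AUC and then smaller-depth
  tie-breaks.
* **Decision threshold** on the vote fraction is 0.5 (majority).
* **Stage seeds** all derive from one global seed through a string-keyed
  hash (`derive_seed()`), so any stage can be re-run independently and
  the whole pipeline is bit-reproducible. Regenerating a stream is
  therefore equivalent to caching it, which `run_pipeline()` exploits to
  keep only one 1-Hz stream in memory at a time.

## Problem sizes used in the tests

The packaged checks run the full pipeline on cohorts of 30–80 infants
with records of 80–88 h — large enough for every contract (inclusion
boundary at exactly 80 h, full worry windows, both outcome classes on
both sides of the split) while keeping the simulations desk-scale.
Calibration checks use 10,000–100,000-infant cohorts (cohort tables only,
no vitals). The model-ordering property (forest per-infant AUC above the
static-only logistic baseline) is asserted across five seeded end-to-end
runs of 80 infants each.

## Known limitations

* The CRIB-II item table shipped here is a clearly-labelled synthetic
  stand-in with the published structure (component maxima 15/5/7, total
  0–27, monotone risk directions), not the published cell values; swap in
  the real table for any clinical use.
* The per-infant ROC score (mean worry probability over the final six
  hours) is one reasonable construction of a per-infant continuous score;
  others (e.g. peak probability) would give different per-infant AUCs.
* Integer race codes are a modelling convenience forced by the fixed
  34-feature count; with tree learners the encoding is harmless, but for
  the logistic baseline it imposes an ordering on an unordered category.
* Mean imputation is deliberately simple; it ignores temporal structure
  and can bias rolling SDs toward zero in heavily corrupted stretches.
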