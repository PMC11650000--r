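---
title: "Quantifying alpha rhythm slowing: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying alpha rhythm slowing: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphaslow)
```

## The analysis in one paragraph

In relaxed, eyes-closed wakefulness the dominant cortical rhythm is the
posterior alpha oscillation (8–13 Hz).  In several neurological conditions,
including temporal lobe epilepsy (TLE), this rhythm shifts toward lower
frequencies ("alpha slowing").  `alphaslow` quantifies that shift from
region-of-interest (ROI) EEG or MEG time series with a deliberately simple,
threshold-based statistic: the relative power in a *slow* alpha band
(6–9 Hz) divided by the power in a *fast* alpha band (10–11 Hz), log
transformed,

$$ R_{s,r} \;=\; \log \frac{P_{s,r}(6\text{–}9\,\mathrm{Hz})}
                           {P_{s,r}(10\text{–}11\,\mathrm{Hz})} $$

for subject $s$ and region $r$, where $P$ is Welch relative band power
(power spectral density normalized to sum to one per region).  Positive
values mean relatively more slow alpha, read as deviation from health.
Cohorts are compared with t-tests on hemispheric and global means of
$R$, and the per-subject global mean is evaluated as a patient/control
classifier by ROC analysis.

The pipeline is: bandpass (1–47.5 Hz, zero-phase) → downsample (250 Hz EEG
/ 600 Hz MEG convention) → epoch selection (60 s EEG / 70 s MEG) → Welch
spectra (2-s windows, 1-s overlap) → sum-to-one normalization → band
powers → log ratio → statistics and ROC.

## The synthetic cohort generator

No clinical recordings ship with the package.  Instead,
`simulate_cohort()` generates ROI-level series with the statistical
structure the analysis assumes, so every downstream stage is testable.
Each region's signal is the sum of three components, in units of the
background SD:

* **Aperiodic background** — a Gaussian process with $1/f^{\chi}$ power
  (default $\chi = 1$, a typical resting-state broadband slope), amplitude
  floored below 0.5 Hz so the low-frequency tail has finite power, scaled
  to unit SD.  It is synthesized directly in the frequency domain:
  independent complex-normal Fourier coefficients shaped by the target
  amplitude response, which is exactly a stationary Gaussian process with
  that spectrum and makes a 60-s, 68-region subject cheap to draw.
* **Alpha oscillation** — Gaussian-bandpass-filtered noise centred on the
  subject's drawn peak frequency with spectral SD
  $\sigma_f = \mathrm{FWHM}/2.355$ (default full width at half power
  2 Hz).  A filtered-noise oscillator rather than a sinusoid: real alpha
  has physiological bandwidth, and a pure tone would make band-edge
  sensitivity analyses degenerate.  The oscillator SD is
  `alpha_amplitude` (default 0.5) times the region's topography weight.
* **Measurement noise** — white, SD `noise_sd` (default 0.2).

Peak frequencies are drawn per subject from
$N(\mu_{\text{group}}, 0.5^2)$ Hz, clipped to [4, 14] Hz.  The group
means — controls 10.5 Hz, patients 8 Hz — are *synthetic design choices*
that straddle the 6–9/10–11 Hz bands; they are not estimates of any
clinical cohort and the package makes no claim about real effect sizes.
The default amplitude 0.5 puts the posterior alpha peak roughly an order
of magnitude above the 1/f background (eyes-closed posterior alpha
dominates the spectrum), and gives peak-to-background ratios above 2
everywhere the topography weight is appreciable, the regime in which the
spectral argmax recovers the injected peak to within one 0.5 Hz bin.

The amplitude topography follows the posterior dominance of alpha: the
default 68-region Desikan–Killiany-style parcellation
(`dk68_parcellation()`) is ordered roughly anterior → posterior within
each hemisphere, and weights taper linearly from 1.0 (occipital pole end)
to 0.4 (frontal pole end).

Reproducibility: every subject uses a private Mersenne–Twister substream
derived deterministically from the cohort seed, so cohorts are
bit-reproducible, order-independent, and the caller's RNG state is never
touched.

**What the generator does not emulate.**  No volume conduction or sensor
mixing, no source-reconstruction artefacts (a small sensor-mixing fixture
is built in code only to exercise sign-flip averaging), no
non-stationarity, eye blinks, muscle or cardiac artefacts, no spatial
correlation between regions beyond the shared group peak, and no
age or medication structure.  Passing tests therefore demonstrate that the
*pipeline* recovers what it is designed to measure under its own model
assumptions — not that the biomarker performs at any particular level on
clinical data.

## Numerical and statistical conventions

* **Welch estimator** — periodic Hann taper, one-sided density scaling
  (summing power × 0.5 Hz approximates the variance), segments *not*
  detrended so DC is preserved; with a Hann taper a constant signal leaks
  only into the first side bin.  2-s windows give 0.5 Hz resolution at
  both 250 and 600 Hz.
* **Normalization band** — sum-to-one over (1, 47.5) Hz, matching the
  analysis bandpass.  Band edges are inclusive on bin centres: at 0.5 Hz
  resolution the slow band covers 7 bins (6.0–9.0), the fast band 3 bins
  (10.0–11.0), and 9.5 Hz belongs to neither — the gap between the bands
  is deliberate.
* **Log base** — natural.  Sign and every rank-based quantity are
  base-invariant; the choice is recorded in the ratio table
  (`log_base`).
* **Zero-power guard** — band powers are floored at $10^{-12}$ before
  division; floored cells are flagged in the table rather than silently
  altered.  Only degenerate synthetic inputs trigger this.
* **Filters** — 4th-order Butterworth applied forward–backward
  (zero phase, 8th-order magnitude response); resampling is polyphase
  anti-aliased with rational rate ratios.  The pipeline order is fixed as
  bandpass → resample → epoch; on band-limited input this perturbs
  in-band relative power by well under 5%.
* **Epoch selection** — the default takes the first window
  (deterministic); `min_variance` scans 1-s steps for the window with the
  smallest mean per-region variance as an automated surrogate for manual
  "most artefact-free" selection, which cannot be replicated
  algorithmically.  Ties break to the earliest window.
* **Sign-flip averaging** — each source is aligned to the sign of its
  correlation with the region's first principal direction (zero
  correlation counts +1), then averaged; the result is flipped if needed
  to correlate non-negatively with the region's first source.  The
  principal-direction reference makes the result invariant to arbitrary
  input polarity, up to that final documented sign convention.
* **t-tests** — Student's equal-variance by default (Welch optional);
  statistic positive when the first group's mean is larger; Cohen's d
  with pooled SD attached.  Zero-variance degenerate cases return
  boundary p-values (0 or 1) with a flag instead of raising, so
  large sweeps never abort.
* **Chi-square** — Pearson, df = 1, *without* Yates continuity
  correction: this convention reproduces the published demographic
  sex-table statistics (2.17, 1.52) exactly, so it is adopted throughout.
* **Bonferroni** — `min(1, m p)` with the family size m stated explicitly
  in every result; the subject-level hemisphere family has m = 2, and the
  region-paired comparisons (one paired t per hemisphere) likewise form
  an m = 2 family.
* **Normality** — Anderson–Darling with the standard small-sample
  adjustment; Lilliefors with a seeded Monte-Carlo null (default 10 000
  replicates) rather than an asymptotic approximation, because the
  composite-null KS distribution is otherwise only roughly approximated
  at cohort-scale n.
* **ROC** — orientation is fixed (higher ratio ⇒ more patient-like)
  rather than auto-flipped, because the directional hypothesis is stated
  a priori and auto-flipping biases null AUC upward.  Ties are grouped at
  one threshold; the trapezoidal AUC then equals the Mann–Whitney
  U/(n₁n₀) with half-weight ties, which the tests verify to $10^{-10}$.

## Problem sizes used by the test-suite

The property and calibration tests run Monte-Carlo sweeps of 100 seeded
cohorts of 20 controls + 20 patients at the default generative parameters
with 20-s epochs — long enough for 19 Welch segments per subject and
stable band powers, small enough that the full suite runs comfortably on
a laptop core.  Single-subject recovery checks (1/f slope within ±0.15,
peak within one bin) use 60-s recordings, and the null calibrations use
identical-parameter cohorts distinguished only by group label.  These
sizes are the package's chosen trade-off between Monte-Carlo resolution
and runtime; the generator's defaults (60 s, 68 regions) remain the
simulation conditions for single cohorts, as in the worked example.

## Known limitations

* The generator's group difference is purely a peak-frequency shift;
  amplitude, bandwidth and exponent differences between groups, though
  plausible clinically, are not part of the default conditions (they can
  be produced by overriding `cohort_spec` fields).
* `min_variance` epoch selection is a crude artefact proxy; it knows
  nothing about spikes, blinks or electrode pops.
* The EDF reader slot in `read_recording()` is an interface placeholder;
  only the tabular TSV + JSON-sidecar format is implemented.
* No peak-alpha-frequency estimator is exported: the package's statistic
  is the band-ratio, and the internal detrended-argmax estimator exists
  only as a test oracle.
* Regions are treated as exchangeable in all statistics; no spatial
  modelling, covariate adjustment or mixed models.
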