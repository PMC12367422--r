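---
title: "Detecting wake slow waves and interictal discharges, and relating their interplay to surgical outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wakeslow methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wakeslow)
```

## Scope and model

`wakeslow` analyses awake intracranial EEG for two event classes and their
temporal relationship:

* **IEDs** — interictal epileptiform discharges, brief pathological
  spike-and-wave transients carrying 20–80 Hz energy;
* **LoWS** — local wake slow waves, 0.5–4 Hz half-waves accompanied by a
  *downstate*: a transient suppression of high-gamma (HG, 45–130 Hz) power,
  the package's proxy for local neuronal activity.

The working hypothesis is homeostatic: LoWS are generated in response to
pathological excitability and dampen it, so the *waiting time from an IED to
the next LoWS* on the same electrode carries information about local
regulation. The package quantifies that waiting time, corrects it for event
incidence, relates it to resection status and surgical outcome (Engel
scale) with linear mixed models, and classifies patients from the
resected/non-resected corrected-delay ratio.

## Detection pipeline

All detection operates per channel on awake, gray-matter data, in
microvolts, with half-open `[start, end)` intervals and times in seconds
from recording start.

**Wake selection.** The signal is windowed (10 s default) and a window is
awake when the alpha (8–12 Hz) to delta (0.5–4 Hz) band-power ratio exceeds
a threshold (default 1). Two robustness choices matter on realistic data:
band power per window is the *lower quartile* of the squared band-passed
samples — a scale statistic proportional to mean power for stationary noise
that sparse, high-amplitude slow waves (which are themselves wake events)
cannot flip to "sleep" — and the ratio is computed per channel with a
cross-channel median vote, so that one channel's transients never reclassify
a window for the whole montage. The exact windowing and threshold of the
staging literature are not standardised; both are configurable
(`ws_params()`).

**Notch.** Line noise is removed with a spectral notch (Fourier
coefficients within ±1 Hz of 60 Hz zeroed). This filter is exactly
zero-phase — peak latencies, on which every delay statistic rests, are
untouched — and exactly idempotent, which a forward-backward IIR notch is
not (its transition band attenuates again on every pass; we measured ~1%
relative RMS change on a second application).

**IED detector.** Band-pass 20–80 Hz (zero-phase 4th-order Butterworth),
envelope as the modulus of the analytic signal. Candidates are excursions
above 3.5x the channel's mean wake envelope; excursions closer than 40 ms
are merged (one transient, one event), ties at equal envelope break to the
earlier sample. A candidate is vetoed when the peak envelope of the 5-Hz
high-passed signal within the excursion is below 4x that signal's mean wake
envelope — this second rule discards events that stand out in-band but not
in the raw trace. Both thresholds are ratios to per-channel means, so the
detector is invariant to global rescaling; means are computed over wake
samples only, since only wake data enter any analysis. Whether the
reference means should instead pool all channels of a recording is an open
choice; per-channel is the default here because electrode gain and tissue
contact vary per contact. Bursts — consecutive same-channel IEDs with
inter-peak gaps under 0.2 s, chained gap-wise — collapse to their first
event so that propagated discharges are not double counted.

**LoWS detector.** Zero-crossings of the 0.5–4 Hz signal delimit
half-waves of either polarity; durations outside [0.25, 1] s are rejected;
amplitudes (max |filtered| between crossings) at or below the channel's
90th percentile are discarded (strictly-above survives, so equal-amplitude
degenerate inputs keep nothing); candidates within 1 s of a same-channel
IED are removed (post-IED slow waves are a different entity); and the
downstate gate keeps a wave only if mean HG power inside the half-wave is
at most `(1 - margin)` times the mean over flanking baselines ([-1.5, -0.5]
and [+0.5, +1.5] s around the peak). HG power for the gate is the squared
Hilbert envelope of the 45–130 Hz band-passed signal — a scalar criterion
needs no time-frequency map. The margin defaults to 0.4: the
relative sampling error of mean band power over a window of duration T and
bandwidth B is `1/sqrt(B x T)` — about 20% for a 0.4-s half-wave at 85 Hz
bandwidth — so a required 40% drop sits ~2 standard errors below equality.
A "strictly lower" rule would pass half of all ordinary waves by symmetry,
destroying the gate's specificity, while a true downstate passes with huge
margin (80% amplitude suppression leaves ~4% power under the suppression
taper, an in/flank power ratio near 0.3).

## Interplay statistics

**Rates** are events per minute of wake, per channel. **Delays** pair each
IED with the next same-channel LoWS peak (or the reverse); unpaired events
and pairs crossing wake-segment boundaries are censored, not truncated.
**Corrected delays** divide the raw delay by the chance expectation under
homogeneous rates, `1 / rate(target kind)`: the result is dimensionless
with chance level 1, invariant to joint rescaling of time and rates, and
for a Poisson target train is Exp(1)-distributed — its per-channel median
converges to log 2, which the tests verify, along with invariance of the
whole distribution under 2x thinning of the target train. This
normalisation is the simplest one that removes the mechanical dependence of
waiting times on incidence; a shuffle-based expectation would serve the
same purpose at far higher cost.

**Excitability.** Each IED is expanded to a ±3 s window and decomposed with
sliding 0.2-s Hanning tapers (90% overlap, 5-Hz resolution), read out at
45–130 Hz in ±0.05 s around the peak, log-transformed, and normalised by
subtracting the log of the [-3, -1] s baseline of the same window — an
epoch outside both the IED and its 1-s LoWS exclusion zone. The baseline
interval and taper length are defaults, not published constants. The
delay–excitability association is fitted as
`ied_hg ~ 1 + delay + (1 + delay | patient)` (REML, Satterthwaite F);
singular fits drop the random slope and are flagged.

**Channel and patient summaries.** Within a channel the *median* corrected
delay (waiting times are heavy-tailed right); across channels within the
resected and non-resected groups, the mean of channel medians.

## Outcome models

The prognostic models (`fit_outcome_lmm()`) regress a per-patient,
per-resection-group summary on resection status, the linearised Engel
score, and their interaction, with a random patient intercept. The
interaction is the headline term: an index that delineates the
epileptogenic zone must differ between resected and spared tissue *as a
function of outcome*. Satterthwaite denominator degrees of freedom
reproduce the fractional df convention of the field. The extended model
adds random coefficients for SOZ membership, lesional status and therapy
type, simplifying stepwise when they are unsupported by the data (flagged
in the result). The Engel linearisation maps I–IV to 1–4 with subclasses
interpolated in quarter steps; any strictly monotone user map is accepted.
ILAE scores substitute directly for the ordinal column.

ROUT outlier removal is re-implemented for location data (the Prism
implementation is closed): median centre, robust standard deviation from
the 68.27th percentile of absolute residuals with an n/(n-1) correction,
t-tail probabilities, and an FDR sweep at Q = 1% flagging from the largest
residual inward.

Preictal analyses define the SOZ as contacts within 10 mm (Euclidean, native
coordinates) of the visually identified onset contacts, the preictal period
as file start to 10 s before onset, and interictal epochs at least 2 h from
any seizure; LoWS detection reuses the interictal amplitude threshold
unchanged (`threshold_ref`), so preictal rate changes are not an artifact of
threshold adaptation. Repeated-measures ANOVAs (region x period per event
kind; three-way with event kind) use `aov` error strata with Holm-adjusted
paired post hocs on the preictal-minus-interictal differences.

## Classification

The patient metric is the resected/non-resected ratio of mean channel-median
corrected IED-to-LoWS delays. `roc_evaluate()` computes the rank AUC (good
outcome positive, low metric the positive direction, ties ½) with the
Hanley–McNeil standard error. `train_validate()` runs repeated stratified
70/30 splits: the training set picks the threshold maximising *balanced*
accuracy (ties to the lower threshold), the validation set is classified
(metric below threshold → predicted good), and all performance measures are
summarised as median [IQR] with the threshold mean and SD. Raw accuracy is
also reported, but is not the training objective: with a ~3:1 good:poor
prevalence an accuracy-maximising threshold collapses to calling every
patient good (accuracy = prevalence, sensitivity 1, specificity 0), a rule
that clinically meaningful operating points (sensitivity and specificity
both well away from their degenerate extremes) visibly do not follow. Chance level
comes from label permutations of the entire procedure; the permutation
p-value compares mean validation balanced accuracy — a summary a degenerate
threshold cannot inflate, and smooth enough to avoid tie-induced
discreteness.

## The synthetic data generator

The generator exists so that every stage can be tested against ground
truth; it emulates the statistical structure the detectors rely on, not
cortical biophysics.

* **Background**: Gaussian 1/f (slope 1 by default) at 25 µV RMS,
  band-limited at 130 Hz as in clinical acquisition chains, plus a narrow
  8–12 Hz alpha rhythm (amplitude 1.3x the delta-band RMS) during
  alternating 30-s wake blocks — enough for the alpha/delta criterion to
  have something to reject.
* **IED template**: a Mexican-hat spike (sigma 8 ms, spectral peak near
  30 Hz) riding on an aligned slow wave (sigma 18 ms), ~150 ms total,
  scaled so the template's 20–80 Hz envelope peak is `ied_amp_factor` times
  the channel's mean background envelope. The slow-wave component is what
  gives clinical IEDs raw amplitudes well above their in-band envelope; a
  pure 20–80 Hz wavelet can never pass the detector's 4x raw-amplitude
  veto, because the broadband reference envelope always exceeds the in-band
  one.
* **LoWS template**: a raised-cosine half-wave with duration drawn from
  [0.3, 0.8] s, amplitude compensated for the 0.5–4 Hz filter response so
  the *detected* amplitude lands ~2.1x above the channel's 90th percentile
  regardless of duration; when the wave carries a downstate, the 45–130 Hz
  background content is multiplicatively suppressed by `downstate_depth`
  (default 0.8) under a half-sine taper.
* **Scheduling**: homogeneous Poisson per channel and kind at rates typical of
  awake clinical cohorts (0.71 IED/min, 3.82 LoWS/min), with refractory spacing (0.5 s
  for IEDs, 2 s for LoWS so injected waves do not pile into one wake-scoring
  window) and a 1.3-s keep-out between LoWS and IEDs so injected ground
  truth is not structurally censored by the 1-s exclusion rule.
* **Cohorts** (`simulate_cohort()`): event-level only — channels in a 60-mm
  cube with an onset contact and a 10-mm SOZ, resection covering the SOZ
  preferentially, Engel classes drawn from a distribution typical of
  surgical series (good outcome ~3/4), and each IED's waiting time to
  the next LoWS drawn from the delay law with mean multiplied, on resected
  channels, by `1 + planted_interaction * (engel_linear - 2.5)`. Centring
  at Engel 2.5 makes the planted effect cross over — short delays in
  resected tissue of good-outcome patients *and* long delays in resected
  tissue of poor-outcome patients — matching the clinically described pattern; an
  uncentred shift could only produce one sign. The default effect size 0.25
  comes from a pre-hoc power sketch: channel-median corrected delays have
  standard error ~0.38 at ~7 IEDs per channel, group means over ~10
  channels ~0.12, so a slope of ~0.17 per Engel step (0.25 x log 2) is
  detectable with power >0.9 at 20 patients.

What the generator does *not* emulate — electrode geometry of real
implants, non-stationary background, artifacts, true sleep architecture,
IED subtypes, seizure morphology (preictal periods are labelled segments
with shifted rates) — bounds what green tests mean: they validate the
statistical machinery and its calibration, not detector performance on
clinical signals.

## Numerical and degenerate-input conventions

Sampling rates below 500 Hz are rejected outright (harmonising with the
cohort the method targets). Zero or constant channels yield empty detector
output, not errors. Half-wave ties at the percentile threshold are
discarded. Envelope ties at peak picking break to the earlier sample.
Candidates whose downstate flanks cross a recording edge are skipped and
logged. Exponential-family delays crossing wake-segment boundaries are
censored. The EDF writer quantises to 16 bits over each channel's physical
range; round-trip error is bounded by one quantisation step (verified
against an independent reader). All simulation randomness flows through
explicit integer seeds, and every analysis function is deterministic given
its inputs.

## Problem sizes used by the test suite and acceptance script

Detector recovery runs on a 10-channel, 10-minute recording; mixed-model
calibration on 20-patient, 20-channel cohorts (500 null and 200 planted in
the tests; 250 and 100 in the script); corrected-delay calibration on 100
(tests) or 60 (script) seeded train pairs; the classifier on a 55-patient
cohort with 200 validation repeats and 499 permutations. These sizes give
Monte-Carlo error comfortably inside the asserted bounds while keeping a
full run in the minutes range on a single core.

## Known limitations

The downstate gate margin, excitability baseline window, alpha/delta
threshold, Engel subclass interpolation, incidence-correction formula, and
classifier split scheme are all reasoned defaults standing in for
unpublished implementation details; each is configurable, and conclusions
that depend on them should be checked for robustness. Electrode-level
recommendation (which contacts to resect) is out of scope: per-channel
delay estimates at clinical recording lengths (~7 IEDs per channel in
10 minutes) are far too noisy for that use.
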