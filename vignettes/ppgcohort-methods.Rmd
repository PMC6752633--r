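---
title: "Methods: ECG-anchored finger/toe PPG feature extraction and cohort screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ECG-anchored finger/toe PPG feature extraction and cohort screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Pulse latencies measured between an ECG R peak and landmarks of a
peripheral photoplethysmogram (PPG) — pulse arrival time (PAT, R peak to
pulse onset), pulse transit time (PTT, R peak to the maximum-slope rising
point), and the systolic/diastolic peak transit times (SPTT/DPTT) — carry
information about arterial stiffness, path length, and vascular tone.
Together with waveform-area morphology (the inflection point area ratio
IPA = A2/A1 and the S2/S1 sub-area ratio), they are screened across a
cohort for dependence on anthropometric and physiological covariates
(sex, height, weight, BMI, heart rate and its variance, blood pressure).
The scientific question this package operationalizes is *site
specificity*: effects such as sex can act on the finger pulse while
leaving the toe pulse statistically untouched.

`ppgcohort` implements that analysis end to end — band-limiting, QRS
detection, beat-wise fiducial extraction, feature computation with height
normalization, and the pairwise regression/t-test battery with a dual
significance gate — plus a fully annotated synthetic-cohort generator
used to validate every stage against ground truth.

## Signal conditioning

Channels are band-limited with Butterworth stages: PPG with a 2nd-order
high-pass at 0.5 Hz and a 6th-order low-pass at 25 Hz; ECG with a
2nd-order high-pass at 0.5 Hz and a 6th-order low-pass at 100 Hz.
Butterworth is chosen for its maximally flat passband — the default in
pulse-wave work; the stated orders and corners are kept as the stage
specifications.

Each stage is applied forward and backward (zero phase).  Latency
features live or die on landmark *timing*, and a causal IIR filter's
group delay would bias every latency; the price is that the effective
attenuation is the squared magnitude response, which is accounted for in
the tests' frequency-response oracles.  Edge transients are controlled by
odd-reflection padding (the extension is pinned to the edge value),
sized at three times the slowest stage's effective impulse-response span,
`3 * fs / f_hp`.  Filtering is linear and length-preserving; a symmetric
pulse's peak moves by at most one sample.

## QRS detection

The ECG is passed through the five-tap derivative filter

V[n] = (2 u[n] + u[n−1] − u[n−3] − 2 u[n−4]) / 8,

squared, and smoothed by a causal moving average spanning 32 ms of
samples (32 samples at the 1 kHz reference rate; rescaled at other
rates).  Detection uses an adaptive threshold: a fraction (default 0.3)
of an exponentially smoothed estimate (factor 0.125) of recent
supra-threshold peak levels, initialized from the 98th percentile of the
first 2 s of the integrated signal.  Each contiguous supra-threshold
region is annotated at its temporal midpoint (an area-centroid rule is
available), and regions starting within a 250 ms refractory period of the
previous detection are merged with it — a physiological upper rate bound.

Two numerical choices matter:

* **Group-delay compensation.**  The derivative filter is antisymmetric
  about lag 2 and the causal L-sample moving average delays by (L−1)/2;
  the annotated midpoint is shifted back by `round(2 + (L-1)/2)` samples
  (18 at 1 kHz).  Without this the annotation sits ~17 ms after the true
  R peak, an offset that would propagate into every latency.
* **Scale invariance.**  Both the initialization percentile and the peak
  tracker scale linearly with the signal, so detections are unchanged
  under positive amplitude scaling.  Delaying the input shifts detections
  by the same amount to within one sample: the initialization window's
  content changes slightly under a shift, which can move one region
  boundary (hence a quantized midpoint) by a single sample.

Instantaneous heart rate is 60/RR per beat-to-beat interval; HR is its
mean and VHR its *population* variance (divide by N — fixed here so test
fixtures have exact expected values).  RR intervals outside (0.25, 3.0) s
are excluded as non-physiological.

## PPG fiducials

Beats are ECG-anchored: each cardiac cycle is the half-open window
between consecutive R peaks.  Within a window:

* **rising point** — global maximum of the first difference (forward
  difference; the argmax is insensitive to the scaling convention);
* **onset** — last crossing of the first difference from ≤ 0 to > 0 at or
  before the rising point, falling back to the pre-rising minimum on
  noisy baselines;
* **systolic peak** — global signal maximum from the rising point on;
* **dicrotic notch** — the most prominent local minimum after the
  systolic peak (prominence = the smaller of the barriers to the
  neighbouring maxima); a second-derivative mode is available but the
  signal-minimum rule is more robust under broadband noise;
* **diastolic peak** — the largest local maximum after the notch.

Failures are encoded in `valid`/`reject_reason`, never raised.  One
deliberate asymmetry: a *diastolic* search failure leaves the beat valid
with an absent landmark, while onset/rising/systolic/notch failures (or
an ordering violation, or a window RR outside (0.25, 3.0) s) invalidate
the beat.  This is what lets the per-site quality policy work the way a
human reviewer would: if a site's diastolic detection rate across valid
beats falls below a threshold (default 50%), all diastolic-derived
features (DPTT) are masked for that site cohort-wide rather than
silently averaging a biased subset — the toe site, whose diastolic wave
is small, is the motivating case.  Had diastolic failure invalidated the
beat, the surviving beats' diastolic rate would be 1 by construction and
the policy could never trigger.

## Features

Latencies are index arithmetic at the sampling rate, reported in
milliseconds.  Areas are trapezoidal integrals of the signal above the
beat's baseline — the amplitude at the onset sample, which makes areas
offset-invariant under the residual baseline left by high-pass
filtering — over four landmark-delimited panels: S1 (onset to rising),
S2 (rising to systolic), S3 (systolic to notch), S4 (notch to cycle
end).  A1 = S1+S2+S3, A2 = S4, IPA = A2/A1.  The rising point is used as
the divider between S1 and S2; the pre-notch region must contain two
panels and the rising point is the only interior landmark available.
An alternative "pre/post-notch ratio" reading of S2/S1 (equal to 1/IPA)
exists in the literature; the four-panel decomposition is the one
implemented, and the alternative is recoverable from the reported IPA.

Per-subject aggregation is the mean over valid beats (median available),
with at least 5 valid beats per site required; BMI = weight/height² and
height-normalized latencies (ms/m) are attached.  Aggregated tables
carry a schema version that downstream analysis refuses to ignore.

## The statistical battery

Every response in {PAT, PTT, SPTT, S2/S1} × {finger, toe} is regressed
on every available predictor in {SBP, DBP, height, weight, BMI, HR, VHR,
sex, same-site IPA} with pairwise-complete deletion.  Both the OLS slope
and the Pearson correlation are reported — the two coincide after
standardization, and reporting both removes any ambiguity about which
the gate uses.  The p-value is the two-sided zero-correlation test,
t = r·√(n−2)/√(1−r²) on n−2 df, identical to the OLS slope test.  A cell
is *significant* only when p < 0.05 **and** r² > 0.11 — a dual gate whose
second arm is equivalent to |r| > √0.11 ≈ 0.33.  Sex is coded female = 0,
male = 1, so positive effects mean longer male latencies; for a binary
predictor the regression p equals the pooled two-sample t-test p (an
algebraic identity the tests verify to 1e-9).  No multiple-testing
correction is applied by default, reproducing the reference procedure
across ~70 cells; smokers and hypertensive subjects are retained (their
numbers are too low for a separate stratum), with an exclusion switch.

The dual gate is not decorative.  Under the null its false-positive rate
can only be below the p-only rate (monotonicity), and — more interesting
scientifically — it screens out *mediated* correlations of moderate size:
a sex difference in height induces a height-mediated sex–latency
correlation at both sites, and the r² floor is what keeps that pathway
below significance at the toe while the direct finger effect passes.

## The synthetic cohort generator

No public co-registered finger/toe dataset with beat-level annotations
exists, so validation runs on a seeded generator whose defaults *are* the
study conditions:

* cohort of 80 subjects, 41/80 male, heights N(1.78, 0.07) m for males
  and N(1.64, 0.07) m for females; BMI-derived weights; ~14% smokers,
  ~8% hypertensive; SBP/DBP N(119, 11)/N(77, 9) mmHg, jointly missing
  with probability 0.15 (BP was optional in the emulated protocol);
* 1 kHz sampling, 180 s recordings (the emulated protocol's three
  minutes); tests and the acceptance script state shorter durations
  explicitly where they need less data;
* per-subject heart rate N(70, 10) bpm; RR jitter log-normal (σ = 0.03)
  truncated to [0.5, 2.5] s;
* programmed latencies
  `PTT = base + sex_effect·male + height_slope·(height − 1.71) +
  hr_coupling·(HR − 70) + noise`, with `PAT = PTT − gap₁`,
  `SPTT = PTT + gap₂` (gaps 40/80 ms, jittered per subject);
  base PTT 250 ms finger / 350 ms toe; height slope 80 ms/m; HR coupling
  −1 ms/bpm; sex effect +20 ms finger, 0 toe; residual spread 15 ms
  finger, 55 ms toe.  The larger toe residual reflects the longer, more
  heterogeneous arterial path to the lower limb; quantitatively it is
  what makes the generator's encoded structure self-consistent — with it,
  the height-mediated sex–toe correlation sits near r ≈ 0.10, below the
  gate, while the finger correlation sits near r ≈ 0.64.  (With a steeper
  height slope and a tight toe spread, mediation alone would push the toe
  cell over the |r| > 0.33 threshold and the encoded "finger-only" sex
  effect would be false by construction.)

Each PPG pulse is a C¹ piecewise-cosine two-lobe surrogate: an upstroke
whose slope is maximal exactly at the programmed rising point, a systolic
peak of unit amplitude, a descent to the dicrotic notch (default level
0.40 of the peak, at 35% of the pulse duration), a secondary diastolic
wave (amplitude 0.15 finger / 0.08 toe above the notch), and a decay to
baseline at the cycle end.  Every landmark of the clean waveform
coincides with its own detection definition (argmax of slope, global
maximum, inter-lobe minimum) to within one sample — the property that
makes ground truth usable as an oracle.  The ECG is a train of narrow
biphasic raised-cosine complexes; only the R landmark matters downstream.
Noise is added last: broadband Gaussian, sinusoidal baseline wander
(0.15–0.35 Hz), and 60 Hz interference, each with configurable relative
amplitude (defaults 0.02 / 0.05 / 0.01).

All randomness derives from one root seed through per-subject
substreams, so cohorts are bit-reproducible and subjects independent.
Landmark times are stored in seconds at full precision; quantization
happens only when waveforms are rendered.  Per-subject jitter of the
latency gaps, notch level, and diastolic amplitude gives the morphology
features real between-subject variance — without it S2/S1 and IPA would
be cohort constants and any correlation involving them degenerate.

**What the generator does not emulate:** motion artifacts, arrhythmia or
ectopy, probe-contact drift, the skewed and heavy-tailed latency
distributions of real cohorts, within-subject latency drift, and any
BP–PTT coupling.  Passing tests therefore demonstrate that the pipeline
recovers what the generative model encodes at realistic noise levels —
not that it is robust to everything a clinical recording can contain.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle:
closed-form impulse/ramp responses for the derivative filter; designed
frequency responses for the filters; ground-truth landmark times for QRS
(100% sensitivity and precision within ±10 ms on clean 60-beat records)
and PPG fiducials (onset/rising/systolic mean absolute error ≤ 5 ms
clean, ≤ 15 ms at ~20 dB SNR, on 20-subject one-minute cohorts);
hand-computed covariance and t formulas for the statistics (agreement to
1e-9).  Cohort-level behaviour is validated by parameter recovery: the
configured height slope and HR-coupling sign are recovered from ground
truth at n = 500; a 20-ms finger-only sex effect is flagged — finger
significant, toe not — in ≥ 90% of 20 replicates of an 80-subject cohort
(20 s recordings keep the end-to-end run tractable); and with all effects
zeroed the per-cell p-only false-positive rate over 300 replicates sits
inside the 99% binomial band around 0.05, with the joint gate's rate
never above it.  The null calibration uses the generator's ground-truth
feature tables directly — the quantity under test is the battery's
calibration, which does not depend on the waveform path.

## Known limitations

* Detection-rate asymmetries between sites are modeled only through the
  diastolic amplitude; real toe PPG degrades in more ways.
* The onset rule inherits the usual foot-detection sensitivity to
  low-frequency noise; at very poor SNR the onset is the first landmark
  to drift.
* The battery is strictly pairwise — no covariate adjustment, no mixed
  models — by design, to mirror the reference procedure.
* The abstract-style "pre/post-notch" S2/S1 reading is not separately
  computed; it equals 1/IPA under the four-panel definitions.
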