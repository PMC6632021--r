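---
title: "Methods: detecting myocardial infarction from a single-lead wearable ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting myocardial infarction from a single-lead wearable ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmi)
```

## The problem

Myocardial infarction announces itself on the ECG chiefly through two
morphological changes: elevation (or depression) of the ST segment
relative to the isoelectric line, and inversion of the T wave. A wearable
single-lead monitor that watches for these changes must run a complete
chain on-device: denoise the raw signal, find each heartbeat, locate the
landmarks that define the ST segment and the isoelectric reference,
and decide — every few seconds — whether the morphology has turned
pathological. `ecgmi` implements that chain twice over: a fast *linear*
rule that thresholds the measured ST deviation and T amplitude, and a
*machine-learning* path that extracts time-, frequency- and joint
time-frequency features from fixed-length beat traces and classifies them
with a polynomial-kernel SVM (or KNN) under five-fold cross-validation.

Because the package is hardware-free, a synthetic generator stands in for
both the wearable device and a clinical beat database. It is first-class,
tested code: every quantitative claim the test suite makes is a claim
about the pipeline run end-to-end on generator output.

## The synthetic generator

Each beat is a sum of five Gaussian bumps (P, Q, R, S, T) with per-wave
amplitude (mV), width (Gaussian sigma, ms) and center offset from the R
peak (ms). Defaults: P(0.15, 20, -180), Q(-0.10, 10, -25), R(1.0, 12, 0),
S(-0.15, 10, +25), T(0.30, 25, +200). Pathology is injected by
construction: ST elevation/depression adds a ±0.20 mV plateau between the
S end and the T onset (raised-cosine ramps, 20 ms), and T inversion flips
the T wave's sign. 0.20 mV is twice the clinical 1 mm decision threshold
at standard calibration — a frank, unambiguous infarct pattern.

The wave widths deserve a note, because they interact with the baseline
estimator. The 200 ms/600 ms median cascade (below) treats as "baseline"
any feature that fills more than half of its window. A beat whose
elevated ST-plus-T span exceeds roughly 300 ms therefore has part of its
ST elevation absorbed into the baseline estimate and subtracted away. The
default T wave (sigma 25 ms at +200 ms, QT about 275 ms) keeps the
elevated span near 215 ms, so an injected 0.20 mV offset survives the
pipeline and is recovered within a few percent. With a broad, late T
(sigma 60 ms at +300 ms) the recovery drops to a quarter of the injected
value — a genuine limitation of median-filter baseline removal on wide
repolarization waves, which real ST-monitoring systems sidestep by
anchoring the baseline to PR-segment knots.

Noise emulates the wearable environment: a 0.3 Hz sinusoidal baseline
wander (respiration; default 0.1 mV), 50 Hz mains pickup (0.02 mV),
broadband white "EMG" noise (0.01 mV), and motion artifacts. A motion
event is a sustained shaking burst — a 2-5 Hz oscillation under a 3 s
raised-cosine envelope — rather than an isolated spike, because electrode
motion in a vehicle corrupts the trace for seconds at a time and because
isolated sub-second bumps are flattened by the median cascade and never
reach the classifier. The `"motion"` preset uses 2 mV bursts (twice the R
amplitude) at 6 events/min.

The device emulation maps the bipolar mV signal through a front-end gain
(default 100, the AD8232 instrumentation-amplifier class) to a mid-rail
biased 0-3 V range, quantizes with a 10-bit converter
(step 3.0 V / 1024 = 2.93 mV), and reconstructs. Battery arithmetic is
`hours = capacity / load x derating` with the conventional 0.70 derating.

What the generator does **not** emulate: inter-patient morphology
variability beyond what its parameters span, arrhythmias and ectopy,
electrode-contact impedance drift, respiration-coupled RR dynamics, and
the continuum of borderline ST changes. Perfect synthetic-data scores
therefore say the pipeline is implemented correctly and is sensitive at
frank effect sizes; they do not predict clinical accuracy.

## Preprocessing

Three length-preserving stages, all reflect-padded at the edges:

1. **Mains notch** — a second-order IIR notch (quality factor 30) at
   50 Hz, applied forward-backward for zero phase. Passband ripple below
   40 Hz is under 1 dB.
2. **FIR smoothing** — a centered 20 ms moving average. The window is a
   compromise: long enough to suppress broadband EMG noise, short enough
   to attenuate a 12 ms-sigma R wave by only a few percent.
3. **Baseline-wander correction** — a 200 ms running median (flattens QRS
   and P), cascaded into a 600 ms running median (flattens T); the result
   is the baseline estimate, subtracted from the smoothed signal. Widths
   are rounded to odd sample counts so the window has a center sample.

The corrected signal has its isoelectric segments at zero mV, which the
delineator and the linear classifier both rely on. The correction is
exactly invariant to additive constants. It is *approximately*
idempotent: re-subtracting the baseline from an already corrected signal
changes it by about 1-3% RMS (median leakage under the beat waves), and
re-running the full chain also re-smooths the QRS. We test the 3% figure;
exact idempotence is not achievable with this operator.

## Delineation

R peaks are detected on the undecimated (a-trous) dyadic wavelet
transform at scale 2^4, using the quadratic-spline filter pair
(low-pass [1,3,3,1]/8, high-pass [2,-2]) that is standard in ECG
delineation; the transform is computed with direct convolution and its
group delay compensated so coefficients align with the signal. Within
each 10 s analysis window, candidate local maxima of the coefficient
magnitude must exceed 0.6 of the window maximum — a relative threshold,
so detection is invariant to amplitude scaling — and are accepted
strongest-first under a 200 ms refractory period, then refined to the raw
signal's local maximum within half a QRS duration (30 ms).

Per beat: Q and S are the minima within 32 ms before/after R. J (QRS end,
ST onset) is primarily the first point after S where the local slope
flattens below 2 mV/s over 10 ms, with "first return to the zero band
(±0.02 mV)" as fallback; the flattening rule is needed because an
ST-depressed beat never returns to zero and an ST-elevated beat crosses
zero while still on the upstroke. I mirrors J before Q, but with the
priorities swapped — the PR side sits at the true isoelectric level even
in ST-shifted beats, so the zero-crossing is authoritative there. The T
peak is the largest *absolute* excursion between J+80 ms and R+400 ms
(an inverted T must be found at its trough); K sits 35 ms after T, H
35 ms before P, and P is the maximum between R-400 ms and I-80 ms.
Landmarks whose windows fall outside the record are reported absent and
the beat is flagged incomplete rather than erroring.

## The linear classifier

Per beat, the isoelectric level is the median of the 20 ms PR segment
ending at I, and the ST level is the mean over the first 80 ms after J —
the clinical ST-measurement span, which by construction ends where the
T-peak search begins. (A span running all the way to K would average the
T wave into the "ST level" and report ~0.14 mV of spurious deviation on
perfectly normal beats.) The decision thresholds are 0.10 mV for ST
elevation/depression (the 1 mm clinical criterion at 10 mm/mV) and
0.05 mV below baseline for T inversion, with ST states taking precedence.

Streaming decisions use 10 s windows advancing by one mean interbeat
interval (so consecutive beat-aligned windows overlap by about half an
interval); each window's label is the majority over its complete beats,
ties broken toward the more severe label. On noise-free streams of all
three classes this rule is 100% correct; under the `"motion"` preset it
reliably mislabels windows — the documented failure mode that motivates
the machine-learning path.

## Quadratic time-frequency distributions

All three distributions share one discrete core: the instantaneous
autocorrelation `K[n, tau] = z[n+tau] conj(z[n-tau])` of the analytic
signal, Fourier-transformed over the lag axis. The number of frequency
bins defaults to the next power of two at or above twice the trace
length; the frequency axis runs 0 to fs/2. All values are scaled so that
`sum(values) dt df` equals the signal energy `sum(x^2)/fs`.

* **WVD** is the bare transform. It is real by Hermitian symmetry and its
  energy identity is exact up to the analytic-signal construction (which
  is why the energy tests use zero-mean, band-limited traces: a signal
  with appreciable DC or Nyquist-bin energy violates the
  `|z|^2 = 2|x|^2` bookkeeping that any analytic-signal method relies
  on).
* **SPEC** is a sliding short-time spectrogram, one unit-energy Hann
  frame centered at every sample. It is computed one-sided from the
  *real* signal (the magnitude spectrum of a real frame is symmetric, so
  folding is exact), with reflect-padded edges and a per-sample coverage
  renormalization that depends only on the window and the record
  geometry — making its energy accounting exact for every input.
* **EMBD** multiplies the ambiguity function by a separable kernel
  `g1(nu) g2(tau)` built from `|Gamma(a + i pi u)|^2 / Gamma(a)^2`
  factors, with Doppler `nu` in cycles/sample and lag expressed as the
  fraction `tau/N`, both in [-0.5, 0.5). The kernel is 1 at the origin,
  so total energy matches the WVD exactly. Defaults alpha = beta = 0.1
  (sharp cross-term suppression); at alpha = beta = 50 the kernel is
  nearly flat and the EMBD reproduces the WVD within a few percent —
  both limits are tested. Doppler smoothing is circular in time, a
  standard discretization compromise.

## Features and screening

Time-domain features are the population (divide-by-N) moments: mean,
variance, skewness, non-excess kurtosis, coefficient of variation;
degenerate inputs (zero variance, zero mean) yield `NA` sentinels rather
than errors. Frequency-domain features over the positive-frequency
magnitude spectrum: spectral flatness (geometric/arithmetic mean ratio),
normalized spectral entropy, and spectral flux over frames of a quarter
of the trace with 50% overlap (the framing is a design choice; flux is
otherwise defined only in words). Joint (t,f) features extend these to
the TFD plane: the five moments over the flattened TFD magnitudes — so
the mean scales as amplitude squared and the shape statistics are
scale-free — and the three spectral features per time slice, averaged
over time, with flux taken between consecutive slices.

Feature screening uses the Mann-Whitney AUC (midranks; ties count half),
which equals the pairwise concordance probability and is verified against
a brute-force count. Selection applies the inclusive `AUC >= 0.5` rule to
the raw AUC; the direction-folded value `max(AUC, 1-AUC)` is reported
alongside so anti-correlated features remain visible, but folding is not
used for selection (it would make every feature pass the 0.5 bar).

## Classification and evaluation

The SVM uses a third-degree polynomial kernel (cost 1, coef0 1); KNN uses
k = 5 with Euclidean distance. Both standardize features with statistics
computed from the training data only, stored in the model and re-applied
at prediction time — the cross-validation harness therefore cannot leak
test-fold information through the scaling. Folds are stratified by class
and shuffled under a seed; every sample is tested exactly once, and the
six confusion-matrix metrics (recall, specificity, FPR, precision,
F-score, accuracy) are reported per fold with mean and standard
deviation. Metrics with zero denominators are `NA`, not errors. Because
folds are stratified, the fold count cannot exceed the smaller class —
leave-one-out over a binary problem is deliberately out of reach.

Two binary tasks mirror the clinical split: STEMI (normal vs ST
elevation) and NSTEMI (normal vs T inversion), evaluated with identical
protocols so the three TFD variants can be compared like-for-like.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
the dataset-count check assembles 500 traces from each of 21 synthetic
subjects (7 per class, 250 Hz, ~102,000 samples each); the
cross-validated evaluation uses 600 traces per class (three subjects per
class at the default wearable noise level, trace length 350 samples at
500 Hz) with both EMBD and WVD features; R-peak metrics use a five-minute
clean record; energy-conservation checks use 100 random band-limited
traces per distribution. These sizes give stable statistics while keeping
a full run in a few minutes on one core.

## Known limitations

* The synthetic classes are separated by frank, fixed effect sizes;
  cross-validated accuracies near 100% on this phantom are a correctness
  statement, not a clinical performance estimate.
* Median-cascade baseline removal attenuates ST offsets whenever the
  elevated span approaches half the long median window; wide-T
  morphologies need a knot-based baseline instead.
* The J/I delineation rules assume a reasonably clean corrected signal;
  under heavy motion artifacts the linear path fails by design, and only
  the feature-based path degrades gracefully.
* EMBD parameters are exposed but not auto-tuned; the defaults follow
  common practice in the quadratic TFD literature.
* The streaming loop processes recorded streams deterministically; true
  asynchronous acquisition (partial buffers, clock drift) is out of
  scope, and the alert path abstracts telephony to pluggable sinks.
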