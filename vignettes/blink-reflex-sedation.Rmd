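---
title: "Blink-reflex EMG as a sedation-depth monitor: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blink-reflex EMG as a sedation-depth monitor: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinksed)
```

# Overview

`blinksed` analyses the electrically evoked blink reflex as a monitor of
sedation depth during propofol/remifentanil induction. A supraorbital
stimulus evokes two orbicularis-oculi EMG components: R1, brief, at about
10 ms latency, and R2, prolonged, at about 30 ms, which drives the visible
blink. Rising effect-site propofol concentration (Ce) attenuates and then
abolishes these components in a fixed order — R2 first (LOR2), then R1
(LOR1), and finally responsiveness itself (LORP, score −5 on an adapted
Richmond Agitation–Sedation Scale, aRASS, assessed every 6 s). The package
provides the pharmacokinetic simulation, a calibrated synthetic-data
generator, the signal-processing and feature-extraction pipeline, the
prediction-probability (Pk) statistic, a multinomial logistic model of
aRASS, and endpoint detection with cohort summaries.

Because the clinical EMG dataset behind the original analysis is not
public, every cohort-level number this package produces comes from the
synthetic generator. This vignette records what that generator emulates,
the numerical conventions of the pipeline, and the design decisions taken
where the published description was ambiguous — so that a green test suite
is read for what it actually establishes.

# Pharmacokinetic model

Propofol disposition follows the Schnider covariate model: a
three-compartment mammillary system with V1 = 4.27 L and V3 = 238 L fixed,
V2 and the inter-compartmental clearance Cl2 linear in age, and metabolic
clearance Cl1 linear in weight, height and James lean body mass. An effect
compartment equilibrates with plasma at ke0 = 0.456 /min. All constants
live in one table, `schnider_constants()`. Points worth noting:

* **ke0 is an assumption.** The study protocol does not print its pump's
  effect-site constant; 0.456 /min is the value associated with the cited
  effect-site model and common TCI implementations. It is configurable
  (`pk_ke0_per_min`).
* **Remifentanil is a constant covariate** (2.5 ng/mL target, assumed
  pseudo-equilibrated before induction) and is never simulated: the
  analysis never uses remifentanil Ce as a variable. The published
  protocol text gives the target in ng/mL; an inconsistent µg/mL mention
  elsewhere is treated as a typo.
* **Validity bounds.** Schnider V2 becomes non-positive above age ≈ 101;
  `schnider_parameters()` rejects such covariates, and the population
  generator truncates age at 95 (and weight/height to a plausible adult
  surgical range) so drawn patients always have a valid model.

The infusion protocol is a single zero-order segment: 3.3 mL/kg/h of 1%
propofol (10 mg/mL), i.e. `rate = 0.55 * weight` mg/min, run until the
first −5 sedation record.

## Integration

The spec'd integrator is classical fixed-step 4th-order Runge–Kutta at
dt = 0.1 s. For this linear system the RK4 step is exactly an affine map
`x <- A x + P b r` with `A = I + hM + (hM)²/2 + (hM)³/6 + (hM)⁴/24`;
`simulate_infusion()` therefore propagates the map through an
eigendecomposition, vectorised over runs of constant infusion rate, with a
literal step loop available as `method = "loop"`. The two paths are the
same scheme and agree to roundoff (tested at 1e-10); the fast path makes
1000-patient cohorts practical in pure R. Mass balance is co-integrated
(cumulative elimination) and audited to 0.5%; halving dt changes the final
Ce by under 0.1%.

# The synthetic-data generator

## Patient population

The three per-patient thresholds (Ce at LOR2, LOR1, LORP) are normal with
the clinical cohort's means and SDs — 1.45 ± 0.85, 2.99 ± 1.19 and
4.22 ± 1.24 µg/mL — and are coupled by a shared standard-normal
"sensitivity" factor with equicorrelation 0.9 (`ce_correlation`). The
coupling is deliberate and load-bearing:

* It is physiologically sensible: the premise of the paradigm is that
  between-patient propofol requirement varies about three-fold, and a
  patient who tolerates more drug before losing one response tolerates
  more before losing the others.
* With *independent* draws, enforcing the ordering LOR2 < LOR1 < LORP by
  rejection discards a fifth of all triples and shifts the conditional
  means far from the calibration targets (we measured LORP drifting from
  4.22 to ≈ 4.66 µg/mL). With correlation 0.9, ordering violations are
  rare (≈ 2%) and the calibrated marginals survive conditioning.
* The 0.1 µg/mL floor is likewise applied per component, by drawing the
  component's idiosyncratic deviate from its truncated conditional
  (inverse CDF) given the shared factor. Rejecting whole triples at the
  floor would preferentially discard low-sensitivity patients and inflate
  all three means through the shared factor.

Demographics are drawn from the cohort summary (61 ± 13 y, 72 ± 11 kg,
162 ± 9 cm, 64% female), truncated as above.

## Sweeps

Each stimulus yields a 200-ms, 10-kHz sweep: 20-Hz high-passed
(4th-order Butterworth, zero-phase — implemented in-package since no DSP
library ships with the target environment) white Gaussian noise plus one
Gaussian-envelope burst per surviving component. Component defaults:

| component | latency | envelope SD | carrier | amplitude | abolished at |
|-----------|---------|-------------|---------|-----------|--------------|
| R1 | 10.5 ms (jitter SD 0.2 ms) | 1.5 ms | 150 Hz | 80 µV | patient's `ce_lor1` |
| R2 | 32 ms (jitter SD 1.0 ms) | 12 ms | 60 Hz | 50 µV | patient's `ce_lor2` |

Amplitude scales as `max(0, 1 − Ce/abolition)^gamma` with `gamma = 1`
(linear fade) for analyzability. Tying the abolition thresholds to the
drawn LOR2/LOR1 values makes the Table-1-style calibration direct. The
noise SD default (2 µV) and burst amplitudes are conventions, chosen so the
baseline SNR is comfortable while presence detection is also exercised at
much lower SNR in the tests.

Three waveform details exist purely for numerical hygiene:

* envelopes are hard-truncated to the component's analysis window, so the
  T1/T2 split is exact (the untruncated Gaussian with these defaults would
  put roughly a third of R1's energy below 10 ms);
* the carrier is a sine anchored at the window's left edge, so the
  truncated burst starts at zero — no step discontinuity, no broadband
  spectral spill (a cosine anchored at the latency shifted the measured
  mean frequency of a pure 60-Hz burst by more than 10 Hz);
* each burst gets an envelope-scaled offset making its net area exactly
  zero, so sweep-level DC removal and detrending cannot smear burst energy
  into the other window.

## Sessions and ground truth

Stimulation runs every 6 s with four pre-infusion baseline sweeps. (The
published acquisition text mentions a 5-ms interstimulus interval, which is
physiologically impossible for 200-ms sweeps at a 0.16-Hz stimulation rate;
the 6-s cadence of the sedation assessments is used and the discrepancy
left documented, not resolved.) A sedation record is taken at every
stimulus from a deterministic staircase: score −k once Ce reaches fraction
(0.45, 0.62, 0.78, 0.92, 1.00) × `ce_lorp`. The fractions were chosen once
so that the median aRASS at the mean LOR2 and LOR1 concentrations
reproduces the clinical medians (0 and −2). The infusion stops at the
first −5 record; observation continues for four further stimuli — the
sliding 4-sweep average otherwise right-censors a component whose abolition
falls within three stimuli of LORP. Ground truth per session: the
interpolated Ce-crossing times of the two abolition thresholds, and the
first −5 record.

What the generator does **not** emulate: stimulus artifacts (invisible to
the pipeline, whose windows start at 10 ms), R2 habituation, bilateral
recording, burst-shape variability beyond latency jitter, non-stationary
or non-Gaussian EMG noise, measurement error in the sedation assessments,
and any pharmacodynamic interaction with remifentanil. A green cohort test
therefore establishes that the pipeline recovers the stated world's
calibration — not that it would perform identically on clinical EMG.

# Preprocessing and features

The pipeline order is fixed: DC removal → linear detrend → sliding
4-sweep average (advancing one stimulus at a time, so the 6-s cadence is
preserved) → half-open windows T1 = [10, 25) ms and T2 = [25, 200) ms
(sample k sits at k/fs; the 25-ms sample belongs to T2) →
rectification/normalisation on the *time-domain branch only*. Spectral
features are computed on the detrended, un-rectified window: rectification
distorts the spectrum, and the published frequency values are
physiological. This is a documented interpretation — the source text does
not state whether rectification preceded PSD estimation.

The Welch estimate uses Hamming windows with 50% overlap: the T2 window
(1750 samples) gives 8 segments of 389 samples (nfft 512); T1
(150 samples) is too short for segmentation and falls back to a single
Hamming periodogram with nfft 256. The PSD is scaled so that
`sum(power) × resolution` equals the window variance (Parseval, tested to
2% on white noise).

Features and conventions (all powers linear except SNR):

* `v_mean`, `v_diff = 1 − v_mean` on the rectified/normalised window.
* `f_mean` = power-weighted mean frequency; `p_fmean` by linear
  interpolation of the PSD at `f_mean`.
* `f_median`: equal-area split treating each bin's power as spread over
  its frequency interval `[f − df/2, f + df/2)`, interpolated inside the
  crossing bin — so a single-bin spectrum has its median exactly at that
  bin.
* `p_band`: sum of PSD values over 30–120 Hz; `p_total`: sum over all bins.
* `snr_db = 10·log10(p_total / (n_bins × median(power)))`: the published
  "background noise power" is ambiguous; a median-bin noise floor is the
  documented stand-in.
* `p_bandwidth`: span between the outermost linear-interpolated crossings
  of half the maximum (the full span, not the main lobe's −3 dB width).
* `spectral_entropy`: Shannon entropy base 2 of the normalised PSD divided
  by `log2(n_bins)`, so it lives in [0, 1] (consistent with published
  entropy values below 1); zero-power bins contribute 0.

A silent window (possible in noise-free synthesis after abolition) yields
an NA feature row rather than an error, flagging component absence.

# Prediction probability

`prediction_probability()` counts, over all unordered cross-class pairs,
concordant / discordant / indicator-tied pairs and returns
`(C + T/2)/(C + D + T)`; pairs tied on class are ignored. aRASS is ordered
0 (awake) down to −5. Because the published table reports values at or
above 0.5 even for negatively correlated features, both the raw and the
direction-folded value `max(pk, 1 − pk)` are emitted. The standard error
is a delete-one jackknife (the original SE machinery is not reproduced in
the source); replicates whose leave-one-out subset degenerates are skipped
with a warning. Pair counting is O(n²), acceptable at pooled sizes, and
the jackknife reuses per-observation pair counts so it stays O(n²)
overall. Correlations default to an automatic choice: Pearson iff both
variables pass a Kolmogorov–Smirnov normality check at 0.05, Spearman
otherwise.

# Multinomial model

`fit_multinomial()` maximises the multinomial logit likelihood by
Newton–Raphson with step-halving; the reference class is the most awake
class (the published final equation is expressed for P(aRASS = −5), so the
deepest class must be a non-reference category). Probabilities go through
log-sum-exp; convergence is score below 1e-6 or relative likelihood change
below 1e-10; coefficients beyond |β| = 500, or a fit that saturates every
observation, raise a separation error naming the offending predictor.
Predictors are not standardised (the published coefficient magnitudes
imply raw units). Diagnostics: overall chi-squared against the
intercept-only fit, Nagelkerke R², in-sample accuracy (argmax class, ties
to the deeper class), and per-predictor likelihood-ratio tests (df 5 per
single-column predictor when all six classes are present).

Feature selection follows the published rule — direction-folded Pk
strictly above 0.700, with |R| > 0.5 versus Ce flagged — and the published
final predictor set ships as `paper_predictors()`. One deviation: that set
lists both Vmean(T1) and Vdiff(T1), but `v_diff = 1 − v_mean` identically,
so including both with an intercept is a singular design; the preset
carries `v_mean_T1` only. The published unresponsiveness logit is shipped
as a versioned data file (`inst/extdata/eq1_coefficients.csv`) and
evaluated by `eval_eq1()` exactly as printed; it is treated as a binary
logit, not re-derived from the 6-class fit (the collapse is not explained
in the source), and its frequency-feature units are passed through as-is.

# Endpoint detection

`component_present()` replaces expert marking: a component is present when
the maximum absolute amplitude in its window exceeds
`baseline mean + k × baseline SD`, baseline being the pre-R1 0–9 ms
segment of the same averaged sweep. Two calibrations matter:

* A fixed k = 3 has a false-positive probability of roughly 33% on the
  150-sample T1 window and near-certainty on the 1750-sample T2 window
  (the maximum of m Gaussian samples grows like √(2 log m)), which would
  destroy "last seen" detection. The default `k = "auto"` therefore uses
  the extreme-value bound `k = qnorm(1 − alpha/(2m))` with alpha = 1e-3,
  holding the per-window false-positive rate fixed regardless of window
  length. A numeric k (including 3) remains available.
* An absolute floor (0.005 µV — an order of magnitude above the
  conditioning residue of a noise-free sweep, three orders below any
  physiological component) keeps the threshold meaningful when the
  baseline SD collapses to numerical residue in noise-free synthesis. A
  constant *nonzero* baseline has no usable noise reference and errors.

Because each sweep contributes to four consecutive sliding averages, a
real component always appears in a run of averaged records; an isolated
single-record positive is discounted as a noise artifact.

**Attribution.** The sliding average shows a component for up to three
stimuli after its true abolition (its last constituent persists), so
stamping the endpoint with the averaged record's own time would lag truth
by up to three intervals and break both the tightness invariant and the
calibration. `detect_endpoints()` instead treats the loss as
interval-censored: presence in the last presenting average is guaranteed
only for its earliest constituent, absence from the next stimulus on; the
endpoint is reported at the bracket midpoint, with Ce read from the
trajectory there. LORP is bracketed the same way between the last record
above −5 and the first −5 record. Midpoint attribution is unbiased under
the 6-s observation grid; in noise-free sessions the detected Ce is within
one inter-stimulus Ce increment of the generator truth.

`summarize_cohort()` produces the cohort table (mean ± SD times and Ce,
median [min, max] aRASS) and paired comparisons, choosing paired t versus
Wilcoxon signed-rank by a KS normality pre-test on the differences;
zero-variance differences are flagged, not crashed.

# Numerical and interface conventions

* Delimited text is the package's exact-precision interchange format
  (UTF-8, comma, `.` decimal, header row); sweep amplitudes are written
  with `%.17g` and parsed with strtod, so round-trips are bit-identical.
  EDF export was dropped: no EDF library exists in the supported
  environment and the format is binary; the text dialect carries the same
  information losslessly.
* `run_pipeline()` executes simulate → features → Pk → model → endpoints →
  summary, stamps artifacts with the seed and a config hash, and is
  byte-identical under a fixed seed. Unknown configuration keys are
  rejected before any computation.
* Per-patient RNG streams derive from (master seed, patient index), so
  enlarging a cohort never changes earlier patients' data.

# Known limitations

* All cohort-level statistics are generator-calibrated, not clinical; the
  published real-data feature ranges, Pk values, chi-squares, accuracy and
  Nagelkerke R² are not reproducible without the original 25-patient EMG
  dataset and are not targets of this package's tests.
* The presence criterion, SNR definition, Welch segmentation, jackknife
  SE, and rectification placement are documented interpretations of an
  under-specified pipeline; alternatives are configurable but the defaults
  are fixed for test stability.
* The aRASS staircase is deterministic in Ce; real assessments are noisy
  and rater-dependent, so synthetic Pk values against aRASS are optimistic
  upper bounds.
* Endpoint detection under heavy noise biases early (the diluted terminal
  burst in the sliding average falls below threshold); the bias is
  bounded by about two stimulus intervals at the default calibration and
  vanishes in the noise-free setting used for calibration checks.
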