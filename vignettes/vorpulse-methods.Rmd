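---
title: "Biomimetic pulse-rate encoding and VOR modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biomimetic pulse-rate encoding and VOR modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(vorpulse)
```

vorpulse models how a vestibular prosthesis converts angular head velocity
into electrical pulse rates, how those pulses drive the vestibulo-ocular
reflex (VOR), and how the resulting eye movements are analysed. This
vignette documents the science behind each stage, the parameter choices, the
numerical decisions, and what the synthetic-data tests do and do not
establish about real recordings.

## The encoder: a linear–nonlinear cascade

A prosthesis mapping converts head velocity $V_H(t)$ (deg/s, positive =
rotation toward the implanted ear) into a commanded pulse rate. The linear
stage is

$$r_\mathrm{linear}(t) = (H * V_H)(t) + r_0, \qquad
H(s) = \frac{k\,s\,(s + 1/T_1)}{(s + 1/T_c)(s + 1/T_2)},\quad s = i2\pi f,$$

with baseline $r_0 = 150$ pps. Five mappings are registered in
`build_mapping()`:

| kind              | constants                                              | emulates |
|-------------------|--------------------------------------------------------|----------|
| `regular`         | $k=5.056$, $T_1=0.0175$, $T_2=0.0027$, $T_c=5.7$       | regular canal afferents |
| `irregular`       | $k=38.889$, $T_1=0.03$, $T_2=0.0006$, $T_c=5.7$        | irregular canal afferents |
| `super_high_pass` | $k=76.76$, $T_1=0.06$ (others as irregular)            | exaggerated high-pass tuning |
| `mixed`           | $n\,(H_\mathrm{reg}+H_\mathrm{irr})/2$, $n=1.5923$     | intermediate tuning |
| `static`          | flat 0.78 pps per deg/s, zero phase                    | conventional clinical mapping |

The doubled-gain (`gain_multiplier = 2`) condition doubles only $k$, $n$, or
the flat gain — never the dynamics.

The fixed cutoff nonlinearity is the sigmoid
$r_\mathrm{final} = c_3 / (1 + e^{-c_1 (r_\mathrm{linear} - c_2)})$
with $c_3 = 500$ pps, $c_1 = 4/c_3$ (so the maximum slope, at the inflection
point $c_2 \approx 255.9$ pps, is exactly 1) and $c_2$ placed so the
baseline 150 pps is a fixed point. Negative linear rates are passed into the
sigmoid unmodified: the sigmoid, which is total on the reals, enforces
positivity; there is no hard clip.

**The mixed-mapping constant is internally inconsistent.** The printed
$n = 1.5923$ is described as matching the mixed mapping's 0.5 Hz gain to the
static 0.78 pps/dps — but the regular and irregular responses each already
have magnitude 0.780 at 0.5 Hz, so their rescaled mean comes out at 1.24.
Both behaviours are provided: the default uses the printed constant
verbatim, and `build_mapping("mixed", renormalize_mixed = TRUE)` instead
solves $n$ so that $|H_\mathrm{mixed}(0.5\,\mathrm{Hz})| = 0.78$
($n \approx 1.0003$), which realizes the stated gain match. Neither is
asserted as ground truth. Similarly, the super-high-pass $k = 76.76$ is kept
verbatim even though doubling the irregular $k$ would give 77.778.

**Discretization.** Continuous transfer functions are realized as discrete
filters by the bilinear transform at the series sample rate (default
1 kHz), via the `signal` package; this matches the digitization rate of the
data the package emulates and is accurate to well below 0.1% under 50 Hz.
The analytic frequency response (`mapping_frequency_response()`) is retained
as an oracle, and the test suite verifies time-domain filtering against it
to 0.5% gain / 0.5° phase at all seven study frequencies. One numerical
wrinkle: `signal::fir1` does not scale its Hamming-window low-pass designs
to unit DC gain, so the package renormalizes FIR coefficients to sum to 1.

**Warm-up.** Filters start from rest, so the first
$\max(5 T_1,\, 3/(2\pi \cdot 0.2\,\mathrm{Hz})) \approx 2.39$ s of any
encoded series is flagged as warm-up (attribute `warmup_s`) and excluded
from steady-state analyses. The slow $T_c = 5.7$ s canal pole dominates this
transient; at high frequencies its excitation is weak, but the flag is kept
conservative and uniform.

**Pulse generation.** `rate_to_pulse_times()` integrates the final rate and
emits a pulse each time the integral crosses the next integer
(reset-by-subtraction), with the crossing time interpolated linearly within
a sample. This is deterministic and rate-faithful (reconstructed 1/ISI
tracks the commanded rate to well under 5% for rates ≥ 50 pps at 1 kHz);
pulse-timing jitter is deliberately not modelled.

## The VOR forward model

`simulate_eye_velocity()` implements a linear control-systems chain from
afferent firing to slow-phase eye velocity:

$$EV(f) = T_{VN}(f)\, T_{NI}(f)\, T_{Plant}(f)\, AFR(f),$$

with the vestibular-nucleus (velocity-storage) stage
$T_{VN}(s) = -g_\mathrm{VOR}\, T_\mathrm{VOR} (s T_c + 1) / (T_c (s T_\mathrm{VOR} + 1))$,
and the neural-integrator/plant pair collapsing to
$e^{-s\tau}/(s T_{e2} + 1)$ because the shared time constant $T_{e1}$
cancels. The flattened published form of $T_{VN}$ admits more than one
bracketing; the reading used here cancels the canal pole $(sT_c+1)$, has
high-frequency gain exactly $g_\mathrm{VOR}$, and is the standard
velocity-storage form — the stated $T_{e1}$ cancellation confirms the
analogous readings of the integrator and plant stages.

Defaults: $T_\mathrm{VOR} = 16$ s, $T_c = 5.7$ s, pathway delay
$\tau = 6$ ms (implemented as an integer-sample shift; at 1 kHz a
fractional-delay filter would change nothing observable). Two presets carry
the subject-specific constants: `monkey_G_like` ($T_{e2} = 0.025$ s,
adaptation cutoff 3.5 Hz) and `monkey_Y_like` ($T_{e2} = 0.008$ s, 0.2 Hz).

Upstream of the chain, `pulses_to_afferent_rate()` applies the stimulation
efficacy (the fraction of pulses that evoke an afferent spike; 500 pps at
28% efficacy yields 140 sp/s) and a first-order high-pass "adaptation"
filter that reproduces the low-frequency roll-off seen in prosthesis-evoked
responses. Two open choices were resolved as follows: the high-pass acts on
the *modulation about baseline* rather than the absolute rate (a DC rate
drives no sustained eye velocity through the chain either way, so only the
transient bookkeeping differs, and modulation keeps the stage linear around
rest); and the filter is first order, the minimal model consistent with a
single quoted cutoff frequency — the order is a parameter (`hp_order`).

$g_\mathrm{VOR}$ is calibrated by `calibrate_gvor()` so that the *natural*
VOR — torsion-pendulum canal dynamics $sT_c/(sT_c+1)$ on head velocity,
which the $T_{VN}$ numerator exists to cancel — has gain exactly 1 at 2 Hz.
Only the magnitude is constrained; the phase at 2 Hz is left free, since
"perfect compensation" pins down one scalar and the chain's phase is fixed
by its time constants. An optional central-pathway depression factor
(0.17) scales the output by 0.83.

## The synthetic-data generator

`synthesize_recording()` stands in for in-vivo eye-coil recordings. It runs
the deterministic forward model, then adds, under a single integer seed:

* **On/off asymmetry** (default 0.8): ipsilaterally directed model eye
  velocity is scaled by a static factor, emulating the weaker off-direction
  responses of unilateral stimulation. A static output gain is the simplest
  model consistent with the qualitative observation; no quantitative model
  was published. Note that the sigmoid's floor *also* compresses
  off-direction drive, so the off/on gain ratio of large transients falls
  below the factor itself; the factor is cleanly recoverable by comparing a
  recording against its symmetric (`asymmetry = 1`) counterpart.
* **Saccades**: 30 ms minimum-jerk position steps of configurable amplitude
  at Poisson times. Defaults (0.5 events/s, 3°) are plausible for a
  head-fixed monkey in darkness; they are placeholders, not estimates
  fitted to any recording.
* **Measurement noise**: white Gaussian position noise (default 0.02°,
  the order of scleral-coil precision).

Eye position is the trapezoidal integral of eye velocity — rectangular
accumulation would introduce a half-sample phase lead (3.6° at 20 Hz) that
the analysis would then misattribute to the model.

The `truth` attribute stores everything the analysis is later asked to
recover: for sinusoids, the gain and phase of the noiseless eye-velocity
fundamental relative to head velocity, obtained by projection onto the
stimulus frequency over post-warm-up complete cycles (a numerical, not
analytic, truth — it includes the sigmoid's harmonic distortion and the
asymmetry's effect on the fundamental, which an analytic small-signal gain
would not); for transients, the programmed 6 ms latency and the
peak-velocity gain; plus the saccade intervals and all generator
parameters.

**What passing tests show.** Round-trip recovery on synthetic data
validates the *procedures*: that the analysis pipeline measures what the
forward model produced, at stated tolerances, under noise and saccades that
the generator controls. It does not validate the forward model against real
monkeys — published in-vivo quantities that depend on the deposited
recordings (fitted VAFs of 0.91/0.90, efficacies of 28%/4.5%) are
reproduced here only as *parameter-recovery* exercises at those same
values.

## The eye-movement analysis pipeline

`preprocess_eye()` follows the standard chain for 1 kHz coil data:
zero-phase 51-tap Hamming low-pass at 125 Hz on position,
central-difference differentiation, saccade masking, zero-phase 51-tap
Hamming low-pass at 50 Hz on slow-phase velocity.

**Saccade detection.** Thresholding is under-specified in the literature
this package follows; the detector used is: flag samples where velocity
deviates from a slow-phase reference — velocity low-passed at 10 Hz with a
sharp 201-tap zero-phase FIR — by more than 50 deg/s, then pad ±10 ms. The
reference cutoff must sit *above* the stimulus band (≤ 20 Hz slow-phase
content largely cancels in the deviation) but *below* the content of a
30 ms saccade; a 50 Hz reference fails this test — it passes a 30 ms
saccade almost entirely (peak deviation ≈ 21 deg/s, under threshold) — which
is why the slower, sharper reference is the default. Both threshold and
cutoff are arguments. Masked samples are flagged, never interpolated in the
output; the final 50 Hz smoothing runs on a gap-bridged copy so saccade
energy does not leak into neighbouring slow-phase samples.

**Cycle fits.** "Dynamic linear regression" is realized as a per-cycle
least-squares fit of $a\sin(2\pi f t) + b\cos(2\pi f t) + c$ over unmasked
samples — it estimates exactly the stated per-cycle quantities (gain,
offset, phase). Eye velocity is sign-inverted relative to head velocity, so
phase 0 = perfectly compensatory and positive phase = eye leads. Inclusion
thresholds: ≥ 40% slow phase per cycle at 0.2–0.5 Hz, ≥ 60% above;
summaries require ≥ 3 included cycles (low frequencies) or ≥ 10 (high).
Because the 2.39 s encoder warm-up exceeds a 10-cycle presentation at high
frequencies, analyses use several 10-cycle presentations;
`n_cycles_for()` returns the whole number of presentations that leaves the
required minima after warm-up with a 1.5× margin for saccade losses.

Fitted amplitudes are corrected for the *known* amplitude response of the
measurement chain at the stimulus frequency (the two zero-phase FIRs, each
applied forward-and-backward, and the derivative estimator) — about 0.1% at
1 Hz and 3% at 20 Hz. The chain is zero-phase, so phases need no
correction. This is an instrument-response deconvolution with an exactly
known instrument; it can be disabled (`compensate_filters = FALSE`).

**Summaries.** `summarize_response()` returns per-frequency mean ± SE gain
and phase plus the derived scalars: the log-linear slope of gain over
5–20 Hz (regression of mean gain on $\log_{10} f$), the mean absolute
phase over 5–20 Hz, the per-frequency ×2/×1 gain ratio (each ×2 data point
divided by the mean ×1 gain), and optional normalization by a reference
condition. `bootstrap_phase_se()` resamples whole cycle fits (the
independent units of the summaries — not samples) with replacement, 2,000
iterations by default.

**Transients.** Trials with any saccade within 50 ms of the stimulus are
excluded; at least 4 eligible trials are required, and metrics are computed
on the trial-averaged trace. Latency is the x-intercept of a line fitted to
the 10 samples before and after the first crossing of twice the baseline
SD (baseline = the 100 ms before onset). Two guards make the rule total:
with zero baseline SD (noise-free synthetic data) a floor of 1% of the peak
response stands in for the threshold, and the crossing must stay above
threshold for 10 consecutive samples, since Gaussian noise alone exceeds a
2 SD line on ~5% of samples. Transient gain divides the peak absolute eye
velocity by the *peak head velocity* (giving the dimensionless gain the
field plots); a displacement-based alternative can be computed from the
same traces. `subtract_baseline()` provides the pointwise differencing used
for physical-motion conditions.

## System identification

`fit_rational_tf()` fits a continuous-domain rational transfer function to
gain/phase data by weighted complex least squares with Sanathanan–Koerner
iterative reweighting ($w = 1/|A_{k-1}(i\omega)|^2$), to a coefficient
change below $10^{-8}$ or 50 iterations. The fixed 6 ms pathway delay is
removed from the phase before fitting and re-applied in simulation;
unstable poles of the converged fit are reflected into the left half-plane.
On exact data the fit recovers a known system to machine precision and is
idempotent.

**Input domain.** The default input is commanded *pulse-rate modulation*,
so a single model per subject predicts all mappings — every nonlinearity
(the sigmoid) sits upstream of the pulse rate, leaving only linear dynamics
between input and eye velocity. `pulse_rate_response()` builds the
corresponding frequency-response table from analysed recordings, and a
head-velocity input domain is available simply by fitting tables from
`summarize_response()` per mapping instead. Whether the original analysis
fitted per mapping or per subject is not stated; both routes exist here and
neither is asserted.

`estimate_efficacy()` exploits the model's linearity in efficacy: the
predicted peak eye velocities at efficacy 1 are computed once per
condition, and the scalar efficacy in (0, 1] minimizing the summed squared
error is found by bounded minimization (`stats::optimize`, with the
closed-form least-squares optimum used when it falls inside the bounds —
the objective is exactly quadratic). Least squares is assumed; the original
objective was not stated. The depression variant scales predictions by
0.83 before fitting and therefore returns estimates larger by 1/0.83.

`saturation_diagnostic()` compares peak pre- and post-sigmoid rates per
condition and flags post/pre ratios below 0.9. With the renormalized mixed
mapping, the super-high-pass ×2 mapping at 20 Hz is the unique flagged
condition (peak linear rate ≈ 732 pps against the 500 pps bound); with the
printed mixed constant, the mixed ×2 condition crosses the threshold too —
a direct consequence of the constant inconsistency discussed above.

## Problem sizes and reproducibility

All simulation-based tests run at the study's native conditions: 1 kHz
sampling, 50 deg/s sinusoids at 0.2–20 Hz in 10-cycle presentations
(as many presentations as the cycle minima require), 200 deg/s / 150 ms
raised-cosine transients, 2,000 bootstrap iterations. A full
`run_experiment()` over 5 mappings × 2 gains × 7 frequencies plus
transients completes in well under a minute. Every stochastic stage derives
its seed from the configuration's single master seed, so identical
configurations give byte-identical bundles.

## Known limitations

* The forward model is linear beyond the encoder sigmoid: no spiking, no
  synaptic dynamics, no quick-phase generation (saccades exist only as
  injected nuisance events in the generator).
* The nuisance model is deliberately simple — stationary white position
  noise, stereotyped saccades, a static asymmetry factor. Real recordings
  have drift, blinks, torsional cross-talk, and state-dependent saccade
  statistics, none of which are emulated; conclusions from passing tests
  are about the pipeline, not about monkeys.
* Only horizontal responses are modelled; file I/O uses delimited text with
  a JSON sidecar (a single dialect).
* The latency rule's line fit inherits the brittleness of any
  threshold-crossing estimator at low signal-to-noise; the sustained-
  crossing guard mitigates but does not remove it.
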