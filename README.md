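# vorpulse

Biomimetic pulse-rate encoding and vestibulo-ocular reflex (VOR) modelling
for vestibular prostheses.

A vestibular prosthesis restores gaze stability after bilateral vestibular
loss by sensing angular head velocity and stimulating the ampullary nerve
with electrical pulses. The central design question is the **mapping**: how
should head velocity (deg/s) be converted into a stimulation pulse rate
(pps)? vorpulse implements and evaluates mappings that mimic the natural
high-pass tuning of semicircular-canal afferents, a control-systems model of
the prosthesis-driven VOR, a synthetic eye-movement recording generator with
stored ground truth, and the full slow-phase eye-movement analysis pipeline
used to score performance. It is aimed at researchers designing prosthesis
encodings or analysing prosthesis-evoked eye movements.

## The model

**Encoder (linear–nonlinear cascade).** The linear stage maps head velocity
V_H into a pulse rate about a 150 pps baseline,

    r_linear(t) = (H * V_H)(t) + r0,
    H(s) = k s (s + 1/T1) / ((s + 1/Tc)(s + 1/T2)),   s = i 2 pi f

with constants per mapping (`regular`, `irregular`, `mixed`,
`super_high_pass`, or the conventional flat `static` mapping at 0.78
pps/dps). A fixed sigmoid r_final = c3 / (1 + exp(-c1 (r_linear - c2)))
with c3 = 500 pps, unit maximum slope, and a fixed point at the baseline
caps the delivered rate.

**VOR pathway.** Afferent drive (pulse rate × stimulation efficacy, passed
through a first-order adaptation high-pass) enters the chain

    EV(s) = T_VN(s) · e^(-s tau) / (s Te2 + 1) · AFR(s),
    T_VN(s) = -gVOR · TVOR (s Tc + 1) / (Tc (s TVOR + 1))

with TVOR = 16 s, Tc = 5.7 s, tau = 6 ms, and a plant time constant Te2 of
8 or 25 ms (`monkey_Y_like` / `monkey_G_like` presets). gVOR is calibrated
so the natural canal-driven VOR has unit gain at 2 Hz.

**Analysis.** 1 kHz eye position → zero-phase 125 Hz low-pass →
differentiation → saccade masking → 50 Hz low-pass → per-cycle sinusoid
fits (gain, phase, offset; 40/60% slow-phase inclusion rules) →
frequency-response tables with bootstrap SEs; transient latency/gain/peak
timing; rational transfer-function fits (Sanathanan–Koerner complex least
squares) with variance-accounted-for (VAF) scoring; stimulation-efficacy
estimation from peak-velocity curves.

## Worked example

Encode a 2 Hz rotation with the regular-afferent mapping, simulate the
evoked eye movements of a synthetic subject at 28% stimulation efficacy,
and recover the response from the noisy recording:

```r
library(vorpulse)

mapping <- build_mapping("regular")
mapping_frequency_response(mapping, c(0.2, 0.5, 2, 20))
#> # A tibble: 4 × 3
#>   frequency_hz gain_pps_per_dps phase_deg
#>          <dbl>            <dbl>     <dbl>
#> 1          0.2            0.773      9.01
#> 2          0.5            0.780      5.86
#> 3          2              0.798     11.3
#> 4         20              1.78      46.9

params <- vor_params("monkey_G_like", efficacy = 0.28)
rec <- synthesize_recording(
  stimulus_spec("sinusoid", frequency = 2, n_cycles = 20),
  mapping, params, noise_spec(seed = 1))

fits <- fit_cycles(preprocess_eye(rec))
summarize_response(fits)
#> # A tibble: 1 × 6
#>   frequency_hz mean_gain  se_gain mean_phase_deg se_phase_deg n_cycles
#>          <dbl>     <dbl>    <dbl>          <dbl>        <dbl>    <int>
#> 1            2    0.0836 0.000203           49.0       0.0956       15

bootstrap_phase_se(fits, seed = 1)
#> [1] 0.09327892

attr(rec, "truth")$gain     # 0.08354989
attr(rec, "truth")$phase_deg  # 49.015
```

The mapping's gain rises from 0.78 pps/dps at 0.5 Hz to 1.78 at 20 Hz with
a growing phase lead — the high-pass signature of regular canal afferents.
The analysed VOR gain (0.0836 ± 0.0002) and phase (49.0°) recover the
generator's ground truth (0.0835, 49.0°) from 15 accepted cycles despite
injected saccades and measurement noise; the 49° lead at 2 Hz reflects the
monkey-G-like 3.5 Hz adaptation high-pass. `autoplot()` methods visualize
frequency-response tables and fitted transfer functions;
`run_experiment()` orchestrates the full mapping × gain × stimulus grid
from one seeded configuration.

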