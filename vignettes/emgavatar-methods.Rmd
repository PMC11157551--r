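---
title: "Methods: the EMG-driven avatar model and its analysis"
author: "emgavatar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the EMG-driven avatar model and its analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgavatar)
```

## The control loop being modelled

A person flexes and extends a virtual elbow using surface EMG from an
agonist-antagonist muscle pair (biceps and triceps). The motor command is not
a trigger but a continuous quantity rooted in the equilibrium-point view of
motor control: the **agonist-antagonist (AA) ratio**

$$r = \frac{m_e}{m_f + m_e}, \qquad s = m_f + m_e,$$

where $m_e$ and $m_f$ are the extensor and flexor activations in %MVC. The
ratio $r$ plays the role of the commanded equilibrium point (here, the elbow
angle) while the sum $s$ reflects co-contraction, i.e. joint stiffness. The
deviation $\Delta r = r - r_{\text{baseline}}$ drives a **neuromusculoskeletal
(NMSS) model**: a cascade of two second-order low-pass sections, the
neuromuscular one carrying a pure dead time,

$$G_{NM}(s) = K_{NM}\,\frac{\omega_{nNM}^2}{s^2 + 2\zeta_{NM}\omega_{nNM}s + \omega_{nNM}^2}\,e^{-L_{NM}s},
\qquad
G_{MS}(s) = K_{MS}\,\frac{\omega_{nMS}^2}{s^2 + 2\zeta_{MS}\omega_{nMS}s + \omega_{nMS}^2}.$$

The cascade output is the angular displacement $\Delta\theta(t)$ in degrees
from a standard position of 90°, simulated at 1 kHz and resampled to a 30 FPS
frame grid for rendering. The model is treated as time-invariant: although
human NMSS parameters are known to move with co-contraction level $s$,
scheduling parameters on $s$ is deliberately out of scope here.

Because EMG activates before the limb moves, a cascade with a high natural
angular frequency can make the avatar *lead* the person's own dynamics --
negative delay. That regime, unreachable with the usual screen-delay
manipulations, is the reason the settings catalogs below push
$\omega_n$ as high as 72 rad/s.

## The signal chain

Raw two-channel EMG sampled at 1000 Hz passes through:

1. acquisition band-pass: 10 Hz high-pass, then a low-pass whose cutoff
   depends on the amplifier profile (100 Hz for `web5000`, 120 Hz for
   `ebm102`);
2. full-wave rectification (absolute value);
3. a 22 Hz envelope low-pass;
4. normalization to %MVC against a per-muscle calibration.

The source system ran in real time, so filters default to **causal**
second-order Butterworth sections (`filter_spec(causal = TRUE)`); the filter
family and order are not dictated by the problem and are configurable.
Zero-phase (`filtfilt`) filtering is available for offline work. Two
consequences of the causal choice are documented behaviour: the envelope can
undershoot slightly below zero after rectification (it is clamped at zero to
keep activations non-negative), and the whole chain carries a group delay of
roughly 20-30 ms, which matters when comparing recovered envelopes against
commanded ones.

The MVC calibration value is the maximum of the 22 Hz envelope over the MVC
recording (`mvc_from_recording(method = "max")`); a 95th-percentile variant
is available for recordings with transient spikes.

**Degenerate AA samples.** When both muscles are essentially silent
($s < \varepsilon$, default $\varepsilon = 0.5$ %MVC) the ratio is
mathematically undefined; `compute_aa()` holds the last defined value, or the
baseline before any sample was defined. The baseline ratio itself defaults to
0.5 -- balanced co-contraction mapped to the 90° standard position -- because
nothing in the source material fixes how the resting ratio anchors the
standard position; it is a configurable assumption, not a derived fact.

## Discretizing the cascade

`build_cascade()` discretizes each second-order section in state space at the
simulation rate using a **first-order (triangle) hold** on the section input,
with the transition and input-weight matrices obtained from the augmented
matrix exponential (`Matrix::expm`). We initially used the more common
zero-order hold, but its effective half-sample input delay is visible at
1 kHz: against a dense ODE solution of the equivalent fourth-order system,
ZOH leaves errors of about $5\times10^{-3}$ of the output range for natural
frequencies around 50-70 rad/s, while the triangle hold brings that down to
about $2\times10^{-5}$. The triangle hold preserves the DC gain
$K_{NM}K_{MS}$ and the step-response asymptote exactly, and remains strictly
causal in streaming form: the state update for sample $k$ is completed when
sample $k$ arrives.

Two realization details are deliberate:

* **Sections are simulated as state-space recursions, not transfer-function
  filters.** Converting the hold to a difference equation and running it
  through a generic IIR filter injects a spurious feedthrough at the first
  sample (the one-sided z-transform of the input-advance term), which shows
  up as a percent-level transient error for fast, lightly damped settings.
* **Dead time is an integer-sample FIFO on the cascade output** of length
  `round((l_nm + l_ms) * sim_rate)`. For a linear time-invariant cascade an
  input-side and an output-side delay are identical; the output-side FIFO
  makes the pure-delay identity -- delayed output equals the zero-padded
  shift of the undelayed output -- hold bit-exactly, which is also how the
  dead-time catalogs are validated.

The printed transfer function of the musculoskeletal section carries no dead
time factor even though $L_{MS}$ is defined alongside it; we therefore treat
the total dead time as $L_{NM} + L_{MS}$ with $L_{MS}$ defaulting to zero.

**Gain units.** The catalogs' gain of 300 is read as degrees of displacement
per unit of $\Delta r$: a ratio excursion of 0.2 then spans the 60° of the
flexion task, which is the only interpretation that makes the task geometry
work. Positive $\Delta\theta$ is flexion (90° toward 150°).

## Settings catalogs

All catalogs share the standard setting $K_{NM}K_{MS} = 300$,
$\omega_{nNM} = \omega_{nMS} = 6$ rad/s, $\zeta = 0.7$, $L = 0$; each
comparison setting varies exactly one parameter group:

| catalog | varied parameter | values |
|---|---|---|
| `preliminary_omega` | $\omega_n$ (both sections) | 8, 6, 4, 2 rad/s |
| `preliminary_deadtime` | $L_{NM}$ | 0, 50, 150, 300 ms |
| `main_omega` | $\omega_n$ (both sections) | 72, 36, 18, 9, 4, 2 rad/s |

Only the product of the two gains is observable, so the catalogs store
$K_{NM} = 300, K_{MS} = 1$.

## Characterizing a setting's response

"Delay" is operationalized as the argmax of the normalized cross-correlation
between a setting's output and the standard setting's output on a common
probe input, at sample resolution (parabolic sub-sample refinement exists
but is off by default; one sample at 1 kHz is finer than anything the
perceptual experiments resolve). The probe is the decaying logistic

$$\Delta r(t) = \frac{1}{1 + \exp\!\big(\tfrac{20}{3}(t - 0.5)\big)},$$

whose inflection sits exactly at $t = 0.5$ s with value $\tfrac12$. A
closed-form cross-check, the cascade's group delay at DC
($2\zeta_{NM}/\omega_{nNM} + 2\zeta_{MS}/\omega_{nMS} + L$), is exposed as
`dc_group_delay()`. For the negative-delay claim the reference is the
standard-setting model driven by the same input -- a desk artifact cannot
observe a participant's actual elbow, so "leads the real limb" becomes
"leads the standard dynamics".

Settling-time bookkeeping matters for gain and overshoot measurements: an
overdamped section's slow pole decays at
$\omega(\zeta - \sqrt{\zeta^2 - 1})$, which can be far slower than
$\zeta\omega$; simulations run 14 of those slowest time constants past the
dead time before the final value is read.

## The synthetic data generators

The generators stand in for hardware EMG and human raters; they are
first-class, tested code.

**EMG.** Each channel is a unit-variance band-limited carrier (default
20-90 Hz) amplitude-modulated by the commanded %MVC envelope, scaled so that
the exact consumer chain recovers the envelope; the modulation constant is
calibrated at generation time against the `filter_spec` the consumer will
use. Two carriers are available:

* `"noise"` (default): band-limited Gaussian noise, the standard surface-EMG
  surrogate, with its sub-12 Hz intensity drift divided out so the
  short-time intensity follows the commanded envelope rather than the
  carrier's own random walk;
* `"chirp"`: a constant-modulus triangular frequency sweep with seeded random
  phase -- spectrally similar but with essentially no intensity noise, so
  any envelope-recovery error is attributable to the processing chain alone.

Even so, a recovered envelope is not the commanded one sample-for-sample:
full-wave rectification of a stochastic carrier leaves ripple throughout the
envelope band, and the causal chain adds its group delay. The round-trip
guarantee is therefore stated -- and tested -- for envelopes band-limited
below 5 Hz, comparing in that band after aligning for the chain delay, at
10% RMS. The generator does not model fatigue, electrode shift, crosstalk,
or any biomechanical link between the two channels.

**Protocol.** `make_protocol()` reproduces the trial structure: in the
preliminary form, each standard exposure is followed by a block of three
rated comparison slots with a final block of two; in the main form standard
and comparison strictly alternate. Every comparison setting appears exactly
twice, in seeded random order, and "dummy" trials (the standard setting
presented as a comparison) are inserted uniformly at random. The dummy count
is stated only as "occurs randomly" in the source material; we default to
the smallest positive count that closes the preliminary block structure
(three dummies for a four-setting catalog: $8 + 3 = 11 = 3+3+3+2$) and one
dummy for the main form. One plan is applied to all virtual participants;
no order or learning effects are modelled, so per-participant reshuffling
would change nothing measurable.

**Raters.** Each virtual participant carries, per characteristic (sense of
ownership, sense of agency, comfort level), a Gaussian-bump response curve
over the setting index -- floor, peak height, peak location, peak width --
plus a rating noise scale. A rating is the curve value plus Gaussian noise,
clipped to $[-3, 3]$ and rounded to 0.25 steps (the questionnaire scale,
anchored at 0 = "same as standard"). Heterogeneous peak locations are the
point: they emulate the observation that the most strongly perceived
dynamics differ across individuals. With the noise at zero the rating *is*
the quantized curve, so a participant's "true peak" is defined as the argmax
of the quantized curve -- on a 0.25-step scale that is the only version of
the truth a rater can express, and it is what `peak_distribution()`
recovers exactly in the round-trip test.

## The questionnaire analysis

Ratings are averaged over the two repetitions within participant, then
compared pairwise across settings per characteristic:

* **Test family:** paired t-tests on the per-participant means
  ($df = n - 1 = 5$ for six participants). The original analysis names only
  "multiple comparisons (Holm-Bonferroni)" through a statistics package
  whose internal error model is not documented; the paired reading is the
  conservative default, and a pooled-error variant (two-way ANOVA residual
  mean square, $df = (n-1)(k-1)$) is available behind
  `method = "pooled"` for sensitivity analysis.
* **Adjustment:** Holm's step-down procedure across all pairs within a
  characteristic (`p.adjust(method = "holm")`), $\alpha = 0.05$.
* **Effect size:** $ES = \sqrt{t^2/(t^2 + df)}$, categorized as *large*
  ($\geq .5$, starred `**`), *medium* ($\geq .3$, starred `*`), *small*
  ($\geq .1$) and *slight* ($< .1$). The source material prints both
  "$\geq .1$ small" and "$\leq .1$ slight"; we resolve the boundary so that
  $ES = 0.1$ is *small*.
* **Degenerate comparisons:** a zero-variance difference vector has no t
  statistic; it is flagged, with $ES = 1$ (p = 0) for a nonzero mean
  difference and $ES = 0$ (p = 1) when all differences vanish.
* **Missing data are an error, never imputed** -- the design has no
  missingness, so a hole in the table means a broken file.

Peaks ("setting(s) with a participant's maximal mean rating, ties all
count") are tallied into a per-setting histogram via `peak_distribution()`.

## Numerical and testing choices

* Matrix exponentials use `Matrix::expm`; a Padé implementation from another
  library was measured at ~$5\times10^{-7}$ per-step error, which compounds
  to percent level over a transient, and was rejected.
* The ODE cross-check integrates the equivalent fourth-order system with
  `deSolve::lsoda` at `rtol = 1e-10` on the undelayed cascade, applying dead
  time afterwards as an exact shift (an input-side step discontinuity at
  $t = L$ otherwise stalls the stiff integrator).
* Lag searches use windowed Pearson correlation over integer lags within
  $\pm$`max_lag`; antisymmetry and exact dead-time additivity are
  property-tested.
* Test problem sizes: 2 s probes at 1 kHz for response characterization,
  10 s for the steady-state gain, six-participant rating tables, 500
  permuted null tables for the family-wise-error check, and a handful of
  random parameter draws for each property. These sizes keep the full suite
  under a minute while leaving every tolerance comfortably resolved.

## Known limitations

* The NMSS model is linear and time-invariant: no AA-sum-scheduled
  parameters, no joint-angle limits or saturation.
* The synthetic EMG is a statistical surrogate; passing round-trip tests
  says the pipeline is self-consistent, not that it would behave
  identically on physiological signals with crosstalk and nonstationary
  spectra.
* Virtual raters have no sequence effects (no habituation, no drift), so
  protocol randomization is exercised structurally but not statistically.
* The deposited raw questionnaire table is not redistributable with the
  package; the reproduction of its published dead-time ownership effect
  size runs only when a mapped copy is placed at
  `inst/extdata/supp1_ratings.csv`.
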