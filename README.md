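# emgavatar

Simulation and analysis tools for an EMG-driven virtual-arm (avatar) control
loop, built for researchers studying how avatar dynamics shape perceptual
characteristics — sense of ownership (SoO), sense of agency (SoA) and comfort
level (CL) — including the *negative delay* regime in which the avatar moves
before the user's own limb would.

## The model

Surface EMG from an antagonistic muscle pair (extensor `m_e`, flexor `m_f`,
both in %MVC after band-pass filtering, rectification and a 22 Hz envelope)
is condensed into the agonist–antagonist ratio and sum

```
r = m_e / (m_f + m_e)        s = m_f + m_e
```

`r` acts as an equilibrium-point-like motor command; its deviation
`Δr = r − baseline` drives a neuromusculoskeletal (NMSS) cascade of two
second-order transfer functions, the neuromuscular one with dead time:

```
G_NM(s) = K_NM · ω²_nNM / (s² + 2ζ_NM ω_nNM s + ω²_nNM) · e^(−L_NM s)
G_MS(s) = K_MS · ω²_nMS / (s² + 2ζ_MS ω_nMS s + ω²_nMS)
```

The output is the elbow angular displacement Δθ(t) in degrees from a 90°
standard position, simulated at 1 kHz and rendered at 30 FPS. The standard
setting is gain `K_NM·K_MS = 300`, natural angular frequency 6 rad/s,
damping 0.7, dead time 0; built-in catalogs vary natural angular frequency
(8…2 rad/s; 72…2 rad/s) or dead time (0…300 ms), one parameter group at a
time. Low natural frequency produces phase delay; high natural frequency
makes the avatar *lead* the standard dynamics, because EMG precedes limb
motion.

On the analysis side, questionnaire ratings (−3…+3 in 0.25 steps, relative
to the standard setting) are compared pairwise across settings with paired
t-tests and Holm–Bonferroni adjustment, summarised by the effect size
`ES = sqrt(t² / (t² + df))` (slight/small/medium/large at 0.1/0.3/0.5), and
condensed into per-participant "peak" histograms. Seeded generators provide
synthetic EMG with known activation envelopes, randomized experimental
protocols, and virtual raters with individual preference curves, so the
whole pipeline runs without hardware or participants.

## Worked example

```r
library(emgavatar)

# 1. characterize the dead-time catalog on the sigmoid probe input
res <- characterize_catalog(nmss_catalog("preliminary_deadtime"),
                            sigmoid_input(duration = 2))
print(res, n = 5)
#> # A tibble: 5 × 5
#>   setting  lag_s dc_gain overshoot reference
#>   <chr>    <dbl>   <dbl>     <dbl> <chr>
#> 1 standard  0       300.    0.0669 standard
#> 2 L_1       0       300.    0.0669 standard
#> 3 L_2       0.05    300.    0.0669 standard
#> 4 L_3       0.15    300.    0.0669 standard
#> 5 L_4       0.3     300.    0.0669 standard
```

Each dead-time setting trails the zero-dead-time response by exactly its
dead time, while gain (300° per unit Δr) and overshoot are untouched.

```r
# 2. negative delay: the 72 rad/s setting leads the standard dynamics
sig   <- sigmoid_input(duration = 2)
y_std <- simulate_trial(sig, standard_setting_of())$delta_theta_deg
y_72  <- simulate_trial(sig,
  catalog_setting(nmss_catalog("main_omega"), "omega_nm1"))$delta_theta_deg
estimate_lag(y_std, y_72, rate = 1000, max_lag = 0.9)
#> [1] -0.538
```

A negative lag: the fast avatar anticipates the sluggish standard dynamics
by about half a second on this probe.

```r
# 3. virtual raters -> pairwise effect sizes and peak histogram
plan <- make_protocol("main", nmss_catalog("main_omega"), seed = 7)
vp   <- virtual_participants(6, settings = paste0("omega_nm", 1:6),
                             seed = 7, noise_sd = 0.25)
tab  <- synth_ratings(vp, plan, seed = 7)
pairwise_compare(tab, "cl")
#> <perception_pairwise> CL, 6 participants, 15 pairs (paired t, Holm alpha = 0.05)
#>  setting_a setting_b      t p_holm    ES category
#>  omega_nm1 omega_nm2 -1.497  1.000 .56**    large
#>  omega_nm1 omega_nm3 -0.334  1.000   .15    small
#>  ...
#>  omega_nm3 omega_nm6  2.764  0.595 .78**    large
```

`tidy()` returns the full comparison table, `glance()` a one-row summary,
and `autoplot()` an effect-size tile plot; `peak_distribution(tab, "cl")`
tallies which setting each virtual participant rated highest (ties count
everywhere). With six heterogeneous raters nothing survives the Holm
adjustment here — effect sizes, which do not depend on sample size, are the
informative summary, exactly why they accompany every pair.

A thin command-line interface wraps the same functions
(`inst/cli/emgavatar`): `simulate`, `characterize`,
`synth emg|ratings|protocol`, `analyze`, with YAML configuration via
`load_config()`.

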