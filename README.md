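# cachalot

Passive-acoustic line-transect abundance estimation for sperm whales
(*Physeter macrocephalus*), with an availability-bias correction derived
from bio-logging data, and a sustainability check of ship-strike mortality
against the stock's recruitment capability.

Sperm whales are detected far more reliably by ear than by eye: their
echolocation ("usual") clicks carry for kilometres and are picked up by a
towed two-element hydrophone array. But a two-element array only gives a
conical, side-ambiguous *bearing* to each click, and a whale that is
silent while the vessel passes is missed entirely. This package implements
the full analysis chain that turns towed-array survey data into an
absolute abundance estimate:

1. **Localization** — successive bearings to an individual whale are
   crossed by least squares as the vessel steams past, the port/starboard
   ambiguity resolved by picking the side with the more coherent
   intersection, yielding the perpendicular distance *x* to the track line
   (`cross_bearings`).
2. **Detection function** — hazard-rate
   g(x) = 1 − exp(−(x/σ)^−b) and half-normal keys are fitted to the
   truncated distances by maximum likelihood and selected by AIC; the
   effective strip half-width is μ̂ = ∫₀ʷ g(x) dx, with a delta-method
   variance (`fit_detection`, `eshw`, `select_model`).
3. **Availability bias** — dive records from tagged whales are segmented
   into cycles of echolocating (t_e) and silent (t_ne) phases
   (`segment_dive_cycles`, `extract_phase_durations`); a Monte Carlo
   alternating-renewal model then estimates g(0), the probability that a
   whale on the track line is vocal at least once during the detection
   time window 2μ̂/v (`simulate_g0`), with a closed-form exponential-phase
   oracle (`analytic_g0_exponential`).
4. **Density and abundance** —

   D̂ = n / (2 μ̂ L (1 − o)) × 1/g(0),  N̂ = A × D̂

   with n detections, effort L, corner-overlap fraction o and survey area
   A; CVs combine in quadrature and intervals are log-normal
   (`estimate_density`, `abundance_estimate`, `lognormal_ci`).
5. **Sustainability** — recruitment r_max × N̂ is compared with observed
   annual mortality (`sustainability`).

A synthetic-data module (`generate_tag_series`,
`generate_survey_scenario`, `generate_perp_distances`) simulates
stereotyped sperm-whale dive cycles and whole surveys with known truth,
so every stage is validated end to end; `make_fixtures` +
`run_pipeline` chain everything on a directory of plain CSV inputs.

## Worked example

```r
library(cachalot)

cs <- canary_survey()   # published constants of the Canary Islands survey
est <- abundance_estimate(cs$n, cs$mu_km, cs$L_km, cs$overlap,
                          g0 = cs$g0, g0_sd = cs$g0_sd, A = cs$A_km2,
                          cv_er = cs$cv_er)
est
#> Density  D = 4.23 whales/1000 km^2 (95% CI 2.29-7.83)
#> Abundance N = 224 whales in 52933 km^2 (95% CI 121-415)
#> CV 32.2% (encounter 32.0%, ESHW 0.0%, g0 3.4%)
#> Inputs: n = 83, ESHW = 4.168 km, L = 2668 km, overlap 4.2%, g(0) = 0.92

sustainability(est$N, r_max = cs$r_max, mortality = cs$mortality)
#> Recruitment 2.5 whales/yr (N = 224, r_max = 1.1%/yr)
#> Observed mortality 2.0 whales/yr: within recruitment (margin 0.5)

g0 <- simulate_g0(phase_spec(), eshw_km = 4.168, speed_kmh = 11.8,
                  n_runs = 2000, seed = 1)
g0
#> g(0) = 0.918 (sd 0.041) over 2000 runs; detection window 42.4 min
```

With 83 whales localized over 2668 km of effort and an effective strip
half-width of 4.168 km, the survey strip holds 3.90 whales/1000 km² if
every whale on the line were heard; dividing by the simulated
availability g(0) ≈ 0.92 (whales spend ~60% of their time clicking, but
silent stretches occasionally outlast the ~42-minute detection window)
raises this to ~4.24 whales/1000 km², i.e. about 224 animals in the
52 933 km² survey area. Their maximum recruitment, at 1.1%/yr, is ~2.5
whales per year — of the same order as the two ship-struck strandings
recorded annually.

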