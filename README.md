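# morphspec

Do painted 3D prey models match the colours of the live animal *as the
relevant receivers see them* — and do predators treat them accordingly?
morphspec is an R package for researchers running model-presentation
experiments in visual ecology. It covers the two computational arms of such
a study:

**Colour arm.** Hyperspectral cubes of specimens and models (330–800 nm)
are calibrated against an 18% grey card: optional dark correction, a single
between-day illumination gain g = mean_b(card_ref[b] / card_target[b]),
conversion to relative reflectance, and Gaussian spectral smoothing
(9 taps, σ = 1.6 samples). Pooled anonymised pixel spectra are clustered
with a full-covariance Gaussian mixture fitted by EM (eigenvalue-floor
regularisation 0.01, tolerance 1e-6, AIC elbow selection over K = 3…15).
Cluster centroid colours are then compared under tetrachromatic avian
(peaks 372/456/544/609 nm, cone densities 1:2:4:3) and lacertid
(362/447/492/586 nm, 1:2:6:6) visual systems with the receptor-noise-
limited model: channel contrasts Δf_i = ln(q_i^a / q_i^b), noises
e_i = w·sqrt(η_LWS/η_i) (Weber fraction w = 0.1), and

    ΔS² = Σ_{i<j} (Π_{k∉{i,j}} e_k)² (Δf_i − Δf_j)²  /  Σ_i (Π_{k≠i} e_k)²

in just-noticeable differences (JND); pairs at ΔS ≥ 1 are discriminable.

**Behavioural arm.** Forced-exploration trials (one pheasant, one model,
600 s limit; an attack ends the trial) are scored into right-censored
alert/attack latencies, then analysed with from-scratch survival
machinery: Kaplan–Meier product-limit curves with Greenwood log-scale
confidence intervals, Cox proportional hazards via Newton–Raphson on the
partial likelihood with Efron ties, and the Schoenfeld-residual
proportional-hazards test (km/rank/identity time transforms).

Synthetic-data generators for both arms (`simulate_cube`,
`simulate_trials`) reproduce the statistical structure the analyses assume,
so the whole pipeline is testable without any recordings.

## Worked example

```r
library(morphspec)

## --- colour arm: simulate a two-day cube pair and run the pipeline
sim <- simulate_cube(cube_sim_spec(seed = 1))   # 6 colour classes, gain 1.25
res <- run_colour_pipeline(list(sim$day1, sim$day2), "colour_out",
         pipeline_config(k_values = 3:9, n_restarts = 2, decimate = 3, seed = 1))
res$gains
#>    day1    day2
#> 1.00000 1.24981
res$scan
#> <aic_scan> K in {3, 4, 5, 6, 7, 8, 9}; selected K = 6
res$jnd$reptile
#> <jnd_matrix> 6 colours under the reptile system
#>          colour_1 colour_2 colour_3 colour_4 colour_5 colour_6
#> colour_1    0.000    9.378    6.668    7.957    8.264    5.571
#> colour_2    9.378    0.000   14.198   16.674    2.175    8.275
#> ...
```

The recovered day-2 gain (1.24981) matches the simulated 1.25; the AIC
elbow recovers the six simulated colour classes; and every centroid pair
is above 1 JND for the lizard receiver (smallest distance 2.175), i.e. all
six colours are mutually discriminable.

```r
## --- behavioural arm: simulate trials and fit the survival models
tab <- simulate_trials(trial_sim_spec(seed = 1))   # 330 adult + 150 juvenile
fit <- cox_fit(tab, tab$alert_time_s, tab$alert_event, "age_class")
fit
#> <cox_model> n = 480, events = 123, ties = efron
#>                     coef    HR     se     z        p
#> age_classjuvenile 1.1028 3.013 0.1809 6.095 1.09e-09
schoenfeld_ph_test(fit)
#>           covariate      chi2 df         p transform
#> 1 age_classjuvenile 0.3719105  1 0.5419647        km
km <- km_estimate(tab$alert_time_s, tab$alert_event, strata = tab$age_class)
km_at_times(km$adult, 570)
#>   time  survival    ci_low  ci_high n_risk
#> 1  570 0.8258747 0.7854093 0.868425    259
```

Juveniles alert to the models about 3 times faster than adults in this
replicate (the generator's true hazard ratio is 2.77, inside the fitted
CI); the PH test finds no violation, as expected under the generator's
constant hazards; and adult survival at 570 s is 0.826 with 259 birds still
at risk.

Deposited study tables can be consumed directly: `read_latency_table()`
maps foreign CSV headers onto the canonical trial schema via a YAML
mapping, and `read_centroid_spectra()` reads wavelength-by-colour
reflectance tables for `pairwise_jnd()`.

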