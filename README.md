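# hillfuse

Fused sEMG + ultrasound driven Hill-type neuromuscular model of ankle
plantarflexion.

## What problem this solves

Controllers for ankle exoskeletons, exosuits and functional electrical
stimulation need a continuous estimate of the user's intended net
plantarflexion (PF) moment during walking — outside the motion-capture lab
that inverse dynamics requires. Surface electromyography (sEMG) senses the
neural drive but picks up cross-talk from neighbouring muscles; B-mode
ultrasound senses the mechanical deformation (muscle thickness, MT) but its
tracking drifts over repeated gait cycles. `hillfuse` is for researchers in
neuromuscular biomechanics and rehabilitation robotics who want to test
whether fusing the two modalities inside a physiological muscle model beats
either one alone.

## The model

Two muscle–tendon units (lateral gastrocnemius, soleus). Per muscle *i*, the
activation is a convex fusion of an sEMG-derived and an ultrasound-derived
component:

    N_i(t_k) = alpha_i u_i(t_k - tau) - beta1_i N_i(t_k-1) - beta2_i N_i(t_k-2)
    a1_i = (exp(A_i N_i) - 1) / (exp(A_i) - 1)
    a2_i = (MT_i - MT_min_i) / (MT_max_i - MT_min_i)
    a_i  = delta_i a1_i + (1 - delta_i) a2_i,   delta_i in [0, 1]

The musculotendon path is a two-segment geometry,
`l_mt = sqrt(l_OA^2 + l_OB^2 - 2 l_OA l_OB cos q)` with moment arm
`r = d l_mt / d q`; a piecewise tendon force–strain law (quadratic toe
region below strain 0.0127, linear above) is balanced against Hill-type
contractile + passive fascicle force at every sample by a bracketed root
solve, and the net PF moment is `sum_i F_mt_i r_mt_i`. The parameters
`{A_i, tendon slack length, F_max_i, delta_i}` are calibrated by bounded
Levenberg–Marquardt least squares against inverse-dynamics benchmark
moments, in single-speed or inter-speed mode, and the calibrated model is
validated on held-out stance cycles. Accuracy is reported as RMSE, N-RMSE
(percent of the subject's peak PF moment), BM-RMSE (per kg body mass) and
R². A seeded synthetic five-speed gait generator with known ground truth
makes the whole pipeline testable end to end. See
`vignettes/hillfuse-methods.Rmd` for assumptions and numerical choices.

## Worked example

```r
library(hillfuse)

trials <- forward_generate(synthetic_config(seed = 7))  # 5 speeds, known truth
fit <- hnm_fit(trials, mode = "inter", variant = "fused", seed = 7)
print(fit)
#> Hill-type neuromuscular model fit (fused variant, inter mode)
#>   objective (mean squared moment error): 28.01 (N.m)^2
#>   converged: TRUE after 23 iterations
#> Hill-type model parameters (per muscle):
#>           A   ltsk     Fmax  delta
#> lgs -0.7500 0.3754  900.000 0.0986
#> sol -1.8174 0.2122 2226.847 0.8384

evaluate_fit(fit)
#>   speed n_samples     rmse   n_rmse    bm_rmse        r2
#> 1  0.50       555 6.598697 5.167158 0.08459867 0.9396703
#> 2  0.75       500 3.406469 2.667460 0.04367268 0.9879954
#> 3  1.00       445 5.762598 4.512445 0.07387946 0.9730336
#> 4  1.25       390 5.434323 4.255387 0.06967081 0.9800605
#> 5  1.50       335 5.303017 4.152566 0.06798740 0.9844923
```

Held-out N-RMSE stays at 2.7–5.2 % of the peak moment (R² 0.94–0.99) at
every speed — well inside the 15 % "excellent" band — so the calibrated
model generalizes across the speeds it was calibrated on. Note the
calibration RMSE here (~5 N m) reflects the injected benchmark noise, and
with noisy data the per-muscle parameters are only weakly identified even
when the predicted moment is accurate (this replicate trades allocation
gain between the two muscles); on noise-free data the calibration recovers
the generating parameters nearly exactly (see `scripts/acceptance.R`
output). Compare variants with
`hnm_fit(..., variant = "semg_only" | "us_only" | "random_signal")` and
summarize a grid with `compare_variants()`.

A thin command-line front end (`inst/cli/hillfuse`) exposes
`simulate`, `calibrate`, `predict` and `evaluate` for shell pipelines.

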