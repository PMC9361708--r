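---
title: "Methods: a fused sEMG and ultrasound driven Hill-type neuromuscular model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a fused sEMG and ultrasound driven Hill-type neuromuscular model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillfuse)
```

## The problem

During walking, the ankle plantarflexors — here the lateral gastrocnemius
(LGS) and soleus (SOL) — generate the push-off moment in late stance. A
human–machine interface for assistive devices needs a continuous estimate of
this net plantarflexion moment from wearable sensing, without a motion-capture
laboratory. Surface electromyography (sEMG) measures the electrical correlate
of muscle excitation but suffers from cross-talk; B-mode ultrasound measures
an architectural correlate — muscle thickness (MT) — but accumulates tracking
drift over many gait cycles. The two fail differently, which is exactly the
situation in which fusing them should beat either alone.

`hillfuse` implements a calibratable Hill-type neuromuscular model whose
muscle activation is a convex fusion of an sEMG-derived and an
ultrasound-derived component, predicts the net plantarflexion moment over
the stance phase across walking speeds, and quantifies whether the fusion
actually helps.

## Model

### Weighted activation

For each muscle $i$, the normalized sEMG envelope $u_i(t_k)$ (band-pass
20–450 Hz, full-wave rectified, low-pass 6 Hz, divided by the subject's
cross-speed task peak) drives a delayed second-order recursive filter

$$N_i(t_k) = \alpha_i\,u_i(t_{k-\tau}) - \beta_{1i} N_i(t_{k-1})
  - \beta_{2i} N_i(t_{k-2}),$$

with $\beta_{1i} = \gamma_{1i}+\gamma_{2i}$,
$\beta_{2i} = \gamma_{1i}\gamma_{2i}$ and
$\alpha_i - \beta_{1i} - \beta_{2i} = 1$, $|\gamma_{1i}|,|\gamma_{2i}| < 1$.
The constraint pins the steady-state gain at exactly one, so a sustained
envelope level passes through unchanged; $\tau$ is the electromechanical
delay (30–120 ms). Neural activation then maps to muscle activation through
the nonlinear shaping

$$a_{1i} = \frac{e^{A_i N_i} - 1}{e^{A_i} - 1}, \qquad A_i \in [-3, 0],$$

evaluated as the analytic limit $a_{1i} = N_i$ at $A_i = 0$. The
ultrasound component normalizes thickness by subject-constant bounds,
$a_{2i} = (MT_i - MT_{i\min})/(MT_{i\max} - MT_{i\min})$, clipped to
$[0,1]$. The fused activation is the convex combination
$a_i = \delta_i a_{1i} + (1-\delta_i) a_{2i}$ with allocation gain
$\delta_i \in [0,1]$; $\delta_i = 1$ and $\delta_i = 0$ recover the
sEMG-only and ultrasound-only model variants.

We keep $\gamma_{1i} = \gamma_{2i} = 0.5$ and $\tau = 40$ ms fixed: the
calibration set is deliberately restricted to
$\{A_i, l^{sk}_{t_i}, F^{\max}_i, \delta_i\}$, and the filter poles and delay
are weakly identified from stance-phase data alone. Both are exposed in
`hnm_control()` / `activation_filter_params()` for users who want to fit
them externally.

### Geometry

The musculotendon path is a two-segment construction in the sagittal plane:
with segment lengths $l_{OA}$ (ankle centre to proximal junction) and
$l_{OB}$ (ankle centre to heel) and included angle $q$,

$$l_{mt} = \sqrt{l_{OA}^2 + l_{OB}^2 - 2 l_{OA} l_{OB} \cos q}, \qquad
  r_{mt} = \frac{\partial l_{mt}}{\partial q}
         = \frac{l_{OA} l_{OB} \sin q}{l_{mt}}.$$

Two conventions exist in the literature for the moment arm: the exact
derivative above, and a law-of-sines form that is twice it. The derivative
convention is the package default because it is the one consistent with the
geometry ($r$ *is* $\partial l_{mt}/\partial q$); `moment_arm(...,
convention = "printed")` reproduces the doubled form for comparison.

The anatomical ankle angle $\theta$ (dorsiflexion positive) maps to the
included angle as $q = q_{\mathrm{neutral}} + \theta$ with
$q_{\mathrm{neutral}} = \pi/2$ by default. The sign is chosen so that
dorsiflexion lengthens the plantarflexor path, which is the physiological
direction; with the opposite sign the tendon would be loaded during
plantarflexion, which is wrong for this muscle group.

### Contraction dynamics and the equilibrium solve

The tendon obeys a piecewise force–strain law in
$\xi = (l_t - l^{sk}_t)/l^{sk}_t$: zero when slack, a quadratic toe region
$1480.3\,F^{\max}\xi^2$ for $0 < \xi < 0.0127$ and a linear region
$(37.5\,\xi - 0.2375)F^{\max}$ beyond; the branches agree at the junction to
better than $10^{-4}$ relative and their slopes differ by about 0.3 %.
The fascicle force is Hill-type,

$$F_{mt} = \left(F^{\max} f_l(\tilde l)\, f_v(\tilde v)\, a
  + F^{\max} f_p(\tilde l)\right)\cos\phi,$$

with lengths normalized to the activation-dependent optimal fascicle length
$l_{m}^{0}(a) = l_{mo}^{0}(\lambda(1-a)+1)$, $\lambda = 0.15$, and
velocities to $v^{\max} = 10\,l_{mo}^{0}$ per second. The generic curve
shapes are standard choices, all exposed in `muscle_curves()`:

* $f_l(\tilde l) = \exp(-(\tilde l - 1)^2/0.45)$ — Gaussian, unimodal,
  $f_l(1) = 1$;
* $f_v$ — hyperbolic shortening branch $(1+\tilde v)/(1-\tilde v/0.25)$
  ($f_v(0)=1$, $f_v(-1)=0$) and an exponential eccentric branch rising to a
  plateau of 1.4, slope-matched at zero velocity so the curve is $C^1$ —
  a smooth curve keeps the least-squares Jacobian well behaved;
* $f_p(\tilde l) = (e^{4(\tilde l - 1)/0.6} - 1)/(e^4 - 1)$ above optimal
  length, zero below.

The pennation angle follows the constant-thickness assumption
$l_m \sin\phi = l_m^0 \sin\phi^0$. This gives the fascicle state in closed
form for a candidate tendon length: with $w = l_{mt} - l_t$ and
$h = l_m^0 \sin\phi^0$, $l_m = \sqrt{w^2 + h^2}$ and $\phi = \mathrm{atan2}(h, w)$
— the arcsin argument can never exceed one on this path, so the solve cannot
step outside the model's domain.

At each sample the tendon–fascicle force balance $F_t(\xi) = F_{mt}$ is a
scalar root problem in $l_t$, bracketed by construction: at the slack end
$F_t = 0 \le F_{mt}$, and at $l_t = l_{mt}$ the fascicle projection vanishes
so $F_{mt} = 0 \le F_t$. We solve it by safeguarded bisection to a bracket
width of $10^{-14}$ m (force residuals around $10^{-9}\,F^{\max}$, well
inside the asserted $10^{-6} F^{\max}$), warm information entering only
through the fascicle velocity, which is the backward difference against the
previous solved sample (zero at the first sample). The stored state keeps
that raw backward difference — smoothing a reported copy would break the
residual identity between the stored fields. A per-sample root solve was
chosen over integrating the contraction ODE because at a 100 Hz grid it is
robust, warm-startable and makes the equilibrium residual directly
assertable; the sequential inner loop is compiled (Rcpp). If no force is
transmitted at all, the solver returns the slack solution
$l_t = \min(l_{mt}, l^{sk}_t)$ exactly.

The net moment is $\sum_i F_{mt_i} r_{mt_i}$ over LGS and SOL.

### Calibration

Parameters $\{A_i, l^{sk}_{t_i}, F^{\max}_i, \delta_i\}_{i \in \{LGS,
SOL\}}$ (eight in the fused variant) minimize the mean squared difference
between the model's net moment and the inverse-dynamics benchmark over the
stance samples of the calibration cycles. Bounds are 50–150 % of the
literature values carried in `muscle_constants()` (for the negative $A$ the
interval is flipped accordingly and intersected with $[-3, 0]$); $\delta_i$
is bounded in $[0,1]$; the start is the midpoint of every box. The optimizer
is Levenberg–Marquardt with box constraints (`minpack.lm::nls.lm`), the
faithful equivalent of a bounded `lsqcurvefit`; parameters are rescaled to a
unit box so the Jacobian columns are comparably scaled. Single-speed mode
uses 10 steady cycles of one speed; inter-speed mode uses 2 steady cycles
from each of the five speeds. "Steady" means the cycle duration lies within
10 % of the trial median — the data-driven reading of steady gait. Held-out
cycles (up to 5 per trial, disjoint from the calibration draw) support
prediction tests. Cycle draws are seeded and reproducible.

Each calibration/prediction window is solved with a 15-sample mechanical
run-in before heel strike so the backward-difference velocity state settles
before any scored sample; the activation filter runs over the whole trial
(it is parameter-independent given fixed poles, so it is precomputed once).
The run-in transient decays by roughly an order of magnitude per few
samples; at 15 samples the objective floor on noise-free data sits below
$10^{-12}$ (N m)$^2$.

## Signal preprocessing

All filters are Butterworth (order 4 by default, matching the benchmark
pipeline convention) applied forward–backward. The forward pass uses
steady-state initial conditions derived from the first sample plus
odd-reflection padding, so a constant trace passes through bit-exactly — a
property the tests assert to $10^{-9}$ and which plain zero-padded
implementations violate at the record edges. Rate conversion to the 100 Hz
model grid uses a zero-phase anti-alias low-pass at 45 % of the target rate
followed by exact decimation (or grid interpolation for non-integer
ratios). Stance segmentation thresholds the vertical ground reaction force
at 20 N with a 0.2 s minimum contact — conventional gait-laboratory
settings — and discards contacts truncated by the record edges.

## The synthetic generator, and what it does not emulate

No public dataset accompanies this problem, so the package ships a
first-class generator (`forward_generate()`) whose defaults are the study
conditions: five speeds 0.50–1.50 m/s, 16 cycles per speed (about a 20 s
record), body mass 78 kg, and a benchmark moment produced by the forward
model itself under known in-bounds parameters
($\delta_{LGS} = 0.60$, $\delta_{SOL} = 0.50$). Kinematics follow a
periodic spline through key stance postures (early plantarflexion dip,
dorsiflexion ramp, push-off plantarflexion), with stride time and stance
fraction shrinking and activation burst amplitude growing with speed. The
sEMG channel is written directly in normalized-envelope units with its
cross-speed maximum scaled to exactly one, i.e. the task-peak normalization
holds by construction; the thickness channel is the exact inverse of the
activation normalization. Muscle geometry constants are gait2392-informed
choices verified once to keep the model in a physiological operating range
(fascicle lengths roughly 0.5–1.2 optimal, peak net moment 1.0–1.6 N m/kg
rising with speed).

The noise model is deliberately complementary: short multiplicative bursts
on the sEMG envelope (cross-talk analogue, SD 0.3, about 0.7 bursts/s),
slow linear drift on muscle thickness (tracking-error accumulation, slope
SD 0.05 mm/s), and white noise on the benchmark moment (SD 2 N m). Each
unimodal variant therefore has a distinct failure mode and fusion has a
mechanism to win — which is the hypothesis under test, not a foregone
conclusion: the allocation gain could in principle collapse to either
extreme.

What the generator does **not** emulate: real fascicle-tracking physics
(B-mode speckle, probe motion), antagonist co-contraction (tibialis
anterior), step-to-step kinematic variability beyond small amplitude
jitter, non-stationary noise, or any mismatch between the generating and
fitting model families. Passing the parameter-recovery and
fusion-advantage tests therefore shows the estimator is correct and the
fusion mechanism works as designed under model-consistent data; it does not
certify accuracy on real walking data, where model misspecification
dominates.

## Numerical choices and degenerate inputs

* Equilibrium bracket $[0.9\,l^{sk}_t,\ l_{mt}]$; slack fallback when the
  fascicle transmits no force; 100 bisection iterations capped, typically
  terminated by the $10^{-14}$ m bracket-width criterion.
* Neural-activation output and all activations clipped to $[0,1]$; the
  clip only acts on pathological inputs, all nominal paths stay inside.
* $A = 0$ handled as the analytic linear limit (no $0/0$).
* Pennation `pennation()` clamps arcsin arguments above one with a warning
  (reachable only when called directly with an inconsistent state).
* Optimizer tolerances `ftol = ptol = 1e-8`, at most 200 iterations, single
  start at the box midpoint; on noise-free data the fit converges in a
  handful of iterations.
* Problem sizes in the shipped tests: 8–16 cycles per speed at 100 Hz,
  benchmarks over 5–10 replicate seeds — enough for the comparisons to be
  stable while keeping a full run in minutes on one core.

## Worked example

```{r example, eval = FALSE}
trials <- forward_generate(synthetic_config(seed = 7))
fit <- hnm_fit(trials, mode = "inter", variant = "fused", seed = 7)
summary(fit)
evaluate_fit(fit)          # held-out RMSE / N-RMSE / BM-RMSE / R^2 per speed
correlation_table(fit$dataset$trials)
plot(fit)
```

## Known limitations

* Two muscles only; the medial gastrocnemius is folded into the LGS force
  scale and the antagonist is ignored, so absolute force values are
  effective, not anatomical.
* The allocation gain is subject- and condition-specific; nothing in the
  model makes it transfer across subjects.
* The activation filter poles and delay are fixed, not calibrated; mild
  misspecification of $\tau$ is absorbed by the shape factor.
* Inferential statistics (normality tests, repeated-measures ANOVA, effect
  sizes) are out of scope; `compare_variants()` reports descriptive
  summaries only.
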