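---
title: "Methods: tight-binding kinetics, ITC and DSF analysis in propkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tight-binding kinetics, ITC and DSF analysis in propkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propkin)
```

`propkin` analyses the three quantitative assays used to characterize a
propeptide acting as a tight, slow-binding inhibitor of its cognate
protease: chromogenic progress curves, ITC titrations and DSF melts. This
vignette records the models, the assumptions behind them, and the design
choices made where the underlying methodology leaves them open.

## 1. The tight slow-binding progress-curve model

### Mechanism and observables

The kinetic scheme is one-step association under competing substrate,

$$E + I \underset{k_{off}}{\overset{k_{on}^{app}}{\rightleftharpoons}} EI,
\qquad \frac{dP}{dt} = v_{spec}\,\frac{[E]_{free}}{E_t},$$

where $k_{on}^{app}$ is already reduced by the substrate competition
factor, so the ratio $K_i' = k_{off}/k_{on}^{app}$ is an *apparent*
inhibition constant (the substrate's $K_m$ is not needed and is not an
input). Because inhibitor concentrations are comparable to the enzyme
concentration (both nanomolar), free inhibitor is depleted by binding:
the complex concentration $x(t)$ obeys a Riccati equation whose
equilibrium roots $x_1 < x_2$ solve
$x^2 - (E_t + I_t + K_i')x + E_tI_t = 0$. Integrating product formation
gives the observable model

$$A(t) = v_s t + \frac{(1-\gamma)(v_0-v_s)}{k\gamma}
\ln\!\frac{1-\gamma e^{-kt}}{1-\gamma} + A_0,$$

with $v_s = v_0(E_t-x_1)/E_t$, $k = k_{on}^{app}(x_2-x_1)$ and
$\gamma = x_1/x_2$. An algebraic identity ties the depletion factor to
the velocities alone:

$$\gamma = \frac{E_t(1-v_s/v_0)^2}{I_t},$$

which is what `gamma_of()` computes and what the fitter exploits.

### Fitting choices

* **$\gamma$ is never a free parameter.** It is recomputed from the
  candidate $(v_0, v_s)$ at every residual evaluation, keeping the fit at
  four parameters $(v_0, v_s, k, A_0)$ and automatically consistent with
  the depletion theory.
* **Bounds by reparameterization.** $v_s = f\,v_0$ with $f \in [0, 1]$
  makes $v_s \le v_0$ structural; the lower bound on $f$ is set per curve
  so that $\gamma < 1$ throughout the search (at $\gamma \ge 1$ the model's
  logarithm is undefined — physically, velocities inconsistent with a
  reachable steady state).
* **Rate-constant bounds** $k \in [10^{-6}, 1]\ \mathrm{s^{-1}}$ bracket
  everything observable on a 15 min – 2 h assay window.
* **Initialization**: $v_0$ from the slope of the first 10% of points,
  $v_s$ from the last 20%, $A_0$ from the first point, $k$ multi-started
  over a geometric ladder (up to 5 restarts) because the curvature
  timescale is the one quantity a linear glance cannot give.
* **Unweighted least squares** — the absorbance noise is approximately
  homoscedastic over the small dynamic range of one curve, and no
  weighting scheme is part of the published procedure being reproduced.
* **Numerics**: the log term goes through `log1p`, so small $\gamma$ is
  continuous with the analytic $\gamma \to 0$ limit
  $A(t) = v_st + (v_0-v_s)(1-e^{-kt})/k + A_0$, which is used verbatim
  below machine epsilon.
* **Degenerate inputs**: an uninhibited trace fed to the tight-binding
  fitter converges to $v_s \approx v_0$ and is flagged
  `k_identifiable = FALSE` instead of failing; the $I_t = 0$ reference is
  routed to `fit_uninhibited()` (ordinary linear regression below 20% of
  the theoretical plateau), since $\gamma$ is undefined at $I_t = 0$.

### The Henderson regression

For exact steady states the identity
$I_t/(1-v_s/v_0) = K_i'\,(v_0/v_s) + E_t$ holds, so regressing
$y = I_t/(1-v_s/v_0)$ on $x = v_0/v_s$ across the series gives $K_i'$ as
the slope. Although the classical presentation of this linearization
omits the intercept, the identity above has one — equal to $E_t$ — and
forcing the line through the origin provably biases the slope upward (a
property test asserts this on a grid of exact steady states). The
regression therefore fits a free intercept, uses only the slope as
$K_i'$, and reports `intercept_minus_Et` as a self-consistency
diagnostic. Per-curve fitted $v_0$ is used for the x-coordinate (rather
than the uninhibited control's slope): it keeps each point's coordinates
internally consistent and makes the noiseless identity exact.

## 2. What the progress-curve generator emulates

The generator reproduces the study conditions: 2 nM enzyme, 0.5 mM
substrate, inhibitor at 0/1/2/4/8 nM, 1800 s windows sampled every 2 s at
25 °C and 900 s windows sampled every 1 s at 50 °C, with ground-truth
apparent constants $K_i' = 0.33$ nM (25 °C) and 20 pM (50 °C).

The split of each $K_i'$ into $k_{on}^{app}$ and $k_{off}$ is not an
observable of the fitted model and had to be chosen. We require the
series to *equilibrate on the assay window* — $k \cdot t_{end} \ge 4$ for
every inhibitor concentration in the grid — because the steady-state
velocity $v_s$ is otherwise an extrapolation rather than a measurement
and the whole Henderson construction presumes attained steady states
(the study's own fitted curves visibly plateau). That gives
$k_{on}^{app} = 2\times10^6\ \mathrm{M^{-1}s^{-1}}$ at 25 °C and
$5\times10^6$ at 50 °C (association accelerating with temperature, as the
100-fold drop in $K_D$ at 50 °C suggests), with
$k_{off} = K_i' k_{on}^{app}$.

The uninhibited velocity is expressed on the absorbance scale
(`v0_abs`, AU/s) because no turnover numbers for the substrate are
published; defaults (2×10⁻⁴ AU/s at 25 °C, 4×10⁻⁴ at 50 °C, with
ε₄₁₀ = 8800 M⁻¹cm⁻¹ for p-nitroaniline in a 1 cm cuvette) give traces of
a few tenths of an AU while consuming ~8% of the substrate over the
window — inside the 10% free-substrate budget that the integrated model
assumes. The generator warns when a configuration would breach it. Noise
is multiplicative Gaussian at 1% (spec default for photometric traces).

What the generator deliberately does **not** emulate: substrate
depletion feedback on the velocity (available as an ODE option for
robustness probing, but the fitted model assumes free substrate),
two-step isomerization mechanisms (EI ⇌ EI*), enzyme autolysis or
inhibitor degradation over the window, and instrument drift. Passing
recovery tests here therefore shows the estimator chain is correct and
noise-stable, not that real traces are free of those effects.

An independent check guards the closed form: the full-species ODE system
(E, I, EI, P; integrated with `deSolve::lsoda` at rtol 10⁻¹¹) must agree
with the Riccati/Eq.-integrated curve to ≤10⁻⁷ relative across a 5×5 grid
of $(k_{on}, k_{off})$, and must conserve enzyme and inhibitor mass to
10⁻⁹ relative. The double-root case $k_{off}=0, I_t=E_t$ (where
$k = 0$ and the general solution degenerates to a $1/t$ approach) has its
own closed form.

## 3. The ITC independent-sites isotherm

Displacement-cell dilution uses the standard half-volume bookkeeping for
cumulative injected volume $\Delta V$ into active volume $V_0$:

$$M_t = M_0\frac{1-\Delta V/2V_0}{1+\Delta V/2V_0},\qquad
X_t = X_s\frac{\Delta V/V_0}{1+\Delta V/2V_0}.$$

The occupied-site fraction $\Theta_i$ is the smaller root of
$\Theta^2-\Theta(1+X_t/nM_t+K_D/nM_t)+X_t/nM_t = 0$ (evaluated in the
stable product form), cumulative heat is $Q_i = n\Theta_iM_t\Delta H V_0$
and the modeled injection heat adds the average-displacement term
$(dV_i/V_0)(Q_i+Q_{i-1})/2$ — applied symmetrically in the generator and
the fitter, with a switch to disable it for sensitivity checks.

Fitting is Levenberg–Marquardt on $(\ln n, \ln K_D, \Delta H)$ —
positivity by construction, and the log scale matters because $K_D$
spans decades — multi-started over $K_D \in M_0\cdot\{10^{-4}…1\}$. The
geometry defaults mirror the study: 19 × 5 µL of 100 µM titrant into
5 µM cell protein, $V_0 = 950$ µL (a typical active volume for this
instrument class; not printed, hence configurable and always carried in
the fixtures), final molar ratio ≈ 2.1 so the titration spans the
equivalence point for $n \le 1$. $\Delta H = -50$ kJ/mol in the fixtures
is a free choice consistent with the exothermic peaks reported; only
$n$ and $K_D$ are printed constants.

The Wiseman value $c = nM_0/K_D$ is attached to every fit: at the 96 nM
fixture $c \approx 35$ (well-conditioned), at the 1.3 nM fixture
$c \approx 3400$, where $K_D$ is weakly identified *by construction* —
the fit emits a conditioning warning and recovery is only asserted to a
factor of two. This mirrors the practical reality that a sub-nanomolar
$K_D$ from a direct titration at micromolar cell concentration carries
little information, whatever uncertainty the instrument software prints.
Fits whose isotherm explains less than half the heat variance are flagged
`no_binding`. First-injection dropping is available (`drop_first`) but
off by default; on noiseless data it shifts $n$ by well under 2%.

## 4. DSF melting curves

The operational definition of $T_m$ is the half-point of the unfolding
transition. The model is a Boltzmann sigmoid between linear baselines,

$$F(T) = N(T) + \frac{U(T)-N(T)}{1+e^{(T_m-T)/a}},$$

so $T_m$ is the half-transition point by construction and $a$ (°C) sets
the transition width. Environment-sensitive dyes quench above the
fluorescence peak, where the two-state model no longer applies, so curves
are truncated at their global maximum before fitting
(`truncate_quench()`); an inverted curve (maximum at the first point) is
an error. Replicates are fitted independently and summarized as
mean ± sd.

Robust initialization matters more than the optimizer here: the starting
$T_m$ comes from the half-crossing of a heavily smoothed trace, with the
derivative peak and the ramp midpoint as fallback multi-starts (noisy
ramps can otherwise trap the fit at a boundary where the "transition" is
pushed past the data). The derivative estimator `tm_by_derivative()`
(smoothed dF/dT maximum, default 5-point window, configurable — wide
windows are advisable on full-resolution noisy ramps) is kept as a
cross-check; for symmetric transitions with flat baselines the two agree
to within one grid step, and sloping baselines offset the derivative peak
by a documented fraction of $a$.

The generator samples 25→99 °C in 0.05 °C steps (1 s sampling at the
0.05 °C/s ramp rate), with fixture truths $T_m$ = 67.8 °C and 85.2 °C,
width $a = 1.5$ °C, baseline levels/slopes and the exponential quench
tail (onset $T_m + 3a$, decay scale 4 °C) chosen as plausible
SYPRO-type values — strong enough that fitting *without* truncation is
visibly biased, which is what the truncation step exists to fix. Noise is
2% multiplicative. Real melts can show pre-transition dye binding, double
transitions and baseline curvature that this generator does not produce;
the recovery tests validate the estimator, not those phenomena.

## 5. Problem sizes, determinism and tolerances

The validation suite runs entirely on synthetic data: per-curve fits use
450–900 point traces; Ki′ recovery uses 10 seeded replicates of the
5-curve series at each temperature; ITC recovery uses the 19-injection
geometry (noiseless for the deterministic checks, 20 seeded replicates at
0.5 µJ noise for the stochastic one); DSF recovery uses 20 seeded
replicates of the 1481-point ramp. All generators are pure functions of
(fixture, seed) — regeneration is bit-identical and the caller's RNG
state is left untouched. Exact identities (Henderson slope/intercept,
analytic-vs-ODE agreement, mass conservation) are asserted at 10⁻⁷–10⁻¹⁰
relative; stochastic recoveries at the tolerances stated in the test
suite (median errors: 25% for Ki′, 15% for noisy $K_D$, 0.3 °C for noisy
$T_m$).

## 6. Known limitations

* One-step binding only; slow isomerization after binding (common for
  propeptide complexes) would need the two-exponential extension.
* True $K_i$ cannot be separated from the apparent $K_i'$ without the
  substrate's $K_m$, which is not an input.
* The ITC model is single-site/independent; no competitive or sequential
  variants, no baseline drift, no raw thermogram integration.
* DSF extracts $T_m$ only — no $\Delta H_{vH}$ or two-transition
  deconvolution.
* CSV is the only input format; vendor instrument exports must be
  converted upstream.
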