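# propkin

Quantitative analysis of propeptide–protease interaction assays in R:
tight slow-binding inhibition kinetics, isothermal titration calorimetry
(ITC) isotherms, and differential scanning fluorimetry (DSF) melting
curves — each paired with a mechanistic synthetic-data generator so every
fitting stage can be validated by parameter recovery.

It is written for enzymologists studying zymogen maturation: subtilase
propeptides act as tight, slow-binding inhibitors of their cognate
catalytic domains, with apparent inhibition constants in the picomolar
range and dissociation constants measurable by ITC in the nanomolar range.

## Models

**Progress curves.** Hydrolysis of a chromogenic peptide substrate
(p-nitroaniline release, A410) in the presence of a slow, tight-binding
inhibitor follows

```
A(t) = vs·t + (1−γ)(v0−vs)/(k·γ) · ln[(1 − γ·e^(−k·t))/(1 − γ)] + A0
```

with initial velocity `v0`, steady-state velocity `vs`, observed rate `k`,
and the depletion factor

```
γ = Et·(1 − vs/v0)² / It
```

which equals x₁/x₂, the root ratio of the equilibrium binding quadratic
`x² − (Et + It + Ki′)x + Et·It = 0`. `propkin` fits `(v0, vs, k, A0)` per
curve with γ recomputed from the candidate velocities at every step (never
a free parameter), then extracts the apparent inhibition constant Ki′ as
the slope of the Henderson linearization

```
It/(1 − vs/v0) = Ki′·(v0/vs) + Et
```

fitted with a free intercept whose agreement with Et is reported as a
diagnostic.

**ITC.** Integrated injection heats are fitted to the independent
(identical, non-interacting) binding-sites isotherm with
displacement-cell dilution bookkeeping, yielding stoichiometry `n`,
dissociation constant `KD` and enthalpy `ΔH`, plus the Wiseman
conditioning value `c = n·M0/KD` (KD is well determined roughly for
1 < c < 1000; outside that range a warning fires).

**DSF.** Melt curves are truncated at the fluorescence maximum (dye
quench) and fitted to a Boltzmann sigmoid with linear native and unfolded
baselines; `Tm` is the half-point of the transition by construction, with
a smoothed-derivative estimator as a cross-check.

## Worked example

Simulate a 25 °C inhibition series (2 nM enzyme, 0.5 mM substrate,
inhibitor 0–8 nM, 1% noise) and recover the apparent Ki′:

```r
library(propkin)
fx <- propkin_fixture("pernisine_25C")
curves <- simulate_inhibition_series(fx, sim_noise(seed = 11))
res <- fit_inhibition_series(curves, Et = 2e-9, fx$design)
res$henderson
#> Henderson analysis of a tight-binding inhibition series
#>   apparent Ki'      : 0.3275 nM (slope; se 0.0002 nM)
#>   intercept         : 1.984 nM (theory: Et = 2 nM)
#>   r-squared         : 0.999999 over 4 curves
```

The recovered slope (0.3275 nM) is the apparent inhibition constant; the
intercept near 2 nM confirms the Henderson identity against the known
enzyme concentration, and r² close to 1 shows the linearization holds.
The fixture's ground truth is Ki′ = 0.33 nM.

ITC and DSF stages work the same way:

```r
fi <- propkin_fixture("itc_25C")
fit_itc(simulate_itc(fi), fi$design)
#> Independent-binding-sites ITC fit
#>   n  = 0.680 sites
#>   KD = 96 nM
#>   dH = -50 kJ/mol
#>   c  = 35.4

fd <- propkin_fixture("dsf_UP")
fit_melt_sigmoid(truncate_quench(simulate_melt(fd, sim_noise(seed = 11))))
#> <melt_fit> dsf_UP: Tm = 67.53 C (width a = 1.51 C, sigmoid)
```

Real data enter through the CSV readers (`read_progress_csv`,
`read_itc_csv`, `read_melt_csv`; schemas in their help pages), and
`run_pipeline(fixture, seed)` chains simulation → fitting → a JSON report.

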