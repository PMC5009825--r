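# leukodyn

Compartmental modeling of normal and leukemic hematopoietic cell kinetics.

Acute myeloid leukemia does not only expand its own clone — it remodels
normal blood production: marrow cellularity falls, spleen counts rise and
then collapse, peripheral counts surge, and hematopoietic stem cells
(HSCs) slip into deep quiescence. `leukodyn` is an R package for asking
*which cellular mechanisms* produce those kinetics. It provides, for
three connected tissues (peripheral blood PB, spleen SP, bone marrow BM)
with nested stem/progenitor (HSC/HPC) and quiescence (G0) sub-models:

* a catalogue of elementary kinetic rate laws (zero-order, first-order,
  exponential-saturating, Michaelis–Menten, Hill) with Hill-type
  leukemic-influence multipliers `K(L)`;
* declarative model specification, structure enumeration (assigning each
  process a candidate form), and an exact leukemia-free control
  reduction;
* stiff-capable ODE simulation (`deSolve::lsoda`) with nonnegativity
  guards;
* genetic-algorithm parameter estimation with bounded
  Levenberg–Marquardt refinement against the fitness criterion `d ≤ s`
  (root-mean-square deviation within the experimental SD, per series);
* parametric analysis: mechanistic rate decomposition along fitted
  trajectories, interval fluxes (e.g. HSCs differentiating toward HPCs
  per day), and acting-factor ranking;
* model selection between rival mechanisms (cell mobility; HSC G0
  re-entry) by one-tailed Welch t-tests on per-restart fit errors;
* a synthetic-data generator that emulates the experimental measurement
  design (days 0, 7, 10, 12, 14, 21; three replicates; multiplicative
  lognormal noise), so the whole pipeline is testable without any
  external data.

The model core is the per-population balance

```
dX/dt = f_Prolif − f_Death − f_Export + f_Import
```

with each `f_i` an elementary form in the population count, optionally
multiplied by a suppressive `1/(1 + (L/θ_L)^h_L)` or stimulative
`1 + β L^h_L/(θ_L^h_L + L^h_L)` function of the local leukemic burden
`L`. See `vignette source in vignettes/leukodyn-methods.Rmd` for the full
model description, fitting machinery, and design rationale.

## A worked example

Generate a noisy tri-tissue dataset from the calibrated default scenario,
fit the model, and check the per-series fitness criterion:

```r
library(leukodyn)

data <- generate_kinetics(default_scenario(), seed = 1)
spec <- tissue_model("pb_coupled")
fit  <- fit_model(spec, data,
                  ga = ga_config(pop_size = 36, generations = 30),
                  seed = 1,
                  solver = solver_control(rtol = 1e-5, atol = 1,
                                          dense_dt = 21))
fit
#> <leuk_fit> tissue_pb_coupled: objective=3.6479 (seed 1, refined)
#>   tissue population     d     s  pass
#> 1     BM   leukemic 88959 75262 FALSE
#> 2     BM     normal  8969 11371  TRUE
#> 3     PB   leukemic  3664  7941  TRUE
#> 4     PB     normal  2083  5030  TRUE
#> 5     SP   leukemic 16733 32971  TRUE
#> 6     SP     normal  3994 13573  TRUE
```

Each row is one measured series: `d` is the root-mean-square deviation of
the fitted curve from the observed means (cells), `s` the pooled
experimental standard deviation of that series, and `pass` the `d ≤ s`
acceptance flag — here five of six series sit well inside the noise and
the steeply-growing BM leukemic series is marginal for this noise draw
(`ga_config(polish = TRUE)` adds a minimax stage that optimizes the worst
ratio directly). The aggregate objective is `Σ d/s` over series.

Mechanism questions are asked with the selection machinery:

```r
sel <- run_selection_experiment(
  data,
  list(pb_coupled = tissue_model("pb_coupled"),
       constant   = tissue_model("constant")),
  ga = ga_config(pop_size = 40, generations = 25),
  n_restarts = 10, seed0 = 0,
  solver = solver_control(rtol = 1e-5, atol = 1, dense_dt = 21))
sel
#> <leuk_selection_experiment> 2 variants, 10 restarts
#>   pb_coupled: mean error 3.6479
#>   constant: mean error 4.4909
#> <leuk_selection> pb_coupled vs constant: t=-9.496, one-tail p=2.747e-06, winner: pb_coupled
```

(Mean errors are per-restart whole-model aggregate objectives on the
same seed-1 dataset.) The PB-coupled mobility model — cell
import into spleen and marrow proportional to the circulating count —
beats the constant-import rival decisively, because only it reproduces
the peripheral-blood rise that the cross-tissue mass balance ties to the
marrow efflux.

A command-line wrapper over the same functions ships in
`inst/scripts/leukodyn-cli.R` (subcommands `synth`, `simulate`, `fit`,
`decompose`, `flux`, `select`).

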