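# gastroSim

Component-network simulation of gastric emptying with an ileal-brake
feedback loop, plus the ¹³C-octanoic-acid breath-test analytics needed to
calibrate it.

## What it is for

Gastric emptying — the stomach gradually releasing a meal into the small
intestine — is regulated by negative feedback: nutrients reaching the ileum
trigger vagal signalling through the CNS that slows further emptying (the
*ileal brake*). gastroSim is for researchers who want to simulate and
calibrate this loop against breath-test data, and more generally for anyone
who wants to assemble small physiological network models from a tabular
specification file without writing simulator code.

The package has two layers:

* **A plug-and-play simulation framework.** A model is a set of components
  wired by named *information channels*, declared row-wise in a delimited
  text file (`readModelSpec()`); per-component behaviour is a transfer
  function registered at run time (`registerFunction()`). The simulator
  (`simulateNetwork()`) advances in fixed cycles; reads see the previous
  cycle's writes, so arbitrary feedback wiring runs without algebraic-loop
  solving, and components can be added or removed at cycle boundaries.
* **A gastric-emptying application.** Stomach retention follows
  `N(t) = N0·[1 − (1 − e^(−kt))^b]` with `b = e^(k·T_LAG)`; emptied
  calories (scaled by the ileal caloric grade `CAL_GRD = 0.6`) drive a
  vagal afferent convolution response peaking `T_MAX = 10` min after each
  bolus; the CNS reflects it back, and whenever the sigmoid-transformed
  efferent signal exceeds the threshold `THD`, the emptying rate constant
  is reduced by `BRK = 3%` (a *brake event*). Breath-test curves
  `y = a·t^b·e^(−ct)` are fitted population-wide (`fitPopulationCurve()`),
  with the half-excretion time as a gamma median (`thalfFromFit()`), the
  lag time as the curve peak `b/c` (`tlagFromFit()`), χ²-score outlier
  screening and the S1/S2/S3 cohort selection policies
  (`selectSubjects()`), feeding the calibration pipeline
  (`calibrateGastricModel()`).

## Worked example

```r
library(gastroSim)

## forward placebo simulation with the reference calibrated parameters
sc <- runScenario(meal = 35.6, horizon = 240)
sc
#> GastricScenario:
#>   Thalf = 148.88 min, TLag = 91.72 min, 0 brake events
```

The meal of 35.6 caloric units half-empties after 148.88 min; under
placebo conditions the efferent signal never crosses the brake threshold,
so the trajectory is the pure retention curve.

```r
## synthetic breath-test cohort with injected artifacts, screened and fitted
cohort <- makeCohort(cohortRecipe(nSubjects = 8, nNegative = 1,
                                  nOutlier = 1, seed = 42))
fit <- fitPopulationCurve(selectSubjects(cohort, "S3"))
fit
#> BreathCurveFit: y = 0.4223 * t^0.9477 * exp(-0.009772 t)
#>   rss = 211.4 over 77 points; Thalf = 166.43 min, TLag = 96.98 min

predictionError(scenarioThalf(sc), measured = thalfFromFit(fit))
#>   abs   rel
#> 17.54 10.54
```

The S3 policy drops the constructed outlier subject; the population fit of
the remaining 77 points yields a measured half-excretion time of 166.43
min, and the placebo simulation misses it by 17.5 min (10.5%) — this
synthetic cohort was generated with inter-individual variation and is not
calibrated to the simulation.

An ileal infusion scenario adds
`infusion = list(rate = 0.5, per = 5, start = 30, end = 120)`; see the
vignette (`vignettes/gastric-emptying-model.Rmd`) for the brake-trigger
semantics (`brakeTrigger = "level"` vs `"edge"`) and why the infusion arm
is near-critical at the reference parameters.

A thin command-line wrapper with `validate`, `simulate`, `fit-curve`,
`calibrate`, `predict` and `synth` subcommands ships at
`inst/scripts/gastrosim.R`.

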