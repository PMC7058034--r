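# colonyhet

Colony-level quantification of phenotypic heterogeneity in fluorescence
reporter expression.

## The problem

Auxotrophic bacteria that report expression of a high-affinity nutrient
transporter with a promoter–GFP fusion can split into two stably inherited
subpopulations. On agar plates this shows up at the *colony* level: at low
methionine, roughly 45% of colonies are GFP+ (high *met*-transporter
expression) and the rest GFP−; at high methionine only GFP− colonies
remain. Phenotype switches during colony growth are rare (< 3% of colonies
at the lowest concentration) and appear as angular sectors.

`colonyhet` is for researchers who need to turn plate images of such
experiments into numbers: per-colony records, GFP+/GFP− classification,
dose–response and switching-rate curves, and the accompanying statistics.
Because the original image sets are not publicly deposited, the package
ships a seeded synthetic plate generator with exact ground truth, so the
whole pipeline is testable end to end.

## The model in brief

* **GFP+ dose–response**: fraction of GFP+ colonies vs methionine
  concentration *x* (mM), fitted by the steep step
  *y* = *a* − *a*/(1 + e^(−100·(*x*+*b*))) — plateau *a* at low dose, zero
  at high dose.
* **Switching rate**: fraction of sectored colonies vs concentration,
  fitted by *y* = e^(−*a*·(*x*−*b*)).
* **Classification**: two-component log-normal mixture (EM) on colony mean
  fluorescence; threshold at the posterior-0.5 point between the modes.
* **Detection**: binarize (log-domain Otsu) → size/shape/border filters on
  8-connected regions (circularity 4πA/P²) → algebraic circle fit →
  angular-bin sector score → optional manual curation.
* **Generations**: *n* = log(*X*)/log(2) for a colony of *X* cells founded
  by one cell, with *X* scaled up from flow-cytometry events counted in
  120 of 400 µL.

Full derivations, parameter defaults and design rationale are in the
methods vignette: `vignettes/colonyhet-methods.Rmd`.

## Worked example

```r
library(colonyhet)

cfg <- sim_config()                    # default simulated experiment
plate <- simulate_plate(cfg, concentration = 0.025, plate_index = 1)
records <- detect_colonies(plate)
head(records[, c("colony_id", "radius_px", "diameter_mm", "mean_fluor")])
#>   colony_id radius_px diameter_mm mean_fluor
#> 1         1     20.54       2.054      15642
#> 2         2     19.35       1.935      11230
#> 3         3     18.40       1.840      10077
#> 4         4     19.93       1.993      16801
#> 5         5     17.66       1.766      10293
#> 6         6     17.45       1.745       8991

mix <- fit_intensity_mixture(records$mean_fluor, seed = 1)
mix
#> two-component log-normal mixture fit
#>   component 1: exp(mean) 9740.4, log-sd 0.128, weight 0.613
#>   component 2: exp(mean) 18897.1, log-sd 0.140, weight 0.387
#>   threshold: 13561   degenerate: FALSE
```

The two intensity modes are the GFP− (~10,000 a.u.) and GFP+
(~19,000 a.u.) colony classes; colonies at or above the threshold are
labeled GFP+ by `classify_colonies()`.

```r
study <- run_simulation_study(cfg, plates_per_conc = 1)  # full grid demo
study$dose[1:3, ]
#>   concentration_mM  n n_gfp_pos frac_gfp_pos n_sectored frac_sectored
#> 1            0.025 80        31       0.3875          1        0.0125
#> 2            0.050 80        40       0.5000          1        0.0125
#> 3            0.100 80        32       0.4000          0        0.0000

study$step
#> step fit y = a - a/(1 + exp(-100 (t(x) + b))), transform = identity
#>   a = 0.4250 +/- 0.0162 (p = 4.74e-09)
#>   b = -0.7654 +/- 0.006241 (p = 2.19e-14)
#>   RSS = 0.01047 on 10 points
```

With one 80-colony plate per concentration the fitted plateau is
0.425 ± 0.016 — the GFP+ fraction at low methionine, within sampling error
of the generator's 0.45 truth; the step sits at ~0.77 mM. Generation
numbers from flow-cytometry counts:

```r
estimate_generations(300, analyzed_volume = 120, total_volume = 400)
#> 300 events in 120 of 400 uL -> X = 1000 cells -> n = 9.966 generations
```

A command-line interface covering the same stages (`simulate`, `detect`,
`classify`, `dose-response`, `fit-step`, `fit-switch`, `flow-sim`,
`flow-gate`, `generations`, `report`) is installed at `exec/colonyhet`;
every stage writes a checksummed run manifest.

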