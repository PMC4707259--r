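# rootzn

Root-efficiency analysis of zinc uptake in rice grown on Zn-deficient
soils.

Zinc deficiency is a major constraint on lowland rice, and genotypes differ
strongly in how well they tolerate it.  Two root-level mechanisms can drive
that difference: growing **more root** (crown-root number, root surface
area) and taking up **more Zn per unit root** — the *root efficiency*.
`rootzn` implements the growth-analysis machinery needed to separate the
two from field time-series data:

- Cumulative per-plant Zn uptake and root surface area over the 14–28 days
  after transplanting (DAT) are modelled as offset exponentials,

  U(t) = a·e^(bt) − c,  RSA(t) = p·e^(qt) − s,

  with model time t = DAT − 14 (uptake before 14 DAT is negligible: newly
  transplanted seedlings live off retranslocated shoot Zn while regrowing
  roots).  Fitting is bounded nonlinear least squares with the rate
  profiled out, deterministic under a fixed multi-start grid.

- The root efficiency is RE(t) = (dU/dt)/RSA(t) = a·b·e^(bt)/RSA(t),
  in µg Zn cm⁻² d⁻¹.  It lumps every mechanism that raises uptake per unit
  root area, including root-induced rhizosphere changes.

- Counterfactual curve swaps integrate hybrid pairings,
  U_cf(T) = ∫₀ᵀ RE_A(t)·RSA_B(t) dt, to attribute the tolerant–sensitive
  uptake gap to root efficiency, root growth, and their interaction.

- Companion tools: per-plant total-uptake estimation from shoot
  measurements (root Zn cannot be measured in puddled soil; it is estimated
  as 1.7× the shoot concentration), ANOVA-protected LSD genotype
  comparisons, Pearson trait correlations, planting-density fold-change
  analysis, shoot→root Zn retranslocation metrics from a root-excision
  solution experiment, and a synthetic-trial generator that emulates the
  full randomized-block design so the entire pipeline is testable offline.

## Worked example

The bundled reference coefficients (tolerant vs sensitive genotype groups
of a severely Zn-deficient field trial) reproduce the headline numbers:

```r
library(rootzn)
gc <- default_group_curves()
print(gc$tolerant)
#> <efficiency_curve 'tolerant'>
#>   uptake: <exp_curve uptake> 1.09 * exp(0.171 t) - 1.09  [ug/plant, t in d]
#>   rsa:    <exp_curve rsa> 110.2 * exp(0.082 t) - 22.2  [cm2/plant, t in d]
#>   RE(0) = 0.002118 ug cm-2 d-1

eval_curve(gc$tolerant$rsa, 0)    # 88.0 cm2/plant at 14 DAT
eval_curve(gc$sensitive$rsa, 0)   # 70.7

# tolerant roots are ~56% more efficient already at 14 DAT
root_efficiency(gc$tolerant, 0) / root_efficiency(gc$sensitive, 0)
#> 1.56

# give the sensitive root system the tolerant efficiency: uptake by
# 21 DAT rises from 1.2 to 1.8 ug/plant
counterfactual_uptake(gc$tolerant, gc$sensitive, 7)$uptake
#> 1.765561

decompose_difference(gc$tolerant, gc$sensitive, 7)
#> <attribution, 0-7 d> delta = 1.33 ug/plant
#>   RE 43.4% + RSA 38.3% + interaction 18.3%
decompose_difference(gc$tolerant, gc$sensitive, 14)
#> <attribution, 0-14 d> delta = 6.27 ug/plant
#>   RE 29.3% + RSA 51.0% + interaction 19.6%
```

So at 21 DAT root efficiency explains ~43% of the uptake gap and root
growth ~38%; by 28 DAT root growth dominates (~51%) — the two mechanisms
contribute roughly equally overall, and the remainder is their interaction
(the extra root area working at the higher efficiency).

The full pipeline runs from a tidy plant-level CSV or a simulated trial:

```r
run_pipeline(list(simulate = list(experiment = "field", seed = 1,
                                  noise_cv = 0.10),
                  outdir = "report"))
```

which writes fitted curves (JSON), an RE grid, the attribution table and
group summaries.  `inst/scripts/rootzn` exposes the same stages as CLI
subcommands (`simulate`, `fit`, `counterfactual`, `density`,
`redistribution`, `report`).

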