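# pemosi

Mechanistic PK/PD modelling of schedule-dependent synergy between
pemetrexed (PEM) and osimertinib (OSI) in EGFR-mutant NSCLC xenografts.

Sequential PEM→OSI dosing with a ~48 h gap inhibits HCC827 xenograft
growth far more strongly than concurrent PEM + OSI. `pemosi` implements
the quantitative-systems-pharmacology explanation as a coupled ODE model —
two-compartment PK for both drugs, indirect-response turnover of the
folate pathway (PEM stimulates loss of folate-metabolising enzyme, the
folate deficit `D = max(0, 1 − Folate)` drives cytotoxicity) and of EGFR
signalling (OSI stimulates signal loss; damaged cells feed back on
synthesis, the pro-survival rebound), wired into an extended Simeoni
tumour model

```
dX1/dt = λ0·X1·EGFR^γEGFR / [1 + (λ0/λ1·X)^ψ]^(1/ψ)  −  k1·X1·(1 + Emax,fol·D^γfol/(EC50,fol^γfol + D^γfol))·min(EGFR,1)^γG1
dXi/dt = transit chain X2→X3→X4→dead at rate k2·(1 + kbim·max(0, 1−EGFR)^γbim)
```

so that the G1-arrest antagonism (concurrent dosing), the EGFR rebound
(PEM alone) and the Bim-mediated apoptosis boost (OSI after PEM) all
emerge from one parameter set. Around the core model the package provides
the in vitro→in vivo extrapolation chain (free-fraction potency
correction, molar↔mass conversion, growth-rate scaling), the stepwise
calibration fitters (EGFR recovery, 4PL dose-response, mini tumour
models, two-compartment PK, NCA and the 0.8–1.25 bioequivalence DDI
rule), dosing-interval comparison, Sobol global sensitivity analysis
(Saltelli sampling, Jansen estimators), Monte Carlo virtual-population
ORR simulation with BIM-deletion genotypes, and synthetic-data generators
with known ground truth for every calibration input.

## Worked example

```r
library(pemosi)

## IVIVE: in vitro OSI potency (14.49 nM) to the plasma scale
ec50_to_plasma(14.49, binding_context(fu_plasma = 0.0535, protein_ratio = 10),
               drug_osi())
#> [1] 48.86402        # ug/L

## How much does the PEM->OSI interval matter?
cmp <- compare_intervals(default_params())
cmp$summary
#>   interval_h final_volume_mm3 final_TGIPct total_dead_mm3
#> 1          0        470.26896     55.56808       175.9405
#> 2         24        287.80619     72.80751       204.1342
#> 3         48        110.36176     89.57281       254.7245
#> 4         72        102.66044     90.30045       265.0416
#> 5         96        110.48154     89.56149       270.3223
```

Day-21 endpoint volumes: concurrent dosing (interval 0) ends at 470 mm³,
a 24 h gap at 288 mm³, and a 48 h gap at 110 mm³ — less than half the
24 h value — while 72 h and 96 h add nothing (all within 10% of the 48 h
endpoint). That is the schedule-dependence the model was built to
explain: by 48 h the folate-driven damage pool has plateaued, so later
OSI starts forfeit growth control without gaining damage.

```r
## Reduced OSI sensitivity erases the sequential advantage
perturb_scenario(default_params(), c(EC50_osi = 5, Imax_osi = 0.2))$gap
#>    baseline    modified
#> -359.907213   -7.076904   # sequential-minus-concurrent endpoint volume (mm3)
```

## Configuration-driven runs

`load_config()` reads a YAML/JSON parameter file (units mandatory for
rates and concentrations; per-day and per-hour declarations are converted
automatically) and `run_pipeline()` executes selected stages (`synth`,
`fit`, `simulate`, `intervals`, `population`), writing CSV/JSON artifacts
plus a manifest carrying the master seed and the configuration hash. A
thin command-line wrapper lives in `inst/scripts/run_pipeline.R`.
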