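# bactaging

Replicative aging analysis for bacterial single-cell and population growth
data.

Bacteria followed in a "mother machine" — a microfluidic array that traps one
mother cell per dead-end channel — divide for tens of generations, then stop
proliferating, persist for hours in a senescent, post-replicative state, and
finally lyse. `bactaging` provides the full analysis chain for such
experiments, together with the matching population-level growth-curve
analysis and a synthetic-data generator with known ground truth, so every
stage of the pipeline can be validated by parameter recovery.

## What it computes

**Single-cell lineages.** From a cell-length time series the package detects
division events (sawtooth resets), extracts per-cycle birth length (BL),
exponential elongation rate (EER, the slope of ln length vs time) and
doubling rate (DR, the inverse cycle duration), and aligns per-generation
statistics to the *last replicative cycle*, the standard way to expose
end-of-life changes when the age at trap entry is unknown.

**Lifespan decomposition.** Using a viability dye (propidium iodide, which
enters only permeabilised cells) the observed lifespan splits into the
apparent replicative lifespan (aRL, up to the last division) and the
post-replicative lifespan (PRL, from there to dye entry). Death phenotypes
are classified from morphology and a chromosome-label fluorescence channel:

* **Ia** — chromosome lost at the last division (sudden single-frame drop of
  the label),
* **Ib** — chromosome retained, label decaying gradually during the PRL,
* **II** — filamentation: the cell's length in its final cycle exceeds 3x
  the cohort mean cell length,

with cells that lose the label plasmid mid-life excluded from the counts.

**Survival and aging rates.** Survival functions are estimated with the
Kaplan–Meier product-limit estimator
S(t) = prod over t_i <= t of (1 − d_i / n_i),
and fitted with the Gompertz mortality law

    S(t) = exp(−(a/b)(e^{bt} − 1)),   λ(t) = a·e^{bt},

whose rate *b* (the aging, or hazard-accumulation, rate) quantifies how fast
mortality risk grows; *b* = 0 is the memoryless, non-aging limit. Fits are
available as nonlinear least squares on the KM curve or as a censoring-aware
maximum-likelihood estimate, both with bootstrap 95% confidence bounds, on
an hours or generations clock.

**Population growth curves.** From OD600 series the package extracts the
maximum growth rate (MGR), saturation point of growth (SPG), area under the
log-growth curve (AUC) and exponential-phase duration (Texp), assembles
z-scored strain-by-feature panels across media, and reproduces the
principal-component + average-linkage clustering workflow used to group
mutant strains by growth profile.

**Population model.** A stochastic three-compartment, age-structured model
(proliferating → post-replicative → lysed) links single-cell division,
age-dependent replicative arrest (Gompertz hazard) and lysis to the apparent
culture-level growth curve, including extinction probes as a function of the
aging rate.

## Worked example

```r
library(bactaging)

cfg    <- lineage_sim_config()                 # LB-like: 30-min doubling, 3-min frames
cohort <- simulate_cohort(cfg, n_cells = 150, seed = 42)
res    <- analyze_cohort(cohort$traces)

head(res$records[, c("cell_id", "arl_h", "arl_generations", "prl_h",
                     "lysis_time", "phenotype")], 4)
#>      cell_id arl_h arl_generations prl_h lysis_time phenotype
#> 1 cell_00001 27.10              54 11.35      38.45        II
#> 2 cell_00002 25.85              52  7.70      33.55        II
#> 3 cell_00003 19.20              38 10.55      29.75        Ia
#> 4 cell_00004  7.95              16  6.10      14.05        Ib

phenotype_fractions(res$records)
#>   strain medium   n n_excluded   frac_Ia frac_Ib   frac_II
#> 1     wt     LB 150          0 0.3866667    0.32 0.2933333

fit_gompertz(lifespan_events(res$records), n_boot = 500, seed = 1)
#> <gompertz_fit> (nls_on_km, hours clock)
#>   a = 0.004314 1/h (95% CI 0.002585-0.006719)
#>   b = 0.1018 1/h (95% CI 0.087-0.1204)
#>   n = 150 (150 deaths), KM RMSE = 0.019
```

Each row of the lifespan table decomposes one cell: this cohort's first cell
divided 54 times over 27.1 h, spent 11.4 h post-replicative and filamented
(phenotype II). The recovered phenotype fractions track the generator's
planted (0.4, 0.3, 0.3) mix, and the fitted aging rate b = 0.102/h (95% CI
0.087–0.120) recovers the configured Gompertz aging rate of 0.1/h.

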