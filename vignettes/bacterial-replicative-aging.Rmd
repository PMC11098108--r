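---
title: "Methods: quantifying bacterial replicative aging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying bacterial replicative aging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactaging)
```

This vignette is the package's own account of the models it implements, the
choices behind its defaults, and what its synthetic-data tests do and do not
demonstrate about real data.

## The measurement setting

A mother machine traps one bacterial "mother" cell per dead-end channel and
images it every few minutes for days. The observable per cell is a
multi-channel time series: cell length (and width), a constitutively
expressed DNA-binding fluorescent label reporting chromosome presence, and a
viability dye that only enters cells whose membrane has become permeable.
Because the cell has already divided an unknown number of times before
entering the trap, its replicative lifespan is only *apparent* (aRL); the
phase between the last division and dye entry is the post-replicative
lifespan (PRL). `bactaging` assumes traces are already extracted from the
images; no image processing is performed.

## Survival model

Lifespan distributions are modelled with the Gompertz law,

$$S(t) = \exp\!\Big(-\frac{a}{b}\big(e^{bt} - 1\big)\Big), \qquad
  \lambda(t) = a\,e^{bt},$$

where $a$ (1/h or 1/generation) is the initial hazard and $b$ the aging
rate: the exponential rate at which mortality risk accumulates. $b = 0$ is
the memoryless limit $S(t) = e^{-at}$, implemented as an exact branch and
approached continuously (the code evaluates $(a/b)(e^{bt}-1)$ via `expm1`,
so values like $b = 10^{-8}$ are numerically safe). Survival curves are
estimated nonparametrically with the Kaplan–Meier product-limit estimator;
ties follow the standard convention that records censored at a death time
are still at risk at that time.

`fit_gompertz()` offers two routes:

* **`nls_on_km`** (default): nonlinear least squares of $S(t;a,b)$ against
  the KM curve evaluated at its death times. This mirrors how survival
  curves are usually fitted in the literature and is the default because the
  quantity of interest is the plotted survival function itself.
* **`mle`**: the censoring-aware likelihood
  $\prod_{\text{deaths}} \lambda(t_i) \prod_{\text{all}} S(t_i)$. For fixed
  $b$ the maximising $a$ is closed-form, so the fit is a one-dimensional
  profile search over $b$ — no starting values, deterministic, and robust.

Both constrain $b \ge 0$: a negative aging rate is reported as a fit pinned
at the boundary (`boundary_b`) rather than allowed, since "negative aging"
from sampling noise would otherwise leak into downstream comparisons.
Confidence bounds come from a nonparametric bootstrap over cells
(percentile, default 1000 replicates, seeded) rather than asymptotic
covariances, because real groups are small (tens of cells). The least-squares
core (`fit_gompertz_curve()`) takes L-BFGS-B from two data-driven starts
(exponential-rate scale; slope of the log cumulative hazard) and polishes
with Levenberg–Marquardt, which on noiseless curves recovers generating
parameters to numerical precision.

Fits carry a `clock` label (`"hours"` or `"generations"`). Whether the death
event is lysis (dye entry) or the end of replication is not hard-wired
either: `lifespan_events()` exposes both `event = "lysis"` and
`event = "arrest"`, and the generation clock applies to the replicative
phase. Both clocks and both event definitions are legitimate readings of a
lifespan experiment, so they are explicit arguments the caller must name.

## Lineage analysis

Divisions are detected as single-frame relative length drops of at least
`drop_fraction` (default 0.25): symmetric division halves the length in one
frame, while between-frame elongation at a 30-min doubling time and 3-min
framing is about 7%, so the two populations of frame-to-frame changes are
widely separated. Per cycle, the elongation rate (EER) is the least-squares
slope of $\ln(\text{length})$ on time over the cycle's frames — a fit using
all frames rather than an endpoint ratio, to be robust to single-frame
noise; whether the underlying experimental quantity was a per-cycle fit or
an averaged frame-wise derivative is not decidable from the literature, and
the per-frame slopes remain computable from the trace if needed. The
doubling rate is the inverse cycle duration, so `dr * duration == 1` holds
identically.

The segment before the first detected division and cycles truncated by the
movie are excluded from population statistics (the cell's age at trap entry
is unknowable); the non-dividing tail after the last division is kept
separately as the terminal segment. `align_to_last_replicative()` indexes
each cell's cycles backwards from generation 0, the last cycle with EER
above `eps_growth` (default 0.01/h, the operational meaning of "nonzero
growth rate"), and the reference mean excludes the last three generations
(indices 0, −1, −2) — end-of-life deviations are judged against a baseline
that cannot be contaminated by them. Dispersion statistics use the
population (n-denominator) SD in CV = SD/mean.

## Lifespan decomposition and phenotypes

Dye entry is the first time the viability channel exceeds
`baseline mean + k_sigma * baseline SD` (defaults: 5 SD over the cell's own
first 10 frames) for at least `sustain_frames = 2` consecutive frames.
Because 10 frames give a noisy SD estimate, an occasional cell would draw a
threshold low enough for two-frame noise runs to fire hours early. Dye entry
is absorbing, so the detector additionally requires persistence: the median
of the ~20 frames following a candidate must also exceed the threshold.
This rejects transient speckle without moving the detected time (the first
frame of a true step is unchanged) and without altering the declared
threshold parameters.

The aRL ends at the last detected division (or the last growing frame if no
division is on record); PRL runs from there to dye entry, so
`arl_h + prl_h = lysis_time` exactly for uncensored cells, and censored
cells carry the observed PRL lower bound.

Phenotype classification applies rules in a fixed order:

1. **excluded** — a sudden chromosome-label drop *before* the final cycle
   while the cell keeps dividing is plasmid loss of the label, not death;
2. **II** — maximum length during the final cycle or PRL above
   `filament_factor` (default 3) times the cohort mean length. The cohort
   mean is computed from replicative-phase frames only, so filamented
   corpses do not inflate the baseline. Filamentation is assessed only in
   the final cycle and PRL: transient mid-life filaments that resume
   division do not trigger II (whether such cells were ever counted as II
   experimentally is ambiguous; this package's rule is the conservative
   reading that II means a terminal replicative crisis);
3. **Ia** — a single-frame label drop of at least `gfp_drop_fraction`
   (default 0.5) of the replicative-phase median level, within one frame of
   the last division;
4. **Ib** — the residual class: label retained, typically decaying
   gradually. "Gradual" needs no threshold of its own precisely because Ib
   is the residual.

Drops are measured relative to the replicative-phase median signal, so
fluctuations around a near-zero post-loss signal can never re-trigger the
rule. Censored, non-filamented cells are `I-unresolved`, as are
non-filamented cells without a chromosome channel.

## Growth curves and strain panels

All parameters are defined on $y = \ln(N/N_0)$. $N_0$ is the mean of the
first three OD readings — a single noisy first read would otherwise bias
every derived quantity — and ODs below $10^{-4}$ are clipped before the log
and counted. The four parameters: MGR is the maximum sliding-window
least-squares slope of $y$ (window default 5 points; the window is exposed
because published extraction pipelines differ in smoothing details); SPG is
the maximum of a 3-point running median of $y$ (a plateau statistic should
not be set by one noisy maximum); AUC is the trapezoidal integral of $y$
over the full record; Texp is the total time the local slope stays above
`exp_fraction` (default 0.5) of MGR — Texp has no standard operational
definition, so the fraction is a named argument rather than a constant.

Panels average replicates per strain and medium, require a complete
strain-by-medium grid (missing cells are an error, never silently imputed),
and z-score each parameter-by-medium feature column. Decomposition is an SVD
of the centred matrix; clustering is average-linkage on Euclidean distances
over the first two component scores, matching the convention of grouping
strains on the leading two principal components; both the number of
retained scores and of clusters are arguments.

## Synthetic data: what it emulates, and what it does not

The generator plants known ground truth underneath every downstream
operation. Its defaults describe a fast-growth condition: 0.5 h mean
doubling time (media with ~31 and ~100 min doubling times are emulated by
changing `mean_doubling_time`), frames every 3 min (the fast end of typical
3–10 min acquisition), birth length 2.5 µm, symmetric division
(`division_ratio` 0.5), Gompertz lifespans with $a = 0.01$/h, $b = 0.1$/h
(median ~21 h, in the range of observed mother-machine survival), a
truncated-normal PRL of mean 8 h and SD 3 h (observed PRL distributions are
broad and hours-long; no generative form is established, so the simplest
non-negative unimodal choice is used), phenotype mix (0.4, 0.3, 0.3), and a
72 h movie, long enough that censoring is negligible at these rates while
still finite so censoring paths stay exercised.

Noise model: per-cycle elongation rates are multiplied by unit-mean
lognormal noise (default SD 0.05) — multiplicative and positive by
construction; fluorescence channels get additive Gaussian noise (default SD
10 a.u. against a 1000 a.u. label baseline and a 500 a.u. lysis step).
Phenotype signatures are planted literally: Ia drops the label to 5% of
baseline at the last division frame; Ib decays it with a 2 h half-life
during the PRL; II grows without dividing at 0.7x the cycle elongation rate
until 1.3x `filament_factor` times its replicative-phase mean length. Two
generator-level regularisations keep planted truth realisable: each lineage
is conditioned on completing at least one division (a trapped mother is by
construction observed dividing), and a phenotype II cell's PRL is floored at
the time needed to cross the filament threshold plus two frames.

Deliberately **not** simulated: length measurement noise (the length signal
is smooth within cycles, so division detection and EER recovery on synthetic
data are near-exact — recovery rates on real, pixel-noisy traces will be
lower); birth-size variability and division asymmetry (the old-pole /
new-pole distinction); growth-rate inheritance between cycles; plasmid-loss
events (the excluded class is exercised with constructed traces instead);
trap geometry and imaging artefacts. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated noise model, not
performance bounds on microscopy data.

## Population model

The population model is a deliberately minimal reconstruction consistent
with the three-compartment picture (proliferating, post-replicative, lysed);
its outputs are labelled a reconstruction and no claim of equivalence to any
specific published formulation is made. Proliferating cells divide at rate
$r$; each cell arrests at the age-dependent hazard $a e^{b\,\text{age}}$;
post-replicative cells lyse at rate $\mu$. Division produces exactly two
cells with no growth-rate inheritance. The default `"lineage"` age clock
keeps the aged mother's clock running and starts daughters at age zero —
the clock the mother-machine measurement actually follows; the `"cell"`
clock (both post-division cells inherit the mother's age) is provided
because pole-age arguments admit either reading.

Simulation is event-driven with exact waiting times: exponential draws for
the constant division and lysis rates, and an exact inverse-CDF draw of the
residual Gompertz arrest time conditional on current age,
$w = \frac{1}{b}\log\!\big(1 - \tfrac{b}{a}e^{-b\,\text{age}}\log U\big)$.
An exact draw was preferred over hazard thinning against an upper bound
because the age-dependent hazard is unbounded over a cell's life, so
thinning would need an arbitrary age cap and extra rejections; the inverse
CDF is exact, cap-free and faster. Cells are processed depth-first from a
stack (runtime linear in events); counts are reconstructed on a recording
grid from the sorted event times, which makes the flow-balance identities
(births − net proliferating change − arrests = 0; arrests − post-replicative
− lysed = 0) exact by construction and checkable. Beyond `max_cells`,
daughters are either an explicit overflow error or, with
`subsample = TRUE`, dropped and counted — a recorded truncation of the
branching process, biased low by design and flagged, intended for extinction
probes where only the extinct/alive outcome matters.

## Problem sizes and numerical tolerances in the test suite

The suite validates: sampler/survival round trips at $10^{-12}$;
distributional agreement of $10^5$ sampled lifespans with the closed form at
Kolmogorov–Smirnov distance < 0.01; parameter recovery of $(a, b)$ from
1000 lifespans within 10% with bootstrap-interval calibration over 100
seeded replicate experiments (200 bootstrap draws each); division, dye-entry
and PRL recovery on a 500-cell cohort at default noise (within one frame);
phenotype agreement on 200 noiseless and 2000 noisy cells; growth parameters
against closed forms within 1%; and population-model limits (pure-birth
growth slope within 5%, Gompertz-cohort agreement at KS ≤ 0.02 with $10^4$
cells). These sizes were chosen as the smallest at which the binomial /
Monte-Carlo error of each check is comfortably below its tolerance.

## Known limitations

* Recovery figures quoted by the tests are upper bounds on real-data
  performance (no length measurement noise; see above).
* The Gompertz fits assume a homogeneous cohort per group; frailty or
  competing-risk structure is out of scope.
* The population model has no nutrient feedback or medium switching, so it
  describes early, resource-unlimited growth, not saturation.
* Generation-clock fits treat generation counts as discrete times; with
  heavy ties the KM curve has few steps and the least-squares route can be
  unstable below a few dozen cells (the profile MLE is preferable there).
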