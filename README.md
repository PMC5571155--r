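# pathkin

Sequential Bayesian identification of branched chemical transformation
pathways and their reaction kinetics, with sound uncertainty propagation
between calibration stages.

## The problem

Trace chemicals in complex biological matrices — the motivating case is
heroin and codeine biomarkers (HER, 6MAM, MOR, MORG, COE, NCOE) in
untreated wastewater, the raw signal of wastewater-based epidemiology —
transform along branched abiotic/biotic pathway networks. The kinetic
model is linear ASM-X-style:

```
dC_i/dt = Σ_j∈form(i) s_j r_j − Σ_j∈rem(i) r_j
r_j = k_abio,j · C_src(j)            (abiotic, k in 1/d)
r_j = k_bio,j · X_TSS · C_src(j)     (biotic, k in L/gTSS/d)
```

Estimating all rate constants at once from batch-experiment concentration
series is badly conditioned: parameters are correlated and posteriors
uninformative. `pathkin` implements a level-wise alternative: parameters
are estimated in the order the pathway dictates, and the **95% credibility
interval and fitted posterior distribution** of each upstream parameter
become the prior of that parameter at every later level. Parameters are
*primary* (first estimated, uniform prior), *subsidiary* (propagated from
upstream) or *combinatorial* (the total removal rate of a branching
compound, `k_X = k_X,1 + k_X,2`, split into its members one level later
under a soft sum constraint).

Around that core the package provides:

* a DE-MC sampler with a past-state archive, snooker and subspace
  (crossover) updates, driven by the range-normalized SSE objective;
* Theil-inequality-coefficient (TIC ≤ 0.3) posterior filtering;
* two benchmark schemes — *lumped* (everything at once, wide priors) and
  *fixed-upstream* (upstream medians frozen; branch pairs split by the
  hard constraint `k_X,2 = k_X − k_X,1`);
* assessment: RMSE/MAE, Monte Carlo prediction bands, ARIL/coverage/ILTC,
  collinearity (LCC, |LCC| > 0.7 non-identifiable), relative-CI checks,
  SRC global sensitivity;
* pathway-gap discovery: residual/runs/mass-balance diagnostics that flag
  systematic deviations and propose new branches to unknown
  transformation products;
* a synthetic-data generator with a ready-made heroin/codeine fixture, so
  every stage is testable without measured data.

## Worked example

```r
library(pathkin)

fx <- heroin_codeine_fixture(seed = 101)   # network + synthetic batch data
plan_levels(fx$network)
```

```
<pk_plan> 6 sub-levels over 4 levels
  1(A): primary [k_abio_HER] comb [k_abio_COE{=k_abio_COE_1+k_abio_COE_2}] frozen [k_abio_MORG] | data: HER, MORG, COE
  2(A): primary [k_abio_COE_1, k_abio_COE_2, k_abio_6MAM, k_abio_NCOE] | data: HER, MORG, COE, 6MAM, NCOE
  2(B): primary [] comb [k_bio_HER{...}, k_bio_MORG{...}, k_bio_COE{...}] | data: HER, MORG, COE
  3(A): primary [k_abio_MOR] | data: HER, MORG, COE, 6MAM, NCOE, MOR
  3(B): primary [k_bio_HER_1, k_bio_HER_2, k_bio_COE_1, k_bio_COE_2, k_bio_6MAM, k_bio_NCOE] | data: HER, MORG, COE, 6MAM, NCOE
  4(B): primary [k_bio_MORG_1, k_bio_MORG_2, k_bio_MOR] | data: HER, MORG, COE, 6MAM, NCOE, MOR
```

The plan reads: level 1 estimates the abiotic heroin rate and the
combinatorial codeine total against the series of compounds whose kinetics
are already fully specified; the codeine branches split at level 2; biotic
totals follow one level after their compound's abiotic stage; morphine —
fed by three routes — comes last. Each objective accumulates every series
identified so far within its experiment phase.

```r
cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 5000))
fit <- calibrate_method1(fx$network, fx$dataset, cfg, seed = 11)
tidy(fit)
```

```
# A tibble: 20 × 8
  param_id     phase   level role          median  cri_lo cri_hi family
1 k_abio_HER   abiotic 1(A)  primary       2.01   1.43     3.02  lognormal
2 k_abio_COE   abiotic 1(A)  combinatorial 0.475  0.358    0.609 gamma
3 k_abio_COE_1 abiotic 2(A)  primary       0.288  0.201    0.417 gamma
4 k_abio_COE_2 abiotic 2(A)  primary       0.163  0.121    0.216 lognormal
5 k_abio_6MAM  abiotic 2(A)  primary       0.536  0.431    0.609 weibull
...
```

Medians and 95% credibility intervals per rate constant (units: abiotic
1/d, biotic L/gTSS/d); in this run all 15 free generating constants of the
fixture (e.g. `k_abio_HER = 2.0`) fall inside their intervals. `glance(fit)`
summarizes budget, acceptance and TIC rejection; `autoplot(fit)` draws the
estimate/error-bar panel; `assessment_report(fit, fx$dataset)` adds
RMSE/MAE, ARIL/coverage/ILTC and identifiability flags, and
`residual_diagnostics()` / `propose_branches()` drive pathway-gap
discovery. A thin command-line launcher (`inst/scripts/pathkin`) exposes
`synth`, `simulate`, `calibrate`, `assess` and `discover` subcommands over
the same functions.

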