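# hscdynamics

Human hematopoietic stem cells (HSCs) sit in quiescence (G0) and must
transition out of it before they can divide. `hscdynamics` is an R package
for quantifying that transition and exploring its consequences: it treats
the duration of **G0 exit** as a kinetic parameter separate from
cell-cycle transit, estimates both from single-cell division tracking, and
simulates what independent control of G0 exit means for long-term
stem-cell pool homeostasis. It is aimed at stem-cell biologists and
modellers who work with division-tracking, label-incorporation or
limiting-dilution data.

## What it computes

* **Division kinetics** — cumulative first- and second-division curves
  from interval-censored single-cell tracks, least-squares log-logistic
  sigmoid fits `F(t) = plateau / (1 + 10^(slope (log10 EC50 − log10 t)))`,
  and the kinetic triplet per subtype: time to first division
  `t_first_div = EC50(first)`, cycle transit `t_second_div = EC50(second,
  transit axis)`, and `t_g0_exit = t_first_div − t_second_div`. Paired
  t tests and extra sum-of-squares F tests compare subtypes and
  treatment groups.
* **BrdU incorporation** — fits `F(t) = plateau (1 − 2^(−t/T_d))` so the
  half-time of the fit is the population doubling time `T_d`, plus
  doubling-time ratios with a shared-`T_d` significance test.
* **Limiting dilution** — single-hit Poisson maximum likelihood
  `P(engraft | dose d) = 1 − exp(−f d)` with profile-likelihood 95% CIs
  (ELDA-style) and likelihood-ratio frequency comparisons.
* **Agent-based homeostasis model** — LT-HSC, ST-HSC and progenitor
  compartments in a closed demand loop (24 cells/day leave the HSC pool
  at homeostasis; 5% signal noise), comparing one-parameter division
  control (HYP1) against two-parameter control without (HYP2.1) or with
  (HYP2.2) the measured 5.8 h LT-HSC G0-exit delay, including injury
  perturbations and delay scans.
* **Synthetic data** for all of the above, so every stage is testable
  offline.

## Worked example

```r
library(hscdynamics)

# A synthetic 576-well tracking experiment at the default configuration
tracks <- simulate_division_tracks(timing_config(seed = 1))
fit_division_kinetics(tracks, sample_id = "CB01")
#>   sample_id subtype t_first_div t_second_div t_g0_exit r_squared_first
#> 1      CB01      LT       56.19        25.80     30.38          0.9991
#> 2      CB01      ST       46.54        23.33     23.20          0.9995
```

LT-HSCs take 56.2 h to their first division versus 46.5 h for ST-HSCs
(the configured 9 h gap), their cycle transit is ~2.5 h longer, and the
remaining difference is slower G0 exit — here 7.2 h for a single sample;
across ≥ 20 seeded samples the mean gap settles near the configured
5.8 h. First-division fits exceed R² = 0.99.

```r
# Homeostasis at the calibrated defaults (two-parameter control + delay)
run_replicates(abm_params(), n_runs = 8, seed = 1)
#> 8 replicate runs (HYP2_2):
#>   subtype mean_divisions_per_year sd_divisions_per_year mean_interdivision_days
#> 1 LT                        4259.                  54.4                    288.
#> 2 ST                        4708.                  53.8                    261.
```

At target pools of 3,360 cells per subtype and 24 cells/day leaving the
HSC pool, each LT-HSC divides about once every 288 days — consistent with
the ~280-day estimate for human HSCs — while ST-HSCs divide more often;
the difference is produced entirely by the slower LT-HSC G0 exit, which
makes LT cells lose demand races and abort uncommitted exits.
`compare_hypotheses()` shows the yearly LT division count ordering
HYP1 > HYP2.1 > HYP2.2 (4526 > 4450 > 4259 at 8 runs/arm), i.e. late
commitment spares stem-cell divisions, and `delay_scan()` quantifies the
sparing as a monotone function of the delay.

## Acceptance script

`scripts/acceptance.R` regenerates every headline quantity from scratch
with the installed package: the LT–ST G0-exit and first-division gaps
recovered by the sigmoid pipeline from default synthetic tracks (40
samples), the BrdU doubling-time ratio (20 series), the simulated LT-HSC
interdivision interval (32 one-year runs), and the smallest G0-exit delay
that significantly reduces yearly LT divisions (1.3 h grid, 64 runs per
point). Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All quantities are recomputed at run time from the given seed; the JSON
maps each quantity to its value and the problem size used.
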