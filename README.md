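# pushpull

Mechanistic modelling of how budding yeast matches hexose-transporter (HXT)
expression to extracellular glucose.

Yeast expresses seven main glucose transporters whose affinities span low
(Hxt1, Hxt3), medium (Hxt2, Hxt4), and high (Hxt6, Hxt7); cells predominantly
express the transporters whose affinity matches the current glucose
concentration. The glucose-sensing network achieves this with **push-pull
regulation** by two repressor pairs: rising glucose weakens ("pulls")
repression by Mth1 and Std1 — co-repressors acting through promoter-bound
Rgt1 and inactivated by the sensors Snf3 and Rgt2 — while strengthening
("pushes") repression by Mig1 and Mig2, activated in glucose through SNF1
inhibition and *MIG2* de-repression. Each *HXT* promoter couples to the two
pairs with strengths that place its expression window at low, medium, or
high glucose.

The package provides, end to end:

* an ODE model of the Snf3-Rgt2/SNF1 network — five differential states
  (Mth1 `M`, nuclear Std1 `S`, nuclear Mig1 `G1`, Mig2 `G2`, tagged Hxt `H`)
  plus one algebraic relation (intracellular glucose) — simulated for any
  deletion genotype under any piecewise-linear glucose programme
  (`simulate_hxt()`, `steady_state()`, `apply_deletion()`);
* Hill-function promoter logic over all 15 non-empty subsets of the four
  repressors, with transcription rate `aH / (1 + W)` and repression weight
  `W = sum_i (R_i/K_i)^(n_i)` (`promoter_structures()`,
  `transcription_rate()`, `pair_repression()`);
* weighted least-squares calibration with a seedable, box-constrained
  differential-evolution search plus local polish (`wss_objective()`,
  `fit_model()`, `select_mechanism_class()`);
* ABC-SMC model selection over promoter structures with an adaptive
  population Monte Carlo tolerance schedule (`abc_smc()`,
  `bootstrap_repression()`);
* a promoter occupancy-bias score from binding-site posterior tables
  (`occupancy_score()`, `promoter_bias()`);
* a synthetic-data generator emulating the microfluidics fluorescence
  measurements and their normalisation (`synth_config()`, `generate_raw()`,
  `normalise_raw()`), built on a packaged, fully synthetic reference
  calibration (`reference_calibration()`).

All user-facing functions take and return tibbles where the data are
tabular, so results chain with the pipe; fitted objects support `tidy()` /
`glance()`, and result types have `autoplot()` / `plot_*()` methods.

## Worked example

Simulate wild-type Hxt4-GFP under the canonical 1 % glucose pulse (3 h
glucose-free lead-in, rise at 1.5 %/h, 8 h plateau, fall at 2 %/h) and
quantify the timescale separation between the repressor pairs:

```r
library(pushpull)

ref <- reference_calibration()
pulse <- glucose_pulse(plateau_pct = 1)
traj <- simulate_hxt(character(0), pulse, ref$params, ref$promoters$HXT4)

pair_response_summary(traj)
#> # A tibble: 2 × 4
#>   phase   mth_std_h mig_mig_h ratio
#>   <chr>       <dbl>     <dbl> <dbl>
#> 1 falling      2.30     0.514  4.47
#> 2 rising       1.46     0.608  2.41
```

Mig1/Mig2 respond 2.4× faster than Mth1/Std1 while glucose rises and 4.5×
faster while it falls. That separation is the mechanism of Hxt4's
falling-glucose spike: when glucose is removed, Mig1 and Mig2 inactivate
within ~30 minutes while Mth1 and Std1 take hours to re-accumulate, opening
a transient expression window — in this trajectory the post-fall peak of `H`
is 1.88× its plateau level (`max(traj$H[traj$time_h > 11.7]) /
max(traj$H[traj$time_h <= 11.7 & traj$time_h > 9])`).

Deletion strains are simulated structurally, never refitted. At the
glucose-free steady state the *mth1Δ* strain expresses 8.2× more Hxt4 than
wild type:

```r
steady_state(0, ref$params, ref$promoters$HXT4, "MTH1")$H /
  steady_state(0, ref$params, ref$promoters$HXT4)$H
#> [1] 8.224963
```

Promoter-model selection runs per HXT with the signalling parameters fixed;
`tidy()` on the posterior gives the model table:

```r
obs <- synth_dataset(synth_config(design = pulse_series_design(), replicates = 3), seed = 11)
post <- abc_smc(obs, "HXT4", ref$params,
                config = abc_config(n_particles = 150), seed = 1)
tidy(post)          # posterior probability per promoter structure
autoplot(post)      # bar chart of the same
bootstrap_repression(post, ref$params, n_samples = 100, seed = 1)
```

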