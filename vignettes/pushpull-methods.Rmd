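---
title: "Push-pull regulation of the yeast HXT genes: model, inference, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Push-pull regulation of the yeast HXT genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(pushpull)
library(dplyr)
```

## The biological problem

Budding yeast carries seven main hexose-transporter genes (*HXT1*–*HXT7*)
whose transporters differ in glucose affinity: Hxt1/Hxt3 are low-affinity
(efficient in high glucose), Hxt2/Hxt4 medium, Hxt6/Hxt7 high-affinity
(efficient in low glucose). Cells express predominantly the transporters whose
affinity matches the current extracellular glucose concentration. This
package implements a mechanistic account of how the glucose-sensing network
achieves that matching: two pairs of transcriptional repressors respond to
glucose in opposite directions — rising glucose *pulls* (weakens) repression
by Mth1 and Std1 while *pushing* (strengthening) repression by Mig1 and
Mig2 — and each *HXT* promoter couples to the two pairs with strengths that
place its expression window at low, medium, or high glucose.

## The mechanistic model

The model has five differential state variables and one algebraic relation.
Time is in hours, glucose in % w/v (g/100 mL), protein amounts in arbitrary
units scaled to the fluorescence data.

**Sensors.** Snf3 (high-affinity) and Rgt2 (low-affinity) each contribute a
saturating signal $\sigma(g_e) = g_e^h / (K^h + g_e^h)$ of extracellular
glucose $g_e$, with half-saturations $K_\mathrm{snf3} \ll K_\mathrm{rgt2}$.

**Mth1** ($M$) is synthesised at a rate repressed by nuclear Mig1 and Mig2
(competitive Hill terms) and degraded at a basal rate plus sensor-mediated
rates:
$$\dot M = \frac{a_M}{1 + (G_1/K_{M,\mathrm{mig1}})^{n_M} + (G_2/K_{M,\mathrm{mig2}})^{n_M}}
 - \bigl(d_{0M} + d_{\mathrm{snf3}}\sigma_\mathrm{snf3} + d_{\mathrm{rgt2}}\sigma_\mathrm{rgt2}\bigr) M.$$

**Nuclear Std1** ($S$): total Std1 is constant ($S_T$); the nuclear pool is
imported from the remainder and exported at a basal plus sensor-mediated
rate. In glucose the nuclear pool empties (the cytoplasmic condensation of
Std1 is represented only through this glucose-dependent export).

**Nuclear Mig1** ($G_1$): total Mig1 is constant ($G_{1T}$); export is basal
plus proportional to SNF1 kinase activity
$$A(g, S) = \frac{K_{Ag}^{h_A}}{K_{Ag}^{h_A} + g^{h_A}}
 \Bigl(\beta_0 + \beta_1 \frac{S}{S + K_{AS}}\Bigr),$$
which falls with glucose and rises with nuclear Std1. So at low glucose SNF1
is active, Mig1 is phosphorylated and cytoplasmic; in glucose Mig1
accumulates in the nucleus.

**Mig2** ($G_2$) is synthesised at a rate repressed by Mth1 and Std1 and
degraded at a rate that *decreases* with intracellular glucose
($d_{G2}(g_i) = d_{G2,\min} + (d_{G2,\max}-d_{G2,\min}) K_{dG2}/(K_{dG2}+g_i)$),
so Mig2 accumulates in glucose both by de-repression and by stabilisation.

**Tagged Hxt** ($H$): transcription $a_H / (1 + W)$ with the repression
weight
$$W = \sum_{i \in \text{structure}} (R_i / K_i)^{n_i}$$
summed over the repressors bound by that promoter ($R_i$ the active nuclear
amount), and degradation that is faster without glucose (mirroring the Mig2
form). The identity $\text{rate}\cdot(1+W) = a_H$ is exact and unit-tested.

**Intracellular glucose** ($g_i$, the algebraic relation) is minimal without
extracellular glucose and otherwise follows
$g_i(t) = g_{\max}\, g_e(t)\, L(t - t_\mathrm{on})$, a logistic ramp $L$
(seed $L_0 = 0.01$, growth rate $r_g$) anchored at the most recent
glucose onset — transporters must accumulate before import saturates. $r_g$
is indexed per (glucose plateau, genotype). SNF1's activity uses
extracellular glucose by default and Mig2's degradation uses intracellular
glucose; the literature states the dependencies both ways, so both are
configuration switches (`snf1_glucose`, `mig2_glucose`) rather than
hard-coded choices.

Gene deletions act structurally (`apply_deletion()`): *MTH1* zeroes $a_M$,
*STD1* zeroes $S_T$, *MIG1* zeroes $G_{1T}$, and each sensor deletion zeroes
its two mediated amplitudes. Rgt1 is not a state: it is assumed always
promoter-bound, with Mth1/Std1 binding through it.

```{r model-overview}
model_equations()
```

## Glucose programmes

Experiments deliver piecewise-linear glucose programmes: a ~3 h glucose-free
lead-in, a linear rise at 1.5 %/h to a plateau (0.2, 0.4 or 1 %), an 8 h
hold, and a fall at 2 %/h. Media switches in the device take minutes; exact
linear ramps at the measured rates are used because the model consumes
$g_e(t)$ only through saturating functions, so sub-minute switch kinetics are
immaterial and ramps are reproducible.

```{r pulse}
pulse <- glucose_pulse(plateau_pct = 1)
head(render_profile(pulse, dt_min = 30))
```

## Numerical choices

* Integration uses `deSolve::ode` (lsoda, stiff-capable), relative tolerance
  `1e-6`, absolute `1e-9`, sampled on the experimental 5-minute grid.
  Halving tolerances changes trajectories by far less than any assertion
  tolerance (tested).
* Steady states are solved rather than simulated: $S$ and $G_1$ have closed
  forms, leaving a damped two-variable fixed-point iteration for the
  mutually repressing $M$ and $G_2$ (negative feedback makes the damped
  iteration contract), with a numerical-Jacobian Newton fallback. The test
  suite checks agreement with the $t \to \infty$ simulation to `1e-6`
  relative over random parameter draws.
* Initial conditions are the glucose-free steady state (cells are pre-grown
  on a gluconeogenic source); galactose-history effects on initial Hxt2/6/7
  levels are represented only as an optional non-zero initial $H$.
* Response times are half-change times within a phase window, by linear
  interpolation between samples; a flat trajectory raises a typed error
  rather than returning a number.

## Reference calibration

Fitted parameter values for this network are not available in
machine-readable form, so the package ships a *synthetic* reference
calibration (`reference_calibration()`): one versioned parameter set
constructed to satisfy the qualitative behaviour reported for the system —
push-pull monotonicity of the two pairs at steady state; a spike of Hxt4
after glucose removal with low plateau expression; the deletion-strain
orderings (mth1Δ high without glucose, mig1Δ high in glucose, std1Δ slightly
reduced in glucose, snf3Δ lower and rgt2Δ higher than wild type in glucose);
the Std1-activates-SNF1 mechanism class; Mig1/Mig2 responding at least twice
as fast as Mth1/Std1 in both phases of a 1 % pulse; and the affinity-matched
steady-state ordering of HXT1/3 vs HXT6/7. Promoter structures are the modal
inferred architectures (all four repressors for HXT4/6/7, Std1+Mig1 for
HXT3, Mth1+Mig1 for HXT2, Std1 for HXT1). These constraints are re-verified
by the test suite on every run; no quantitative agreement with unpublished
numbers is claimed.

```{r timescales}
ref <- reference_calibration()
traj <- simulate_hxt(character(0), pulse, ref$params, ref$promoters$HXT4)
pair_response_summary(traj)
```

The timescale separation above is the mechanism of the falling-glucose
spike: when glucose is removed, Mig1 and Mig2 inactivate quickly while Mth1
and Std1 need hours to re-accumulate, opening a transient expression window.

## Calibration machinery

`wss_objective()` is a weighted sum of squares over all records and time
points, with weights equal to the measurement SEM floored at 5 % of the
dataset's maximum fluorescence — the floor stops near-zero-variance points
dominating; the original weighting floor is unpublished, so this is a stated
package default. `fit_model()` performs a differential-evolution global
search (rand/1/bin, stratified initial population) over a parameter box —
log scale for rates and constants, linear for Hill numbers — followed by an
L-BFGS-B polish; it is seedable and exactly reproducible, and a budget no
larger than the population returns the best initial member. Deletion strains
are fitted through `apply_deletion()`, never by refitting per strain; `r_g`
is indexed per condition and genotype.

Because tens of parameter sets can be consistent with the data, the honest
recovery target is *prediction* recovery: `prediction_nrmse()` measures the
normalised RMSE of fitted-model trajectories against the generating ones,
and the acceptance suite requires < 10 % on noiseless synthetic data at a
small search budget (populations of 16, several hundred evaluations over
four parameters spanning one to two decades — sizes chosen so the whole
suite stays quick while the contract is still exercised end-to-end).

Where two mechanism classes fit equally well (Std1 stimulating SNF1 versus
Std1 repressing *MIG2*), `select_mechanism_class()` picks a near-optimal fit
in the Std1-activates-SNF1 class, defined testably by comparing Std1's share
of SNF1 stimulation at the glucose-free steady state with its share of the
*MIG2*-promoter repression weight.

## Promoter-model selection by ABC-SMC

For every other *HXT*, the signalling parameters stay fixed and only the
promoter is inferred: which of the 15 non-empty repressor subsets binds, and
with what $a_H$, degradation parameters, $K_i$ and $n_i$. Prior knowledge
from deletion screens restricts the candidate list (Std1 is required for
*HXT1* and *HXT3*); *HXT5* is excluded as it is not regulated by this
network. The model prior is uniform over allowed structures; parameter
priors are log-uniform over four decades centred on the calibrated HXT4
values; Hill numbers are uniform on [1, 8]; degradation is parameterised as
$d_{H,\max}$ and the ratio $d_{H,\min}/d_{H,\max}$ (log-uniform on
$[10^{-3}, 1]$) so the bound constraint holds by construction.

The sampler is sequential Monte Carlo with an adaptive population Monte
Carlo tolerance schedule: each generation keeps the best $\alpha$-quantile of
particles as survivors, proposes replacements from a mixture of fresh prior
draws and kernel perturbations (componentwise Gaussian, scale
$\sqrt{2\,\widehat{\mathrm{Var}}}$ per model), computes exact importance
weights under that mixture, sets the tolerance to the $\alpha$-quantile of
the pooled distances (enforced non-increasing), and stops when the proposal
acceptance rate falls below a threshold or at a generation cap. The distance
is the SEM-weighted L2 norm used by the calibration objective.

Three design choices matter at small populations and are worth recording:

* **Calibration generation.** The first generation draws
  `init_factor` $\times N$ prior-predictive samples, stratified equally over
  the candidate structures, so every structure starts from the best region
  its prior can reach. Without it, whichever structure stumbles on a
  mediocre fit first tends to capture the survivor set.
* **Elitist archive.** Each structure's best few particles ever seen remain
  part of the proposal pool (their selection probabilities enter the mixture
  weights exactly), so a structure squeezed out of the survivor set can
  re-enter once the tolerance approaches its best achievable distance.
  Without the archive, model extinction is effectively irreversible at small
  $N$.
* **Patience.** The acceptance-rate stop (0.5 %) only applies after
  `min_gen` generations: the calibration generation starts the schedule at a
  demanding tolerance, making early acceptance rates uninformative. The
  stop threshold is deliberately low because acceptance stalls exactly when
  an incorrect structure sits at its distance floor — the moment the archive
  needs time to break through.

Defaults are population 500, $\alpha = 0.3$, cap 25 generations,
`init_factor` 20. The test suite runs the model-recovery problem at
population 150, where the generating structure was the posterior mode in 29
of 30 tuning runs (at population 50 that reliability drops to roughly 87 %,
which is why the suite does not scale down further); each run takes a few
seconds because the signalling states are promoter-independent and are
simulated once per glucose programme, leaving only a scalar linear ODE per
candidate promoter, integrated in closed form between grid points.

`bootstrap_repression()` then summarises what the posterior says about
regulation: 100 draws of (structure, parameters) from the weighted particles,
steady states at 0.01 / 0.1 / 1 % glucose, and the repression weight of each
pair, reported with percentile 95 % intervals; `affinity_repression()`
averages the two member HXTs of each affinity class.

## Synthetic data generator

No raw measurement data are deposited with the study, so the package
generates fully synthetic datasets with the statistical structure of the
microfluidics measurements (`synth_config()`, `generate_raw()`,
`normalise_raw()`): ground-truth trajectories from the reference calibration
on a 5-minute grid; an additive autofluorescence offset modelled as a
positive, slowly drifting stationary AR(1) (the simplest process with the
right role); a per-replicate multiplicative day effect (log-normal) shared by
all chambers of a device; and i.i.d. additive measurement noise. Each
replicate device carries two control chambers: an untagged autofluorescence
control and a Mig1-GFP normalisation control whose underlying signal is the
constant total Mig1 (1 model unit), so normalised data land on the model
scale. Normalisation subtracts the autofluorescence chamber pointwise and
divides by the pre-glucose mean of the corrected control chamber — by
construction the day effect cancels exactly, which the tests assert.

Noise defaults (`autofluor_sd` 0.05, `day_sd` 0.08, `meas_sd` 0.15 a.u.,
2–5 replicates) give replicate SEMs around 5–10 % of the signal range,
the error-band scale typical of such measurements; the true
instrument noise model is unpublished, so these are versioned package
defaults, not estimates. What passing round-trip tests show is that the
normalisation procedure inverts this noise model; they cannot show that the
model captures effects absent from the generator — single-cell
heterogeneity, cell-cycle structure, vacuolar versus membrane GFP
localisation, or mother/bud asymmetry.

```{r synth}
ds <- synth_dataset(synth_config(design = pulse_series_design(), replicates = 3), seed = 11)
head(ds)
```

## Occupancy bias

Binding-site posterior tables (promoter, TF, site coordinates, posterior
probability — the output format of genome-wide motif scanners) are summarised
in the low-TF-concentration limit, where occupancy is linear in site
availability: the occupancy of a TF group is the sum of its sites'
posteriors (a `1 - prod(1 - p)` alternative sits behind a flag). The
promoter bias is
$\log_2[(\mathrm{occ}_\mathrm{Rgt1} + c)/(\mathrm{occ}_\mathrm{Mig1,Mig2} + c)]$
with pseudocount $c = 0.01$ guarding empty groups; positive values mean
Mth1/Std1-biased promoters (low-affinity transporters), negative values
Mig1/Mig2-biased ones (high-affinity). Promoter extent is the caller's
responsibility: intergenic-region length artefacts (the *HXT7* region is more
than twice as long as *HXT6*'s) are documented, not auto-corrected.

## Known limitations

* The upstream supplementary equations and fitted values are unavailable;
  all glucose and regulator dependencies are Hill/saturating forms satisfying
  the stated monotonicities, isolated behind small functions so alternative
  forms can be swapped. Repression terms combine additively in a single
  `1 + W` denominator (competitive, OR-like repression) — a multiplicative
  combination across pairs is a plausible alternative that the data used
  here cannot distinguish.
* The reference calibration is a constructed stand-in, not a fit to real
  data; quantitative values (absolute fluorescence, rates) are meaningful
  only relative to the synthetic generator.
* PKA phosphorylation of Rgt1, mechanistic Std1 condensation, single-cell
  stochasticity, and Hxt5 are out of scope by design.
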