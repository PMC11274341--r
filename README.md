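# adckinetics

Mechanistic kinetic modeling of the conjugation reaction that creates
antibody-drug conjugates (ADCs): the attachment of maleimide-functionalized
cytotoxic payloads to reactive cysteine thiols on a monoclonal antibody
(mAb). The package is for process modelers and reaction engineers who want
to simulate, calibrate and screen conjugation reactions for the two dominant
cysteine modalities:

* **site-specific (DAR 2)** — payload on two engineered hinge cysteines of
  the heavy chain;
* **interchain-disulfide (DAR 8)** — stochastic payload attachment to the
  eight cysteines freed by full reduction of the interchain disulfides.

## The model

The observable data are chain-level: a reducing RP-UHPLC assay splits every
quenched sample into heavy and light chains carrying 0..n payloads (H0, H1,
..., L0, L1). Conjugation is modeled as a consecutive scheme of irreversible
second-order steps on chains indexed by payloads bound *d* and initial
reactive sites *n<sub>c</sub>*:

```
dc(d,nc)/dt = k_step(d) * c(d-1,nc) * c_drug  -  k_step(d+1) * c(d,nc) * c_drug
dc_drug/dt  = -(sum of conjugation fluxes)    -  k_drug * c_drug   [+ feed terms]
```

with a frozen first-order payload-depletion rate `k_drug` (measured
separately from absorbance decay), an ADC-specific initial reactive-cysteine
distribution inferred from saturated final drug-load distributions, and
fed-batch dilution terms for runs where the payload is pumped in over 10–30
minutes. Candidate models use either one shared rate (`simple`) or
step-specific rates (`detailed`; for DAR 8: light-chain `k1`, heavy-chain
`k2`, `k3` and the lumped `k4/5`). Rates are estimated by normalized
nonlinear least squares; candidates are compared by parameter uncertainty
(`sigma/estimate < 25%`), one-at-a-time sensitivity ranking
(`sum delta_msqr`), and leave-one-run-out / test-set errors (RMSECV, RMSEP).

## Worked example

Simulate a saturating-excess DAR 8 batch conjugation (1.5 g/L mAb, 11x NPM)
with the calibrated detailed rates, then calibrate a DAR 2 model on a
synthetic campaign:

```r
library(adckinetics)

sim <- simulate_conjugation(
  model_spec("DAR8", "detailed"),
  rate_set(c(1.220, 1.853, 5.117, 2.312), payload_presets()[["NPM"]]),
  run_condition(1.5, 11, "batch"),
  adc2_distribution())
sim
#> Conjugation simulation (DAR8 detailed): 207 time points to 3600 s
#>   final DAR 7.839, residual free payload 0.002679 mmol/L

final <- sim$observed[nrow(sim$observed), ]
round(100 * final[paste0("H", 0:4)] / sum(final[paste0("H", 0:4)]), 1)
#>   H0   H1   H2   H3   H4
#>  0.0  0.5  9.0 84.4  6.0
```

The reaction saturates at DAR 7.84 — the stoichiometric site count of the
distribution — and the final heavy-chain drug-load distribution mirrors the
initial cysteine distribution (84% of heavy chains carry three payloads).

```r
ds <- generate_dataset("dataset2_DAR2_NPM", noise_model(seed = 1))
fit <- fit_rates(ds)
fit
#> Conjugation-rate fit (DAR2 simple), converged, n = 160, p = 1
#>    estimate  sigma     lb     ub
#> k1    5.033 0.2832 4.4737 5.5922
#> train RMSE 0.2185 umol/L
```

The estimator recovers the generating rate (4.840 L mmol⁻¹ s⁻¹) within its
confidence interval from 160 noisy synthetic observations.

Other entry points: `infer_distribution()` (initial cysteine distribution
from final DLD snapshots), `fit_depletion_rate()` (payload depletion from
absorbance decay), `oat_sensitivity()` / `cross_validate_loro()` /
`select_model()` (identifiability and candidate selection),
`screen_conditions()` (in-silico screening of mAb concentration and drug
excess), and `run_command()` with the thin CLI wrapper in `inst/cli/adck.R`.
The methods vignette (`vignettes/adc-conjugation-kinetics.Rmd`) documents
the model, its assumptions and the numerical choices.

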