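# jmsnp — joint models of a longitudinal biomarker and disease onset for SNP association

`jmsnp` is an R package for testing genetic variants for *joint*
association with a repeatedly measured biomarker and a time-to-event
trait — the motivating application is fasting plasma glucose (FPG,
mmol/L, measured at 3-yearly visits) and incident type-2 diabetes (T2D)
over a 9-year follow-up. It is aimed at statistical geneticists and
biostatisticians who need to run such analyses per SNP at array scale,
and at methodologists who want to study the estimators themselves.

## The model

For individual `i` with allele dosage `z_i` the biomarker follows a
random-intercept/random-slope trajectory and the event hazard sees the
*error-free* trajectory:

    Y_ij = X_i(t_ij) + e_ij,   X_i(t) = theta0_i + theta1_i * t + gamma * z_i
    (theta0_i, theta1_i) ~ N2(mu, Sigma),   e_ij ~ N(0, sigma^2)

    lambda_i(t) = lambda0(t) * exp( beta * X_i(t) + alpha * z_i )

* `gamma` — per-allele effect on the biomarker (mmol/L per allele)
* `alpha` — direct per-allele log-hazard-ratio on disease onset
* `beta`  — trajectory–hazard link (log hazard per mmol/L)

FPG is an *endogenous* covariate: after diagnosis patients are treated,
so measurements stop at the event (event-driven dropout). Three
estimators are implemented:

| Estimator | Function | Character |
|---|---|---|
| Joint model (JM) | `fit_joint()` | Full shared-parameter likelihood; piecewise-constant baseline (two knots at event-time tertiles), adaptive Gauss–Hermite quadrature; least biased, slowest |
| Two-step (TS) | `fit_two_step()` | Mixed-model fit, empirical-Bayes trajectories plugged into the Cox partial likelihood; fast scan workhorse, attenuates `beta` |
| Extended Cox | `build_locf_episodes()` + `fit_cox()` | Observed biomarker carried forward (LOCF); the naive standard practice |

Around them: a closed-form simulation engine with baseline-rate
calibration (`desir_defaults()`, `calibrate_lambda()`,
`simulate_cohort()`), variant QC including an exact Hardy–Weinberg test
(`qc_filter_variants()`, `hwe_exact_pvalue()`), a scenario evaluation
harness (`run_scenario()`, `compare_methods()`), and per-SNP scans with a
two-stage TS→JM strategy (`scan_variants()`, `two_stage_scan()`).

## Worked example

Simulate one cohort under the reference generative parameters (estimated
for a TCF7L2 variant: `gamma = 0.0229`, `alpha = 0.265`, `beta = 3.17`,
allele frequency 0.244, 3.84% incidence over 9 years) and fit the joint
model:

```r
library(jmsnp)

p <- desir_defaults()
p$lambda0 <- calibrate_lambda(p)     # match the 3.84% 9-year incidence
sim <- simulate_cohort(scenario_spec(m = 4, n = 2500, f = 0.244,
                                     d = 0.0384), p, seed = 12)
print(sim)
#> <simulated_cohort> n=2500, events=106 (4.24%), m=4 visits

jm <- fit_joint(sim$cohort, se = TRUE)
print(jm)
#> <joint_fit> n=2500, events=106, logLik=-5721.544, converged=TRUE (81 iter)
#>         estimate      se
#> mu0      4.54267 0.01165
#> mu1      0.01057 0.00108
#> gamma    0.03362 0.01392
#> sigma_e  0.30295 0.00307
#> beta     3.25293 0.32059
#> alpha    0.41464 0.14774
#>   baseline knots: 3.16, 6.64; rates: 5.553e-10, 4.673e-10, 6.082e-10

wald_tests(jm, c("gamma", "alpha", "beta"))
#>   parameter   estimate         se         z            p
#> 1     gamma 0.03362395 0.01392058  2.415413 1.571736e-02
#> 2     alpha 0.41464041 0.14773511  2.806648 5.005996e-03
#> 3      beta 3.25293178 0.32058597 10.146832 3.422965e-24
```

At this sample size a single replicate scatters around the truth
(0.0229 / 0.265 / 3.17) within its standard errors; averaged over
replicates the estimates centre on the generating values (that is what
`scripts/acceptance.R` and the test suite measure). The analysis
workflow in `analysis/01...05_*.R` walks the full study: cohort
generation, the three estimators side by side, the scenario comparison
(RMSE/bias/variance of `beta` across sample sizes and methods), power
and type-I error, and a 20-variant two-stage scan, each writing its
table under `results/`. On the reference cohort (`analysis/02`,
n = 4,352) the three estimators line up exactly as the method
comparison predicts for the link coefficient: JM `beta = 3.16`,
TS `beta = 2.64` (shrinkage attenuation), extended Cox `beta = 1.91`
(measurement-error attenuation on top), with `gamma` nearly identical
for JM and TS (0.035 vs 0.034).

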