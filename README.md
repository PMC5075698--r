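# jmbench

Simulation benchmark of shared random-effects **joint models** against
conventional **Cox regression** when a time-to-event outcome is predicted
by an error-prone longitudinal measurement.

The setting is a psychosis-risk cohort followed for a year: monthly
assessments of a symptom score, and the outcome "time to transition".
The conventional analyses — Cox regression on the baseline score only,
or on the last observed score carried forward (LOCF) — use a stale,
noisy surrogate of the score's current true value and attenuate its
estimated effect. The joint model couples

$$y_i(t) = m_i(t) + \varepsilon_i(t), \quad
  m_i(t) = a_0 + a_1 t + b_{0i} + b_{1i} t, \quad
  b_i \sim N(0, D), \ \varepsilon_i(t) \sim N(0,\sigma^2)$$

$$h_i(t) = h_0(t)\, \exp\big(\gamma u_i + \alpha\, m_i(t)\big)$$

and estimates $(\alpha, \gamma, a, D, \sigma^2, h_0)$ by maximum
likelihood, integrating the random effects with pseudo-adaptive
Gauss–Hermite quadrature (compiled likelihood kernel; Weibull or
piecewise-constant baseline hazard).

The package is aimed at biostatisticians who want a transparent,
self-contained re-implementation of this comparison: a daily-hazard
piecewise-exponential simulator with known truth (36 scenario sets:
two trajectory slopes × four random-effects covariance forms × two error
variances × two missingness regimes, plus four non-zero group-effect
clones), the competing estimators written from scratch against the same
counting-process structures, and a replicate harness reporting 95%
CI coverage and the percentage of estimates below the truth.

## Worked example

```r
library(jmbench)

sc <- scenario_grid(seed = 1)[["set1"]]   # monotone visits, Var(eps)=16,
ds <- simulate_dataset(sc, 1)             # a1=0.02, covariance form a
ds
#> Simulated dataset (replicate 1): 300 subjects, 96 events, 1501 visits

fit_cox(build_baseline_table(ds))         # day-0 value + group
#> Cox fit (96 events, converged)
#>              coef         se     lower95     upper95
#> value -0.03783639 0.01419367 -0.06565598 -0.01001681
#> group  0.18224629 0.20546920 -0.22047334  0.58496593

fit_joint(ds, joint_spec("weibull"))
#> Joint model (weibull baseline, converged)
#>   alpha -0.04956 (se 0.01132), gamma 0.2101 (se 0.2054)
#>   beta (39.860, 0.01952), sigma2 16.255, loglik -5390.088
```

The true values are $\lambda_1 = -0.03$ for the score effect and
$\tau = 0$ for the group effect. On this replicate both methods cover
the truth, but the pattern that emerges over 100 replicates is the point
of the benchmark: the baseline-value Cox estimates sit mostly *above*
$-0.03$ (only ~1 in 4 falls below it — attenuation toward zero), while
the joint model stays centered on the truth with near-nominal coverage.
The study drivers reproduce those tables:

```sh
Rscript analysis/01_simulate.R              # example datasets + grid
Rscript analysis/02_cox_simulation_study.R  # 100-replicate Cox cells
Rscript analysis/03_joint_simulation_study.R --replicates 30
Rscript analysis/04_cohort_analysis.R       # cohort-format stage
```

Stage 4 analyses a counting-process cohort table (subject, family
history yes/no, period start/end day, transition status, depression
score). Pass the published study file with `--data path.csv` if you have
it; without it the driver uses the package's clearly labelled synthetic
cohort with known parameters.

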