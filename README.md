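# kinlearn

Simulation and analysis of two-arm pre/post educational intervention trials
in which the outcomes evolve by first-order kinetics between weekly
sessions.

The setting: a 12-week trial with 75 students per arm. The experimental arm
uses an adaptive software agent (three roles, five difficulty levels,
rule-based switching on quiz accuracy and a self-reported anxiety slider);
the control arm gets static drills. Vocabulary retention `V` (0–100 test
score) and anxiety `A` (1–5 Likert) follow

    dV/dt = k1 * I(t) - k2 * V
    dA/dt = k3 * S(t) - k4 * A

where `I(t)` is intervention intensity and `S(t)` stress, both in [0, 1]
and piecewise-constant over session weeks, and `k1..k4` are rate constants
(defaults 0.05, 0.02, 0.03, 0.04 per week). Motivation, self-efficacy and
life satisfaction are measured pre/post on 1–5 scales.

The package provides, as testable modules:

* **`rk_core`** — a tableau-generic explicit embedded Runge–Kutta engine
  with adaptive step-size control (`integrate_adaptive()`); the canonical
  Dormand–Prince 5(4) pair ships as exact rationals and
  `validate_tableau()` checks consistency conditions in exact arithmetic.
* **`kinetics`** — the model above with exact closed-form solutions under
  piecewise-constant forcing (`closed_form()`), used as the oracle for
  every numerical test.
* **`agent`** — the decision rules (`decide()`, strict thresholds at 80% /
  60% accuracy and slider > 3, at most 3 adaptations per session) and a
  documented, configurable map from agent state to `(I, S)`.
* **`cohort_sim`** — a seeded synthetic cohort generator
  (`simulate_cohort()`) with student-level rate-constant dispersion,
  observation noise, MCAR missingness, injected outliers, and an optional
  calibration mode that pins endpoint means/SDs to the configured group
  summaries exactly.
* **`fitting`** — differential evolution (rand/1/bin,
  `differential_evolution()`) fitting `(k1, k2)` and `(k3, k4)` on a 70/30
  student-level split with holdout R² and bootstrap CIs
  (`fit_kinetics()`).
* **`trial_stats`** — `|z| > 3.29` outlier screening with mean imputation
  (`clean_dataset()`), pooled/Welch two-sample t, split-plot mixed ANOVA
  with partial η² (`mixed_anova()`), Cohen's d, Cronbach's α, and the
  low-baseline subgroup analysis.
* **`run_pipeline()` / `load_config()`** — one-command end-to-end run from
  a YAML/JSON config, byte-identical under a fixed seed.

## Worked example

```r
library(kinlearn)

cfg <- sim_config(n_per_arm = 75, weeks = 12, seed = 11, solver = "exact")
d <- simulate_cohort(cfg)
cleaned <- clean_dataset(d)
cleaned$log
#> Cleaning log: 34 outliers removed (|z| > 3.29), 135 values imputed, 0 cells skipped

compute_stats_report(cleaned$data)
#> Trial statistics report
#>   vocab: exp 60.2 (5.8) -> 78.5 (6.2) [+30.4%]; ctrl 59.8 (6.0) -> 70.1 (7.1) [+17.2%]
#>     post t(148) = 7.75, p = 1.37e-12; interaction F(1,148) = 176.00, p = 5.82e-27, partial eta^2 = 0.543
#>   anxiety: exp 3.1 (0.5) -> 2.1 (0.4) [-32.3%]; ctrl 3.1 (0.6) -> 2.8 (0.5) [-9.7%]
#>     post t(148) = -9.60, p = 2.92e-17; interaction F(1,148) = 134.55, p = 1.56e-22, partial eta^2 = 0.476
#>   ...
#>   low-baseline vocabulary gains: exp 35.1% vs ctrl 18.3% (t = 11.04, p = 5.54e-17)
```

The cohort was simulated with calibration on, so the endpoint descriptives
match the configured group summaries exactly (hence +30.4% observed
against the +30.2% implied by the target means — the cleaning step's
imputation moves the post mean a hair). The inferential statistics (t, F,
η²) are then honest functions of the simulated within- and between-student
variability.

Parameter estimation is demonstrated on data where the constants are
identifiable (see the vignette's scale caveat — on the 0–100 score scale
the forced term `k1*I` is ~0.03 points/week and cannot be resolved against
test noise):

```r
bl <- default_baseline()
bl$vocab <- list(experimental = c(mean = 0.5, sd = 0.2),
                 control = c(mean = 0.5, sd = 0.2))
cfg <- sim_config(seed = 42, baseline = bl, dispersion = 0,
                  calibrate = FALSE, missing_rate = 0, outlier_rate = 0,
                  solver = "exact",
                  noise_sd = c(vocab = 0.04, anxiety = 0.05,
                               quiz_accuracy = 0.05, anxiety_slider = 0.3))
fit_kinetics(simulate_cohort(cfg), seed = 42, n_boot = 0)
#> Kinetic model fit (differential evolution, student-level holdout)
#>   vocab: k1 = 0.0497, k2 = 0.0202; holdout R^2 = 0.9470 (train n = 104, holdout n = 46)
#>   anxiety: k3 = 0.0317, k4 = 0.0403; holdout R^2 = 0.9897 (train n = 104, holdout n = 46)
```

See `vignettes/kinetic-trial-pipeline.Rmd` for the full account of the
model, the agent rules, the simulator's assumptions and the design
decisions.

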