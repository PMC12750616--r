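test_that("differential evolution solves standard benchmark problems", {
  # sphere: global optimum 0 at the origin
  fit <- differential_evolution(function(x) sum(x^2), rep(-5, 4), rep(5, 4),
                                de_config(seed = 1))
  expect_lt(fit$value, 1e-6)
  # constant objective: any member is optimal
  flat <- differential_evolution(function(x) 3.5, c(0, 0), c(1, 1),
                                 de_config(np = 10, generations = 5,
                                           seed = 2))
  expect_identical(flat$value, 3.5)
  # Rosenbrock 2-D: optimum at (1, 1)
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  fit <- differential_evolution(rosen, c(-2, -2), c(2, 2),
                                de_config(generations = 400, seed = 3))
  expect_lt(fit$value, 1e-3)
})

test_that("the best-objective trace is non-increasing and bounds are respected", {
  fit <- differential_evolution(function(x) sum((x - 0.3)^2), c(0, 0),
                                c(1, 1), de_config(generations = 50,
                                                   seed = 4))
  expect_true(all(diff(fit$trace) <= 0))
  expect_true(all(fit$par >= 0 & fit$par <= 1))
  expect_error(
    differential_evolution(function(x) NaN, c(0, 0), c(1, 1),
                           de_config(seed = 5)),
    class = "kinlearn_initialization_error")
})

test_that("r_squared follows its definition", {
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)),
               class = "kinlearn_domain_error")
})

test_that("the split is by student, arm-stratified, near 70/30 and disjoint", {
  cfg <- quiet_sim_config(n_per_arm = 10, weeks = 4, seed = 14)
  d <- simulate_cohort(cfg)
  parts <- kinlearn:::.split_students(d, 0.7, seed = 9)
  expect_length(intersect(parts$train, parts$holdout), 0)
  expect_setequal(c(parts$train, parts$holdout), unique(d$student_id))
  expect_equal(length(parts$train), 14)  # round(0.7 * 10) per arm
  for (arm_prefix in c("E", "C")) {
    n_tr <- sum(startsWith(parts$train, arm_prefix))
    expect_lte(abs(n_tr - 7), 1)
  }
})

test_that("noiseless data recover the generating constants to high precision", {
  # 20 seeded replicates; every recovered constant within 1e-3 of truth
  errs <- sapply(1:20, function(s) {
    cfg <- quiet_sim_config(n_per_arm = 4, weeks = 12, seed = 100 + s)
    d <- simulate_cohort(cfg)
    fit <- fit_kinetics(d, seed = s, n_boot = 0,
                        de = de_config(np = 25, generations = 120))
    max(abs(c(fit$fits$vocab$params - c(0.05, 0.02),
              fit$fits$anxiety$params - c(0.03, 0.04))))
  })
  expect_lt(max(errs), 1e-3)
})

test_that("the exact and Runge-Kutta predictors agree", {
  cfg <- quiet_sim_config(n_per_arm = 3, weeks = 6, seed = 19,
                          noise = c(vocab = 0.5, anxiety = 0.05))
  d <- simulate_cohort(cfg)
  Y <- kinlearn:::.measure_matrix(d, "vocab")
  Fm <- kinlearn:::.measure_matrix(d, "forcing_I")
  pe <- kinlearn:::.predict_exact(0.05, 0.02, Y[, 1], Fm)
  pr <- kinlearn:::.predict_rk(0.05, 0.02, Y[, 1], Fm,
                               integrator_config(rtol = 1e-10, atol = 1e-12,
                                                 h_init = 0.5, h_max = 1))
  expect_equal(pe, pr, tolerance = 1e-8)
})

test_that("holdout R-squared is high under modest noise and the fit is deterministic", {
  cfg <- quiet_sim_config(n_per_arm = 15, weeks = 12, seed = 23,
                          noise = c(vocab = 0.5, anxiety = 0.05))
  d <- simulate_cohort(cfg)
  f1 <- fit_kinetics(d, seed = 11, n_boot = 10,
                     de = de_config(np = 20, generations = 80))
  f2 <- fit_kinetics(d, seed = 11, n_boot = 10,
                     de = de_config(np = 20, generations = 80))
  expect_identical(f1$fits$vocab$params, f2$fits$vocab$params)
  expect_identical(f1$fits$anxiety$ci, f2$fits$anxiety$ci)
  expect_gt(f1$fits$vocab$r2_holdout, 0.9)
  expect_lte(f1$fits$vocab$r2_holdout, 1)
  expect_true(all(diff(f1$fits$vocab$trace) <= 0))
  # CIs contain the point estimates
  for (oc in c("vocab", "anxiety")) {
    ci <- f1$fits[[oc]]$ci
    est <- f1$fits[[oc]]$params
    expect_true(all(ci[, 1] <= est & est <= ci[, 2]))
  }
})

test_that("noisy-data estimates stay close and bootstrap intervals cover", {
  # noise SD ~ 5% of the signal range; across 20 replicates the median
  # absolute error is <= 10% of each true constant and the 95% percentile
  # bootstrap covers the truth at least 80% of the time
  reps <- 20
  # vocabulary baselines on the model's intrinsic scale so the forced
  # component is identifiable; noise SD is 5% of the noiseless signal range
  d0 <- simulate_cohort(quiet_sim_config(n_per_arm = 25, weeks = 12,
                                         seed = 500,
                                         baseline = model_scale_baseline()))
  sd5 <- 0.05 * diff(range(d0$value[d0$measure == "vocab"]))
  res <- lapply(seq_len(reps), function(s) {
    cfg <- quiet_sim_config(n_per_arm = 25, weeks = 12, seed = 500 + s,
                            noise = c(vocab = sd5, anxiety = 0.05),
                            baseline = model_scale_baseline())
    d <- simulate_cohort(cfg)
    fit_kinetics(d, outcomes = "vocab", seed = s, n_boot = 60,
                 de = de_config(np = 20, generations = 60),
                 boot_de = de_config(np = 15, generations = 40))
  })
  est <- t(sapply(res, function(f) f$fits$vocab$params))
  err <- abs(sweep(est, 2, c(0.05, 0.02)))
  expect_lte(median(err[, 1]) / 0.05, 0.10)
  expect_lte(median(err[, 2]) / 0.02, 0.10)
  covered <- sapply(res, function(f) {
    ci <- f$fits$vocab$ci
    all(ci[, 1] <= c(0.05, 0.02) & c(0.05, 0.02) <= ci[, 2])
  })
  expect_gte(mean(covered), 0.80)
})
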