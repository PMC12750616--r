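test_that("simulation is reproducible and seeds matter", {
  cfg <- quiet_sim_config(n_per_arm = 4, weeks = 4, seed = 3,
                          noise = c(vocab = 1, anxiety = 0.1))
  d1 <- simulate_cohort(cfg)
  d2 <- simulate_cohort(cfg)
  expect_identical(d1, d2)
  d3 <- simulate_cohort(quiet_sim_config(n_per_arm = 4, weeks = 4, seed = 4,
                                         noise = c(vocab = 1, anxiety = 0.1)))
  expect_false(identical(d1$value, d3$value))
})

test_that("the dataset has the expected structure and ranges", {
  cfg <- sim_config(n_per_arm = 5, weeks = 12, seed = 2, solver = "exact",
                    missing_rate = 0, outlier_rate = 0, calibrate = FALSE)
  d <- simulate_cohort(cfg)
  vocab <- d[d$measure == "vocab", ]
  expect_identical(nrow(vocab), 10L * 13L)  # 10 students x 13 weekly points
  expect_true(all(vocab$value >= 0 & vocab$value <= 100))
  lik <- d[d$measure %in% c("anxiety", "motivation", "self_efficacy",
                            "life_satisfaction"), ]
  expect_true(all(lik$value >= 1 & lik$value <= 5))
  expect_setequal(unique(d$arm), c("experimental", "control"))
  # at most one record per (student, week, measure)
  expect_false(any(duplicated(d[, c("student_id", "week", "measure")])))
})

test_that("a noiseless non-adaptive student follows the closed form exactly", {
  cfg <- quiet_sim_config(n_per_arm = 2, weeks = 12, seed = 5)
  d <- simulate_student("control", cfg, seed = 99, student_id = "C001")
  traj <- d$value[d$measure == "vocab"]
  V0 <- traj[1]
  # control forcing is static: I = 0.5, S = 0.6
  truth <- closed_form(V0, constant_forcing(0.5, 0.6), cfg$params, 0:12)
  expect_equal(traj, truth, tolerance = 1e-12)
  anx <- d$value[d$measure == "anxiety"]
  truth_a <- closed_form(anx[1], constant_forcing(0.5, 0.6), cfg$params,
                         0:12, "anxiety")
  expect_equal(anx, truth_a, tolerance = 1e-12)
})

test_that("the Runge-Kutta and exact solvers agree on a student trajectory", {
  base <- list(n_per_arm = 2, weeks = 6, seed = 5)
  cfg_rk <- do.call(quiet_sim_config, c(base, list(solver = "rk")))
  cfg_ex <- do.call(quiet_sim_config, base)
  d_rk <- simulate_student("experimental", cfg_rk, seed = 7)
  d_ex <- simulate_student("experimental", cfg_ex, seed = 7)
  expect_equal(d_rk$value[d_rk$measure == "vocab"],
               d_ex$value[d_ex$measure == "vocab"], tolerance = 1e-6)
})

test_that("the control arm never adapts", {
  cfg <- quiet_sim_config(n_per_arm = 5, weeks = 12, seed = 8,
                          noise = c(vocab = 2, anxiety = 0.15))
  d <- simulate_cohort(cfg)
  ctrl <- d[d$arm == "control", ]
  expect_true(all(ctrl$value[ctrl$measure == "difficulty"] ==
                    cfg$start_difficulty))
  expect_true(all(ctrl$value[ctrl$measure == "forcing_I"] == 0.5))
  expect_true(all(ctrl$value[ctrl$measure == "forcing_S"] == 0.6))
})

test_that("experimental support intensity dominates the control arm", {
  cfg <- sim_config(n_per_arm = 15, weeks = 12, seed = 21, solver = "exact",
                    missing_rate = 0, outlier_rate = 0, calibrate = FALSE)
  d <- simulate_cohort(cfg)
  I <- d[d$measure == "forcing_I", ]
  mean_I <- tapply(I$value, I$arm, mean)
  expect_gte(mean_I[["experimental"]], mean_I[["control"]])
  # experimental mean anxiety trajectory is non-increasing in expectation
  anx <- d[d$measure == "anxiety" & d$arm == "experimental", ]
  path <- tapply(anx$value, anx$week, mean)
  expect_true(all(diff(path) < 0.05))  # small noise-driven slack
})

test_that("calibration hits the endpoint targets exactly", {
  cfg <- sim_config(n_per_arm = 30, weeks = 12, seed = 6, solver = "exact",
                    missing_rate = 0, outlier_rate = 0, calibrate = TRUE)
  d <- simulate_cohort(cfg)
  bl <- default_baseline()
  tg <- default_targets()
  for (m in names(tg)) {
    for (arm in c("experimental", "control")) {
      pre <- d$value[d$measure == m & d$week == 0 & d$arm == arm]
      post <- d$value[d$measure == m & d$week == 12 & d$arm == arm]
      expect_lt(abs(mean(pre) - bl[[m]][[arm]][["mean"]]), 1e-9)
      expect_lt(abs(mean(post) - tg[[m]][[arm]][["mean"]]), 1e-9)
      expect_lt(abs(sd(pre) / bl[[m]][[arm]][["sd"]] - 1), 0.02)
      expect_lt(abs(sd(post) / tg[[m]][[arm]][["sd"]] - 1), 0.02)
    }
  }
  expect_true(attr(d, "sim_meta")$calibrated)
})

test_that("missingness and outlier injection do what the config says", {
  cfg <- sim_config(n_per_arm = 20, weeks = 12, seed = 10, solver = "exact",
                    missing_rate = 0.05, outlier_rate = 0.02)
  d <- simulate_cohort(cfg)
  meta <- attr(d, "sim_meta")
  expect_gt(meta$n_missing, 0)
  expect_gt(nrow(meta$outliers), 0)
  # injected cells sit exactly at arm-cell mean + 4 SD of the clean values
  # and are therefore flaggable by a z screen
  d0 <- simulate_cohort(sim_config(n_per_arm = 20, weeks = 12, seed = 10,
                                   solver = "exact", missing_rate = 0.05,
                                   outlier_rate = 0))
  j <- meta$outliers[1, ]
  arm <- if (substr(j$student_id, 1, 1) == "E") "experimental" else "control"
  clean_cell <- d0$value[d0$measure == j$measure & d0$week == j$week &
                           d0$arm == arm]
  injected <- d$value[d$measure == j$measure & d$week == j$week &
                        d$student_id == j$student_id]
  expect_equal(injected, mean(clean_cell) + 4 * sd(clean_cell),
               tolerance = 1e-9)
})

test_that("uncalibrated arm means converge to the model mean trajectory", {
  # law of large numbers at n = 800 per arm, dispersion 0: the mean observed
  # control vocabulary trajectory matches the shared deterministic path
  # within 3 standard errors
  cfg <- quiet_sim_config(n_per_arm = 800, weeks = 6, seed = 33,
                          noise = c(vocab = 2, anxiety = 0.15))
  d <- simulate_cohort(cfg)
  ctrl <- d[d$arm == "control" & d$measure == "vocab", ]
  mpath <- tapply(ctrl$value, ctrl$week, mean)
  spath <- tapply(ctrl$value, ctrl$week, sd) / sqrt(800)
  truth <- closed_form(60, constant_forcing(0.5, 0.6), cfg$params, 0:6)
  # week 0 mean is the baseline draw around 59.8
  truth0 <- closed_form(59.8, constant_forcing(0.5, 0.6), cfg$params, 0:6)
  expect_true(all(abs(mpath - truth0) <= 3 * spath))
})

test_that("trial datasets round-trip through CSV with their sidecar", {
  cfg <- quiet_sim_config(n_per_arm = 3, weeks = 3, seed = 12)
  d <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(d, path)
  back <- read_trial_csv(path)
  expect_equal(back$value, d$value)
  expect_identical(back$student_id, d$student_id)
  expect_equal(attr(back, "sim_meta")$seed, attr(d, "sim_meta")$seed)
})

test_that("the null pre/post generator has the configured correlation", {
  d <- simulate_prepost_null(n_per_arm = 2000, rho = 0.5, seed = 4)
  w <- merge(d[d$week == 0, c("student_id", "value")],
             d[d$week == 12, c("student_id", "value")], by = "student_id")
  expect_equal(cor(w$value.x, w$value.y), 0.5, tolerance = 0.05)
})

test_that("config validation enforces the documented ranges", {
  expect_error(sim_config(n_per_arm = 1), class = "kinlearn_error")
  expect_error(sim_config(rho = 1), class = "kinlearn_error")
  expect_error(sim_config(missing_rate = 0.2), class = "kinlearn_error")
})
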