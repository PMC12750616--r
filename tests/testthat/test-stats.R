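test_that("the z screen removes exactly the constructed outlier", {
  # 149 students at 60 plus noise, one at mean + 4 SD
  set.seed(1)
  vals <- rnorm(149, 60, 5)
  extreme <- mean(vals) + 4 * sd(c(vals, mean(vals)))
  d <- data.frame(student_id = sprintf("S%03d", 1:150),
                  arm = rep(c("experimental", "control"), 75),
                  week = 0, measure = "vocab", value = c(vals, extreme),
                  stringsAsFactors = FALSE)
  out <- clean_dataset(d)
  expect_identical(nrow(out$log$outliers_removed), 1L)
  expect_identical(out$log$outliers_removed$student_id, "S150")
  expect_gt(abs(out$log$outliers_removed$z), 3.29)
  # the removed cell is re-imputed with the arm mean of the survivors
  expect_identical(nrow(out$log$values_imputed), 1L)
  arm_vals <- d$value[d$arm == "control" & d$student_id != "S150"]
  expect_equal(out$data$value[out$data$student_id == "S150"],
               mean(arm_vals))
})

test_that("clean data pass through unchanged", {
  d <- random_prepost(10, 10, seed = 2)
  out <- clean_dataset(d)
  expect_identical(nrow(out$log$outliers_removed), 0L)
  expect_identical(nrow(out$log$values_imputed), 0L)
  expect_equal(sort(out$data$value), sort(d$value))
})

test_that("missing cells are imputed with the arm-by-week mean", {
  d <- random_prepost(6, 6, seed = 3)
  drop <- which(d$student_id == "C01" & d$week == 12)
  d2 <- d[-drop, ]
  out <- clean_dataset(d2)
  expect_identical(nrow(out$log$values_imputed), 1L)
  others <- d2$value[d2$arm == "control" & d2$week == 12]
  expect_equal(out$data$value[out$data$student_id == "C01" &
                                out$data$week == 12], mean(others))
})

test_that("cleaning is idempotent", {
  cfg <- sim_config(n_per_arm = 25, weeks = 6, seed = 17, solver = "exact",
                    missing_rate = 0.04, outlier_rate = 0.02)
  d <- simulate_cohort(cfg)
  once <- clean_dataset(d)
  twice <- clean_dataset(once$data)
  expect_equal(twice$data$value, once$data$value)
  expect_identical(nrow(twice$log$outliers_removed), 0L)
  expect_identical(nrow(twice$log$values_imputed), 0L)
})

test_that("zero-SD cells are skipped and logged", {
  d <- data.frame(student_id = sprintf("S%02d", 1:10),
                  arm = rep(c("experimental", "control"), 5),
                  week = 0, measure = "vocab", value = 60,
                  stringsAsFactors = FALSE)
  out <- clean_dataset(d)
  expect_identical(nrow(out$log$cells_skipped), 1L)
  expect_identical(out$log$cells_skipped$reason, "zero SD")
})

test_that("percent change is exact arithmetic on the means", {
  expect_identical(percent_change(60.2, 78.4), 30.2)
  expect_identical(percent_change(59.8, 70.1), 17.2)
  expect_identical(percent_change(50, 50), 0)
  expect_error(percent_change(0, 10), class = "kinlearn_domain_error")
})

test_that("two-sample t from summaries matches closed forms and t.test", {
  # pooled t on the baseline vocabulary summaries: t(148) = 0.42, p = 0.68
  tt <- two_sample_t(60.2, 5.8, 75, 59.8, 6.0, 75)
  expect_identical(round(tt$t, 2), 0.42)
  expect_identical(tt$df, 148)
  expect_identical(round(tt$p, 2), 0.68)
  # unit-variance groups: t = 1 / sqrt(2/50) = 5 on 98 df
  tt <- two_sample_t(1, 1, 50, 0, 1, 50)
  expect_equal(tt$t, 5, tolerance = 1e-12)
  expect_identical(tt$df, 98)
  expect_identical(two_sample_t(3, 1, 10, 3, 2, 12)$t, 0)
  expect_error(two_sample_t(1, 0, 10, 1, 0, 10),
               class = "kinlearn_domain_error")
  # cross-check both variants against stats::t.test on raw data
  set.seed(4)
  x <- rnorm(14, 1, 2); y <- rnorm(9, 0, 1)
  pooled <- two_sample_t(mean(x), sd(x), 14, mean(y), sd(y), 9)
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(pooled$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(pooled$p, ref$p.value, tolerance = 1e-12)
  welch <- two_sample_t(mean(x), sd(x), 14, mean(y), sd(y), 9, "welch")
  refw <- t.test(x, y)
  expect_equal(welch$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(welch$df, unname(refw$parameter), tolerance = 1e-12)
})

test_that("the split-plot ANOVA matches the aov oracle on random data", {
  for (s in 1:6) {
    n1 <- sample(4:12, 1)
    n2 <- sample(4:12, 1)
    d <- random_prepost(n1, n2, seed = 30 + s)
    mine <- mixed_anova(d, "vocab")
    oracle <- aov_oracle(d, "vocab")
    expect_equal(mine$F[mine$effect == "group"], oracle$F_group,
                 tolerance = 1e-10)
    expect_equal(mine$F[mine$effect == "time"], oracle$F_time,
                 tolerance = 1e-10)
    expect_equal(mine$F[mine$effect == "group_time"], oracle$F_inter,
                 tolerance = 1e-10)
    # interaction F equals the squared pooled t on change scores
    sub <- d[d$measure == "vocab", ]
    w <- merge(sub[sub$week == 0, c("student_id", "arm", "value")],
               sub[sub$week == 12, c("student_id", "value")],
               by = "student_id")
    ch <- w$value.y - w$value.x
    che <- ch[w$arm == "experimental"]; chc <- ch[w$arm == "control"]
    tt <- two_sample_t(mean(che), sd(che), length(che),
                       mean(chc), sd(chc), length(chc))
    expect_equal(mine$F[mine$effect == "group_time"], tt$t^2,
                 tolerance = 1e-10)
    # full sums-of-squares decomposition
    dec <- attr(mine, "decomposition")
    expect_equal(dec[["ss_total"]], sum(dec[-1]), tolerance = 1e-10)
    # partial eta squared in [0, 1]
    expect_true(all(mine$partial_eta_sq >= 0 & mine$partial_eta_sq <= 1))
  }
})

test_that("ANOVA respects symmetry and detects no effect where none exists", {
  d <- random_prepost(10, 10, seed = 50)
  swapped <- d
  swapped$arm <- ifelse(d$arm == "experimental", "control", "experimental")
  a1 <- mixed_anova(d, "vocab")
  a2 <- mixed_anova(swapped, "vocab")
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$partial_eta_sq, a2$partial_eta_sq, tolerance = 1e-10)
  # both arms change by the same pattern: interaction exactly zero while the
  # within-subject error stays positive
  ids <- sprintf("S%02d", 1:12)
  arms <- rep(c("experimental", "control"), 6)
  set.seed(51)
  pre <- rnorm(12, 60, 5)
  change <- rep(c(5, 7, 9), 4)  # same change distribution in each arm
  d0 <- data.frame(student_id = rep(ids, 2), arm = rep(arms, 2),
                   week = rep(c(0, 12), each = 12), measure = "vocab",
                   value = c(pre, pre + change), stringsAsFactors = FALSE)
  a0 <- mixed_anova(d0, "vocab")
  inter <- a0[a0$effect == "group_time", ]
  expect_lt(inter$F, 1e-20)
  expect_lt(inter$partial_eta_sq, 1e-20)
})

test_that("the between-cells ANOVA flag delegates to aov", {
  d <- random_prepost(8, 8, seed = 60)
  a <- mixed_anova(d, "vocab", type = "between")
  expect_identical(a$effect, c("group", "time", "group_time"))
  expect_equal(unique(a$df_error), 28)  # 32 obs - 4 cells
})

test_that("the interaction test holds its nominal type-I error rate", {
  # 2000 null datasets from the cohort simulator's null generator
  n_sims <- 2000
  p <- vapply(seq_len(n_sims), function(s) {
    d <- simulate_prepost_null(n_per_arm = 20, rho = 0.5, seed = s)
    a <- mixed_anova(d, "vocab")
    a$p[a$effect == "group_time"]
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
  # the baseline two-sample t is similarly calibrated
  pt <- vapply(seq_len(n_sims), function(s) {
    d <- simulate_prepost_null(n_per_arm = 20, rho = 0.5, seed = 10000 + s)
    pre <- d[d$week == 0, ]
    e <- pre$value[pre$arm == "experimental"]
    c0 <- pre$value[pre$arm == "control"]
    two_sample_t(mean(e), sd(e), length(e), mean(c0), sd(c0), length(c0))$p
  }, numeric(1))
  expect_gte(mean(pt < 0.05), 0.03)
  expect_lte(mean(pt < 0.05), 0.07)
})

test_that("Cohen's d follows its definitions", {
  expect_identical(cohens_d(5, 2, 10, 5, 2, 10), 0)
  expect_equal(cohens_d(1, 1, 20, 0, 1, 20), 1)
  # change-score variant: mean / sd of the differences
  expect_equal(cohens_d(3, 2, 15, variant = "change_score"), 1.5)
  expect_error(cohens_d(1, 0, 10, 2, 0, 10), class = "kinlearn_domain_error")
  # the between-group post value from printed-style summaries, for reference:
  # (78.4 - 70.1) / sqrt(((74)*6.2^2 + (74)*7.1^2) / 148)
  d <- cohens_d(78.4, 6.2, 75, 70.1, 7.1, 75)
  expect_equal(d, (78.4 - 70.1) / sqrt((6.2^2 + 7.1^2) / 2),
               tolerance = 1e-12)
})

test_that("Cronbach's alpha matches closed forms and the definitional formula", {
  # identical items: perfect reliability
  x <- rnorm(20)
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1, tolerance = 1e-12)
  # two items with correlation exactly 0.5: Spearman-Brown 2r/(1+r) = 2/3
  skip_if_not_installed("MASS")
  X <- MASS::mvrnorm(40, c(0, 0), matrix(c(1, 0.5, 0.5, 1), 2),
                     empirical = TRUE)
  expect_equal(cronbach_alpha(X), 2 / 3, tolerance = 1e-12)
  # independent items at large n: alpha near 0
  set.seed(8)
  Z <- matrix(rnorm(5000 * 4), 5000, 4)
  expect_lt(abs(cronbach_alpha(Z)), 0.1)
  # brute-force definitional check on a random matrix
  set.seed(9)
  M <- matrix(rnorm(12 * 5, 3, 1), 12, 5)
  k <- ncol(M)
  brute <- (k / (k - 1)) *
    (1 - sum(diag(stats::cov(M))) / sum(stats::cov(M)))
  expect_equal(cronbach_alpha(M), brute, tolerance = 1e-10)
  expect_error(cronbach_alpha(matrix(1, 5, 3)),
               class = "kinlearn_domain_error")
})

test_that("subgroup analysis isolates low-baseline students", {
  # constructed cohort: low-baseline experimental students gain 22%,
  # control 14%
  ids <- c(sprintf("E%02d", 1:6), sprintf("C%02d", 1:6))
  arms <- rep(c("experimental", "control"), each = 6)
  pre <- c(50, 52, 54, 70, 72, 74, 50, 52, 54, 70, 72, 74)
  gain <- ifelse(arms == "experimental", 1.22, 1.14)
  post <- pre * gain
  d <- data.frame(student_id = rep(ids, 2), arm = rep(arms, 2),
                  week = rep(c(0, 12), each = 12), measure = "vocab",
                  value = c(pre, post), stringsAsFactors = FALSE)
  out <- subgroup_gains(d, baseline_threshold = 60)
  expect_equal(out$gain, c(experimental = 22, control = 14))
  expect_identical(out$n, c(experimental = 3L, control = 3L))
  expect_error(subgroup_gains(d, baseline_threshold = 10),
               class = "kinlearn_insufficient_data_error")
  # identical arms: t near zero
  d2 <- d
  d2$value[13:24] <- d2$value[1:12] * 1.2
  expect_lt(abs(subgroup_gains(d2, 60)$t), 1e-10)
})

test_that("the full report assembles descriptives, tests and notes", {
  cfg <- sim_config(n_per_arm = 20, weeks = 6, seed = 27, solver = "exact",
                    missing_rate = 0, outlier_rate = 0)
  d <- simulate_cohort(cfg)
  rep <- compute_stats_report(clean_dataset(d)$data)
  expect_s3_class(rep, "stats_report")
  expect_setequal(names(rep$measures),
                  c("vocab", "anxiety", "motivation", "self_efficacy",
                    "life_satisfaction"))
  v <- rep$measures$vocab
  expect_equal(v$descriptives$experimental$pre[["mean"]], 60.2,
               tolerance = 1e-9)
  expect_equal(v$descriptives$experimental$percent_change, 30.2)
  expect_equal(v$descriptives$control$percent_change, 17.2)
  expect_true(all(c("lmm", "alpha") %in% names(rep$notes)))
  expect_true(is.list(rep$subgroup) || is.character(rep$subgroup))
})
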