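# Shared fixtures and independent oracles for the test suite.

# a fast, quiet cohort: exact weekly propagator, no injected artifacts
quiet_sim_config <- function(n_per_arm = 10, weeks = 12, seed = 1,
                             noise = c(vocab = 0, anxiety = 0),
                             solver = "exact", ...) {
  sim_config(n_per_arm = n_per_arm, weeks = weeks, seed = seed,
             dispersion = 0, calibrate = FALSE, missing_rate = 0,
             outlier_rate = 0, solver = solver,
             noise_sd = c(vocab = unname(noise["vocab"]),
                          anxiety = unname(noise["anxiety"]),
                          quiz_accuracy = 0.05, anxiety_slider = 0.3),
             ...)
}

# baseline summaries on the kinetic model's intrinsic vocabulary scale
# (steady state k1/k2 = 2.5 at full intensity): used for parameter-recovery
# studies, where the forced component must be identifiable against noise
model_scale_baseline <- function() {
  bl <- default_baseline()
  bl$vocab <- list(experimental = c(mean = 0.5, sd = 0.2),
                   control = c(mean = 0.5, sd = 0.2))
  bl
}

# independent split-plot ANOVA oracle via stats::aov with an Error() stratum
aov_oracle <- function(data, measure) {
  sub <- data[data$measure == measure, ]
  wks <- range(sub$week)
  w <- merge(sub[sub$week == wks[1], c("student_id", "arm", "value")],
             sub[sub$week == wks[2], c("student_id", "value")],
             by = "student_id")
  long <- data.frame(
    y = c(w$value.x, w$value.y),
    subj = factor(rep(w$student_id, 2)),
    group = factor(rep(w$arm, 2)),
    time = factor(rep(c("pre", "post"), each = nrow(w)),
                  levels = c("pre", "post")))
  fit <- stats::aov(y ~ group * time + Error(subj), data = long)
  s <- summary(fit)
  between <- s[["Error: subj"]][[1]]
  within <- s[["Error: Within"]][[1]]
  list(F_group = between["group", "F value"],
       F_time = within["time", "F value"],
       F_inter = within["group:time", "F value"],
       ss = c(group = between["group", "Sum Sq"],
              err_b = between["Residuals", "Sum Sq"],
              time = within["time", "Sum Sq"],
              inter = within["group:time", "Sum Sq"],
              err_w = within["Residuals", "Sum Sq"]))
}

# random pre/post two-arm dataset with arbitrary effects, for oracle checks
random_prepost <- function(n1, n2, seed) {
  set.seed(seed)
  ids <- c(sprintf("E%02d", seq_len(n1)), sprintf("C%02d", seq_len(n2)))
  arms <- rep(c("experimental", "control"), c(n1, n2))
  pre <- rnorm(n1 + n2, 60, 6)
  post <- pre + rnorm(n1 + n2, ifelse(arms == "experimental", 8, 3), 4)
  data.frame(student_id = rep(ids, 2), arm = rep(arms, 2),
             week = rep(c(0, 12), each = n1 + n2), measure = "vocab",
             value = c(pre, post), stringsAsFactors = FALSE)
}
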