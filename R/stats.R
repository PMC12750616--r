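# Pre/post trial statistics: outlier screening, mean imputation, descriptive
# tables, two-sample t tests, split-plot (mixed) ANOVA with partial eta
# squared, Cohen's d, Cronbach's alpha, and the low-baseline subgroup
# analysis.

#' Clean a trial dataset
#'
#' Outlier screening and mean imputation, iterated to a fixed point so the
#' function is idempotent. Within each measure-by-week cell, pooled across
#' arms, values with `|z| > z_threshold` are removed; cells with zero SD (or
#' fewer than 3 values) are skipped and logged. Every missing (student,
#' week, measure) cell of the observed grid -- whether missing in the input
#' or removed by the screen -- is then imputed with the
#' arm-by-week-by-measure mean of the retained values. Because imputation
#' shifts the cell statistics, the screen is repeated until no further value
#' exceeds the threshold (imputed values sit at their cell mean and are
#' never flagged), so applying the function twice equals applying it once.
#' The student roster is taken from the input data, so a student whose only
#' record is removed is still imputed.
#'
#' @param data Long-format trial data frame.
#' @param z_threshold Two-sided z cutoff (default 3.29).
#' @param measures Measures subject to screening and imputation; defaults to
#'   the five outcome instruments. Session metadata (difficulty, forcing,
#'   quiz accuracy) passes through untouched.
#' @return A list with `data` (the cleaned dataset) and `log` (a
#'   `cleaning_log` with `outliers_removed`, `values_imputed`,
#'   `cells_skipped`, `z_threshold`).
#' @export
clean_dataset <- function(data, z_threshold = 3.29,
                          measures = c("vocab", "anxiety", "motivation",
                                       "self_efficacy",
                                       "life_satisfaction")) {
  stopifnot(nrow(data) > 0)
  passthrough <- data[!(data$measure %in% measures) & !is.na(data$value), ]
  data <- data[data$measure %in% measures & !is.na(data$value), ]
  if (!nrow(data)) {
    stop(.kinlearn_error("no records for any screened measure"))
  }
  students <- unique(rbind(data, passthrough)[, c("student_id", "arm")])
  # the observed grid: weeks at which each screened measure appears
  grid <- unique(data[, c("measure", "week")])

  removed <- data.frame(student_id = character(), measure = character(),
                        week = numeric(), z = numeric(),
                        stringsAsFactors = FALSE)
  skipped <- data.frame(measure = character(), week = numeric(),
                        reason = character(), stringsAsFactors = FALSE)
  imputed_cells <- data.frame(student_id = character(), measure = character(),
                              week = numeric(), stringsAsFactors = FALSE)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    key <- paste(data$measure, data$week)
    drop_idx <- integer(0)
    skipped <- skipped[0, ]
    for (k in unique(key)) {
      idx <- which(key == k)
      x <- data$value[idx]
      if (length(x) < 3 || stats::sd(x) == 0) {
        skipped <- rbind(skipped, data.frame(
          measure = data$measure[idx[1]], week = data$week[idx[1]],
          reason = if (length(x) < 3) "too few values" else "zero SD",
          stringsAsFactors = FALSE))
        next
      }
      z <- (x - mean(x)) / stats::sd(x)
      out <- which(abs(z) > z_threshold)
      # imputed rows sit at their arm-cell mean and are never removed
      if (nrow(imputed_cells)) {
        imp <- paste(data$student_id[idx], data$measure[idx],
                     data$week[idx]) %in%
          paste(imputed_cells$student_id, imputed_cells$measure,
                imputed_cells$week)
        out <- out[!imp[out]]
      }
      if (length(out)) {
        removed <- rbind(removed, data.frame(
          student_id = data$student_id[idx[out]],
          measure = data$measure[idx[out]], week = data$week[idx[out]],
          z = z[out], stringsAsFactors = FALSE))
        drop_idx <- c(drop_idx, idx[out])
      }
    }
    if (length(drop_idx)) data <- data[-drop_idx, ]

    # (re-)impute every missing cell of the grid with the arm-cell mean;
    # previously imputed cells are refreshed, not duplicated
    if (nrow(imputed_cells)) {
      imp_key <- paste(data$student_id, data$measure, data$week)
      known <- paste(imputed_cells$student_id, imputed_cells$measure,
                     imputed_cells$week)
      data <- data[!(imp_key %in% known), ]
    }
    new_rows <- list()
    for (g in seq_len(nrow(grid))) {
      m <- grid$measure[g]; wk <- grid$week[g]
      cell <- data[data$measure == m & data$week == wk, ]
      missing_ids <- setdiff(students$student_id, cell$student_id)
      for (sid in missing_ids) {
        arm <- students$arm[students$student_id == sid][1]
        vals <- cell$value[cell$arm == arm]
        if (!length(vals)) next
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          student_id = sid, arm = arm, week = wk, measure = m,
          value = mean(vals), stringsAsFactors = FALSE)
        already <- any(imputed_cells$student_id == sid &
                         imputed_cells$measure == m &
                         imputed_cells$week == wk)
        if (!already) {
          imputed_cells <- rbind(imputed_cells, data.frame(
            student_id = sid, measure = m, week = wk,
            stringsAsFactors = FALSE))
        }
      }
    }
    if (length(new_rows)) data <- rbind(data, do.call(rbind, new_rows))
    # stop only once a screen over the fully imputed data finds nothing:
    # imputation shifts cell statistics, so the first (pre-imputation)
    # screen alone does not guarantee a fixed point
    if (!length(drop_idx) && iter > 1L) break
  }

  data <- rbind(data, passthrough)
  data <- data[order(data$student_id, data$measure, data$week), ]
  rownames(data) <- NULL
  imp_key <- paste(data$student_id, data$measure, data$week)
  known <- paste(imputed_cells$student_id, imputed_cells$measure,
                 imputed_cells$week)
  imputed <- data[imp_key %in% known,
                  c("student_id", "measure", "week", "value")]
  rownames(imputed) <- NULL
  log <- structure(list(outliers_removed = removed, values_imputed = imputed,
                        cells_skipped = skipped, z_threshold = z_threshold),
                   class = "cleaning_log")
  list(data = data, log = log)
}

#' @export
print.cleaning_log <- function(x, ...) {
  cat(sprintf("Cleaning log: %d outliers removed (|z| > %g), %d values imputed, %d cells skipped\n",
              nrow(x$outliers_removed), x$z_threshold, nrow(x$values_imputed),
              nrow(x$cells_skipped)))
  invisible(x)
}

#' Percent change between two means
#'
#' `100 * (post - pre) / pre`, reported to one decimal place.
#'
#' @param pre_mean,post_mean Means; `pre_mean` must be non-zero.
#' @return Percent change, rounded to 1 decimal.
#' @export
#' @examples
#' percent_change(60.2, 78.4)  # 30.2
percent_change <- function(pre_mean, post_mean) {
  if (pre_mean == 0) {
    stop(.kinlearn_error("percent change undefined for a zero pre mean",
                         class = "kinlearn_domain_error"))
  }
  round(100 * (post_mean - pre_mean) / pre_mean, 1)
}

#' Two-sample t test from summary statistics
#'
#' @param m1,s1,n1 Mean, SD and size of group 1.
#' @param m2,s2,n2 Mean, SD and size of group 2.
#' @param variant `"pooled"` (Student, pooled variance) or `"welch"`
#'   (Satterthwaite degrees of freedom).
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' two_sample_t(60.2, 5.8, 75, 59.8, 6.0, 75)  # t ~ 0.42 on 148 df
two_sample_t <- function(m1, s1, n1, m2, s2, n2,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  if (s1 == 0 && s2 == 0) {
    if (m1 == m2) {
      stop(.kinlearn_error("t undefined: zero variance and equal means",
                           class = "kinlearn_domain_error"))
    }
  }
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1
    v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t <- (m1 - m2) / se
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# wide pre/post extraction: one row per student with both endpoint values
.prepost_wide <- function(data, measure) {
  sub <- data[data$measure == measure & !is.na(data$value), ]
  if (!nrow(sub)) stop(.kinlearn_error(paste("no records for measure", measure)))
  wks <- range(sub$week)
  pre <- sub[sub$week == wks[1], c("student_id", "arm", "value")]
  post <- sub[sub$week == wks[2], c("student_id", "value")]
  names(pre)[3] <- "pre"
  names(post)[2] <- "post"
  wide <- merge(pre, post, by = "student_id")
  dropped <- setdiff(unique(sub$student_id), wide$student_id)
  attr(wide, "dropped") <- dropped
  attr(wide, "weeks") <- wks
  wide
}

#' Split-plot (mixed) ANOVA for a pre/post two-arm design
#'
#' One between-subjects factor (group) and one within-subjects factor (time,
#' pre vs post). The group effect is tested against the between-subject
#' error; time and the group-by-time interaction against the within-subject
#' error. Partial eta squared is `SS_effect / (SS_effect + SS_error)` with
#' each effect's own error term. With two time points the interaction F
#' equals the squared pooled two-sample t on per-student change scores.
#' Students lacking either endpoint are dropped listwise (recorded in the
#' `dropped` attribute). `type = "between"` instead fits a purely
#' between-cells two-way ANOVA (all observations treated as independent) via
#' [stats::aov()] for comparison.
#'
#' @param data Long-format trial data frame (cleaned).
#' @param measure Measure to analyse.
#' @param type `"mixed"` (split-plot, default) or `"between"`.
#' @return A data frame with rows `group`, `time`, `group_time`: columns
#'   `effect`, `df`, `df_error`, `ss`, `ss_error`, `F`, `p`,
#'   `partial_eta_sq`. The full sums-of-squares decomposition is attached as
#'   attribute `decomposition`.
#' @export
mixed_anova <- function(data, measure, type = c("mixed", "between")) {
  type <- match.arg(type)
  wide <- .prepost_wide(data, measure)
  if (type == "between") {
    long <- data.frame(
      value = c(wide$pre, wide$post),
      group = factor(rep(wide$arm, 2)),
      time = factor(rep(c("pre", "post"), each = nrow(wide)),
                    levels = c("pre", "post")))
    fit <- stats::aov(value ~ group * time, data = long)
    tab <- summary(fit)[[1]]
    ss_err <- tab["Residuals", "Sum Sq"]
    df_err <- tab["Residuals", "Df"]
    eff <- c("group", "time", "group:time")
    out <- data.frame(
      effect = c("group", "time", "group_time"),
      df = tab[eff, "Df"], df_error = df_err, ss = tab[eff, "Sum Sq"],
      ss_error = ss_err, F = tab[eff, "F value"], p = tab[eff, "Pr(>F)"],
      partial_eta_sq = tab[eff, "Sum Sq"] / (tab[eff, "Sum Sq"] + ss_err),
      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    return(out)
  }

  arms <- sort(unique(wide$arm))
  if (length(arms) != 2) stop(.kinlearn_error("exactly two arms required"))
  ns <- table(factor(wide$arm, levels = arms))
  if (any(ns < 2)) {
    stop(.kinlearn_error("fewer than 2 students per arm after deletion",
                         class = "kinlearn_insufficient_data_error"))
  }
  N <- nrow(wide)
  # orthogonal within-subject decomposition: subject means carry the
  # between-subject part, scaled change scores the within-subject part
  smean <- (wide$pre + wide$post) / 2
  contr <- (wide$post - wide$pre) / sqrt(2)
  g <- factor(wide$arm, levels = arms)

  grand_s <- mean(smean)
  gmeans_s <- tapply(smean, g, mean)
  ss_group <- 2 * sum(as.numeric(ns) * (gmeans_s - grand_s)^2)
  ss_err_between <- 2 * sum((smean - gmeans_s[g])^2)

  cbar <- mean(contr)
  gmeans_c <- tapply(contr, g, mean)
  ss_time <- N * cbar^2
  ss_inter <- sum(as.numeric(ns) * (gmeans_c - cbar)^2)
  ss_err_within <- sum((contr - gmeans_c[g])^2)

  df_err <- N - 2
  ms_err_b <- ss_err_between / df_err
  ms_err_w <- ss_err_within / df_err
  Fs <- c(ss_group / ms_err_b, ss_time / ms_err_w, ss_inter / ms_err_w)
  ss <- c(ss_group, ss_time, ss_inter)
  ss_err <- c(ss_err_between, ss_err_within, ss_err_within)
  out <- data.frame(
    effect = c("group", "time", "group_time"),
    df = 1, df_error = df_err, ss = ss, ss_error = ss_err, F = Fs,
    p = stats::pf(Fs, 1, df_err, lower.tail = FALSE),
    partial_eta_sq = ss / (ss + ss_err), stringsAsFactors = FALSE)
  y <- c(wide$pre, wide$post)
  attr(out, "decomposition") <- c(
    ss_total = sum((y - mean(y))^2), ss_group = ss_group,
    ss_error_between = ss_err_between, ss_time = ss_time,
    ss_interaction = ss_inter, ss_error_within = ss_err_within)
  attr(out, "dropped") <- attr(wide, "dropped")
  out
}

#' Cohen's d
#'
#' `variant = "pooled"`: standardized mean difference between two groups
#' using the pooled SD. `variant = "change_score"`: the within-group effect
#' `mean(change) / sd(change)`, where `(m1, s1, n1)` summarize the
#' per-student change scores and the second group is ignored.
#'
#' @inheritParams two_sample_t
#' @param variant `"pooled"` or `"change_score"`.
#' @return Cohen's d.
#' @export
cohens_d <- function(m1, s1, n1, m2 = NULL, s2 = NULL, n2 = NULL,
                     variant = c("pooled", "change_score")) {
  variant <- match.arg(variant)
  if (variant == "change_score") {
    if (s1 == 0) {
      stop(.kinlearn_error("d undefined: zero spread",
                           class = "kinlearn_domain_error"))
    }
    return(m1 / s1)
  }
  stopifnot(!is.null(m2), !is.null(s2), !is.null(n2))
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  if (sp == 0) {
    stop(.kinlearn_error("d undefined: zero pooled spread",
                         class = "kinlearn_domain_error"))
  }
  (m1 - m2) / sp
}

#' Cronbach's alpha
#'
#' Internal-consistency reliability of a multi-item scale:
#' `alpha = k/(k-1) * (1 - sum(item variances) / var(total score))`.
#'
#' @param item_matrix Numeric matrix, students in rows, items in columns
#'   (>= 2 of each).
#' @return Alpha.
#' @export
cronbach_alpha <- function(item_matrix) {
  item_matrix <- as.matrix(item_matrix)
  k <- ncol(item_matrix)
  stopifnot(k >= 2, nrow(item_matrix) >= 2)
  total_var <- stats::var(rowSums(item_matrix))
  if (total_var == 0) {
    stop(.kinlearn_error("alpha undefined: zero total-score variance",
                         class = "kinlearn_domain_error"))
  }
  (k / (k - 1)) * (1 - sum(apply(item_matrix, 2, stats::var)) / total_var)
}

#' Subgroup gains for low-baseline students
#'
#' Restricts to students whose pre-test score is strictly below
#' `baseline_threshold`, computes each student's percent change, and compares
#' the arm means with a pooled two-sample t test on the per-student gains.
#'
#' @param data Long-format trial data frame.
#' @param baseline_threshold Pre-score cutoff (default 60).
#' @param measure Measure to analyse (default `"vocab"`).
#' @return List with `gain` (named mean percent gain per arm, 1 decimal),
#'   `t`, `df`, `p`, and `n` per arm.
#' @export
subgroup_gains <- function(data, baseline_threshold = 60, measure = "vocab") {
  wide <- .prepost_wide(data, measure)
  low <- wide[wide$pre < baseline_threshold, ]
  ns <- table(factor(low$arm, levels = c("experimental", "control")))
  if (any(ns < 2)) {
    stop(.kinlearn_error(
      "fewer than 2 low-baseline students in an arm",
      class = "kinlearn_insufficient_data_error"))
  }
  low$gain <- 100 * (low$post - low$pre) / low$pre
  ge <- low$gain[low$arm == "experimental"]
  gc <- low$gain[low$arm == "control"]
  tt <- two_sample_t(mean(ge), stats::sd(ge), length(ge),
                     mean(gc), stats::sd(gc), length(gc))
  list(gain = c(experimental = round(mean(ge), 1),
                control = round(mean(gc), 1)),
       t = tt$t, df = tt$df, p = tt$p,
       n = c(experimental = length(ge), control = length(gc)))
}

#' Full trial statistics report
#'
#' Runs the complete pre/post analysis on a (cleaned) trial dataset: per
#' measure and arm the endpoint descriptives and percent change, baseline
#' and post between-group t tests, the split-plot ANOVA with partial eta
#' squared, Cohen's d (between groups at post, and per-arm change-score d),
#' and the low-baseline vocabulary subgroup analysis. A note records that a
#' linear mixed model with a class random intercept is not fitted (two
#' classes give a degenerate random-effect variance) and that item-level
#' responses, hence scale reliabilities, are not part of the simulated data.
#'
#' @param data Long-format (cleaned) trial data frame.
#' @param measures Measures to analyse.
#' @param anova_type Passed to [mixed_anova()].
#' @param t_variant Passed to [two_sample_t()].
#' @param baseline_threshold Passed to [subgroup_gains()].
#' @return An object of class `stats_report` (nested list).
#' @export
compute_stats_report <- function(data,
                                 measures = c("vocab", "anxiety",
                                              "motivation", "self_efficacy",
                                              "life_satisfaction"),
                                 anova_type = "mixed",
                                 t_variant = "pooled",
                                 baseline_threshold = 60) {
  measures <- intersect(measures, unique(data$measure))
  per_measure <- list()
  for (m in measures) {
    wide <- .prepost_wide(data, m)
    desc <- list()
    for (arm in c("experimental", "control")) {
      w <- wide[wide$arm == arm, ]
      desc[[arm]] <- list(
        n = nrow(w),
        pre = c(mean = mean(w$pre), sd = stats::sd(w$pre)),
        post = c(mean = mean(w$post), sd = stats::sd(w$post)),
        percent_change = percent_change(mean(w$pre), mean(w$post)))
    }
    we <- wide[wide$arm == "experimental", ]
    wc <- wide[wide$arm == "control", ]
    t_pre <- two_sample_t(mean(we$pre), stats::sd(we$pre), nrow(we),
                          mean(wc$pre), stats::sd(wc$pre), nrow(wc),
                          variant = t_variant)
    t_post <- two_sample_t(mean(we$post), stats::sd(we$post), nrow(we),
                           mean(wc$post), stats::sd(wc$post), nrow(wc),
                           variant = t_variant)
    anova <- mixed_anova(data, m, type = anova_type)
    d_between_post <- cohens_d(mean(we$post), stats::sd(we$post), nrow(we),
                               mean(wc$post), stats::sd(wc$post), nrow(wc))
    ch_e <- we$post - we$pre
    ch_c <- wc$post - wc$pre
    per_measure[[m]] <- list(
      descriptives = desc, t_pre = t_pre, t_post = t_post,
      anova = anova,
      cohens_d = list(
        between_post = d_between_post,
        change_experimental = cohens_d(mean(ch_e), stats::sd(ch_e),
                                       length(ch_e),
                                       variant = "change_score"),
        change_control = cohens_d(mean(ch_c), stats::sd(ch_c), length(ch_c),
                                  variant = "change_score")))
  }
  subgroup <- tryCatch(
    subgroup_gains(data, baseline_threshold = baseline_threshold),
    kinlearn_insufficient_data_error = function(e) conditionMessage(e))
  structure(list(
    measures = per_measure,
    subgroup = subgroup,
    notes = c(
      lmm = paste("linear mixed model with a class random intercept not",
                  "fitted: only two classes, the random-effect variance is",
                  "degenerate"),
      alpha = paste("Cronbach's alpha requires item-level responses, which",
                    "the cohort simulator does not generate; use",
                    "cronbach_alpha() on item matrices directly"))),
    class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Trial statistics report\n")
  for (m in names(x$measures)) {
    r <- x$measures[[m]]
    e <- r$descriptives$experimental
    c0 <- r$descriptives$control
    cat(sprintf("  %s: exp %.1f (%.1f) -> %.1f (%.1f) [%+.1f%%]; ctrl %.1f (%.1f) -> %.1f (%.1f) [%+.1f%%]\n",
                m, e$pre["mean"], e$pre["sd"], e$post["mean"], e$post["sd"],
                e$percent_change, c0$pre["mean"], c0$pre["sd"],
                c0$post["mean"], c0$post["sd"], c0$percent_change))
    inter <- r$anova[r$anova$effect == "group_time", ]
    cat(sprintf("    post t(%g) = %.2f, p = %.3g; interaction F(1,%g) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
                r$t_post$df, r$t_post$t, r$t_post$p, inter$df_error, inter$F,
                inter$p, inter$partial_eta_sq))
  }
  if (is.list(x$subgroup)) {
    cat(sprintf("  low-baseline vocabulary gains: exp %.1f%% vs ctrl %.1f%% (t = %.2f, p = %.3g)\n",
                x$subgroup$gain["experimental"], x$subgroup$gain["control"],
                x$subgroup$t, x$subgroup$p))
  }
  invisible(x)
}
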