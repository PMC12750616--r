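# First-order kinetic model of vocabulary retention and learner anxiety:
#   dV/dt = k1 * I(t) - k2 * V      (score points per week)
#   dA/dt = k3 * S(t) - k4 * A      (Likert units per week)
# with piecewise-constant forcing I(t) (intervention intensity) and S(t)
# (stress), both normalized to [0, 1]. The two states are uncoupled, so each
# has an exact piecewise-exponential solution used as the numerical oracle.

#' Rate constants of the kinetic model
#'
#' @param k1 Learning-gain rate (score points per week per unit intensity).
#' @param k2 Forgetting rate (per week).
#' @param k3 Stress-to-anxiety rate (Likert units per week per unit stress).
#' @param k4 Anxiety-decay rate (per week).
#' @return An object of class `ode_params`.
#' @export
#' @examples
#' ode_params()  # the default calibration
ode_params <- function(k1 = 0.05, k2 = 0.02, k3 = 0.03, k4 = 0.04) {
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(!is.finite(ks)) || any(ks < 0)) {
    stop(.kinlearn_error("rate constants must be finite and >= 0"))
  }
  structure(as.list(ks), class = "ode_params")
}

#' @export
print.ode_params <- function(x, ...) {
  cat(sprintf("Kinetic rate constants: k1 = %g, k2 = %g, k3 = %g, k4 = %g (per week)\n",
              x$k1, x$k2, x$k3, x$k4))
  invisible(x)
}

#' Piecewise-constant forcing schedule
#'
#' Intervention intensity `I(t)` and stress `S(t)` held constant on each
#' interval `[breakpoints[i], breakpoints[i + 1])`; the final interval is
#' closed on the right.
#'
#' @param breakpoints Strictly increasing week boundaries, length `m + 1`.
#' @param I Intensities in `[0, 1]`, length `m`.
#' @param S Stress levels in `[0, 1]`, length `m`.
#' @return An object of class `forcing_schedule`.
#' @export
forcing_schedule <- function(breakpoints, I, S) {
  stopifnot(length(breakpoints) >= 2, all(diff(breakpoints) > 0))
  m <- length(breakpoints) - 1L
  if (length(I) != m || length(S) != m) {
    stop(.kinlearn_error(
      "I and S must have one level per interval (length(breakpoints) - 1)"))
  }
  if (any(I < 0 | I > 1) || any(S < 0 | S > 1)) {
    stop(.kinlearn_error("forcing levels must lie in [0, 1]"))
  }
  structure(list(breakpoints = as.numeric(breakpoints), I = as.numeric(I),
                 S = as.numeric(S)),
            class = "forcing_schedule")
}

#' Constant forcing over an interval
#'
#' @param I,S Constant levels in `[0, 1]`.
#' @param t0,t_end Interval covered.
#' @return A `forcing_schedule` with a single piece.
#' @export
constant_forcing <- function(I, S, t0 = 0, t_end = 12) {
  forcing_schedule(c(t0, t_end), I, S)
}

#' Evaluate a forcing schedule at time t
#'
#' @param schedule A `forcing_schedule`.
#' @param t Time (weeks); vectorized.
#' @return A list with components `I` and `S`.
#' @export
forcing_at <- function(schedule, t) {
  bp <- schedule$breakpoints
  if (any(t < bp[1]) || any(t > bp[length(bp)])) {
    stop(.kinlearn_error(sprintf(
      "time outside schedule span [%g, %g]", bp[1], bp[length(bp)]),
      class = "kinlearn_domain_error"))
  }
  idx <- findInterval(t, bp, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(schedule$I))
  list(I = schedule$I[idx], S = schedule$S[idx])
}

#' Vocabulary retention rate
#'
#' `dV/dt = k1 * I - k2 * V`.
#'
#' @param V Vocabulary retention (score points).
#' @param I Intervention intensity in `[0, 1]`.
#' @param params An [ode_params()].
#' @return dV/dt (score points per week).
#' @export
vocab_rate <- function(V, I, params = ode_params()) {
  params$k1 * I - params$k2 * V
}

#' Anxiety rate
#'
#' `dA/dt = k3 * S - k4 * A`.
#'
#' @param A Anxiety (Likert units).
#' @param S Stress level in `[0, 1]`.
#' @param params An [ode_params()].
#' @return dA/dt (Likert units per week).
#' @export
anxiety_rate <- function(A, S, params = ode_params()) {
  params$k3 * S - params$k4 * A
}

#' Steady state under constant forcing
#'
#' Setting the rates to zero gives `V* = k1 * I / k2` and `A* = k3 * S / k4`.
#'
#' @param params An [ode_params()]; requires `k2 > 0` and `k4 > 0`.
#' @param I,S Constant forcing levels.
#' @return Named vector `c(V = , A = )`.
#' @export
steady_state <- function(params = ode_params(), I = 1, S = 1) {
  if (params$k2 <= 0 || params$k4 <= 0) {
    stop(.kinlearn_error("steady state undefined when a decay rate is zero",
                         class = "kinlearn_domain_error"))
  }
  c(V = params$k1 * I / params$k2, A = params$k3 * S / params$k4)
}

# advance one linear kinetic state across an interval of constant forcing;
# exact for the model, including the k_decay = 0 limit
.advance_exact <- function(y, gain, decay, level, dt) {
  if (decay == 0) return(y + gain * level * dt)
  ystar <- gain * level / decay
  ystar + (y - ystar) * exp(-decay * dt)
}

#' Exact solution of the kinetic model under piecewise-constant forcing
#'
#' On each constant-forcing interval the model is linear with constant
#' coefficients, so `y(t) = y* + (y_start - y*) exp(-k_decay * dt)` with
#' `y* = k_gain * level / k_decay`; intervals are chained exactly. This is
#' the analytic oracle against which the Runge-Kutta engine is checked.
#'
#' @param y0 Initial state at the start of the schedule.
#' @param schedule A `forcing_schedule`.
#' @param params An [ode_params()].
#' @param t Evaluation times (weeks) within the schedule span; vectorized.
#' @param which `"vocab"` (uses `k1`, `k2`, `I`) or `"anxiety"` (`k3`, `k4`,
#'   `S`).
#' @return State values at `t`.
#' @export
#' @examples
#' p <- ode_params(k1 = 0.05, k2 = 0.02)
#' closed_form(0, constant_forcing(1, 0, 0, 12), p, t = 10)  # 2.5*(1 - exp(-0.2))
closed_form <- function(y0, schedule, params, t,
                        which = c("vocab", "anxiety")) {
  which <- match.arg(which)
  gain <- if (which == "vocab") params$k1 else params$k3
  decay <- if (which == "vocab") params$k2 else params$k4
  levels <- if (which == "vocab") schedule$I else schedule$S
  bp <- schedule$breakpoints
  if (any(t < bp[1]) || any(t > bp[length(bp)])) {
    stop(.kinlearn_error(sprintf(
      "evaluation time outside schedule span [%g, %g]", bp[1], bp[length(bp)]),
      class = "kinlearn_domain_error"))
  }
  # state at the start of each interval, chained exactly
  starts <- numeric(length(levels) + 1L)
  starts[1] <- y0
  for (i in seq_along(levels)) {
    starts[i + 1L] <- .advance_exact(starts[i], gain, decay, levels[i],
                                     bp[i + 1L] - bp[i])
  }
  idx <- findInterval(t, bp, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(levels))
  vapply(seq_along(t), function(j) {
    i <- idx[j]
    .advance_exact(starts[i], gain, decay, levels[i], t[j] - bp[i])
  }, numeric(1))
}

#' Derivative function for the joint (V, A) system
#'
#' Packages the two kinetic rates and a forcing schedule into an `f(t, y)`
#' suitable for [integrate_adaptive()]; the state is `c(V, A)`.
#'
#' @param params An [ode_params()].
#' @param schedule A `forcing_schedule`.
#' @return A function `f(t, y)`.
#' @export
kinetic_rhs <- function(params, schedule) {
  function(t, y) {
    frc <- forcing_at(schedule, t)
    c(vocab_rate(y[1], frc$I, params),
      anxiety_rate(y[2], frc$S, params))
  }
}

# ---- forcing schedule CSV i/o ----------------------------------------------

#' Read a forcing schedule from CSV
#'
#' Expects columns `week_start`, `week_end`, `I`, `S`, with contiguous
#' intervals.
#'
#' @param path CSV path.
#' @return A `forcing_schedule`.
#' @export
read_forcing_csv <- function(path) {
  df <- utils::read.csv(path)
  required <- c("week_start", "week_end", "I", "S")
  if (!all(required %in% names(df))) {
    stop(.kinlearn_error(paste("forcing CSV must have columns:",
                               paste(required, collapse = ", "))))
  }
  df <- df[order(df$week_start), ]
  if (any(abs(df$week_start[-1] - df$week_end[-nrow(df)]) > 1e-12)) {
    stop(.kinlearn_error("forcing intervals must be contiguous"))
  }
  forcing_schedule(c(df$week_start, df$week_end[nrow(df)]), df$I, df$S)
}

#' Write a forcing schedule to CSV
#'
#' @param schedule A `forcing_schedule`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(schedule, path) {
  m <- length(schedule$I)
  df <- data.frame(week_start = schedule$breakpoints[seq_len(m)],
                   week_end = schedule$breakpoints[seq_len(m) + 1L],
                   I = schedule$I, S = schedule$S)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
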