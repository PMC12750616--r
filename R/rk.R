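# Generic explicit embedded Runge-Kutta stepping with adaptive step-size
# control. Time is measured in weeks throughout the package, but the engine
# itself is unit-agnostic.

.kinlearn_error <- function(message, class = "kinlearn_error", data = list()) {
  structure(class = c(class, "kinlearn_error", "error", "condition"),
            c(list(message = message, call = NULL), data))
}

#' Integrator configuration
#'
#' Tolerances and step bounds for [integrate_adaptive()]. The error test is a
#' mixed absolute/relative weighted RMS norm, so `atol` carries the units of
#' the state (score points or Likert units here) while `rtol` is
#' dimensionless.
#'
#' @param rtol Relative tolerance.
#' @param atol Absolute tolerance (state units).
#' @param h_init Initial step size (weeks).
#' @param h_min,h_max Step-size bounds (weeks).
#' @param safety Step-safety factor in (0, 1).
#' @param max_steps Cap on step attempts before giving up.
#' @return An object of class `integrator_config`.
#' @export
integrator_config <- function(rtol = 1e-6, atol = 1e-8, h_init = 0.1,
                              h_min = 1e-10, h_max = 10, safety = 0.9,
                              max_steps = 100000L) {
  stopifnot(rtol > 0, atol > 0, h_min > 0, h_min <= h_init, h_init <= h_max,
            safety > 0, safety < 1, max_steps >= 1)
  structure(list(rtol = rtol, atol = atol, h_init = h_init, h_min = h_min,
                 h_max = h_max, safety = safety,
                 max_steps = as.integer(max_steps)),
            class = "integrator_config")
}

#' Take one embedded Runge-Kutta step
#'
#' Evaluates all stages of the tableau and forms both the propagating
#' (`b_high`) and embedded (`b_low`) solutions, together with the weighted
#' RMS norm of their difference against the scale
#' `atol + rtol * max(|y|, |y_high|)` componentwise. An error norm of 1 marks
#' the boundary between acceptable and unacceptable local error.
#'
#' @param f Derivative function `f(t, y)` returning `dy/dt`.
#' @param t Current time.
#' @param y Current state vector.
#' @param h Step size (> 0).
#' @param tableau A `butcher_tableau`.
#' @param atol,rtol Tolerances used only for the error norm.
#' @return A list with `y_high`, `y_low`, `err_norm`.
#' @export
rk_step <- function(f, t, y, h, tableau, atol = 1e-8, rtol = 1e-6) {
  stopifnot(h > 0)
  s <- tableau$stages
  n <- length(y)
  k <- matrix(0, s, n)
  for (i in seq_len(s)) {
    yi <- y
    if (i > 1L) {
      incr <- drop(tableau$a[i, seq_len(i - 1L), drop = FALSE] %*%
                     k[seq_len(i - 1L), , drop = FALSE])
      yi <- y + h * incr
    }
    ki <- f(t + tableau$c[i] * h, yi)
    if (any(!is.finite(ki))) {
      stop(.kinlearn_error(
        sprintf("non-finite derivative at t = %g, stage %d", t, i),
        class = "kinlearn_integration_error",
        data = list(t = t, stage = i)))
    }
    k[i, ] <- ki
  }
  y_high <- y + h * drop(tableau$b_high %*% k)
  y_low <- y + h * drop(tableau$b_low %*% k)
  scale <- atol + rtol * pmax(abs(y), abs(y_high))
  err_norm <- sqrt(mean(((y_high - y_low) / scale)^2))
  list(y_high = y_high, y_low = y_low, err_norm = err_norm)
}

.solution_path <- function(times, states, accepted, rejected) {
  states <- do.call(rbind, states)
  structure(list(times = times, states = states,
                 accepted_steps = accepted, rejected_steps = rejected),
            class = "rk_solution")
}

#' @export
print.rk_solution <- function(x, ...) {
  cat(sprintf("Runge-Kutta solution path: %d points on [%g, %g], %d accepted / %d rejected steps\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              x$accepted_steps, x$rejected_steps))
  invisible(x)
}

#' Adaptive embedded Runge-Kutta integration
#'
#' Integrates `dy/dt = f(t, y)` from `t0` to `t_end` with local-error control:
#' a step is accepted when the embedded error norm is at most 1, and the next
#' step is `h * safety * err^(-1/(order_low + 1))`, with the growth factor
#' clamped to `[0.2, 5]` and the step itself to `[h_min, h_max]`. The final
#' step is truncated so the path lands exactly on `t_end`. If `times` is
#' given, the integrator steps exactly onto each requested time and the
#' returned path contains exactly those times (plus the endpoints).
#'
#' @param f Derivative function `f(t, y)`.
#' @param t0,t_end Integration interval, `t_end > t0`.
#' @param y0 Initial state vector.
#' @param tableau A `butcher_tableau`; validated unless `validate = FALSE`.
#' @param config An [integrator_config()].
#' @param times Optional increasing vector of output times inside
#'   `[t0, t_end]`.
#' @param validate Check the tableau before integrating.
#' @return An `rk_solution` with fields `times`, `states` (matrix, one row per
#'   time), `accepted_steps`, `rejected_steps`.
#' @export
#' @examples
#' sol <- integrate_adaptive(function(t, y) -y, 0, 1, 1, rk_dp54(),
#'                           integrator_config(rtol = 1e-8))
#' abs(sol$states[nrow(sol$states), 1] - exp(-1)) < 1e-7
integrate_adaptive <- function(f, t0, t_end, y0, tableau = rk_dp54(),
                               config = integrator_config(), times = NULL,
                               validate = TRUE) {
  stopifnot(t_end > t0)
  if (validate) {
    v <- validate_tableau(tableau)
    if (nrow(v) > 0) {
      stop(.kinlearn_error(paste("invalid tableau:",
                                 paste(v$message, collapse = "; "))))
    }
  }
  record_all <- is.null(times)
  knots <- if (record_all) t_end else {
    stopifnot(all(diff(times) > 0), all(times >= t0), all(times <= t_end))
    sort(unique(c(times, t_end)))
  }
  exponent <- -1 / (tableau$order_low + 1)

  t <- t0
  y <- as.numeric(y0)
  out_t <- t0
  out_y <- list(y)
  accepted <- 0L
  rejected <- 0L
  h <- min(config$h_init, t_end - t0)
  attempts <- 0L

  for (knot in knots) {
    repeat {
      if (t >= knot - 1e-14 * max(1, abs(knot))) break
      h <- min(h, knot - t)
      attempts <- attempts + 1L
      if (attempts > config$max_steps) {
        stop(.kinlearn_error(
          sprintf("max_steps exceeded at t = %g", t),
          class = "kinlearn_integration_error", data = list(t = t)))
      }
      step <- rk_step(f, t, y, h, tableau, atol = config$atol,
                      rtol = config$rtol)
      err <- step$err_norm
      if (err <= 1) {
        t <- t + h
        y <- step$y_high
        accepted <- accepted + 1L
        if (record_all) {
          out_t <- c(out_t, t)
          out_y[[length(out_y) + 1L]] <- y
        }
      } else {
        rejected <- rejected + 1L
        if (h <= config$h_min * (1 + 1e-12)) {
          stop(.kinlearn_error(
            sprintf("step size underflow below h_min at t = %g", t),
            class = "kinlearn_integration_error", data = list(t = t)))
        }
      }
      factor <- if (err == 0) 5 else
        min(5, max(0.2, config$safety * err^exponent))
      h <- min(config$h_max, max(config$h_min, h * factor))
    }
    t <- knot  # land exactly on the knot
    if (!record_all) {
      out_t <- c(out_t, knot)
      out_y[[length(out_y) + 1L]] <- y
    }
  }
  if (!record_all) {
    keep <- c(TRUE, out_t[-1] %in% c(times, t_end))
    # drop duplicated t0 if requested in times
    dup <- duplicated(out_t)
    keep <- keep & !dup
    out_y <- out_y[keep]
    out_t <- out_t[keep]
  }
  .solution_path(out_t, out_y, accepted, rejected)
}

#' Fixed-step Runge-Kutta integration
#'
#' Uniform steps with the propagating (`b_high`) solution only; used for
#' convergence-order verification.
#'
#' @inheritParams integrate_adaptive
#' @param n_steps Number of uniform steps (>= 1).
#' @return An `rk_solution` with `n_steps + 1` points.
#' @export
integrate_fixed <- function(f, t0, t_end, y0, tableau = rk_dp54(), n_steps) {
  stopifnot(n_steps >= 1, t_end > t0)
  h <- (t_end - t0) / n_steps
  t <- t0
  y <- as.numeric(y0)
  out_t <- t0
  out_y <- list(y)
  for (i in seq_len(n_steps)) {
    step <- rk_step(f, t, y, h, tableau)
    y <- step$y_high
    t <- t0 + i * h
    out_t <- c(out_t, t)
    out_y[[length(out_y) + 1L]] <- y
  }
  .solution_path(out_t, out_y, as.integer(n_steps), 0L)
}
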