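# Rule-based adaptive agent: maps per-session quiz accuracy and a 1-5
# self-reported anxiety slider to difficulty changes and role switches, and
# from the resulting agent state to the forcing functions I(t) and S(t) that
# drive the kinetic model.

.agent_roles <- c("tutor", "peer_supporter", "motivator")

#' Agent configuration
#'
#' Decision thresholds are strict inequalities: accuracy above
#' `advance_threshold` raises difficulty, accuracy below
#' `remediate_threshold` lowers it with remedial hints, and an anxiety
#' slider above `anxiety_threshold` switches the agent out of the default
#' tutor role. At most `max_adaptations` adaptations (difficulty or role
#' changes) are applied per session. The `forcing` block defines the
#' documented numeric map from agent state to the `[0, 1]` forcing levels:
#' `I = base_I + role_bonus * (role != tutor) + adapt_bonus * adaptations`
#' and `S = difficulty / levels - peer_stress_relief * (role ==
#' peer_supporter)`, both clamped to `[0, 1]`.
#'
#' @param levels Number of difficulty levels `L`.
#' @param advance_threshold Accuracy above which difficulty increases.
#' @param remediate_threshold Accuracy below which difficulty decreases.
#' @param anxiety_threshold Slider value above which the role switches.
#' @param max_adaptations Cap on adaptations per session.
#' @param base_I,role_bonus,adapt_bonus,peer_stress_relief Forcing-map
#'   constants.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(levels = 5L, advance_threshold = 0.80,
                         remediate_threshold = 0.60, anxiety_threshold = 3,
                         max_adaptations = 3L, base_I = 0.5, role_bonus = 0.1,
                         adapt_bonus = 0.05, peer_stress_relief = 0.1) {
  stopifnot(levels >= 1, advance_threshold > remediate_threshold,
            advance_threshold <= 1, remediate_threshold >= 0,
            anxiety_threshold >= 1, anxiety_threshold <= 5,
            max_adaptations >= 0)
  structure(list(levels = as.integer(levels),
                 advance_threshold = advance_threshold,
                 remediate_threshold = remediate_threshold,
                 anxiety_threshold = anxiety_threshold,
                 max_adaptations = as.integer(max_adaptations),
                 forcing = list(base_I = base_I, role_bonus = role_bonus,
                                adapt_bonus = adapt_bonus,
                                peer_stress_relief = peer_stress_relief)),
            class = "agent_config")
}

#' Agent state
#'
#' @param difficulty Integer difficulty level in `[1, levels]`.
#' @param role One of `"tutor"`, `"peer_supporter"`, `"motivator"`.
#' @param adaptations Adaptations already applied this session (0-3).
#' @param levels Number of difficulty levels.
#' @return An object of class `agent_state`.
#' @export
agent_state <- function(difficulty = 3L, role = "tutor", adaptations = 0L,
                        levels = 5L) {
  role <- match.arg(role, .agent_roles)
  stopifnot(difficulty >= 1, difficulty <= levels, adaptations >= 0)
  structure(list(difficulty = as.integer(difficulty), role = role,
                 adaptations = as.integer(adaptations),
                 levels = as.integer(levels)),
            class = "agent_state")
}

#' Per-session observation
#'
#' @param quiz_accuracy Fraction correct in `[0, 1]`.
#' @param anxiety_slider Integer 1-5 self-report.
#' @return An object of class `session_observation`.
#' @export
session_observation <- function(quiz_accuracy, anxiety_slider) {
  stopifnot(quiz_accuracy >= 0, quiz_accuracy <= 1,
            anxiety_slider %in% 1:5)
  structure(list(quiz_accuracy = quiz_accuracy,
                 anxiety_slider = as.integer(anxiety_slider)),
            class = "session_observation")
}

#' Agent decision rule
#'
#' Pure function of the observation and state. Accuracy strictly above the
#' advance threshold raises difficulty by one; strictly below the remediate
#' threshold lowers it by one with remedial hints; otherwise difficulty is
#' unchanged. A slider strictly above the anxiety threshold switches the role
#' to `peer_supporter` when the student is also struggling (accuracy below
#' the remediate threshold) and to `motivator` (with a reward badge)
#' otherwise; a slider at or below the threshold selects `tutor`. When the
#' per-session adaptation cap has been reached the agent takes no action.
#' Boundary values (accuracy exactly at a threshold, slider exactly at the
#' anxiety threshold) are inert.
#'
#' @param obs A [session_observation()].
#' @param state An [agent_state()].
#' @param config An [agent_config()].
#' @return An `agent_action`: list with `difficulty_delta` (-1, 0, +1),
#'   `new_role`, `remedial_hints`, `reward_badge`.
#' @export
#' @examples
#' decide(session_observation(0.85, 2), agent_state(difficulty = 3))
decide <- function(obs, state, config = agent_config()) {
  if (state$adaptations >= config$max_adaptations) {
    return(structure(list(difficulty_delta = 0L, new_role = state$role,
                          remedial_hints = FALSE, reward_badge = FALSE),
                     class = "agent_action"))
  }
  acc <- obs$quiz_accuracy
  delta <- 0L
  hints <- FALSE
  if (acc > config$advance_threshold) {
    delta <- 1L
  } else if (acc < config$remediate_threshold) {
    delta <- -1L
    hints <- TRUE
  }
  badge <- FALSE
  if (obs$anxiety_slider > config$anxiety_threshold) {
    if (acc < config$remediate_threshold) {
      role <- "peer_supporter"
    } else {
      role <- "motivator"
      badge <- TRUE
    }
  } else {
    role <- "tutor"
  }
  structure(list(difficulty_delta = delta, new_role = role,
                 remedial_hints = hints, reward_badge = badge),
            class = "agent_action")
}

#' Apply an agent action to the state
#'
#' Clamps difficulty to `[1, levels]`. An adaptation is counted when the
#' action actually changes the state (an effective difficulty change or a
#' role change); a delta nullified by clamping does not count.
#'
#' @param state An [agent_state()].
#' @param action An action from [decide()].
#' @param config An [agent_config()].
#' @return The updated `agent_state`.
#' @export
apply_action <- function(state, action, config = agent_config()) {
  new_diff <- min(max(state$difficulty + action$difficulty_delta, 1L),
                  config$levels)
  changed <- (new_diff != state$difficulty) || (action$new_role != state$role)
  agent_state(difficulty = new_diff, role = action$new_role,
              adaptations = state$adaptations + as.integer(changed),
              levels = config$levels)
}

#' Map agent state to forcing levels
#'
#' The documented, configurable numeric link from the agent to the kinetic
#' model: intensity rises with non-tutor support roles and with the number of
#' within-session adaptations; stress scales with relative difficulty and is
#' relieved by the peer-supporter role. Both outputs are clamped to `[0, 1]`.
#'
#' @param state An [agent_state()]; if `action` is supplied it is applied
#'   first.
#' @param action Optional `agent_action` to apply before evaluating the map.
#' @param config An [agent_config()].
#' @return Named vector `c(I = , S = )`.
#' @export
#' @examples
#' session_forcing(agent_state(difficulty = 3, role = "tutor"))  # c(I = 0.5, S = 0.6)
session_forcing <- function(state, action = NULL, config = agent_config()) {
  eff <- if (is.null(action)) state else apply_action(state, action, config)
  fc <- config$forcing
  I <- fc$base_I + fc$role_bonus * (eff$role != "tutor") +
    fc$adapt_bonus * eff$adaptations
  S <- eff$difficulty / config$levels -
    fc$peer_stress_relief * (eff$role == "peer_supporter")
  c(I = min(max(I, 0), 1), S = min(max(S, 0), 1))
}
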