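#' Weighted up-down adaptive staircase
#'
#' Adaptive measurement of the relative rate-difference threshold
#' d = (rate_comparison - rate_standard) / rate_standard. A correct response
#' reduces d by the current step size; an incorrect response increases it by
#' three times that step, so the procedure converges on the level where
#' p(correct) = 3/4 (down-step x p = up-step x (1 - p)). When d is already at
#' or below one step size, a correct response halves d instead (d can never
#' reach 0). The initial 1% step is halved after 6 and again after 12
#' reversals; a run ends after 18 reversals and the threshold is the mean of
#' the last six reversal values.
#'
#' @name staircase
NULL

#' Staircase configuration
#'
#' @param start_value starting relative difference (> 0).
#' @param initial_step initial step size (default 0.01).
#' @param step_halving_reversals reversal counts at which the step is halved
#'   (default `c(6, 12)`).
#' @param up_weight incorrect-response step multiplier (default 3).
#' @param stop_reversals reversals ending the run (default 18).
#' @param n_threshold_reversals trailing reversals averaged into the
#'   threshold (default 6).
#' @param ceiling maximal allowed d; runaway staircases from degenerate
#'   observers are clipped here and the clip logged (default 0.5, the
#'   maximal expected threshold).
#' @export
staircase_config <- function(start_value = 0.20, initial_step = 0.01,
                             step_halving_reversals = c(6L, 12L),
                             up_weight = 3, stop_reversals = 18L,
                             n_threshold_reversals = 6L, ceiling = 0.5) {
  stopifnot(start_value > 0, initial_step > 0, up_weight >= 1,
            stop_reversals > n_threshold_reversals, ceiling > 0,
            all(diff(step_halving_reversals) > 0))
  structure(list(start_value = start_value, initial_step = initial_step,
                 step_halving_reversals = as.integer(step_halving_reversals),
                 up_weight = up_weight,
                 stop_reversals = as.integer(stop_reversals),
                 n_threshold_reversals = as.integer(n_threshold_reversals),
                 ceiling = ceiling),
            class = "staircase_config")
}

#' Start values across the standard-rate grid
#'
#' Linearly increasing from 20% to 27% across the 8 standard rates (1% steps),
#' all well above expected thresholds. Training-trial start values sit 10
#' percentage points higher (30-37%).
#'
#' @param grid a [rate_grid()] (or any length-8 grid).
#' @param training logical: return the training-trial values instead.
#' @return numeric vector of 8 start values.
#' @export
start_values <- function(grid = rate_grid(), training = FALSE) {
  n <- if (is.list(grid)) length(grid$rates) else length(grid)
  if (n != 8) stop("the start-value schedule is defined for an 8-rate grid")
  seq(0.20, 0.27, length.out = 8) + if (training) 0.10 else 0
}

#' Fresh staircase state
#' @param config a [staircase_config()].
#' @export
staircase_init <- function(config) {
  stopifnot(inherits(config, "staircase_config"))
  structure(list(current_d = config$start_value,
                 current_step = config$initial_step,
                 reversal_values = numeric(0),
                 last_direction = "none",
                 clipped = 0L,
                 trial_log = data.frame(trial = integer(0), d = numeric(0),
                                        step = numeric(0),
                                        response_correct = logical(0),
                                        direction = character(0),
                                        reversal = logical(0))),
            class = "staircase_state")
}

#' Has the staircase terminated?
#' @param state a staircase state.
#' @param config a [staircase_config()].
#' @export
staircase_complete <- function(state, config) {
  length(state$reversal_values) >= config$stop_reversals
}

#' Advance the staircase by one response
#'
#' Correct: d decreases by the current step, except when d <= step, in which
#' case d is halved. Incorrect: d increases by `up_weight` x step (clipped at
#' the ceiling). A reversal is recorded at the presented d whenever the
#' movement direction flips; the step size halves when the cumulative
#' reversal count reaches each entry of `step_halving_reversals`.
#'
#' @param state a staircase state (not complete).
#' @param config a [staircase_config()].
#' @param correct logical response.
#' @return the updated state.
#' @export
staircase_update <- function(state, config, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  if (staircase_complete(state, config))
    stop("staircase already complete: no further updates allowed")
  d <- state$current_d
  step <- state$current_step
  dir <- if (correct) "down" else "up"
  reversal <- state$last_direction != "none" && dir != state$last_direction
  state$trial_log <- rbind(state$trial_log, data.frame(
    trial = nrow(state$trial_log) + 1L, d = d, step = step,
    response_correct = correct, direction = dir, reversal = reversal))
  if (reversal) {
    state$reversal_values <- c(state$reversal_values, d)
    if (length(state$reversal_values) %in% config$step_halving_reversals)
      state$current_step <- step <- step / 2
  }
  # halving branch applies only when d <= one (current) step size
  new_d <- if (correct) {
    if (d <= step) d / 2 else d - step
  } else {
    d + config$up_weight * step
  }
  if (new_d > config$ceiling) {
    new_d <- config$ceiling
    state$clipped <- state$clipped + 1L
  }
  state$current_d <- new_d
  state$last_direction <- dir
  state
}

#' Threshold estimate from a completed staircase
#'
#' Arithmetic mean of the final `n_threshold_reversals` reversal values.
#'
#' @param state a completed staircase state.
#' @param config a [staircase_config()].
#' @param rate_hz optional standard rate for the report.
#' @return list of class `threshold_estimate` with `threshold`, `rate_hz`,
#'   `n_trials`, `reversal_values`.
#' @export
estimate_threshold <- function(state, config, rate_hz = NA_real_) {
  if (!staircase_complete(state, config))
    stop("staircase not complete: threshold undefined before ",
         config$stop_reversals, " reversals")
  k <- config$n_threshold_reversals
  rv <- utils::tail(state$reversal_values, k)
  structure(list(threshold = mean(rv), rate_hz = rate_hz,
                 n_trials = nrow(state$trial_log), reversal_values = rv),
            class = "threshold_estimate")
}

#' Run a full staircase against a simulated observer
#'
#' Repeatedly queries the observer at the current d (Bernoulli response from
#' its psychometric function) until 18 reversals are reached; deterministic
#' under the seed. A `max_trials` guard (default 2000) bounds pathological
#' response streams; the reversal logic itself terminates any non-degenerate
#' observer far earlier.
#'
#' @param observer an [make_observer()] object.
#' @param config a [staircase_config()].
#' @param seed integer seed.
#' @param rate_hz optional standard rate recorded in the estimate.
#' @param max_trials hard trial cap.
#' @return a `threshold_estimate` with the full `trial_log` and the final
#'   `state` attached.
#' @export
run_staircase <- function(observer, config = staircase_config(), seed = 1L,
                          rate_hz = NA_real_, max_trials = 2000L) {
  stopifnot(inherits(observer, "observer_model"))
  set.seed(seed)
  state <- staircase_init(config)
  while (!staircase_complete(state, config) &&
         nrow(state$trial_log) < max_trials) {
    p <- observer_p_correct(observer, state$current_d)
    state <- staircase_update(state, config, runif(1) < p)
  }
  if (!staircase_complete(state, config))
    stop("staircase did not complete within max_trials")
  est <- estimate_threshold(state, config, rate_hz)
  est$trial_log <- state$trial_log
  est$state <- state
  est
}
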