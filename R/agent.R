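#' Pause-and-go agent configuration
#'
#' Generative model of intermittent tethered-locust locomotion. Walking
#' bouts terminate at random with no memory (exponential durations, mean
#' `tau_w`); pause durations follow a bounded power law with survival
#' `S(t) = (t_min / (t + t_min))^(alpha - 1)` capped at `t_max`. Visual
#' evidence `E` about the stimulus direction is accumulated by a leaky
#' integrator whose input gain depends on the behavioural state —
#' `w_pause >= w_walk` embodies the hypothesis that visual information
#' is acquired mostly during pauses. Evidence against the heading
#' (`E < 0`) multiplies the pause hazard by `1 + beta * |E|` (shorter
#' pauses: the animal "hurries" to rejoin the swarm) and raises the
#' probability of starting a turning rather than a straight walking bout
#' through a logistic with gain `k_turn` and baseline bias `b_turn`.
#'
#' The default `w_walk = 0` means an in-phase stimulus (active only
#' while walking, up to detector latency) injects essentially no
#' evidence, mirroring the loss of direction-dependent differences in
#' that condition.
#'
#' @param tau_w mean walking-bout duration, s.
#' @param t_min,alpha,t_max pause-law scale (s), tail exponent (> 1) and
#'   hard cap (s).
#' @param v_walk forward speed while walking, cm/s.
#' @param turn_yaw_rate yaw rate during turning bouts, rad/s.
#' @param w_pause,w_walk evidence input weights (1/s) during pauses and
#'   walks; `w_pause >= w_walk >= 0`.
#' @param tau_e evidence decay time constant, s.
#' @param beta pause-shortening gain (dimensionless).
#' @param k_turn,b_turn logistic gain and bias of the turn decision made
#'   at each pause end; `b_turn = -2.944` gives a 5% baseline turn rate.
#' @param sigma additive Gaussian sensor noise per sample (cm).
#' @param sample_rate sensor sampling rate, Hz (equals the stimulus
#'   frame rate: single shared clock).
#' @return An object of class `pg_agent_config`.
#' @export
agent_config <- function(tau_w = 2,
                         t_min = 0.5, alpha = 1.8, t_max = 60,
                         v_walk = 3, turn_yaw_rate = 1,
                         w_pause = 1, w_walk = 0, tau_e = 3,
                         beta = 3, k_turn = 4, b_turn = -2.944,
                         sigma = 0.002, sample_rate = 120) {
  check_scalar(tau_w, "tau_w", positive = TRUE)
  check_scalar(t_min, "t_min", positive = TRUE)
  check_scalar(alpha, "alpha")
  if (alpha <= 1) config_error("'alpha' must be > 1")
  check_scalar(t_max, "t_max", positive = TRUE)
  if (t_max <= t_min) config_error("'t_max' must be > t_min")
  check_scalar(v_walk, "v_walk", positive = TRUE)
  check_scalar(turn_yaw_rate, "turn_yaw_rate", nonneg = TRUE)
  check_scalar(w_pause, "w_pause", nonneg = TRUE)
  check_scalar(w_walk, "w_walk", nonneg = TRUE)
  if (w_walk > w_pause) config_error("'w_pause' must be >= w_walk")
  check_scalar(tau_e, "tau_e", positive = TRUE)
  check_scalar(beta, "beta", nonneg = TRUE)
  check_scalar(k_turn, "k_turn")
  check_scalar(b_turn, "b_turn")
  check_scalar(sigma, "sigma", nonneg = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  structure(list(tau_w = tau_w, t_min = t_min, alpha = alpha, t_max = t_max,
                 v_walk = v_walk, turn_yaw_rate = turn_yaw_rate,
                 w_pause = w_pause, w_walk = w_walk, tau_e = tau_e,
                 beta = beta, k_turn = k_turn, b_turn = b_turn,
                 sigma = sigma, sample_rate = sample_rate),
            class = "pg_agent_config")
}

#' @export
print.pg_agent_config <- function(x, ...) {
  cat(sprintf(paste0(
    "pause-and-go agent: tau_w=%g s, pause law (t_min=%g, alpha=%g, ",
    "t_max=%g), v_walk=%g cm/s, w_pause=%g, w_walk=%g, tau_e=%g s, ",
    "beta=%g, sigma=%g cm @ %g Hz\n"),
    x$tau_w, x$t_min, x$alpha, x$t_max, x$v_walk, x$w_pause, x$w_walk,
    x$tau_e, x$beta, x$sigma, x$sample_rate))
  invisible(x)
}

#' Leaky evidence-integrator update
#'
#' One Euler step of `dE/dt = -E / tau_e + w(behaviour) * s * active`,
#' where `s = +1` for a `"FORWARD"` signal and `-1` for `"BACKWARD"`,
#' and `w` is `w_pause` during pauses, `w_walk` otherwise. The steady
#' state under a constantly active stimulus during an indefinite pause
#' is `s * w_pause * tau_e`.
#'
#' @param E current evidence.
#' @param stimulus_active logical: is the stimulus moving?
#' @param signal_direction `"FORWARD"` or `"BACKWARD"`.
#' @param behaviour `"PAUSE"`, `"WALK_FORWARD"` or `"WALK_TURN"`.
#' @param dt time step, s.
#' @param config an [agent_config()].
#' @return Updated evidence.
#' @export
update_evidence <- function(E, stimulus_active, signal_direction, behaviour,
                            dt, config = agent_config()) {
  if (dt <= 0) config_error("'dt' must be > 0")
  signal_direction <- match_enum(signal_direction, .pg_directions,
                                 "signal_direction")
  behaviour <- match_enum(behaviour, .pg_behaviours, "behaviour")
  s <- if (signal_direction == "FORWARD") 1 else -1
  w <- if (behaviour == "PAUSE") config$w_pause else config$w_walk
  E + dt * (-E / config$tau_e + w * s * as.numeric(stimulus_active))
}

#' Pause-termination hazard
#'
#' Baseline hazard `h0(t) = (alpha - 1) / (t + t_min)` for
#' `t < t_max` (infinite at the cap), which yields the bounded
#' power-law pause survival `S(t) = (t_min / (t + t_min))^(alpha - 1)`.
#' Evidence against the heading shortens pauses:
#' `h = h0 * (1 + beta * max(0, -E))`; evidence along the heading never
#' lengthens them.
#'
#' @param t time since pause onset, s (vectorised).
#' @param E current evidence (scalar).
#' @param config an [agent_config()].
#' @return Hazard, 1/s.
#' @export
pause_hazard <- function(t, E, config = agent_config()) {
  if (any(t < 0)) config_error("'t' must be >= 0")
  h0 <- ifelse(t >= config$t_max, Inf,
               (config$alpha - 1) / (t + config$t_min))
  h0 * (1 + config$beta * max(0, -E))
}

#' Sample baseline pause durations by exact inversion
#'
#' Draws from the pause-duration law implied by [pause_hazard()] at
#' constant evidence: survival
#' `S(t) = (t_min / (t + t_min))^((alpha - 1) * m)` with
#' `m = 1 + beta * max(0, -E)`, truncated at `t_max`. Inverse-CDF
#' sampling, so the draws follow the continuous law exactly.
#'
#' @param n number of draws.
#' @param config an [agent_config()].
#' @param E evidence held fixed over the pause (default 0: baseline).
#' @return Numeric vector of pause durations, s.
#' @export
sample_pause_duration <- function(n, config = agent_config(), E = 0) {
  m <- 1 + config$beta * max(0, -E)
  u <- runif(n)
  pmin(config$t_min * (u^(-1 / ((config$alpha - 1) * m)) - 1), config$t_max)
}

#' Expected pause duration and renewal walking fraction
#'
#' Closed-form mean of the capped baseline pause law,
#' `E[min(T, t_max)] = integral of S(t) over [0, t_max]`, and the
#' renewal-theory walking fraction `tau_w / (tau_w + E[pause])` expected
#' in the absence of any stimulus modulation.
#'
#' @param config an [agent_config()].
#' @return List with elements `mean_pause` (s) and `walking_fraction`.
#' @export
renewal_expectation <- function(config = agent_config()) {
  a <- config$alpha; tmin <- config$t_min; tmax <- config$t_max
  mean_pause <- if (abs(a - 2) < 1e-12) {
    tmin * log((tmax + tmin) / tmin)
  } else {
    tmin^(a - 1) * ((tmax + tmin)^(2 - a) - tmin^(2 - a)) / (2 - a)
  }
  list(mean_pause = mean_pause,
       walking_fraction = config$tau_w / (config$tau_w + mean_pause))
}

#' Decide the next bout at a pause end
#'
#' At every pause termination the agent makes a small directional
#' decision: start a turning bout with probability
#' `p_turn = plogis(k_turn * (-E) + b_turn)` (evidence against the
#' heading promotes turning), otherwise walk straight on. The walk-bout
#' duration is drawn from Exponential(mean `tau_w`). The turn direction
#' itself is a persistent per-subject trait (`turn_sign`), drawn once
#' per subject, not here.
#'
#' @param E evidence at the pause end.
#' @param config an [agent_config()].
#' @param turn_sign persistent turn direction, `+1` or `-1`.
#' @return List with `behaviour` (`"WALK_TURN"` or `"WALK_FORWARD"`),
#'   `duration` (s) and `turn_sign`.
#' @export
choose_bout_at_pause_end <- function(E, config = agent_config(),
                                     turn_sign = 1) {
  p_turn <- 1 / (1 + exp(-(config$k_turn * (-E) + config$b_turn)))
  behaviour <- if (runif(1) < p_turn) "WALK_TURN" else "WALK_FORWARD"
  duration <- rexp(1, rate = 1 / config$tau_w)
  list(behaviour = behaviour, duration = duration, turn_sign = turn_sign)
}

#' Initial agent state
#'
#' The agent starts paused (time-in-bout 0) with zero evidence and
#' heading 0. The persistent turn sign is drawn here (fair coin) unless
#' imposed.
#'
#' @param config an [agent_config()].
#' @param turn_sign `NULL` to draw, else `+1`/`-1`.
#' @return List of class `pg_agent_state`.
#' @export
init_agent_state <- function(config = agent_config(), turn_sign = NULL) {
  if (is.null(turn_sign)) turn_sign <- if (runif(1) < 0.5) -1 else 1
  structure(list(behaviour = "PAUSE", time_in_bout = 0,
                 walk_end = 0, evidence = 0, heading = 0,
                 turn_sign = turn_sign),
            class = "pg_agent_state")
}

#' Advance the agent by one sample
#'
#' One step of the discrete-time loop: (1) bout transition — a pause
#' terminates stochastically by thinning the [pause_hazard()]
#' (probability `min(1, h * dt)`, plus the hard cap at `t_max`), after
#' which [choose_bout_at_pause_end()] picks and schedules the next walk
#' bout; a walk bout ends at its scheduled duration and re-enters PAUSE.
#' (2) Emission — forward increment `v_walk * dt` during walk bouts, yaw
#' increment `turn_sign * turn_yaw_rate * dt` during turning bouts, each
#' channel (forward, yaw, lateral) plus Gaussian noise `sigma`.
#' (3) Evidence update via [update_evidence()]; the heading advances by
#' the noiseless yaw increment.
#'
#' This R implementation is the reference single-step semantics; whole
#' trials run the same loop natively (see [run_trial()]) with an
#' identical random-draw order, so the two agree sample-for-sample under
#' a shared seed.
#'
#' @param state a `pg_agent_state`.
#' @param stimulus_active logical: stimulus moving this sample.
#' @param signal_direction `"FORWARD"` or `"BACKWARD"`.
#' @param config an [agent_config()].
#' @param dt time step, s; must equal `1 / sample_rate`.
#' @return List with `state` (updated) and `sample` (named numeric:
#'   `d_forward_cm`, `d_yaw_rad`, `d_lateral_cm`) plus the noiseless
#'   `behaviour` label.
#' @export
step_agent <- function(state, stimulus_active, signal_direction,
                       config = agent_config(), dt = 1 / config$sample_rate) {
  if (abs(dt - 1 / config$sample_rate) > 1e-12)
    config_error("'dt' must equal 1 / sample_rate")
  if (state$behaviour == "PAUSE") {
    term <- if (state$time_in_bout >= config$t_max - 1e-12) TRUE else {
      h <- pause_hazard(state$time_in_bout, state$evidence, config)
      runif(1) < min(1, h * dt)
    }
    if (term) {
      ch <- choose_bout_at_pause_end(state$evidence, config, state$turn_sign)
      state$behaviour <- ch$behaviour
      state$walk_end <- ch$duration
      state$time_in_bout <- 0
    }
  } else if (state$time_in_bout >= state$walk_end - 1e-12) {
    state$behaviour <- "PAUSE"
    state$time_in_bout <- 0
  }

  f0 <- if (state$behaviour != "PAUSE") config$v_walk * dt else 0
  y0 <- if (state$behaviour == "WALK_TURN")
    state$turn_sign * config$turn_yaw_rate * dt else 0
  nz <- rnorm(3)
  smp <- c(d_forward_cm = f0 + config$sigma * nz[1],
           d_yaw_rad    = y0 + config$sigma * nz[2],
           d_lateral_cm = 0  + config$sigma * nz[3])

  state$evidence <- update_evidence(state$evidence, stimulus_active,
                                    signal_direction, state$behaviour,
                                    dt, config)
  state$heading <- state$heading + y0
  state$time_in_bout <- state$time_in_bout + dt
  list(state = state, sample = smp, behaviour = state$behaviour)
}

#' Run one closed-loop virtual trial
#'
#' Couples the agent, the motion detector, the gate and the stimulus at
#' a single shared clock (`sample_rate == frame_rate`): the sensor
#' sample at `t` feeds the detector, whose gated output drives the
#' stimulus frame at `t + 1` (one-sample latency). Returns the aligned
#' trackball trace (with noiseless ground-truth labels), the gate log,
#' and optionally the full stimulus frame log. Deterministic given
#' `seed`.
#'
#' @param agent an [agent_config()].
#' @param stimulus a [stimulus_config()]; its `frame_rate` must equal
#'   the agent's `sample_rate`.
#' @param mode gating mode (see [gate()]).
#' @param detector a [motion_detector_config()].
#' @param duration trial duration, s.
#' @param seed integer seed.
#' @param turn_sign `NULL` (draw per trial) or `+1`/`-1` (persistent
#'   per-subject trait in within-subject designs).
#' @param record_frames logical: also materialise the dot-field frame
#'   log (large; off by default).
#' @return Object of class `pg_trial`: list with `trace` (a
#'   `pg_trace` data frame: `t_s`, `d_forward_cm`, `d_yaw_rad`,
#'   `d_lateral_cm`, `true_behaviour`, `stimulus_active`, `evidence`),
#'   `gate_log`, `frames` (or `NULL`), `mode`, `direction`, `seed`,
#'   `turn_sign` and the three configs.
#' @examples
#' tr <- run_trial(duration = 10, seed = 1, mode = "OUT_OF_PHASE")
#' head(tr$trace)
#' @export
run_trial <- function(agent = agent_config(),
                      stimulus = stimulus_config(),
                      mode = c("OPEN_LOOP", "IN_PHASE", "OUT_OF_PHASE"),
                      detector = motion_detector_config(),
                      duration = 300, seed = 1L,
                      turn_sign = NULL, record_frames = FALSE) {
  mode <- match.arg(mode)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(seed, "seed", integerish = TRUE)
  if (abs(agent$sample_rate - stimulus$frame_rate) > 1e-9)
    config_error("agent sample_rate (%g) must equal stimulus frame_rate (%g)",
                 agent$sample_rate, stimulus$frame_rate)
  if (abs(detector$sample_rate - agent$sample_rate) > 1e-9)
    config_error("detector sample_rate (%g) must equal agent sample_rate (%g)",
                 detector$sample_rate, agent$sample_rate)
  n <- round(duration * agent$sample_rate)
  if (n < 1L) config_error("'duration' shorter than one sample")
  s <- if (stimulus$signal_direction == "FORWARD") 1 else -1
  mode_code <- match(mode, .pg_modes) - 1L

  set.seed(as.integer(seed))
  raw <- agent_trial_cpp(unclass(agent), as.integer(n), mode_code, s,
                         detector$threshold, detector$debounce_on,
                         detector$debounce_off,
                         if (is.null(turn_sign)) 0 else turn_sign)

  trace <- data.frame(t_s = seq_len(n) / agent$sample_rate,
                      d_forward_cm = raw$d_forward_cm,
                      d_yaw_rad = raw$d_yaw_rad,
                      d_lateral_cm = raw$d_lateral_cm,
                      true_behaviour = .pg_behaviours[raw$behaviour + 1L],
                      stimulus_active = raw$stimulus_active,
                      evidence = raw$evidence)
  attr(trace, "sample_rate") <- agent$sample_rate
  class(trace) <- c("pg_trace", "data.frame")

  gate_log <- data.frame(sample_index = seq_len(n),
                         displacement = raw$magnitude,
                         moving = raw$moving,
                         mode = mode,
                         active = raw$stimulus_active)

  frames <- NULL
  if (record_frames) {
    frames <- simulate_frames(stimulus, active = raw$stimulus_active,
                              seed = if (is.null(stimulus$seed))
                                derive_seed(seed, "stimulus") else NULL)
  }

  structure(list(trace = trace, gate_log = gate_log, frames = frames,
                 mode = mode, direction = stimulus$signal_direction,
                 seed = as.integer(seed), turn_sign = raw$turn_sign,
                 agent = agent, stimulus = stimulus, detector = detector,
                 duration = n / agent$sample_rate),
            class = "pg_trial")
}

#' @export
print.pg_trial <- function(x, ...) {
  wf <- mean(x$trace$true_behaviour != "PAUSE")
  cat(sprintf(
    "virtual trial: %s / %s, %.0f s @ %g Hz, seed %d (true walking fraction %.2f)\n",
    x$mode, x$direction, x$duration, x$agent$sample_rate, x$seed, wf))
  invisible(x)
}

#' Write / read a trackball trace as CSV
#'
#' Round-trips the per-sample trace including ground-truth labels. The
#' sample rate is recovered from the time column.
#'
#' @param trace a `pg_trace`.
#' @param path file path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns a `pg_trace`.
#' @export
write_trace <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("t_s", "d_forward_cm", "d_yaw_rad", "d_lateral_cm")
  if (!all(need %in% names(df)))
    config_error("trace file lacks required columns: %s",
                 paste(setdiff(need, names(df)), collapse = ", "))
  attr(df, "sample_rate") <- 1 / stats::median(diff(df$t_s))
  class(df) <- c("pg_trace", "data.frame")
  df
}
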