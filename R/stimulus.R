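#' Random-dot kinematogram configuration
#'
#' Parameters of the two-screen RDK used as the visual stimulus: a field
#' of dots of which a `coherence` fraction (the SIGNAL dots) drift
#' coherently along the screen axis aligned with the tethered animal's
#' heading, while the remainder (NOISE dots) drift at fixed random
#' per-dot directions. Defaults follow the experimental stimulus: 100%
#' coherence, 5 cm/s dot speed, 120 frames/s. Screen geometry and dot
#' count are not constrained by the kinematics and default to a 30 x 20
#' cm screen with 50 dots.
#'
#' @param n_dots_per_screen dots per screen (>= 1).
#' @param dot_speed drift speed of every dot, cm/s.
#' @param coherence fraction of SIGNAL dots in `[0, 1]`.
#' @param frame_rate display refresh rate, frames/s.
#' @param screen_width,screen_height screen size, cm.
#' @param signal_direction `"FORWARD"` (SIGNAL dots move along the
#'   heading, +x) or `"BACKWARD"`.
#' @param seed integer seed for dot placement, or `NULL` to let the
#'   caller derive one.
#' @return An object of class `pg_stimulus_config`.
#' @examples
#' stimulus_config(coherence = 1, dot_speed = 5, frame_rate = 120)
#' @export
stimulus_config <- function(n_dots_per_screen = 50L,
                            dot_speed = 5,
                            coherence = 1,
                            frame_rate = 120,
                            screen_width = 30,
                            screen_height = 20,
                            signal_direction = c("FORWARD", "BACKWARD"),
                            seed = NULL) {
  signal_direction <- match.arg(signal_direction)
  check_scalar(n_dots_per_screen, "n_dots_per_screen", positive = TRUE,
               integerish = TRUE)
  check_scalar(dot_speed, "dot_speed", positive = TRUE)
  check_scalar(coherence, "coherence", nonneg = TRUE)
  if (coherence > 1) config_error("'coherence' must lie in [0, 1]")
  check_scalar(frame_rate, "frame_rate", positive = TRUE)
  check_scalar(screen_width, "screen_width", positive = TRUE)
  check_scalar(screen_height, "screen_height", positive = TRUE)
  if (!is.null(seed)) check_scalar(seed, "seed", integerish = TRUE)
  structure(list(n_dots_per_screen = as.integer(n_dots_per_screen),
                 dot_speed = dot_speed, coherence = coherence,
                 frame_rate = frame_rate, screen_width = screen_width,
                 screen_height = screen_height,
                 signal_direction = signal_direction,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "pg_stimulus_config")
}

#' @export
print.pg_stimulus_config <- function(x, ...) {
  cat(sprintf(
    "RDK stimulus: %d dots/screen, %.3g cm/s, coherence %.0f%%, %g fps, %s\n",
    x$n_dots_per_screen, x$dot_speed, 100 * x$coherence, x$frame_rate,
    x$signal_direction))
  invisible(x)
}

init_screen <- function(config, seed) {
  set.seed(seed)
  n <- config$n_dots_per_screen
  n_signal <- round_half_up(config$coherence * n)
  role <- rep(c("SIGNAL", "NOISE"), c(n_signal, n - n_signal))
  list(x = runif(n, 0, config$screen_width),
       y = runif(n, 0, config$screen_height),
       role = role,
       # fixed per-dot drift direction for NOISE dots (rad); SIGNAL dots
       # drift along +/- x per signal_direction and ignore this angle
       noise_angle = runif(n, 0, 2 * pi))
}

#' Initialise the two-screen dot field
#'
#' Places dots uniformly at random on each screen, independently per
#' screen (distinct sub-seeds derived from the config seed), and assigns
#' SIGNAL/NOISE roles so that the SIGNAL count is
#' `round(coherence * n_dots)` (half-up).
#'
#' @param config a [stimulus_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return An object of class `pg_dot_field`: per-screen dot positions,
#'   roles and noise directions, plus a `frame_index` counter starting
#'   at 0.
#' @examples
#' f <- init_dot_field(stimulus_config(seed = 1))
#' table(f$screens$left$role)
#' @export
init_dot_field <- function(config, seed = NULL) {
  if (!inherits(config, "pg_stimulus_config"))
    config_error("'config' must be a pg_stimulus_config")
  seed <- if (!is.null(seed)) as.integer(seed) else config$seed
  if (is.null(seed))
    config_error("no 'seed' available: set it in the config or pass one")
  screens <- list(left  = init_screen(config, derive_seed(seed, "screen", "left")),
                  right = init_screen(config, derive_seed(seed, "screen", "right")))
  structure(list(screens = screens, frame_index = 0L, seed = seed),
            class = "pg_dot_field")
}

#' Advance the dot field by one frame
#'
#' If `active`, SIGNAL dots are displaced by `dot_speed / frame_rate`
#' along the screen's heading axis (+x for `"FORWARD"`, -x for
#' `"BACKWARD"`) and NOISE dots by the same distance along their own
#' fixed random directions, with toroidal wrapping. If not `active`
#' (stimulus frozen), positions are unchanged. The frame counter always
#' advances.
#'
#' @param field a `pg_dot_field`.
#' @param config the [stimulus_config()] the field was built from.
#' @param active logical: does the stimulus move this frame?
#' @return The updated `pg_dot_field`.
#' @export
step_dots <- function(field, config, active) {
  if (!inherits(field, "pg_dot_field"))
    config_error("'field' must be a pg_dot_field")
  stopifnot(is.logical(active), length(active) == 1L, !is.na(active))
  if (active) {
    d <- config$dot_speed / config$frame_rate
    sgn <- if (config$signal_direction == "FORWARD") 1 else -1
    for (s in names(field$screens)) {
      sc <- field$screens[[s]]
      sig <- sc$role == "SIGNAL"
      dx <- ifelse(sig, sgn * d, d * cos(sc$noise_angle))
      dy <- ifelse(sig, 0,       d * sin(sc$noise_angle))
      sc$x <- (sc$x + dx) %% config$screen_width
      sc$y <- (sc$y + dy) %% config$screen_height
      field$screens[[s]] <- sc
    }
  }
  field$frame_index <- field$frame_index + 1L
  field
}

#' Simulate a whole frame log for a sequence of active flags
#'
#' Equivalent to repeated [step_dots()] starting from `field` (or a
#' fresh [init_dot_field()]), but computed in closed form from the
#' cumulative count of active frames. Returns the standard frame log.
#'
#' @param config a [stimulus_config()].
#' @param active logical vector of per-frame active flags.
#' @param field optional starting `pg_dot_field`.
#' @param seed used if `field` is `NULL` and the config has no seed.
#' @return A `data.frame` with columns `frame_index`, `screen`,
#'   `dot_id`, `role`, `x_cm`, `y_cm`, `active`; frame 0 is the initial
#'   placement (active is `NA` there).
#' @export
simulate_frames <- function(config, active, field = NULL, seed = NULL) {
  stopifnot(is.logical(active), !anyNA(active))
  if (is.null(field)) field <- init_dot_field(config, seed = seed)
  d <- config$dot_speed / config$frame_rate
  sgn <- if (config$signal_direction == "FORWARD") 1 else -1
  n_active <- c(0, cumsum(active))          # frames 0..length(active)
  frames <- seq_along(n_active) - 1L + field$frame_index
  out <- vector("list", 2L)
  for (k in seq_along(field$screens)) {
    sc <- field$screens[[k]]
    sig <- sc$role == "SIGNAL"
    ux <- ifelse(sig, sgn, cos(sc$noise_angle))
    uy <- ifelse(sig, 0,   sin(sc$noise_angle))
    nd <- length(sc$x)
    # outer(): dot x frame displacement counts
    x <- (sc$x + d * outer(ux, n_active)) %% config$screen_width
    y <- (sc$y + d * outer(uy, n_active)) %% config$screen_height
    out[[k]] <- data.frame(
      frame_index = rep(frames, each = nd),
      screen = names(field$screens)[k],
      dot_id = rep(seq_len(nd), times = length(frames)),
      role = rep(sc$role, times = length(frames)),
      x_cm = as.vector(x), y_cm = as.vector(y),
      active = rep(c(NA, active), each = nd))
  }
  rbind(out[[1L]], out[[2L]])
}

#' Measure realised dot speed from a frame log
#'
#' Mean per-frame displacement of dots between consecutive frames,
#' multiplied by the frame rate, over dot-frame pairs that did not wrap
#' around the screen edge (displacement larger than half the screen in
#' either axis). A fully frozen log yields 0; frames logged while the
#' stimulus ran at the configured speed yield that speed.
#'
#' @param frame_log a frame log from [simulate_frames()] (or the same
#'   columns logged via [step_dots()]).
#' @param config the matching [stimulus_config()].
#' @return Realised mean dot speed, cm/s.
#' @export
measure_field_speed <- function(frame_log, config) {
  frames <- sort(unique(frame_log$frame_index))
  if (length(frames) < 2L)
    insufficient_data_error("need at least 2 frames to measure speed")
  o <- order(frame_log$screen, frame_log$dot_id, frame_log$frame_index)
  fl <- frame_log[o, ]
  same_dot <- diff(fl$frame_index) == 1L &
    fl$screen[-1L] == fl$screen[-nrow(fl)] &
    fl$dot_id[-1L] == fl$dot_id[-nrow(fl)]
  dx <- diff(fl$x_cm)[same_dot]
  dy <- diff(fl$y_cm)[same_dot]
  wrapped <- abs(dx) > config$screen_width / 2 |
    abs(dy) > config$screen_height / 2
  mean(sqrt(dx[!wrapped]^2 + dy[!wrapped]^2)) * config$frame_rate
}

#' Write a frame log to CSV
#' @param frame_log frame log data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_frame_log <- function(frame_log, path) {
  write.csv(frame_log, path, row.names = FALSE)
  invisible(path)
}
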