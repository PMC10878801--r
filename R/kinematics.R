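#' Reconstruct the fictive 2D path from a trackball trace
#'
#' Dead-reckons the path the tethered animal "would have" walked by
#' integrating per-sample rotation increments (already arc lengths in
#' cm, so sphere radius never enters): the heading advances by the yaw
#' increment, then the position by the forward/lateral increments
#' rotated into the world frame. The frame is fixed to the initial
#' heading along +x; the path starts at the origin and has one more row
#' than the trace.
#'
#' @param trace a `pg_trace` (or any data frame with `d_forward_cm`,
#'   `d_yaw_rad`, `d_lateral_cm` and `t_s`).
#' @return Object of class `pg_path`: data frame with `t_s`, `x_cm`,
#'   `y_cm`, `heading_rad`.
#' @examples
#' tr <- run_trial(duration = 5, seed = 1)
#' path <- integrate_path(tr$trace)
#' @export
integrate_path <- function(trace) {
  if (is.null(nrow(trace)) || nrow(trace) == 0L)
    insufficient_data_error("empty trace")
  phi <- cumsum(trace$d_yaw_rad)       # heading after each sample's yaw
  dx <- trace$d_forward_cm * cos(phi) - trace$d_lateral_cm * sin(phi)
  dy <- trace$d_forward_cm * sin(phi) + trace$d_lateral_cm * cos(phi)
  out <- data.frame(t_s = c(0, trace$t_s),
                    x_cm = c(0, cumsum(dx)),
                    y_cm = c(0, cumsum(dy)),
                    heading_rad = c(0, phi))
  class(out) <- c("pg_path", "data.frame")
  out
}

#' Bout-segmentation configuration
#'
#' @param window centred moving-average smoothing window for the speed
#'   signal, s.
#' @param speed_threshold walk/pause speed threshold, cm/s (default 10%
#'   of the default agent walking speed).
#' @param min_bout minimum bout duration, s; shorter interior bouts are
#'   merged into their neighbours.
#' @return An object of class `pg_segmentation_config`.
#' @export
segmentation_config <- function(window = 0.25, speed_threshold = 0.3,
                                min_bout = 0.3) {
  check_scalar(window, "window", positive = TRUE)
  check_scalar(speed_threshold, "speed_threshold", positive = TRUE)
  check_scalar(min_bout, "min_bout", positive = TRUE)
  structure(list(window = window, speed_threshold = speed_threshold,
                 min_bout = min_bout),
            class = "pg_segmentation_config")
}

# centred moving average with shrinking (partial) windows at the edges
centred_mean <- function(x, half) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

runs_to_bouts <- function(kind, dt) {
  r <- rle(kind)
  ends <- cumsum(r$lengths)
  data.frame(kind = r$values,
             start_s = (ends - r$lengths) * dt,
             duration_s = r$lengths * dt)
}

# merge interior bouts shorter than min_bout, shortest first (ties:
# earliest); flipping an interior bout's kind coalesces it with both
# neighbours. First and last bouts are exempt.
merge_short_bouts <- function(bouts, min_bout) {
  repeat {
    n <- nrow(bouts)
    if (n <= 2L) return(bouts)
    interior <- seq_len(n)[-c(1L, n)]
    short <- interior[bouts$duration_s[interior] < min_bout - 1e-9]
    if (length(short) == 0L) return(bouts)
    i <- short[which.min(bouts$duration_s[short])]
    # absorb bout i and its successor into bout i - 1
    bouts$duration_s[i - 1L] <- bouts$duration_s[i - 1L] +
      bouts$duration_s[i] + bouts$duration_s[i + 1L]
    bouts <- bouts[-c(i, i + 1L), , drop = FALSE]
    rownames(bouts) <- NULL
  }
}

#' Segment a trace into alternating walk and pause bouts
#'
#' Smoothed instantaneous speed is computed by centred moving averaging
#' of the forward and lateral displacement components and taking the
#' magnitude of the averaged vector times the sample rate (averaging
#' the components first cancels zero-mean sensor noise; rectifying to a
#' magnitude before smoothing would turn that noise into a standing
#' positive speed bias of `sigma * rate * sqrt(pi / 2)` during pauses).
#' Samples above the threshold are WALK, the rest PAUSE. Interior bouts
#' shorter than the minimum duration are merged into their neighbours
#' (shortest first), so the output is a contiguous, strictly
#' alternating cover of the trial.
#'
#' @param trace a `pg_trace` (needs a `sample_rate` attribute or
#'   regular `t_s`).
#' @param config a [segmentation_config()].
#' @return Object of class `pg_bouts`: data frame with `kind`
#'   (`"WALK"`/`"PAUSE"`), `start_s`, `duration_s`.
#' @export
segment_bouts <- function(trace, config = segmentation_config()) {
  rate <- attr(trace, "sample_rate")
  if (is.null(rate)) rate <- 1 / stats::median(diff(trace$t_s))
  n <- nrow(trace)
  w <- max(1L, round(config$window * rate))
  if (n <= w)
    insufficient_data_error(
      "trace (%d samples) not longer than smoothing window (%d samples)", n, w)
  half <- w %/% 2L
  sf <- centred_mean(trace$d_forward_cm, half)
  sl <- centred_mean(trace$d_lateral_cm, half)
  smooth <- sqrt(sf^2 + sl^2) * rate
  kind <- ifelse(smooth > config$speed_threshold, "WALK", "PAUSE")
  bouts <- merge_short_bouts(runs_to_bouts(kind, 1 / rate), config$min_bout)
  class(bouts) <- c("pg_bouts", "data.frame")
  bouts
}

#' Summarise trial kinematics
#'
#' The four headline intermittency/path metrics plus path straightness:
#' walking fraction (summed WALK durations over trial time), mean pause
#' duration (0 with `no_pause = TRUE` if the animal never pauses), total
#' distance (summed per-sample translational displacement magnitudes),
#' total side motion (summed `|dy|` in the tether frame, i.e. lateral
#' progress perpendicular to the initial heading), and straightness (net
#' displacement over total distance).
#'
#' @param path a `pg_path` from [integrate_path()].
#' @param bouts a `pg_bouts` from [segment_bouts()].
#' @param trace the originating `pg_trace`.
#' @return Object of class `pg_summary`: one-row data frame with
#'   `walking_fraction`, `mean_pause_duration`, `total_distance`,
#'   `total_side_motion`, `straightness`, `no_pause`.
#' @export
summarize_kinematics <- function(path, bouts, trace) {
  if (nrow(path) != nrow(trace) + 1L)
    config_error("path (%d) and trace (%d) lengths are inconsistent",
                 nrow(path), nrow(trace))
  total_t <- sum(bouts$duration_s)
  walk_t <- sum(bouts$duration_s[bouts$kind == "WALK"])
  pauses <- bouts$duration_s[bouts$kind == "PAUSE"]
  no_pause <- length(pauses) == 0L
  step_len <- sqrt(trace$d_forward_cm^2 + trace$d_lateral_cm^2)
  total_distance <- sum(step_len)
  net <- sqrt(path$x_cm[nrow(path)]^2 + path$y_cm[nrow(path)]^2)
  out <- data.frame(
    walking_fraction = walk_t / total_t,
    mean_pause_duration = if (no_pause) 0 else mean(pauses),
    total_distance = total_distance,
    total_side_motion = sum(abs(diff(path$y_cm))),
    straightness = if (total_distance > 0) net / total_distance else 1,
    no_pause = no_pause)
  class(out) <- c("pg_summary", "data.frame")
  out
}

#' Full kinematic analysis of one trace
#'
#' Convenience wrapper: [integrate_path()], [segment_bouts()],
#' [summarize_kinematics()].
#'
#' @param trace a `pg_trace`.
#' @param config a [segmentation_config()].
#' @return List with `path`, `bouts`, `summary`.
#' @export
analyze_trace <- function(trace, config = segmentation_config()) {
  path <- integrate_path(trace)
  bouts <- segment_bouts(trace, config)
  list(path = path, bouts = bouts,
       summary = summarize_kinematics(path, bouts, trace))
}

#' Write kinematics artifacts to CSV
#' @param path a `pg_path`; `bouts` a `pg_bouts`; `summary` one or more
#'   `pg_summary` rows.
#' @param file output file path.
#' @return `file`, invisibly.
#' @export
write_path <- function(path, file) {
  write.csv(as.data.frame(path), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_path
#' @param bouts a `pg_bouts`.
#' @export
write_bouts <- function(bouts, file) {
  write.csv(as.data.frame(bouts), file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_path
#' @param summary a `pg_summary` (or stacked rows).
#' @export
write_summary <- function(summary, file) {
  write.csv(as.data.frame(summary), file, row.names = FALSE)
  invisible(file)
}

#' Plot the fictive path of a trial
#'
#' @param x a `pg_trial`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.pg_trial <- function(x, ...) {
  p <- integrate_path(x$trace)
  graphics::plot(p$x_cm, p$y_cm, type = "l", asp = 1,
                 xlab = "x (cm, initial heading)", ylab = "y (cm)",
                 main = sprintf("fictive path: %s / %s", x$mode, x$direction),
                 ...)
  graphics::points(0, 0, pch = 16)
  invisible(x)
}
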