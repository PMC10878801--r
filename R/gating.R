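#' Motion-detector configuration (threshold + debounce)
#'
#' Models the rig's displacement-sensor thresholding: the controller
#' declares the animal MOVING after `debounce_on` consecutive samples
#' with displacement magnitude above `threshold`, and NOT_MOVING again
#' after `debounce_off` consecutive samples at or below it. The debounce
#' run-lengths suppress single-sample sensor glitches.
#'
#' @param threshold displacement per sample (cm) separating movement
#'   from sensor noise.
#' @param debounce_on,debounce_off consecutive samples required to enter
#'   / leave the MOVING state (>= 1).
#' @param sample_rate sensor sampling rate, Hz.
#' @return An object of class `pg_detector_config`.
#' @export
motion_detector_config <- function(threshold = 0.01,
                                   debounce_on = 5L,
                                   debounce_off = 5L,
                                   sample_rate = 120) {
  check_scalar(threshold, "threshold", nonneg = TRUE)
  check_scalar(debounce_on, "debounce_on", positive = TRUE, integerish = TRUE)
  check_scalar(debounce_off, "debounce_off", positive = TRUE, integerish = TRUE)
  check_scalar(sample_rate, "sample_rate", positive = TRUE)
  structure(list(threshold = threshold,
                 debounce_on = as.integer(debounce_on),
                 debounce_off = as.integer(debounce_off),
                 sample_rate = sample_rate),
            class = "pg_detector_config")
}

#' Detect the motion state from a displacement stream
#'
#' Causal hysteresis automaton over per-sample displacement magnitudes.
#' The automaton starts in NOT_MOVING (a trial begins before locomotion
#' is confirmed); the output at sample `t` uses only samples `1..t`, so
#' truncating the input truncates the output without changing the
#' shared prefix.
#'
#' @param displacements numeric vector of non-negative per-sample
#'   displacement magnitudes (cm).
#' @param config a [motion_detector_config()].
#' @return Logical vector of per-sample MOVING flags, same length as the
#'   input.
#' @examples
#' detect_motion(rep(0.05, 8), motion_detector_config(debounce_on = 3))
#' @export
detect_motion <- function(displacements, config = motion_detector_config()) {
  if (length(displacements) == 0L)
    insufficient_data_error("empty displacement stream")
  if (any(!is.finite(displacements)) || any(displacements < 0))
    config_error("'displacements' must be finite and >= 0")
  n <- length(displacements)
  moving <- logical(n)
  state <- FALSE
  cnt_on <- 0L; cnt_off <- 0L
  supra <- displacements > config$threshold
  for (t in seq_len(n)) {
    if (supra[t]) { cnt_on <- cnt_on + 1L; cnt_off <- 0L }
    else          { cnt_off <- cnt_off + 1L; cnt_on <- 0L }
    if (!state && cnt_on >= config$debounce_on) state <- TRUE
    else if (state && cnt_off >= config$debounce_off) state <- FALSE
    moving[t] <- state
  }
  moving
}

#' Gate stimulus activity on the detected motion state
#'
#' The experimental-condition truth table: `OPEN_LOOP` stimuli always
#' move; `IN_PHASE` stimuli move while the animal moves and freeze while
#' it pauses; `OUT_OF_PHASE` stimuli freeze while it moves and move
#' while it pauses. `IN_PHASE` and `OUT_OF_PHASE` are exact per-sample
#' complements for any motion stream.
#'
#' @param mode one of `"OPEN_LOOP"`, `"IN_PHASE"`, `"OUT_OF_PHASE"`.
#' @param moving logical vector of detected motion states.
#' @return Logical vector of stimulus-active flags, same length as
#'   `moving`.
#' @examples
#' gate("OUT_OF_PHASE", c(TRUE, FALSE))
#' @export
gate <- function(mode, moving) {
  mode <- match_enum(mode, .pg_modes, "mode")
  stopifnot(is.logical(moving), !anyNA(moving))
  switch(mode,
         OPEN_LOOP    = rep(TRUE, length(moving)),
         IN_PHASE     = moving,
         OUT_OF_PHASE = !moving)
}

#' Write a gate log to CSV
#' @param gate_log data frame with columns `sample_index`,
#'   `displacement`, `moving`, `mode`, `active`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gate_log <- function(gate_log, path) {
  write.csv(gate_log, path, row.names = FALSE)
  invisible(path)
}
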