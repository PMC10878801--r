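#' Experiment configuration
#'
#' Describes a full virtual experiment: which gating conditions and
#' stimulus directions to cross, how many subjects per cell, and whether
#' distinct subjects fill each cell (`"BETWEEN_SUBJECT"`, the default
#' design) or every subject experiences every cell in seeded random
#' order (`"WITHIN_SUBJECT"`).
#'
#' @param agent an [agent_config()].
#' @param stimulus a [stimulus_config()]; its `signal_direction` is
#'   overridden per cell.
#' @param detector a [motion_detector_config()].
#' @param segmentation a [segmentation_config()].
#' @param conditions subset of `"OPEN_LOOP"`, `"IN_PHASE"`,
#'   `"OUT_OF_PHASE"`.
#' @param directions subset of `"FORWARD"`, `"BACKWARD"`.
#' @param n_subjects subjects per cell (between) or in total (within).
#' @param protocol `"BETWEEN_SUBJECT"` or `"WITHIN_SUBJECT"`.
#' @param duration trial duration, s.
#' @param master_seed integer; every trial seed is derived from it.
#' @param output_dir directory for CSV/JSON artifacts, or `NULL` to
#'   keep everything in memory.
#' @param save_traces logical: also write per-sample trace/path/bout
#'   CSVs for every trial (large; the manifest makes traces exactly
#'   regenerable from seeds either way).
#' @return Object of class `pg_experiment_config`.
#' @export
experiment_config <- function(agent = agent_config(),
                              stimulus = stimulus_config(),
                              detector = motion_detector_config(),
                              segmentation = segmentation_config(),
                              conditions = .pg_modes,
                              directions = .pg_directions,
                              n_subjects = 15L,
                              protocol = c("BETWEEN_SUBJECT", "WITHIN_SUBJECT"),
                              duration = 300,
                              master_seed = 1L,
                              output_dir = NULL,
                              save_traces = FALSE) {
  protocol <- match.arg(protocol)
  if (length(conditions) == 0L || !all(conditions %in% .pg_modes))
    config_error("'conditions' must be a non-empty subset of %s",
                 paste(.pg_modes, collapse = ", "))
  if (length(directions) == 0L || !all(directions %in% .pg_directions))
    config_error("'directions' must be a non-empty subset of %s",
                 paste(.pg_directions, collapse = ", "))
  check_scalar(n_subjects, "n_subjects", positive = TRUE, integerish = TRUE)
  check_scalar(duration, "duration", positive = TRUE)
  check_scalar(master_seed, "master_seed", integerish = TRUE)
  structure(list(agent = agent, stimulus = stimulus, detector = detector,
                 segmentation = segmentation,
                 conditions = conditions, directions = directions,
                 n_subjects = as.integer(n_subjects), protocol = protocol,
                 duration = duration, master_seed = as.integer(master_seed),
                 output_dir = output_dir, save_traces = isTRUE(save_traces)),
            class = "pg_experiment_config")
}

set_direction <- function(stimulus, direction) {
  stimulus$signal_direction <- direction
  stimulus
}

run_one_cell_trial <- function(config, subject, condition, direction,
                               turn_sign = NULL) {
  seed <- derive_seed(config$master_seed, subject, condition, direction)
  trial <- run_trial(agent = config$agent,
                     stimulus = set_direction(config$stimulus, direction),
                     mode = condition, detector = config$detector,
                     duration = config$duration, seed = seed,
                     turn_sign = turn_sign)
  res <- analyze_trace(trial$trace, config$segmentation)
  list(trial = trial, analysis = res, seed = seed)
}

write_trial_artifacts <- function(config, trial, analysis, tag) {
  dir <- file.path(config$output_dir, "trials")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(trace = file.path(dir, paste0(tag, "_trace.csv")),
             path  = file.path(dir, paste0(tag, "_path.csv")),
             bouts = file.path(dir, paste0(tag, "_bouts.csv")))
  write_trace(trial$trace, paths["trace"])
  write_path(analysis$path, paths["path"])
  write_bouts(analysis$bouts, paths["bouts"])
  paths
}

#' Run a full virtual experiment
#'
#' Crosses the configured gating conditions with stimulus directions,
#' runs `n_subjects` closed-loop trials per cell (between-subject) or
#' all cells per subject in seeded random order with persistent
#' per-subject traits (within-subject), analyses every trace, and
#' compares forward vs backward groups per condition and metric with
#' [mann_whitney_u()]. Each trial's seed is derived from the master seed
#' and its (subject, condition, direction) labels, so the whole
#' experiment is deterministic and any single trial can be regenerated
#' in isolation.
#'
#' If `output_dir` is set, writes `summaries.csv`, `comparisons.csv` and
#' a JSON `manifest.json` (config echo, package version, every trial's
#' seed) from which every number in the tables can be recomputed;
#' `save_traces = TRUE` additionally writes per-trial trace/path/bout
#' CSVs.
#'
#' @param config an [experiment_config()].
#' @param quiet suppress per-trial progress lines (default `TRUE`).
#' @return Object of class `pg_experiment`: list with `trials` (per
#'   subject x cell metric rows), `comparisons` (see [compare_all()])
#'   and `manifest`.
#' @examples
#' cfg <- experiment_config(conditions = "OPEN_LOOP", n_subjects = 2,
#'                          duration = 20, master_seed = 7)
#' ex <- run_experiment(cfg)
#' ex$comparisons
#' @export
run_experiment <- function(config, quiet = TRUE) {
  if (!inherits(config, "pg_experiment_config"))
    config_error("'config' must be a pg_experiment_config")
  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) {
      ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      if (!ok) pg_stop("pg_io_error", "cannot create output dir '%s'", out_dir)
    }
    if (file.access(out_dir, 2) != 0)
      pg_stop("pg_io_error", "output dir '%s' is not writable", out_dir)
  }

  cells <- expand.grid(condition = config$conditions,
                       direction = config$directions,
                       stringsAsFactors = FALSE)
  rows <- list()

  add_row <- function(subject, condition, direction, res) {
    s <- res$analysis$summary
    paths <- c(trace = NA_character_, path = NA_character_,
               bouts = NA_character_)
    if (!is.null(out_dir) && config$save_traces) {
      tag <- sprintf("%s_%s_%s", subject, condition, direction)
      paths <- write_trial_artifacts(config, res$trial, res$analysis, tag)
    }
    if (!quiet)
      message(sprintf("trial %s %s/%s seed=%d wf=%.3f",
                      subject, condition, direction, res$seed,
                      s$walking_fraction))
    cbind(data.frame(subject = subject, condition = condition,
                     direction = direction, seed = res$seed,
                     turn_sign = res$trial$turn_sign),
          as.data.frame(s),
          data.frame(trace_path = unname(paths["trace"]),
                     path_path = unname(paths["path"]),
                     bouts_path = unname(paths["bouts"])))
  }

  if (config$protocol == "BETWEEN_SUBJECT") {
    for (ci in seq_len(nrow(cells))) {
      cond <- cells$condition[ci]; dirn <- cells$direction[ci]
      for (i in seq_len(config$n_subjects)) {
        subject <- sprintf("s%02d_%s_%s", i, cond, dirn)
        res <- run_one_cell_trial(config, subject, cond, dirn)
        rows[[length(rows) + 1L]] <- add_row(subject, cond, dirn, res)
      }
    }
  } else {
    for (i in seq_len(config$n_subjects)) {
      subject <- sprintf("s%02d", i)
      set.seed(derive_seed(config$master_seed, subject, "subject_traits"))
      turn_sign <- if (runif(1) < 0.5) -1 else 1
      set.seed(derive_seed(config$master_seed, subject, "cell_order"))
      order_idx <- sample.int(nrow(cells))
      for (ci in order_idx) {
        cond <- cells$condition[ci]; dirn <- cells$direction[ci]
        res <- run_one_cell_trial(config, subject, cond, dirn,
                                  turn_sign = turn_sign)
        rows[[length(rows) + 1L]] <- add_row(subject, cond, dirn, res)
      }
    }
  }

  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  set.seed(derive_seed(config$master_seed, "comparisons"))
  comparisons <- compare_all(trials, conditions = config$conditions)

  manifest <- list(
    package = "pausegate",
    version = as.character(packageVersion("pausegate")),
    master_seed = config$master_seed,
    protocol = config$protocol,
    duration_s = config$duration,
    n_subjects = config$n_subjects,
    conditions = config$conditions,
    directions = config$directions,
    agent = unclass(config$agent),
    stimulus = unclass(config$stimulus),
    detector = unclass(config$detector),
    segmentation = unclass(config$segmentation),
    trials = trials[, c("subject", "condition", "direction", "seed",
                        "turn_sign")])

  if (!is.null(out_dir)) {
    write_summary(trials, file.path(out_dir, "summaries.csv"))
    write_comparisons(comparisons, file.path(out_dir, "comparisons.csv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
  }

  structure(list(trials = trials, comparisons = comparisons,
                 manifest = manifest, config = config),
            class = "pg_experiment")
}

#' @export
print.pg_experiment <- function(x, ...) {
  cat(sprintf("virtual experiment: %s, %d subjects/cell, %g s trials\n",
              x$config$protocol, x$config$n_subjects, x$config$duration))
  cat(sprintf("cells: {%s} x {%s}; %d trials\n",
              paste(x$config$conditions, collapse = ", "),
              paste(x$config$directions, collapse = ", "),
              nrow(x$trials)))
  print(x$comparisons)
  invisible(x)
}

#' Bar-panel plot of group metrics per condition and direction
#'
#' Per-metric bar panels of group means (open bars: forward stimulus;
#' shaded: backward) with per-subject points, one group of bars per
#' gating condition, annotated with the Mann-Whitney p-values.
#'
#' @param x a `pg_experiment`.
#' @param metrics metric columns to draw.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.pg_experiment <- function(x, metrics = c("walking_fraction",
                                              "mean_pause_duration",
                                              "total_side_motion",
                                              "total_distance"), ...) {
  tr <- x$trials
  conds <- x$config$conditions
  old <- graphics::par(mfrow = c(ceiling(length(metrics) / 2), 2),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (m in metrics) {
    means <- sapply(conds, function(cond) c(
      FORWARD = mean(tr[[m]][tr$condition == cond & tr$direction == "FORWARD"]),
      BACKWARD = mean(tr[[m]][tr$condition == cond & tr$direction == "BACKWARD"])))
    bp <- graphics::barplot(means, beside = TRUE,
                            col = c("white", "grey60"),
                            ylim = c(0, max(tr[[m]]) * 1.15),
                            ylab = m, names.arg = conds, cex.names = 0.7)
    for (j in seq_along(conds)) {
      for (k in 1:2) {
        dirn <- c("FORWARD", "BACKWARD")[k]
        v <- tr[[m]][tr$condition == conds[j] & tr$direction == dirn]
        graphics::points(jitter(rep(bp[k, j], length(v)), amount = 0.15), v,
                         pch = 1, cex = 0.6)
      }
      p <- x$comparisons$p[x$comparisons$metric == m &
                             x$comparisons$condition == conds[j]]
      if (length(p) == 1L)
        graphics::mtext(ifelse(p < 0.05, sprintf("p=%.3g *", p),
                               sprintf("p=%.3g", p)),
                        side = 3, at = mean(bp[, j]), cex = 0.6)
    }
  }
  invisible(x)
}

#' Read an experiment configuration from JSON
#'
#' Reads a single nested JSON document whose top-level keys mirror the
#' [experiment_config()] arguments (`agent`, `stimulus`, `detector`,
#' `segmentation` as objects of field overrides; the rest as scalars or
#' arrays). Absent fields keep package defaults.
#'
#' @param path JSON file path.
#' @return A `pg_experiment_config`.
#' @export
read_experiment_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  build <- function(ctor, over) {
    over <- as.list(over)
    if (length(over) == 0L) return(ctor())
    bad <- setdiff(names(over), names(formals(ctor)))
    if (length(bad)) config_error("unknown config field(s): %s",
                                  paste(bad, collapse = ", "))
    do.call(ctor, over)
  }
  args <- list(agent = build(agent_config, js$agent),
               stimulus = build(stimulus_config, js$stimulus),
               detector = build(motion_detector_config, js$detector),
               segmentation = build(segmentation_config, js$segmentation))
  for (f in c("conditions", "directions", "n_subjects", "protocol",
              "duration", "master_seed", "output_dir", "save_traces")) {
    if (!is.null(js[[f]])) args[[f]] <- js[[f]]
  }
  do.call(experiment_config, args)
}
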