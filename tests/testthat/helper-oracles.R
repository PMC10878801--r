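# Independent reference implementations used as oracles. These stay
# deliberately naive and share no code with the package internals.

# Kolmogorov-Smirnov distance between a sample and a (possibly mixed)
# distribution: cdf is the right-continuous CDF, cdf_left its left
# limit (they differ only at atoms, e.g. a hard duration cap).
ks_stat <- function(x, cdf, cdf_left = cdf) {
  x <- sort(x)
  n <- length(x)
  max(seq_len(n) / n - cdf(x), cdf_left(x) - (seq_len(n) - 1) / n)
}

# Brute-force bout segmentation: threshold a speed series, enumerate
# runs, then repeatedly relabel the shortest interior run below the
# minimum duration (earliest on ties) and re-enumerate from scratch.
# No smoothing: use with a segmentation window below one sample.
oracle_segment <- function(speed, dt, threshold, min_bout) {
  labels <- ifelse(speed > threshold, "WALK", "PAUSE")
  repeat {
    r <- rle(labels)
    k <- length(r$lengths)
    if (k <= 2L) break
    dur <- r$lengths * dt
    cand <- which(dur < min_bout - 1e-9)
    cand <- cand[cand > 1L & cand < k]
    if (!length(cand)) break
    i <- cand[which.min(dur[cand])]
    lo <- sum(r$lengths[seq_len(i - 1L)]) + 1L
    hi <- lo + r$lengths[i] - 1L
    labels[lo:hi] <- r$values[i - 1L]
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  data.frame(kind = r$values,
             start_s = (ends - r$lengths) * dt,
             duration_s = r$lengths * dt)
}

# R reference closed-loop trial built from the exported single-step
# operations, consuming the RNG in the documented order; must agree
# sample-for-sample with run_trial() under a shared seed.
reference_trial <- function(agent, detector, mode, direction, n_samples,
                            seed) {
  dt <- 1 / agent$sample_rate
  set.seed(seed)
  state <- init_agent_state(agent)
  moving <- FALSE
  cnt_on <- 0L; cnt_off <- 0L
  active <- gate(mode, moving)
  out <- data.frame(d_forward_cm = numeric(n_samples),
                    d_yaw_rad = numeric(n_samples),
                    d_lateral_cm = numeric(n_samples),
                    evidence = numeric(n_samples),
                    behaviour = character(n_samples),
                    active = logical(n_samples),
                    moving = logical(n_samples))
  for (t in seq_len(n_samples)) {
    step <- step_agent(state, active, direction, agent, dt)
    state <- step$state
    s <- step$sample
    out$d_forward_cm[t] <- s["d_forward_cm"]
    out$d_yaw_rad[t] <- s["d_yaw_rad"]
    out$d_lateral_cm[t] <- s["d_lateral_cm"]
    out$evidence[t] <- state$evidence
    out$behaviour[t] <- step$behaviour
    out$active[t] <- active
    m <- sqrt(s["d_forward_cm"]^2 + s["d_lateral_cm"]^2)
    if (m > detector$threshold) { cnt_on <- cnt_on + 1L; cnt_off <- 0L }
    else { cnt_off <- cnt_off + 1L; cnt_on <- 0L }
    if (!moving && cnt_on >= detector$debounce_on) moving <- TRUE
    else if (moving && cnt_off >= detector$debounce_off) moving <- FALSE
    out$moving[t] <- moving
    active <- gate(mode, moving)
  }
  out
}

# ground-truth walking time (s) from a trace's noiseless labels
true_walk_time <- function(trace) {
  rate <- attr(trace, "sample_rate")
  sum(trace$true_behaviour != "PAUSE") / rate
}
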