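test_that("evidence integrator: fixed point, steady state, and in-phase null drive", {
  cfg <- agent_config()
  dt <- 1 / cfg$sample_rate
  # inactive stimulus at E = 0 is a fixed point
  expect_equal(update_evidence(0, FALSE, "BACKWARD", "PAUSE", dt, cfg), 0)

  # constant active BACKWARD stimulus during an indefinite pause:
  # Euler iteration converges to the closed-form limit -w_pause * tau_e
  E <- 0
  for (i in seq_len(12000)) E <- update_evidence(E, TRUE, "BACKWARD",
                                                 "PAUSE", dt, cfg)
  expect_equal(E, -cfg$w_pause * cfg$tau_e, tolerance = 1e-6)

  # with w_walk = 0, an active stimulus during walking injects nothing
  expect_equal(update_evidence(0, TRUE, "BACKWARD", "WALK_FORWARD", dt, cfg), 0)
})

test_that("pause hazard: baseline power law, shortening only for opposing evidence", {
  cfg <- agent_config(beta = 3)
  expect_equal(pause_hazard(1, 0, cfg), (cfg$alpha - 1) / (1 + cfg$t_min))
  expect_equal(pause_hazard(1, 2, cfg), pause_hazard(1, 0, cfg))   # E > 0: no change
  expect_equal(pause_hazard(1, -0.5, cfg),
               pause_hazard(1, 0, cfg) * (1 + 3 * 0.5))
  expect_identical(pause_hazard(cfg$t_max, 0, cfg), Inf)
  cfg0 <- agent_config(beta = 0)
  expect_equal(pause_hazard(2, -5, cfg0), pause_hazard(2, 0, cfg0))
})

test_that("baseline pause sampler: exact survival law, median at t_min for alpha = 2", {
  set.seed(101)
  cfg2 <- agent_config(alpha = 2, t_min = 0.5)
  x <- sample_pause_duration(1e5, cfg2)
  expect_equal(median(x), 0.5, tolerance = 0.02)

  # KS distance against the analytic capped power-law CDF (atom at t_max)
  cfg <- agent_config()
  y <- sample_pause_duration(1e5, cfg)
  cdf <- function(t) ifelse(t >= cfg$t_max, 1,
                            1 - (cfg$t_min / (t + cfg$t_min))^(cfg$alpha - 1))
  cdf_left <- function(t) 1 - (cfg$t_min / (pmin(t, cfg$t_max) +
                                              cfg$t_min))^(cfg$alpha - 1)
  expect_lt(ks_stat(y, cdf, cdf_left), 0.01)
  expect_true(all(y <= cfg$t_max))
})

test_that("turn decision: baseline rate, saturation, and gain-off constancy", {
  cfg <- agent_config(k_turn = 4, b_turn = -2.944)
  p_base <- 1 / (1 + exp(2.944))
  expect_equal(p_base, 0.05, tolerance = 1e-3)
  set.seed(7)
  turns <- replicate(1e4, choose_bout_at_pause_end(0, cfg)$behaviour)
  se <- sqrt(p_base * (1 - p_base) / 1e4)
  expect_lt(abs(mean(turns == "WALK_TURN") - p_base), 3 * se)

  # saturating limit and gain off
  set.seed(8)
  expect_identical(choose_bout_at_pause_end(-100, cfg)$behaviour, "WALK_TURN")
  cfg0 <- agent_config(k_turn = 0, b_turn = 2)
  p_const <- 1 / (1 + exp(-2))
  set.seed(9)
  t2 <- replicate(4000, choose_bout_at_pause_end(runif(1, -5, 5),
                                                 cfg0)$behaviour)
  expect_lt(abs(mean(t2 == "WALK_TURN") - p_const),
            3 * sqrt(p_const * (1 - p_const) / 4000))
})

test_that("single agent steps: silent pauses, exact walking increments", {
  cfg <- agent_config(sigma = 0)
  dt <- 1 / cfg$sample_rate
  set.seed(5)
  st <- init_agent_state(cfg, turn_sign = 1)
  # force a scheduled walk: terminate the pause by hand
  st$behaviour <- "WALK_FORWARD"; st$walk_end <- 1
  stp <- step_agent(st, FALSE, "FORWARD", cfg, dt)
  expect_equal(unname(stp$sample["d_forward_cm"]), cfg$v_walk * dt)
  expect_equal(unname(stp$sample["d_yaw_rad"]), 0)

  st$behaviour <- "PAUSE"; st$time_in_bout <- 0.01
  stp2 <- step_agent(st, FALSE, "FORWARD", cfg, dt)
  if (stp2$behaviour == "PAUSE") {
    expect_equal(unname(stp2$sample), c(0, 0, 0))
  }
  expect_error(step_agent(st, FALSE, "FORWARD", cfg, dt = dt * 2),
               class = "pg_config_error")
})

test_that("native trial loop agrees sample-for-sample with the R single-step reference", {
  agent <- agent_config(sigma = 0.002)
  det <- motion_detector_config()
  for (case in list(list(mode = "OUT_OF_PHASE", dir = "BACKWARD", seed = 21L),
                    list(mode = "IN_PHASE", dir = "FORWARD", seed = 22L),
                    list(mode = "OPEN_LOOP", dir = "BACKWARD", seed = 23L))) {
    n <- 600L
    tr <- run_trial(agent = agent,
                    stimulus = stimulus_config(signal_direction = case$dir),
                    mode = case$mode, detector = det,
                    duration = n / agent$sample_rate, seed = case$seed)
    ref <- reference_trial(agent, det, case$mode, case$dir, n, case$seed)
    expect_equal(tr$trace$d_forward_cm, ref$d_forward_cm, tolerance = 1e-12)
    expect_equal(tr$trace$d_yaw_rad, ref$d_yaw_rad, tolerance = 1e-12)
    expect_equal(tr$trace$evidence, ref$evidence, tolerance = 1e-12)
    expect_identical(tr$trace$true_behaviour, ref$behaviour)
    expect_identical(tr$trace$stimulus_active, ref$active)
    expect_identical(tr$gate_log$moving, ref$moving)
  }
})

test_that("trials are deterministic given a seed and alternate bouts properly", {
  a <- run_trial(duration = 30, seed = 99L, mode = "OUT_OF_PHASE")
  b <- run_trial(duration = 30, seed = 99L, mode = "OUT_OF_PHASE")
  expect_identical(a$trace, b$trace)

  kinds <- rle(ifelse(a$trace$true_behaviour == "PAUSE", "P", "W"))$values
  expect_true(all(kinds[-1] != kinds[-length(kinds)]))

  # open loop: gate log all-active regardless of the trace
  ol <- run_trial(duration = 10, seed = 4L, mode = "OPEN_LOOP")
  expect_true(all(ol$gate_log$active))
})

test_that("no-stimulus walking fraction matches the renewal-theory ratio", {
  agent <- agent_config(w_pause = 0, w_walk = 0)
  theory <- renewal_expectation(agent)$walking_fraction
  wf <- vapply(1:40, function(i) {
    tr <- run_trial(agent = agent, duration = 300, seed = 1000L + i,
                    mode = "OPEN_LOOP")
    mean(tr$trace$true_behaviour != "PAUSE")
  }, numeric(1))
  se <- sd(wf) / sqrt(length(wf))
  expect_lt(abs(mean(wf) - theory), 3 * se + 0.005)
})

test_that("evidence magnitude: out-of-phase exceeds in-phase on matched seeds", {
  for (seed in c(31L, 32L, 33L)) {
    stim <- stimulus_config(signal_direction = "BACKWARD")
    e_out <- mean(abs(run_trial(stimulus = stim, mode = "OUT_OF_PHASE",
                                duration = 60, seed = seed)$trace$evidence))
    e_in <- mean(abs(run_trial(stimulus = stim, mode = "IN_PHASE",
                               duration = 60, seed = seed)$trace$evidence))
    expect_gte(e_out, e_in)
  }
})

test_that("backward stimulation shortens pauses relative to forward over paired seeds", {
  mp <- function(dir, seed) {
    tr <- run_trial(stimulus = stimulus_config(signal_direction = dir),
                    mode = "OUT_OF_PHASE", duration = 120, seed = seed)
    analyze_trace(tr$trace)$summary$mean_pause_duration
  }
  seeds <- 400L + seq_len(50)
  mpb <- vapply(seeds, function(s) mp("BACKWARD", s), numeric(1))
  mpf <- vapply(seeds, function(s) mp("FORWARD", s), numeric(1))
  expect_lt(mean(mpb), mean(mpf))
})
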