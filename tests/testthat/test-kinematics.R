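mk_trace <- function(fwd, yaw, lat = 0, rate = 120) {
  n <- max(length(fwd), length(yaw))
  df <- data.frame(t_s = seq_len(n) / rate,
                   d_forward_cm = rep_len(fwd, n),
                   d_yaw_rad = rep_len(yaw, n),
                   d_lateral_cm = rep_len(lat, n))
  attr(df, "sample_rate") <- rate
  class(df) <- c("pg_trace", "data.frame")
  df
}

test_that("path integration: stillness, straight dead-reckoning, closed-form circle", {
  still <- integrate_path(mk_trace(rep(0, 50), 0))
  expect_equal(max(abs(still$x_cm)), 0)
  expect_equal(max(abs(still$y_cm)), 0)
  expect_identical(nrow(still), 51L)

  rate <- 120; v <- 3; t_tot <- 4
  straight <- integrate_path(mk_trace(rep(v / rate, rate * t_tot), 0))
  expect_equal(tail(straight$x_cm, 1), v * t_tot, tolerance = 1e-9)
  expect_equal(max(abs(straight$y_cm)), 0)

  # constant (v, omega): circle of radius v / omega, O(dt) accurate
  omega <- 1; t_tot <- 10; dt <- 1 / rate; n <- rate * t_tot
  circ <- integrate_path(mk_trace(rep(v * dt, n), omega * dt))
  tt <- circ$t_s
  exact_x <- (v / omega) * sin(omega * tt)
  exact_y <- (v / omega) * (1 - cos(omega * tt))
  err <- sqrt((circ$x_cm - exact_x)^2 + (circ$y_cm - exact_y)^2)
  expect_lt(max(err), v * omega * t_tot * dt)

  expect_error(integrate_path(mk_trace(numeric(0), 0)[0, ]),
               class = "pg_insufficient_data_error")
})

test_that("path integration is additive under concatenation with carried state", {
  set.seed(17)
  tr1 <- mk_trace(runif(200, 0, 0.05), rnorm(200, 0, 0.02), rnorm(200, 0, 0.01))
  tr2 <- mk_trace(runif(150, 0, 0.05), rnorm(150, 0, 0.02), rnorm(150, 0, 0.01))
  both <- mk_trace(c(tr1$d_forward_cm, tr2$d_forward_cm),
                   c(tr1$d_yaw_rad, tr2$d_yaw_rad),
                   c(tr1$d_lateral_cm, tr2$d_lateral_cm))
  p1 <- integrate_path(tr1); p2 <- integrate_path(tr2)
  p12 <- integrate_path(both)
  phi <- tail(p1$heading_rad, 1)
  x0 <- tail(p1$x_cm, 1); y0 <- tail(p1$y_cm, 1)
  x2 <- x0 + p2$x_cm * cos(phi) - p2$y_cm * sin(phi)
  y2 <- y0 + p2$x_cm * sin(phi) + p2$y_cm * cos(phi)
  expect_equal(tail(p12$x_cm, 150), tail(x2, 150), tolerance = 1e-9)
  expect_equal(tail(p12$y_cm, 150), tail(y2, 150), tolerance = 1e-9)
})

test_that("segmentation matches a brute-force run-length oracle on handcrafted traces", {
  rate <- 10; dt <- 1 / rate
  no_smooth <- segmentation_config(window = 1e-4, speed_threshold = 1,
                                   min_bout = 0.25)
  cases <- list(
    c(0, 0, 2, 2, 2, 0, 0, 0, 2, 0),                  # one clean walk run
    c(2, 2, 0, 2, 2, 2, 0, 0, 0, 0),                  # leading walk, glitch
    rep(c(0, 2), 25),                                  # rapid alternation
    c(rep(0, 40), rep(2, 5), 0, rep(2, 30), rep(0, 24)))
  for (speed in cases) {
    tr <- mk_trace(speed / rate, 0, rate = rate)
    got <- segment_bouts(tr, no_smooth)
    want <- oracle_segment(speed, dt, threshold = 1, min_bout = 0.25)
    expect_equal(as.data.frame(got), want, tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(sum(got$duration_s), nrow(tr) * dt, tolerance = 1e-12)
    kinds <- got$kind
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
})

test_that("noiseless agent traces segment to the ground-truth labels up to smoothing blur", {
  agent <- agent_config(sigma = 0)
  tr <- run_trial(agent = agent, duration = 120, seed = 71L,
                  mode = "OPEN_LOOP")$trace
  rate <- agent$sample_rate
  seg <- segmentation_config(window = 0.25, speed_threshold = 0.3,
                             min_bout = 1 / rate)  # no merging
  bouts <- segment_bouts(tr, seg)
  # reconstruct per-sample labels from the segmentation
  lab <- rep(bouts$kind, round(bouts$duration_s * rate))
  truth <- ifelse(tr$true_behaviour == "PAUSE", "PAUSE", "WALK")
  # mismatches may only sit within half a window of a true transition
  half <- round(0.25 * rate) %/% 2
  trans <- which(diff(truth == "WALK") != 0)
  near <- rep(FALSE, nrow(tr))
  for (k in trans) near[max(1, k - half):min(nrow(tr), k + half + 1)] <- TRUE
  mism <- which(lab != truth)
  expect_true(all(mism %in% which(near)))
})

test_that("kinematic summary: degenerate and analytic cases", {
  rate <- 120
  # walks the whole trial
  tr <- mk_trace(rep(3 / rate, 600), 0, rate = rate)
  res <- analyze_trace(tr)
  expect_equal(res$summary$walking_fraction, 1)
  expect_true(res$summary$no_pause)
  expect_equal(res$summary$mean_pause_duration, 0)
  expect_equal(res$summary$total_side_motion, 0)
  expect_equal(res$summary$straightness, 1, tolerance = 1e-12)

  # all-zero trace: one pause covering [0, T]
  tz <- mk_trace(rep(0, 600), 0, rate = rate)
  bz <- segment_bouts(tz, segmentation_config())
  expect_identical(nrow(bz), 1L)
  expect_identical(bz$kind, "PAUSE")
  expect_equal(bz$duration_s, 5)

  # continuous turning: straightness < 1 and side motion > 0
  tc <- mk_trace(rep(3 / rate, 1200), 1 / rate, rate = rate)
  rc <- analyze_trace(tc)
  expect_lt(rc$summary$straightness, 1)
  expect_gt(rc$summary$total_side_motion, 0)
  # matched analytic values on the circle: net displacement / arc length
  t_tot <- 10
  net <- 2 * 3 * abs(sin(t_tot / 2))  # chord of a unit-rate circle, v = 3
  expect_equal(rc$summary$straightness, net / (3 * t_tot), tolerance = 1e-3)
})

test_that("summary inequalities hold on simulated trials", {
  for (seed in c(55L, 56L)) {
    tr <- run_trial(duration = 60, seed = seed, mode = "OUT_OF_PHASE",
                    stimulus = stimulus_config(signal_direction = "BACKWARD"))
    res <- analyze_trace(tr$trace)
    p <- res$path
    expect_gte(res$summary$total_side_motion + 1e-12,
               abs(tail(p$y_cm, 1)))
    expect_gte(res$summary$total_distance + 1e-12,
               sqrt(tail(p$x_cm, 1)^2 + tail(p$y_cm, 1)^2))
    expect_lte(res$summary$straightness, 1 + 1e-12)
    expect_equal(sum(res$bouts$duration_s), tail(tr$trace$t_s, 1),
                 tolerance = 1e-9)
  }
})

test_that("walking fraction is stable under sensor noise of the default amplitude", {
  agent0 <- agent_config(sigma = 0)
  tr <- run_trial(agent = agent0, duration = 120, seed = 77L,
                  mode = "OPEN_LOOP")$trace
  wf0 <- analyze_trace(tr)$summary$walking_fraction
  set.seed(78)
  noisy <- tr
  noisy$d_forward_cm <- noisy$d_forward_cm + rnorm(nrow(tr), 0, 0.002)
  noisy$d_lateral_cm <- noisy$d_lateral_cm + rnorm(nrow(tr), 0, 0.002)
  noisy$d_yaw_rad <- noisy$d_yaw_rad + rnorm(nrow(tr), 0, 0.002)
  wf1 <- analyze_trace(noisy)$summary$walking_fraction
  expect_lt(abs(wf1 - wf0), 0.02)
})

test_that("trace round-trips through CSV", {
  tr <- run_trial(duration = 5, seed = 3L)$trace
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$d_forward_cm, tr$d_forward_cm, tolerance = 1e-12)
  expect_equal(attr(back, "sample_rate"), 120, tolerance = 1e-6)
  expect_identical(back$true_behaviour, tr$true_behaviour)
  unlink(f)
})
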