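test_that("the inclusion rule keeps events out of the noise range only", {
  pr <- recording_protocol(duration_s = 10)
  cfg <- analysis_config()
  # pure noise: excluded
  noise <- simulate_channel_trace(
    channel_model(data.frame(label = c("closed", "open"),
                             conductance_pS = c(0, 800)),
                  matrix(0, 2, 2), noise_sd = 0.5), pr, seed = 4)
  f_noise <- fit_mixture(noise$current_pA)
  expect_false(has_events(noise, f_noise, cfg))
  # 16 pA openings over 0.5 pA trace noise: gap >> 3 sigma, included
  set.seed(8)
  x <- rep(c(0, 16), each = 5000) + rnorm(10000, 0, 0.5)
  tr16 <- ptp_trace(x, recording_protocol())
  expect_true(has_events(tr16, fit_mixture(tr16$current_pA), cfg))
  # 1 pA "openings" over 0.5 pA trace noise: gap < 3 sigma, excluded
  set.seed(9)
  x1 <- rep(c(0, 1), each = 5000) + rnorm(10000, 0, 0.5)
  tr1 <- ptp_trace(x1, recording_protocol())
  expect_false(has_events(tr1, fit_mixture(tr1$current_pA), cfg))
})

test_that("G_max takes the largest fast transition and honours the 10-ms rule", {
  cfg <- analysis_config()
  expect_true(is.na(compute_gmax(NULL, cfg)))
  ev0 <- data.frame(time_s = numeric(0), duration_ms = numeric(0),
                    from_level = integer(0), to_level = integer(0),
                    delta_g_pS = numeric(0))
  expect_true(is.na(compute_gmax(ev0, cfg)))

  fs <- 10000
  pr <- recording_protocol(sampling_rate_hz = fs)
  # 0 <-> 16 pA steps at +20 mV -> 800 pS
  tr <- step_trace(c(0, 16, 0, 16), rep(0.5, 4), fs = fs)
  lev <- define_levels(c(0, 16), pr)
  ev <- detect_transitions(idealize(tr, lev), tr, lev)
  expect_equal(compute_gmax(ev, cfg), 800)

  # fast 0 <-> 300 pS steps plus one slow (20 ms) 300 -> 800 pS ramp:
  # the slow large transition is excluded, G_max comes from the fast ones
  ramp <- seq(6, 16, length.out = 0.02 * fs)
  x <- c(rep(0, fs), rep(6, fs), rep(0, fs), rep(6, fs), ramp,
         rep(16, fs))
  tr2 <- ptp_trace(x, pr)
  lev2 <- define_levels(c(0, 6, 16), pr)
  ev2 <- detect_transitions(idealize(tr2, lev2), tr2, lev2)
  expect_equal(nrow(ev2), 4L)
  expect_equal(max(abs(ev2$delta_g_pS)), 500)   # the ramp event exists...
  expect_equal(compute_gmax(ev2, cfg), 300)     # ...but does not count
})

test_that("G_mean averages activity samples in the pre-blocker window", {
  fs <- 10000
  pr <- recording_protocol(sampling_rate_hz = fs)
  cfg <- analysis_config()
  # constant 800 pS throughout the window
  tr <- step_trace(c(0, 16), c(5, 35), fs = fs)
  lev <- define_levels(c(0, 16), pr)
  ideal <- idealize(tr, lev, cfg)
  gm <- compute_gmean(tr, ideal, lev, blocker_time = 40, cfg)
  expect_equal(as.numeric(gm), 800, tolerance = 1e-6)
  expect_equal(attr(gm, "window"), c(10, 40))

  # equal-duration 800/400 pS alternation with closed gaps excluded -> 600
  cyc <- c(16, 0, 8, 0)
  tr2 <- step_trace(rep(cyc, 10), rep(c(1, 0.5, 1, 0.5), 10), fs = fs)
  lev2 <- define_levels(c(0, 8, 16), pr)
  ideal2 <- idealize(tr2, lev2, cfg)
  gm2 <- compute_gmean(tr2, ideal2, lev2, blocker_time = 30, cfg)
  expect_equal(as.numeric(gm2), 600, tolerance = 1e-6)
  # including closed time instead halves it (2 s open per 3 s cycle window)
  cfg_all <- analysis_config(gmean_include_closed = TRUE)
  gm3 <- compute_gmean(tr2, ideal2, lev2, blocker_time = 30, cfg_all)
  expect_equal(as.numeric(gm3), 600 * 2 / 3, tolerance = 1e-6)
  # short pre-blocker span is truncated and flagged
  gm4 <- compute_gmean(tr2, ideal2, lev2, blocker_time = 20, cfg)
  expect_true(attr(gm4, "truncated"))
  expect_equal(attr(gm4, "window")[1], 0)
})

test_that("Q_4s integrates the best 4-s window of charge", {
  fs <- 10000
  pr <- recording_protocol(sampling_rate_hz = fs)
  cfg <- analysis_config()
  # constant 16 pA open channel: 16 pA x 4 s = 64 pC
  tr <- step_trace(c(0, 16), c(1, 8), fs = fs)
  lev <- define_levels(c(0, 16), pr)
  ideal <- idealize(tr, lev, cfg)
  q <- compute_q4s(tr, ideal, lev, cfg)
  expect_equal(as.numeric(q), 64, tolerance = 0.01)
  w <- attr(q, "window")
  expect_equal(w[2] - w[1], 4)
  expect_gte(w[1], 1 - 1e-6)   # the window sits inside the open stretch

  # 50% duty cycle at 16 pA: 32 pC whatever the window alignment
  tr2 <- step_trace(rep(c(16, 0), 10), rep(0.5, 20), fs = fs)
  ideal2 <- idealize(tr2, lev, cfg)
  expect_equal(as.numeric(compute_q4s(tr2, ideal2, lev, cfg)), 32,
               tolerance = 0.05)

  # trace shorter than the window
  tr3 <- step_trace(16, 2, fs = fs)
  ideal3 <- idealize(tr3, define_levels(16, pr), cfg)
  expect_error(compute_q4s(tr3, ideal3, define_levels(16, pr), cfg),
               "shorter than")
})

test_that("Q_4s never exceeds the G_max charge bound", {
  tr <- simulate_preset("wt_hela_ptp", seed = 31)
  res <- analyze_trace(tr)
  expect_true(res$included)
  bound <- res$gmax_pS * tr$protocol$holding_potential_mV * 4 / 1000
  expect_lte(res$q4s_pC, bound)
  expect_lte(res$gmean_pS,
             max(res$levels$levels$conductance_pS) + 1e-9)
})

test_that("paired blocker test matches the textbook t formula", {
  # identical pre/post: t = 0, p = 1
  r0 <- blocker_effect(c(500, 600), c(500, 600))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  # worked example against the closed-form paired t computed here
  pre <- c(800, 850, 900); post <- c(100, 120, 80)
  d <- pre - post
  t_ref <- mean(d) / (sd(d) / sqrt(3))
  p_ref <- 2 * pt(-abs(t_ref), df = 2)
  r <- blocker_effect(pre, post)
  expect_equal(r$statistic, t_ref, tolerance = 1e-10)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, p_ref, tolerance = 1e-10)
  expect_equal(round(r$statistic, 1), 20.8)
  expect_true(r$paired)
  expect_error(blocker_effect(1, 1), "at least 2")
  expect_error(blocker_effect(c(1, 2), c(1, 2, 3)), "pair by experiment")
})

test_that("group comparison matches pooled and Welch formulas", {
  r0 <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$p_value, 1)
  expect_error(group_compare(c(0, 0, 0), c(1, 1, 1)), "zero variance")
  expect_error(group_compare(1, c(1, 2)), "at least 2")

  set.seed(13)
  a <- rnorm(50, 0, 1); b <- rnorm(50, 1, 1)
  # pooled-variance reference computed from first principles
  sp2 <- ((49) * var(a) + (49) * var(b)) / 98
  t_ref <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 50 + 1 / 50))
  r <- group_compare(a, b)
  expect_equal(r$statistic, t_ref, tolerance = 1e-10)
  expect_equal(r$df, 98)
  expect_equal(r$p_value, 2 * pt(-abs(t_ref), 98), tolerance = 1e-10)
  expect_lt(r$p_value, 1e-3)
  # Welch reference
  se2 <- var(a) / 50 + var(b) / 50
  t_w <- (mean(a) - mean(b)) / sqrt(se2)
  df_w <- se2^2 / ((var(a) / 50)^2 / 49 + (var(b) / 50)^2 / 49)
  rw <- group_compare(a, b, welch = TRUE)
  expect_equal(rw$statistic, t_w, tolerance = 1e-10)
  expect_equal(rw$df, df_w, tolerance = 1e-10)
})

test_that("excluded traces report no activity rather than zero conductance", {
  tr <- simulate_preset("null_closed", seed = 2)
  res <- analyze_trace(tr)
  expect_false(res$included)
  expect_true(is.na(res$gmax_pS))
  expect_true(is.na(res$gmean_pS))
  expect_match(res$note, "no current activity")
  out <- capture.output(print(res))
  expect_true(any(grepl("no current activity", out)))
})
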