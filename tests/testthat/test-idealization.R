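test_that("amplitude histogram conserves counts and localizes constants", {
  tr <- step_trace(5, 1)
  h <- build_histogram(tr)
  expect_equal(sum(h$counts), h$n)
  expect_equal(sum(h$counts > 0), 1L)
  centers <- (h$bin_edges_pA[-1] + h$bin_edges_pA[-length(h$bin_edges_pA)]) / 2
  expect_lt(abs(centers[which(h$counts > 0)] - 5), 0.2)

  # 50/50 noiseless mixture of 0 and 16 pA: two occupied bins, equal counts
  tr2 <- ptp_trace(rep(c(0, 16), each = 500), recording_protocol())
  h2 <- build_histogram(tr2)
  expect_equal(sum(h2$counts > 0), 2L)
  expect_equal(unname(h2$counts[h2$counts > 0]), c(500L, 500L))

  # conservation for arbitrary noisy input and window
  tr3 <- ptp_trace(rnorm(4000), recording_protocol())
  h3 <- build_histogram(tr3, window = c(0.05, 0.35))
  expect_equal(sum(h3$counts), h3$n)
  expect_equal(h3$n, 3000L)
  expect_error(build_histogram(tr3, window = c(10, 11)), "empty window")
})

test_that("mixture fit recovers generating parameters and component count", {
  set.seed(101)
  # one component
  f1 <- fit_mixture(rnorm(10000, 0, 0.5))
  expect_equal(f1$k, 1L)
  expect_lt(abs(f1$components$mean_pA), 0.05)
  expect_lt(abs(f1$components$sd_pA - 0.5), 0.05)
  # two components at 0 and 16 pA
  f2 <- fit_mixture(c(rnorm(5000, 0, 0.5), rnorm(5000, 16, 0.5)))
  expect_equal(f2$k, 2L)
  expect_lt(abs(f2$components$mean_pA[1] - 0), 0.1)
  expect_lt(abs(f2$components$mean_pA[2] - 16), 0.1)
  expect_equal(f2$components$weight, c(0.5, 0.5), tolerance = 0.05)
  # three components including a substate
  f3 <- fit_mixture(c(rnorm(4000, 0, 0.5), rnorm(3000, 8.7, 0.5),
                      rnorm(3000, 16.5, 0.5)))
  expect_equal(f3$k, 3L)
  expect_equal(f3$components$mean_pA, c(0, 8.7, 16.5), tolerance = 0.1)
  expect_error(fit_mixture(rnorm(100)), "at least 200 samples")
})

test_that("mixture estimates tighten as the sample grows", {
  gen <- function(n, seed) {
    set.seed(seed)
    c(rnorm(n / 2, 0, 0.5), rnorm(n / 2, 10, 0.5))
  }
  err <- function(n) {
    f <- fit_mixture(gen(n, 77))
    max(abs(f$components$mean_pA - c(0, 10)))
  }
  expect_lt(err(1e5), err(1e3) + 1e-9)
  expect_lt(err(1e5), 0.02)
})

test_that("level extraction converts currents to conductances at V_h", {
  pr <- recording_protocol()
  # single component: baseline only
  l1 <- extract_levels(manual_fit(1, 0.1, 0.3), pr)
  expect_equal(nrow(l1$levels), 1L)
  expect_equal(l1$levels$conductance_pS, 0)
  # 0 and 16 pA at +20 mV: one 800 pS level
  l2 <- extract_levels(manual_fit(c(0.5, 0.5), c(0, 16), c(0.5, 0.5)), pr)
  expect_equal(l2$levels$conductance_pS, c(0, 800))
  # sub-threshold component merged into baseline (0.8 pA < 3 x 0.5 pA)
  l3 <- extract_levels(manual_fit(c(0.6, 0.4), c(0, 0.8), c(0.5, 0.5)), pr)
  expect_equal(nrow(l3$levels), 1L)
  expect_equal(l3$baseline_current_pA, 0.6 * 0 + 0.4 * 0.8)
  pr0 <- pr
  pr0$holding_potential_mV <- 0
  expect_error(extract_levels(manual_fit(1, 0, 0.5), pr0), "non-zero")
})

test_that("noise-free idealization recovers the exact step structure", {
  fs <- 10000
  tr <- step_trace(c(0, 16, 6, 16, 0), c(0.5, 0.3, 0.2, 0.4, 0.1), fs = fs)
  lev <- define_levels(c(0, 6, 16), tr$protocol)
  ideal <- idealize(tr, lev, exact_config(fs))
  seg <- ideal$segments
  expect_equal(nrow(seg), 5L)
  expect_equal(seg$level, c(0L, 2L, 1L, 2L, 0L))
  expect_equal(seg$start_s, c(0, 0.5, 0.8, 1.0, 1.4), tolerance = 1e-9)
  # partition: segments tile the trace exactly
  expect_equal(seg$start[-1], seg$end[-nrow(seg)])
  expect_equal(sum(seg$end - seg$start), ideal$n_samples)
  expect_true(all(diff(seg$level) != 0))
})

test_that("single-level traces idealize to one spanning segment", {
  tr <- step_trace(3, 1)
  lev <- define_levels(3, tr$protocol)
  ideal <- idealize(tr, lev)
  expect_equal(nrow(ideal$segments), 1L)
  expect_equal(ideal$segments$end - ideal$segments$start, ideal$n_samples)
})

test_that("idealization is robust to noise on dwell cores", {
  # square wave, 16 pA gap, sd 0.5 noise (gap/32): labels on samples away
  # from boundaries must be unaffected, >99% of all samples correct
  fs <- 10000
  truth_levels <- rep(c(0L, 1L), 10)
  x_clean <- unlist(lapply(truth_levels, function(l) rep(16 * l, 0.1 * fs)))
  set.seed(42)
  x_noisy <- x_clean + rnorm(length(x_clean), 0, 0.5)
  pr <- recording_protocol(sampling_rate_hz = fs)
  filt <- lowpass_gaussian(x_noisy, fs, 500)
  tr <- ptp_trace(filt, pr)
  lev <- define_levels(c(0, 16), pr, baseline_sd_pA = 0.5)
  ideal <- idealize(tr, lev, analysis_config())
  lab <- idealized_levels(ideal)
  truth_lab <- rep(truth_levels, each = 0.1 * fs)
  expect_gt(mean(lab == truth_lab), 0.99)
  # dwell cores (> 2 filter rise times ~ 1.4 ms from any boundary)
  core <- rep(c(rep(FALSE, 14), rep(TRUE, 0.1 * fs - 28), rep(FALSE, 14)),
              length(truth_levels))
  expect_true(all(lab[core] == truth_lab[core]))
  # boundaries within 2 rise times of the truth
  b_est <- ideal$segments$start_s[-1]
  b_true <- seq_len(19) * 0.1
  expect_equal(length(b_est), 19L)
  expect_lt(max(abs(b_est - b_true)), 2 * 0.68e-3)
})

test_that("transitions carry signed conductance changes and crossing times", {
  fs <- 10000
  pr <- recording_protocol(sampling_rate_hz = fs)
  # constant trace: no events
  tr0 <- step_trace(5, 1, fs = fs)
  lev0 <- define_levels(5, pr)
  expect_equal(nrow(detect_transitions(idealize(tr0, lev0), tr0, lev0)), 0L)

  # constructed 0 -> 800 -> 300 -> 800 pS path (steps at +20 mV)
  tr <- step_trace(c(0, 16, 6, 16), c(0.5, 0.5, 0.5, 0.5), fs = fs)
  lev <- define_levels(c(0, 6, 16), pr)
  ideal <- idealize(tr, lev, exact_config(fs))
  ev <- detect_transitions(ideal, tr, lev)
  expect_equal(ev$delta_g_pS, c(800, -500, 500))
  expect_true(all(ev$duration_ms < 1))
  # antisymmetry: the reversed path negates every delta_g
  tr_r <- step_trace(rev(c(0, 16, 6, 16)), c(0.5, 0.5, 0.5, 0.5), fs = fs)
  ev_r <- detect_transitions(idealize(tr_r, lev, exact_config(fs)), tr_r, lev)
  expect_equal(ev_r$delta_g_pS, rev(-ev$delta_g_pS))
})

test_that("a slow linear ramp measures its 10-90% crossing time", {
  fs <- 10000
  pr <- recording_protocol(sampling_rate_hz = fs)
  ramp <- seq(0, 16, length.out = 0.02 * fs)   # 20 ms linear ramp
  x <- c(rep(0, 0.5 * fs), ramp, rep(16, 0.5 * fs))
  tr <- ptp_trace(x, pr)
  lev <- define_levels(c(0, 16), pr)
  ev <- detect_transitions(idealize(tr, lev), tr, lev)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_ms, 16, tolerance = 0.1)
  # an instantaneous step filtered at 500 Hz measures the filter rise time
  xs <- lowpass_gaussian(c(rep(0, 0.5 * fs), rep(16, 0.5 * fs)), fs, 500)
  trs <- ptp_trace(xs, pr)
  evs <- detect_transitions(idealize(trs, lev), trs, lev)
  expect_equal(evs$duration_ms, 0.68, tolerance = 0.15)
})

test_that("baseline drift is removed by the piecewise-linear correction", {
  fs <- 10000
  pr <- recording_protocol(sampling_rate_hz = fs)
  n <- 3 * fs
  drift <- 0.3 * (seq_len(n) - 1) / fs            # 0.3 pA/s
  lv <- rep(c(0, 16, 0, 16, 0, 16), each = n / 6)
  tr <- ptp_trace(lv + drift, pr)
  levels <- define_levels(c(0.2, 16.2), pr)
  ideal <- idealize(tr, levels, analysis_config())
  corrected <- correct_baseline(tr, ideal, levels)
  open <- idealized_levels(ideal) == 1L
  closed_core <- !open
  expect_lt(max(abs(corrected[closed_core])), 0.15)
  expect_equal(mean(corrected[open]), 16, tolerance = 0.05)
})
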