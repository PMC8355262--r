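test_that("swollen fraction normalizes the Ca2+ drop by the alamethicin drop", {
  expect_equal(swollen_fraction(make_absorbance(0.7))$fraction, 0.5)
  expect_equal(swollen_fraction(make_absorbance(1.0))$fraction, 0)
  expect_equal(swollen_fraction(make_absorbance(0.4))$fraction, 1)
  # affine rescaling of the absorbance leaves the fraction unchanged
  s <- make_absorbance(0.7)
  s2 <- s; s2$a540 <- 3.2 * s$a540 + 0.7
  attr(s2, "ca_time_s") <- attr(s, "ca_time_s")
  attr(s2, "ala_time_s") <- attr(s, "ala_time_s")
  expect_equal(swollen_fraction(s2)$fraction,
               swollen_fraction(s)$fraction, tolerance = 1e-12)
  # degenerate assay: baseline at/below the alamethicin floor
  bad <- make_absorbance(0.4, a0 = 0.4)
  expect_error(swollen_fraction(bad), "degenerate assay")
})

test_that("simulated swelling assays reproduce their closed-form fraction", {
  # rate -> infinity limit: A(t > ca) = A0 - amplitude, fraction = 0.5
  p <- swelling_params(a0 = 1.0, swollen_amplitude = 0.3, rate_constant = 100,
                       ala_floor = 0.4, noise_sd = 0)
  s <- simulate_swelling(p, with_ca = TRUE, seed = 1)
  expect_equal(swollen_fraction(s)$fraction, 0.5, tolerance = 1e-6)
  # without Ca2+ the series stays flat until alamethicin
  s0 <- simulate_swelling(swelling_params(noise_sd = 0.002), with_ca = FALSE,
                          seed = 2)
  pre_ala <- s0$a540[s0$time_s < attr(s0, "ala_time_s")]
  expect_lt(max(abs(pre_ala - 1.0)), 0.01)
  expect_true(is.na(attr(s0, "ca_time_s")))
  # determinism
  expect_identical(simulate_swelling(p, TRUE, seed = 5)$a540,
                   simulate_swelling(p, TRUE, seed = 5)$a540)
  expect_error(swelling_params(ca_time_s = 100, ala_time_s = 50),
               "after the Ca2")
})

test_that("CRC counts retained pulses and converts to nmol per mg", {
  # capacity 50 uM at 2.5 uM pulses: exactly 20 retained, 125 nmol/mg
  s <- simulate_crc(crc_params(capacity_uM = 50), seed = 3)
  r <- crc(s)
  expect_equal(r$retained_pulses, 20L)
  expect_equal(r$crc_nmol_mg, 20 * 2.5 / 0.4)
  expect_equal(r$release_time_s, attr(s, "truth")$release_pulse_time_s)
  # zero capacity: the first pulse is never taken up
  r0 <- crc(simulate_crc(crc_params(capacity_uM = 0), seed = 4))
  expect_equal(r0$retained_pulses, 0L)
  expect_equal(r0$crc_nmol_mg, 0)
})

test_that("CRC recovery is exact to one pulse and monotone in capacity", {
  caps <- c(0, 10, 25, 50, 75, 100)
  got <- vapply(caps, function(cp) {
    crc(simulate_crc(crc_params(capacity_uM = cp), seed = 11))$retained_pulses
  }, 0L)
  expect_true(all(abs(got - floor(caps / 2.5)) <= 1))
  expect_true(all(diff(got) >= 0))
})

test_that("OCR summary subtracts non-mitochondrial respiration", {
  mk <- function(pre, post_oligo, post_fccp, post_rot, post_aa,
                 protein = 1) {
    t <- seq(0, 4500, by = 30)
    y <- rep(pre, length(t))
    y[t >= 1080] <- post_oligo; y[t >= 2160] <- post_fccp
    y[t >= 3240] <- post_rot; y[t >= 3360] <- post_aa
    structure(data.frame(time_s = t, ocr = y),
              injections_s = c(oligomycin = 1080, fccp = 2160,
                               rotenone = 3240, antimycin_a = 3360),
              protein_ug = protein,
              class = c("ocr_series", "data.frame"))
  }
  # worked closed form: pre 100, post-oligo 40, nonmito 10
  s <- mk(100, 40, 150, 20, 10)
  r <- ocr_summary(s)
  expect_equal(r$basal, 90)
  expect_equal(r$oligo_sensitive, 60)
  # flat trace with nonmito 0: basal = raw mean, nothing oligo-sensitive
  r0 <- ocr_summary(mk(80, 80, 80, 80, 0))
  expect_equal(r0$basal, 80)
  expect_equal(r0$oligo_sensitive, 0)
  # adding a constant to the whole series changes nothing
  s2 <- s; s2$ocr <- s$ocr + 17
  r2 <- ocr_summary(s2)
  expect_equal(r2$basal, r$basal)
  expect_equal(r2$oligo_sensitive, r$oligo_sensitive)
  # protein normalization
  r3 <- ocr_summary(mk(100, 40, 150, 20, 10, protein = 2))
  expect_equal(r3$basal, 45)
  # simulated series match their design plateaus
  sim <- simulate_ocr(ocr_params(basal = 100, nonmito = 10,
                                 oligo_frac = 0.6, noise_sd = 0.5), seed = 6)
  rs <- ocr_summary(sim)
  expect_equal(rs$basal, 90, tolerance = 2)
  expect_equal(rs$oligo_sensitive, 54, tolerance = 2)
})

test_that("timecourse summary normalizes, averages and reads out at 8 min", {
  p <- timecourse_params(n_rois = 30, noise_sd = 1,
                         protection_factors = c(none = 1, CsA = Inf))
  # full protection: both channels stay at baseline
  prot <- simulate_cell_timecourse(p, drug = "CsA", seed = 21)
  s_prot <- summarize_timecourse(prot)
  ro <- s_prot$readouts
  expect_equal(ro$mean[ro$channel == "calcein"], 1, tolerance = 0.02)
  expect_equal(ro$mean[ro$channel == "tmrm"], 1, tolerance = 0.02)
  # SEM follows the ROI count
  d <- s_prot$roi_readouts
  expect_equal(ro$sem[ro$channel == "calcein"],
               sd(d$calcein) / sqrt(nrow(d)), tolerance = 1e-12)
  expect_equal(unique(ro$n_rois), 30)
  # instant onset, fast decay: readout at the floor
  p_inst <- timecourse_params(n_rois = 20, noise_sd = 0.5, onset_mean_s = 1e-9,
                              calcein_decay = 10, tmrm_decay = 10,
                              calcein_floor = 0.2, tmrm_floor = 0.2)
  inst <- simulate_cell_timecourse(p_inst, drug = "none", seed = 22)
  ri <- summarize_timecourse(inst)$readouts
  expect_equal(ri$mean[ri$channel == "calcein"], 0.2, tolerance = 0.03)
  expect_error(simulate_cell_timecourse(p, drug = "mystery", seed = 1),
               "unknown drug label")
})

test_that("protection increases the 8-min readout monotonically", {
  readout_at <- function(pf, seed = 30) {
    p <- timecourse_params(n_rois = 40, noise_sd = 1,
                           protection_factors = c(none = pf))
    s <- summarize_timecourse(simulate_cell_timecourse(p, "none", seed = seed))
    s$readouts$mean[s$readouts$channel == "calcein"]
  }
  vals <- vapply(c(0.2, 1, 5, 25), readout_at, 0)
  expect_true(all(diff(vals) > 0))
  # and the unprotected/protected contrast is detected statistically
  p2 <- timecourse_params(n_rois = 40, noise_sd = 1)
  none <- simulate_cell_timecourse(p2, "none", seed = 31)
  csa <- simulate_cell_timecourse(p2, "CsA", seed = 32)
  cmp <- summarize_timecourse(list(none, csa))$comparisons
  expect_lt(min(cmp$p_value), 1e-3)
})

test_that("GCaMP ratio is background-corrected and scale-invariant", {
  expect_equal(gcamp_ratio(c(5, 7), c(5, 7)), c(1, 1))
  expect_equal(gcamp_ratio(200, 100, bg475 = 50, bg410 = 25), 2)
  f1 <- gcamp_ratio(c(120, 180), c(60, 90))
  f2 <- gcamp_ratio(2 * c(120, 180), 2 * c(60, 90))
  expect_equal(f1, f2)
  expect_warning(r <- gcamp_ratio(c(10, 10), c(5, 0), bg410 = 1), "masked")
  expect_true(is.na(r[2]) && !is.na(r[1]))
  expect_error(gcamp_ratio(1:3, 1:4), "equal length")
})
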