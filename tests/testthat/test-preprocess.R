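test_that("optical-density conversion is exact and scale-invariant", {
  n <- 300
  rec <- generate_nirs_recording(sim_config(amp_frontal = 0, amp_parietal = 0),
                                 seed = 1, noise = FALSE,
                                 artifacts = FALSE)$recording
  od <- intensity_to_od(rec)
  expect_true(all(od$od == 0)) # constant intensity -> zero OD
  # a single half-intensity sample gives ln 2 (up to the tiny shift of the
  # temporal mean that sample itself induces)
  rec$intensity[50, 1, 1] <- rec$intensity[50, 1, 1] / 2
  od2 <- intensity_to_od(rec)
  expect_equal(od2$od[50, 1, 1], log(2), tolerance = 1e-3)
  # scaling intensity leaves OD unchanged
  rec2 <- rec
  rec2$intensity[, 1, ] <- rec2$intensity[, 1, ] * 7.3
  expect_equal(intensity_to_od(rec2)$od[, 1, ], od2$od[, 1, ], tolerance = 1e-12)
  # non-positive intensity is a data error naming the location
  rec$intensity[10, 2, 1] <- 0
  expect_error(intensity_to_od(rec), "sample 10, channel 2")
})

test_that("cardiac QC passes sinusoid-plus-noise and rejects white noise", {
  fs <- 3.47
  t <- seq(0, 300, by = 1 / fs)
  set.seed(19)
  sine <- sin(2 * pi * 1.0 * t) + rnorm(length(t), 0, 0.1)
  od <- make_od(cbind(sine))
  expect_true(cardiac_quality_check(od)$qc_passed)
  # white noise: fails in at least 95% of 100 seeds
  fails <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    !cardiac_quality_check(make_od(cbind(rnorm(length(t)))))$qc_passed
  }, logical(1))
  expect_gte(mean(fails), 0.95)
  # an all-zero channel fails
  expect_false(cardiac_quality_check(make_od(cbind(numeric(length(t)))))$qc_passed)
  # too-short recordings are not evaluable
  expect_error(cardiac_quality_check(make_od(cbind(sine[1:100]))), "60 s")
})

test_that("wavelet correction removes spikes and preserves length", {
  fs <- 3.47
  t <- seq(0, 400, by = 1 / fs) # odd, non-power-of-two length
  clean <- sin(2 * pi * 0.05 * t)
  spiked <- clean
  spiked[700] <- spiked[700] + 10
  od <- wavelet_motion_correct(make_od(cbind(spiked)))
  corrected <- od$od[, 1, 1]
  expect_length(corrected, length(t))
  dev_before <- max(abs(spiked - clean))
  dev_after <- max(abs(corrected - clean))
  expect_lt(dev_after, 0.2 * dev_before)
  expect_true(od$motion_corrected)
  # all-zero in, all-zero out
  z <- wavelet_motion_correct(make_od(cbind(numeric(512))))
  expect_true(all(z$od == 0))
})

test_that("band-pass rejects DC, passes 0.04 Hz, kills 1 Hz per closed form", {
  fs <- 3.47
  t <- seq(0, 600, by = 1 / fs)
  central <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  # DC
  dc <- bandpass_filter(make_od(cbind(rep(2, length(t)))))
  expect_lt(max(abs(dc$od[central, 1, 1])), 1e-6 * 2)
  # closed-form two-pass Butterworth magnitude
  gain2 <- function(f, fc, n) 1 / (1 + (f / fc)^(2 * n))   # |H|^2 = one pass of filtfilt
  chain_gain <- function(f) gain2(f, 0.08, 3) *
    (f / 0.01)^10 / (1 + (f / 0.01)^10)
  pass <- bandpass_filter(make_od(cbind(sin(2 * pi * 0.04 * t))))
  amp_pass <- max(abs(pass$od[central, 1, 1]))
  expect_lt(abs(amp_pass - 1), 0.1)
  expect_equal(amp_pass, chain_gain(0.04), tolerance = 0.02)
  stop_ <- bandpass_filter(make_od(cbind(sin(2 * pi * 1.0 * t))))
  amp_stop <- max(abs(stop_$od[central, 1, 1]))
  expect_lt(amp_stop, 1e-3)
  # zero-phase contract: cross-correlation with the input peaks at lag 0
  x <- sin(2 * pi * 0.04 * t)
  cc <- ccf(pass$od[central, 1, 1], x[central], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # invalid cut-offs
  expect_error(bandpass_filter(make_od(cbind(x)), high = 2), "Nyquist")
  expect_error(bandpass_filter(make_od(cbind(x)), low = 0.1, high = 0.05),
               "below")
})

test_that("age-dependent pathlength factor evaluates the printed formula", {
  expect_equal(compute_dpf(0), 4.99)
  expect_equal(compute_dpf(25), 4.99 + 0.067 * 25^0.814)
  expect_equal(compute_dpf(25), 5.911, tolerance = 1e-3)
  expect_equal(compute_dpf(69.18), 7.098, tolerance = 1e-3)
  expect_gt(compute_dpf(80), compute_dpf(40)) # increasing in age
  expect_error(compute_dpf(-1), "age")
})

test_that("Beer-Lambert inversion is the exact inverse of the forward map", {
  set.seed(23)
  n <- 200
  hbo <- matrix(rnorm(n * 2), n, 2) # molar x 1e-8
  hhb <- matrix(rnorm(n * 2), n, 2)
  ext <- extinction_coefficients()
  dpf <- compute_dpf(70)
  d_cm <- 3
  od1 <- (ext["760", "HbO2"] * hbo + ext["760", "HHb"] * hhb) * 1e-8 * d_cm * dpf
  od2 <- (ext["850", "HbO2"] * hbo + ext["850", "HHb"] * hhb) * 1e-8 * d_cm * dpf
  od <- make_od(od1, od2, age = 70)
  hb <- mbll_invert(od)
  expect_equal(hb$hbo, hbo, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(hb$hhb, hhb, tolerance = 1e-10, ignore_attr = TRUE)
  # HbT and HBdiff identities hold exactly
  expect_equal(hb$hbt, hb$hbo + hb$hhb)
  expect_equal(hb$hbdiff, hb$hbo - hb$hhb)
  # zero OD -> zero concentrations
  hb0 <- mbll_invert(make_od(matrix(0, n, 1)))
  expect_true(all(hb0$hbo == 0) && all(hb0$hhb == 0))
  # doubling the pathlength halves concentrations
  hb2 <- mbll_invert(od, dpf = 2 * dpf)
  expect_equal(hb2$hbo, hbo / 2, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("block averaging is the baseline-corrected epoch mean", {
  fs <- 3.47
  nt <- 800
  tm <- (seq_len(nt) - 1) / fs
  # a finite 20 s pulse placed at two onsets -> two identical epochs
  pulse <- function(u) sin(2 * pi * 0.05 * u) * (u >= 0 & u < 20)
  x <- pulse(tm - 30) + pulse(tm - 130)
  events <- data.frame(condition = c("2-back", "2-back"), onset = c(30, 130))
  ba <- block_average(make_hb(cbind(x), events = events), measures = "hbo")
  # the average of two identical epochs equals either epoch
  onset_idx <- round(30 * fs) + 1
  i0 <- onset_idx - round(2 * fs)
  ep1 <- x[i0:(i0 + length(ba$time) - 1)]
  expect_equal(ba$hbo[, 1, 1], ep1 - mean(ep1[seq_len(round(2 * fs))]),
               tolerance = 1e-9)
  # adding a constant offset to one epoch changes nothing
  x2 <- x + 5 * (tm >= 120)
  ba2 <- block_average(make_hb(cbind(x2), events = events), measures = "hbo")
  expect_equal(ba2$hbo[, 1, 1], ba$hbo[, 1, 1], tolerance = 1e-9)
  # epochs a and -a cancel
  x3 <- pulse(tm - 30) - pulse(tm - 130)
  ba3 <- block_average(make_hb(cbind(x3), events = events), measures = "hbo")
  expect_lt(max(abs(ba3$hbo[, 1, 1])), 1e-9)
  # out-of-bounds epochs are dropped with a warning
  ev_bad <- data.frame(condition = "2-back", onset = c(30, 229))
  expect_warning(block_average(make_hb(cbind(x), events = ev_bad),
                               measures = "hbo"), "outside recording")
})

test_that("channel outlier filter flags exactly the extreme channel", {
  expect_false(any(suppressWarnings(channel_outlier_filter(rep(1, 30)))))
  set.seed(4)
  vals <- rnorm(30)
  vals[7] <- mean(vals[-7]) + 10 * sd(vals[-7])
  expect_equal(which(channel_outlier_filter(vals)), 7L)
  expect_error(channel_outlier_filter(c(1, 2)), "at least 3")
})

test_that("hemoglobin difference is the pointwise linear contrast", {
  expect_equal(hemoglobin_difference(2, -1), 3)
  expect_equal(hemoglobin_difference(1, 1), 0)
  x <- matrix(rnorm(20), 5)
  y <- matrix(rnorm(20), 5)
  expect_equal(hemoglobin_difference(3 * x, 3 * y),
               3 * hemoglobin_difference(x, y))
})

test_that("preprocessing refuses out-of-order stage invocation", {
  rec <- generate_nirs_recording(seed = 31)$recording
  od <- intensity_to_od(rec)
  filt <- bandpass_filter(od)
  expect_error(wavelet_motion_correct(filt), "before band-pass")
  expect_error(cardiac_quality_check(filt), "before motion correction")
})

test_that("QC drops no channels on clean simulated data with cardiac noise", {
  gen <- generate_nirs_recording(seed = 41, artifacts = FALSE)
  pp <- preprocess_recording(gen$recording)
  expect_equal(pp$qc_drop_rate, 0)
})

test_that("full chain recovers evoked amplitudes with noise disabled", {
  gen <- generate_nirs_recording(seed = 7, noise = FALSE, artifacts = FALSE)
  ret <- gen$recording$montage$roi != "excluded"
  # reference: ground-truth concentrations through the same band-pass and
  # block averaging (excludes the filter's known pass-band attenuation)
  nyq <- 3.47 / 2
  hp <- signal::butter(5, 0.01 / nyq, "high")
  lp <- signal::butter(3, 0.08 / nyq, "low")
  ref_mat <- apply(gen$truth$hbo, 2, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x)))
  hbref <- make_hb(ref_mat, events = gen$recording$events)
  ref_pk <- channel_summary(block_average(hbref, measures = "hbo"),
                            measure = "hbo", stat = "peak")[, "2-back"]
  pp <- preprocess_recording(gen$recording, qc = FALSE)
  pk <- channel_summary(pp$block_average, measure = "hbo",
                        stat = "peak")[, "2-back"]
  expect_lt(max(abs(pk[ret] - ref_pk[ret]) / abs(ref_pk[ret])), 0.05)
  # HHb amplitudes recover equally well
  refh_mat <- apply(gen$truth$hhb, 2, function(x)
    signal::filtfilt(lp, signal::filtfilt(hp, x)))
  hrefpk <- channel_summary(block_average(make_hb(refh_mat,
                                                  events = gen$recording$events),
                                          measures = "hbo"),
                            measure = "hbo", stat = "peak")[, "2-back"]
  pkh <- channel_summary(pp$block_average, measure = "hhb",
                         stat = "peak")[, "2-back"]
  expect_lt(max(abs(pkh[ret] - hrefpk[ret]) / abs(hrefpk[ret])), 0.05)
})
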