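test_that("Hanning-windowed band power recovers a pure tone's a^2/2", {
  for (a in c(1, 20, 150)) {
    x <- a * sin(2 * pi * 10 * (0:255) / 200)
    expect_equal(band_power(x, 200), a^2 / 2, tolerance = 0.05)
  }
  expect_equal(band_power(rep(0, 256), 200), 0)
})

test_that("band powers add up to the total within one bin's leakage", {
  set.seed(50)
  for (i in 1:10) {
    x <- rnorm(256, sd = 30)
    bp <- band_powers(x, 200)
    leak <- max(segment_psd(x, 200)$psd) * (200 / 256)
    expect_lt(abs(sum(bp[c("delta", "theta", "alpha", "beta")]) -
                    bp[["total"]]), leak)
    expect_true(all(bp >= 0))
  }
})

test_that("seizure duration is the onset-endpoint difference", {
  ann <- fixed_annotation(5.12, 39.68)
  expect_equal(seizure_duration(ann)$value, 34.56)
  no_seiz <- seizure_annotation(status = "no_seizure")
  expect_equal(seizure_duration(no_seiz)$missing_reason, "no_endpoint")
  expect_error(fixed_annotation(5, 5))
})

test_that("ASEI equals a^2/2 for a sine and scales quadratically", {
  rec <- sine_record(10, amp = 100, dur = 30)
  ann <- fixed_annotation(0, 25.6)
  expect_equal(asei(rec, ann)$value, 100^2 / 2, tolerance = 0.01)
  rec2 <- rec
  rec2$channels <- rec2$channels * 2
  expect_equal(asei(rec2, ann)$value, 4 * asei(rec, ann)$value,
               tolerance = 1e-10)
  zero <- eeg_record(matrix(0, 6000, 1), 200, 0)
  expect_equal(asei(zero, ann)$value, 0)
})

test_that("MSP is 8x the per-segment PSD sum for a stationary signal", {
  rec <- sine_record(10, amp = 50, dur = 40)
  ann <- fixed_annotation(0, 38.4)
  ip <- ictal:::ictal_segment_psd(rec, ann, 1.28)
  expect_equal(msp(rec, ann)$value, 8 * ip$psd[1], tolerance = 0.01)
  short <- fixed_annotation(0, 7 * 1.28)  # 7 ictal segments
  expect_equal(msp(rec, short)$missing_reason, "ictal_too_short")
})

test_that("MSP's maximizing window covers a mid-seizure burst", {
  fs <- 200
  t <- (0:(40 * fs - 1)) / fs
  x <- 20 * sin(2 * pi * 8 * t)
  burst <- t >= 15 & t < 15 + 8 * 1.28
  x[burst] <- 120 * sin(2 * pi * 8 * t[burst])
  rec <- eeg_record(x, fs, 0)
  ann <- fixed_annotation(0, 38.4)
  full_burst_psd <- 8 * max(ictal:::ictal_segment_psd(rec, ann, 1.28)$psd)
  expect_gt(msp(rec, ann)$value, 0.8 * full_burst_psd)
})

test_that("TTPP finds the scripted power peak and stays within duration", {
  g <- generate_record(synth_config(seed = 60, peak_frac = 0.5,
                                    ictal_s = 32))
  tt <- ttpp(g$record, g$annotation)
  # envelope peaks at peak_frac * (ictal_s - tail) = 10 s after onset
  expect_equal(tt$value, 10, tolerance = 1.28)
  expect_lte(tt$value, g$annotation$duration)
  # a decaying tone peaks in the first ictal segment
  t <- (0:5999) / 200
  rec <- eeg_record(50 * exp(-t / 8) * sin(2 * pi * 10 * t), 200, 0)
  expect_equal(ttpp(rec, fixed_annotation(0, 25.6))$value, 0)
})

test_that("EIA matches closed forms and MIA dominates it", {
  rec_c <- eeg_record(matrix(5, 8000, 1), 200, 0)
  ann <- fixed_annotation(0, 12 * 1.28)
  expect_equal(eia(rec_c, ann)$value, 5)
  a <- 80
  rec_s <- sine_record(10, amp = a, dur = 40)
  expect_equal(eia(rec_s, ann)$value, 2 * a / pi, tolerance = 0.01)
  # stationary: mia equals eia; and mia is always >= eia
  expect_equal(mia(rec_s, ann)$value, eia(rec_s, ann)$value,
               tolerance = 0.01)
  g <- generate_record(synth_config(seed = 61))
  expect_gte(mia(g$record, g$annotation)$value + 1e-9,
             eia(g$record, g$annotation)$value)
  # sign flip leaves mia unchanged
  flipped <- g$record
  flipped$channels <- -flipped$channels
  expect_equal(mia(flipped, g$annotation)$value,
               mia(g$record, g$annotation)$value)
  short <- fixed_annotation(0, 7 * 1.28)
  expect_equal(mia(rec_s, short)$missing_reason, "ictal_too_short")
  expect_equal(eia(rec_s, short)$missing_reason, "ictal_too_short")
})

test_that("a mid-seizure amplitude doubling doubles MIA", {
  fs <- 200
  t <- (0:(50 * fs - 1)) / fs
  x <- 30 * sin(2 * pi * 9 * t)
  x[t >= 20 & t < 35] <- 2 * x[t >= 20 & t < 35]
  rec <- eeg_record(x, fs, 0)
  ann <- fixed_annotation(0, 48)
  base_maa <- mean(abs(30 * sin(2 * pi * 9 * t[1:(10 * fs)])))
  expect_equal(mia(rec, ann)$value, 2 * base_maa, tolerance = 0.02)
})

test_that("PSI follows its closed form and clips at zero", {
  fs <- 200
  make_rec <- function(post_scale) {
    t <- (0:(60 * fs - 1)) / fs
    x <- 100 * sin(2 * pi * 9 * t)
    x[t >= 30] <- post_scale * x[t >= 30]
    eeg_record(x, fs, 0)
  }
  ann <- fixed_annotation(0, 30)
  expect_equal(psi(make_rec(0), ann)$value, 100, tolerance = 0.5)
  expect_equal(psi(make_rec(0.2), ann)$value, 80, tolerance = 0.5)
  expect_equal(psi(make_rec(1.5), ann)$value, 0)   # postictal increase
  # record ending right after the endpoint cannot support PSI
  short <- make_rec(0.2)
  short$channels <- short$channels[1:(33 * fs), , drop = FALSE]
  expect_equal(psi(short, ann)$missing_reason, "postictal_too_short")
})

test_that("coherence is 100% for identical channels and low for noise", {
  set.seed(62)
  x <- rnorm(8000, sd = 30)
  same <- eeg_record(cbind(x, x), 200, 0)
  ann <- fixed_annotation(0, 38.4)
  expect_equal(coh(same, ann)$value, 100, tolerance = 1e-6)
  indep <- eeg_record(cbind(rnorm(8000, sd = 30), rnorm(8000, sd = 30)),
                      200, 0)
  expect_lt(coh(indep, ann)$value, 30)
  # invariant to per-channel amplitude scaling
  scaled <- same
  scaled$channels[, 1] <- scaled$channels[, 1] * 7
  scaled$channels[, 2] <- scaled$channels[, 2] * 0.3
  expect_equal(coh(scaled, ann)$value, coh(same, ann)$value,
               tolerance = 1e-9)
  single <- eeg_record(x, 200, 0)
  expect_equal(coh(single, ann)$missing_reason, "single_channel")
  expect_equal(coh(same, fixed_annotation(0, 6))$missing_reason,
               "ictal_too_short")
})

test_that("compute_indices reports per-index missing reasons, no errors", {
  g <- generate_record(synth_config(seed = 63))
  no_seiz <- seizure_annotation(status = "no_seizure")
  qi <- compute_indices(g$record, no_seiz)
  expect_true(all(qi$missing_reason == "no_endpoint"))
  # a 6-segment seizure keeps duration but loses the 8-segment indices
  short_ann <- fixed_annotation(7, 7 + 6 * 1.28)
  qi2 <- compute_indices(g$record, short_ann)
  expect_equal(qi2$missing_reason[qi2$index == "duration"], "ok")
  for (ix in c("eia", "mia", "msp")) {
    expect_equal(qi2$missing_reason[qi2$index == ix], "ictal_too_short")
  }
  # a full two-channel synthetic seizure yields all eight
  qi3 <- compute_indices(g$record, g$annotation)
  expect_true(all(qi3$missing_reason == "ok"))
  expect_true(all(qi3$value[qi3$index %in% c("psi", "coh")] <= 100))
})

test_that("indices obey their amplitude-scaling laws", {
  g <- generate_record(synth_config(seed = 64))
  rec <- g$record; ann <- g$annotation
  scaled <- rec
  scaled$channels <- scaled$channels * 3
  expect_equal(eia(scaled, ann)$value, 3 * eia(rec, ann)$value,
               tolerance = 1e-9)
  expect_equal(mia(scaled, ann)$value, 3 * mia(rec, ann)$value,
               tolerance = 1e-9)
  expect_equal(asei(scaled, ann)$value, 9 * asei(rec, ann)$value,
               tolerance = 1e-9)
  expect_equal(msp(scaled, ann)$value, 9 * msp(rec, ann)$value,
               tolerance = 1e-9)
  for (ix in c("duration", "psi", "coh", "ttpp")) {
    f <- get(if (ix == "duration") "seizure_duration" else ix,
             envir = asNamespace("ictal"))
    v1 <- if (ix == "duration") f(ann) else f(rec, ann)
    v2 <- if (ix == "duration") f(ann) else f(scaled, ann)
    expect_equal(v2$value, v1$value, tolerance = 1e-9)
  }
})

test_that("whole-window time shifts leave every index unchanged", {
  g <- generate_record(synth_config(seed = 65, baseline_s = 5.12,
                                    postictal_s = 15))
  rec <- g$record; ann <- g$annotation
  shift <- 2 * 1.28
  spw <- round(shift * rec$sampling_rate)
  shifted <- rec
  shifted$channels <- rec$channels[-seq_len(spw), , drop = FALSE]
  shifted$stimulus_end <- rec$stimulus_end - shift
  ann2 <- fixed_annotation(ann$onset_time - shift,
                           ann$endpoint_time - shift)
  qi1 <- compute_indices(rec, ann)
  qi2 <- compute_indices(shifted, ann2)
  expect_equal(qi2$value[qi2$index != "duration"],
               qi1$value[qi1$index != "duration"], tolerance = 1e-9)
})

test_that("batch index tables tabulate missing reasons", {
  g1 <- generate_record(synth_config(seed = 66), record_id = "a")
  g2 <- generate_record(synth_config(seed = 67), record_id = "b")
  tab <- indices_table(list(g1$record, g2$record),
                       list(g1$annotation,
                            seizure_annotation(status = "no_seizure")))
  expect_equal(nrow(tab), 16)
  mc <- attr(tab, "missing_counts")
  expect_equal(sum(mc), 8)  # record b misses all eight
})
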