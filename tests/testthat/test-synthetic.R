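test_that("schedule validation names the offending field", {
  ep <- tibble::tibble(start_s = 0, end_s = 60, freq_hz = 0.2, duty = 0.3,
                       amplitude = 1)
  expect_error(synth_schedule(dplyr::mutate(ep, freq_hz = 0)), "freq_hz")
  expect_error(synth_schedule(dplyr::mutate(ep, duty = 1.5)), "duty")
  expect_error(synth_schedule(dplyr::mutate(ep, end_s = 0)), "epochs")
  expect_error(
    synth_schedule(tibble::tibble(start_s = c(0, 50), end_s = c(60, 100),
                                  freq_hz = 0.2, duty = 0.3, amplitude = 1)),
    "non-overlapping")
  expect_error(synth_schedule(ep, noise_sd = -1), "noise_sd")
  expect_error(synth_schedule(ep, channel_phase_offsets = c(bad = 0)),
               "channel_phase_offsets")
})

test_that("burst counts follow frequency x duration on every channel", {
  vr <- generate_ventral_root(alt_schedule(dur_s = 60, freq_hz = 0.2,
                                           duty = 0.3))
  counts <- table(vr$truth$channel)
  expect_setequal(names(counts), c("lL2", "rL2", "lL5", "rL5"))
  expect_true(all(counts == 12))

  # conservation within one-burst edge effects across frequencies
  for (f in c(0.1, 0.25, 0.5)) {
    vrf <- generate_ventral_root(alt_schedule(dur_s = 90, freq_hz = f))
    n <- sum(vrf$truth$channel == "lL2")
    expect_lte(abs(n - floor(f * 90)), 1)
  }
})

test_that("seeding contract: identical seed reproduces, different seed differs", {
  a <- generate_ventral_root(alt_schedule(noise_sd = 0.1, seed = 7L, dur_s = 20))
  b <- generate_ventral_root(alt_schedule(noise_sd = 0.1, seed = 7L, dur_s = 20))
  c <- generate_ventral_root(alt_schedule(noise_sd = 0.1, seed = 8L, dur_s = 20))
  expect_identical(a$recording, b$recording)
  expect_identical(a$truth, b$truth)
  expect_false(identical(a$recording$lL2, c$recording$lL2))
})

test_that("zero offsets and zero noise give sample-identical channels", {
  sched <- synth_schedule(
    tibble::tibble(start_s = 0, end_s = 30, freq_hz = 0.3, duty = 0.3,
                   amplitude = 1),
    channel_phase_offsets = c(lL2 = 0, rL2 = 0, lL5 = 0, rL5 = 0),
    noise_sd = 0, fs = 200)
  vr <- generate_ventral_root(sched)
  expect_identical(vr$recording$lL2, vr$recording$rL2)
  expect_identical(vr$recording$lL2, vr$recording$lL5)
  expect_identical(vr$recording$lL2, vr$recording$rL5)
})

test_that("dose series recovers each programmed frequency through the pipeline", {
  doses <- c(0.21, 0.34, 0.43)
  series <- generate_dose_series(doses, alt_schedule(dur_s = 180))
  expect_length(series, 3)
  for (i in seq_along(series)) {
    ev <- detect_channel(series[[i]], "lL2")
    est <- locomotor_parameters(ev, c(0, 180))$frequency_hz
    expect_lt(abs(est - doses[i]), 1 / 180 + 1e-9)
  }
  expect_length(generate_dose_series(0.3, alt_schedule(dur_s = 30)), 1)
  expect_error(generate_dose_series(numeric(0), alt_schedule()), "non-empty")
  expect_error(generate_dose_series(c(0.2, 0), alt_schedule()), "> 0")
})

test_that("CNO time course ramps between the programmed plateaus", {
  cno <- generate_cno_timecourse(0.30, -10, onset_s = 600, ramp_s = 300,
                                 total_s = 1800, fs = 100)
  expect_equal(unname(cno$plateaus), c(0.30, 0.27))
  ev <- dplyr::filter(cno$truth, channel == "lL2")
  wf <- windowed_frequency(ev, 120, c(0, 1800))
  early <- mean(wf$frequency_hz[wf$bin_end_s <= 600])
  late <- mean(wf$frequency_hz[wf$bin_start_s >= 900])
  # one-burst quantization on 120-s bins is 1/120 Hz
  expect_lt(abs(late / early - 0.90), 2 * (1 / 120) / 0.30)
  expect_error(generate_cno_timecourse(0.3, -100, 60, 60, 300),
               "percent_change")
})

test_that("zero percent change yields a stationary rhythm", {
  cno <- generate_cno_timecourse(0.30, 0, onset_s = 100, ramp_s = 50,
                                 total_s = 400, fs = 100)
  ev <- dplyr::filter(cno$truth, channel == "lL2")
  expect_true(all(abs(diff(ev$onset_s) - 1 / 0.30) < 1e-9))
})

test_that("light epochs contain all bursts when baseline is silent", {
  li <- generate_light_epoch(0, 0.27, light_onsets_s = 100,
                             light_window_s = 20, total_s = 200, fs = 1000)
  ev <- dplyr::filter(li$truth, channel == "lL2")
  expect_true(all(ev$onset_s >= 100 & ev$onset_s < 120))
  expect_gt(nrow(ev), 0)
  # a 30-s epoch at 1 kHz spans 30,000 samples
  li30 <- generate_light_epoch(0.1, 0.3, light_onsets_s = 60,
                               light_window_s = 30, total_s = 150, fs = 1000)
  ep <- li30$light_epochs
  expect_equal((ep$end_s - ep$start_s) * 1000, 30000)
  expect_error(
    generate_light_epoch(0, 0.3, light_onsets_s = c(10, 20),
                         light_window_s = 20, total_s = 100),
    "overlap")
})

test_that("light at baseline frequency is statistically indistinguishable", {
  li <- generate_light_epoch(0.3, 0.3, light_onsets_s = 60,
                             light_window_s = 30, total_s = 150, fs = 100)
  ev <- dplyr::filter(li$truth, channel == "lL2")
  # constant rate throughout: all inter-onset intervals equal
  expect_true(all(abs(diff(ev$onset_s) - 1 / 0.3) < 1e-9))
})

test_that("calcium movie has duration x rate frames and localized energy", {
  cs <- small_antiphase_movie(duration_s = 30)
  expect_equal(dim(cs$movie$frames)[3], 300)
  # noiseless: pixels outside all footprints are temporally constant
  osc <- cs$truth$oscillators
  mask <- matrix(FALSE, 80, 100)
  for (k in seq_len(nrow(osc))) {
    mask[osc$row0[k]:osc$row1[k], osc$col0[k]:osc$col1[k]] <- TRUE
  }
  outside <- which(!mask, arr.ind = TRUE)[1:50, ]
  for (i in seq_len(nrow(outside))) {
    px <- cs$movie$frames[outside[i, 1], outside[i, 2], ]
    expect_equal(stats::sd(px), 0)
  }
})

test_that("movie with no oscillators and no noise is constant", {
  cs <- generate_calcium_movie(oscillators = tibble::tibble(
    row0 = integer(0), row1 = integer(0), col0 = integer(0),
    col1 = integer(0), side = character(0)),
    duration_s = 10, height = 40, width = 50, noise_sd = 0)
  expect_equal(max(cs$movie$frames) - min(cs$movie$frames), 0)
})

test_that("half-cycle left-right offset anticorrelates the drive traces", {
  cs <- small_antiphase_movie(duration_s = 60)
  left_k <- which(cs$truth$oscillators$side == "left")
  right_k <- which(cs$truth$oscillators$side == "right")
  tr_l <- cs$truth$drive_traces[, left_k[1]]
  tr_r <- cs$truth$drive_traces[, right_k[1]]
  expect_lt(cor(tr_l, tr_r), -0.5)
})

test_that("oscillator footprints outside the frame are rejected", {
  expect_error(
    generate_calcium_movie(
      oscillators = tibble::tibble(row0 = 1, row1 = 200, col0 = 1, col1 = 10,
                                   side = "left"),
      duration_s = 5, height = 40, width = 50),
    "footprint")
})

test_that("recording round-trips through TSV + YAML sidecar", {
  vr <- generate_ventral_root(alt_schedule(dur_s = 10, noise_sd = 0.05))
  tmp <- tempfile(fileext = ".tsv")
  write_recording(vr$recording, tmp, fs = vr$fs,
                  annotations = list(drug_onset_s = 0))
  back <- read_recording(tmp)
  expect_equal(back$fs, vr$fs)
  expect_equal(back$annotations$drug_onset_s, 0)
  expect_equal(as.data.frame(back$recording), as.data.frame(vr$recording),
               tolerance = 1e-6)
})

test_that("calcium movie round-trips through 16-bit TIFF + JSON sidecar", {
  cs <- generate_calcium_movie(n_per_side = 1, duration_s = 5, height = 40,
                               width = 50, noise_sd = 0.5, seed = 3L)
  tmp <- tempfile(fileext = ".tif")
  write_calcium_movie(cs$movie, tmp)
  back <- read_calcium_movie(tmp)
  expect_equal(back$fs, cs$movie$fs)
  expect_equal(back$landmarks$left_col, cs$movie$landmarks$left_col)
  rng <- max(cs$movie$frames) - min(cs$movie$frames)
  expect_lt(max(abs(back$frames - cs$movie$frames)), rng / 65535 * 2)
})
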