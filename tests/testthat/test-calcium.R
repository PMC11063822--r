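test_that("the grid is 500 disjoint ROIs covering the field, 250 per side", {
  grid <- build_grid()
  expect_equal(nrow(grid), 500)
  expect_equal(sum(grid$side == "right"), 250)
  expect_equal(sum(grid$side == "left"), 250)
  expect_true(all(grid$roi_id[grid$side == "right"] <= 250))
  expect_true(all(grid$roi_id[grid$side == "left"] > 250))
  ids <- spinalrhythm:::grid_pixel_ids(grid)
  expect_true(all(ids > 0))                    # covering
  expect_equal(dim(ids), c(400, 500))
  expect_true(all(table(ids) == 400))          # 25 x 16 px each, disjoint
  expect_error(build_grid(400, 500), "500 columns")
})

test_that("field normalization emits 400 x 500 and is identity when already normalized", {
  cs <- small_antiphase_movie(duration_s = 10)
  nm <- normalize_field(cs$movie)
  expect_equal(dim(nm$frames)[1:2], c(400, 500))
  expect_true(nm$normalized)
  # re-normalizing a normalized movie changes nothing (landmarks at borders)
  nm2 <- normalize_field(nm)
  expect_lt(max(abs(nm2$frames - nm$frames)), 1e-9)
})

test_that("a point source at the left cord edge maps to the first columns", {
  frames <- array(0, dim = c(40, 60, 5))
  frames[20, 11, ] <- 100   # at the left edge landmark
  mv <- calcium_movie(frames, 10,
                      landmarks = list(canal = c(row = 20, col = 30.5),
                                       left_col = 10.5, right_col = 50.5,
                                       dorsal_row = 5.5, ventral_row = 35.5))
  nm <- normalize_field(mv)
  hot <- which(nm$frames[, , 1] > 0, arr.ind = TRUE)
  expect_lte(min(hot[, 2]), 2)
  bad <- calcium_movie(frames, 10,
                       landmarks = list(canal = c(row = 20, col = 10.5),
                                        left_col = 10.5, right_col = 50.5,
                                        dorsal_row = 5.5, ventral_row = 35.5))
  expect_error(normalize_field(bad), "degenerate")
})

test_that("dF is zero on constant movies and follows its definition", {
  frames <- array(7, dim = c(40, 50, 150))
  mv <- calcium_movie(frames, 10, normalized = TRUE)
  mv$frames <- array(7, dim = c(400, 500, 150))
  grid <- build_grid()
  tr <- extract_delta_f(mv, grid)
  expect_false(tr$normalized)  # no positive signal to scale by
  expect_true(all(tr$traces == 0))

  # one ROI reads 12 on one frame against a trailing baseline of 10
  frames2 <- array(10, dim = c(400, 500, 150))
  frames2[grid$row0[7]:grid$row1[7], grid$col0[7]:grid$col1[7], 20] <- 12
  mv2 <- calcium_movie(frames2, 10, normalized = TRUE)
  tr2 <- extract_delta_f(mv2, grid)
  expect_equal(tr2$global_max_df, 2)
  expect_equal(max(tr2$traces), 1)  # normalized global max is 1
  expect_equal(unname(tr2$traces[20, 7]), 1)
})

test_that("dF is linear in intensity and normalization removes the scale", {
  cs <- small_antiphase_movie(duration_s = 20)
  nm <- normalize_field(cs$movie)
  grid <- build_grid()
  tr1 <- extract_delta_f(nm, grid)
  nm_k <- nm
  nm_k$frames <- nm$frames * 3
  tr3 <- extract_delta_f(nm_k, grid)
  expect_equal(tr3$global_max_df, 3 * tr1$global_max_df, tolerance = 1e-9)
  expect_equal(tr3$traces, tr1$traces, tolerance = 1e-9)
})

test_that("the 500 ROI means conserve the whole-field mean frame by frame", {
  cs <- small_antiphase_movie(duration_s = 15, noise_sd = 1)
  nm <- normalize_field(cs$movie)
  grid <- build_grid()
  idvec <- as.vector(spinalrhythm:::grid_pixel_ids(grid))
  for (tt in c(1, 50, 150)) {
    f <- nm$frames[, , tt]
    roi_means <- rowsum(as.vector(f), idvec)[, 1] / 400
    expect_equal(mean(roi_means), mean(f), tolerance = 1e-12)
  }
})

test_that("the low-pass keeps slow oscillations and rejects fast ones", {
  fs <- 10
  t <- (0:1799) / fs
  slow <- sin(2 * pi * 0.4 * t)
  fast <- sin(2 * pi * 4.9 * t)
  grid <- build_grid()
  x <- make_roi_traces(cbind(slow, fast, 0 * t), fs, grid)
  y <- preprocess_traces(x, lowpass_hz = 2)
  amp <- function(v) (max(v) - min(v)) / 2
  expect_gt(amp(y$traces[, 1]), 0.98 * amp(slow))
  expect_lt(amp(y$traces[100:1700, 2]), 0.1 * amp(fast))
  expect_lt(max(abs(y$traces[, 3])), 1e-9)          # constant -> zero
  expect_lt(abs(mean(y$traces[, 1])), 1e-6)         # DC removed
  expect_error(preprocess_traces(x, lowpass_hz = 5), "Nyquist")
})

test_that("oscillation index hits 2 for sinusoids, stays near 0 for noise", {
  fs <- 10
  t <- (0:1999) / fs
  x <- sin(2 * pi * 0.4 * t)
  idx <- oscillation_index(x, fs, c(2, 3))
  expect_gt(idx, 1.98)
  # white-noise null, seed-averaged
  idx_noise <- mean(vapply(1:5, function(s) {
    set.seed(s)
    oscillation_index(rnorm(1800), fs, c(2, 3))
  }, numeric(1)))
  expect_lt(idx_noise, 0.2)
  expect_equal(oscillation_index(rep(1, 100), fs, c(2, 3)), 0)
})

test_that("oscillation index grows monotonically with SNR", {
  fs <- 10
  t <- (0:1799) / fs
  sig <- sin(2 * pi * 0.4 * t)
  idx_by_snr <- vapply(c(0.25, 0.5, 1, 2, 4), function(snr) {
    mean(vapply(1:3, function(s) {
      set.seed(s)
      oscillation_index(sig * snr + rnorm(length(t)), fs, c(2, 3))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(idx_by_snr) > 0))
})

test_that("index maps share one divisor across the two hemifields", {
  grid <- build_grid()
  raw <- rep(0.2, 500)
  raw[430] <- 1.6            # left-side ROI holds the global max
  m <- normalize_index_map(raw, grid)
  expect_equal(m$norm[m$roi_id == 430], 1)
  expect_lt(max(m$norm[m$side == "right"]), 1)   # shared divisor
  uni <- normalize_index_map(rep(0.7, 500), grid)
  expect_true(all(uni$norm == 1))
  zero <- normalize_index_map(rep(0, 500), grid)
  expect_true(attr(zero, "all_zero"))
  expect_true(all(zero$norm == 0))
})

test_that("averaged maps pick the reference from the mean, not any input", {
  grid <- build_grid()
  m1 <- normalize_index_map(replace(rep(0.1, 500), 10, 1), grid)
  m2 <- normalize_index_map(replace(rep(0.8, 500), 200, 1), grid)
  single <- average_maps_and_reference(list(m1))
  expect_equal(single$reference_roi, 10)
  both <- average_maps_and_reference(list(m1, m2))
  avg <- (m1$norm + m2$norm) / 2
  expect_equal(both$reference_roi, which.max(avg))
  g2 <- grid[c(2:500, 1), ]
  m_bad <- normalize_index_map(rep(1, 500), g2)
  expect_error(average_maps_and_reference(list(m1, m_bad)), "grids")
})

test_that("phase map is 0 at the reference and additive under delays", {
  fs <- 10
  period <- 2.5
  t <- (0:1199) / fs
  ref <- sin(2 * pi * t / period)
  quarter <- round(period * fs / 4)
  delayed <- c(rep(0, quarter), ref)[1:length(ref)]
  flat <- rep(0, length(ref))
  grid <- build_grid()
  x <- make_roi_traces(cbind(ref, delayed, flat), fs, grid)
  pm <- phase_map(x, reference_roi = grid$roi_id[1], cycle_period_s = period)
  expect_equal(pm$phase[1], 0)
  expect_equal(pm$phase[2], quarter / (period * fs), tolerance = 0.02)
  expect_true(is.na(pm$phase[3]))

  # delaying any trace by delta adds delta/period (mod 1)
  for (lag_n in c(5, 12, 20)) {
    shifted <- c(rep(0, lag_n), ref)[1:length(ref)]
    xs <- make_roi_traces(cbind(ref, shifted), fs, grid)
    pms <- phase_map(xs, grid$roi_id[1], period)
    expect_equal(pms$phase[2], (lag_n / fs / period) %% 1, tolerance = 0.03)
  }
})

test_that("ROIs locked to one root are in phase with it and anti-phase with the other", {
  fs <- 10
  period <- 2.5
  t <- (0:1199) / fs
  onsets_i <- seq(0.25, max(t), by = period)
  onsets_c <- onsets_i + period / 2
  mk <- function(on) tibble::tibble(onset_s = on, offset_s = on + 1)
  trace <- vapply(t, function(tt) {
    any(tt >= onsets_i & tt < onsets_i + 1) * 1.0
  }, numeric(1))
  grid <- build_grid()
  x <- make_roi_traces(cbind(trace, trace), fs, grid)
  rp <- root_phase_comparison(x, mk(onsets_i), mk(onsets_c), period)
  expect_lt(min(rp$phase_vs_ipsi[1], 1 - rp$phase_vs_ipsi[1]), 0.05)
  expect_lt(abs(rp$phase_vs_contra[1] - 0.5), 0.05)
  # synchronous trains give equal phases
  rp_same <- root_phase_comparison(x, mk(onsets_i), mk(onsets_i), period)
  expect_equal(rp_same$phase_vs_ipsi, rp_same$phase_vs_contra)
  expect_error(
    root_phase_comparison(x, mk(onsets_i + 1e5), mk(onsets_c), period),
    "overlap")
})

test_that("autoplot methods return ggplot objects", {
  grid <- build_grid()
  m <- normalize_index_map(runif(500), grid)
  expect_s3_class(autoplot(m), "ggplot")
  pm <- m
  pm$phase <- runif(500)
  class(pm) <- c("phase_map", class(tibble::tibble()))
  expect_s3_class(autoplot(pm), "ggplot")
  preps <- lapply(c(170, 180, 190), function(m) {
    tibble::tibble(cycle = 1:4, angle_deg = rep(m, 4))
  })
  expect_s3_class(autoplot(summarize_coordination(preps)), "ggplot")
  vr <- generate_ventral_root(alt_schedule(dur_s = 10))
  expect_s3_class(plot_recording(vr$recording), "ggplot")
})
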