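#' Build a synthesis schedule for ventral-root-like recordings
#'
#' A schedule is the full parametrisation of a synthetic fictive-locomotion
#' recording: a set of non-overlapping epochs, each with its own burst
#' frequency, duty cycle and amplitude, plus per-channel phase offsets, a
#' noise level, the sampling rate of the rendered envelope and the RNG seed.
#'
#' The default phase offsets encode the alternating gait of drug-induced
#' locomotor-like activity: left and right flexor roots (L2) alternate
#' (180 degrees), ipsilateral flexor and extensor roots (L2 vs L5) alternate,
#' and diagonal roots are synchronous.
#'
#' @param epochs Data frame with columns `start_s`, `end_s`, `freq_hz`,
#'   `duty`, `amplitude`. Epochs must be ordered and non-overlapping.
#' @param channel_phase_offsets Named numeric vector of phase offsets in
#'   degrees relative to the left-L2 reference. Names select the channels to
#'   synthesize (any subset of `lL2`, `rL2`, `lL5`, `rL5`).
#' @param noise_sd Standard deviation of additive Gaussian noise (a.u.) on
#'   the rendered envelope.
#' @param fs Sampling rate of the rendered envelope in Hz.
#' @param seed Integer RNG seed; every random draw in the generators comes
#'   from one generator seeded with this value.
#' @param taper Fraction of each burst spent in the raised-cosine onset and
#'   offset ramps (the middle `1 - 2 * taper` of the burst is flat).
#' @return An object of class `synth_schedule`.
#' @export
#' @examples
#' sched <- synth_schedule(
#'   epochs = tibble::tibble(start_s = 0, end_s = 60, freq_hz = 0.2,
#'                           duty = 0.3, amplitude = 1))
synth_schedule <- function(epochs,
                           channel_phase_offsets = c(lL2 = 0, rL2 = 180,
                                                     lL5 = 180, rL5 = 0),
                           noise_sd = 0, fs = 1000, seed = 1L,
                           taper = 0.25) {
  epochs <- as_tibble(epochs)
  req <- c("start_s", "end_s", "freq_hz", "duty", "amplitude")
  missing_cols <- setdiff(req, names(epochs))
  if (length(missing_cols) > 0) {
    abort(paste0("epochs: missing column(s) ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(epochs) == 0) abort("epochs: at least one epoch is required")
  if (any(epochs$end_s <= epochs$start_s)) abort("epochs: end_s must exceed start_s")
  if (nrow(epochs) > 1) {
    if (any(diff(epochs$start_s) <= 0) ||
        any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
      abort("epochs: must be ordered and non-overlapping")
    }
  }
  if (any(epochs$freq_hz <= 0)) abort("freq_hz: must be > 0")
  if (any(epochs$duty <= 0 | epochs$duty > 1)) abort("duty: must be in (0, 1]")
  if (any(epochs$amplitude < 0)) abort("amplitude: must be >= 0")
  if (is.null(names(channel_phase_offsets)) ||
      !all(names(channel_phase_offsets) %in% c("lL2", "rL2", "lL5", "rL5"))) {
    abort("channel_phase_offsets: names must be among lL2, rL2, lL5, rL5")
  }
  if (!is.numeric(fs) || fs <= 0) abort("fs: must be > 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("noise_sd: must be >= 0")
  if (taper <= 0 || taper > 0.5) abort("taper: must be in (0, 0.5]")
  structure(
    list(epochs = epochs,
         channel_phase_offsets = channel_phase_offsets %% 360,
         noise_sd = noise_sd, fs = fs, seed = as.integer(seed),
         taper = taper),
    class = "synth_schedule")
}

# Raised-cosine burst envelope on a relative position u in [0, 1].
burst_window <- function(u, taper) {
  w <- numeric(length(u))
  inside <- u >= 0 & u <= 1
  ui <- u[inside]
  wi <- rep(1, length(ui))
  lo <- ui < taper
  hi <- ui > 1 - taper
  wi[lo] <- 0.5 * (1 - cos(pi * ui[lo] / taper))
  wi[hi] <- 0.5 * (1 - cos(pi * (1 - ui[hi]) / taper))
  w[inside] <- wi
  w
}

# Burst onset times for one channel across the schedule's epochs.
schedule_onsets <- function(epochs, offset_deg) {
  purrr::pmap_dfr(epochs, function(start_s, end_s, freq_hz, duty, amplitude) {
    period <- 1 / freq_hz
    shift <- (offset_deg %% 360) / 360 * period
    onsets <- seq(start_s + shift, end_s, by = period)
    onsets <- onsets[onsets < end_s]
    tibble(onset_s = onsets,
           offset_s = onsets + duty * period,
           amplitude = amplitude,
           freq_hz = freq_hz,
           duty = duty)
  })
}

# Render a burst train as an envelope over a fixed time grid.
render_bursts <- function(time_s, bursts, fs, taper) {
  env <- numeric(length(time_s))
  if (nrow(bursts) == 0) return(env)
  for (b in seq_len(nrow(bursts))) {
    on <- bursts$onset_s[b]
    dur <- bursts$offset_s[b] - on
    i0 <- max(1L, floor(on * fs) + 1L)
    i1 <- min(length(time_s), ceiling((on + dur) * fs) + 1L)
    if (i1 < i0) next
    idx <- i0:i1
    u <- (time_s[idx] - on) / dur
    env[idx] <- pmax(env[idx], bursts$amplitude[b] * burst_window(u, taper))
  }
  env
}

#' Generate a synthetic four-channel ventral-root recording
#'
#' Renders every channel of the schedule as a train of raised-cosine burst
#' envelopes plus additive Gaussian noise, and returns the recording together
#' with its ground truth (every programmed burst, per channel and epoch).
#' Identical schedules (including the seed) produce bit-identical output.
#'
#' @param schedule A [synth_schedule()].
#' @return A list of class `vr_synth` with elements `recording` (tibble with
#'   `time_s` plus one column per channel), `truth` (tibble of programmed
#'   bursts: `channel`, `epoch`, `onset_s`, `offset_s`, `amplitude`,
#'   `freq_hz`, `duty`), `fs` and `schedule`.
#' @export
generate_ventral_root <- function(schedule) {
  if (!inherits(schedule, "synth_schedule")) {
    abort("schedule: must be a synth_schedule object")
  }
  fs <- schedule$fs
  total_s <- max(schedule$epochs$end_s)
  n <- round(fs * total_s)
  time_s <- (seq_len(n) - 1) / fs
  channels <- names(schedule$channel_phase_offsets)

  truth <- purrr::map_dfr(channels, function(ch) {
    off <- schedule$channel_phase_offsets[[ch]]
    ep <- schedule$epochs
    purrr::map_dfr(seq_len(nrow(ep)), function(i) {
      b <- schedule_onsets(ep[i, ], off)
      if (nrow(b) == 0) return(b)
      dplyr::mutate(b, channel = ch, epoch = i, .before = 1)
    })
  })

  rec <- tibble(time_s = time_s)
  noise <- with_seed(schedule$seed, {
    purrr::map(channels, function(ch) {
      if (schedule$noise_sd > 0) rnorm(n, 0, schedule$noise_sd) else numeric(n)
    })
  })
  names(noise) <- channels
  for (ch in channels) {
    b <- dplyr::filter(truth, .data$channel == ch)
    rec[[ch]] <- render_bursts(time_s, b, fs, schedule$taper) + noise[[ch]]
  }

  structure(list(recording = rec, truth = truth, fs = fs, schedule = schedule),
            class = "vr_synth")
}

#' Generate a dose series of recordings at fixed programmed frequencies
#'
#' Emulates graded chemical excitation (e.g. increasing NMDA concentration):
#' one recording per requested frequency, all other schedule parameters
#' shared. Each element gets a distinct sub-seed derived from the base seed
#' so the series is reproducible as a whole.
#'
#' @param frequencies Numeric vector of burst frequencies in Hz (all > 0).
#' @param base_schedule A [synth_schedule()] used as the template; its epoch
#'   frequencies are replaced element-wise by each requested frequency.
#' @return List of `vr_synth` objects, one per frequency.
#' @export
generate_dose_series <- function(frequencies, base_schedule) {
  if (length(frequencies) == 0) abort("frequencies: must be non-empty")
  if (any(frequencies <= 0)) abort("frequencies: must be > 0")
  purrr::imap(frequencies, function(f, i) {
    ep <- dplyr::mutate(base_schedule$epochs, freq_hz = f)
    sched <- synth_schedule(ep, base_schedule$channel_phase_offsets,
                            base_schedule$noise_sd, base_schedule$fs,
                            base_schedule$seed + i - 1L, base_schedule$taper)
    generate_ventral_root(sched)
  })
}

# Onsets of a rate profile r(t): quasi-static stepping t_{k+1} = t_k + 1/r(t_k).
rate_profile_onsets <- function(rate_fun, total_s, t0 = 0) {
  onsets <- numeric(0)
  t <- t0
  repeat {
    r <- rate_fun(t)
    if (r <= 0) {
      # skip forward to the next time the rate becomes positive
      grid <- seq(t, total_s, by = 1)
      pos <- grid[vapply(grid, rate_fun, numeric(1)) > 0]
      if (length(pos) == 0) break
      t <- pos[1]
      next
    }
    if (t >= total_s) break
    onsets <- c(onsets, t)
    t <- t + 1 / r
  }
  onsets
}

#' Generate a slow chemogenetic-silencing (CNO-like) frequency time course
#'
#' The instantaneous burst rate stays at `baseline_hz` until `onset_s`, then
#' ramps linearly over `ramp_s` to `baseline_hz * (1 + percent_change/100)`
#' and stays on that plateau until `total_s`. Ground truth records both
#' plateau frequencies and every burst.
#'
#' @param baseline_hz Baseline burst frequency (Hz).
#' @param percent_change Plateau change in percent (negative = slowing); must
#'   be > -100.
#' @param onset_s,ramp_s,total_s Timing of the ramp (s); requires
#'   `total_s > onset_s + ramp_s`.
#' @param duty Duty cycle of each burst.
#' @param amplitude Burst amplitude (a.u.).
#' @param channel_phase_offsets,noise_sd,fs,seed,taper As in [synth_schedule()].
#' @return A `vr_synth` list; its `plateaus` element holds the programmed
#'   early and late plateau frequencies.
#' @export
generate_cno_timecourse <- function(baseline_hz, percent_change, onset_s,
                                    ramp_s, total_s,
                                    duty = 0.3, amplitude = 1,
                                    channel_phase_offsets = c(lL2 = 0, rL2 = 180,
                                                              lL5 = 180, rL5 = 0),
                                    noise_sd = 0, fs = 1000, seed = 1L,
                                    taper = 0.25) {
  if (percent_change <= -100) abort("percent_change: must be > -100")
  if (baseline_hz <= 0) abort("baseline_hz: must be > 0")
  if (total_s <= onset_s + ramp_s) abort("total_s: must exceed onset_s + ramp_s")
  final_hz <- baseline_hz * (1 + percent_change / 100)
  rate_fun <- function(t) {
    if (t < onset_s) baseline_hz
    else if (t < onset_s + ramp_s) {
      baseline_hz + (final_hz - baseline_hz) * (t - onset_s) / ramp_s
    } else final_hz
  }
  synth_from_rate(rate_fun, total_s, duty, amplitude, channel_phase_offsets,
                  noise_sd, fs, seed, taper,
                  extra = list(plateaus = c(early_hz = baseline_hz,
                                            late_hz = final_hz)))
}

# Shared renderer for generators defined by an instantaneous rate profile.
synth_from_rate <- function(rate_fun, total_s, duty, amplitude,
                            channel_phase_offsets, noise_sd, fs, seed, taper,
                            extra = list()) {
  n <- round(fs * total_s)
  time_s <- (seq_len(n) - 1) / fs
  channels <- names(channel_phase_offsets)
  base_onsets <- rate_profile_onsets(rate_fun, total_s)

  truth <- purrr::map_dfr(channels, function(ch) {
    off <- channel_phase_offsets[[ch]] %% 360
    rate <- vapply(base_onsets, rate_fun, numeric(1))
    onsets <- base_onsets + off / 360 / rate
    keep <- onsets < total_s
    tibble(channel = ch, epoch = 1L,
           onset_s = onsets[keep],
           offset_s = onsets[keep] + duty / rate[keep],
           amplitude = amplitude,
           freq_hz = rate[keep], duty = duty)
  })

  rec <- tibble(time_s = time_s)
  noise <- with_seed(seed, {
    purrr::map(channels, function(ch) {
      if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
    })
  })
  names(noise) <- channels
  for (ch in channels) {
    b <- dplyr::filter(truth, .data$channel == ch)
    rec[[ch]] <- render_bursts(time_s, b, fs, taper) + noise[[ch]]
  }
  structure(c(list(recording = rec, truth = truth, fs = fs), extra),
            class = "vr_synth")
}

#' Generate a recording with optogenetic-like light epochs
#'
#' Burst frequency steps from `baseline_hz` to `light_hz` inside each light
#' window and back outside it. A baseline of 0 Hz produces a non-rhythmic
#' recording with bursts only inside the light windows.
#'
#' @param baseline_hz Baseline frequency (Hz, may be 0).
#' @param light_hz Frequency during the light windows (Hz, > 0).
#' @param light_onsets_s Numeric vector of light-onset times (s).
#' @param light_window_s Duration of each light window (s), typically 20 or 30.
#' @param total_s Total recording duration (s).
#' @param duty,amplitude,channel_phase_offsets,noise_sd,fs,seed,taper As in
#'   [generate_cno_timecourse()].
#' @return A `vr_synth` list; its `light_epochs` element is a tibble of the
#'   programmed light windows.
#' @export
generate_light_epoch <- function(baseline_hz, light_hz, light_onsets_s,
                                 light_window_s = 20, total_s = NULL,
                                 duty = 0.3, amplitude = 1,
                                 channel_phase_offsets = c(lL2 = 0, rL2 = 180,
                                                           lL5 = 180, rL5 = 0),
                                 noise_sd = 0, fs = 1000, seed = 1L,
                                 taper = 0.25) {
  if (light_hz <= 0) abort("light_hz: must be > 0")
  if (baseline_hz < 0) abort("baseline_hz: must be >= 0")
  epochs <- tibble(start_s = light_onsets_s,
                   end_s = light_onsets_s + light_window_s)
  epochs <- dplyr::arrange(epochs, .data$start_s)
  if (nrow(epochs) > 1 &&
      any(epochs$start_s[-1] < epochs$end_s[-nrow(epochs)])) {
    abort("light_onsets_s: light windows overlap")
  }
  total_s <- total_s %||% (max(epochs$end_s) + light_window_s)
  if (max(epochs$end_s) > total_s) abort("light windows must fit in total_s")
  in_light <- function(t) any(t >= epochs$start_s & t < epochs$end_s)
  rate_fun <- function(t) if (in_light(t)) light_hz else baseline_hz
  synth_from_rate(rate_fun, total_s, duty, amplitude, channel_phase_offsets,
                  noise_sd, fs, seed, taper,
                  extra = list(light_epochs = epochs))
}

#' Generate a synthetic calcium-imaging movie with known oscillators
#'
#' Each oscillator is a rectangular pixel footprint driven by a periodic
#' burst train (raised-cosine bursts at `freq_hz`, phase given as a cycle
#' fraction) convolved with a single-exponential indicator-decay kernel.
#' Right-hemifield oscillators are offset from left ones by
#' `lr_phase_offset` cycles. A constant background and Gaussian noise are
#' added, and landmark annotations (cord edges, central canal) are attached
#' so the movie can be normalized.
#'
#' @param oscillators Optional tibble with columns `row0`, `row1`, `col0`,
#'   `col1` (inclusive pixel bounds), `side` (`"left"` or `"right"`),
#'   `amplitude` and optionally `phase` (cycle fraction). When `NULL`,
#'   `n_per_side` oscillators per side are placed in the ventromedial part of
#'   the cord.
#' @param n_per_side Number of default oscillators per side.
#' @param freq_hz Drive frequency in Hz.
#' @param fs Frame rate in frames/s.
#' @param duration_s Movie duration in s; `duration_s * fs` must be integral.
#' @param height,width Frame size in pixels.
#' @param lr_phase_offset Cycle-fraction offset of right-side oscillators
#'   relative to left-side ones (0.5 = strict alternation).
#' @param decay_tau Indicator decay constant in s.
#' @param noise_sd Gaussian noise SD (a.u.).
#' @param baseline Constant background intensity (a.u.).
#' @param duty Duty cycle of the drive bursts.
#' @param seed Integer RNG seed.
#' @return A list of class `calcium_synth` with `movie` (a `calcium_movie`:
#'   frames array `H x W x T`, `fs`, `landmarks`, `normalized` flag) and
#'   `truth` (oscillator table, drive frequency, phases, decay constant).
#' @export
generate_calcium_movie <- function(oscillators = NULL, n_per_side = 3,
                                   freq_hz = 0.4, fs = 10, duration_s = 180,
                                   height = 160, width = 200,
                                   lr_phase_offset = 0.5, decay_tau = 0.4,
                                   noise_sd = 0, baseline = 100,
                                   duty = 0.5, seed = 1L) {
  n_frames <- duration_s * fs
  if (abs(n_frames - round(n_frames)) > 1e-9) {
    abort("duration_s: duration_s * fs must be an integer number of frames")
  }
  n_frames <- as.integer(round(n_frames))

  # cord occupies an inset rectangle; canal at its centre column
  margin_r <- max(2L, round(height * 0.05))
  margin_c <- max(2L, round(width * 0.05))
  cord <- list(left = margin_c + 0.5, right = width - margin_c + 0.5,
               dorsal = margin_r + 0.5, ventral = height - margin_r + 0.5)
  canal_col <- (cord$left + cord$right) / 2
  canal_row <- (cord$dorsal + cord$ventral) / 2
  landmarks <- list(canal = c(row = canal_row, col = canal_col),
                    left_col = cord$left, right_col = cord$right,
                    dorsal_row = cord$dorsal, ventral_row = cord$ventral)

  osc <- oscillators
  if (is.null(osc)) {
    osc <- default_oscillators(n_per_side, cord, canal_col, canal_row)
  }
  osc <- as_tibble(osc)
  if (nrow(osc) > 0) {
    if (!"phase" %in% names(osc)) {
      osc$phase <- ifelse(osc$side == "right", lr_phase_offset %% 1, 0)
    }
    if (!"amplitude" %in% names(osc)) osc$amplitude <- 1
    bad <- osc$row0 < 1 | osc$row1 > height | osc$col0 < 1 | osc$col1 > width |
      osc$row0 > osc$row1 | osc$col0 > osc$col1
    if (any(bad)) abort("oscillators: footprint outside frame")
  }

  time_s <- (seq_len(n_frames) - 1) / fs
  period <- 1 / freq_hz
  a <- exp(-1 / (decay_tau * fs))

  frames <- array(baseline, dim = c(height, width, n_frames))
  traces <- matrix(0, nrow = n_frames, ncol = max(1, nrow(osc)))
  if (nrow(osc) > 0) {
    for (k in seq_len(nrow(osc))) {
      onsets <- seq(osc$phase[k] * period, duration_s, by = period)
      onsets <- onsets[onsets < duration_s]
      drive <- render_bursts(time_s,
                             tibble(onset_s = onsets,
                                    offset_s = onsets + duty * period,
                                    amplitude = osc$amplitude[k]),
                             fs, taper = 0.5)
      tr <- as.numeric(stats::filter(drive, a, method = "recursive"))
      tr <- tr * (1 - a)  # unit-gain normalisation of the decay kernel
      traces[, k] <- tr
      rows <- osc$row0[k]:osc$row1[k]
      cols <- osc$col0[k]:osc$col1[k]
      for (tt in seq_len(n_frames)) {
        frames[rows, cols, tt] <- frames[rows, cols, tt] + tr[tt] * 50
      }
    }
  }
  if (noise_sd > 0) {
    frames <- frames + with_seed(seed, array(rnorm(length(frames), 0, noise_sd),
                                             dim = dim(frames)))
  }

  movie <- structure(list(frames = frames, fs = fs, landmarks = landmarks,
                          normalized = FALSE),
                     class = "calcium_movie")
  truth <- list(oscillators = osc, freq_hz = freq_hz,
                lr_phase_offset = lr_phase_offset %% 1,
                decay_tau = decay_tau, drive_traces = traces,
                duration_s = duration_s)
  structure(list(movie = movie, truth = truth), class = "calcium_synth")
}

# Deterministic default placement: ventromedial clusters on each side.
default_oscillators <- function(n_per_side, cord, canal_col, canal_row) {
  h <- cord$ventral - cord$dorsal
  size_r <- max(4L, round(h * 0.08))
  size_c <- size_r
  purrr::map_dfr(c("left", "right"), function(side) {
    purrr::map_dfr(seq_len(n_per_side), function(i) {
      frac <- i / (n_per_side + 1)
      r0 <- round(canal_row + 0.10 * h + frac * 0.25 * h)
      lat <- if (side == "right") -1 else 1
      c0 <- round(canal_col + lat * (0.15 + 0.5 * frac) *
                    (cord$right - canal_col) / 2)
      tibble(row0 = r0, row1 = r0 + size_r - 1L,
             col0 = min(c0, c0 + lat * (size_c - 1L)),
             col1 = max(c0, c0 + lat * (size_c - 1L)),
             side = side)
    })
  })
}
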