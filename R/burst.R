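#' Rectify and smooth a raw channel into a burst envelope
#'
#' Takes the pointwise absolute value and applies a centred moving average of
#' `smooth_window_s` seconds, with edge replication so the output has the same
#' length as the input.
#'
#' @param x Numeric sample series.
#' @param fs Sampling rate (Hz).
#' @param smooth_window_s Moving-average window in seconds (>= 1/fs).
#' @return Non-negative numeric envelope, same length as `x`.
#' @export
rectify_and_smooth <- function(x, fs, smooth_window_s = 0.1) {
  if (length(x) == 0) abort("x: empty series")
  if (smooth_window_s < 1 / fs) abort("smooth_window_s: must be >= 1/fs")
  r <- abs(x)
  w <- max(1L, round(smooth_window_s * fs))
  if (w == 1L) return(r)
  half <- w %/% 2
  padded <- c(rep(r[1], half), r, rep(r[length(r)], w - half - 1))
  k <- rep(1 / w, w)
  sm <- stats::filter(padded, k, sides = 1)
  as.numeric(sm[(w):(w + length(r) - 1)])
}

#' Detect bursts in a rectified envelope
#'
#' Bursts are maximal intervals where the envelope exceeds
#' `valley_floor + threshold_frac * (global peak - valley_floor)`, where the
#' valley floor is the envelope minimum. Supra-threshold intervals separated
#' by gaps shorter than `min_interval_s` are merged; intervals shorter than
#' `min_duration_s` are dropped. Each event carries its internal peak and the
#' minimum of the preceding inter-burst gap as the valley.
#'
#' @param envelope Non-negative numeric envelope (from [rectify_and_smooth()]).
#' @param fs Sampling rate (Hz).
#' @param threshold_frac Fraction of the envelope range used as threshold,
#'   in (0, 1).
#' @param min_duration_s Minimum burst duration (s).
#' @param min_interval_s Gaps shorter than this are merged (s).
#' @return Tibble of class `burst_events` with columns `onset_s`, `offset_s`,
#'   `duration_s`, `peak_time_s`, `peak_amp`, `valley_amp`. A flat envelope
#'   yields zero rows with a warning.
#' @export
detect_bursts <- function(envelope, fs, threshold_frac = 0.3,
                          min_duration_s = 0.2, min_interval_s = 0.3) {
  if (length(envelope) == 0) abort("envelope: empty series")
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    abort("threshold_frac: must be in (0, 1)")
  }
  empty <- tibble(onset_s = numeric(0), offset_s = numeric(0),
                  duration_s = numeric(0), peak_time_s = numeric(0),
                  peak_amp = numeric(0), valley_amp = numeric(0))
  class(empty) <- c("burst_events", class(empty))
  floor_amp <- min(envelope)
  peak_amp <- max(envelope)
  if (peak_amp - floor_amp <= .Machine$double.eps * max(1, abs(peak_amp))) {
    warn("flat envelope: no bursts detected")
    return(empty)
  }
  thr <- floor_amp + threshold_frac * (peak_amp - floor_amp)
  above <- envelope > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iv <- cbind(starts[r$values], ends[r$values])
  if (nrow(iv) == 0) return(empty)

  # merge intervals separated by short gaps
  merged <- list()
  cur <- iv[1, ]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      gap_s <- (iv[i, 1] - cur[2] - 1) / fs
      if (gap_s < min_interval_s) {
        cur[2] <- iv[i, 2]
      } else {
        merged[[length(merged) + 1]] <- cur
        cur <- iv[i, ]
      }
    }
  }
  merged[[length(merged) + 1]] <- cur
  iv <- do.call(rbind, merged)

  dur <- (iv[, 2] - iv[, 1] + 1) / fs
  iv <- iv[dur >= min_duration_s, , drop = FALSE]
  if (nrow(iv) == 0) return(empty)

  out <- purrr::map_dfr(seq_len(nrow(iv)), function(i) {
    s <- iv[i, 1]; e <- iv[i, 2]
    pk <- which.max(envelope[s:e]) + s - 1L
    gap_start <- if (i == 1) 1L else iv[i - 1, 2] + 1L
    gap <- if (gap_start <= s - 1L) envelope[gap_start:(s - 1L)] else envelope[s]
    tibble(onset_s = (s - 1) / fs,
           offset_s = e / fs,
           duration_s = (e - s + 1) / fs,
           peak_time_s = (pk - 1) / fs,
           peak_amp = envelope[pk],
           valley_amp = min(gap))
  })
  class(out) <- c("burst_events", class(out))
  out
}

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return Dimensionless CV.
#' @export
#' @examples
#' coefficient_of_variation(c(2, 4))  # 0.4714
coefficient_of_variation <- function(values) {
  if (length(values) < 2) abort("values: need at least 2 values")
  m <- mean(values)
  if (m == 0) abort("values: mean is zero, CV undefined")
  sd(values) / m
}

#' Locomotor parameters from detected bursts
#'
#' Computes the standard fictive-locomotion parameters over an analysis
#' window: frequency (burst count / window length), mean burst duration,
#' cycle period (1/frequency), duty cycle (duration / period) and amplitude
#' (mean peak minus valley), plus coefficients of variation for duration,
#' period, amplitude (per burst) and frequency (per-cycle instantaneous
#' frequency, 1 / inter-onset interval). Bursts are counted if their onset
#' lies inside the window.
#'
#' @param events A `burst_events` tibble from [detect_bursts()].
#' @param window Numeric length-2 vector `(start_s, end_s)`.
#' @return One-row tibble with the parameters and CVs; with zero events the
#'   frequency is 0 and all ratio parameters are `NA`.
#' @export
locomotor_parameters <- function(events, window) {
  if (length(window) != 2 || diff(window) <= 0) {
    abort("window: must be (start_s, end_s) with positive length")
  }
  ev <- dplyr::filter(events, .data$onset_s >= window[1],
                      .data$onset_s < window[2])
  len <- diff(window)
  n <- nrow(ev)
  freq <- n / len
  if (n == 0) {
    return(tibble(n_bursts = 0L, frequency_hz = 0, burst_duration_s = NA_real_,
                  cycle_period_s = NA_real_, duty_cycle = NA_real_,
                  amplitude = NA_real_, cv_duration = NA_real_,
                  cv_period = NA_real_, cv_amplitude = NA_real_,
                  cv_frequency = NA_real_,
                  window_start_s = window[1], window_end_s = window[2]))
  }
  durations <- ev$offset_s - ev$onset_s
  amps <- ev$peak_amp - ev$valley_amp
  period <- 1 / freq
  ioi <- diff(ev$onset_s)
  inst_freq <- if (length(ioi) > 0) 1 / ioi else numeric(0)
  safe_cv <- function(v) {
    if (length(v) >= 2 && mean(v) != 0) coefficient_of_variation(v) else NA_real_
  }
  tibble(n_bursts = n,
         frequency_hz = freq,
         burst_duration_s = mean(durations),
         cycle_period_s = period,
         duty_cycle = mean(durations) / period,
         amplitude = mean(amps),
         cv_duration = safe_cv(durations),
         cv_period = safe_cv(ioi),
         cv_amplitude = safe_cv(amps),
         cv_frequency = safe_cv(inst_freq),
         window_start_s = window[1], window_end_s = window[2])
}

#' Binned burst frequency over time
#'
#' Frequency per fixed-width bin (burst count / bin width), as used to follow
#' slow frequency changes during chemogenetic silencing. The partial trailing
#' bin is dropped.
#'
#' @param events A `burst_events` tibble.
#' @param bin_s Bin width in seconds (default 120, i.e. 2-minute bins).
#' @param window Optional `(start_s, end_s)`; defaults to `(0, last offset)`.
#' @return Tibble with `bin_center_s`, `bin_start_s`, `bin_end_s`,
#'   `n_bursts`, `frequency_hz`.
#' @export
windowed_frequency <- function(events, bin_s = 120, window = NULL) {
  if (bin_s <= 0) abort("bin_s: must be > 0")
  if (nrow(events) == 0 && is.null(window)) {
    return(tibble(bin_center_s = numeric(0), bin_start_s = numeric(0),
                  bin_end_s = numeric(0), n_bursts = integer(0),
                  frequency_hz = numeric(0)))
  }
  window <- window %||% c(0, max(events$offset_s))
  n_bins <- floor(diff(window) / bin_s)
  if (n_bins < 1) {
    return(tibble(bin_center_s = numeric(0), bin_start_s = numeric(0),
                  bin_end_s = numeric(0), n_bursts = integer(0),
                  frequency_hz = numeric(0)))
  }
  starts <- window[1] + (seq_len(n_bins) - 1) * bin_s
  counts <- vapply(starts, function(s) {
    sum(events$onset_s >= s & events$onset_s < s + bin_s)
  }, integer(1))
  tibble(bin_center_s = starts + bin_s / 2,
         bin_start_s = starts, bin_end_s = starts + bin_s,
         n_bursts = counts, frequency_hz = counts / bin_s)
}

#' Analysis windows for the experimental conditions
#'
#' Encodes the window rules used for the three protocols:
#' * `chronic`: a 5-min window between 25 and 30 min after the onset of
#'   drug-induced activity;
#' * `acute` (CNO silencing): the last 4 min before CNO application paired
#'   with the last 4 min of CNO before washout;
#' * `optogenetic`: a 20-s baseline immediately before the light, the light
#'   window itself, and an equally long post-light window immediately after
#'   light-off.
#'
#' @param condition One of `"chronic"`, `"acute"`, `"optogenetic"`.
#' @param annotations Named list of event times in seconds. `chronic` needs
#'   `drug_onset_s`; `acute` needs `cno_onset_s` and `cno_washout_s`;
#'   `optogenetic` needs `light_on_s` and `light_off_s`.
#' @param baseline_s Baseline/post window length for the optogenetic
#'   condition (s).
#' @return Tibble with columns `window`, `start_s`, `end_s`.
#' @export
select_analysis_window <- function(condition = c("chronic", "acute",
                                                 "optogenetic"),
                                   annotations, baseline_s = 20) {
  condition <- match.arg(condition)
  need <- function(key) {
    if (is.null(annotations[[key]])) {
      abort(paste0("annotations: missing '", key, "' for condition ", condition))
    }
    annotations[[key]]
  }
  switch(condition,
    chronic = {
      t0 <- need("drug_onset_s")
      tibble(window = "chronic", start_s = t0 + 25 * 60, end_s = t0 + 30 * 60)
    },
    acute = {
      on <- need("cno_onset_s")
      wash <- need("cno_washout_s")
      tibble(window = c("baseline", "cno"),
             start_s = c(on - 240, wash - 240),
             end_s = c(on, wash))
    },
    optogenetic = {
      on <- need("light_on_s")
      off <- need("light_off_s")
      tibble(window = c("baseline", "light", "post"),
             start_s = c(on - baseline_s, on, off),
             end_s = c(on, off, off + baseline_s))
    })
}

#' Ventral-root choice per protocol
#'
#' Flexor (L2) roots are used for all locomotor parameters except local
#' optogenetic stimulation of the lower lumbar cord (L5/L6), where the
#' extensor (L5) roots are used.
#'
#' @param protocol One of `"chronic"`, `"acute"`, `"dose"`,
#'   `"optogenetic_broad"`, `"optogenetic_L1L2"`, `"optogenetic_L5L6"`.
#' @return `"L2"` or `"L5"`.
#' @export
choose_analysis_root <- function(protocol = c("chronic", "acute", "dose",
                                              "optogenetic_broad",
                                              "optogenetic_L1L2",
                                              "optogenetic_L5L6")) {
  protocol <- match.arg(protocol)
  if (protocol == "optogenetic_L5L6") "L5" else "L2"
}
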