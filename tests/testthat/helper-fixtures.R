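# Shared fixtures: all synthetic, built in code at test time.

# Default alternating-gait schedule (left-right and flexor-extensor at 180 deg).
alt_schedule <- function(dur_s = 120, freq_hz = 0.3, duty = 0.3, amplitude = 1,
                         noise_sd = 0, fs = 200, seed = 1L, ...) {
  synth_schedule(
    tibble::tibble(start_s = 0, end_s = dur_s, freq_hz = freq_hz,
                   duty = duty, amplitude = amplitude),
    noise_sd = noise_sd, fs = fs, seed = seed, ...)
}

# Detect bursts on one channel of a vr_synth object.
detect_channel <- function(vr, channel, ...) {
  env <- rectify_and_smooth(vr$recording[[channel]], vr$fs)
  detect_bursts(env, vr$fs, ...)
}

# Minimal roi_traces object for trace-level tests (bypasses movie extraction).
make_roi_traces <- function(traces, fs, grid = NULL) {
  if (is.null(grid)) grid <- build_grid()
  colnames(traces) <- as.character(grid$roi_id[seq_len(ncol(traces))])
  structure(list(traces = traces, fs = fs, f0 = rep(0, ncol(traces)),
                 global_max_df = 1, normalized = TRUE, filtered = TRUE,
                 grid = grid[seq_len(ncol(traces)), ]),
            class = "roi_traces")
}

# Small anti-phase two-oscillator movie for calcium tests.
small_antiphase_movie <- function(duration_s = 60, noise_sd = 0, seed = 2L,
                                  freq_hz = 0.4) {
  generate_calcium_movie(n_per_side = 1, freq_hz = freq_hz, fs = 10,
                         duration_s = duration_s, height = 80, width = 100,
                         lr_phase_offset = 0.5, noise_sd = noise_sd,
                         seed = seed)
}
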