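#' Construct a calcium movie object
#'
#' @param frames Numeric array `H x W x T` of intensities (a.u.).
#' @param fs Frame rate in frames/s.
#' @param landmarks List with `canal` (named vector `row`, `col`),
#'   `left_col`, `right_col`, `dorsal_row`, `ventral_row`. Coordinates are in
#'   pixel units where pixel `k` spans `[k - 0.5, k + 0.5]`, so a cord that
#'   fills an `H x W` frame exactly has edges at `0.5` and `W + 0.5`.
#' @param normalized Logical; `TRUE` once [normalize_field()] has been run.
#' @return Object of class `calcium_movie`.
#' @export
calcium_movie <- function(frames, fs, landmarks = NULL, normalized = FALSE) {
  if (length(dim(frames)) != 3) abort("frames: must be an H x W x T array")
  if (fs <= 0) abort("fs: must be > 0")
  structure(list(frames = frames, fs = fs, landmarks = landmarks,
                 normalized = normalized),
            class = "calcium_movie")
}

#' @export
print.calcium_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("calcium_movie: %d x %d pixels, %d frames at %g fps%s\n",
              d[1], d[2], d[3], x$fs,
              if (isTRUE(x$normalized)) " (normalized)" else ""))
  invisible(x)
}

#' Normalize the imaged field to the standard 500 x 400 geometry
#'
#' Resamples the movie so the cord edges meet the borders of a 400-row by
#' 500-column field with the central canal on the vertical midline: the left
#' edge maps to the left border, the right edge to the right border, dorsal
#' to the top, ventral to the bottom, and each hemifield is scaled
#' independently so the canal sits exactly on the column-250/251 boundary.
#' Intensities are interpolated bilinearly.
#'
#' @param movie A `calcium_movie` with all five landmarks.
#' @param out_width,out_height Output size (default 500 x 400).
#' @return A normalized `calcium_movie` of dimension
#'   `out_height x out_width x T`.
#' @export
normalize_field <- function(movie, out_width = 500L, out_height = 400L) {
  lm <- movie$landmarks
  if (is.null(lm) || is.null(lm$canal) || is.null(lm$left_col) ||
      is.null(lm$right_col) || is.null(lm$dorsal_row) || is.null(lm$ventral_row)) {
    abort("landmarks: canal, left_col, right_col, dorsal_row, ventral_row all required")
  }
  xc <- unname(lm$canal["col"])
  xl <- lm$left_col; xr <- lm$right_col
  yd <- lm$dorsal_row; yv <- lm$ventral_row
  if (xc - xl <= 0 || xr - xc <= 0) abort("landmarks: degenerate hemifield width")
  if (yv - yd <= 0) abort("landmarks: degenerate dorso-ventral extent")

  H <- dim(movie$frames)[1]; W <- dim(movie$frames)[2]; T <- dim(movie$frames)[3]
  half <- out_width / 2
  j <- seq_len(out_width)
  u <- (j - 0.5) / half            # 0..2 across the two hemifields
  x <- ifelse(u <= 1, xl + u * (xc - xl), xc + (u - 1) * (xr - xc))
  i <- seq_len(out_height)
  y <- yd + (i - 0.5) / out_height * (yv - yd)

  # bilinear interpolation weights over the source grid (pixel centres)
  xg <- pmin(pmax(x, 1), W); yg <- pmin(pmax(y, 1), H)
  x0 <- pmin(floor(xg), W - 1L); y0 <- pmin(floor(yg), H - 1L)
  wx <- xg - x0; wy <- yg - y0
  # expand to the full output grid (row-major over out_height x out_width)
  Y0 <- matrix(y0, out_height, out_width)
  X0 <- matrix(x0, out_height, out_width, byrow = TRUE)
  WY <- matrix(wy, out_height, out_width)
  WX <- matrix(wx, out_height, out_width, byrow = TRUE)
  i00 <- as.vector(Y0 + (X0 - 1) * H)
  i10 <- i00 + 1L
  i01 <- i00 + H
  i11 <- i01 + 1L
  w00 <- as.vector((1 - WY) * (1 - WX)); w10 <- as.vector(WY * (1 - WX))
  w01 <- as.vector((1 - WY) * WX);       w11 <- as.vector(WY * WX)

  out <- array(0, dim = c(out_height, out_width, T))
  npix <- out_height * out_width
  for (tt in seq_len(T)) {
    f <- movie$frames[, , tt]
    out[, , tt] <- f[i00] * w00 + f[i10] * w10 + f[i01] * w01 + f[i11] * w11
  }
  calcium_movie(out, movie$fs,
                landmarks = list(canal = c(row = out_height / 2 + 0.5,
                                           col = half + 0.5),
                                 left_col = 0.5, right_col = out_width + 0.5,
                                 dorsal_row = 0.5,
                                 ventral_row = out_height + 0.5),
                normalized = TRUE)
}

#' Build the 500-ROI grid over the normalized field
#'
#' Tiles each 250 x 400 hemifield of the normalized 500 x 400 field into 10
#' columns by 25 rows of 25 x 16-pixel rectangles: 500 disjoint ROIs covering
#' the field exactly once. ROIs 1-250 tile the right hemifield (image columns
#' 1-250), ROIs 251-500 the left hemifield (columns 251-500). Within each
#' hemifield the index runs dorsal to ventral within a tile column, sweeping
#' tile columns from lateral to medial.
#'
#' @param width,height Field size; must be 500 x 400.
#' @return Tibble of class `roi_grid` with `roi_id`, `side`, `tile_col`
#'   (1 = lateral), `tile_row` (1 = dorsal), `row0`, `row1`, `col0`, `col1`
#'   (inclusive pixel bounds) and centre coordinates `row_c`, `col_c`.
#' @export
build_grid <- function(width = 500L, height = 400L) {
  if (width != 500L || height != 400L) {
    abort("build_grid: field must be 500 columns x 400 rows (run normalize_field)")
  }
  tile_w <- 25L; tile_h <- 16L
  n_tc <- 10L; n_tr <- 25L
  grid <- purrr::map_dfr(c("right", "left"), function(side) {
    purrr::map_dfr(seq_len(n_tc), function(tc) {
      purrr::map_dfr(seq_len(n_tr), function(tr) {
        # lateral-to-medial: right hemifield starts at column 1 (lateral),
        # left hemifield starts at column 500 (lateral)
        if (side == "right") {
          c0 <- (tc - 1L) * tile_w + 1L
        } else {
          c0 <- 500L - tc * tile_w + 1L
        }
        r0 <- (tr - 1L) * tile_h + 1L
        tibble(side = side, tile_col = tc, tile_row = tr,
               row0 = r0, row1 = r0 + tile_h - 1L,
               col0 = c0, col1 = c0 + tile_w - 1L)
      })
    })
  })
  grid <- dplyr::mutate(grid,
                        roi_id = dplyr::row_number(),
                        row_c = (.data$row0 + .data$row1) / 2,
                        col_c = (.data$col0 + .data$col1) / 2,
                        .before = 1)
  class(grid) <- c("roi_grid", class(grid))
  grid
}

# 400 x 500 integer matrix of ROI ids.
grid_pixel_ids <- function(grid) {
  ids <- matrix(0L, nrow = 400L, ncol = 500L)
  for (k in seq_len(nrow(grid))) {
    ids[grid$row0[k]:grid$row1[k], grid$col0[k]:grid$col1[k]] <- grid$roi_id[k]
  }
  ids
}

#' Extract per-ROI dF traces from a normalized movie
#'
#' For each ROI, `Ft` is the mean intensity over the footprint, `F0` the mean
#' of `Ft` over the last `n_baseline_frames` frames, and `dF = Ft - F0`. All
#' traces are then divided by the single maximum `dF` over all ROIs and
#' frames, so the set of normalized traces has global maximum 1 (when any
#' positive signal exists; otherwise they are returned unnormalized with a
#' flag).
#'
#' @param movie A normalized `calcium_movie`.
#' @param grid A `roi_grid` from [build_grid()].
#' @param n_baseline_frames Number of trailing frames averaged into `F0`
#'   (default 100).
#' @return Object of class `roi_traces`: list with `traces` (matrix
#'   `T x 500`, columns named by `roi_id`), `fs`, `f0`, `global_max_df`,
#'   `normalized`, `filtered`, `grid`.
#' @export
extract_delta_f <- function(movie, grid, n_baseline_frames = 100L) {
  if (!isTRUE(movie$normalized)) {
    abort("movie: must be normalized (run normalize_field first)")
  }
  T <- dim(movie$frames)[3]
  if (T <= n_baseline_frames) {
    abort("movie: needs more frames than n_baseline_frames")
  }
  idvec <- as.vector(grid_pixel_ids(grid))
  counts <- rowsum(rep(1, length(idvec)), idvec)[, 1]
  n_roi <- nrow(grid)
  ft <- matrix(0, nrow = T, ncol = n_roi)
  for (tt in seq_len(T)) {
    s <- rowsum(as.vector(movie$frames[, , tt]), idvec)
    ft[tt, ] <- s[, 1] / counts
  }
  f0 <- colMeans(ft[(T - n_baseline_frames + 1):T, , drop = FALSE])
  df <- sweep(ft, 2, f0)
  gmax <- max(df)
  normalized <- gmax > 0
  if (normalized) df <- df / gmax
  colnames(df) <- as.character(grid$roi_id)
  structure(list(traces = df, fs = movie$fs, f0 = f0, global_max_df = gmax,
                 normalized = normalized, filtered = FALSE, grid = grid),
            class = "roi_traces")
}

#' @export
print.roi_traces <- function(x, ...) {
  cat(sprintf("roi_traces: %d ROIs x %d frames at %g fps (%s%s)\n",
              ncol(x$traces), nrow(x$traces), x$fs,
              if (x$normalized) "normalized" else "unnormalized",
              if (x$filtered) ", filtered" else ""))
  invisible(x)
}

#' @rdname extract_delta_f
#' @param x A `roi_traces` object.
#' @param ... Unused.
#' @export
tidy.roi_traces <- function(x, ...) {
  T <- nrow(x$traces)
  tb <- as_tibble(x$traces)
  tb$time_s <- (seq_len(T) - 1) / x$fs
  tidyr::pivot_longer(tb, -"time_s", names_to = "roi_id", values_to = "df") %>%
    dplyr::mutate(roi_id = as.integer(.data$roi_id)) %>%
    dplyr::arrange(.data$roi_id, .data$time_s)
}

# Piecewise baseline: the `q` quantile over consecutive blocks of
# `window_s`, linearly interpolated back to the full time base.
rolling_quantile_baseline <- function(x, fs, window_s, q) {
  n <- length(x)
  block <- max(2L, round(window_s * fs))
  starts <- seq(1L, n, by = block)
  centers <- pmin(starts + (block - 1) / 2, n)
  vals <- vapply(starts, function(s) {
    stats::quantile(x[s:min(s + block - 1L, n)], q, names = FALSE)
  }, numeric(1))
  if (length(vals) == 1) return(rep(vals, n))
  approx(centers, vals, xout = seq_len(n), rule = 2)$y
}

#' Low-pass filter and baseline-adjust ROI traces
#'
#' Applies a zero-phase Butterworth low-pass (order 4 by default) to every
#' trace, subtracts a slow baseline (the rolling 10th percentile over a 20-s
#' window) and removes the residual mean so the DC component of the output is
#' approximately zero. Constant traces map to all-zero traces.
#'
#' @param x A `roi_traces` object.
#' @param lowpass_hz Cutoff frequency (Hz); must be below the Nyquist
#'   frequency `fs/2`.
#' @param order Butterworth order.
#' @param baseline_window_s Window of the rolling-percentile baseline (s).
#' @param baseline_quantile Percentile used as baseline (default 0.1).
#' @return The `roi_traces` object with filtered traces (`filtered = TRUE`).
#' @export
preprocess_traces <- function(x, lowpass_hz = 2, order = 4,
                              baseline_window_s = 20,
                              baseline_quantile = 0.1) {
  fs <- x$fs
  if (lowpass_hz >= fs / 2) abort("lowpass_hz: must be below Nyquist (fs/2)")
  bf <- signal::butter(order, lowpass_hz / (fs / 2), type = "low")
  out <- x$traces
  for (k in seq_len(ncol(out))) {
    tr <- out[, k]
    if (stats::sd(tr) > 0) tr <- as.numeric(signal::filtfilt(bf, tr))
    bl <- rolling_quantile_baseline(tr, fs, baseline_window_s,
                                    baseline_quantile)
    tr <- tr - bl
    out[, k] <- tr - mean(tr)
  }
  x$traces <- out
  x$filtered <- TRUE
  x
}

# Lagged Pearson correlation of x with itself (lag >= 1) or of two series.
lagged_cor <- function(x, y = x, lag) {
  n <- length(x)
  if (lag >= 0) {
    a <- x[(1 + lag):n]; b <- y[1:(n - lag)]
  } else {
    a <- x[1:(n + lag)]; b <- y[(1 - lag):n]
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Autocorrelation oscillation index of a trace
#'
#' Computes the lagged correlation coefficient of the trace with itself and
#' takes the first side peak within `[0.5, 2] x` the expected period range,
#' minus the deepest trough at shorter (positive) lags. A perfectly periodic
#' trace scores 2 (peak +1, trough -1); noise scores near 0. If no side peak
#' is found in the search range the index is 0.
#'
#' @param trace Numeric trace (filtered; see [preprocess_traces()]).
#' @param fs Sampling rate (Hz).
#' @param expected_period_range Length-2 numeric `(min_s, max_s)` of
#'   plausible cycle periods, e.g. from the concurrent root frequency.
#' @return Raw oscillation index in `[0, 2]` (0 when no peak is found).
#' @export
oscillation_index <- function(trace, fs, expected_period_range) {
  if (length(expected_period_range) != 2 ||
      any(expected_period_range <= 0) ||
      diff(expected_period_range) < 0) {
    abort("expected_period_range: must be (min_s, max_s) > 0")
  }
  if (stats::sd(trace) == 0) return(0)
  lag_lo <- max(1L, floor(0.5 * expected_period_range[1] * fs))
  lag_hi <- min(length(trace) - 3L, ceiling(2 * expected_period_range[2] * fs))
  if (lag_hi <= lag_lo) return(0)
  lags <- seq_len(lag_hi)
  ac <- vapply(lags, function(l) lagged_cor(trace, lag = l), numeric(1))
  win <- lags >= lag_lo
  if (!any(win) || all(is.na(ac[win]))) return(0)
  peak_lag <- lags[win][which.max(ac[win])]
  peak <- ac[peak_lag]
  trough <- min(ac[lags < peak_lag], peak)
  idx <- peak - trough
  if (!is.finite(idx) || idx < 0) return(0)
  idx
}

#' Oscillation-index maps for all ROIs
#'
#' Convenience wrapper: computes the raw oscillation index for every ROI
#' trace, then normalizes the map with [normalize_index_map()].
#'
#' @param x A filtered `roi_traces` object.
#' @param expected_period_range As in [oscillation_index()].
#' @return An `oscillation_map` tibble (see [normalize_index_map()]).
#' @export
oscillation_map <- function(x, expected_period_range) {
  raw <- vapply(seq_len(ncol(x$traces)), function(k) {
    oscillation_index(x$traces[, k], x$fs, expected_period_range)
  }, numeric(1))
  normalize_index_map(raw, x$grid)
}

#' Normalize a raw oscillation-index map
#'
#' Divides every ROI's raw index by the single maximum over all 500 ROIs, so
#' the same divisor applies to the right (1-250) and left (251-500) halves
#' and the map maximum is 1. An all-zero map is returned as-is with an
#' `all_zero` attribute.
#'
#' @param raw Numeric vector of 500 raw indices (ROI order).
#' @param grid A `roi_grid`.
#' @return Tibble of class `oscillation_map`: the grid columns plus `raw`
#'   and `norm`.
#' @export
normalize_index_map <- function(raw, grid) {
  if (length(raw) != nrow(grid)) {
    abort("raw: need one index per ROI in the grid")
  }
  mx <- max(raw)
  norm <- if (mx > 0) raw / mx else raw
  out <- dplyr::mutate(as_tibble(grid), raw = raw, norm = norm)
  attr(out, "all_zero") <- mx <= 0
  class(out) <- c("oscillation_map", class(out))
  out
}

#' Average oscillation maps and pick the reference ROI
#'
#' Element-wise mean of the normalized indices across preparations; the
#' reference ROI is the ROI with the highest averaged index (ties broken by
#' the lowest ROI id, with a message).
#'
#' @param maps List of `oscillation_map` tibbles on the same grid.
#' @return List with `map` (averaged `oscillation_map`) and `reference_roi`.
#' @export
average_maps_and_reference <- function(maps) {
  if (length(maps) < 1) abort("maps: need at least one map")
  ids <- purrr::map(maps, "roi_id")
  if (!all(vapply(ids, identical, logical(1), ids[[1]]))) {
    abort("maps: grids do not match")
  }
  norm_mat <- vapply(maps, function(m) m$norm, numeric(nrow(maps[[1]])))
  avg <- rowMeans(norm_mat)
  out <- maps[[1]]
  out$raw <- rowMeans(vapply(maps, function(m) m$raw, numeric(nrow(out))))
  out$norm <- avg
  mx <- max(avg)
  ref_candidates <- out$roi_id[avg == mx]
  if (length(ref_candidates) > 1) {
    inform(paste0("reference ROI tie among ", length(ref_candidates),
                  " ROIs; taking lowest id"))
  }
  list(map = out, reference_roi = min(ref_candidates))
}

# Cross-correlation phase of `trace` against `ref` in cycle units:
# positive phase means the trace lags the reference. The peak lag is refined
# to sub-sample precision by parabolic interpolation through the three
# correlations around the maximum.
xcorr_phase <- function(trace, ref, fs, cycle_period_s) {
  if (stats::sd(trace) == 0) return(NA_real_)
  half <- ceiling(cycle_period_s * fs / 2)
  lags <- (-half):half
  cc <- vapply(lags, function(l) lagged_cor(trace, ref, l), numeric(1))
  if (all(is.na(cc))) return(NA_real_)
  k <- which.max(cc)
  best <- lags[k]
  if (k > 1 && k < length(cc) && !is.na(cc[k - 1]) && !is.na(cc[k + 1])) {
    denom <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
    if (denom < 0) {
      best <- best + 0.5 * (cc[k - 1] - cc[k + 1]) / denom
    }
  }
  ((best / fs) / cycle_period_s) %% 1
}

#' Cross-correlation phase map against the reference ROI
#'
#' For each ROI, the lag of the maximum cross-correlation with the reference
#' ROI trace within plus or minus half the locomotor cycle period, divided by
#' the period and mapped to `[0, 1)`. The reference ROI's phase is exactly 0;
#' flat traces yield `NA`. A phase of 0.5 is strict alternation with the
#' reference.
#'
#' @param x A filtered `roi_traces` object.
#' @param reference_roi ROI id of the reference (from
#'   [average_maps_and_reference()]).
#' @param cycle_period_s Locomotor cycle period in seconds (e.g. from the
#'   concurrent ventral-root frequency).
#' @return Tibble of class `phase_map`: grid columns plus `phase` (cycles);
#'   attribute `cycle_period_s`.
#' @export
phase_map <- function(x, reference_roi, cycle_period_s) {
  ref <- x$traces[, as.character(reference_roi)]
  if (stats::sd(ref) == 0) abort("reference_roi: reference trace is flat")
  phases <- vapply(seq_len(ncol(x$traces)), function(k) {
    xcorr_phase(x$traces[, k], ref, x$fs, cycle_period_s)
  }, numeric(1))
  phases[x$grid$roi_id == reference_roi] <- 0
  out <- dplyr::mutate(as_tibble(x$grid), phase = phases)
  attr(out, "cycle_period_s") <- cycle_period_s
  class(out) <- c("phase_map", class(out))
  out
}

#' Phase of each ROI against ipsilateral and contralateral root bursts
#'
#' Builds a burst-train indicator (1 during a burst, 0 otherwise, mean
#' removed) from each root's events, sampled on the movie's time base, and
#' computes each ROI's cross-correlation phase against it in cycle units. An
#' ROI locked to the ipsilateral root scores ~0 against it and ~0.5 against
#' the contralateral root during alternating activity.
#'
#' @param x A filtered `roi_traces` object.
#' @param ipsi_events,contra_events `burst_events` tibbles for the two roots
#'   (times on the movie clock).
#' @param cycle_period_s Locomotor cycle period (s).
#' @param movie_start_s Time of the first movie frame on the event clock.
#' @return Tibble: grid columns plus `phase_vs_ipsi`, `phase_vs_contra`.
#' @export
root_phase_comparison <- function(x, ipsi_events, contra_events,
                                  cycle_period_s, movie_start_s = 0) {
  T <- nrow(x$traces)
  t_end <- movie_start_s + T / x$fs
  make_ind <- function(ev, label) {
    if (nrow(ev) == 0 || max(ev$offset_s) <= movie_start_s ||
        min(ev$onset_s) >= t_end) {
      abort(paste0(label, "_events: no temporal overlap with the movie"))
    }
    tt <- movie_start_s + (seq_len(T) - 1) / x$fs
    ind <- numeric(T)
    for (i in seq_len(nrow(ev))) {
      ind[tt >= ev$onset_s[i] & tt < ev$offset_s[i]] <- 1
    }
    ind - mean(ind)
  }
  ipsi <- make_ind(ipsi_events, "ipsi")
  contra <- make_ind(contra_events, "contra")
  ph <- function(ref) {
    vapply(seq_len(ncol(x$traces)), function(k) {
      xcorr_phase(x$traces[, k], ref, x$fs, cycle_period_s)
    }, numeric(1))
  }
  dplyr::mutate(as_tibble(x$grid),
                phase_vs_ipsi = ph(ipsi),
                phase_vs_contra = ph(contra))
}
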