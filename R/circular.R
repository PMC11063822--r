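#' Cycle-by-cycle phases of a test burst train within a reference train
#'
#' For each reference cycle `[onset_i, onset_{i+1})` the phase of the test
#' burst onset falling inside that cycle is
#' `360 * (t_test - onset_i) / (onset_{i+1} - onset_i)` degrees. Cycles
#' containing zero or more than one test onset are skipped and counted;
#' nothing is interpolated. By convention 0 degrees is synchrony and 180
#' degrees strict alternation.
#'
#' @param ref_events,test_events `burst_events` tibbles (from
#'   [detect_bursts()]) or tibbles with an `onset_s` column.
#' @return Tibble of class `phase_series` with columns `cycle` and
#'   `angle_deg` (in `[0, 360)`), plus attributes `n_skipped_empty` and
#'   `n_skipped_multiple`.
#' @export
extract_cycle_phases <- function(ref_events, test_events) {
  ref <- sort(ref_events$onset_s)
  test <- sort(test_events$onset_s)
  if (length(ref) < 4) {
    abort("ref_events: need at least 3 reference cycles (4 onsets)")
  }
  n_cycles <- length(ref) - 1
  skipped_empty <- 0L
  skipped_multi <- 0L
  rows <- vector("list", n_cycles)
  for (i in seq_len(n_cycles)) {
    lo <- ref[i]; hi <- ref[i + 1]
    inside <- test[test >= lo & test < hi]
    if (length(inside) == 0) {
      skipped_empty <- skipped_empty + 1L
    } else if (length(inside) > 1) {
      skipped_multi <- skipped_multi + 1L
    } else {
      rows[[i]] <- tibble(cycle = i,
                          angle_deg = 360 * (inside - lo) / (hi - lo))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) out <- tibble(cycle = integer(0), angle_deg = numeric(0))
  out$angle_deg <- out$angle_deg %% 360
  attr(out, "n_skipped_empty") <- skipped_empty
  attr(out, "n_skipped_multiple") <- skipped_multi
  class(out) <- c("phase_series", class(out))
  out
}

# Accept a phase_series tibble or a bare numeric vector of degrees.
as_angles_deg <- function(x) {
  if (is.data.frame(x)) x$angle_deg else as.numeric(x)
}

#' Circular mean angle and resultant vector length
#'
#' The mean angle is `atan2(mean sin, mean cos)` mapped to `[0, 360)`; `r` is
#' the length of the mean resultant vector, 1 when all angles coincide and 0
#' for perfectly balanced (e.g. antipodal) sets. When `r` is numerically zero
#' the mean angle is undefined and returned as `NA`.
#'
#' @param angles A `phase_series` tibble or numeric vector of degrees.
#' @return One-row tibble with `mean_deg`, `r`, `n`.
#' @export
#' @examples
#' circular_mean(c(0, 90, 90))  # mean 63.43 deg, r 0.745
circular_mean <- function(angles) {
  a <- as_angles_deg(angles) * pi / 180
  if (length(a) < 1) abort("angles: need at least one angle")
  C <- mean(cos(a)); S <- mean(sin(a))
  r <- sqrt(C^2 + S^2)
  mean_deg <- if (r < 1e-12) NA_real_ else (atan2(S, C) * 180 / pi) %% 360
  tibble(mean_deg = mean_deg, r = r, n = length(a))
}

#' Rayleigh test of circular uniformity
#'
#' Tests whether angles are non-uniformly distributed (i.e. whether coupling
#' exists). Uses `Z = n * rbar^2` with the standard small-sample
#' approximation `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`, where
#' `R = n * rbar`. Optionally weights each angle (e.g. each preparation's
#' mean by its vector length); the weighted form is off by default.
#'
#' @param angles A `phase_series` tibble or numeric vector of degrees
#'   (typically per-preparation mean angles).
#' @param weights Optional non-negative weights (e.g. per-preparation `r`).
#' @return One-row tibble with `rbar`, `z`, `p_value`, `n`.
#' @export
rayleigh_test <- function(angles, weights = NULL) {
  a <- as_angles_deg(angles) * pi / 180
  n <- length(a)
  if (n < 3) abort("angles: Rayleigh test needs n >= 3")
  if (is.null(weights)) {
    C <- mean(cos(a)); S <- mean(sin(a))
  } else {
    if (length(weights) != n || any(weights < 0)) {
      abort("weights: must be non-negative, one per angle")
    }
    C <- sum(weights * cos(a)) / sum(weights)
    S <- sum(weights * sin(a)) / sum(weights)
  }
  rbar <- sqrt(C^2 + S^2)
  R <- n * rbar
  z <- n * rbar^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  tibble(rbar = rbar, z = z, p_value = min(1, max(0, p)), n = n)
}

# Best-fitting von Mises concentration for a given mean resultant length.
a1inv <- function(rbar) {
  if (rbar >= 0 && rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Watson-Williams test for equality of mean directions
#'
#' High-concentration F test comparing the mean angles of two or more groups,
#' with the von Mises concentration correction `K = 1 + 3 / (8 * kappa)`.
#' When the pooled concentration is low (`rbar < 0.45`) the F approximation
#' is unreliable; the result is still returned but carries a warning flag.
#'
#' @param groups List of two or more angle sets (each a `phase_series` or a
#'   numeric vector of degrees), each with at least 3 angles.
#' @return One-row tibble with `f_statistic`, `df1`, `df2`, `p_value`,
#'   `rbar_pooled`, `low_concentration`.
#' @export
watson_williams_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("groups: need a list of >= 2 angle sets")
  }
  a <- purrr::map(groups, function(g) as_angles_deg(g) * pi / 180)
  sizes <- lengths(a)
  if (any(sizes < 3)) abort("groups: each group needs n >= 3")
  k <- length(a)
  N <- sum(sizes)
  res_len <- function(x) {
    sqrt(sum(cos(x))^2 + sum(sin(x))^2)
  }
  Ri <- vapply(a, res_len, numeric(1))
  all_angles <- unlist(a)
  R <- res_len(all_angles)
  rw <- sum(Ri) / N
  low <- rw < 0.45
  if (low) {
    warn("pooled concentration rbar < 0.45: Watson-Williams F approximation unreliable")
  }
  kappa <- a1inv(rw)
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - k) * (sum(Ri) - R)) / ((k - 1) * (N - sum(Ri)))
  Fstat <- max(0, Fstat)
  p <- pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  tibble(f_statistic = Fstat, df1 = k - 1, df2 = N - k,
         p_value = p, rbar_pooled = rw, low_concentration = low)
}

#' Summarise left-right / flexor-extensor coordination across preparations
#'
#' Computes the circular mean angle and vector length for each preparation,
#' the grand mean (circular mean of the per-preparation mean angles) and the
#' Rayleigh test over the per-preparation means (optionally weighted by each
#' preparation's `r`).
#'
#' @param per_prep List of `phase_series` (one per preparation) or a single
#'   `phase_series`.
#' @param weighted_rayleigh If `TRUE`, weight each preparation's mean angle
#'   by its vector length in the Rayleigh test. Default off.
#' @return An object of class `circular_summary` with fields `per_prep`
#'   (tibble `prep`, `mean_deg`, `r`, `n`), `grand_mean_deg`, `grand_r`,
#'   `rayleigh_p`, `n_prep`. Use [tidy()] / [glance()] to extract tibbles.
#' @export
summarize_coordination <- function(per_prep, weighted_rayleigh = FALSE) {
  if (is.data.frame(per_prep)) per_prep <- list(per_prep)
  if (length(per_prep) < 1) abort("per_prep: need at least one preparation")
  pp <- purrr::imap_dfr(per_prep, function(ps, i) {
    cm <- circular_mean(ps)
    tibble(prep = i, mean_deg = cm$mean_deg, r = cm$r, n = cm$n)
  })
  gm <- circular_mean(pp$mean_deg[!is.na(pp$mean_deg)])
  ray_p <- if (nrow(pp) >= 3) {
    w <- if (weighted_rayleigh) pp$r else NULL
    rayleigh_test(pp$mean_deg, weights = w)$p_value
  } else {
    NA_real_
  }
  structure(list(per_prep = pp, grand_mean_deg = gm$mean_deg,
                 grand_r = gm$r, rayleigh_p = ray_p, n_prep = nrow(pp)),
            class = "circular_summary")
}

#' @export
print.circular_summary <- function(x, ...) {
  cat("Coordination summary over", x$n_prep, "preparation(s)\n")
  cat(sprintf("  grand mean angle: %.1f deg (r = %.3f)\n",
              x$grand_mean_deg, x$grand_r))
  if (!is.na(x$rayleigh_p)) {
    cat(sprintf("  Rayleigh p = %.4g\n", x$rayleigh_p))
  }
  invisible(x)
}

#' @rdname summarize_coordination
#' @param x A `circular_summary` object.
#' @param ... Unused.
#' @export
tidy.circular_summary <- function(x, ...) x$per_prep

#' @rdname summarize_coordination
#' @export
glance.circular_summary <- function(x, ...) {
  tibble(grand_mean_deg = x$grand_mean_deg, grand_r = x$grand_r,
         rayleigh_p = x$rayleigh_p, n_prep = x$n_prep)
}
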