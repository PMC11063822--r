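---
title: "Analysing fictive locomotion: burst parameters, coordination statistics and calcium maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing fictive locomotion: burst parameters, coordination statistics and calcium maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The experimental system and what this package computes

An isolated neonatal mouse spinal cord bathed in NMDA and serotonin produces
*fictive locomotion*: rhythmic bursting on the lumbar ventral roots that
mirrors the locomotor pattern without any movement. Suction electrodes on the
left and right L2 (flexor-related) and L5 (extensor-related) roots give four
rhythmic channels; during locomotor-like activity, left and right L2 roots
alternate (phase 180°), as do ipsilateral L2 and L5. The same preparations
can carry a genetically encoded calcium indicator, in which case a
transversally cut face of the cord is imaged at 10 frames/s while the roots
are recorded.

`spinalrhythm` implements the complete desk-side analysis for such
experiments:

1. **Burst analysis** — rectified-envelope burst detection and the five
   locomotor parameters (frequency, burst duration, cycle period, duty
   cycle, amplitude) with their coefficients of variation;
2. **Coordination statistics** — cycle-by-cycle phases between root pairs
   and circular statistics (mean angle, vector length *r*, Rayleigh test,
   Watson–Williams test);
3. **Calcium mapping** — normalization of the imaged field to a canonical
   500 × 400-pixel geometry, a fixed 500-ROI grid, ΔF extraction, an
   autocorrelation *oscillation index* per ROI, and cross-correlation
   *phase maps* against a reference ROI or against the root bursts;
4. **Table procedures** — differential-expression threshold filtering with
   transcription-factor ranking, section-coordinate normalization to the
   central canal, and the normality-gated statistical-test selector;
5. **Synthetic data** — generators for all of the above with fully known
   ground truth.

Everything user-facing takes data frames and returns tibbles, so analyses
chain with the pipe; maps and summaries have `autoplot()` methods and
`tidy()`/`glance()` accessors.

## Burst detection and locomotor parameters

The analyses act on *rectified envelopes*: `rectify_and_smooth()` takes the
absolute value of a channel and applies a centred moving average (default
window 0.1 s). `detect_bursts()` then thresholds the envelope at a fraction
(default 0.3) of the range between the envelope minimum (the valley floor)
and the global peak. Supra-threshold intervals separated by less than
`min_interval_s` (default 0.3 s) are merged, and intervals shorter than
`min_duration_s` (default 0.2 s) are discarded. These three knobs are the
entire detection rule; they are exposed as arguments so every analysis is
reproducible from its call. The rule is deliberately simple: it is monotone
(raising the threshold can only remove bursts), and on clean envelopes it
recovers programmed burst counts exactly across the whole 0.1–0.5 Hz
locomotor range.

Each burst carries its internal peak and, as the *valley*, the minimum of
the preceding inter-burst gap (the first burst uses the pre-burst stretch at
the start of the record). Burst amplitude is peak minus valley.

The locomotor parameters follow their field definitions exactly: frequency
is burst count divided by window length (a burst belongs to a window if its
*onset* is inside, which keeps the count/duration identity exact); cycle
period is 1/frequency; duty cycle is mean burst duration over cycle period;
each coefficient of variation is the sample (n − 1) standard deviation over
the mean. The CV of frequency, which needs repeated measurements, is
computed over per-cycle instantaneous frequencies (1 / inter-onset
interval).

Analysis windows are protocol-specific and encoded in
`select_analysis_window()`: a 5-min window 25–30 min after drug onset for
chronic manipulations; the last 4 min before CNO versus the last 4 min of
CNO before washout for acute chemogenetic silencing (with 2-min frequency
bins over the whole time course via `windowed_frequency()`); and
20-s baseline / light / post-light windows for optogenetic epochs. Flexor
(L2) roots are used for all parameters except local stimulation of the
lower lumbar cord, where the extensor (L5) root is analysed
(`choose_analysis_root()`).

## Coordination statistics

Phases are referenced to cycle onsets: for each reference cycle
`[onset_i, onset_{i+1})`, the phase of the single test-burst onset inside it
is the elapsed cycle fraction times 360°. Cycles with zero or multiple test
onsets are skipped and counted, never interpolated. For burst-like signals
this reproduces the mean angle and vector length that wavelet-based phase
extraction reports, which is all the downstream statistics consume; no
time-resolved coherence is attempted.

The circular toolbox is standard: the mean angle is
`atan2(mean sin, mean cos)`, *r* is the mean resultant length, the Rayleigh
test uses `Z = n r̄²` with the small-sample exponential approximation, and
the Watson–Williams test is the high-concentration F statistic with the von
Mises correction `K = 1 + 3/(8 κ̂)`. Below a pooled `r̄` of 0.45 the F
approximation is unreliable and the result carries a warning flag. Both
tests are validated in the test suite against resampling oracles (uniform
resampling for Rayleigh, label permutation for Watson–Williams). Per
convention, 0° is synchrony and 180° alternation; summaries are reported per
preparation, with the grand mean being the circular mean of the
per-preparation mean angles, and the Rayleigh test applied to those means
(an optional variant weights them by each preparation's *r*; it is off by
default since the unweighted form is the common reading).

## The calcium pipeline

`normalize_field()` maps the imaged transverse section onto a canonical
400-row × 500-column field using the five landmark annotations: the cord's
left/right edges go to the lateral borders, dorsal/ventral edges to the top
and bottom, and each hemifield is scaled *independently* so the central
canal lands exactly on the vertical midline (the boundary between columns
250 and 251). Intensities are interpolated bilinearly. Landmarks use pixel
units in which pixel *k* spans `[k − 0.5, k + 0.5]`, so a movie that already
fills the canonical geometry round-trips unchanged.

`build_grid()` tiles each 250 × 400 hemifield with 10 columns × 25 rows of
25 × 16-pixel rectangles — 500 disjoint ROIs covering the field exactly.
Only the ROI count and the right = 1–250 / left = 251–500 split are fixed by
convention; the specific tile shape is this package's choice, made so that an
integer tiling exists, and the raster order (dorsal→ventral within a
lateral→medial sweep) is documented in `?build_grid`.

`extract_delta_f()` computes, per ROI, the footprint-mean fluorescence
`F_t`, the baseline `F0` as the mean of the **last 100 frames**, and
`ΔF = F_t − F0`, then divides every trace by the single maximum ΔF over all
500 ROIs. One global divisor (not per-hemifield) is used throughout,
including for the oscillation-index maps: the side with weaker oscillation
therefore shows values below 1, which is what makes the maps comparable
across the midline. `preprocess_traces()` applies a zero-phase 4th-order
Butterworth low-pass (default cutoff 2 Hz) followed by baseline adjustment
(subtraction of an interpolated rolling 10th percentile over 20-s blocks)
and mean removal; the defaults are package choices, since only "a low-pass
filter and an adjustment of the baseline" is conventionally specified.

The **oscillation index** of a trace is the first side peak of its lagged
autocorrelation minus the trough preceding that peak. We compute the lagged
*Pearson correlation coefficient* (correlating the overlapping segments at
each lag) rather than the biased autocovariance estimator, because the index
is defined by its ±1 correlation endpoints: with this estimator a long pure
sinusoid scores exactly +1 at one period and the index attains its nominal
maximum of 2. The peak is searched within 0.5–2× the expected cycle period
(taken from the concurrent root frequency), which disambiguates the "first"
side peak in noisy traces; white noise scores near 0 and the index grows
monotonically with oscillator signal-to-noise. Per-preparation maps are
normalized to their global maximum, averaged across preparations, and the
ROI with the highest averaged index becomes the **reference ROI**.

**Phase maps** assign each ROI the lag of its cross-correlation maximum with
the reference ROI within ± half a cycle period, expressed as a cycle
fraction in `[0, 1)` (positive = lagging the reference; the reference itself
is exactly 0, flat traces are `NA`, and 0.5 is strict alternation). The peak
lag is refined to sub-sample precision by parabolic interpolation through
the three correlations around the maximum — at 10 frames/s a locomotor
half-cycle is typically a non-integer number of frames, and interpolation
removes that quantization. `root_phase_comparison()` computes the same
quantity against mean-removed burst-train indicators built from the
ipsilateral and contralateral root events, so an ROI locked to its
ipsilateral root scores ~0 against it and ~0.5 against the other side during
alternating activity.

## Table procedures

`filter_de_table()` applies the differential-expression cut
`padj ≤ 0.05` and `|log2FC| ≥ 0.59` with **inclusive** boundaries (the
parenthetical form of the rule), excluding genes without a valid adjusted
p-value; the upstream count model itself (shrinkage, outlier handling,
independent filtering) is consumed, not re-implemented. `rank_top_tf()`
orders a supplied transcription-factor subset by descending `|log2FC|`
(ties by ascending `padj`, then gene id) — the ranking key is a declared
package choice. `normalize_section_coords()` maps cell positions to
`[−1, 1]²` with the central canal at the origin and each side scaled by its
own canal-to-edge extent; `denormalize_section_coords()` inverts it exactly.

`compare_groups()` encodes the test-selection tree: Shapiro–Wilk on every
group at α = 0.05 (the gate's α is a package default, exposed as an
argument); all normal → Welch's t (two unpaired groups), paired t (two
paired), Welch's one-way ANOVA (≥3 unpaired) or repeated-measures ANOVA (≥3
paired); any non-normal → Mann–Whitney U or Wilcoxon signed rank. The
two-group nonparametric branches are the conventional ones; for ≥3 groups
the tree is completed with Kruskal–Wallis (unpaired) and Friedman (paired),
a package choice since only the two-group branches are conventionally
fixed. The chosen test is always part of the output.

## The synthetic generators

The generators exist so that every analysis stage can be exercised against
known ground truth. They synthesize *rectified envelopes* directly (the
analyses never see a raw extracellular waveform, so none is simulated):
each burst is a raised-cosine window — cosine ramps over the first and last
quarter of the burst, flat in between — at the programmed amplitude, plus
additive Gaussian noise. Phase offsets between channels shift burst *onset
times* by a cycle fraction; the default offsets encode the alternating gait
(left–right 180°, flexor–extensor 180°). Envelopes are rendered at 1 kHz by
default — ample for burst timing, given the 0.1–0.5 Hz rhythms and ≥0.2-s
bursts under study.

Condition-specific generators reproduce the experimental designs:
`generate_dose_series()` renders one recording per programmed frequency
(emulating graded NMDA excitation, e.g. the measured 0.21/0.34/0.43 Hz
steps); `generate_cno_timecourse()` ramps the instantaneous burst rate
linearly between two plateaus (minutes-scale chemogenetic silencing), using
quasi-static stepping `t_{k+1} = t_k + 1/rate(t_k)`, valid because the rate
changes on a much slower timescale than a cycle; `generate_light_epoch()`
steps the rate inside 20- or 30-s light windows, including from a silent
(0 Hz) baseline.

`generate_calcium_movie()` drives rectangular oscillator footprints with
periodic burst trains convolved with a single-exponential indicator-decay
kernel (default τ = 0.4 s, typical of fast indicators), offsets the right
hemifield by a programmable cycle fraction (default 0.5, strict
alternation), and adds a constant background plus Gaussian noise; landmark
annotations are attached so the movie is normalizable. All randomness comes
from one seeded generator per call, so identical parameters give
bit-identical output.

**What the generators do not emulate:** drifting frequency within an epoch,
burst-shape asymmetries, electrode artifacts, movement of the preparation,
photobleaching, and out-of-focus fluorescence. Passing the recovery tests
therefore demonstrates that the analysis code implements its definitions
correctly, not that it is robust to every pathology of real recordings.

## Numerical choices and degenerate inputs

* A flat envelope yields zero bursts with a warning, never an error; an
  empty analysis window reports frequency 0 and missing (not 0) ratio
  parameters.
* The circular mean is flagged undefined (`NA`) when `r < 1e−12`
  (e.g. perfectly antipodal angles).
* Burst-onset detection by threshold crossing is systematically late by a
  fraction of the onset ramp; this cancels in all phase computations
  (both channels are detected the same way) and does not affect counts.
* An all-zero oscillation map normalizes to all zeros with a flag rather
  than dividing by zero; ties for the reference ROI resolve to the lowest
  ROI id, with a message.
* `ΔF` traces whose global maximum is non-positive are returned
  unnormalized with `normalized = FALSE`.
* Problem sizes in the test suite: recordings are rendered at 200 Hz to
  1 kHz for 1–10 min, and movies at 80 × 100 px before normalization with
  300–1800 frames — sizes at which every recovery property is already
  exercised end to end.

## Worked example

```{r, eval = FALSE}
library(spinalrhythm)
library(dplyr)

# A 5-minute alternating recording at 0.3 Hz with 5% noise
sched <- synth_schedule(
  tibble(start_s = 0, end_s = 300, freq_hz = 0.3, duty = 0.3, amplitude = 1),
  noise_sd = 0.05, fs = 1000, seed = 21)
vr <- generate_ventral_root(sched)

detect <- function(ch)
  detect_bursts(rectify_and_smooth(vr$recording[[ch]], vr$fs), vr$fs)

locomotor_parameters(detect("lL2"), window = c(0, 300))

phases <- extract_cycle_phases(detect("lL2"), detect("rL2"))
summarize_coordination(phases)   # grand mean ~180 deg: alternation

# Calcium pipeline on a synthetic anti-phase movie
cs <- generate_calcium_movie(freq_hz = 0.4, duration_s = 180, noise_sd = 1)
tr <- cs$movie |> normalize_field() |> extract_delta_f(build_grid()) |>
  preprocess_traces()
om <- oscillation_map(tr, expected_period_range = c(2, 3))
ref <- average_maps_and_reference(list(om))
pm <- phase_map(tr, ref$reference_roi, cycle_period_s = 1 / 0.4)
autoplot(pm)                     # contralateral ROIs near 0.5
```

## Known limitations

* Cycle-onset phase referencing assumes one burst per cycle per channel;
  double bursting is skipped (and counted), which can thin the phase sample
  in irregular rhythms.
* The Watson–Williams F approximation degrades at low concentration; the
  warning flag should be respected rather than suppressed.
* The oscillation index depends on the supplied expected-period range; a
  grossly wrong range can lock onto a harmonic.
* Field normalization is piecewise-affine (per hemifield); it does not
  correct nonlinear tissue distortion.
* The repeated-measures ANOVA branch reports the uncorrected univariate F;
  sphericity corrections are out of scope here.
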