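#' Construct a calcium recording
#'
#' Container for a time-aligned GCaMP recording: neuron and background
#' fluorescence, optionally a 2-D centroid trajectory and the geometry of a
#' circular bacterial lawn.
#'
#' @param time Frame times in seconds, strictly increasing.
#' @param f_neuron,f_background Fluorescence series, same length as `time`.
#' @param x,y Optional centroid coordinates (mm), same length as `time`.
#' @param lawn Optional list `list(center = c(x, y), radius = r)` in mm.
#' @param encounter_frame Optional index of the first on-lawn frame.
#' @return List of class `recording`.
#' @export
recording <- function(time, f_neuron, f_background, x = NULL, y = NULL,
                      lawn = NULL, encounter_frame = NULL) {
  n <- length(time)
  if (length(f_neuron) != n || length(f_background) != n) {
    stop("fluorescence series must match the time base", call. = FALSE)
  }
  if (n > 1 && any(diff(time) <= 0)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  if (!is.null(x) && (length(x) != n || length(y) != n)) {
    stop("trajectory must match the time base", call. = FALSE)
  }
  if (!is.null(lawn) && (is.null(lawn$radius) || lawn$radius <= 0)) {
    stop("lawn radius must be positive", call. = FALSE)
  }
  structure(list(time = as.numeric(time), f_neuron = as.numeric(f_neuron),
                 f_background = as.numeric(f_background),
                 x = if (is.null(x)) NULL else as.numeric(x),
                 y = if (is.null(y)) NULL else as.numeric(y),
                 lawn = lawn, encounter_frame = encounter_frame),
            class = "recording")
}

#' Background subtraction
#'
#' Elementwise `f_neuron - f_background`. Individual frames may come out
#' negative when the neuron is dim and noise dominates.
#'
#' @param rec A `recording`.
#' @return Numeric series of background-subtracted fluorescence.
#' @export
subtract_background <- function(rec) {
  if (length(rec$f_neuron) != length(rec$f_background)) {
    stop("neuron and background series differ in length", call. = FALSE)
  }
  rec$f_neuron - rec$f_background
}

#' Moving median smoothing
#'
#' Centred sliding-window median; for an even window of `w` frames the window
#' at index `i` spans `i - floor((w-1)/2)` through `i + ceiling((w-1)/2)`.
#' Edge windows are truncated to the available samples, so the output has the
#' same length as the input. The 10-frame default corresponds to 1 s at the
#' 10 fps acquisition rate.
#'
#' @param series Numeric series.
#' @param window Window length in frames (>= 1, default 10).
#' @return Smoothed series, same length as the input.
#' @export
moving_median <- function(series, window = 10L) {
  n <- length(series)
  if (n == 0) stop("empty series", call. = FALSE)
  if (window < 1) stop("window must be >= 1", call. = FALSE)
  left <- floor((window - 1) / 2)
  right <- window - 1 - left
  vapply(seq_len(n), function(i) {
    stats::median(series[max(1, i - left):min(n, i + right)])
  }, numeric(1))
}

#' Percentile baseline
#'
#' q-th percentile of a fluorescence series under the linear-interpolation
#' convention (R's default quantile type 7). Used as F0 for dF/F0, so a
#' non-positive value is an error rather than a silent division problem.
#'
#' @param series Numeric series (typically the smoothed, background-subtracted
#'   trace).
#' @param q Percentile in percent (default 5).
#' @return Baseline scalar.
#' @export
percentile_baseline <- function(series, q = 5) {
  if (!length(series)) stop("empty series", call. = FALSE)
  baseline <- unname(stats::quantile(series, q / 100, type = 7, names = FALSE))
  if (baseline <= 0) {
    stop("baseline is not positive (", format(baseline),
         "); dF/F0 undefined", call. = FALSE)
  }
  baseline
}

#' dF/F0 trace for a freely-moving recording
#'
#' Background-subtracts, smooths with a centred moving median, takes the
#' baseline as the q-th percentile of the smoothed trace over the whole
#' recording, and returns `(smoothed - baseline) / baseline`.
#'
#' @param rec A `recording`.
#' @param window Moving-median window in frames (default 10 = 1 s at 10 fps).
#' @param baseline_percentile Baseline percentile (default 5).
#' @return List of class `dff_trace`: `time`, `dff`, `smoothed`, `baseline`,
#'   plus the recording's trajectory/lawn fields carried through.
#' @export
compute_dff <- function(rec, window = 10L, baseline_percentile = 5) {
  subtracted <- subtract_background(rec)
  smoothed <- moving_median(subtracted, window = window)
  baseline <- percentile_baseline(smoothed, q = baseline_percentile)
  structure(list(
    time = rec$time,
    dff = (smoothed - baseline) / baseline,
    smoothed = smoothed,
    baseline = baseline,
    x = rec$x, y = rec$y, lawn = rec$lawn,
    encounter_frame = rec$encounter_frame
  ), class = "dff_trace")
}

#' Detect calcium transients in a dF/F0 trace
#'
#' Local maxima of the dF/F0 series above `min_amplitude`, kept greedily in
#' decreasing amplitude order subject to a minimum separation in time.
#' Duration is the full width at half maximum: the contiguous stretch around
#' the peak where dF/F0 stays above half the peak amplitude.
#'
#' @param trace `dff_trace` from [compute_dff()].
#' @param min_amplitude Detection threshold in dF/F0 units (default 0.2).
#' @param min_separation Minimum peak separation in seconds (default 2).
#' @return Tibble with one row per peak: `time`, `amplitude`, `duration`,
#'   `start`, `end` (frame indices of the half-maximum region).
#' @export
detect_peaks <- function(trace, min_amplitude = 0.2, min_separation = 2) {
  if (min_amplitude <= 0 || min_separation <= 0) {
    stop("detection thresholds must be positive", call. = FALSE)
  }
  dff <- trace$dff
  time <- trace$time
  n <- length(dff)
  if (n < 3) {
    return(tibble::tibble(time = numeric(0), amplitude = numeric(0),
                          duration = numeric(0), start = integer(0),
                          end = integer(0)))
  }
  i <- 2:(n - 1)
  cand <- i[dff[i] > dff[i - 1] & dff[i] >= dff[i + 1] & dff[i] >= min_amplitude]
  cand <- cand[order(dff[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (idx in cand) {
    if (!length(kept) || all(abs(time[idx] - time[kept]) >= min_separation)) {
      kept <- c(kept, idx)
    }
  }
  kept <- sort(kept)
  rows <- lapply(kept, function(idx) {
    half <- dff[idx] / 2
    s <- idx; while (s > 1 && dff[s - 1] >= half) s <- s - 1
    e <- idx; while (e < n && dff[e + 1] >= half) e <- e + 1
    fwhm <- time[e] - time[s]
    tibble::tibble(time = time[idx], amplitude = dff[idx], duration = fwhm,
                   start = as.integer(s), end = as.integer(e))
  })
  if (!length(rows)) {
    return(tibble::tibble(time = numeric(0), amplitude = numeric(0),
                          duration = numeric(0), start = integer(0),
                          end = integer(0)))
  }
  do.call(rbind, rows)
}

#' Epoch configuration for microfluidic odor-delivery trials
#'
#' Default windows for a 30 s trial: baseline window for F0 at seconds 2-3,
#' `Pre` 0.0-4.9 s, `Stim` (odor pulse) 5.0-15.0 s, `Post` 15.1-29.9 s. All
#' bounds are inclusive; frames falling between two windows (e.g. in
#' (4.9, 5.0)) belong to neither.
#'
#' @param pre,stim,post Length-2 numeric windows in seconds.
#' @param f0_window Window over which F0 is averaged.
#' @return List of class `epoch_config`.
#' @export
epoch_config <- function(pre = c(0.0, 4.9), stim = c(5.0, 15.0),
                         post = c(15.1, 29.9), f0_window = c(2.0, 3.0)) {
  for (w in list(pre, stim, post, f0_window)) {
    if (length(w) != 2 || w[2] <= w[1]) {
      stop("each epoch window must be an increasing length-2 vector",
           call. = FALSE)
    }
  }
  structure(list(pre = pre, stim = stim, post = post, f0_window = f0_window),
            class = "epoch_config")
}

in_window <- function(time, w, tol = 1e-8) {
  time >= w[1] - tol & time <= w[2] + tol
}

#' Percent fluorescence change and epoch maxima (microfluidic trials)
#'
#' F0 is the mean background-subtracted fluorescence over the F0 window
#' (seconds 2-3 by default); each frame is expressed as
#' `(F/F0 - 1) * 100` percent, and the maximum percent change is reported for
#' the Pre, Stim and Post windows.
#'
#' @param f Background-subtracted fluorescence series.
#' @param time Frame times in seconds (same length as `f`).
#' @param cfg `epoch_config` (defaults as printed above).
#' @return List with `percent` (series), `f0`, `pre_max`, `stim_max`,
#'   `post_max`.
#' @export
microfluidic_percent_change <- function(f, time, cfg = epoch_config()) {
  if (length(f) != length(time)) stop("f and time differ in length", call. = FALSE)
  sel <- in_window(time, cfg$f0_window)
  if (!any(sel)) stop("no frames inside the F0 window", call. = FALSE)
  f0 <- mean(f[sel])
  if (f0 <= 0) stop("F0 is not positive; percent change undefined", call. = FALSE)
  percent <- (f / f0 - 1) * 100
  epoch_max <- function(w) {
    inside <- in_window(time, w)
    if (!any(inside)) NA_real_ else max(percent[inside])
  }
  list(percent = percent, f0 = f0,
       pre_max = epoch_max(cfg$pre),
       stim_max = epoch_max(cfg$stim),
       post_max = epoch_max(cfg$post))
}

#' Signed distance to the lawn boundary
#'
#' Euclidean distance from each trajectory point to the boundary of a
#' circular lawn: positive outside, zero on the boundary, negative inside.
#' The signed convention keeps the distance continuous through the encounter,
#' so pre- and post-encounter frames share one axis.
#'
#' @param x,y Centroid coordinates in mm.
#' @param lawn List `list(center = c(x, y), radius = r)`.
#' @return Numeric series of signed distances (mm).
#' @export
distance_to_lawn <- function(x, y, lawn) {
  if (is.null(lawn)) stop("lawn geometry required", call. = FALSE)
  sqrt((x - lawn$center[1])^2 + (y - lawn$center[2])^2) - lawn$radius
}

#' Bin dF/F0 by distance from the lawn boundary
#'
#' Half-open bins `[d, d + width)` aligned to multiples of the bin width.
#' Bins inside the spanned range with no frames are reported with `n = 0`.
#'
#' @param dff dF/F0 series.
#' @param distance Signed distance series (mm), same length.
#' @param bin_width Bin width in mm (default 0.5).
#' @return Tibble with `bin_lo`, `bin_hi`, `bin_mid`, `mean`, `sem`, `n`.
#' @export
bin_dff_by_distance <- function(dff, distance, bin_width = 0.5) {
  if (length(dff) != length(distance)) {
    stop("dff and distance differ in length", call. = FALSE)
  }
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  idx <- floor(distance / bin_width)
  lo <- min(idx):max(idx)
  rows <- lapply(lo, function(b) {
    sel <- idx == b
    n <- sum(sel)
    tibble::tibble(
      bin_lo = b * bin_width, bin_hi = (b + 1) * bin_width,
      bin_mid = (b + 0.5) * bin_width,
      mean = if (n) mean(dff[sel]) else NA_real_,
      sem = if (n > 1) stats::sd(dff[sel]) / sqrt(n) else NA_real_,
      n = as.integer(n)
    )
  })
  do.call(rbind, rows)
}

#' Two-way ANOVA for a feeding-state effect on binned dF/F0
#'
#' Fixed-effects two-way ANOVA of per-animal bin means against feeding state
#' and distance bin (with interaction), the test behind "significant effect
#' of feeding state" on distance-binned GCaMP signal.
#'
#' @param binned Data frame with one row per (animal, bin): columns `animal`,
#'   `state`, `bin`, `dff`.
#' @return Tibble from [two_way_anova()] with terms `state`, `bin`,
#'   `state:bin`.
#' @export
state_effect_anova <- function(binned) {
  binned <- as.data.frame(binned)
  req <- c("animal", "state", "bin", "dff")
  if (!all(req %in% names(binned))) {
    stop("binned data needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(binned$bin)) < 2) stop(">= 2 bins required", call. = FALSE)
  per_state <- tapply(binned$animal, binned$state,
                      function(a) length(unique(a)))
  if (any(per_state < 2)) stop(">= 2 animals per state required", call. = FALSE)
  two_way_anova(binned, response = "dff", factor_a = "state", factor_b = "bin")
}
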