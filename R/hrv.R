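# Heart-rate variability from the optical signal.
#
# The cardiac pulse rides on the 830 nm optical-density traces; after
# band-limiting to 0.01-2 Hz the beat peaks are detected and SDNN (the sample
# standard deviation of normal-to-normal beat intervals) summarises
# beat-to-beat variability.

#' Cardiac band filter for the 830 nm optical-density signal
#'
#' Band-passes the signal to 0.01-2 Hz, removing baseline drift and
#' out-of-band noise while preserving the cardiac fundamental (1-1.5 Hz).
#'
#' @param od830 numeric vector (or channel x time matrix) of 830 nm optical
#'   density.
#' @param rate sampling rate in Hz; must exceed 4 Hz so the 2 Hz upper edge
#'   is below Nyquist.
#' @return filtered signal of the same shape.
#' @export
cardiac_filter <- function(od830, rate) {
  if (rate <= 4) stopf("cardiac filtering needs a sampling rate above 4 Hz (got %g)", rate)
  # remove the mean first: a finite record resolves the 0.01 Hz edge poorly,
  # so the high-pass alone leaves a DC transient
  if (is.matrix(od830)) od830 <- od830 - rowMeans(od830)
  else od830 <- od830 - mean(od830)
  bandpass_filter(od830, 0.01, 2, rate)
}

# Topographic prominence of each candidate local maximum: height above the
# higher of the two minima separating it from higher terrain on either side.
peak_prominences <- function(x, idx) {
  n <- length(x)
  vapply(idx, function(i) {
    h <- x[i]
    lmin <- h; j <- i - 1
    while (j >= 1 && x[j] <= h) { lmin <- min(lmin, x[j]); j <- j - 1 }
    rmin <- h; j <- i + 1
    while (j <= n && x[j] <= h) { rmin <- min(rmin, x[j]); j <- j + 1 }
    h - max(lmin, rmin)
  }, 0)
}

#' Detect heartbeat peaks in a cardiac signal
#'
#' Local-maximum detection with an adaptive prominence threshold and a
#' refractory period: candidate maxima must have topographic prominence
#' above a fraction of the large-peak (95th percentile) prominence, and
#' accepted peaks (greedily, by prominence) must be at least `min_period_s`
#' apart. The prominence criterion makes detection insensitive to the slow
#' drifts that survive the 0.01-2 Hz cardiac band. Peak times are refined to
#' sub-sample resolution by parabolic interpolation through each maximum
#' (disable with `refine = FALSE` for strict sample-resolution times).
#'
#' @param x numeric vector, cardiac-band signal.
#' @param rate sampling rate in Hz.
#' @param min_period_s refractory period in seconds (default 0.4 s, i.e. a
#'   150 bpm ceiling).
#' @param prominence fraction of the 95th-percentile candidate prominence a
#'   peak must exceed (default 0.35).
#' @param refine parabolic sub-sample refinement of peak times (default
#'   TRUE).
#' @return numeric vector of peak times in seconds, increasing.
#' @export
detect_peaks <- function(x, rate, min_period_s = 0.4, prominence = 0.35,
                         refine = TRUE) {
  if (min_period_s <= 0) stopf("`min_period_s` must be positive")
  n <- length(x)
  if (n < 3) stopf("insufficient data: signal too short for peak detection")
  cand <- which(c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
                  FALSE))
  if (length(cand) < 3)
    stopf("insufficient data: fewer than 3 candidate peaks detected")
  pr <- peak_prominences(x, cand)
  thr <- prominence * stats::quantile(pr, 0.95, names = FALSE)
  keep_cand <- cand[pr > thr]
  pr <- pr[cand %in% keep_cand]
  if (length(keep_cand) < 3)
    stopf("insufficient data: fewer than 3 prominent peaks detected")
  min_gap <- min_period_s * rate
  keep <- integer(0)
  for (i in keep_cand[order(pr, decreasing = TRUE)]) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  if (length(keep) < 3)
    stopf("insufficient data: fewer than 3 peaks after refractory pruning")
  keep <- sort(keep)
  t_pk <- (keep - 1) / rate
  if (refine) {
    ok <- keep > 1 & keep < n
    num <- x[keep[ok] - 1] - x[keep[ok] + 1]
    den <- x[keep[ok] - 1] - 2 * x[keep[ok]] + x[keep[ok] + 1]
    shift <- ifelse(abs(den) > 1e-12, num / (2 * den), 0)
    t_pk[ok] <- t_pk[ok] + pmax(-0.5, pmin(0.5, shift)) / rate
  }
  t_pk
}

#' SDNN from beat times
#'
#' Computes normal-to-normal intervals `rr_i = t_{i+1} - t_i`, their mean, and
#' SDNN as the sample standard deviation
#' `sqrt( sum (rr_i - mean_rr)^2 / (N - 2) )` over the `N - 1` intervals
#' derived from `N` peaks.
#'
#' @param peak_times numeric vector of at least 3 beat times in seconds.
#' @return object of class `hrv_result`: list with `peak_times`,
#'   `rr_intervals`, `mean_rr`, `sdnn` (all in seconds) and `n_peaks`.
#' @export
sdnn <- function(peak_times) {
  if (length(peak_times) < 3)
    stopf("SDNN needs at least 3 peaks (got %d)", length(peak_times))
  if (any(diff(peak_times) <= 0)) stopf("peak times must be strictly increasing")
  rr <- diff(peak_times)
  structure(list(peak_times = peak_times, rr_intervals = rr,
                 mean_rr = mean(rr), sdnn = stats::sd(rr),
                 n_peaks = length(peak_times)),
            class = "hrv_result")
}

#' @export
print.hrv_result <- function(x, ...) {
  cat(sprintf("<hrv_result> %d peaks, mean RR %.3f s (%.1f bpm), SDNN %.1f ms\n",
              x$n_peaks, x$mean_rr, 60 / x$mean_rr, 1000 * x$sdnn))
  invisible(x)
}

#' Estimate HRV from a recording phase
#'
#' Extracts the cardiac signal from the 830 nm optical-density traces of a
#' session phase, band-limits it to 0.01-2 Hz, detects beats and computes
#' SDNN. By default the cardiac source is the first principal component
#' across all channels (averaging over channels boosts pulse SNR); a single
#' channel can be requested instead. Because the 0.01-2 Hz band still
#' carries hemodynamic fluctuations much larger than the pulse, detection is
#' two-stage: the cardiac fundamental is located as the dominant spectral
#' peak in 0.6-2 Hz, the signal is re-band-limited to 0.5-2 times that
#' frequency, and peaks are detected there.
#'
#' @param rec a [nirs_recording()] whose `phases` table contains `phase`.
#' @param phase session phase to analyse (`"rest_pre"`, `"breathing"`,
#'   `"rest_post"`).
#' @param channel optional single channel id; `NULL` (default) uses the first
#'   principal component over all channels.
#' @param min_period_s refractory period for [detect_peaks()].
#' @return an `hrv_result`.
#' @export
estimate_hrv <- function(rec, phase = "rest_pre", channel = NULL,
                         min_period_s = 0.4) {
  stopifnot(inherits(rec, "nirs_recording"))
  if (is.null(rec$phases) || !phase %in% rec$phases$phase)
    stopf("recording has no phase '%s'", phase)
  ph <- rec$phases[rec$phases$phase == phase, ][1, ]
  od <- intensity_to_od(rec)
  w830 <- which(abs(od$wavelengths - 830) < 1e-6)
  if (!length(w830)) stopf("recording has no 830 nm wavelength")
  fs <- rec$sampling_rate
  i0 <- floor(ph$onset * fs) + 1L
  i1 <- min(dim(od$od)[3], ceiling((ph$onset + ph$duration) * fs))
  seg <- od$od[, w830, i0:i1, drop = TRUE]
  sig <- if (!is.null(channel)) {
    seg[channel, ]
  } else {
    # first PC over channels: dominant shared oscillation = cardiac pulse
    sc <- stats::prcomp(t(seg), center = TRUE, scale. = FALSE)$x[, 1]
    # orient so that systolic peaks point up
    if (abs(min(sc)) > abs(max(sc))) sc <- -sc
    sc
  }
  filtered <- cardiac_filter(sig, fs)
  sp <- stats::spec.pgram(filtered, plot = FALSE, spans = 25)
  fr <- sp$freq * fs
  in_card <- fr > 0.6 & fr < 2
  if (!any(in_card)) stopf("segment too short to locate a cardiac peak")
  f0 <- fr[in_card][which.max(sp$spec[in_card])]
  narrow <- bandpass_filter(filtered, 0.5 * f0, min(2 * f0, 0.95 * fs / 2), fs)
  if (abs(min(narrow)) > abs(max(narrow))) narrow <- -narrow
  sdnn(detect_peaks(narrow, fs, min_period_s = min_period_s))
}
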