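# Optical-density / hemoglobin conversion, resampling and band filtering.

#' Molar extinction coefficients for HbO2 and Hb
#'
#' Compiled molar extinction coefficients (cm^-1 per mol/L) of oxy- and
#' deoxyhemoglobin at the two laser wavelengths. Rows are wavelengths in nm,
#' columns `HbO` and `HbR`. The standard compiled values for 690 and 830 nm
#' are shipped as the default; any 2x2 table over two wavelengths with an
#' invertible cross-section can be supplied instead.
#'
#' @param wavelengths numeric vector of wavelengths; only 690 and 830 nm are
#'   built in.
#' @return numeric matrix with rownames = wavelengths, colnames HbO, HbR.
#' @export
extinction_coefficients <- function(wavelengths = c(690, 830)) {
  tab <- rbind(`690` = c(HbO = 276.00, HbR = 2051.96),
               `830` = c(HbO = 974.00, HbR = 693.04))
  key <- as.character(wavelengths)
  miss <- setdiff(key, rownames(tab))
  if (length(miss))
    stopf("no built-in extinction coefficients for wavelength(s) %s nm; supply a table",
          paste(miss, collapse = ", "))
  tab[key, , drop = FALSE]
}

#' Convert raw intensities to optical-density changes
#'
#' Computes `dOD(t) = -log(I(t) / Ibar)` per channel and wavelength, where
#' `Ibar` is the temporal geometric mean of that channel/wavelength over the
#' whole session (the mean optical density). With this baseline each dOD
#' trace has exactly zero mean, so every downstream concentration change is
#' referenced to the session mean; an arithmetic-mean baseline would leave a
#' spurious DC offset of half the OD variance (Jensen gap).
#'
#' @param rec a [nirs_recording()] (strictly positive intensities).
#' @return object of class `od_series`: list with `od` (channel x wavelength
#'   x time array), `sampling_rate`, `wavelengths`, `layout`.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "nirs_recording"))
  ints <- rec$intensities
  bad <- which(ints <= 0)
  if (length(bad)) {
    k <- arrayInd(bad[1], dim(ints))
    stopf("non-positive intensity at channel %d, wavelength %g nm, sample %d",
          k[1], rec$layout$wavelengths[k[2]], k[3])
  }
  dims <- dim(ints)
  od <- array(0, dims)
  for (ch in seq_len(dims[1])) for (w in seq_len(dims[2])) {
    lx <- log(ints[ch, w, ])
    od[ch, w, ] <- -(lx - mean(lx))
  }
  structure(list(od = od, sampling_rate = rec$sampling_rate,
                 wavelengths = rec$layout$wavelengths, layout = rec$layout),
            class = "od_series")
}

#' Invert the modified Beer-Lambert law
#'
#' Per time point solves the 2x2 linear system
#' `dOD_lambda = sum_c eps(c, lambda) * dC_c * L * DPF_lambda`
#' for the oxy- and deoxyhemoglobin concentration changes `dC` (in uM), where
#' `L` is the emitter-detector separation in cm and `DPF` the differential
#' pathlength factor per wavelength.
#'
#' @param od an `od_series` from [intensity_to_od()].
#' @param dpf differential pathlength factors, one per wavelength (default
#'   6.0 at both wavelengths).
#' @param separation_cm emitter-detector separation in cm; defaults to the
#'   layout's nominal separation.
#' @param extinction 2x2 extinction table as from [extinction_coefficients()].
#' @return object of class `hemoglobin_series`: list with `hbo`, `hbr`
#'   (channel x time matrices, uM), `sampling_rate`, `layout`, `provenance`.
#' @export
od_to_hemoglobin <- function(od, dpf = c(6, 6), separation_cm = NULL,
                             extinction = NULL) {
  stopifnot(inherits(od, "od_series"))
  wl <- od$wavelengths
  if (length(dpf) == 1) dpf <- rep(dpf, length(wl))
  if (length(dpf) != length(wl))
    stopf("`dpf` must supply one factor per wavelength")
  separation_cm <- separation_cm %||% od$layout$separation_cm
  extinction <- extinction %||% extinction_coefficients(wl)
  if (abs(det(extinction)) < 1e-12)
    stopf("extinction matrix is singular; the two wavelengths do not separate HbO from HbR")
  # dOD = E %*% C * 1e-6 * L * dpf  (C in uM, E in cm^-1 M^-1, L in cm)
  A <- extinction * (separation_cm * 1e-6) * dpf   # row-wise dpf scaling
  Ainv <- solve(A)
  n_ch <- dim(od$od)[1]; n_t <- dim(od$od)[3]
  hbo <- matrix(0, n_ch, n_t); hbr <- matrix(0, n_ch, n_t)
  for (ch in seq_len(n_ch)) {
    conc <- Ainv %*% od$od[ch, , ]
    hbo[ch, ] <- conc[1, ]
    hbr[ch, ] <- conc[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, sampling_rate = od$sampling_rate,
                 layout = od$layout,
                 provenance = list(dpf = dpf, separation_cm = separation_cm,
                                   extinction = extinction)),
            class = "hemoglobin_series")
}

#' Forward modified Beer-Lambert projection
#'
#' Maps hemoglobin concentration changes (uM) to optical-density changes per
#' wavelength; the exact inverse of [od_to_hemoglobin()]. Used by the
#' simulator and by round-trip tests.
#'
#' @param hbo,hbr channel x time matrices of concentration change in uM.
#' @param wavelengths wavelengths in nm.
#' @inheritParams od_to_hemoglobin
#' @return channel x wavelength x time array of dOD.
#' @export
hemoglobin_to_od <- function(hbo, hbr, wavelengths = c(690, 830),
                             dpf = c(6, 6), separation_cm = 3,
                             extinction = NULL) {
  extinction <- extinction %||% extinction_coefficients(wavelengths)
  if (length(dpf) == 1) dpf <- rep(dpf, length(wavelengths))
  A <- extinction * (separation_cm * 1e-6) * dpf
  n_ch <- nrow(hbo); n_t <- ncol(hbo)
  od <- array(0, c(n_ch, length(wavelengths), n_t))
  for (ch in seq_len(n_ch)) {
    od[ch, , ] <- A %*% rbind(hbo[ch, ], hbr[ch, ])
  }
  od
}

# Zero-phase anti-aliased decimation of one trace: Butterworth low-pass at
# 90% of the target Nyquist through filtfilt (no group delay), then spline
# evaluation on the target sample grid. Decimation therefore introduces no
# temporal shift of event-locked responses.
anti_alias_resample <- function(x, fs, target_hz) {
  n_out <- floor(length(x) * target_hz / fs)
  lp <- signal::butter(6, 0.9 * target_hz / fs, type = "low")
  xf <- signal::filtfilt(lp, x)
  t_in <- (seq_along(x) - 1) / fs
  t_out <- (seq_len(n_out) - 1) / target_hz
  stats::spline(t_in, xf, xout = t_out)$y
}

#' Anti-aliased resampling of a hemoglobin series
#'
#' Zero-phase anti-aliased decimation of both hemoglobin traces to a lower
#' rate, as required before first-level modeling (2 Hz) and connectivity
#' (4 Hz): a low-pass at 90% of the target Nyquist applied forward-backward
#' (no group delay), followed by interpolation onto the target grid. Output
#' length is `floor(n * target / current)`; the signal mean and the timing
#' of event-locked responses are preserved.
#'
#' @param hb a `hemoglobin_series`.
#' @param target_hz target sampling rate, `0 < target_hz <=` current rate.
#' @param components which traces to resample (default both; analyses that
#'   model HbO only can skip the HbR work, in which case the HbR trace is
#'   replaced by zeros of the output length).
#' @return a `hemoglobin_series` at `target_hz`.
#' @export
resample_hemoglobin <- function(hb, target_hz, components = c("hbo", "hbr")) {
  stopifnot(inherits(hb, "hemoglobin_series"))
  fs <- hb$sampling_rate
  if (!is.numeric(target_hz) || target_hz <= 0 || target_hz > fs + 1e-9)
    stopf("`target_hz` must be in (0, %g]", fs)
  if (abs(target_hz - fs) < 1e-9) return(hb)
  res <- function(m) t(apply(m, 1, anti_alias_resample, fs = fs,
                             target_hz = target_hz))
  n_out <- floor(ncol(hb$hbo) * target_hz / fs)
  hbo <- if ("hbo" %in% components) res(hb$hbo) else
    matrix(0, nrow(hb$hbo), n_out)
  hbr <- if ("hbr" %in% components) res(hb$hbr) else
    matrix(0, nrow(hb$hbr), n_out)
  structure(list(hbo = hbo, hbr = hbr, sampling_rate = target_hz,
                 layout = hb$layout, provenance = hb$provenance),
            class = "hemoglobin_series")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) Butterworth filtering implemented as a
#' high-pass/low-pass cascade, 4th order per section. The cascade keeps the
#' design numerically stable when the lower edge sits far below Nyquist
#' (e.g. 0.01 Hz at 25 Hz sampling). A `low_hz` of 0 gives a pure low-pass.
#' Through the zero-phase pass a mid-band sinusoid retains more than 95% of
#' its amplitude while a tone an octave beyond either edge is attenuated by
#' more than 90%.
#'
#' @param x numeric vector, or channel x time matrix (rows filtered
#'   independently).
#' @param low_hz,high_hz band edges in Hz, `0 <= low_hz < high_hz < rate/2`.
#' @param rate sampling rate in Hz.
#' @param order Butterworth order per section (default 4).
#' @return filtered vector/matrix of the same shape.
#' @export
bandpass_filter <- function(x, low_hz, high_hz, rate, order = 4) {
  nyq <- rate / 2
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz < 0 ||
      high_hz <= low_hz || high_hz >= nyq)
    stopf("infeasible band [%g, %g] Hz at sampling rate %g Hz (need 0 <= low < high < %g)",
          low_hz, high_hz, rate, nyq)
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  hp <- if (low_hz > 0) signal::butter(order, low_hz / nyq, type = "high") else NULL
  f1 <- function(v) {
    y <- signal::filtfilt(lp, v)
    if (!is.null(hp)) y <- signal::filtfilt(hp, y)
    y
  }
  if (is.matrix(x)) t(apply(x, 1, f1)) else f1(x)
}

#' Band-filter a hemoglobin series
#'
#' Applies [bandpass_filter()] to both hemoglobin traces.
#'
#' @param hb a `hemoglobin_series`.
#' @inheritParams bandpass_filter
#' @return a `hemoglobin_series` with filtered traces.
#' @export
bandpass_hemoglobin <- function(hb, low_hz, high_hz, order = 4) {
  stopifnot(inherits(hb, "hemoglobin_series"))
  hb$hbo <- bandpass_filter(hb$hbo, low_hz, high_hz, hb$sampling_rate, order)
  hb$hbr <- bandpass_filter(hb$hbr, low_hz, high_hz, hb$sampling_rate, order)
  hb
}

#' Crop a hemoglobin series to a time window or session phase
#'
#' @param hb a `hemoglobin_series`.
#' @param start_s,end_s half-open window `[start_s, end_s)` in seconds.
#' @return a `hemoglobin_series` restricted to the window.
#' @export
crop_hemoglobin <- function(hb, start_s, end_s) {
  stopifnot(inherits(hb, "hemoglobin_series"))
  n <- ncol(hb$hbo)
  i0 <- max(1L, floor(start_s * hb$sampling_rate) + 1L)
  i1 <- min(n, ceiling(end_s * hb$sampling_rate))
  if (i1 < i0) stopf("empty crop window [%g, %g) s", start_s, end_s)
  hb$hbo <- hb$hbo[, i0:i1, drop = FALSE]
  hb$hbr <- hb$hbr[, i0:i1, drop = FALSE]
  hb
}

#' Convert a recording straight to hemoglobin concentrations
#'
#' Convenience chain: [intensity_to_od()] then [od_to_hemoglobin()].
#'
#' @inheritParams intensity_to_od
#' @inheritParams od_to_hemoglobin
#' @return a `hemoglobin_series`.
#' @export
recording_to_hemoglobin <- function(rec, dpf = c(6, 6), extinction = NULL) {
  od_to_hemoglobin(intensity_to_od(rec), dpf = dpf, extinction = extinction)
}
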