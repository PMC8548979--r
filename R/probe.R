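#' Probe layout for a two-wavelength fNIRS montage
#'
#' A probe layout describes the optode montage: which emitter-detector pairs
#' form measurement channels, the laser wavelengths, the nominal
#' emitter-detector separation, and a static map from each channel to the
#' anatomical region its midpoint overlies. Channels are kept in canonical
#' order, sorted by (emitter, detector); every matrix produced downstream
#' (activation maps, connectivity matrices) indexes channels in this order.
#'
#' @param channels data.frame with integer columns `emitter` and `detector`,
#'   one row per channel.
#' @param wavelengths numeric vector of laser wavelengths in nm.
#' @param separation_cm nominal emitter-detector separation in cm.
#' @param region_map character vector of region labels, one per channel, each
#'   one of [region_labels()].
#' @return an object of class `probe_layout`.
#' @seealso [default_probe_layout()] for the 8-emitter, 28-detector,
#'   45-channel montage used throughout.
#' @export
probe_layout <- function(channels, wavelengths = c(690, 830),
                         separation_cm = 3, region_map) {
  if (!is.data.frame(channels) || !all(c("emitter", "detector") %in% names(channels)))
    stopf("`channels` must be a data.frame with columns emitter, detector")
  channels <- channels[order(channels$emitter, channels$detector), , drop = FALSE]
  rownames(channels) <- NULL
  if (anyDuplicated(channels[c("emitter", "detector")]))
    stopf("duplicate emitter-detector pairs in channel list")
  if (length(wavelengths) < 2 || anyDuplicated(wavelengths))
    stopf("at least two distinct wavelengths are required")
  if (!is.numeric(separation_cm) || separation_cm <= 0)
    stopf("`separation_cm` must be a positive number")
  if (length(region_map) != nrow(channels))
    stopf("`region_map` must name a region for each of the %d channels (got %d)",
          nrow(channels), length(region_map))
  bad <- setdiff(unique(region_map), region_labels())
  if (length(bad))
    stopf("unknown region label(s): %s; valid labels are: %s",
          paste(bad, collapse = ", "), paste(region_labels(), collapse = ", "))
  channels$channel <- seq_len(nrow(channels))
  channels$region <- as.character(region_map)
  structure(
    list(
      emitters = sort(unique(channels$emitter)),
      detectors = sort(unique(channels$detector)),
      channels = channels[c("channel", "emitter", "detector", "region")],
      wavelengths = as.numeric(wavelengths),
      separation_cm = as.numeric(separation_cm)
    ),
    class = "probe_layout"
  )
}

#' Valid anatomical region labels
#'
#' The static channel-to-region vocabulary: bilateral anterior prefrontal
#' cortex (aPFC), dorsolateral prefrontal cortex (DLPFC), premotor cortex
#' (PMC), supplementary motor area (SMA), motor cortex (M1), primary
#' somatosensory cortex (S1), visual cortex (V1), superior temporal gyrus
#' (STG), temporo-parietal junction (TPJ), inferior parietal lobule (IPL),
#' and `other` for channels outside these regions.
#'
#' @return character vector of valid labels.
#' @export
region_labels <- function() {
  c("aPFC", "DLPFC", "PMC", "SMA", "M1", "S1", "V1", "STG", "TPJ", "IPL", "other")
}

#' Default study montage: 8 emitters, 28 detectors, 45 channels
#'
#' Builds the standard montage used by the simulator and examples: 45
#' emitter-detector channels at 3 cm separation measured at 690 and 830 nm,
#' with a fixed channel-to-region table covering prefrontal, sensorimotor,
#' temporal, parietal and occipital regions. The exact pairing is a
#' deterministic stand-in with the correct emitter/detector/channel counts;
#' the published montage does not include a machine-readable pairing list, so
#' only the counts and the region vocabulary are meaningful.
#'
#' @return a [probe_layout()].
#' @export
default_probe_layout <- function() {
  counts <- c(6, 6, 6, 6, 6, 5, 5, 5)  # 45 channels over 8 emitters
  chans <- do.call(rbind, lapply(seq_along(counts), function(e) {
    k <- counts[e]
    start <- round((e - 1) * (28 - k) / 7) + 1
    data.frame(emitter = e, detector = start:(start + k - 1))
  }))
  regions <- character(45)
  regions[1:8] <- "aPFC"
  regions[9:14] <- "PMC"
  regions[c(15:21, 24, 25, 41)] <- "other"
  regions[c(22, 23, 42)] <- "STG"
  regions[c(26, 33, 34)] <- "SMA"
  regions[27:28] <- "M1"
  regions[c(29, 30, 35, 36)] <- "S1"
  regions[31:32] <- "DLPFC"
  regions[37:38] <- "IPL"
  regions[39:40] <- "TPJ"
  regions[43:45] <- "V1"
  probe_layout(chans, wavelengths = c(690, 830), separation_cm = 3,
               region_map = regions)
}

#' Channels belonging to an anatomical region
#'
#' @param layout a [probe_layout()].
#' @param region a single region label from [region_labels()].
#' @return integer vector of channel ids (possibly empty).
#' @export
region_channels <- function(layout, region) {
  stopifnot(inherits(layout, "probe_layout"))
  if (length(region) != 1 || !region %in% region_labels())
    stopf("unknown region label '%s'; valid labels are: %s",
          as.character(region)[1], paste(region_labels(), collapse = ", "))
  layout$channels$channel[layout$channels$region == region]
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("<probe_layout> %d emitters, %d detectors, %d channels @ %s nm, %.1f cm\n",
              length(x$emitters), length(x$detectors), nrow(x$channels),
              paste(x$wavelengths, collapse = "/"), x$separation_cm))
  print(table(x$channels$region))
  invisible(x)
}

#' Event design for a stimulation paradigm
#'
#' @param onsets numeric vector of event onsets in seconds from recording
#'   start; must be non-decreasing (ties are allowed across conditions).
#' @param durations numeric vector of event durations in seconds (positive).
#'   Events occupy the half-open interval `[onset, onset + duration)`.
#' @param labels character vector of condition names (e.g. `"tqst_trial"`).
#' @return data.frame of class `event_design` with columns onset, duration,
#'   label.
#' @export
event_design <- function(onsets, durations, labels) {
  if (length(onsets) != length(durations) || length(onsets) != length(labels))
    stopf("onsets, durations and labels must have equal length")
  if (length(onsets) == 0) {
    ev <- data.frame(onset = numeric(0), duration = numeric(0),
                     label = character(0))
    class(ev) <- c("event_design", "data.frame")
    return(ev)
  }
  if (any(diff(onsets) < 0)) stopf("event onsets must be increasing")
  if (any(durations <= 0)) stopf("event durations must be positive")
  ev <- data.frame(onset = as.numeric(onsets), duration = as.numeric(durations),
                   label = as.character(labels))
  class(ev) <- c("event_design", "data.frame")
  ev
}

#' Raw two-wavelength intensity recording
#'
#' The container for one subject-session: strictly positive detector
#' intensities per channel and wavelength, event markers, session phase
#' boundaries and subject metadata.
#'
#' @param layout a [probe_layout()].
#' @param intensities numeric array `channels x wavelengths x time` of
#'   strictly positive detector counts.
#' @param sampling_rate sampling rate in Hz (study default 25 Hz).
#' @param events an [event_design()] (times in seconds from recording start).
#' @param phases data.frame with columns `phase`, `onset`, `duration`
#'   describing the session structure (`rest_pre`, `breathing`, `tqst`,
#'   `rest_post`).
#' @param subject subject identifier.
#' @param group group label, `"TMB"` (traditional mindful breathing) or
#'   `"VRB"` (virtual-reality breathing).
#' @param visit visit number (1 or 2).
#' @return object of class `nirs_recording`.
#' @export
nirs_recording <- function(layout, intensities, sampling_rate = 25,
                           events = event_design(numeric(0), numeric(0), character(0)),
                           phases = NULL, subject = "S01", group = "TMB",
                           visit = 1L) {
  stopifnot(inherits(layout, "probe_layout"))
  n_ch <- nrow(layout$channels)
  n_wl <- length(layout$wavelengths)
  if (length(dim(intensities)) != 3)
    stopf("`intensities` must be a 3-d array (channel x wavelength x time)")
  if (dim(intensities)[1] != n_ch || dim(intensities)[2] != n_wl)
    stopf("intensity array is %d x %d x %d but layout has %d channels and %d wavelengths",
          dim(intensities)[1], dim(intensities)[2], dim(intensities)[3], n_ch, n_wl)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stopf("`sampling_rate` must be positive")
  bad <- which(intensities <= 0 | !is.finite(intensities))
  if (length(bad)) {
    k <- arrayInd(bad[1], dim(intensities))
    stopf("non-positive intensity at channel %d, wavelength %g nm, sample %d (log transform requires strictly positive intensities)",
          k[1], layout$wavelengths[k[2]], k[3])
  }
  dur <- dim(intensities)[3] / sampling_rate
  if (nrow(events) && any(events$onset + events$duration > dur + 1e-9))
    stopf("event window [%g, %g) extends beyond recording duration %g s",
          max(events$onset), max(events$onset + events$duration), dur)
  if (!is.null(phases)) {
    if (!all(c("phase", "onset", "duration") %in% names(phases)))
      stopf("`phases` must have columns phase, onset, duration")
    if (any(phases$onset + phases$duration > dur + 1e-9))
      stopf("phase '%s' extends beyond recording duration %g s",
            phases$phase[which.max(phases$onset + phases$duration)], dur)
  }
  if (!group %in% c("TMB", "VRB"))
    stopf("`group` must be 'TMB' or 'VRB', got '%s'", group)
  if (!visit %in% c(1L, 2L)) stopf("`visit` must be 1 or 2")
  structure(
    list(layout = layout, sampling_rate = as.numeric(sampling_rate),
         intensities = intensities, events = events, phases = phases,
         subject = as.character(subject), group = group, visit = as.integer(visit)),
    class = "nirs_recording"
  )
}

#' @export
print.nirs_recording <- function(x, ...) {
  cat(sprintf("<nirs_recording> %s (%s, visit %d): %d ch x %d wl x %d samples @ %g Hz (%.1f s), %d events\n",
              x$subject, x$group, x$visit, dim(x$intensities)[1],
              dim(x$intensities)[2], dim(x$intensities)[3], x$sampling_rate,
              dim(x$intensities)[3] / x$sampling_rate, nrow(x$events)))
  invisible(x)
}

#' Behavioral table of thermal pain thresholds
#'
#' One row per subject and visit with the mean thermal quantitative sensory
#' test (tQST) threshold in degrees Celsius, plus optional questionnaire
#' scores. Thresholds are constrained to the thermode's operating range
#' (30 degC ramp floor to 50 degC safety ceiling).
#'
#' @param subject character vector of subject ids.
#' @param group group labels (`"TMB"` / `"VRB"`).
#' @param visit visit numbers (1 or 2).
#' @param mean_threshold_c mean tQST thresholds in degC, within \[30, 50\].
#' @param serenity,fatigue optional questionnaire scores.
#' @return data.frame of class `behavioral_table`.
#' @export
behavioral_table <- function(subject, group, visit, mean_threshold_c,
                             serenity = NULL, fatigue = NULL) {
  n <- length(subject)
  if (length(group) != n || length(visit) != n || length(mean_threshold_c) != n)
    stopf("subject, group, visit, mean_threshold_c must have equal length")
  if (!all(group %in% c("TMB", "VRB")))
    stopf("group labels must be 'TMB' or 'VRB'")
  if (!all(visit %in% c(1, 2))) stopf("visit must be 1 or 2")
  if (any(mean_threshold_c < 30 | mean_threshold_c > 50))
    stopf("mean thresholds must lie within the 30-50 degC thermode range")
  if (anyDuplicated(paste(subject, visit)))
    stopf("behavioral table must have one row per subject x visit")
  tbl <- data.frame(subject = as.character(subject), group = as.character(group),
                    visit = as.integer(visit),
                    mean_threshold_c = as.numeric(mean_threshold_c))
  if (!is.null(serenity)) tbl$serenity <- as.numeric(serenity)
  if (!is.null(fatigue)) tbl$fatigue <- as.numeric(fatigue)
  class(tbl) <- c("behavioral_table", "data.frame")
  tbl
}
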