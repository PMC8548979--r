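# Forward simulator of the study design.
#
# Generates raw two-wavelength intensity recordings for a 2-group x 2-visit
# cohort with known ground truth at every level the analysis chain estimates:
# per-channel activation amplitudes during thermal testing, band-limited
# channel-pair connectivity during breathing practice, beat-to-beat heart
# period variability, and a linear coupling between a connectivity edge and
# the thermal pain threshold.

#' Simulation configuration
#'
#' Collects every knob of the forward model. The defaults reproduce the
#' study conditions: 2 groups x 20 subjects x 2 visits sampled at 25 Hz;
#' a session of 5 min rest, 10 min breathing practice, 20 thermal ramp
#' trials (30 degC baseline, 1 degC/s, 50 degC ceiling, 10 s rests) and
#' 5 min closing rest; cardiac (1.1 Hz base with beat-to-beat jitter),
#' Mayer (0.1 Hz) and respiratory (0.35 Hz) oscillations; AR(1) measurement
#' noise; three planted connectivity edges at r = 0.6; and group x visit
#' mean thresholds of 45.4/46.0 degC (TMB) and 46.5/47.1 degC (VRB) with the
#' first planted edge coupled to the threshold.
#'
#' @param n_per_group subjects per group.
#' @param visits visits per subject (1 or 2).
#' @param layout a [probe_layout()].
#' @param sampling_rate acquisition rate, Hz.
#' @param rest_pre_s,breathing_s,rest_post_s phase durations, seconds.
#' @param n_trials,baseline_c,ramp_rate,tqst_rest_s thermal test paradigm:
#'   trial count, baseline degC, ramp rate degC/s, inter-trial rest s.
#' @param trial_jitter_sd within-subject SD of single-trial thresholds, degC.
#' @param active_channels named numeric vector: HbO response amplitude (uM)
#'   per activated channel id during thermal trials.
#' @param edge_set data.frame `ch_a`, `ch_b`, `r`: planted channel pairs and
#'   their target band-limited correlations (|r| < 1).
#' @param edge_z_sd between-subject SD of each planted edge's Fisher Z.
#' @param lf_sd_um SD (uM) of the band-limited (0.01-0.08 Hz) resting
#'   hemodynamic fluctuation carrying the connectivity structure.
#' @param cardiac_hz base heart rate (study band 1-1.5 Hz).
#' @param rr_jitter_sd marginal SD of the heart-period deviations, seconds
#'   (the planted SDNN scale).
#' @param rr_ar lag-1 autocorrelation of successive heart-period deviations
#'   (default 0.8; autonomic RR modulation is slow relative to the beat).
#' @param cardiac_amp_um,mayer_amp_um,resp_amp_um oscillation amplitudes, uM.
#' @param mayer_hz,resp_hz Mayer-wave and respiratory frequencies, Hz.
#' @param ar_coefficient lag-1 serial correlation of measurement noise, \[0, 1).
#' @param noise_sd marginal SD of the AR(1) noise, uM.
#' @param hbr_ratio neural HbR amplitude as a fraction of HbO (default -1/3).
#' @param hbr_noise_sd independent HbR noise SD, uM.
#' @param behavior_coupling list: `edge` (row of `edge_set` coupled to the
#'   threshold), `slope` (degC per Fisher-Z unit), `residual_sd` (degC),
#'   `group_visit_means` (matrix groups x visits of mean thresholds, degC).
#' @param dpf differential pathlength factors per wavelength.
#' @param baseline_intensity detector counts around which intensities
#'   fluctuate.
#' @param seed root seed; all subject/component substreams derive from it.
#' @return validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_per_group = 20, visits = 2, layout = default_probe_layout(),
    sampling_rate = 25,
    rest_pre_s = 300, breathing_s = 600, rest_post_s = 300,
    n_trials = 20, baseline_c = 30, ramp_rate = 1, tqst_rest_s = 10,
    trial_jitter_sd = 0.5,
    active_channels = c(`29` = 0.1, `30` = 0.1, `35` = 0.1, `36` = 0.1),
    edge_set = data.frame(ch_a = c(2, 9, 29), ch_b = c(6, 13, 35), r = 0.6),
    edge_z_sd = 0.3, lf_sd_um = 0.5,
    cardiac_hz = 1.1, rr_jitter_sd = 0.05, rr_ar = 0.8, cardiac_amp_um = 0.4,
    mayer_hz = 0.1, mayer_amp_um = 0.15, resp_hz = 0.35, resp_amp_um = 0.15,
    ar_coefficient = 0.3, noise_sd = 0.3,
    hbr_ratio = -1 / 3, hbr_noise_sd = 0.05,
    behavior_coupling = list(edge = 1, slope = 3, residual_sd = 0.9,
                             group_visit_means = rbind(TMB = c(45.4, 46.0),
                                                       VRB = c(46.5, 47.1))),
    dpf = c(6, 6), baseline_intensity = 1000, seed = 1) {
  stopifnot(inherits(layout, "probe_layout"))
  if (n_per_group < 1) stopf("`n_per_group` must be >= 1")
  if (!visits %in% c(1, 2)) stopf("`visits` must be 1 or 2")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stopf("`ar_coefficient` must lie in [0, 1)")
  if (nrow(edge_set) && (any(abs(edge_set$r) >= 1) ||
                         any(edge_set$ch_a == edge_set$ch_b)))
    stopf("planted edge correlations must have |r| < 1 and distinct channels")
  if (cardiac_hz <= 0) stopf("`cardiac_hz` must be positive")
  if (rr_jitter_sd < 0) stopf("`rr_jitter_sd` must be >= 0")
  if (rr_ar < 0 || rr_ar >= 1) stopf("`rr_ar` must lie in [0, 1)")
  n_ch <- nrow(layout$channels)
  if (nrow(edge_set) && any(c(edge_set$ch_a, edge_set$ch_b) > n_ch))
    stopf("edge_set references channels beyond the %d-channel layout", n_ch)
  if (length(active_channels) &&
      any(as.integer(names(active_channels)) > n_ch))
    stopf("active_channels references channels beyond the layout")
  # implied channel correlation structure must be realisable
  lam2 <- numeric(n_ch)
  for (k in seq_len(nrow(edge_set))) {
    lam2[edge_set$ch_a[k]] <- lam2[edge_set$ch_a[k]] + abs(edge_set$r[k])
    lam2[edge_set$ch_b[k]] <- lam2[edge_set$ch_b[k]] + abs(edge_set$r[k])
  }
  if (any(lam2 > 1))
    stopf("planted edge correlation matrix is not positive semidefinite on channel(s) %s; reduce |r|",
          paste(which(lam2 > 1), collapse = ", "))
  cfg <- list(n_per_group = n_per_group, visits = visits, layout = layout,
              sampling_rate = sampling_rate, rest_pre_s = rest_pre_s,
              breathing_s = breathing_s, rest_post_s = rest_post_s,
              n_trials = n_trials, baseline_c = baseline_c,
              ramp_rate = ramp_rate, tqst_rest_s = tqst_rest_s,
              trial_jitter_sd = trial_jitter_sd,
              active_channels = active_channels, edge_set = edge_set,
              edge_z_sd = edge_z_sd, lf_sd_um = lf_sd_um,
              cardiac_hz = cardiac_hz, rr_jitter_sd = rr_jitter_sd,
              rr_ar = rr_ar,
              cardiac_amp_um = cardiac_amp_um, mayer_hz = mayer_hz,
              mayer_amp_um = mayer_amp_um, resp_hz = resp_hz,
              resp_amp_um = resp_amp_um, ar_coefficient = ar_coefficient,
              noise_sd = noise_sd, hbr_ratio = hbr_ratio,
              hbr_noise_sd = hbr_noise_sd,
              behavior_coupling = behavior_coupling, dpf = dpf,
              baseline_intensity = baseline_intensity, seed = seed)
  class(cfg) <- "simulation_config"
  cfg
}

#' Thermal QST event design
#'
#' Builds the 20-trial thermal ramp paradigm: trial `i` lasts
#' `(threshold_i - baseline_c) / ramp_rate` seconds (the thermode ramps at
#' `ramp_rate` degC/s from `baseline_c` until the subject signals pain at
#' `threshold_i`), followed by a `rest_s` inter-trial rest.
#'
#' @param n_trials number of trials (default 20).
#' @param baseline_c thermode baseline, degC (default 30).
#' @param ramp_rate ramp rate, degC/s (default 1).
#' @param thresholds per-trial thresholds, degC, in `(baseline_c, 50]`;
#'   recycled to `n_trials`.
#' @param rest_s inter-trial rest, seconds (default 10).
#' @param start_s onset of the first trial, seconds.
#' @return an [event_design()] with label `tqst_trial`.
#' @export
simulate_tqst_events <- function(n_trials = 20, baseline_c = 30,
                                 ramp_rate = 1, thresholds = 46,
                                 rest_s = 10, start_s = 0) {
  if (n_trials < 1) stopf("`n_trials` must be >= 1")
  thresholds <- rep_len(thresholds, n_trials)
  if (any(thresholds <= baseline_c))
    stopf("trial thresholds must exceed the %g degC baseline", baseline_c)
  if (any(thresholds > 50))
    stopf("trial thresholds cannot exceed the 50 degC thermode ceiling")
  durations <- (thresholds - baseline_c) / ramp_rate
  onsets <- start_s + c(0, cumsum(durations[-n_trials] + rest_s))
  event_design(onsets, durations, rep("tqst_trial", n_trials))
}

# Unit-variance band-limited Gaussian series (the carrier of planted
# connectivity and of narrowband physiological activity). Synthesised
# spectrally: Gaussian Fourier coefficients restricted to the band, inverse
# transformed; O(n log n) and exactly band-limited.
band_noise <- function(n, rate, band = c(0.01, 0.08)) {
  # synthesise at a 2-3-5-smooth length (fast mixed-radix FFT), then truncate
  nf <- stats::nextn(n, c(2, 3, 5))
  freqs <- seq(0, rate / 2, length.out = floor(nf / 2) + 1)
  keep <- freqs >= band[1] & freqs <= band[2]
  if (!any(keep)) return(numeric(n))
  spec <- complex(length.out = length(freqs))
  k <- sum(keep)
  spec[keep] <- complex(real = stats::rnorm(k), imaginary = stats::rnorm(k))
  full <- c(spec, Conj(rev(spec[2:(nf - length(freqs) + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE))[seq_len(n)]
  s <- stats::sd(x)
  if (s < 1e-12) return(numeric(n))
  x / s
}

#' Simulate one subject-session recording
#'
#' Runs the forward model: HbO per channel is the sum of (a) the activation
#' response, `beta x (trial boxcar convolved with the canonical HRF)`, (b) a
#' band-limited resting fluctuation built from per-edge latent factors with
#' `sqrt(|r|)` loadings so planted channel pairs hit their target
#' correlations, (c) a cardiac oscillation driven by a phase accumulator
#' over the jittered beat-period sequence (ground-truth SDNN is exact by
#' construction), (d) Mayer and respiratory sinusoids, and (e) AR(1)
#' measurement noise. HbR is `hbr_ratio` times the neural HbO component plus
#' independent noise. Concentrations are forward-projected through the
#' modified Beer-Lambert model and exponentiated around a positive baseline
#' intensity with per-channel gains. Identical seeds give identical output.
#'
#' @param cfg a [simulation_config()].
#' @param subject,group,visit metadata for the recording.
#' @param threshold_c the subject's mean threshold, degC; `NULL` draws it
#'   from the behavior-coupling model.
#' @param edge_z per-edge subject Fisher-Z values; `NULL` draws them around
#'   `atanh(r)` with SD `edge_z_sd`.
#' @param subject_seed integer substream seed; `NULL` derives one from
#'   `cfg$seed` and the metadata.
#' @param store_signals keep the noiseless concentration ground truth
#'   (`hbo`, `hbr` matrices) in the truth object (memory-heavy for cohorts).
#' @param events optional [event_design()] overriding the generated thermal
#'   paradigm.
#' @return list with `recording` (a [nirs_recording()]) and `truth` (class
#'   `ground_truth`): planted betas, per-edge z/r, beat times, RR intervals,
#'   true SDNN, thresholds, and optionally the session-mean-referenced
#'   concentration signals.
#' @export
simulate_subject <- function(cfg, subject = "S01", group = "TMB", visit = 1,
                             threshold_c = NULL, edge_z = NULL,
                             subject_seed = NULL, store_signals = FALSE,
                             events = NULL) {
  stopifnot(inherits(cfg, "simulation_config"))
  seed <- subject_seed %||%
    split_seed(cfg$seed, match(group, c("TMB", "VRB")),
               sum(utf8ToInt(subject)), visit)
  set.seed(seed)
  fs <- cfg$sampling_rate
  layout <- cfg$layout
  n_ch <- nrow(layout$channels)
  n_edges <- nrow(cfg$edge_set)

  # --- subject-level latent quantities -------------------------------------
  if (is.null(edge_z) && n_edges) {
    edge_z <- stats::rnorm(n_edges, atanh(cfg$edge_set$r), cfg$edge_z_sd)
  } else if (is.null(edge_z)) edge_z <- numeric(0)
  edge_r <- tanh(edge_z)
  bc <- cfg$behavior_coupling
  if (is.null(threshold_c)) {
    mu <- bc$group_visit_means[group, min(visit, ncol(bc$group_visit_means))]
    if (n_edges) {
      e <- bc$edge
      mu <- mu + bc$slope * (edge_z[e] - atanh(cfg$edge_set$r[e]))
    }
    threshold_c <- min(50, max(30, mu + stats::rnorm(1, 0, bc$residual_sd)))
  }

  # --- session timeline ----------------------------------------------------
  tqst_start <- cfg$rest_pre_s + cfg$breathing_s
  if (is.null(events)) {
    lo <- cfg$baseline_c + 2 * cfg$trial_jitter_sd + 0.5
    trial_thr <- pmin(50, pmax(lo, threshold_c +
                                 stats::rnorm(cfg$n_trials, 0, cfg$trial_jitter_sd)))
    events <- simulate_tqst_events(cfg$n_trials, cfg$baseline_c,
                                   cfg$ramp_rate, trial_thr,
                                   cfg$tqst_rest_s, start_s = tqst_start)
  } else trial_thr <- numeric(0)
  tqst_end <- max(events$onset + events$duration) + cfg$tqst_rest_s
  total_s <- tqst_end + cfg$rest_post_s
  phases <- data.frame(
    phase = c("rest_pre", "breathing", "tqst", "rest_post"),
    onset = c(0, cfg$rest_pre_s, tqst_start, tqst_end),
    duration = c(cfg$rest_pre_s, cfg$breathing_s, tqst_end - tqst_start,
                 cfg$rest_post_s))
  n_t <- ceiling(total_s * fs)
  tgrid <- (seq_len(n_t) - 1) / fs

  # --- neural response -----------------------------------------------------
  u <- numeric(n_t)
  for (k in seq_len(nrow(events)))
    u[tgrid >= events$onset[k] & tgrid < events$onset[k] + events$duration[k]] <- 1
  hrf_reg <- hrf_convolve(u, fs)
  betas <- numeric(n_ch)
  if (length(cfg$active_channels))
    betas[as.integer(names(cfg$active_channels))] <- cfg$active_channels
  neural <- outer(betas, hrf_reg)                      # n_ch x n_t

  # --- band-limited connectivity carrier -----------------------------------
  lf <- matrix(0, n_ch, n_t)
  if (cfg$lf_sd_um > 0) {
    lam <- matrix(0, n_ch, max(1, n_edges))
    for (k in seq_len(n_edges)) {
      lam[cfg$edge_set$ch_a[k], k] <- sqrt(abs(edge_r[k]))
      lam[cfg$edge_set$ch_b[k], k] <- sign(edge_r[k]) * sqrt(abs(edge_r[k]))
    }
    lam2 <- rowSums(lam^2)
    if (any(lam2 > 1))
      stopf("subject-level edge correlations imply a non-positive-semidefinite structure; reduce |r| or edge_z_sd")
    f <- vapply(seq_len(max(1, n_edges)), function(k) band_noise(n_t, fs),
                numeric(n_t))                           # n_t x K
    for (ch in seq_len(n_ch)) {
      own <- band_noise(n_t, fs)
      lf[ch, ] <- cfg$lf_sd_um *
        (as.numeric(f %*% lam[ch, ]) + sqrt(1 - lam2[ch]) * own)
    }
  }

  # --- physiological oscillations ------------------------------------------
  sdnn_true <- 0; beat_times <- numeric(0); rr <- numeric(0)
  cardiac <- numeric(n_t)
  if (cfg$cardiac_amp_um > 0) {
    mean_rr <- 1 / cfg$cardiac_hz
    n_beats <- ceiling(total_s / max(mean_rr - 4 * cfg$rr_jitter_sd, 0.3)) + 2
    # slow autonomic modulation: AR(1) over beats, marginal SD = rr_jitter_sd
    jit <- if (cfg$rr_jitter_sd > 0) {
      inn <- stats::rnorm(n_beats, 0, cfg$rr_jitter_sd * sqrt(1 - cfg$rr_ar^2))
      as.numeric(stats::filter(inn, cfg$rr_ar, method = "recursive"))
    } else numeric(n_beats)
    rr <- pmax(0.3, mean_rr + jit)
    beat_times <- cumsum(rr)
    keep <- beat_times <= total_s
    phase <- stats::approx(x = c(0, beat_times), y = 0:length(beat_times),
                           xout = tgrid, rule = 2)$y
    cardiac <- cos(2 * pi * phase)
    beat_times <- beat_times[keep]
    rr <- diff(c(0, beat_times))
    sdnn_true <- if (length(rr) > 1) stats::sd(rr) else 0
  }
  # Mayer and respiratory activity drift in amplitude and phase and couple
  # to each channel's local vasculature; model them as channel-local
  # narrowband stochastic processes centred on their nominal frequencies.
  # The cardiac beat train is systemic and shared across channels (with
  # channel-specific gain), which is what lets a principal component across
  # channels recover the pulse for HRV.
  narrowband <- function(f0) {
    lo <- max(f0 * 0.8, 0.005); hi <- min(f0 * 1.2, fs / 2 * 0.95)
    band_noise(n_t, fs, band = c(lo, hi))
  }
  card_gain <- exp(stats::rnorm(n_ch, 0, 0.15))

  # --- assemble concentrations ---------------------------------------------
  ar_noise <- function(sd) {
    if (sd <= 0) return(numeric(n_t))
    phi <- cfg$ar_coefficient
    inn <- stats::rnorm(n_t, 0, sd * sqrt(1 - phi^2))
    if (phi == 0) inn
    else as.numeric(stats::filter(inn, phi, method = "recursive"))
  }
  hbo <- neural + lf
  hbr <- cfg$hbr_ratio * neural
  for (ch in seq_len(n_ch)) {
    mayer <- if (cfg$mayer_amp_um > 0) narrowband(cfg$mayer_hz) else 0
    resp <- if (cfg$resp_amp_um > 0) narrowband(cfg$resp_hz) else 0
    hbo[ch, ] <- hbo[ch, ] + card_gain[ch] * cfg$cardiac_amp_um * cardiac +
      cfg$mayer_amp_um * mayer + cfg$resp_amp_um * resp + ar_noise(cfg$noise_sd)
    hbr[ch, ] <- hbr[ch, ] + ar_noise(cfg$hbr_noise_sd)
  }

  # --- forward Beer-Lambert and detector intensities -----------------------
  od <- hemoglobin_to_od(hbo, hbr, wavelengths = layout$wavelengths,
                         dpf = cfg$dpf, separation_cm = layout$separation_cm)
  gains <- matrix(cfg$baseline_intensity *
                    exp(stats::runif(n_ch * length(layout$wavelengths), -0.5, 0.5)),
                  n_ch, length(layout$wavelengths))
  ints <- array(0, dim(od))
  for (w in seq_along(layout$wavelengths))
    ints[, w, ] <- gains[, w] * exp(-od[, w, , drop = TRUE])

  rec <- nirs_recording(layout, ints, sampling_rate = fs, events = events,
                        phases = phases, subject = subject, group = group,
                        visit = visit)
  truth <- structure(list(
    subject = subject, group = group, visit = visit, seed = seed,
    betas = betas, edge_set = cfg$edge_set, edge_z = edge_z, edge_r = edge_r,
    beat_times = beat_times, rr_intervals = rr, sdnn = sdnn_true,
    threshold_c = threshold_c, trial_thresholds = trial_thr,
    coupling = bc), class = "ground_truth")
  if (store_signals) {
    truth$hbo <- hbo - rowMeans(hbo)  # session-mean referenced, as recovered
    truth$hbr <- hbr - rowMeans(hbr)
  }
  list(recording = rec, truth = truth)
}

#' Simulate a full cohort
#'
#' Generates `2 x n_per_group` subjects over `visits` visits: for each
#' subject-visit the planted edge strengths are drawn around their targets,
#' the mean threshold follows the behavior-coupling model around the group x
#' visit mean (truncated to the 30-50 degC thermode range), and a complete
#' session recording is produced by [simulate_subject()]. Every recording
#' derives its seed from the root seed through a documented substream
#' scheme, so the same configuration always yields the identical cohort.
#'
#' @param cfg a [simulation_config()].
#' @param store_signals keep per-recording concentration ground truth
#'   (memory-heavy; default FALSE).
#' @return list with `recordings` (list of [nirs_recording()]),
#'   `behavior` (a [behavioral_table()]), and `truth` (per-recording
#'   `ground_truth` list, keyed `subject/visit`).
#' @export
simulate_cohort <- function(cfg, store_signals = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  recordings <- list(); truths <- list()
  rows <- NULL
  for (gi in 1:2) {
    g <- c("TMB", "VRB")[gi]
    for (s in seq_len(cfg$n_per_group)) {
      id <- sprintf("%s%02d", g, s)
      for (v in seq_len(cfg$visits)) {
        seed <- split_seed(cfg$seed, gi, s, v)
        sim <- simulate_subject(cfg, subject = id, group = g, visit = v,
                                subject_seed = seed,
                                store_signals = store_signals)
        key <- sprintf("%s/%d", id, v)
        recordings[[key]] <- sim$recording
        truths[[key]] <- sim$truth
        rows <- rbind(rows, data.frame(subject = id, group = g, visit = v,
                                       mean_threshold_c = sim$truth$threshold_c))
      }
    }
  }
  behavior <- behavioral_table(rows$subject, rows$group, rows$visit,
                               rows$mean_threshold_c)
  list(recordings = recordings, behavior = behavior, truth = truths,
       config = cfg)
}
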