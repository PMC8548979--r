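# Convenience chains wiring the modules together the way the study design
# uses them: first-level activation on the thermal-testing phase at 2 Hz,
# connectivity on the breathing phase at 4 Hz, HRV on resting phases, and a
# cohort-level driver that writes the standard CSV/JSON outputs.

hb_with_meta <- function(hb, rec) {
  attr(hb, "subject") <- rec$subject
  attr(hb, "group") <- rec$group
  attr(hb, "visit") <- rec$visit
  hb
}

phase_window <- function(rec, phase) {
  if (is.null(rec$phases) || !phase %in% rec$phases$phase)
    stopf("recording has no phase '%s'", phase)
  ph <- rec$phases[rec$phases$phase == phase, ][1, ]
  c(ph$onset, ph$onset + ph$duration)
}

#' First-level activation fit for the thermal-testing phase
#'
#' Converts the recording to hemoglobin concentrations (session-mean
#' baseline), crops the thermal-testing phase, down-samples to 2 Hz, builds
#' the trial design (variable-duration ramp boxcars convolved with the
#' canonical HRF plus intercept and linear drift) and runs the prewhitened
#' robust GLM.
#'
#' @param rec a [nirs_recording()] with a `tqst` phase and `tqst_trial`
#'   events.
#' @param rate_hz modeling rate (default 2 Hz).
#' @param ... passed to [fit_first_level()].
#' @return a `first_level_result`.
#' @export
tqst_first_level <- function(rec, rate_hz = 2, ...) {
  stopifnot(inherits(rec, "nirs_recording"))
  win <- phase_window(rec, "tqst")
  hb <- recording_to_hemoglobin(rec)
  hb <- crop_hemoglobin(hb, win[1], win[2])
  n_native <- ncol(hb$hbo)
  hb <- resample_hemoglobin(hb, rate_hz, components = "hbo")
  hb <- hb_with_meta(hb, rec)
  ev <- rec$events[rec$events$onset >= win[1] & rec$events$onset < win[2], ]
  ev$onset <- ev$onset - win[1]
  ev <- event_design(ev$onset, ev$duration, ev$label)
  des <- build_design_decimated(ev, n_native, rec$sampling_rate, rate_hz)
  fit_first_level(hb, des, ...)
}

#' Subject connectivity for the breathing-practice phase
#'
#' Crops the breathing phase, down-samples to 4 Hz and computes the
#' band-limited robust connectivity matrix.
#'
#' @param rec a [nirs_recording()] with a `breathing` phase.
#' @param band `"low"` or `"high"`; see [subject_connectivity()].
#' @param method correlation method.
#' @return a `connectivity_matrix`.
#' @export
breathing_connectivity <- function(rec, band = "low",
                                   method = c("robust", "pearson")) {
  stopifnot(inherits(rec, "nirs_recording"))
  win <- phase_window(rec, "breathing")
  hb <- recording_to_hemoglobin(rec)
  hb <- crop_hemoglobin(hb, win[1], win[2])
  hb <- resample_hemoglobin(hb, 4, components = "hbo")
  subject_connectivity(hb, band = band, method = match.arg(method),
                       subject = rec$subject, group = rec$group,
                       visit = rec$visit)
}

#' Run the full analysis chain on a simulated or loaded cohort
#'
#' For every recording: HRV (SDNN) from the pre-task rest, first-level
#' activation during thermal testing, and breathing-phase connectivity.
#' Then per group: the mixed-effects group activation map with FDR control,
#' the group edge map, and elastic-net selection of edges predicting the
#' thermal thresholds (per-group, visits pooled as rows). When `out_dir` is
#' given, writes `hrv.csv`, `behavior.csv`, `activation_<group>.csv`,
#' `edges_<group>.csv` and `selection_<group>.json`.
#'
#' @param cohort list with `recordings` and `behavior`, as from
#'   [simulate_cohort()].
#' @param band connectivity band for selection (default `"low"`).
#' @param method connectivity correlation method.
#' @param folds,reps,seed elastic-net CV controls (see
#'   [elastic_net_select()]).
#' @param out_dir optional output directory for CSV/JSON artifacts.
#' @return list with `hrv`, `first_levels`, `connectivity`, `activation`
#'   (per group), `edges` (per group), `selection` (per group).
#' @export
run_study_pipeline <- function(cohort, band = "low",
                               method = c("robust", "pearson"), folds = 10,
                               reps = 100, seed = 1, out_dir = NULL) {
  method <- match.arg(method)
  recs <- cohort$recordings
  hrv_rows <- NULL
  first_levels <- list()
  mats <- list()
  for (key in names(recs)) {
    rec <- recs[[key]]
    hr <- tryCatch(estimate_hrv(rec, "rest_pre"), error = function(e) NULL)
    hrv_rows <- rbind(hrv_rows, data.frame(
      subject = rec$subject, group = rec$group, visit = rec$visit,
      n_peaks = if (is.null(hr)) NA_integer_ else hr$n_peaks,
      mean_rr_s = if (is.null(hr)) NA_real_ else hr$mean_rr,
      sdnn_ms = if (is.null(hr)) NA_real_ else 1000 * hr$sdnn))
    first_levels[[key]] <- tqst_first_level(rec)
    mats[[key]] <- breathing_connectivity(rec, band = band, method = method)
  }
  groups <- unique(vapply(recs, function(r) r$group, ""))
  activation <- list(); edges <- list(); selection <- list()
  for (g in groups) {
    in_g <- vapply(recs, function(r) r$group == g, TRUE)
    activation[[g]] <- fit_group(first_levels[in_g])
    edges[[g]] <- group_edges(mats[in_g])
    beh_g <- cohort$behavior[cohort$behavior$group == g, ]
    class(beh_g) <- class(cohort$behavior)
    tbl <- assemble_features(mats[in_g], beh_g)
    selection[[g]] <- elastic_net_select(tbl, folds = folds, reps = reps,
                                         seed = split_seed(seed, match(g, groups)))
  }
  out <- list(hrv = hrv_rows, first_levels = first_levels,
              connectivity = mats, activation = activation, edges = edges,
              selection = selection)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(hrv_rows, file.path(out_dir, "hrv.csv"), row.names = FALSE)
    write_behavioral(cohort$behavior, file.path(out_dir, "behavior.csv"))
    for (g in groups) {
      utils::write.csv(as.data.frame(activation[[g]]),
                       file.path(out_dir, sprintf("activation_%s.csv", g)),
                       row.names = FALSE)
      utils::write.csv(as.data.frame(edges[[g]]),
                       file.path(out_dir, sprintf("edges_%s.csv", g)),
                       row.names = FALSE)
      s <- selection[[g]]
      jsonlite::write_json(
        list(group = g, alpha = s$alpha, lambda = s$lambda, rule = s$rule,
             folds = s$folds, reps = s$reps, seed = s$seed,
             selected = s$selected),
        file.path(out_dir, sprintf("selection_%s.json", g)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  out
}
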