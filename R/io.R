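# Recording and table I/O.
#
# Recordings are stored as a plain directory: one CSV intensity matrix per
# wavelength (time in rows, channels in columns), a JSON metadata file
# carrying the probe geometry, session phases and subject fields at full
# float precision, and a CSV event table. The format is dependency-light,
# diffable, and round-trips losslessly.

#' Save a recording to a plain-directory container
#'
#' Writes `metadata.json` (probe layout, sampling rate, subject fields,
#' phases, events at full float precision) and one
#' `intensity_<wavelength>nm.csv` per wavelength (time x channel).
#'
#' @param rec a [nirs_recording()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_recording <- function(rec, path) {
  stopifnot(inherits(rec, "nirs_recording"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stopf("cannot create directory '%s'", path)
  meta <- list(
    format = "nirspain-recording",
    version = 1L,
    subject = rec$subject, group = rec$group, visit = rec$visit,
    sampling_rate = rec$sampling_rate,
    wavelengths = rec$layout$wavelengths,
    separation_cm = rec$layout$separation_cm,
    channels = rec$layout$channels,
    phases = rec$phases,
    events = as.data.frame(rec$events)
  )
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (w in seq_along(rec$layout$wavelengths)) {
    m <- t(rec$intensities[, w, , drop = TRUE])
    colnames(m) <- sprintf("ch_%d", seq_len(ncol(m)))
    data.table::fwrite(data.table::as.data.table(m),
                       file.path(path, sprintf("intensity_%gnm.csv",
                                               rec$layout$wavelengths[w])))
  }
  invisible(path)
}

#' Load a recording from a plain-directory container
#'
#' Reads a directory written by [save_recording()], validating the probe
#' geometry, intensity positivity and event consistency; any violation raises
#' a format error naming the offending field.
#'
#' @param path directory containing `metadata.json` and per-wavelength
#'   intensity CSVs.
#' @return a validated [nirs_recording()].
#' @export
load_recording <- function(path) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf)) stopf("not a recording directory: missing %s", mf)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (field in c("subject", "group", "visit", "sampling_rate", "wavelengths",
                  "separation_cm", "channels"))
    if (is.null(meta[[field]]))
      stopf("format error in %s: missing field '%s'", mf, field)
  layout <- probe_layout(meta$channels[c("emitter", "detector")],
                         wavelengths = meta$wavelengths,
                         separation_cm = meta$separation_cm,
                         region_map = meta$channels$region)
  mats <- lapply(meta$wavelengths, function(wl) {
    f <- file.path(path, sprintf("intensity_%gnm.csv", wl))
    if (!file.exists(f))
      stopf("format error: missing intensity table for wavelength %g nm (%s)", wl, f)
    as.matrix(data.table::fread(f))
  })
  n_t <- unique(vapply(mats, nrow, 0L))
  if (length(n_t) != 1)
    stopf("format error: intensity tables disagree on sample count")
  arr <- array(0, dim = c(nrow(layout$channels), length(meta$wavelengths), n_t))
  for (w in seq_along(mats)) {
    if (ncol(mats[[w]]) != nrow(layout$channels))
      stopf("format error: intensity table for %g nm has %d channels, layout has %d",
            meta$wavelengths[w], ncol(mats[[w]]), nrow(layout$channels))
    arr[, w, ] <- t(mats[[w]])
  }
  ev <- if (!is.null(meta$events) && length(meta$events) && nrow(as.data.frame(meta$events))) {
    e <- as.data.frame(meta$events)
    event_design(e$onset, e$duration, e$label)
  } else event_design(numeric(0), numeric(0), character(0))
  phases <- if (!is.null(meta$phases) && length(meta$phases)) as.data.frame(meta$phases) else NULL
  nirs_recording(layout, arr, sampling_rate = meta$sampling_rate, events = ev,
                 phases = phases, subject = meta$subject, group = meta$group,
                 visit = meta$visit)
}

#' Write / read a behavioral threshold table as CSV
#'
#' CSV with header `subject,group,visit,mean_threshold_c` (plus any optional
#' score columns).
#'
#' @param tbl a [behavioral_table()].
#' @param path CSV file path.
#' @return `read_behavioral()` returns a validated [behavioral_table()].
#' @export
write_behavioral <- function(tbl, path) {
  stopifnot(inherits(tbl, "behavioral_table"))
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_behavioral
#' @export
read_behavioral <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "group", "visit", "mean_threshold_c")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("behavioral CSV missing column(s): %s",
                          paste(miss, collapse = ", "))
  behavioral_table(d$subject, d$group, d$visit, d$mean_threshold_c,
                   serenity = d$serenity, fatigue = d$fatigue)
}

#' Read a channel-to-region map from YAML or JSON
#'
#' The file maps channel index (1-based) to a region label; either a YAML
#' mapping (`"1": aPFC`) or a JSON object. Returns a character vector ordered
#' by channel index.
#'
#' @param path file path ending in `.yaml`/`.yml` or `.json`.
#' @return named character vector, names = channel indices.
#' @export
read_region_map <- function(path) {
  m <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  m <- unlist(m)
  ord <- order(as.integer(names(m)))
  m <- m[ord]
  bad <- setdiff(unique(m), region_labels())
  if (length(bad)) stopf("region map contains unknown label(s): %s",
                         paste(bad, collapse = ", "))
  m
}
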