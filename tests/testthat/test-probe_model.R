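test_that("default montage has the study geometry and a partitioning region map", {
  lay <- default_probe_layout()
  expect_length(lay$emitters, 8)
  expect_length(lay$detectors, 28)
  expect_equal(nrow(lay$channels), 45)
  expect_equal(lay$wavelengths, c(690, 830))
  expect_equal(lay$separation_cm, 3)

  # canonical channel order: sorted by (emitter, detector)
  ord <- order(lay$channels$emitter, lay$channels$detector)
  expect_equal(ord, seq_len(45))

  # union over region labels partitions the channel set
  by_region <- lapply(region_labels(), region_channels, layout = lay)
  all_ch <- sort(unlist(by_region))
  expect_equal(all_ch, 1:45)
  expect_equal(anyDuplicated(unlist(by_region)), 0L)

  s1 <- region_channels(lay, "S1")
  expect_gt(length(s1), 0)
  expect_true(all(c(29, 30, 35, 36) %in% s1))
})

test_that("region_channels validates labels and handles empty regions", {
  lay <- default_probe_layout()
  expect_error(region_channels(lay, "S99"), "valid labels")
  all_other <- probe_layout(lay$channels[c("emitter", "detector")],
                            region_map = rep("other", 45))
  expect_length(region_channels(all_other, "S1"), 0)
})

test_that("event designs enforce ordering and positivity", {
  ev <- event_design(c(0, 30), c(16, 16), c("a", "a"))
  expect_s3_class(ev, "event_design")
  expect_error(event_design(c(30, 0), c(1, 1), c("a", "a")), "increasing")
  expect_error(event_design(c(0, 30), c(1, -1), c("a", "a")), "positive")
  expect_error(event_design(c(0, 30), c(1, 1), "a"), "equal length")
})

test_that("recordings reject non-positive intensities and out-of-range events", {
  lay <- tiny_layout(2)
  ints <- array(1, c(2, 2, 100))
  expect_s3_class(nirs_recording(lay, ints, 25), "nirs_recording")
  bad <- ints; bad[2, 1, 50] <- 0
  expect_error(nirs_recording(lay, bad, 25), "channel 2.*sample 50")
  ev <- event_design(3, 5, "x")  # extends to 8 s, recording is 4 s
  expect_error(nirs_recording(lay, ints, 25, events = ev), "beyond")
})

test_that("behavioral tables enforce one row per subject-visit and threshold range", {
  tbl <- behavioral_table(c("a", "a", "b"), c("TMB", "TMB", "VRB"),
                          c(1, 2, 1), c(45, 46, 47))
  expect_equal(nrow(tbl), 3)
  expect_error(behavioral_table(c("a", "a"), c("TMB", "TMB"), c(1, 1), c(45, 46)),
               "one row per subject")
  expect_error(behavioral_table("a", "TMB", 1, 55), "30-50")
})

test_that("save/load round-trips a recording losslessly", {
  sim <- simulate_subject(quiet_cfg(noise_sd = 0.2), subject_seed = 9,
                          threshold_c = 46)
  rec <- sim$recording
  d <- withr::local_tempdir()
  save_recording(rec, d)
  r2 <- load_recording(d)
  expect_identical(r2$subject, rec$subject)
  expect_identical(r2$group, rec$group)
  expect_identical(r2$visit, rec$visit)
  expect_equal(r2$sampling_rate, rec$sampling_rate)
  expect_identical(r2$events$onset, rec$events$onset)  # bit-exact metadata
  expect_identical(r2$events$duration, rec$events$duration)
  expect_equal(r2$layout$channels, rec$layout$channels)
  expect_equal(r2$intensities, rec$intensities, tolerance = 1e-12)
  expect_equal(r2$phases$onset, rec$phases$onset)
})

test_that("loading a file with a non-positive intensity raises a format error", {
  sim <- simulate_subject(quiet_cfg(), subject_seed = 2, threshold_c = 46)
  d <- withr::local_tempdir()
  save_recording(sim$recording, d)
  f <- file.path(d, "intensity_690nm.csv")
  m <- data.table::fread(f)
  m[5, 1] <- 0
  data.table::fwrite(m, f)
  expect_error(load_recording(d), "non-positive intensity")
})

test_that("behavioral and region-map files round-trip", {
  tbl <- behavioral_table(c("s1", "s2"), c("TMB", "VRB"), c(1, 1), c(45.4, 46.5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_behavioral(tbl, f)
  t2 <- read_behavioral(f)
  expect_equal(as.data.frame(t2), as.data.frame(tbl))

  ym <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c('"1": aPFC', '"2": S1'), ym)
  m <- read_region_map(ym)
  expect_equal(unname(m), c("aPFC", "S1"))
  jm <- withr::local_tempfile(fileext = ".json")
  writeLines('{"1": "V1", "2": "other"}', jm)
  expect_equal(unname(read_region_map(jm)), c("V1", "other"))
  writeLines('{"1": "nope"}', jm)
  expect_error(read_region_map(jm), "unknown label")
})
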