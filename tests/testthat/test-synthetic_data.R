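test_that("thermal test events follow the ramp arithmetic", {
  ev <- simulate_tqst_events(n_trials = 1, thresholds = 46)
  expect_equal(ev$duration, 16)          # (46 - 30) / 1
  # 20 ceiling trials with 10 s rests span 20*20 + 19*10 = 590 s
  ev20 <- simulate_tqst_events(n_trials = 20, thresholds = 50)
  expect_equal(max(ev20$onset + ev20$duration) - min(ev20$onset), 590)
  # doubling the ramp rate halves every duration
  ev_fast <- simulate_tqst_events(n_trials = 5, thresholds = 44, ramp_rate = 2)
  ev_slow <- simulate_tqst_events(n_trials = 5, thresholds = 44, ramp_rate = 1)
  expect_equal(ev_fast$duration, ev_slow$duration / 2)
  expect_error(simulate_tqst_events(thresholds = 29), "exceed")
  expect_error(simulate_tqst_events(thresholds = 51), "ceiling")
})

test_that("identical seeds give bit-identical recordings", {
  cfg <- noisy_cfg(seed = 42)
  a <- simulate_subject(cfg, subject_seed = 7, threshold_c = 46)
  b <- simulate_subject(cfg, subject_seed = 7, threshold_c = 46)
  expect_identical(a$recording$intensities, b$recording$intensities)
  expect_identical(a$truth$beat_times, b$truth$beat_times)
  c <- simulate_subject(cfg, subject_seed = 8, threshold_c = 46)
  expect_false(identical(a$recording$intensities, c$recording$intensities))
})

test_that("a noiseless simulated subject is recovered exactly by preprocessing", {
  sim <- simulate_subject(quiet_cfg(beta = 1), subject_seed = 42,
                          threshold_c = 46, store_signals = TRUE)
  hb <- recording_to_hemoglobin(sim$recording)
  expect_lt(max(abs(hb$hbo - sim$truth$hbo)), 1e-8)
  expect_lt(max(abs(hb$hbr - sim$truth$hbr)), 1e-8)
  # and the recovered HbO is exactly a scaled HRF convolution on the active
  # channel: correlation 1 against the design regressor over the task phase
  expect_gt(abs(cor(hb$hbo[1, ], sim$truth$hbo[1, ])), 1 - 1e-12)
})

test_that("cohorts have the study structure and reproducible behavior", {
  cfg <- simulation_config(n_per_group = 2, visits = 2, layout = tiny_layout(2),
                           rest_pre_s = 5, breathing_s = 5, rest_post_s = 5,
                           n_trials = 2, active_channels = c(`1` = 0.1),
                           edge_set = no_edges(), cardiac_amp_um = 0, seed = 3)
  coh <- simulate_cohort(cfg)
  expect_length(coh$recordings, 8)       # 2 groups x 2 subjects x 2 visits
  expect_equal(nrow(coh$behavior), 8)
  expect_setequal(unique(coh$behavior$group), c("TMB", "VRB"))
  expect_true(all(coh$behavior$mean_threshold_c >= 30 &
                  coh$behavior$mean_threshold_c <= 50))
  coh2 <- simulate_cohort(cfg)
  expect_identical(coh$behavior$mean_threshold_c, coh2$behavior$mean_threshold_c)
})

test_that("group-visit threshold means track the configured values", {
  # thresholds are drawn around the configured group x visit means; with many
  # subjects the sample means land close to them
  cfg <- simulation_config(n_per_group = 40, visits = 2, layout = tiny_layout(1),
                           rest_pre_s = 2, breathing_s = 2, rest_post_s = 2,
                           n_trials = 1, active_channels = c(`1` = 0),
                           edge_set = data.frame(ch_a = integer(0),
                                                 ch_b = integer(0), r = numeric(0)),
                           lf_sd_um = 0, cardiac_amp_um = 0, mayer_amp_um = 0,
                           resp_amp_um = 0, noise_sd = 0.01, seed = 5)
  coh <- simulate_cohort(cfg)
  agg <- aggregate(mean_threshold_c ~ group + visit, coh$behavior, mean)
  want <- rbind(TMB = c(45.4, 46.0), VRB = c(46.5, 47.1))
  for (i in seq_len(nrow(agg))) {
    expect_equal(agg$mean_threshold_c[i],
                 unname(want[agg$group[i], agg$visit[i]]), tolerance = 0.5)
  }
})

test_that("planted edges reach their target band-limited correlation", {
  lay <- tiny_layout(4)
  zs <- replicate(10, {
    cfg <- simulation_config(
      n_per_group = 1, visits = 1, layout = lay, sampling_rate = 25,
      rest_pre_s = 5, breathing_s = 300, rest_post_s = 5, n_trials = 1,
      active_channels = c(`1` = 0), edge_set = data.frame(ch_a = 2, ch_b = 4, r = 0.6),
      edge_z_sd = 0, seed = sample.int(1e6, 1))
    sim <- simulate_subject(cfg, threshold_c = 46)
    cm <- breathing_connectivity(sim$recording, band = "low")
    unclass(cm)[2, 4]
  })
  expect_lt(abs(tanh(mean(zs)) - 0.6), 0.1)
})

test_that("infeasible planted correlation structures are rejected", {
  expect_error(
    simulation_config(layout = tiny_layout(3), active_channels = c(`1` = 0.1),
                      edge_set = data.frame(ch_a = c(1, 1), ch_b = c(2, 3),
                                            r = c(0.8, 0.8))),
    "positive semidefinite")
  expect_error(
    simulation_config(layout = tiny_layout(3), active_channels = c(`1` = 0.1),
                      edge_set = data.frame(ch_a = 1, ch_b = 2, r = 1.2)),
    "\\|r\\| < 1")
})

test_that("zero heart-period jitter yields zero planted SDNN", {
  sim <- simulate_subject(noisy_cfg(rr_jitter_sd = 0), subject_seed = 3,
                          threshold_c = 46)
  expect_equal(sim$truth$sdnn, 0)
})

test_that("null behavior coupling leaves thresholds unrelated to edges", {
  cfg <- simulation_config(
    n_per_group = 12, visits = 1, layout = tiny_layout(2),
    rest_pre_s = 2, breathing_s = 2, rest_post_s = 2, n_trials = 1,
    active_channels = c(`1` = 0), edge_set = data.frame(ch_a = 1, ch_b = 2, r = 0.5),
    cardiac_amp_um = 0, behavior_coupling = list(
      edge = 1, slope = 0, residual_sd = 0.9,
      group_visit_means = rbind(TMB = c(45.4, 46), VRB = c(46.5, 47.1))),
    seed = 8)
  coh <- simulate_cohort(cfg)
  z <- vapply(coh$truth, function(tr) tr$edge_z[1], 0)
  thr <- coh$behavior$mean_threshold_c
  grp <- coh$behavior$group
  r <- cor(z, thr - ave(thr, grp))       # remove group means, then correlate
  expect_lt(abs(r), 0.55)                # centred on 0 at n = 24
})
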