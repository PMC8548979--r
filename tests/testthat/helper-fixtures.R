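# Shared fixtures: small montages and quiet (noise-free) configurations so
# unit tests stay fast; full-scale study conditions live in the simulator
# defaults and are exercised by the acceptance tests.

tiny_layout <- function(n_ch = 2, regions = NULL) {
  ed <- data.frame(emitter = rep(seq_len(ceiling(n_ch / 4)), each = 4)[seq_len(n_ch)],
                   detector = rep_len(1:4, n_ch) +
                     4 * (rep(seq_len(ceiling(n_ch / 4)), each = 4)[seq_len(n_ch)] - 1))
  probe_layout(ed, region_map = regions %||% rep("other", n_ch))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

upper_vec <- function(m) m[upper.tri(m)]

no_edges <- function() data.frame(ch_a = integer(0), ch_b = integer(0),
                                  r = numeric(0))

# noise-free single-channel-active configuration on a small montage;
# ... overrides any base argument
quiet_cfg <- function(n_ch = 2, beta = 1, seed = 1, ...) {
  args <- list(
    n_per_group = 1, visits = 1, layout = tiny_layout(n_ch),
    sampling_rate = 25, rest_pre_s = 20, breathing_s = 20, rest_post_s = 10,
    n_trials = 3, trial_jitter_sd = 0,
    active_channels = stats::setNames(beta, "1"), edge_set = no_edges(),
    lf_sd_um = 0, cardiac_amp_um = 0, mayer_amp_um = 0, resp_amp_um = 0,
    noise_sd = 0, hbr_noise_sd = 0, seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# default-noise configuration on a small montage (study-like physiology)
noisy_cfg <- function(n_ch = 2, beta = 0.1, seed = 1, ...) {
  args <- list(
    n_per_group = 1, visits = 1, layout = tiny_layout(n_ch),
    sampling_rate = 25, rest_pre_s = 10, breathing_s = 10, rest_post_s = 10,
    active_channels = stats::setNames(beta, "1"), edge_set = no_edges(),
    seed = seed)
  do.call(simulation_config, utils::modifyList(args, list(...)))
}

# hemoglobin series wrapper for operation-level tests
as_hb <- function(hbo, rate = 2, hbr = NULL, layout = NULL) {
  structure(list(hbo = hbo, hbr = hbr %||% (-hbo / 3),
                 sampling_rate = rate, layout = layout,
                 provenance = list()),
            class = "hemoglobin_series")
}

# synthetic edge-feature table with three planted edges sharing one latent
# subject factor that also drives the response (total R^2 = 0.5; per-edge
# correlation with the response ~0.5, the regime of reported
# edge-threshold correlations)
latent_feature_table <- function(seed, n = 40, n_ch = 45,
                                 planted = c(10, 500, 900), null = FALSE) {
  set.seed(seed)
  ep <- data.frame(which(upper.tri(matrix(0, n_ch, n_ch)), arr.ind = TRUE))
  names(ep) <- c("ch_a", "ch_b")
  p <- nrow(ep)
  x <- matrix(stats::rnorm(n * p), n)
  z <- stats::rnorm(n)
  if (!null) for (j in planted) x[, j] <- z + stats::rnorm(n)
  y <- 46 + if (null) stats::rnorm(n, 0, sqrt(2)) else z + stats::rnorm(n)
  structure(list(x = scale(x), y = y, edges = ep, behavior = NULL,
                 band = "low"),
            class = "edge_feature_table")
}
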