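# Canonical HRF and first-level design matrices.

#' Canonical hemodynamic response function
#'
#' Double-gamma kernel: a positive response gamma density peaking at 6 s
#' minus a later, smaller undershoot gamma (peak 15 s, one sixth amplitude),
#' sampled over 32 s and scaled to unit peak. The kernel is 0 at t = 0.
#'
#' @param rate sampling rate in Hz.
#' @param duration_s kernel length in seconds (default 32).
#' @return numeric vector of kernel samples at `1/rate` spacing starting at
#'   t = 0.
#' @export
canonical_hrf <- function(rate, duration_s = 32) {
  if (rate <= 0) stopf("`rate` must be positive")
  t <- seq(0, duration_s, by = 1 / rate)
  h <- stats::dgamma(t, shape = 7, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

# Continuous-time convolution of a stimulus function with the canonical HRF,
# approximated as a discrete causal convolution scaled by the sample period.
# The 1/rate factor makes the regressor amplitude independent of sampling
# rate, so coefficients estimated at the 2 Hz analysis rate are on the same
# scale as responses generated at the 25 Hz acquisition rate.
hrf_convolve <- function(u, rate) {
  h <- canonical_hrf(rate)
  # causal convolution with zero initial conditions (stimulus history before
  # recording start is zero)
  v <- stats::convolve(u, rev(h), type = "open")[seq_along(u)] / rate
  v
}

#' Build a first-level design matrix
#'
#' One column per condition label: the condition's boxcar (1 within each
#' `[onset, onset + duration)` event window) convolved with the canonical
#' HRF; plus an intercept and a linear drift column. The matrix must be full
#' column rank; perfectly collinear condition columns raise an error naming
#' the offending pair.
#'
#' @param events an [event_design()]; onsets in seconds relative to the start
#'   of the modeled data segment.
#' @param n_samples number of data samples the design must match.
#' @param rate sampling rate of the data in Hz.
#' @return object of class `design_matrix`: list with `x` (n_samples x
#'   regressors matrix, named columns), `condition_names`, `sampling_rate`.
#' @export
build_design <- function(events, n_samples, rate) {
  if (nrow(events) && any(events$onset + events$duration > n_samples / rate + 1e-9))
    stopf("events extend beyond the modeled segment (%g s)", n_samples / rate)
  conds <- unique(events$label)
  tgrid <- (seq_len(n_samples) - 1) / rate
  cols <- lapply(conds, function(lb) {
    u <- numeric(n_samples)
    ev <- events[events$label == lb, ]
    for (k in seq_len(nrow(ev)))
      u[tgrid >= ev$onset[k] & tgrid < ev$onset[k] + ev$duration[k]] <- 1
    hrf_convolve(u, rate)
  })
  x <- cbind(intercept = rep(1, n_samples),
             drift = seq(-0.5, 0.5, length.out = n_samples))
  if (length(conds)) {
    xc <- do.call(cbind, cols)
    colnames(xc) <- conds
    x <- cbind(xc, x)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    cc <- stats::cor(x[, seq_along(conds), drop = FALSE])
    diag(cc) <- 0
    bad <- which(abs(cc) > 1 - 1e-8, arr.ind = TRUE)
    nm <- if (nrow(bad)) paste(conds[bad[1, 1]], "and", conds[bad[1, 2]])
          else "unknown columns"
    stopf("design matrix is rank deficient: collinear regressors (%s)", nm)
  }
  structure(list(x = x, condition_names = conds, sampling_rate = rate),
            class = "design_matrix")
}

#' Build a design matrix at acquisition rate and decimate it with the data
#'
#' Constructs the condition regressors at the acquisition rate and passes
#' them through the same anti-aliased decimation applied to the data, so
#' that the filter's (small) passband shaping affects data and model
#' identically; a regressor built directly at the analysis rate would bias
#' coefficients downward by a few percent because the prewhitened fit
#' emphasises exactly the frequencies the decimation filter touches.
#' Intercept and drift are attached at the analysis rate.
#'
#' @inheritParams build_design
#' @param native_rate acquisition sampling rate in Hz.
#' @param native_samples number of samples of the modeled segment at the
#'   acquisition rate.
#' @param rate analysis rate in Hz.
#' @return a `design_matrix` at `rate`.
#' @export
build_design_decimated <- function(events, native_samples, native_rate, rate) {
  des_hi <- build_design(events, native_samples, native_rate)
  n_out <- floor(native_samples * rate / native_rate)
  conds <- des_hi$condition_names
  x <- cbind(intercept = rep(1, n_out),
             drift = seq(-0.5, 0.5, length.out = n_out))
  if (length(conds)) {
    xc <- vapply(conds, function(nm)
      anti_alias_resample(des_hi$x[, nm], native_rate, rate), numeric(n_out))
    x <- cbind(xc, x)
  }
  structure(list(x = x, condition_names = conds, sampling_rate = rate),
            class = "design_matrix")
}
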