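# Internal helpers shared across modules.

#' Derive a reproducible substream seed
#'
#' All randomness in the simulator flows from one root seed; per-subject and
#' per-component substreams are derived deterministically from it so that any
#' piece of a cohort can be regenerated in isolation.
#'
#' @param root integer root seed.
#' @param ... integer indices identifying the substream (e.g. group, subject,
#'   visit). Order matters.
#' @return a single integer seed in `[0, 2^31 - 1)`.
#' @keywords internal
split_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483647
  for (i in idx) {
    s <- (s * 69069 + 104729 * (as.double(i) + 1) + 1) %% 2147483647
  }
  as.integer(s)
}

# Enumerate unordered channel pairs in canonical (min, max) order.
edge_pairs <- function(n_channels) {
  idx <- which(upper.tri(matrix(0, n_channels, n_channels)), arr.ind = TRUE)
  data.frame(ch_a = idx[, "row"], ch_b = idx[, "col"])
}

# Upper-triangle vectorisation consistent with edge_pairs().
upper_vec <- function(m) m[upper.tri(m)]

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
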