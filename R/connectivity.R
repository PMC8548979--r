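# Band-limited robust functional connectivity.
#
# Channel pairs are correlated within a frequency band during the breathing
# practice phase. Each series is first AR-prewhitened (serial correlation
# otherwise inflates the effective dof of the correlation), then a Tukey
# bisquare-weighted Pearson correlation is iterated to convergence so that
# gross transients do not dominate the estimate. Correlations are mapped to
# Fisher Z scores for group statistics.

CONNECTIVITY_BANDS <- list(low = c(0.01, 0.08), high = c(0.5, 1))

prewhiten_series <- function(x, max_ar = 10) {
  arfit <- tryCatch(
    stats::ar(x, aic = TRUE, order.max = max_ar, method = "yule-walker"),
    error = function(e) NULL)
  if (is.null(arfit) || !length(arfit$ar)) return(x)
  y <- as.numeric(stats::filter(x - mean(x), c(1, -arfit$ar),
                                method = "convolution", sides = 1))
  y[!is.na(y)]
}

weighted_cor <- function(x, y, w) {
  sw <- sum(w)
  mx <- sum(w * x) / sw; my <- sum(w * y) / sw
  dx <- x - mx; dy <- y - my
  sxy <- sum(w * dx * dy)
  sxx <- sum(w * dx * dx); syy <- sum(w * dy * dy)
  sxy / sqrt(sxx * syy)
}

robust_cor_pair <- function(x, y, tuning = 6, max_iter = 50, tol = 1e-6) {
  sx <- stats::sd(x); sy <- stats::sd(y)
  u <- (x - mean(x)) / sx; v <- (y - mean(y)) / sy
  r <- weighted_cor(u, v, rep(1, length(u)))
  if (abs(r) >= 1 - 1e-12) return(r)
  for (it in seq_len(max_iter)) {
    d2 <- (u^2 - 2 * r * u * v + v^2) / max(1 - r^2, 1e-12)
    d <- sqrt(pmax(d2, 0))
    w <- ifelse(d < tuning, (1 - (d / tuning)^2)^2, 0)
    if (sum(w > 0) < 10) break
    r_new <- weighted_cor(u, v, w)
    if (!is.finite(r_new)) break
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  max(-1, min(1, r))
}

#' Robust correlation between two time series
#'
#' Correlation estimator for serially correlated, occasionally contaminated
#' physiological series: (a) each series is prewhitened by an AIC-selected
#' autoregressive filter, (b) a Pearson correlation with Tukey bisquare
#' weights on the standardized bivariate residual distance is iterated to
#' convergence. With `method = "pearson"` the plain product-moment
#' correlation of the (optionally prewhitened) series is returned instead.
#'
#' @param x,y numeric vectors of equal length (>= 30 samples).
#' @param method `"robust"` (default) or `"pearson"`.
#' @param prewhiten AR-prewhiten both series first (default TRUE).
#' @param tuning bisquare cutoff on the bivariate standardized distance
#'   (default 6; the distance is approximately chi on 2 dof, so points beyond
#'   6 are assigned zero weight).
#' @return correlation in \[-1, 1\].
#' @export
robust_correlation <- function(x, y, method = c("robust", "pearson"),
                               prewhiten = TRUE, tuning = 6) {
  method <- match.arg(method)
  if (length(x) != length(y)) stopf("series lengths differ (%d vs %d)",
                                    length(x), length(y))
  if (length(x) < 30) stopf("need at least 30 samples (got %d)", length(x))
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("zero-variance input series")
  if (prewhiten) {
    x <- prewhiten_series(x); y <- prewhiten_series(y)
    n <- min(length(x), length(y))
    x <- x[seq_len(n)]; y <- y[seq_len(n)]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stopf("zero-variance input series after prewhitening")
  }
  if (method == "pearson") return(stats::cor(x, y))
  robust_cor_pair(x, y, tuning = tuning)
}

#' Fisher Z-transform of a correlation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, variance-stabilising for
#' group-level statistics on correlations.
#'
#' @param r correlation(s) with `|r| < 1`.
#' @return Fisher Z score(s).
#' @export
fisher_z <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) >= 1))
    stopf("Fisher Z requires |r| < 1")
  atanh(r)
}

#' Subject-level band-limited connectivity matrix
#'
#' Band-filters the HbO traces (4 Hz input) to the requested band, then
#' computes all unordered channel-pair correlations with
#' [robust_correlation()] and maps them to Fisher Z. Channel pairs whose
#' correlation is numerically perfect (degenerate duplicated signals) are
#' masked as `NA` with a warning.
#'
#' @param hb a `hemoglobin_series` at 4 Hz (breathing-phase data in the study
#'   design).
#' @param band `"low"` (0.01-0.08 Hz, hemodynamic) or `"high"` (0.5-1 Hz);
#'   both avoid the Mayer (0.1 Hz), respiratory (0.3-0.5 Hz) and cardiac
#'   (1-1.5 Hz) physiological bands.
#' @param method correlation method, see [robust_correlation()].
#' @param subject,group,visit metadata attached to the matrix (defaults taken
#'   from the series attributes when present).
#' @return `connectivity_matrix`: symmetric channel x channel matrix of
#'   Fisher Z scores with `NA` diagonal and attributes `band`, `subject`,
#'   `group`, `visit`, `n_samples`, `method`.
#' @export
subject_connectivity <- function(hb, band = c("low", "high"),
                                 method = c("robust", "pearson"),
                                 subject = NULL, group = NULL, visit = NULL) {
  stopifnot(inherits(hb, "hemoglobin_series"))
  band <- match.arg(band)
  method <- match.arg(method)
  if (abs(hb$sampling_rate - 4) > 1e-6)
    stopf("connectivity expects data down-sampled to 4 Hz (got %g Hz)",
          hb$sampling_rate)
  edges <- CONNECTIVITY_BANDS[[band]]
  filt <- bandpass_filter(hb$hbo, edges[1], edges[2], hb$sampling_rate)
  n_ch <- nrow(filt)
  # prewhitening is per-series: do it once per channel, not once per pair
  wh <- lapply(seq_len(n_ch), function(ch) prewhiten_series(filt[ch, ]))
  n <- min(vapply(wh, length, 0L))
  wh <- vapply(wh, function(v) v[seq_len(n)], numeric(n))
  z <- matrix(NA_real_, n_ch, n_ch)
  degenerate <- FALSE
  for (a in seq_len(n_ch - 1)) for (b in (a + 1):n_ch) {
    r <- tryCatch(
      robust_correlation(wh[, a], wh[, b], method = method, prewhiten = FALSE),
      error = function(e) NA_real_)
    if (is.na(r) || abs(r) >= 1 - 1e-12) {
      degenerate <- degenerate || (!is.na(r))
      z[a, b] <- z[b, a] <- NA_real_
    } else {
      z[a, b] <- z[b, a] <- atanh(r)
    }
  }
  if (degenerate)
    warnf("perfectly correlated channel pair(s) masked as NA (duplicated signals?)")
  structure(z, class = c("connectivity_matrix", "matrix"),
            band = band, method = method, n_samples = n,
            subject = subject %||% attr(hb, "subject") %||% NA_character_,
            group = group %||% attr(hb, "group") %||% NA_character_,
            visit = visit %||% attr(hb, "visit") %||% NA_integer_)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  zs <- upper_vec(unclass(x))
  cat(sprintf("<connectivity_matrix> %s band, %d channels, subject %s visit %s; |Z| median %.3f, max %.3f\n",
              attr(x, "band"), nrow(x), attr(x, "subject"), attr(x, "visit"),
              stats::median(abs(zs), na.rm = TRUE), max(abs(zs), na.rm = TRUE)))
  invisible(x)
}

#' Group-level edge statistics
#'
#' Stacks subject-level Fisher-Z matrices and tests each unordered channel
#' pair. With repeated measures (two visits) each edge is modeled as
#' `Z ~ 1 + (1 | subject)` by restricted maximum likelihood; with one matrix
#' per subject the model reduces to the vectorised one-sample t-test. Raw
#' p-values are FDR-adjusted across the 990 edges, and the "significant
#' pattern" flag marks edges below `p_threshold` (default .001, the map
#' threshold used for group connectivity figures).
#'
#' @param mats list of `connectivity_matrix` objects sharing a band (>= 3
#'   subjects).
#' @param p_threshold uncorrected p threshold for the pattern flag.
#' @param level FDR level for rejection flags.
#' @return `group_edges` data.frame: ch_a, ch_b, mean_z, t, dof, p, q,
#'   reject, pattern.
#' @export
group_edges <- function(mats, p_threshold = 0.001, level = 0.05) {
  if (!is.list(mats) || length(mats) < 3)
    stopf("group edge analysis needs at least 3 subjects")
  bands <- unique(vapply(mats, function(m) attr(m, "band"), ""))
  if (length(bands) != 1)
    stopf("all matrices must share one band (got: %s)", paste(bands, collapse = ", "))
  subjects <- vapply(mats, function(m) as.character(attr(m, "subject")), "")
  if (length(unique(subjects)) < 3)
    stopf("group edge analysis needs at least 3 subjects")
  n_ch <- nrow(mats[[1]])
  ep <- edge_pairs(n_ch)
  zmat <- vapply(mats, function(m) upper_vec(unclass(m)), numeric(nrow(ep)))
  repeated <- anyDuplicated(subjects) > 0
  if (!repeated) {
    m <- rowMeans(zmat)
    se <- apply(zmat, 1, stats::sd) / sqrt(ncol(zmat))
    dof <- rep(ncol(zmat) - 1, nrow(ep))
    tstat <- m / se
  } else {
    sub <- factor(subjects)
    m <- se <- tstat <- dof <- numeric(nrow(ep))
    for (k in seq_len(nrow(ep))) {
      d <- data.frame(y = zmat[k, ], subject = sub)
      fit <- tryCatch(
        suppressMessages(lmerTest::lmer(y ~ 1 + (1 | subject), data = d)),
        error = function(e) NULL)
      if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
        co <- stats::coef(summary(fit))
        m[k] <- co[1, "Estimate"]; se[k] <- co[1, "Std. Error"]
        dof[k] <- co[1, "df"]; tstat[k] <- co[1, "t value"]
      } else {
        m[k] <- mean(zmat[k, ])
        se[k] <- stats::sd(zmat[k, ]) / sqrt(ncol(zmat))
        dof[k] <- ncol(zmat) - 1
        tstat[k] <- m[k] / se[k]
      }
    }
  }
  p <- 2 * stats::pt(-abs(tstat), dof)
  ok <- is.finite(p)
  q <- rep(NA_real_, length(p)); rej <- rep(NA, length(p))
  if (any(ok)) {
    fdr <- fdr_correct(p[ok], q = level)
    q[ok] <- fdr$q; rej[ok] <- fdr$reject
  }
  out <- data.frame(ch_a = ep$ch_a, ch_b = ep$ch_b, mean_z = m, t = tstat,
                    dof = dof, p = p, q = q, reject = rej,
                    pattern = !is.na(p) & p < p_threshold)
  class(out) <- c("group_edges", "data.frame")
  attr(out, "band") <- bands
  out
}
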