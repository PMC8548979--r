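# Group-level activation: mixed-effects model over first-level coefficients,
# channel t-tests and FDR control.

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment of raw p-values with rejection flags at level `q`.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return list with `q` (monotone adjusted values, `>= p` elementwise) and
#'   `reject` (logical flags).
#' @export
fdr_correct <- function(pvals, q = 0.05) {
  if (!length(pvals)) stopf("empty p-value list")
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stopf("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(q = adj, reject = adj <= q)
}

#' Group-level activation map
#'
#' Per channel, models the first-level coefficients of one regressor across
#' subjects with a linear mixed-effects model `beta ~ 1 + (1 | subject)`
#' (restricted maximum likelihood, Satterthwaite degrees of freedom). The
#' group effect is tested with a two-tailed t-test and channel p-values are
#' FDR-adjusted across the montage. When every subject contributes a single
#' coefficient (one visit) the random intercept is unidentifiable and the
#' model reduces to the fixed-effects-only one-sample t-test, flagged in the
#' output; the same fallback (with a warning) is used when the random-effects
#' fit is singular.
#'
#' @param first_levels list of `first_level_result` objects (>= 3 subjects).
#' @param regressor condition column to analyse (default: first condition of
#'   the first fit).
#' @param level FDR level for the rejection flags.
#' @return object of class `group_activation`: data.frame with channel,
#'   region, estimate, se, t, dof, p, q, reject, random_sd, method.
#' @export
fit_group <- function(first_levels, regressor = NULL, level = 0.05) {
  stopifnot(is.list(first_levels), length(first_levels) >= 1)
  if (!all(vapply(first_levels, inherits, TRUE, "first_level_result")))
    stopf("`first_levels` must be a list of first_level_result objects")
  subjects <- vapply(first_levels, function(f) as.character(f$subject), "")
  if (length(unique(subjects)) < 3)
    stopf("group analysis needs at least 3 subjects (got %d)",
          length(unique(subjects)))
  regressor <- regressor %||% first_levels[[1]]$regressors[1]
  n_ch <- nrow(first_levels[[1]]$betas)
  j <- match(regressor, first_levels[[1]]$regressors)
  if (is.na(j)) stopf("unknown regressor '%s'", regressor)
  b <- matrix(vapply(first_levels, function(f) f$betas[, j], numeric(n_ch)),
              nrow = n_ch)                                           # ch x obs
  repeated <- anyDuplicated(subjects) > 0
  if (!repeated) {
    # one coefficient per subject: fixed-effects-only path
    m <- unname(rowMeans(b))
    se <- apply(b, 1, stats::sd) / sqrt(ncol(b))
    dof <- rep(ncol(b) - 1, n_ch)
    tstat <- m / se
    rand_sd <- rep(NA_real_, n_ch)
    method <- rep("fixed", n_ch)
  } else {
    m <- se <- tstat <- rand_sd <- numeric(n_ch)
    dof <- numeric(n_ch)
    method <- character(n_ch)
    sub <- factor(subjects)
    for (ch in seq_len(n_ch)) {
      d <- data.frame(y = b[ch, ], subject = sub)
      fit <- tryCatch(
        suppressMessages(lmerTest::lmer(y ~ 1 + (1 | subject), data = d,
                                        REML = TRUE)),
        error = function(e) NULL)
      if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
        co <- stats::coef(summary(fit))
        m[ch] <- co[1, "Estimate"]; se[ch] <- co[1, "Std. Error"]
        dof[ch] <- co[1, "df"]; tstat[ch] <- co[1, "t value"]
        rand_sd[ch] <- sqrt(as.numeric(lme4::VarCorr(fit)$subject[1]))
        method[ch] <- "lmm"
      } else {
        if (ch == 1)
          warnf("singular random-effects fit; falling back to fixed-effects-only t-test")
        m[ch] <- mean(b[ch, ])
        se[ch] <- stats::sd(b[ch, ]) / sqrt(ncol(b))
        dof[ch] <- ncol(b) - 1
        tstat[ch] <- m[ch] / se[ch]
        rand_sd[ch] <- NA_real_
        method[ch] <- "fixed"
      }
    }
  }
  p <- 2 * stats::pt(-abs(tstat), dof)
  fdr <- fdr_correct(p, q = level)
  region <- first_levels[[1]]$region %||% rep(NA_character_, n_ch)
  out <- data.frame(channel = seq_len(n_ch), region = region, estimate = m,
                    se = se, t = tstat, dof = dof, p = p, q = fdr$q,
                    reject = fdr$reject, random_sd = rand_sd, method = method)
  class(out) <- c("group_activation", "data.frame")
  attr(out, "regressor") <- regressor
  attr(out, "n_subjects") <- length(unique(subjects))
  out
}
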