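test_that("the canonical HRF peaks at 6 s, starts at 0 and integrates to a finite positive value", {
  for (rate in c(2, 25)) {
    h <- canonical_hrf(rate)
    tpk <- (which.max(h) - 1) / rate
    expect_lte(abs(tpk - 6), 1 / rate + 1e-9)
    expect_equal(h[1], 0)
    expect_equal(max(h), 1)
    integral <- sum(h) / rate
    expect_gt(integral, 0)
    expect_true(is.finite(integral))
    # undershoot present
    expect_lt(min(h), 0)
  }
})

test_that("design matrices contain convolved conditions plus nuisance columns", {
  des0 <- build_design(event_design(numeric(0), numeric(0), character(0)), 100, 2)
  expect_equal(colnames(des0$x), c("intercept", "drift"))

  ev <- event_design(10, 16, "tqst_trial")
  des <- build_design(ev, 200, 2)
  expect_equal(colnames(des$x), c("tqst_trial", "intercept", "drift"))
  # independent convolution oracle: direct O(n^2) sum
  h <- canonical_hrf(2)
  u <- as.numeric((0:199) / 2 >= 10 & (0:199) / 2 < 26)
  oracle <- vapply(seq_len(200), function(i) {
    k <- seq_len(min(i, length(h)))
    sum(h[k] * u[i - k + 1]) / 2
  }, 0)
  expect_equal(unname(des$x[, "tqst_trial"]), oracle, tolerance = 1e-10)
  # the response peaks after the trial, lagged by the HRF peak
  tpk <- (which.max(des$x[, "tqst_trial"]) - 1) / 2
  expect_gt(tpk, 10 + 6)
  expect_lt(tpk, 10 + 16 + 10)

  ev2 <- event_design(c(10, 10), c(16, 16), c("a", "b"))
  expect_error(build_design(ev2, 200, 2), "rank deficient")
})

test_that("noise-free channels are recovered exactly and match OLS", {
  ev <- event_design(c(5, 40), c(16, 16), c("tqst_trial", "tqst_trial"))
  des <- build_design(ev, 200, 2)
  beta <- c(1, 0.5, -0.2)
  y <- as.numeric(des$x %*% beta)
  hb <- as_hb(rbind(y, y), rate = 2)
  fl <- fit_first_level(hb, des)
  expect_lt(max(abs(fl$betas[1, ] - beta)), 1e-6)
  expect_true(all(fl$converged))
  # noise-free path equals the closed-form OLS solution
  expect_lt(max(abs(fl$betas[2, ] - qr.solve(des$x, y))), 1e-8)
})

test_that("with white noise the robust prewhitened fit stays close to OLS", {
  set.seed(11)
  ev <- event_design(c(5, 60, 115), c(16, 16, 16), rep("tqst_trial", 3))
  des <- build_design(ev, 400, 2)
  y <- as.numeric(des$x %*% c(1, 0, 0)) + rnorm(400, 0, 0.3)
  fl <- fit_first_level(as_hb(matrix(y, 1), 2), des)
  ols <- qr.solve(des$x, y)
  se <- fl$se[1, 1]
  expect_lt(abs(fl$betas[1, 1] - ols[1]), 0.5 * se)
})

test_that("first-level rescaling equivariance: common scaling leaves beta unchanged", {
  set.seed(12)
  ev <- event_design(5, 16, "tqst_trial")
  des <- build_design(ev, 150, 2)
  y <- as.numeric(des$x %*% c(0.8, 0.1, 0)) + rnorm(150, 0, 0.2)
  f1 <- fit_first_level(as_hb(matrix(y, 1), 2), des)
  des2 <- des; des2$x <- des$x * 3
  f2 <- fit_first_level(as_hb(matrix(3 * y, 1), 2), des2)
  expect_equal(f1$betas[1, 1], f2$betas[1, 1], tolerance = 1e-6)
})

test_that("group maps reduce to the shared value when subjects are identical", {
  ev <- event_design(5, 16, "tqst_trial")
  des <- build_design(ev, 150, 2)
  y <- as.numeric(des$x %*% c(0.7, 0, 0)) + 0.05 * sin(1:150)
  fls <- lapply(sprintf("s%d", 1:4), function(s) {
    hb <- as_hb(rbind(y, y), 2)
    attr(hb, "subject") <- s
    suppressWarnings(fit_first_level(hb, des))
  })
  ga <- fit_group(fls)
  expect_equal(ga$estimate, rep(unname(fls[[1]]$betas[1, 1]), 2),
               tolerance = 1e-10)
  expect_true(all(ga$se < 1e-10))
  expect_true(all(ga$method == "fixed"))
})

test_that("group t equals the contrast over the model covariance", {
  # Eq-style identity |t| = |B| / sqrt(Cov_group), checked on both the
  # fixed-effects path and the mixed-model path
  set.seed(13)
  mk_fl <- function(s, v, b) {
    structure(list(subject = s, visit = v,
                   betas = matrix(b, 1, 1, dimnames = list(NULL, "tqst_trial")),
                   se = matrix(0.1, 1, 1), cov = list(matrix(0.01)),
                   dof = 10, ar = list(numeric(0)), sigma = 1,
                   weight_mean = 1, converged = TRUE,
                   regressors = "tqst_trial", region = "S1"),
              class = "first_level_result")
  }
  b <- rnorm(5, 1, 0.3)
  fls <- Map(mk_fl, sprintf("s%d", 1:5), 1, b)
  ga <- fit_group(fls)
  expect_equal(ga$t, mean(b) / (sd(b) / sqrt(5)), tolerance = 1e-8)
  expect_equal(ga$p, 2 * pt(-abs(ga$t), 4), tolerance = 1e-10)

  b2 <- rnorm(12, 1, 0.3)
  fls2 <- Map(mk_fl, rep(sprintf("s%d", 1:6), each = 2), rep(1:2, 6), b2)
  ga2 <- suppressWarnings(fit_group(fls2))
  expect_equal(abs(ga2$t), abs(ga2$estimate) / ga2$se, tolerance = 1e-8)
})

test_that("mixed-model group estimates recover the population mean", {
  set.seed(14)
  ok <- replicate(30, {
    subj <- rnorm(20, 1, 0.2)
    b <- c(subj + rnorm(20, 0, 0.1), subj + rnorm(20, 0, 0.1))
    fls <- Map(function(s, v, bb)
      structure(list(subject = s, visit = v,
                     betas = matrix(bb, 1, 1, dimnames = list(NULL, "c")),
                     se = matrix(0.1, 1, 1), cov = list(matrix(0.01)),
                     dof = 10, ar = list(numeric(0)), sigma = 1,
                     weight_mean = 1, converged = TRUE, regressors = "c",
                     region = NA_character_),
                class = "first_level_result"),
      rep(sprintf("s%d", 1:20), 2), rep(1:2, each = 20), b)
    ga <- suppressWarnings(fit_group(fls))
    abs(ga$estimate - 1) < 0.15
  })
  expect_gte(mean(ok), 0.85)
})

test_that("degenerate group inputs error or fall back as specified", {
  mk <- function(s, b) structure(
    list(subject = s, visit = 1,
         betas = matrix(b, 1, 1, dimnames = list(NULL, "c")),
         se = matrix(0.1, 1, 1), cov = list(matrix(0.01)), dof = 10,
         ar = list(numeric(0)), sigma = 1, weight_mean = 1, converged = TRUE,
         regressors = "c", region = NA_character_),
    class = "first_level_result")
  expect_error(fit_group(list(mk("a", 1), mk("b", 2))), "at least 3")
})

test_that("Benjamini-Hochberg control follows the step-up rule", {
  expect_error(fdr_correct(numeric(0)), "empty")
  expect_error(fdr_correct(c(0.5, 1.2)), "0, 1")
  r1 <- fdr_correct(rep(1, 10))
  expect_false(any(r1$reject))
  r2 <- fdr_correct(c(0.001, 0.5, 0.9), q = 0.05)
  expect_equal(r2$q, c(0.003, 0.75, 0.9))
  expect_equal(r2$reject, c(TRUE, FALSE, FALSE))
  # adjusted values never fall below raw ones
  set.seed(15)
  p <- runif(50)
  expect_true(all(fdr_correct(p)$q >= p))
})
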