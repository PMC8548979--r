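# Elastic-net selection of connectivity edges predicting pain thresholds,
# followed by Pearson and Spearman correlations for the selected edges.

#' Assemble an edge-feature table
#'
#' Vectorises the upper triangle of each subject-visit connectivity matrix
#' into one feature row per behavioral row, standardises every edge column
#' (zero mean, unit variance), and keeps the thermal threshold response in
#' degC. Zero-variance or incomplete edge columns are dropped with a
#' warning; behavioral rows without a matching matrix raise an error listing
#' the missing keys.
#'
#' @param mats list of `connectivity_matrix` objects with subject/visit
#'   attributes.
#' @param behavior a [behavioral_table()].
#' @return `edge_feature_table`: list with `x` (rows x edges, standardised),
#'   `y` (thresholds, degC), `edges` (data.frame ch_a/ch_b per column),
#'   `behavior` (aligned rows), `band`.
#' @export
assemble_features <- function(mats, behavior) {
  stopifnot(is.list(mats), inherits(behavior, "behavioral_table"))
  keys <- vapply(mats, function(m)
    paste(attr(m, "subject"), attr(m, "visit"), sep = "/"), "")
  want <- paste(behavior$subject, behavior$visit, sep = "/")
  miss <- setdiff(want, keys)
  if (length(miss))
    stopf("no connectivity matrix for behavioral row(s): %s",
          paste(miss, collapse = ", "))
  mats <- mats[match(want, keys)]
  n_ch <- nrow(mats[[1]])
  ep <- edge_pairs(n_ch)
  x <- t(vapply(mats, function(m) upper_vec(unclass(m)), numeric(nrow(ep))))
  colnames(x) <- sprintf("z_%d_%d", ep$ch_a, ep$ch_b)
  keep <- apply(x, 2, function(col) all(is.finite(col)) && stats::sd(col) > 0)
  if (!all(keep))
    warnf("dropping %d constant or incomplete edge column(s)", sum(!keep))
  x <- x[, keep, drop = FALSE]
  ep <- ep[keep, , drop = FALSE]
  x <- scale(x)
  attr(x, "scaled:center") <- NULL; attr(x, "scaled:scale") <- NULL
  structure(list(x = x, y = behavior$mean_threshold_c, edges = ep,
                 behavior = behavior, band = attr(mats[[1]], "band")),
            class = "edge_feature_table")
}

#' Elastic-net edge selection with Monte-Carlo cross-validation
#'
#' Sweeps the elastic-net mixing weight from 0 (ridge) to 1 (lasso) in steps
#' of 0.1. For each weight a penalty path is fit and the cross-validated
#' mean squared error is averaged over `reps` random 10-fold assignments
#' (Monte-Carlo repetition stabilises the CV curve at these sample sizes).
#' The (weight, penalty) pair minimising mean CV error is selected, with
#' exact ties broken toward the sparser model; edges with
#' `|coefficient| > 1e-8` at that point form the selected set.
#' Pearson and Spearman correlations with the threshold are attached for
#' every selected edge (the rank correlation guards the report against
#' outlying observations). Identical seeds give identical selections.
#'
#' @param tbl an [assemble_features()] table.
#' @param alphas mixing grid (default `seq(0, 1, 0.1)`).
#' @param folds number of CV folds (default 10; must not exceed rows).
#' @param reps Monte-Carlo repetitions of the fold assignment (default 100).
#' @param seed integer seed controlling fold assignments.
#' @param rule `"min"` (CV-minimum penalty, default) or `"1se"` (the most
#'   parsimonious model — fewest nonzero coefficients, then largest penalty
#'   — over the whole grid whose CV error is within one standard error of
#'   the minimum; the standard error is the per-repetition fold SE averaged
#'   over repetitions, as repeated CV reuses the same observations).
#' @param nlambda penalty path length per mixing weight.
#' @return `selection_result`: list with `selected` (data.frame of edges,
#'   coefficients and correlations), `alpha`, `lambda`, `cv` (full CV table),
#'   `cv_min`, `rule`, `folds`, `reps`, `seed`.
#' @export
elastic_net_select <- function(tbl, alphas = seq(0, 1, by = 0.1), folds = 10,
                               reps = 100, seed = 1,
                               rule = c("min", "1se"), nlambda = 30) {
  stopifnot(inherits(tbl, "edge_feature_table"))
  rule <- match.arg(rule)
  x <- tbl$x; y <- tbl$y
  n <- nrow(x)
  if (n < folds)
    stopf("%d rows is fewer than %d folds; reduce `folds`", n, folds)
  set.seed(seed)
  fold_ids <- replicate(reps, sample(rep(seq_len(folds), length.out = n)),
                        simplify = FALSE)
  fits <- list()
  cv_tab <- NULL
  for (alpha in alphas) {
    full <- glmnet::glmnet(x, y, alpha = alpha, nlambda = nlambda,
                           standardize = FALSE)
    lam <- full$lambda
    mse <- matrix(0, length(lam), reps * folds)
    rep_se <- matrix(0, length(lam), reps)
    cnt <- 0
    for (rep_i in seq_len(reps)) {
      fold_mse <- matrix(0, length(lam), folds)
      fid <- fold_ids[[rep_i]]
      for (k in seq_len(folds)) {
        hold <- fid == k
        fit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                              alpha = alpha, lambda = lam,
                              standardize = FALSE)
        pred <- stats::predict(fit, x[hold, , drop = FALSE])
        # a fold fit can stop early on the path; reuse its last column
        if (ncol(pred) < length(lam))
          pred <- cbind(pred, matrix(pred[, ncol(pred)], nrow(pred),
                                     length(lam) - ncol(pred)))
        cnt <- cnt + 1
        fold_mse[, k] <- colMeans((pred - y[hold])^2)
        mse[, cnt] <- fold_mse[, k]
      }
      rep_se[, rep_i] <- apply(fold_mse, 1, stats::sd) / sqrt(folds)
    }
    cvm <- rowMeans(mse)
    # repeated-CV standard error: the per-repetition fold SE, averaged over
    # repetitions (repetitions reuse the same data, so they do not shrink it)
    cvse <- rowMeans(rep_se)
    key <- sprintf("a%.3f", alpha)
    fits[[key]] <- full
    cv_tab <- rbind(cv_tab, data.frame(alpha = alpha, lambda = lam,
                                       cvm = cvm, cvse = cvse,
                                       nonzero = full$df))
  }
  # CV-minimum with a deterministic parsimony tie-break (larger penalty,
  # then more lasso-like mixing)
  ord <- order(cv_tab$cvm, -cv_tab$lambda, -cv_tab$alpha)
  best_row <- cv_tab[ord[1], ]
  if (rule == "1se") {
    # most parsimonious model over the whole grid within one SE of the best
    thr <- best_row$cvm + best_row$cvse
    cand <- cv_tab[cv_tab$cvm <= thr, ]
    cand <- cand[order(cand$nonzero, -cand$lambda, -cand$alpha), ]
    best_row <- cand[1, ]
  }
  best_fit <- fits[[sprintf("a%.3f", best_row$alpha)]]
  i <- match(best_row$lambda, best_fit$lambda)
  co <- as.numeric(stats::coef(best_fit)[-1, i])
  sel_idx <- which(abs(co) > 1e-8)
  best <- list(alpha = best_row$alpha, lambda_path = best_fit$lambda,
               cvm = best_row$cvm)
  selected <- cbind(tbl$edges[sel_idx, , drop = FALSE],
                    coefficient = co[sel_idx])
  rownames(selected) <- NULL
  if (nrow(selected)) {
    cors <- edge_threshold_correlation(tbl, sel_idx)
    selected <- cbind(selected, cors[, setdiff(names(cors), c("ch_a", "ch_b")),
                                     drop = FALSE])
  }
  structure(list(selected = selected, alpha = best$alpha,
                 lambda = best_row$lambda, cv = cv_tab, cv_min = best$cvm,
                 rule = rule, folds = folds, reps = reps, seed = seed,
                 n = n),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> alpha %.1f, lambda %.4g (%s rule), %d edge(s) selected from %d rows\n",
              x$alpha, x$lambda, x$rule, nrow(x$selected), x$n))
  if (nrow(x$selected)) print(x$selected)
  invisible(x)
}

#' Pearson and Spearman correlations between edges and thresholds
#'
#' For each requested edge column computes the Pearson correlation (with its
#' two-tailed t-based p) and the Spearman rank correlation (two-tailed p)
#' against the thermal threshold response; the rank statistic is reported
#' alongside to keep outliers from driving the correlation summary.
#' Unadjusted p-values are reported per edge, with an FDR-adjusted column
#' added across the requested set.
#'
#' @param tbl an [assemble_features()] table.
#' @param edges integer indices into the feature columns (nonempty).
#' @return data.frame: ch_a, ch_b, pearson_r, pearson_p, spearman_rho,
#'   spearman_p, pearson_q, spearman_q.
#' @export
edge_threshold_correlation <- function(tbl, edges) {
  stopifnot(inherits(tbl, "edge_feature_table"))
  if (!length(edges)) stopf("`edges` must be a nonempty set of edge indices")
  if (any(edges < 1 | edges > ncol(tbl$x)))
    stopf("edge index out of range 1..%d", ncol(tbl$x))
  res <- lapply(edges, function(j) {
    f <- tbl$x[, j]
    if (stats::sd(f) == 0) stopf("edge column %d is constant", j)
    pe <- stats::cor.test(f, tbl$y, method = "pearson")
    sp <- suppressWarnings(stats::cor.test(f, tbl$y, method = "spearman",
                                           exact = FALSE))
    data.frame(ch_a = tbl$edges$ch_a[j], ch_b = tbl$edges$ch_b[j],
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
  })
  out <- do.call(rbind, res)
  out$pearson_q <- stats::p.adjust(out$pearson_p, "BH")
  out$spearman_q <- stats::p.adjust(out$spearman_p, "BH")
  out
}
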