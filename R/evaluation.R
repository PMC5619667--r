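#' Model-fitting and prediction accuracy metrics
#'
#' Computes the coefficient of determination (squared Pearson correlation
#' of predicted vs observed, with the sum-of-squares variant reported
#' alongside), the mean prediction error (mean absolute error by default;
#' see `mpe`), the root mean squared prediction error, the relative
#' accuracy `100 * (1 - RMSPE / mean(obs))` and the slope of the
#' through-origin least-squares regression of predicted on observed.
#'
#' @param pred,obs equal-length numeric vectors without missing values,
#'   `n >= 2`.
#' @param scope `"fitting"` or `"cv"`, recorded in the report.
#' @param mpe `"absolute"` (mean absolute prediction error, default) or
#'   `"signed"` (mean bias).
#' @return object of class `validation_report`: list with `scope`, `r2`,
#'   `r2_ss`, `mpe`, `rmspe`, `relative_accuracy`, `origin_slope`, `n`.
#' @export
compute_metrics <- function(pred, obs, scope = c("fitting", "cv"),
                            mpe = c("absolute", "signed")) {
  scope <- match.arg(scope)
  mpe <- match.arg(mpe)
  stopifnot(length(pred) == length(obs), length(obs) >= 2L)
  if (anyNA(pred) || anyNA(obs)) stop("pred/obs must not contain NA")
  if (stats::sd(obs) < 1e-12) stop("observations have zero variance")
  err <- pred - obs
  rmspe <- sqrt(mean(err^2))
  structure(list(
    scope = scope,
    r2 = stats::cor(pred, obs)^2,
    r2_ss = 1 - sum(err^2) / sum((obs - mean(obs))^2),
    mpe = if (mpe == "absolute") mean(abs(err)) else mean(err),
    rmspe = rmspe,
    relative_accuracy = 100 * (1 - rmspe / mean(obs)),
    origin_slope = sum(pred * obs) / sum(obs^2),
    n = length(obs)
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Validation (%s, n = %d): R2 = %.3f, MPE = %.2f, RMSPE = %.2f ug/m3, ",
    x$scope, x$n, x$r2, x$mpe, x$rmspe))
  cat(sprintf("relative accuracy = %.1f%%, origin slope = %.3f\n",
              x$relative_accuracy, x$origin_slope))
  invisible(x)
}

#' Random record-level k-fold partition
#'
#' Fold sizes differ by at most one; deterministic given the seed.
#'
#' @param n number of records.
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed.
#' @return integer vector of fold labels in `1..k`.
#' @export
cv_folds <- function(n, k = 10L, seed = 1L) {
  stopifnot(k >= 2L, n >= k)
  set.seed(seed)
  sample(rep(seq_len(k), length.out = n))
}

#' 10-fold cross-validation of the two-stage pipeline
#'
#' Randomly partitions the analysis table into `k` record-level folds.  For
#' each fold, refits stage 1 (with the spec's variable set held fixed) and
#' the monthly stage-2 GWR on the remaining records, then predicts the
#' held-out records: stage-1-only and, if `two_stage`, with the GWR
#' residual correction (targets are the held-out sites; flagged or
#' under-populated months fall back to stage 1 and are counted).  Metrics
#' are computed on the pooled held-out predictions.
#'
#' @param table analysis table.
#' @param stage1 a [stage1_spec()] (post-selection).
#' @param gwr a [gwr_spec()].
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @param bandwidth numeric GWR bandwidth; if `NULL` and the spec says
#'   `"auto"`, selected once from the full-data stage-1 residuals.
#' @param two_stage also compute the stage-2-corrected predictions.
#' @return list with `report` (pooled two-stage metrics, or stage-1 metrics
#'   when `two_stage = FALSE`), `report_stage1` (pooled stage-1-only
#'   metrics), `per_fold` (data.frame of per-fold RMSPE), `predictions`
#'   (record-level pooled predictions), `n_fallback`, `bandwidth`, `folds`.
#' @export
kfold_cv <- function(table, stage1 = stage1_spec(), gwr = gwr_spec(),
                     k = 10L, seed = 1L, bandwidth = NULL,
                     two_stage = TRUE) {
  stopifnot(nrow(table) >= k)
  if (two_stage && is.null(bandwidth)) {
    if (is.numeric(gwr$bandwidth)) {
      bandwidth <- gwr$bandwidth
    } else {
      full_fit <- suppressWarnings(fit_stage1(table, stage1))
      rdf <- stage1_residuals(full_fit, table)
      bandwidth <- as.numeric(suppressWarnings(
        select_bandwidth(rdf, gwr)))
    }
  }
  folds <- cv_folds(nrow(table), k = k, seed = seed)

  pred1 <- pred2 <- rep(NA_real_, nrow(table))
  prov <- rep(NA_character_, nrow(table))
  for (f in seq_len(k)) {
    test <- folds == f
    train <- table[!test, , drop = FALSE]
    fit1 <- suppressWarnings(suppressMessages(fit_stage1(train, stage1)))
    p1 <- as.numeric(predict_stage1(fit1, table[test, , drop = FALSE]))
    pred1[test] <- p1
    if (!two_stage) next
    rdf <- stage1_residuals(fit1, train)
    targets <- unique(data.frame(loc_id = table$site_id[test],
                                 x = table$x[test], y = table$y[test]))
    s2 <- suppressWarnings(
      fit_stage2(rdf, targets, gwr, bandwidth = bandwidth))
    p1df <- data.frame(loc_id = table$site_id[test],
                       date = table$date[test],
                       aod = table$aod[test], pred1 = p1)
    out <- predict_stage2(p1df, s2)
    # predict_stage2 preserves row order for rows with non-missing AOD
    pred2[test] <- out$pred
    prov[test] <- out$provenance
  }

  obs <- table$pm25
  report_stage1 <- compute_metrics(pred1, obs, scope = "cv")
  if (two_stage) {
    report <- compute_metrics(pred2, obs, scope = "cv")
  } else {
    report <- report_stage1
    pred2 <- pred1
  }
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f) {
    i <- folds == f
    data.frame(fold = f, n = sum(i),
               rmspe = sqrt(mean((pred2[i] - obs[i])^2)))
  }))
  list(report = report, report_stage1 = report_stage1, per_fold = per_fold,
       predictions = data.frame(site_id = table$site_id, date = table$date,
                                obs = obs, pred = pred2, pred_stage1 = pred1,
                                fold = folds),
       n_fallback = sum(prov == "stage1_only", na.rm = TRUE),
       bandwidth = bandwidth, folds = folds)
}
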