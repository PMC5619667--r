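MET_FIELDS <- c("rh", "blh", "u_wind", "v_wind", "wind_speed")

#' Specification of the stage-1 mixed-effects model
#'
#' The stage-1 model regresses daily PM2.5 on AOD, meteorology and static
#' land-use covariates with fixed effects for every predictor and
#' day-specific random intercept and slopes.  Random slopes are restricted
#' to AOD and meteorological fields: only time-varying predictors can carry
#' a day-varying coefficient.
#'
#' @param fixed ordered character vector of fixed-effect predictors
#'   (columns of the analysis table).
#' @param random predictors with day-level random slopes, a subset of
#'   `"aod"` and the meteorology fields; the random intercept is always
#'   included.
#' @param estimation `"REML"` (default) or `"ML"`.
#' @param alpha_retain significance level for backward elimination in
#'   [select_variables()].
#' @return object of class `stage1_spec`.
#' @export
stage1_spec <- function(fixed = c("aod", MET_FIELDS, "elevation",
                                  "road_length", "forest_cover",
                                  "point_emissions"),
                        random = c("aod", "rh"),
                        estimation = c("REML", "ML"),
                        alpha_retain = 0.05) {
  estimation <- match.arg(estimation)
  if (!"aod" %in% fixed) stop("fixed terms must include aod")
  allowed <- c("aod", MET_FIELDS)
  if (!all(random %in% allowed)) {
    stop("random slopes are only allowed for AOD and meteorological fields: ",
         paste(setdiff(random, allowed), collapse = ", "))
  }
  if (!all(random %in% fixed)) {
    stop("random terms must be a subset of the fixed terms")
  }
  stopifnot(alpha_retain > 0, alpha_retain < 1)
  structure(list(fixed = fixed, random = random, estimation = estimation,
                 alpha_retain = alpha_retain),
            class = "stage1_spec")
}

# Random-slope covariates enter the random part as anomalies about their
# sample mean (columns "<term>__c"): the day intercept is then the day's
# deviation at typical conditions, which keeps Psi well-conditioned and
# its intercept entry interpretable.
stage1_formula <- function(spec, centered = TRUE) {
  rterms <- if (length(spec$random) == 0) {
    character(0)
  } else if (centered) {
    paste0(spec$random, "__c")
  } else {
    spec$random
  }
  ran <- if (length(rterms) > 0) {
    paste0("(1 + ", paste(rterms, collapse = " + "), " | date)")
  } else {
    "(1 | date)"
  }
  stats::reformulate(c(spec$fixed, ran), response = "pm25")
}

# Assemble the random-effect covariance for grouping factor `date` from a
# lme4 VarCorr object, in the canonical order (Intercept, spec$random).
# A diagonal (||) refit contributes one block per term.
extract_psi <- function(fit, spec) {
  vc <- lme4::VarCorr(fit)
  order_names <- c("(Intercept)",
                   if (length(spec$random)) paste0(spec$random, "__c"))
  psi <- matrix(0, length(order_names), length(order_names),
                dimnames = list(order_names, order_names))
  for (block in vc) {
    b <- as.matrix(block)[, , drop = FALSE]
    nm <- rownames(b)
    psi[nm, nm] <- psi[nm, nm] + b
  }
  psi
}

#' Fit the stage-1 linear mixed-effects model
#'
#' Fits `pm25 ~ fixed terms + (1 + random terms | date)` by REML (or ML)
#' with an unstructured day-level covariance Psi, and extracts fixed
#' effects with standard errors, the BLUPs of every observed day's random
#' effect vector, Psi, the residual variance and the log-likelihood.
#' Random slopes act on covariate anomalies (covariate minus its sample
#' mean, stored in the fit and reused at prediction time), which keeps
#' the day intercept interpretable and Psi well-conditioned.
#'
#' If the unstructured fit is singular, the model is refit with a diagonal
#' Psi (independent random intercept and slopes) and the fit is marked
#' `diagonal_fallback`.  A table containing a single day is fit by ordinary
#' least squares with the day's random effect pinned at zero (fixed and
#' random intercepts are not separately identifiable from one day) and
#' marked `single_day`.
#'
#' @param table analysis table from [build_analysis_table()].
#' @param spec a [stage1_spec()].
#' @return object of class `stage1_fit` with elements `fixed`, `se`,
#'   `vcov`, `random` (per-day BLUPs), `psi`, `sigma2`, `loglik`, `n_days`,
#'   `n_obs`, `spec`, `converged`, `diagonal_fallback`, `single_day`.
#' @export
fit_stage1 <- function(table, spec = stage1_spec()) {
  stopifnot(is.data.frame(table), nrow(table) > 0,
            inherits(spec, "stage1_spec"))
  missing_cols <- setdiff(c("pm25", "date", spec$fixed), names(table))
  if (length(missing_cols) > 0) {
    stop("analysis table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  days <- unique(as.character(table$date))

  centers <- vapply(spec$random, function(r) mean(table[[r]]), numeric(1))

  if (length(days) == 1L) {
    message("single day of data: fitting OLS with the day's random effect ",
            "pinned at zero")
    ols <- stats::lm(stats::reformulate(spec$fixed, "pm25"), data = table)
    q <- 1L + length(spec$random)
    re_names <- c("(Intercept)", spec$random)
    random <- data.frame(date = days, matrix(0, 1L, q),
                         stringsAsFactors = FALSE)
    names(random) <- c("date", re_names)
    fit <- list(
      fixed = stats::coef(ols),
      se = sqrt(diag(stats::vcov(ols))),
      vcov = stats::vcov(ols),
      random = random,
      centers = centers,
      psi = matrix(0, q, q, dimnames = list(re_names, re_names)),
      sigma2 = summary(ols)$sigma^2,
      loglik = as.numeric(stats::logLik(ols)),
      n_days = 1L, n_obs = nrow(table), spec = spec,
      converged = TRUE, diagonal_fallback = FALSE, single_day = TRUE
    )
    return(structure(fit, class = "stage1_fit"))
  }

  dat <- table
  dat$date <- factor(as.character(dat$date))
  for (r in spec$random) dat[[paste0(r, "__c")]] <- dat[[r]] - centers[[r]]
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore")
  reml <- spec$estimation == "REML"
  m <- lme4::lmer(stage1_formula(spec), data = dat, REML = reml,
                  control = ctrl)
  conv_code <- m@optinfo$conv$opt
  if (!is.null(conv_code) && conv_code != 0) {
    stop("stage-1 model did not converge (optimizer code ", conv_code, "): ",
         paste(unlist(m@optinfo$conv$lme4$messages), collapse = "; "))
  }
  diagonal_fallback <- FALSE
  if (lme4::isSingular(m, tol = 1e-5) && length(spec$random) > 0) {
    warning("singular unstructured Psi; refitting with diagonal Psi")
    f_diag <- stats::as.formula(
      paste("pm25 ~", paste(spec$fixed, collapse = " + "),
            "+ (1 +", paste(paste0(spec$random, "__c"), collapse = " + "),
            "|| date)")
    )
    m <- lme4::lmer(f_diag, data = dat, REML = reml, control = ctrl)
    diagonal_fallback <- TRUE
  }

  # lme4 returns one data.frame per random term; with `||` several blocks
  # share the grouping factor `date` -- bind their columns (rows align on
  # the factor levels).
  re_all <- lme4::ranef(m)
  blocks <- re_all[names(re_all) == "date"]
  re <- blocks[[1L]]
  if (length(blocks) > 1L) {
    for (b in blocks[-1L]) re <- cbind(re, b[rownames(re), , drop = FALSE])
  }
  re_cols <- c("(Intercept)",
               if (length(spec$random)) paste0(spec$random, "__c"))
  re <- re[, re_cols, drop = FALSE]
  re_names <- c("(Intercept)", spec$random)
  random <- data.frame(date = rownames(re), re, stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(random) <- c("date", re_names)
  rownames(random) <- NULL

  psi <- extract_psi(m, spec)
  dimnames(psi) <- list(re_names, re_names)

  structure(list(
    fixed = lme4::fixef(m),
    se = sqrt(diag(as.matrix(stats::vcov(m)))),
    vcov = as.matrix(stats::vcov(m)),
    random = random,
    centers = centers,
    psi = psi,
    sigma2 = stats::sigma(m)^2,
    loglik = as.numeric(stats::logLik(m)),
    n_days = length(days), n_obs = nrow(table), spec = spec,
    converged = TRUE, diagonal_fallback = diagonal_fallback,
    single_day = FALSE
  ), class = "stage1_fit")
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat("Stage-1 linear mixed-effects fit (day-specific random effects)\n")
  cat(sprintf("  %d observations over %d days; sigma2 = %.3f; logLik = %.1f\n",
              x$n_obs, x$n_days, x$sigma2, x$loglik))
  if (x$diagonal_fallback) cat("  (diagonal-Psi fallback)\n")
  if (x$single_day) cat("  (single-day OLS reduction)\n")
  coefs <- data.frame(estimate = x$fixed, se = x$se,
                      z = x$fixed / x$se)
  print(round(coefs, 4))
  invisible(x)
}

#' Predict PM2.5 from a stage-1 fit
#'
#' Computes the fixed-effect linear predictor and adds the fitted day's
#' random-effect contribution.  Dates not present in the fit get zero
#' random effects (fixed-effects-only prediction); which rows those were is
#' recorded in the `"fixed_only"` attribute.
#'
#' @param fit a `stage1_fit`.
#' @param newdata data.frame with a `date` column and all retained
#'   predictors.
#' @return numeric vector of predictions with attribute `fixed_only`
#'   (logical per row).
#' @export
predict_stage1 <- function(fit, newdata) {
  stopifnot(inherits(fit, "stage1_fit"))
  spec <- fit$spec
  missing_cols <- setdiff(c("date", spec$fixed), names(newdata))
  if (length(missing_cols) > 0) {
    stop("newdata lacks predictors: ", paste(missing_cols, collapse = ", "))
  }
  # coefficients absent from the fit (dropped for rank deficiency, e.g. a
  # predictor constant in the fitting data) contribute zero
  X <- stats::model.matrix(stats::reformulate(spec$fixed), newdata)
  use <- intersect(colnames(X), names(fit$fixed))
  pred <- unname(drop(X[, use, drop = FALSE] %*% fit$fixed[use]))

  idx <- match(as.character(newdata$date), fit$random$date)
  fixed_only <- is.na(idx)
  if (any(!fixed_only)) {
    re_names <- c("(Intercept)", spec$random)
    B <- as.matrix(fit$random[, re_names, drop = FALSE])
    Zs <- as.matrix(newdata[, spec$random, drop = FALSE])
    if (length(spec$random) > 0) {
      Zs <- sweep(Zs, 2L, fit$centers[spec$random], "-")
    }
    Z <- cbind(`(Intercept)` = 1, Zs)
    rows <- which(!fixed_only)
    pred[rows] <- pred[rows] +
      rowSums(Z[rows, , drop = FALSE] * B[idx[rows], , drop = FALSE])
  }
  attr(pred, "fixed_only") <- fixed_only
  pred
}

#' Stage-1 residuals at observed site-days
#'
#' @param fit a `stage1_fit`.
#' @param table the analysis table the fit was (or would be) computed on.
#' @return the table with `pred1` and `resid` columns appended.
#' @export
stage1_residuals <- function(fit, table) {
  p <- predict_stage1(fit, table)
  table$pred1 <- as.numeric(p)
  table$resid <- table$pm25 - table$pred1
  table
}

#' Backward elimination of non-significant fixed effects
#'
#' Iteratively refits the stage-1 model, dropping the least-significant
#' fixed term whose Wald-z p-value is at or above `alpha_retain`, until all
#' retained terms are significant.  The intercept and AOD are protected and
#' never dropped.  Random slopes follow their fixed terms: a meteorology
#' field removed from the fixed part is also removed from the random part.
#'
#' @param table analysis table.
#' @param spec the full candidate [stage1_spec()].
#' @param quiet suppress progress messages.
#' @return the reduced `stage1_spec`, with attribute `"eliminated"` (a
#'   data.frame of dropped terms and their p-values at removal).
#' @export
select_variables <- function(table, spec = stage1_spec(), quiet = TRUE) {
  stopifnot(inherits(spec, "stage1_spec"))
  eliminated <- data.frame(term = character(), p_value = numeric())
  repeat {
    fit <- suppressWarnings(suppressMessages(fit_stage1(table, spec)))
    z <- fit$fixed / fit$se
    p <- 2 * stats::pnorm(-abs(z))
    candidates <- setdiff(names(p), c("(Intercept)", "aod"))
    if (length(candidates) == 0) break
    pc <- p[candidates]
    worst <- names(pc)[which.max(pc)]
    if (pc[worst] < spec$alpha_retain) break
    if (!quiet) message("dropping ", worst,
                        sprintf(" (p = %.3f)", pc[worst]))
    eliminated <- rbind(eliminated,
                        data.frame(term = worst, p_value = unname(pc[worst])))
    spec <- stage1_spec(fixed = setdiff(spec$fixed, worst),
                        random = setdiff(spec$random, worst),
                        estimation = spec$estimation,
                        alpha_retain = spec$alpha_retain)
  }
  attr(spec, "eliminated") <- eliminated
  spec
}
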