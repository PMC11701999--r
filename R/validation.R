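#' Area under the ROC curve
#'
#' Mann-Whitney formulation with midrank tie handling (tied
#' prediction pairs count one half), which equals the trapezoidal area
#' under the empirical ROC curve.
#'
#' @param predictions numeric risk scores or probabilities.
#' @param outcomes 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(predictions, outcomes) {
  y <- as.numeric(outcomes)
  if (length(y) != length(predictions)) stop("length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both outcome classes")
  r <- rank(predictions, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and 0/1 outcome.
#'
#' @inheritParams auc
#' @return Brier score in `[0, 1]`; lower is better.
#' @export
brier <- function(predictions, outcomes) {
  if (any(predictions < 0 | predictions > 1))
    stop("predictions must be probabilities in [0, 1]")
  mean((predictions - as.numeric(outcomes))^2)
}

clip_probs <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)

#' Calibration slope and intercept
#'
#' Logistic recalibration of the outcomes on the logit of the predicted
#' probabilities: the slope is the coefficient of a fit on
#' `logit(prediction)`; the intercept (calibration-in-the-large) is the
#' intercept of a fit with `logit(prediction)` held as a fixed offset.
#' A perfectly calibrated model has slope 1 and intercept 0 — in
#' particular any ML logistic fit evaluated on its own training data.
#'
#' @inheritParams auc
#' @return named numeric `c(slope, intercept)`.
#' @export
calibration_slope_intercept <- function(predictions, outcomes) {
  lp <- stats::qlogis(clip_probs(predictions))
  if (stats::sd(lp) < 1e-12)
    stop("calibration slope undefined: predictions have zero variance on the logit scale")
  y <- as.numeric(outcomes)
  ctl <- stats::glm.control(epsilon = 1e-12, maxit = 100)
  slope_fit <- suppressWarnings(
    stats::glm.fit(cbind(1, lp), y, family = stats::binomial(),
                   control = ctl))
  int_fit <- suppressWarnings(
    stats::glm.fit(matrix(1, length(y)), y, family = stats::binomial(),
                   offset = lp, control = ctl))
  c(slope = unname(slope_fit$coefficients[2]),
    intercept = unname(int_fit$coefficients[1]))
}

#' Loess calibration curve
#'
#' Local-linear (degree 1, tricube-weighted) smooth of the 0/1 outcomes on
#' the predicted probabilities, evaluated at each patient's prediction and
#' clipped to `[0, 1]`: the smoothed observed event proportion as a
#' function of predicted risk.
#'
#' @inheritParams auc
#' @param span loess span, the fraction of nearest neighbors in each local
#'   fit, in (0, 1].
#' @return numeric vector of smoothed observed proportions, one per
#'   patient, aligned with `predictions`.
#' @export
loess_calibration_curve <- function(predictions, outcomes, span = 0.75) {
  if (length(span) != 1L || !is.finite(span) || span <= 0 || span > 1)
    stop("`span` must lie in (0, 1]")
  if (length(predictions) < 10L)
    stop("loess calibration needs at least 10 observations")
  y <- as.numeric(outcomes)
  fit <- suppressWarnings(
    stats::loess(y ~ p, data = data.frame(p = predictions, y = y),
                 span = span, degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  out <- stats::predict(fit, newdata = data.frame(p = predictions))
  unname(pmin(pmax(out, 0), 1))
}

#' Integrated calibration index (ICI)
#'
#' Mean absolute difference between the loess calibration curve and the
#' line of perfect calibration over the predicted probabilities:
#' `mean(|curve(p_i) - p_i|)`.  Lower is better; 0 is perfect.
#'
#' @inheritParams loess_calibration_curve
#' @return non-negative scalar.
#' @export
ici <- function(predictions, outcomes, span = 0.75) {
  curve <- loess_calibration_curve(predictions, outcomes, span)
  mean(abs(curve - predictions))
}

measure_all <- function(predictions, outcomes, span = 0.75) {
  cal <- calibration_slope_intercept(predictions, outcomes)
  c(AUC = auc(predictions, outcomes),
    ICI = ici(predictions, outcomes, span),
    calibration_intercept = unname(cal["intercept"]),
    calibration_slope = unname(cal["slope"]),
    Brier = brier(predictions, outcomes))
}

#' Harrell optimism-corrected performance
#'
#' Internal validation by the optimism bootstrap.  `procedure` is the full
#' modeling procedure as a callable contract: a function
#' `function(features, outcomes)` returning a list with `predict`, a
#' function mapping a feature data.frame to predicted probabilities, and
#' optionally `degenerate = TRUE` when the resample yielded no usable
#' model (intercept-only or non-converged); degenerate resamples are
#' excluded and counted.  For each resample the procedure is re-run, its
#' apparent performance on the resample and test performance on the
#' original data are measured, and their difference is the optimism.
#' Corrected value = apparent - mean(optimism); 95% CI = percentile
#' interval of `apparent - optimism_b` (ICI clipped at 0).
#'
#' @param features data.frame of predictor columns.
#' @param outcomes 0/1 vector.
#' @param procedure the modeling procedure (see above and
#'   [ntcp_procedure()]).
#' @param B number of bootstrap resamples (default 1000); `B = 0` reports
#'   apparent performance only.
#' @param seed optional integer seed.
#' @param span loess span for the ICI.
#' @return A `"performance_report"`: data.frame `table` with one row per
#'   measure (apparent, optimism, corrected, CI bounds) plus bootstrap
#'   bookkeeping.
#' @export
optimism_correct <- function(features, outcomes, procedure, B = 1000,
                             seed = NULL, span = 0.75) {
  features <- as.data.frame(features)
  if (!is.null(seed)) set.seed(seed)
  n <- length(outcomes)
  full <- procedure(features, outcomes)
  if (isTRUE(full$degenerate))
    stop("modeling procedure is degenerate on the full data")
  apparent <- measure_all(full$predict(features), outcomes, span)
  measures <- names(apparent)
  opt <- matrix(NA_real_, nrow = B, ncol = length(measures),
                dimnames = list(NULL, measures))
  n_degenerate <- 0L
  if (B > 0) {
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      yb <- outcomes[idx]
      if (all(yb == 0) || all(yb == 1)) { n_degenerate <- n_degenerate + 1L; next }
      fb <- features[idx, , drop = FALSE]
      mb <- tryCatch(procedure(fb, yb), error = function(e) NULL)
      if (is.null(mb) || isTRUE(mb$degenerate)) {
        n_degenerate <- n_degenerate + 1L; next
      }
      app_b <- tryCatch(measure_all(mb$predict(fb), yb, span),
                        error = function(e) NULL)
      test_b <- tryCatch(measure_all(mb$predict(features), outcomes, span),
                         error = function(e) NULL)
      if (is.null(app_b) || is.null(test_b)) {
        n_degenerate <- n_degenerate + 1L; next
      }
      opt[b, ] <- app_b - test_b
    }
    if (n_degenerate > B / 2)
      stop("more than half of the bootstrap resamples were degenerate")
  }
  used <- stats::complete.cases(opt)
  tab <- data.frame(measure = measures, apparent = unname(apparent),
                    optimism = NA_real_, corrected = NA_real_,
                    ci_lower = NA_real_, ci_upper = NA_real_,
                    stringsAsFactors = FALSE)
  if (B > 0 && any(used)) {
    mo <- colMeans(opt[used, , drop = FALSE])
    tab$optimism <- unname(mo)
    tab$corrected <- tab$apparent - tab$optimism
    dist <- sweep(-opt[used, , drop = FALSE], 2, apparent, `+`)
    dist[, "ICI"] <- pmax(dist[, "ICI"], 0)
    tab$ci_lower <- apply(dist, 2, stats::quantile, probs = 0.025)
    tab$ci_upper <- apply(dist, 2, stats::quantile, probs = 0.975)
    tab$corrected[tab$measure == "ICI"] <-
      max(tab$corrected[tab$measure == "ICI"], 0)
  }
  structure(list(table = tab, n_bootstraps = sum(used),
                 n_degenerate = n_degenerate, span = span, n = n),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("Performance (n = %d, %d usable bootstraps, %d degenerate)\n",
              x$n, x$n_bootstraps, x$n_degenerate))
  tab <- x$table
  for (i in seq_len(nrow(tab))) {
    if (is.na(tab$corrected[i]))
      cat(sprintf("  %-22s apparent %.4f\n", tab$measure[i], tab$apparent[i]))
    else
      cat(sprintf("  %-22s apparent %.4f   corrected %.4f (%.4f - %.4f)\n",
                  tab$measure[i], tab$apparent[i], tab$corrected[i],
                  tab$ci_lower[i], tab$ci_upper[i]))
  }
  invisible(x)
}

#' Modeling-procedure factory for internal validation
#'
#' Wraps the package's development pipeline — backward elimination,
#' optionally followed by bootstrap uniform shrinkage with intercept
#' re-estimation — into the callable contract [optimism_correct()]
#' expects.  With `nested_shrinkage = TRUE` the shrinkage bootstrap
#' (`B_shrink` inner resamples) is replayed inside every outer resample,
#' replicating the full procedure; turning it off validates the unshrunk
#' selection-only pipeline at a fraction of the cost.
#'
#' @param spec optional [model_spec()] carried into the fitted models.
#' @param nested_shrinkage replay shrinkage inside each resample.
#' @param B_shrink inner bootstrap size when `nested_shrinkage`.
#' @param reselect replay backward elimination inside shrinkage bootstraps.
#' @return a `function(features, outcomes)` returning
#'   `list(model, predict, degenerate)`.
#' @export
ntcp_procedure <- function(spec = NULL, nested_shrinkage = TRUE,
                           B_shrink = 100, reselect = TRUE) {
  function(features, outcomes) {
    m <- backward_eliminate(features, outcomes, spec)
    if (m$intercept_only || !m$converged)
      return(list(model = m, degenerate = TRUE,
                  predict = function(f) rep(mean(outcomes), nrow(f))))
    if (nested_shrinkage) {
      sh <- tryCatch(
        estimate_shrinkage(features, outcomes, spec, B = B_shrink,
                           reselect = reselect),
        error = function(e) NULL)
      if (is.null(sh))
        return(list(model = m, degenerate = TRUE,
                    predict = function(f) rep(mean(outcomes), nrow(f))))
      m <- apply_shrinkage(m, sh$s, features, outcomes)
    }
    list(model = m, degenerate = FALSE,
         predict = function(f) predict_ntcp(m, f))
  }
}
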