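#' Model specification for one NTCP candidate set
#'
#' One candidate predictor set: exactly one dosimetric predictor (the
#' design fits five separate models A-E, one per dose parameter) plus
#' clinical candidates.  `HYPOTREAT` is the hypofractionation-arm
#' indicator; when it survives backward elimination the dose parameter did
#' not describe the dose-response independently of fractionation schedule.
#'
#' @param dose_metric a [dose_metric()].
#' @param clinical ordered subset of `c("ABD_SURG", "HYPOTREAT")`.
#' @param alpha_beta assumed alpha/beta ratio in Gy for the BED transform.
#' @param label optional model label (e.g. `"B"`).
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec(dose_metric("EUD", 0.1), label = "B")
#' @export
model_spec <- function(dose_metric,
                       clinical = c("ABD_SURG", "HYPOTREAT"),
                       alpha_beta = 3, label = NULL) {
  stopifnot(inherits(dose_metric, "dose_metric"))
  if (!all(clinical %in% c("ABD_SURG", "HYPOTREAT")))
    stop("clinical candidates must be a subset of ABD_SURG, HYPOTREAT")
  check_alpha_beta(alpha_beta)
  structure(list(dose_metric = dose_metric, clinical = clinical,
                 alpha_beta = alpha_beta, label = label),
            class = "model_spec")
}

#' Assemble the modeling dataset from a scored cohort
#'
#' Computes the spec's dosimetric predictor for every patient (BED axis by
#' default), attaches the clinical candidates and scores the endpoint.
#' Candidate column order — dose metric first, then `ABD_SURG`, then
#' `HYPOTREAT` — is the elimination tie-break order.
#'
#' @param cohort an [ntcp_cohort()]; patients must carry DVHs.
#' @param spec a [model_spec()].
#' @param dose_scale `"bed"` (default) or `"physical"` (sensitivity use).
#' @param horizon_months endpoint scoring horizon.
#' @return list with `features` (data.frame of candidate columns),
#'   `outcomes` (0/1 integer vector) and `patient_id`.
#' @export
ntcp_data <- function(cohort, spec, dose_scale = c("bed", "physical"),
                      horizon_months = 60) {
  stopifnot(inherits(cohort, "ntcp_cohort"), inherits(spec, "model_spec"))
  dose_scale <- match.arg(dose_scale)
  if (any(vapply(cohort$patients, function(p) is.null(p$dvh), logical(1))))
    stop("cohort contains patients without DVHs; run eligibility_filter()")
  dose <- vapply(cohort$patients, function(p)
    compute_metric(p$dvh, spec$dose_metric, p$scheme,
                   alpha_beta = spec$alpha_beta, dose_scale = dose_scale),
    numeric(1))
  features <- data.frame(dose = dose)
  names(features) <- format(spec$dose_metric)
  if ("ABD_SURG" %in% spec$clinical)
    features$ABD_SURG <- as.integer(vapply(cohort$patients, `[[`, logical(1),
                                           "abd_surg"))
  if ("HYPOTREAT" %in% spec$clinical)
    features$HYPOTREAT <- as.integer(vapply(cohort$patients, function(p)
      p$arm == "HF", logical(1)))
  outcomes <- vapply(cohort$patients, function(p)
    as.integer(score_g2_lrb(p, horizon_months)), integer(1))
  list(features = features, outcomes = outcomes,
       patient_id = vapply(cohort$patients, `[[`, character(1), "patient_id"))
}

#' Maximum-likelihood logistic fit
#'
#' Binomial GLM fit (IRLS via [stats::glm.fit()]) of a 0/1 outcome on a
#' set of predictor columns plus an intercept, returning coefficients,
#' log-likelihood, `AIC = 2k - 2 logLik`, Wald standard errors and
#' convergence diagnostics.  Complete separation is flagged (not errored)
#' so bootstrap callers can discard the degenerate resample: the fit is
#' marked non-converged when IRLS fails, a coefficient is undefined, or a
#' standardized slope magnitude exceeds 20.
#'
#' @param features data.frame or matrix of predictors (no intercept
#'   column), possibly zero columns for an intercept-only model.
#' @param outcomes 0/1 vector; both classes must be present.
#' @return list with `coefficients` (named, `(Intercept)` first), `loglik`,
#'   `aic`, `se`, `p_values` (Wald), `converged`, `n`.
#' @export
fit_logistic <- function(features, outcomes) {
  y <- as.numeric(outcomes)
  if (any(!y %in% c(0, 1))) stop("outcomes must be 0/1")
  if (all(y == 1) || all(y == 0))
    stop("both outcome classes must be present")
  X <- as.matrix(as.data.frame(features))
  if (ncol(X) == 0L)
    X <- matrix(numeric(0), nrow = length(y), ncol = 0)
  if (nrow(X) != length(y))
    stop("features and outcomes have different lengths")
  if (ncol(X) > 0 && is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  Xi <- cbind(`(Intercept)` = rep(1, length(y)), X)
  fit <- suppressWarnings(
    stats::glm.fit(Xi, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100))
  )
  beta <- fit$coefficients
  k <- ncol(Xi)
  ok <- fit$converged && all(is.finite(beta))
  separated <- FALSE
  if (ok && ncol(X) > 0) {
    sdx <- apply(X, 2, stats::sd)
    separated <- any(abs(beta[-1]) * ifelse(sdx > 0, sdx, 1) > 20)
  }
  loglik <- if (all(is.finite(beta))) {
    p <- stats::plogis(drop(Xi %*% beta))
    sum(y * log(pmax(p, 1e-300)) + (1 - y) * log(pmax(1 - p, 1e-300)))
  } else NA_real_
  se <- p_values <- rep(NA_real_, k)
  if (ok) {
    p <- stats::plogis(drop(Xi %*% beta))
    w <- p * (1 - p)
    info <- crossprod(Xi, Xi * w)
    cov <- tryCatch(solve(info), error = function(e) NULL)
    if (!is.null(cov)) {
      se <- sqrt(diag(cov))
      z <- beta / se
      p_values <- 2 * stats::pnorm(-abs(z))
    }
  }
  names(se) <- names(p_values) <- colnames(Xi)
  list(coefficients = beta, loglik = loglik,
       aic = 2 * k - 2 * loglik, se = se, p_values = p_values,
       converged = ok && !separated, n = length(y))
}

new_ntcp_model <- function(spec, candidates, retained, fit,
                           shrinkage = NULL) {
  structure(
    list(spec = spec, candidates = candidates, retained = retained,
         coefficients = fit$coefficients, se = fit$se,
         p_values = fit$p_values, loglik = fit$loglik, aic = fit$aic,
         converged = fit$converged, n = fit$n,
         intercept_only = length(retained) == 0L,
         shrinkage = shrinkage),
    class = "ntcp_model"
  )
}

#' AIC backward elimination
#'
#' Starting from the full candidate model, repeatedly removes the
#' predictor whose removal most decreases the AIC, until no removal
#' decreases it.  The intercept is never removed.  Ties are broken by
#' removing the candidate listed later in the column order of `features`
#' (dose metric first, then ABD_SURG, then HYPOTREAT), so the dose metric
#' is maximally protected.  A model reduced to the intercept alone is
#' flagged `intercept_only`.
#'
#' @param features data.frame of candidate columns in protection order.
#' @param outcomes 0/1 vector.
#' @param spec optional [model_spec()] carried into the result.
#' @return An unshrunk `"ntcp_model"` with `retained`, `coefficients`
#'   (ML), Wald `se`/`p_values`, `loglik`, `aic`.
#' @export
backward_eliminate <- function(features, outcomes, spec = NULL) {
  features <- as.data.frame(features)
  candidates <- names(features)
  current <- candidates
  fit_cur <- fit_logistic(features[current], outcomes)
  repeat {
    if (length(current) == 0L) break
    drop_aic <- vapply(seq_along(current), function(j) {
      f <- fit_logistic(features[current[-j]], outcomes)
      if (is.finite(f$aic)) f$aic else Inf
    }, numeric(1))
    best <- min(drop_aic)
    cur_aic <- if (is.finite(fit_cur$aic)) fit_cur$aic else Inf
    if (!is.finite(best) || best >= cur_aic) break
    # ties: drop the later-listed candidate
    j <- max(which(drop_aic <= best + 1e-9))
    current <- current[-j]
    fit_cur <- fit_logistic(features[current], outcomes)
  }
  new_ntcp_model(spec, candidates, current, fit_cur)
}

#' Was the fractionation-schedule indicator retained?
#'
#' `TRUE` when `HYPOTREAT` survived elimination — the criterion by which a
#' BED-based dose parameter is judged not to describe the dose-response
#' independently of fractionation schedule (such models are disqualified).
#'
#' @param model an `"ntcp_model"`.
#' @export
hypotreat_retained <- function(model) {
  stopifnot(inherits(model, "ntcp_model"))
  "HYPOTREAT" %in% model$retained
}

#' Linear predictor of a fitted NTCP model
#'
#' @param model an `"ntcp_model"`.
#' @param features data.frame covering the retained predictor columns.
#' @return numeric linear predictor (log-odds scale).
#' @keywords internal
ntcp_linear_predictor <- function(model, features) {
  beta <- model$coefficients
  eta <- rep(beta[["(Intercept)"]], nrow(features))
  for (nm in model$retained) {
    if (!nm %in% names(features))
      stop("missing covariate column: ", nm)
    eta <- eta + beta[[nm]] * features[[nm]]
  }
  eta
}

#' Bootstrap uniform shrinkage factor
#'
#' Estimates the single multiplier applied to all slope coefficients to
#' counter overfitting.  For each of `B` bootstrap resamples (with
#' replacement, original size) the full modeling procedure — backward
#' elimination (when `reselect = TRUE`, the default) and ML refit — is
#' replayed; the bootstrap model's linear predictor is evaluated on the
#' original data and the calibration slope of the original outcomes on
#' that linear predictor is recorded.  The shrinkage factor `s` is the
#' mean slope over usable bootstraps.  Degenerate resamples (one outcome
#' class, non-convergence, intercept-only models) are excluded and
#' counted.
#'
#' @inheritParams backward_eliminate
#' @param B number of bootstrap samples (default 300).
#' @param reselect replay backward elimination inside each bootstrap.
#' @param .indices optional list of pre-chosen index vectors (testing
#'   hook; overrides resampling and `B`).
#' @return list with `s`, `slopes`, `n_used`, `n_degenerate`.
#' @export
estimate_shrinkage <- function(features, outcomes, spec = NULL, B = 300,
                               reselect = TRUE, .indices = NULL) {
  features <- as.data.frame(features)
  n <- length(outcomes)
  if (is.null(.indices)) {
    if (B < 1) stop("B must be >= 1")
    .indices <- replicate(B, sample.int(n, n, replace = TRUE),
                          simplify = FALSE)
  }
  base_model <- if (!reselect)
    backward_eliminate(features, outcomes, spec) else NULL
  slopes <- rep(NA_real_, length(.indices))
  for (b in seq_along(.indices)) {
    idx <- .indices[[b]]
    yb <- outcomes[idx]
    if (all(yb == 0) || all(yb == 1)) next
    fb <- features[idx, , drop = FALSE]
    mb <- if (reselect) {
      tryCatch(backward_eliminate(fb, yb, spec), error = function(e) NULL)
    } else {
      f <- tryCatch(fit_logistic(fb[base_model$retained], yb),
                    error = function(e) NULL)
      if (is.null(f)) NULL
      else new_ntcp_model(spec, base_model$candidates, base_model$retained, f)
    }
    if (is.null(mb) || !mb$converged || mb$intercept_only) next
    lp <- ntcp_linear_predictor(mb, features)
    if (stats::sd(lp) < 1e-12) next
    cal <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, lp), outcomes,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(cal) || !cal$converged) next
    slopes[b] <- cal$coefficients[2]
  }
  used <- !is.na(slopes)
  if (!any(used))
    stop("all bootstrap samples were degenerate; cannot estimate shrinkage")
  list(s = mean(slopes[used]), slopes = slopes[used],
       n_used = sum(used), n_degenerate = sum(!used))
}

#' Apply uniform shrinkage and re-estimate the intercept
#'
#' Multiplies every slope coefficient by the shrinkage factor `s`
#' (equivalently, final odds ratios are `OR^s`), then re-estimates the
#' intercept by maximum likelihood with the shrunk linear predictor held
#' as a fixed offset, so the mean predicted probability matches the
#' observed prevalence.
#'
#' @param model an unshrunk `"ntcp_model"`.
#' @param s shrinkage factor, > 0.
#' @param features,outcomes the original modeling data.
#' @return a final `"ntcp_model"` whose `shrinkage` field records `s`,
#'   the unshrunk coefficients and the re-estimated intercept.
#' @export
apply_shrinkage <- function(model, s, features, outcomes) {
  stopifnot(inherits(model, "ntcp_model"))
  if (length(s) != 1L || !is.finite(s) || s <= 0)
    stop("shrinkage factor `s` must be a single positive number")
  features <- as.data.frame(features)
  beta <- model$coefficients
  shrunk <- beta
  slopes <- setdiff(names(beta), "(Intercept)")
  shrunk[slopes] <- s * beta[slopes]
  offset <- rep(0, length(outcomes))
  for (nm in slopes) offset <- offset + shrunk[[nm]] * features[[nm]]
  refit <- suppressWarnings(
    stats::glm(outcomes ~ 1, family = stats::binomial(), offset = offset,
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  shrunk[["(Intercept)"]] <- unname(stats::coef(refit)[1])
  out <- model
  out$coefficients <- shrunk
  out$shrinkage <- list(s = s, unshrunk_coefficients = beta,
                        intercept_reestimated = shrunk[["(Intercept)"]])
  out
}

#' Fit a complete NTCP model
#'
#' The full development pipeline on a scored, eligible cohort: dosimetric
#' feature extraction, AIC backward elimination, bootstrap uniform
#' shrinkage (`B_shrink` resamples) and intercept re-estimation.
#'
#' @param cohort an [ntcp_cohort()].
#' @param spec a [model_spec()].
#' @param B_shrink bootstrap samples for the shrinkage factor.
#' @param seed optional integer seed for the bootstrap.
#' @param reselect replay elimination inside shrinkage bootstraps.
#' @param dose_scale passed to [ntcp_data()].
#' @return a final `"ntcp_model"`; its `unshrunk` field holds the model
#'   before shrinkage.
#' @export
fit_ntcp <- function(cohort, spec, B_shrink = 300, seed = NULL,
                     reselect = TRUE, dose_scale = "bed") {
  dat <- ntcp_data(cohort, spec, dose_scale = dose_scale)
  if (!is.null(seed)) set.seed(seed)
  unshrunk <- backward_eliminate(dat$features, dat$outcomes, spec)
  if (unshrunk$intercept_only) {
    unshrunk$unshrunk <- unshrunk
    return(unshrunk)
  }
  sh <- estimate_shrinkage(dat$features, dat$outcomes, spec, B = B_shrink,
                           reselect = reselect)
  final <- apply_shrinkage(unshrunk, sh$s, dat$features, dat$outcomes)
  final$shrinkage$n_used <- sh$n_used
  final$shrinkage$n_degenerate <- sh$n_degenerate
  final$unshrunk <- unshrunk
  final
}

#' @export
print.ntcp_model <- function(x, ...) {
  lbl <- if (!is.null(x$spec) && !is.null(x$spec$label))
    paste0(" ", x$spec$label) else ""
  cat(sprintf("NTCP logistic model%s (n = %d)\n", lbl, x$n))
  if (x$intercept_only) {
    cat("  intercept-only (all candidates eliminated)\n")
    return(invisible(x))
  }
  or <- exp(x$coefficients[x$retained])
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  cat(sprintf("  intercept: %.4f\n", x$coefficients[["(Intercept)"]]))
  for (nm in x$retained)
    cat(sprintf("  OR[%s] = %.3f\n", nm, or[[nm]]))
  if (!is.null(x$shrinkage))
    cat(sprintf("  uniform shrinkage s = %.3f (intercept re-estimated)\n",
                x$shrinkage$s))
  invisible(x)
}

#' Predicted complication probability
#'
#' Inverse-logit of the model's linear predictor.
#'
#' @param model an `"ntcp_model"`.
#' @param features data.frame covering the retained predictors.
#' @return probabilities in (0, 1).
#' @export
predict_ntcp <- function(model, features) {
  stopifnot(inherits(model, "ntcp_model"))
  stats::plogis(ntcp_linear_predictor(model, as.data.frame(features)))
}

#' @export
predict.ntcp_model <- function(object, newdata, ...) {
  predict_ntcp(object, newdata)
}

MODEL_JSON_VERSION <- "1.0"

#' Serialize / deserialize a fitted NTCP model as JSON
#'
#' Versioned plain-text representation of a fitted model: spec, assumed
#' alpha/beta, candidate and retained predictors, coefficients at full
#' double precision, shrinkage record and provenance.  Round-trips
#' exactly.
#'
#' @param model an `"ntcp_model"`.
#' @param path optional file path; when given the JSON is written there.
#' @return [serialize_model()] returns the JSON string (invisibly when
#'   `path` is given); [deserialize_model()] returns the `"ntcp_model"`.
#' @export
serialize_model <- function(model, path = NULL) {
  stopifnot(inherits(model, "ntcp_model"))
  doc <- list(
    format = "bedntcp-model", version = MODEL_JSON_VERSION,
    spec = if (is.null(model$spec)) NULL else list(
      metric_kind = model$spec$dose_metric$kind,
      metric_parameter = model$spec$dose_metric$parameter,
      clinical = as.list(model$spec$clinical),
      alpha_beta = model$spec$alpha_beta,
      label = model$spec$label),
    candidates = as.list(model$candidates),
    retained = as.list(model$retained),
    coefficients = as.list(model$coefficients),
    loglik = model$loglik, aic = model$aic, n = model$n,
    converged = model$converged,
    shrinkage = if (is.null(model$shrinkage)) NULL else list(
      s = model$shrinkage$s,
      unshrunk_coefficients = as.list(model$shrinkage$unshrunk_coefficients),
      intercept_reestimated = model$shrinkage$intercept_reestimated)
  )
  # 17 significant digits round-trip IEEE doubles exactly
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' @rdname serialize_model
#' @param json a JSON string or path to a JSON file.
#' @export
deserialize_model <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  doc <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyVector = TRUE)
  for (fld in c("format", "version", "coefficients", "retained",
                "candidates", "n"))
    if (is.null(doc[[fld]]))
      stop("model JSON schema violation at field: ", fld)
  if (!identical(doc$format, "bedntcp-model"))
    stop("not a bedntcp model document")
  spec <- NULL
  if (!is.null(doc$spec))
    spec <- model_spec(dose_metric(doc$spec$metric_kind,
                                   doc$spec$metric_parameter),
                       clinical = unlist(doc$spec$clinical),
                       alpha_beta = doc$spec$alpha_beta,
                       label = doc$spec$label)
  shrinkage <- NULL
  if (!is.null(doc$shrinkage))
    shrinkage <- list(
      s = doc$shrinkage$s,
      unshrunk_coefficients = unlist(doc$shrinkage$unshrunk_coefficients),
      intercept_reestimated = doc$shrinkage$intercept_reestimated)
  structure(
    list(spec = spec, candidates = unlist(doc$candidates),
         retained = if (length(doc$retained)) unlist(doc$retained)
                    else character(),
         coefficients = unlist(doc$coefficients), se = NULL, p_values = NULL,
         loglik = doc$loglik, aic = doc$aic, converged = doc$converged,
         n = doc$n, intercept_only = length(doc$retained) == 0L,
         shrinkage = shrinkage),
    class = "ntcp_model"
  )
}
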