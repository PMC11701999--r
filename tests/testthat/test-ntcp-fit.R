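test_that("logistic ML fit matches closed forms", {
  # intercept-only at 50% prevalence: intercept = logit(0.5) = 0
  f0 <- fit_logistic(data.frame(), c(rep(1, 5), rep(0, 5)))
  expect_equal(unname(f0$coefficients[1]), 0, tolerance = 1e-8)
  expect_equal(f0$aic, 2 - 2 * 10 * log(0.5), tolerance = 1e-8)

  # single binary covariate: coefficient = log odds ratio of the 2x2 table
  d <- two_by_two_data(10, 20, 5, 20)
  f <- fit_logistic(d["x"], d$y)
  expect_equal(unname(f$coefficients["x"]), log(3), tolerance = 1e-7)
  expect_true(f$converged)

  expect_error(fit_logistic(data.frame(x = 1:4), rep(1, 4)), "both outcome")
  expect_error(fit_logistic(data.frame(x = 1:4), c(0, 1, 2, 1)), "0/1")
})

test_that("complete separation is flagged, not errored", {
  x <- c(rep(0, 10), rep(1, 10))
  y <- x
  f <- fit_logistic(data.frame(x = x), y)
  expect_false(f$converged)
})

test_that("backward elimination drops null predictors and keeps real ones", {
  spec <- model_spec(dose_metric("EUD", 0.1))
  co <- generate_cohort(5000, seed = 2)
  dat <- ntcp_data(co, spec)

  # matched alpha/beta: the BED metric carries the arm difference
  m <- backward_eliminate(dat$features, dat$outcomes, spec)
  expect_true(format(spec$dose_metric) %in% m$retained)

  # elimination never increases AIC relative to the full model
  full <- fit_logistic(dat$features, dat$outcomes)
  expect_lte(m$aic, full$aic + 1e-9)

  # strong single candidate is retained
  set.seed(5)
  x <- rnorm(2000)
  y <- as.integer(runif(2000) < plogis(-1 + x))
  m1 <- backward_eliminate(data.frame(dose = x), y)
  expect_identical(m1$retained, "dose")

  # pure-noise candidates at modest n usually reduce to intercept only
  set.seed(6)
  noise <- data.frame(a = rnorm(3000), b = rnorm(3000))
  y0 <- as.integer(runif(3000) < 0.14)
  m0 <- backward_eliminate(noise, y0)
  expect_true(is.logical(m0$intercept_only))
  expect_true(length(m0$retained) <= 2)
})

test_that("elimination ties remove the later-listed candidate first", {
  # duplicated column: dropping either gives identical AIC; the later one
  # (lower protection) must go
  set.seed(7)
  x <- rnorm(500)
  y <- as.integer(runif(500) < plogis(-1 + 0.8 * x))
  feats <- data.frame(dose = x, HYPOTREAT = x)
  m <- backward_eliminate(feats, y)
  expect_identical(m$retained, "dose")
})

test_that("HYPOTREAT retention is read off the retained set", {
  spec <- model_spec(dose_metric("EUD", 0.1))
  co <- generate_cohort(600, seed = 3)
  dat <- ntcp_data(co, spec)
  m <- backward_eliminate(dat$features, dat$outcomes, spec)
  expect_identical(hypotreat_retained(m), "HYPOTREAT" %in% m$retained)
})

test_that("self-calibration gives shrinkage factor 1; overfitting gives < 1", {
  spec <- model_spec(dose_metric("EUD", 0.1))
  co <- generate_cohort(400, seed = 4)
  dat <- ntcp_data(co, spec)
  # bootstrap sample forced equal to the original: slope of a model on its
  # own training data is exactly 1
  n <- length(dat$outcomes)
  sh <- estimate_shrinkage(dat$features, dat$outcomes, spec,
                           .indices = list(seq_len(n)))
  expect_equal(sh$s, 1, tolerance = 1e-6)

  # small n, weak effects: shrinkage below 1
  set.seed(8)
  weak <- data.frame(a = rnorm(200), b = rnorm(200), c = rnorm(200))
  yw <- as.integer(runif(200) < plogis(-1.8 + 0.25 * weak$a))
  set.seed(9)
  shw <- estimate_shrinkage(weak, yw, B = 150)
  expect_lt(shw$s, 1)
})

test_that("large-sample strong-effect shrinkage approaches 1", {
  set.seed(10)
  n <- 20000
  x <- rnorm(n); z <- rbinom(n, 1, 0.3)
  y <- as.integer(runif(n) < plogis(-2 + 1 * x + 0.7 * z))
  set.seed(11)
  sh <- estimate_shrinkage(data.frame(dose = x, ABD_SURG = z), y, B = 40)
  expect_equal(sh$s, 1, tolerance = 0.02)
})

test_that("uniform shrinkage scales ORs as OR^s and recalibrates the intercept", {
  spec <- model_spec(dose_metric("EUD", 0.1))
  co <- generate_cohort(656, seed = 5)
  dat <- ntcp_data(co, spec)
  m <- backward_eliminate(dat$features, dat$outcomes, spec)
  s <- 0.9
  fin <- apply_shrinkage(m, s, dat$features, dat$outcomes)
  for (nm in m$retained) {
    expect_equal(fin$coefficients[[nm]], s * m$coefficients[[nm]])
    expect_equal(exp(fin$coefficients[[nm]]),
                 exp(m$coefficients[[nm]])^s)          # OR^s identity
  }
  # intercept re-estimation solves the score equation: mean prediction
  # equals prevalence
  p <- predict_ntcp(fin, dat$features)
  expect_equal(sum(p), sum(dat$outcomes), tolerance = 1e-6)

  # s = 1 leaves everything unchanged at the ML optimum
  same <- apply_shrinkage(m, 1, dat$features, dat$outcomes)
  expect_equal(same$coefficients, m$coefficients, tolerance = 1e-7)
  expect_error(apply_shrinkage(m, 0, dat$features, dat$outcomes), "positive")
  expect_error(apply_shrinkage(m, -0.5, dat$features, dat$outcomes),
               "positive")
})

test_that("predicted probability follows the inverse logit", {
  spec <- model_spec(dose_metric("EUD", 0.1))
  m <- structure(list(
    spec = spec, candidates = c("dose"), retained = "dose",
    coefficients = c(`(Intercept)` = -3, dose = 0.07),
    loglik = NA_real_, aic = NA_real_, converged = TRUE, n = 0L,
    intercept_only = FALSE, shrinkage = NULL), class = "ntcp_model")
  expect_equal(predict_ntcp(m, data.frame(dose = 0)), 1 / (1 + exp(3)))
  expect_equal(predict_ntcp(m, data.frame(dose = 3 / 0.07)), 0.5)
  grid <- data.frame(dose = seq(0, 150, by = 5))
  expect_true(all(diff(predict_ntcp(m, grid)) > 0))    # monotone in dose
  expect_error(predict_ntcp(m, data.frame(other = 1)), "missing covariate")
})

test_that("model JSON serialization round-trips at full precision", {
  spec <- model_spec(dose_metric("EUD", 0.1), label = "B")
  co <- generate_cohort(300, seed = 6)
  m <- fit_ntcp(co, spec, B_shrink = 25, seed = 12)
  json <- serialize_model(m)
  back <- deserialize_model(json)
  expect_identical(back$coefficients, m$coefficients)
  expect_identical(back$retained, m$retained)
  expect_equal(back$shrinkage$s, m$shrinkage$s)
  expect_identical(back$spec$dose_metric$parameter,
                   m$spec$dose_metric$parameter)
  # version tag survives and schema violations are caught
  expect_match(json, '"version": "1.0"', fixed = TRUE)
  bad <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  bad$coefficients <- NULL
  expect_error(deserialize_model(jsonlite::toJSON(bad, auto_unbox = TRUE)),
               "coefficients")
  # file round trip
  tmp <- withr::local_tempfile(fileext = ".json")
  serialize_model(m, tmp)
  expect_identical(deserialize_model(tmp)$coefficients, m$coefficients)
})

test_that("coefficients are recovered on data simulated from a known truth", {
  spec <- model_spec(dose_metric("EUD", 0.1))
  co <- generate_cohort(5000, seed = 13)
  dat <- ntcp_data(co, spec)
  truth <- co$provenance$truth
  f <- fit_logistic(dat$features[c(format(spec$dose_metric), "ABD_SURG")],
                    dat$outcomes)
  expect_lt(abs(f$coefficients[[2]] - truth$beta_dose), 3 * f$se[[2]])
  expect_lt(abs(f$coefficients[[3]] - truth$beta_abd), 3 * f$se[[3]])
})
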