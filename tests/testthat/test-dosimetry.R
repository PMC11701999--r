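test_that("physical-to-BED conversion reproduces worked anchors", {
  expect_equal(round(physical_to_bed(70, scheme_cf(), 3), 1), 111.9)
  expect_equal(round(physical_to_bed(75, scheme_cf(), 2), 1), 147.1)
  expect_equal(physical_to_bed(78, scheme_cf(), 3), 78 * (1 + 2 / 3))
  expect_equal(physical_to_bed(0, scheme_hf(), 3), 0)
})

test_that("BED is increasing in dose, >= physical dose, and rejects bad input", {
  set.seed(11)
  for (scheme in list(scheme_cf(), scheme_hf(), fractionation(20, 60))) {
    d <- sort(runif(50, 0, 90))
    b <- physical_to_bed(d, scheme, 3)
    expect_true(all(diff(b) > 0))
    expect_true(all(b >= d))
    expect_true(all((b > d) == (d > 0)))
  }
  expect_error(physical_to_bed(-1, scheme_cf()), "non-negative")
  expect_error(physical_to_bed(70, scheme_cf(), alpha_beta = 0), "positive")
  expect_error(physical_to_bed(70, scheme_cf(), alpha_beta = -3), "positive")
})

test_that("BED transform of a DVH moves only the dose axis", {
  u <- dvh(78, 60)
  b <- bed_dvh(u, scheme_cf(), 3)
  expect_equal(b$bin_dose, 130)
  expect_equal(b$bin_volume, 60)
  expect_identical(b$dose_kind, "bed")
  expect_error(bed_dvh(b, scheme_cf()), "already")

  set.seed(21)
  for (i in 1:10) {
    x <- random_dvh()
    y <- bed_dvh(x, scheme_hf(), 3)
    expect_equal(total_volume(y), total_volume(x))          # volumes untouched
    expect_identical(y$bin_volume, x$bin_volume)
    expect_true(all(diff(y$bin_dose) > 0))                  # order preserved
    # LQ limit: huge alpha/beta leaves doses unchanged
    z <- bed_dvh(x, scheme_cf(), 1e9)
    expect_equal(z$bin_dose, x$bin_dose, tolerance = 1e-4)
  }
})

test_that("gEUD matches closed forms and the per-voxel expansion oracle", {
  expect_equal(eud(uniform_dvh(64.6), 0.37), 64.6)          # constant dose
  two <- dvh(c(60, 80), c(30, 30))
  expect_equal(eud(two, 1), 70)                             # arithmetic mean
  expect_equal(eud(two, 0.1), (0.5 * 60^10 + 0.5 * 80^10)^0.1,
               tolerance = 1e-12)

  set.seed(31)
  for (i in 1:10) {
    k <- sample(3:100, 1)
    doses <- sort(runif(k, 5, 120)) + seq_len(k) * 1e-6
    units <- sample(1:7, k, replace = TRUE)
    x <- dvh(doses, as.numeric(units))
    for (n in c(0.05, 0.1, 0.2, 0.5, 1))
      expect_equal(eud(x, n), eud_expansion_oracle(doses, units, n),
                   tolerance = 1e-9)
  }
})

test_that("gEUD lies between mean and max, decreases in n, tends to max dose", {
  set.seed(41)
  for (i in 1:10) {
    x <- random_dvh()
    mean_dose <- sum(x$bin_dose * x$bin_volume) / total_volume(x)
    ns <- c(1, 0.5, 0.2, 0.1, 0.05, 0.01)
    vals <- vapply(ns, function(n) eud(x, n), numeric(1))
    expect_true(all(vals >= mean_dose - 1e-9))
    expect_true(all(vals <= max(x$bin_dose) + 1e-9))
    expect_true(all(diff(vals) >= -1e-9))   # non-increasing in n (ns decreasing)
    expect_equal(eud(x, 1e-3), max(x$bin_dose), tolerance = 0.01)
  }
  expect_error(eud(dvh(10, 0), 0.1), "zero total volume")
  expect_error(eud(uniform_dvh(70), 1.5), "\\(0, 1\\]")
})

test_that("V_D counts bin volume at or above the threshold", {
  u <- uniform_dvh(130)
  expect_equal(v_d(u, 111.9), 100)
  expect_equal(v_d(u, 200), 0)
  expect_equal(v_d(u, 0), 100)
  two <- dvh(c(100, 120), c(30, 10))
  expect_equal(v_d(two, 110), 25)            # 10 of 40 cm3 at/above 110
  # non-increasing in threshold
  x <- random_dvh()
  thr <- seq(0, 90, by = 5)
  vals <- vapply(thr, function(t) v_d(x, t), numeric(1))
  expect_true(all(diff(vals) <= 1e-9))
  # thresholds printed at 1 d.p. are honored within half the precision
  expect_equal(v_d(uniform_dvh(111.88), 111.9), 100)
})

test_that("D_xcm3 interpolates the cumulative curve", {
  expect_equal(d_cc(uniform_dvh(70, 60), 0.5), 70)
  expect_equal(d_cc(uniform_dvh(70, 60), 60), 70)
  # cumulative points V(70) = 4, V(75) = 1 -> interpolate at x = 2
  x <- dvh(c(60, 70, 75), c(36, 3, 1))
  expect_equal(d_cc(x, 2), 70 + (4 - 2) / (4 - 1) * 5)
  expect_equal(d_cc(x, total_volume(x)), 60)  # whole organ -> min dose
  expect_error(d_cc(x, 41), "exceeds the organ volume")
  set.seed(51)
  for (i in 1:10) {
    y <- random_dvh()
    expect_gte(d_cc(y, 0.1), d_cc(y, 2))      # nested hottest volumes
  }
})

test_that("V_D and D_xcm3 are mutually consistent within one bin", {
  set.seed(61)
  for (i in 1:20) {
    x <- random_dvh(n_bins = 40)
    for (frac in c(0.1, 0.4, 0.8)) {
      vol <- frac * total_volume(x)
      dstar <- d_cc(x, vol)
      back <- v_d(x, dstar, tol = 0) * total_volume(x) / 100
      bin_vol <- max(x$bin_volume)
      expect_lt(abs(back - vol), bin_vol + 1e-9)
    }
  }
})

test_that("compute_metric composes the BED transform with the metric", {
  u70 <- uniform_dvh(70)
  expect_equal(compute_metric(u70, dose_metric("V_D", 111.9), scheme_cf(), 3),
               100)
  u78 <- uniform_dvh(78)
  expect_equal(compute_metric(u78, dose_metric("EUD", 0.1), scheme_cf(), 3),
               130)
  expect_equal(compute_metric(u78, dose_metric("D_cc", 2), scheme_cf(), 3),
               130)
  # physical scale skips the transform
  expect_equal(compute_metric(u78, dose_metric("EUD", 0.1), scheme_cf(), 3,
                              dose_scale = "physical"), 78)
  b <- bed_dvh(u78, scheme_cf())
  expect_error(compute_metric(b, dose_metric("EUD", 0.1), scheme_cf()),
               "physical-dose DVH")
})

test_that("prescription-BED crossover solves the two-scheme equality", {
  expect_equal(round(alpha_beta_crossover(scheme_cf(), scheme_hf()), 1), 4.7)
  x <- alpha_beta_crossover(scheme_cf(), fractionation(20, 60))
  expect_equal(x, 4 / 3, tolerance = 1e-12, ignore_attr = TRUE)
  # equal BEDs at the crossover
  ab <- alpha_beta_crossover(scheme_cf(), scheme_hf())
  expect_equal(physical_to_bed(78, scheme_cf(), ab),
               physical_to_bed(64.6, scheme_hf(), ab))
  no_sol <- alpha_beta_crossover(fractionation(30, 60), fractionation(20, 60))
  expect_true(is.na(no_sol))
  expect_match(attr(no_sol, "reason"), "equal total doses")
  expect_error(alpha_beta_crossover(scheme_cf(), scheme_cf()), "identical")
})

test_that("DVH constructor enforces its invariants and round-trips CSV", {
  expect_error(dvh(c(10, 5), c(1, 1)), "strictly increasing")
  expect_error(dvh(c(10, 20), c(1, -1)), "non-negative")
  expect_error(dvh(numeric(), numeric()), "empty")
  # cumulative flavor converts to differential
  x <- dvh(c(10, 20, 30), c(40, 25, 10), kind = "cumulative")
  expect_equal(x$bin_volume, c(15, 15, 10))
  expect_equal(total_volume(x), 40)
  cum <- cumulative_dvh(x)
  expect_equal(cum$cum_volume, c(40, 25, 10))
  expect_true(all(diff(cum$cum_volume) <= 0))

  tmp <- withr::local_tempfile(fileext = ".csv")
  y <- random_dvh()
  write_dvh(y, tmp)
  z <- read_dvh(tmp)
  expect_identical(z$bin_dose, y$bin_dose)
  expect_identical(z$bin_volume, y$bin_volume)
})
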