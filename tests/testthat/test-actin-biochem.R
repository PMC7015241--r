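test_that("binding isotherm fit recovers Kd and matches the grid oracle", {
  iso <- gen_binding_isotherm(kd = 7.6, seed = 1)
  fit <- fit_binding_isotherm(iso)
  expect_equal(fit$kd, 7.6, tolerance = 1e-6)
  # a fitted curve always crosses half-saturation at Kd
  expect_equal(unname(predict(fit, fit$kd)), 0.5, tolerance = 1e-12)
  # grid-search oracle agreement to 3 significant figures, noisy data
  for (i in 1:3) {
    noisy <- gen_binding_isotherm(kd = 7.6, noise_sd = 0.05, seed = 500 + i)
    f <- fit_binding_isotherm(noisy)
    expect_equal(f$kd, oracle_kd(noisy$actin_um, noisy$bound_frac),
                 tolerance = 5e-3)
  }
  expect_error(fit_binding_isotherm(c(1, 2, 3), c(0.1, 0.2, 0.3)),
               "4 concentrations")
  expect_error(fit_binding_isotherm(c(10, 12, 14, 16), rep(0.5, 4)),
               "5-fold")
})

test_that("non-binding proteins yield a flagged no-Kd result", {
  iso <- gen_binding_isotherm(kd = 1e9, seed = 1)  # Ig4-like: no binding
  fit <- fit_binding_isotherm(iso)
  expect_true(fit$no_binding)
  expect_true(is.na(fit$kd))
})

test_that("Kd recovery under noise: 200-replicate median within 10%", {
  kds <- sapply(1:200, function(i) {
    iso <- gen_binding_isotherm(kd = 7.6, noise_sd = 0.05, seed = 2000 + i)
    fit_binding_isotherm(iso)$kd
  })
  expect_lt(abs(median(kds) / 7.6 - 1), 0.10)
})

test_that("depletion-corrected quadratic model approaches the simple fit", {
  iso <- gen_binding_isotherm(kd = 7.6, seed = 1)
  fit_q <- fit_binding_isotherm(iso, ligand_um = 0.01, depletion = TRUE)
  # with negligible ligand the quadratic model reduces to simple saturation
  expect_equal(fit_q$kd, 7.6, tolerance = 1e-3)
})

test_that("bundling partition normalizes and is scale invariant", {
  p <- partition_bundling(30, 50, 20)
  expect_equal(unname(p$fractions), c(0.3, 0.5, 0.2))
  expect_equal(sum(p$fractions), 1, tolerance = 1e-9)
  # no-crosslinker control: bundled fraction 0
  p0 <- partition_bundling(0, 70, 30)
  expect_equal(unname(p0$fractions["bundled"]), 0)
  # common rescaling leaves fractions unchanged
  pk <- partition_bundling(30 * 7, 50 * 7, 20 * 7)
  expect_equal(pk$fractions, p$fractions)
  expect_error(partition_bundling(0, 0, 0), "zero")
})

test_that("polymerization normalization is idempotent and affine invariant", {
  tr <- gen_polymerization_trace(0.005, lag = 60, plateau_rfu = 900,
                                 baseline_rfu = 150, seed = 1)
  n1 <- normalize_polymerization(tr)
  expect_equal(n1$f_norm[1], 0, tolerance = 1e-9)
  expect_equal(n1$f_norm[length(n1$f_norm)], 1, tolerance = 1e-3)
  # idempotent
  n2 <- normalize_polymerization(n1)
  expect_equal(n2$f_norm, n1$f_norm, tolerance = 1e-9)
  # affine transform of the raw fluorescence leaves the result unchanged
  tr_aff <- tr
  tr_aff$rfu <- 3.7 * tr$rfu + 42
  expect_equal(normalize_polymerization(tr_aff)$f_norm, n1$f_norm,
               tolerance = 1e-12)
  # plateau <= baseline is an error
  bad <- data.frame(time_s = 1:20, rfu = seq(100, 50, length.out = 20))
  expect_error(normalize_polymerization(bad), "plateau")
})

test_that("polymerization rate: conversion, monotonicity, affine invariance", {
  tr <- gen_polymerization_trace(0.002, plateau_rfu = 1000,
                                 baseline_rfu = 100,
                                 times = seq(0, 4000, by = 2), seed = 1)
  rate <- polymerization_rate(normalize_polymerization(tr),
                              total_actin_um = 5, c_crit_um = 0.1,
                              window_frac = 0.02)
  # max slope of 1 - exp(-kt) inside the 10-60% band sits at the f = 0.1
  # entry (slope k * 0.9), averaged down slightly over the finite window
  expect_equal(rate$slope_per_s, 0.002 * 0.9, tolerance = 0.1)
  expect_equal(rate$rate_nm_per_s, rate$slope_per_s * 4900,
               tolerance = 1e-12)
  # doubling k_obs (sampled on a correspondingly halved time step, so the
  # normalized shape is sampled identically) exactly doubles the rate
  tr2 <- gen_polymerization_trace(0.004, plateau_rfu = 1000,
                                  baseline_rfu = 100,
                                  times = seq(0, 2000, by = 1), seed = 1)
  rate2 <- polymerization_rate(normalize_polymerization(tr2),
                               total_actin_um = 5, c_crit_um = 0.1,
                               window_frac = 0.02)
  expect_equal(rate2$rate_nm_per_s / rate$rate_nm_per_s, 2,
               tolerance = 1e-9)
  # affine transform of raw fluorescence leaves the rate unchanged
  tr_aff <- tr
  tr_aff$rfu <- 2.2 * tr$rfu + 17
  rate_aff <- polymerization_rate(normalize_polymerization(tr_aff),
                                  total_actin_um = 5, c_crit_um = 0.1,
                                  window_frac = 0.02)
  expect_equal(rate_aff$rate_nm_per_s, rate$rate_nm_per_s,
               tolerance = 1e-9)
  # dose series with decreasing k_obs gives strictly decreasing rates
  ks <- c(0.004, 0.003, 0.002, 0.001)
  rates <- sapply(ks, function(k) {
    t <- gen_polymerization_trace(k, plateau_rfu = 1000, baseline_rfu = 100,
                                  times = seq(0, 8000, by = 4), seed = 1)
    polymerization_rate(normalize_polymerization(t), total_actin_um = 5,
                        window_frac = 0.01)$rate_nm_per_s
  })
  expect_true(all(diff(rates) < 0))
  expect_error(polymerization_rate(tr, 5), "normalized")
})

test_that("depolymerization normalization maps final to 0 and max to 1", {
  pair <- gen_depolymerization_pair(0.01, 0.8, seed = 1)
  lata_final <- pair$free$rfu[nrow(pair$free)]
  free_n <- normalize_depolymerization(pair$free, lata_final)
  expect_equal(free_n$f_norm[nrow(free_n)], 0, tolerance = 1e-12)
  expect_equal(max(free_n$f_norm), 1, tolerance = 1e-12)
  # order preserving
  expect_true(all(diff(free_n$f_norm) < 0))
  # noiseless normalization reproduces the exponential up to the final-point
  # offset: (exp(-kt) - c) / (1 - c)
  c0 <- exp(-0.01 * 600)
  expect_equal(free_n$f_norm,
               (exp(-0.01 * free_n$time_s) - c0) / (1 - c0),
               tolerance = 1e-9)
  expect_error(normalize_depolymerization(pair$free, 1e6), "degenerate")
})

test_that("depolymerization decrease: identity, analytic pair, invariances", {
  pair <- gen_depolymerization_pair(0.01, 0.8, seed = 1)
  lata_final <- pair$free$rfu[nrow(pair$free)]
  free_n <- normalize_depolymerization(pair$free, lata_final)
  # identical traces give 0% decrease
  same <- depolymerization_decrease(free_n, free_n)
  expect_equal(same$percent_decrease, 0, tolerance = 1e-12)
  # exponential pair (k, k/2): initial-rate decrease near 50%, matching the
  # analytic initial slopes -k vs -k/2 within 2%
  pair_half <- gen_depolymerization_pair(0.002, 0.5, seed = 1)
  lf <- pair_half$free$rfu[nrow(pair_half$free)]
  dec <- depolymerization_decrease(
    normalize_depolymerization(pair_half$free, lf),
    normalize_depolymerization(pair_half$plus, lf))
  expect_equal(dec$percent_decrease, 50, tolerance = 0.04)
  # exponential-fit mode recovers the rate-constant ratio directly
  dec_exp <- depolymerization_decrease(
    normalize_depolymerization(pair_half$free, lf),
    normalize_depolymerization(pair_half$plus, lf),
    method = "exponential")
  expect_equal(dec_exp$percent_decrease, 50, tolerance = 0.5)
  # invariance to a consistent time-unit rescaling of both traces
  pair_min <- pair
  pair_min$free$time_s <- pair$free$time_s / 60
  pair_min$plus$time_s <- pair$plus$time_s / 60
  dec_s <- run_depoly_pipeline(pair, window_s = 60)
  dec_min <- run_depoly_pipeline(pair_min, window_s = 1)
  expect_equal(dec_min$percent_decrease, dec_s$percent_decrease,
               tolerance = 1e-9)
})
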