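test_that("generators are deterministic under a fixed seed", {
  gens <- list(
    function(s) gen_force_velocity(0.25, 1, 4, 1, noise_sd = 0.05, seed = s),
    function(s) gen_force_pca(2, 6, noise_sd = 0.02, seed = s),
    function(s) gen_binding_isotherm(7.6, noise_sd = 0.05, seed = s),
    function(s) gen_polymerization_trace(0.005, lag = 60, noise_sd = 5,
                                         seed = s),
    function(s) gen_zline_profile(60, noise_sd = 0.05, seed = s),
    function(s) gen_fibre_population(log(1800), 0.35, 200, seed = s)
  )
  for (g in gens) {
    expect_identical(g(7), g(7))
    expect_false(identical(g(7), g(8)))
  }
  pair <- gen_depolymerization_pair(0.01, 0.8, noise_sd = 2, seed = 11)
  expect_identical(pair, gen_depolymerization_pair(0.01, 0.8, noise_sd = 2,
                                                   seed = 11))
})

test_that("noiseless generator output satisfies its model equation", {
  fv <- gen_force_velocity(0.25, 1, 4, 1, loads = c(0, 0.5, 1), seed = 1)
  expect_equal(fv$velocity[1], 4, tolerance = 1e-12)       # V(0) = V0
  expect_equal(fv$velocity[3], 0, tolerance = 1e-12)       # 0.25*5/1.25 - 1
  expect_equal(fv$velocity[2], 0.25 * 5 / 0.75 - 1, tolerance = 1e-12)

  pc <- gen_force_pca(2, 6, pca = c(8, 6, 5.5), seed = 1)
  expect_equal(pc$t_rel[2], 0.5, tolerance = 1e-12)        # definition of pK
  expect_equal(pc$t_rel[3], 1 / (1 + 10^-1), tolerance = 1e-12)
  expect_lt(pc$t_rel[1], 1e-3)                             # saturation limit

  iso <- gen_binding_isotherm(7.6, actin_um = c(7.6, 30), seed = 1)
  expect_equal(iso$bound_frac[1], 0.5, tolerance = 1e-12)  # half-saturation
  expect_equal(iso$bound_frac[2], 30 / 37.6, tolerance = 1e-12)
  weak <- gen_binding_isotherm(1e9, seed = 1)
  expect_true(all(weak$bound_frac < 1e-6))                 # no-binding limit

  tr <- gen_polymerization_trace(0.01, lag = 100, plateau_rfu = 1000,
                                 baseline_rfu = 100,
                                 times = c(0, 50, 100, 1e5), seed = 1)
  expect_equal(tr$rfu[1:3], c(100, 100, 100))              # lag phase
  expect_equal(tr$rfu[4], 1000, tolerance = 1e-6)          # saturation

  pair0 <- gen_depolymerization_pair(0.01, 0, seed = 1)
  expect_equal(pair0$free$rfu, pair0$plus$rfu)             # no protection
  pair <- gen_depolymerization_pair(0.01, 0.8, seed = 1)
  # initial log-slope ratio equals 1 - protection by construction
  k_free <- -diff(log(pair$free$rfu[1:2] - 100))
  k_plus <- -diff(log(pair$plus$rfu[1:2] - 100))
  expect_equal(k_plus / k_free, 0.2, tolerance = 1e-9)
  expect_lt(abs(pair$free$rfu[601] - 100), 3)              # full disassembly
})

test_that("generator parameter validation rejects bad inputs", {
  expect_error(gen_force_velocity(-1, 1, 4, 1, seed = 1), "positive")
  expect_error(gen_force_pca(2, 6, pca = numeric(0), seed = 1), "empty")
  expect_error(gen_binding_isotherm(7.6, actin_um = c(-1, 5), seed = 1),
               "non-negative")
  expect_error(gen_polymerization_trace(0.01, times = c(0, 0, 1), seed = 1),
               "increasing")
  expect_error(gen_depolymerization_pair(0.01, 1.2, seed = 1), "0, 1")
  expect_error(gen_zline_profile(500, positions = seq(-100, 100), seed = 1),
               "support")
  expect_error(gen_fibre_population(7, 0.3, -5, seed = 1), "positive")
  expect_error(gen_force_velocity(1, 1, 1, 1, seed = "x"), "seed")
})

test_that("noise calibration: empirical residual sd matches noise_sd", {
  sd_target <- 0.05
  fv <- gen_force_velocity(0.25, 1, 4, 1, loads = rep(0.5, 2e4),
                           noise_sd = sd_target, seed = 3)
  truth <- 0.25 * 5 / 0.75 - 1
  expect_lt(abs(sd(fv$velocity - truth) / sd_target - 1), 0.05)

  pr <- gen_zline_profile(60, noise_sd = sd_target,
                          positions = seq(-150, 150, length.out = 2e4),
                          seed = 4)
  clean <- gen_zline_profile(60, noise_sd = 0,
                             positions = seq(-150, 150, length.out = 2e4),
                             seed = 4)
  expect_lt(abs(sd(pr$intensity - clean$intensity) / sd_target - 1), 0.05)
})

test_that("bounded observables are clipped to [0, 1] under noise", {
  pc <- gen_force_pca(2, 6, pca = seq(8, 4, by = -0.05), noise_sd = 0.3,
                      seed = 5)
  expect_true(all(pc$t_rel >= 0 & pc$t_rel <= 1))
  iso <- gen_binding_isotherm(7.6, noise_sd = 0.4, seed = 5)
  expect_true(all(iso$bound_frac >= 0 & iso$bound_frac <= 1))
})

test_that("fibre population generator honours structure parameters", {
  pop <- gen_fibre_population(log(1800), 0, 50, seed = 1)
  expect_equal(pop$csa_um2, rep(1800, 50))        # sigma 0 -> all equal
  pop2 <- gen_fibre_population(7, 0.3, 1000,
                               type_props = c(a = 0.2, b = 0.8), seed = 2)
  counts <- table(pop2$fibre_type)
  expect_equal(unname(counts["a"] / 1000), 0.2, tolerance = 0.2)
  expect_equal(unname(counts["b"] / 1000), 0.8, tolerance = 0.05)
  expect_error(gen_fibre_population(7, 0.3, 10,
                                    type_props = c(0.5, 0.4), seed = 1),
               "sum to 1")
})

test_that("zline profile generator encodes the stated base width", {
  pr <- gen_zline_profile(60, peak_amp = 2, background = 0.5,
                          shoulder_frac = 0.1, seed = 1)
  on_plateau <- abs(pr$position_nm) <= 24    # 30 - 6 nm shoulder
  outside <- abs(pr$position_nm) > 30
  expect_true(all(pr$intensity[on_plateau] == 2.5))
  expect_true(all(pr$intensity[outside] == 0.5))
  # doubling the width doubles the measured base width
  w1 <- zline_width(gen_zline_profile(40, seed = 1))$width_nm
  w2 <- zline_width(gen_zline_profile(80, seed = 1))$width_nm
  expect_equal(w2 / w1, 2, tolerance = 1e-9)
})
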