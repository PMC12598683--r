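test_that("leaf spectrum generator saturates to r_nir, is seed-deterministic", {
  g <- uniform_grid()
  p <- leaf_optics_params(noise_sd = 0, lambda0 = 715, slope_s = 5)
  s <- generate_leaf_spectrum(p, g, seed = 1)
  # far beyond the red edge the logistic saturates
  expect_lt(abs(s$values[length(g)] - p$r_nir), 1e-3)
  expect_true(all(s$values >= 0 & s$values <= 1))
  # determinism under a fixed seed, difference under another
  pn <- leaf_optics_params(noise_sd = 0.02)
  s1 <- generate_leaf_spectrum(pn, g, seed = 7)
  s2 <- generate_leaf_spectrum(pn, g, seed = 7)
  s3 <- generate_leaf_spectrum(pn, g, seed = 8)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, s3$values))
})

test_that("lambda0 displacement propagates to the derivative peak", {
  g <- uniform_grid()
  d1 <- first_derivative(smooth_spectrum(logistic_spectrum(715, g)))
  d2 <- first_derivative(smooth_spectrum(logistic_spectrum(702.6, g)))
  diffp <- red_edge_peak(d1)$peak_wavelength -
    red_edge_peak(d2)$peak_wavelength
  expect_lt(abs(diffp - 12.4), 1.8)
})

test_that("parameter and grid validation reject bad input", {
  expect_error(leaf_optics_params(chl_total = -1), "positive")
  expect_error(leaf_optics_params(slope_s = 0), "slope_s")
  expect_error(leaf_optics_params(noise_sd = -0.1), "noise_sd")
  expect_error(leaf_optics_params(r_nir = 1.2), "r_nir")
  expect_error(leaf_optics_params(chl_total = NaN), "non-finite")
  p <- leaf_optics_params()
  expect_error(generate_leaf_spectrum(p, seq(200, 800, 10)), "300")
  expect_error(generate_leaf_spectrum(
    leaf_optics_params(lambda0 = 900), uniform_grid()), "inside")
})

test_that("chlorophyll coupling is monotone: less chl, shorter lambda0, brighter 550 nm", {
  chl <- seq(2, 15, length.out = 20)
  lam <- chl_to_lambda0(chl)
  expect_true(all(diff(lam) > 0))
  g <- uniform_grid()
  i550 <- which.min(abs(g - 550))
  r550 <- sapply(chl, function(cc) {
    p <- leaf_optics_params(chl_total = cc, noise_sd = 0)
    generate_leaf_spectrum(p, g, seed = 1)$values[i550]
  })
  # reflectance at 550 nm never decreases as chlorophyll drops
  expect_true(all(diff(r550) <= 1e-12))
})

test_that("experiment design validates control identity and cell coverage", {
  expect_error(experiment_design(treatments = c("cold", "salt")), "control")
  expect_error(experiment_design(n_plants = 1), "n_plants")
  expect_error(experiment_design(days = c(7, 1)), "ascending")
  eff <- default_effect_table()
  eff$chl_mult[eff$treatment == "control"] <- 1.1
  expect_error(experiment_design(effect_table = eff), "identity")
  eff2 <- default_effect_table()
  eff2 <- eff2[eff2$treatment != "salt", ]
  expect_error(experiment_design(effect_table = eff2), "design cell")
})

test_that("control-only experiments recover the base chlorophyll without shifts", {
  des <- experiment_design(species = "chinense", treatments = "control",
                           days = c(1, 7, 14), n_plants = 8, seed = 5)
  base <- leaf_optics_params()
  sim <- generate_experiment(des, base, bio_cv = 0.05)
  m <- mean(sim$traits$chl_total)
  # group mean equals base chl within plant-level lognormal noise
  expect_lt(abs(m - base$chl_total) / base$chl_total, 3 * 0.05 / sqrt(8))
  # no systematic day trend under control
  daymeans <- tapply(sim$traits$chl_total, sim$traits$day, mean)
  expect_lt(diff(range(daymeans)) / base$chl_total, 0.1)
})

test_that("default effect table reproduces the cold/combined/salt ordering", {
  des <- experiment_design(species = "chinense", days = c(14))
  sim <- generate_experiment(des)
  m <- tapply(sim$traits$chl_total, sim$traits$treatment, mean)
  r_cold <- m[["cold"]] / m[["control"]]
  r_comb <- m[["cold_salt"]] / m[["control"]]
  expect_lt(r_cold, r_comb)
  expect_lt(r_comb, 1)
})

test_that("experiment generation is byte-identical under a fixed seed", {
  des <- experiment_design(species = "annuum", days = c(1, 7),
                           n_plants = 2, seed = 99)
  a <- generate_experiment(des)
  b <- generate_experiment(des)
  expect_identical(a$traits, b$traits)
  expect_identical(lapply(a$spectra, `[[`, "values"),
                   lapply(b$spectra, `[[`, "values"))
})

test_that("absorbance generation inverts the pigment equations exactly", {
  expect_equal(unlist(generate_absorbances(0, 0, 0)),
               c(a470 = 0, a6524 = 0, a6652 = 0))
  ab <- generate_absorbances(5.612, 2.587, 2)
  expect_equal(ab$a6652, 0.5, tolerance = 1e-9)
  expect_equal(ab$a6524, 0.3, tolerance = 1e-9)
  # 1000-way random round trip to 1e-9
  set.seed(42)
  ca <- runif(1000, 0, 25); cb <- runif(1000, 0, 8); cx <- runif(1000, 0, 10)
  ab <- generate_absorbances(ca, cb, cx)
  pc <- pigment_concentrations(ab)
  expect_lt(max(abs(pc$chl_a - ca)), 1e-9)
  expect_lt(max(abs(pc$chl_b - cb)), 1e-9)
  expect_lt(max(abs(pc$caro - cx)), 1e-9)
  expect_error(generate_absorbances(-1, 0, 0), ">= 0")
})

test_that("growth/color generator matches targets before noise", {
  des <- experiment_design(species = "annuum", treatments = c("control"),
                           days = c(7, 14), n_plants = 2, seed = 3)
  g0 <- generate_growth_and_color(des, rgr_targets = c(control = 0),
                                  exg_targets = c(control = 90),
                                  pla_noise_sd = 0, exg_noise_sd = 0)
  expect_true(all(abs(g0$pla - g0$pla[1]) < 1e-12))  # zero growth
  # doubling over 7 days
  gd <- generate_growth_and_color(des,
    rgr_targets = c(control = 100 * log(2) / 7),
    exg_targets = c(control = 90), pla_noise_sd = 0, exg_noise_sd = 0)
  p1 <- gd[gd$plant == 1, ]
  expect_equal(relative_growth_rate(p1$day, p1$pla, 0, 7),
               100 * log(2) / 7, tolerance = 1e-10)
  # equal channels downstream give zero excess greenness
  rec <- data.frame(mean_r = 80, mean_g = 80, mean_b = 80)
  expect_identical(excess_greenness(rec), 0)
  expect_error(generate_growth_and_color(des,
    rgr_targets = c(control = 5), exg_targets = c(control = 90),
    pla0 = -1), "PLA")
  expect_error(generate_growth_and_color(des,
    rgr_targets = c(cold = 5), exg_targets = c(control = 90)),
    "rgr_targets")
})
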