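test_that("smoothing matches the per-band loop oracle and has fixed points", {
  # weights sum to one: constants are invariant
  expect_equal(smooth_spectrum(rep(0.3, 10)), rep(0.3, 10))
  # linear data are fixed points at interior bands
  expect_equal(smooth_spectrum(c(0.1, 0.2, 0.3))[2], 0.2)
  ramp <- seq(0.1, 0.5, length.out = 50)
  expect_equal(smooth_spectrum(ramp)[2:49], ramp[2:49], tolerance = 1e-12)
  # random spectra against the independent loop oracle
  set.seed(101)
  for (i in 1:20) {
    v <- random_spectrum(200)
    expect_equal(smooth_spectrum(v), oracle_smooth(v), tolerance = 1e-12)
  }
  expect_error(smooth_spectrum(c(0.1, 0.2)), "3 bands")
  expect_error(smooth_spectrum(c(0.1, NaN, 0.2)), "finite")
})

test_that("first derivative matches the loop oracle, is linear, kills constants", {
  expect_equal(first_derivative(rep(0.4, 20)), rep(0, 14))
  set.seed(102)
  for (i in 1:20) {
    v <- random_spectrum(100)
    expect_equal(first_derivative(v), oracle_derivative(v),
                 tolerance = 1e-12)
  }
  # linearity of the operator
  a <- random_spectrum(50); b <- random_spectrum(50)
  expect_equal(first_derivative(2 * a + 3 * b),
               2 * first_derivative(a) + 3 * first_derivative(b),
               tolerance = 1e-12)
  expect_error(first_derivative(rep(0.1, 6)), "7 bands")
  expect_error(first_derivative(rep(0.1, 10), delta_lambda = 0),
               "delta_lambda")
})

test_that("literal derivative returns 4x the slope on a ramp; slope-consistent mode returns it", {
  g <- uniform_grid(40)
  b <- 0.0123
  v <- 0.05 + b * g
  rho <- first_derivative(v, delta_lambda = 1.8)
  expect_equal(rho, rep(4 * b, length(rho)), tolerance = 1e-12)
  rho_c <- first_derivative(v, delta_lambda = 1.8, slope_consistent = TRUE)
  expect_equal(rho_c, rep(b, length(rho_c)), tolerance = 1e-12)
})

test_that("derivative spectra drop 3 bands per end and carry delta_lambda", {
  s <- leaf_spectrum(uniform_grid(20), random_spectrum(20))
  d <- first_derivative(smooth_spectrum(s))
  expect_equal(length(d$wavelength), 14)
  expect_equal(d$wavelength, s$wavelength[4:17])
  expect_equal(d$delta_lambda, 1.8)
  expect_equal(d$stage, "derivative")
})

test_that("technical replicate averaging is a per-band mean with key checks", {
  g <- uniform_grid(20)
  mk <- function(vals, rep) leaf_spectrum(g, vals,
    meta = list(species = "a", treatment = "control", day = 1, plant = 1,
                tech_rep = rep))
  s1 <- mk(rep(0.2, 20), 1); s2 <- mk(rep(0.4, 20), 2)
  avg <- average_technical_replicates(list(s1, s2))
  expect_equal(avg$values, rep(0.3, 20))
  expect_equal(avg$meta$tech_rep, "mean")
  # identity on a single spectrum
  expect_equal(average_technical_replicates(list(s1))$values, s1$values)
  # 3 random replicates against a loop mean
  set.seed(103)
  reps <- lapply(1:3, function(i) mk(random_spectrum(20), i))
  man <- sapply(seq_along(g), function(j) {
    mean(c(reps[[1]]$values[j], reps[[2]]$values[j], reps[[3]]$values[j]))
  })
  expect_equal(average_technical_replicates(reps)$values, man)
  # mixed plant keys rejected
  s3 <- leaf_spectrum(g, rep(0.1, 20),
    meta = list(species = "a", treatment = "cold", day = 1, plant = 2,
                tech_rep = 1))
  expect_error(average_technical_replicates(list(s1, s3)), "plant keys")
  # mixed grids rejected
  s4 <- leaf_spectrum(uniform_grid(20, from = 326), rep(0.1, 20), s1$meta)
  expect_error(average_technical_replicates(list(s1, s4)), "grid")
})

test_that("red-edge peak finds the logistic inflection with tie and window rules", {
  s <- logistic_spectrum(715)
  d <- first_derivative(smooth_spectrum(s))
  pk <- red_edge_peak(d)
  expect_lt(abs(pk$peak_wavelength - 715), 0.9)  # half a band spacing
  pki <- red_edge_peak(d, interpolate = TRUE)
  expect_lt(abs(pki$peak_wavelength - 715), 0.2)
  expect_true(pki$interpolated)
  # tie -> lowest wavelength
  dd <- d
  dd$values[] <- 0
  i1 <- which.min(abs(dd$wavelength - 706.3))
  i2 <- which.min(abs(dd$wavelength - 710.0))
  dd$values[c(i1, i2)] <- 1
  expect_equal(red_edge_peak(dd)$peak_wavelength, dd$wavelength[i1])
  # degenerate flat window warns and returns the lowest wavelength
  dflat <- d; dflat$values[] <- 0.5
  expect_warning(pkf <- red_edge_peak(dflat), "degenerate")
  expect_equal(pkf$peak_wavelength,
               min(dflat$wavelength[dflat$wavelength >= 690]))
  expect_error(red_edge_peak(d, window = c(880, 890)), "window")
})

test_that("red-edge shift recovers constructed displacements and is antisymmetric", {
  ga <- list(first_derivative(smooth_spectrum(logistic_spectrum(715))))
  gb <- list(first_derivative(smooth_spectrum(logistic_spectrum(702.6))))
  sh <- red_edge_shift(ga, gb)
  expect_lt(abs(sh - (-12.4)), 1.8)
  expect_equal(red_edge_shift(gb, ga), -sh)
  expect_equal(red_edge_shift(ga, ga), 0)
  # single-spectrum groups equal the difference of per-spectrum peaks
  expect_equal(sh, red_edge_peak(gb[[1]])$peak_wavelength -
                 red_edge_peak(ga[[1]])$peak_wavelength)
  # per-plant mode agrees for single-spectrum groups
  expect_equal(red_edge_shift(ga, gb, per_plant = TRUE), sh)
  expect_error(red_edge_shift(list(), gb), "at least one")
})

test_that("difference spectrum reports signed per-band difference and argmax", {
  g <- uniform_grid(10)
  mk <- function(v) leaf_spectrum(g, v)
  a <- mk(rep(0.2, 10)); b <- mk(c(rep(0.2, 4), 0.5, rep(0.2, 5)))
  ds <- difference_spectrum(list(a), list(b))
  expect_equal(ds$difference, c(rep(0, 4), 0.3, rep(0, 5)))
  expect_equal(ds$argmax_wavelength, g[5])
  # hand-built 5-band two-member groups
  g5 <- uniform_grid(7)
  ga <- list(mk2 <- leaf_spectrum(g5, c(.1, .2, .3, .4, .5, .4, .3)),
             leaf_spectrum(g5, c(.3, .2, .1, .2, .3, .2, .1)))
  gb <- list(leaf_spectrum(g5, c(.2, .2, .2, .2, .2, .2, .2)))
  ds2 <- difference_spectrum(ga, gb)
  expect_equal(ds2$difference, 0.2 - (ga[[1]]$values + ga[[2]]$values) / 2)
  expect_warning(dsd <- difference_spectrum(list(a), list(a)), "identical")
  expect_true(dsd$degenerate)
})

test_that("percent-scaled reflectance is auto-normalized to fractions", {
  g <- uniform_grid(10)
  expect_message(s <- leaf_spectrum(g, seq(10, 55, length.out = 10)),
                 "percent")
  expect_true(all(s$values <= 1))
  expect_equal(max(s$values), 0.55)
})
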