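test_that("gated comparison routes clean data to ANOVA and heavy tails to Kruskal-Wallis", {
  set.seed(31)
  g <- rep(c("control", "cold", "salt", "cold_salt"), each = 8)
  normal <- rnorm(32, mean = rep(c(0, 1, 0, 1), each = 8), sd = 1)
  cn <- compare_treatments(normal, g)
  expect_equal(cn$method, "ANOVA+Tukey")
  heavy <- rcauchy(32) + rep(c(0, 50, 0, 50), each = 8)
  ch <- compare_treatments(heavy, g)
  expect_equal(ch$method, "Kruskal-Wallis+Dunn")
  expect_true(all(c("shapiro_p", "levene_p") %in% names(cn$gate)))
})

test_that("identical groups share one letter; separated groups get distinct letters", {
  g <- rep(c("a", "b", "c", "d"), each = 4)
  same <- compare_treatments(rep(5, 16), g)
  expect_equal(same$omnibus_p, 1)
  expect_length(unique(same$letters), 1)
  set.seed(32)
  sep <- compare_treatments(rep(c(0, 10), each = 8) + rnorm(16, 0, 0.01),
                            rep(c("a", "b"), each = 8))
  expect_false(sep$letters[["a"]] == sep$letters[["b"]])
  expect_lt(sep$omnibus_p, 0.05)
  expect_error(compare_treatments(1:5, c("a", "a", "a", "a", "b")),
               "insufficient replication")
})

test_that("compact letters exactly reproduce the pairwise significance pattern", {
  set.seed(33)
  for (rep_i in 1:25) {
    k <- sample(3:6, 1)
    sig <- matrix(FALSE, k, k, dimnames = list(letters[1:k], letters[1:k]))
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        sig[i, j] <- sig[j, i] <- runif(1) < 0.4
      }
    }
    cl <- compact_letters(sig)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        share <- any(strsplit(cl[i], "")[[1]] %in% strsplit(cl[j], "")[[1]])
        expect_equal(share, !sig[i, j],
                     label = paste("pair", i, j, "rep", rep_i))
      }
    }
  }
})

test_that("Dunn z statistics follow the tie-corrected closed form", {
  set.seed(34)
  v <- c(rnorm(5), rnorm(5, 2), rnorm(5, 4))
  g <- rep(c("a", "b", "c"), each = 5)
  dn <- dunn_test(v, g)
  # closed-form oracle for one pair
  rk <- rank(v)
  n_all <- length(v)
  ties <- table(v)
  v0 <- n_all * (n_all + 1) / 12 - sum(ties^3 - ties) / (12 * (n_all - 1))
  z_ab <- (mean(rk[g == "a"]) - mean(rk[g == "b"])) /
    sqrt(v0 * (1 / 5 + 1 / 5))
  expect_equal(dn$z[dn$group1 == "a" & dn$group2 == "b"], z_ab,
               tolerance = 1e-12)
  expect_equal(dn$p_value, 2 * pnorm(-abs(dn$z)), tolerance = 1e-12)
  # bonferroni adjustment multiplies by the number of pairs
  dnb <- dunn_test(v, g, adjust = "bonferroni")
  expect_equal(dnb$p_value, pmin(1, dn$p_value * 3), tolerance = 1e-12)
})

test_that("correlogram equals the textbook Pearson closed form and flags degenerate traits", {
  set.seed(35)
  g <- uniform_grid(40)
  n <- 12
  spectra <- lapply(seq_len(n), function(i) {
    leaf_spectrum(g, random_spectrum(40),
                  meta = list(species = "chinense", treatment = "control",
                              day = 1, plant = i, tech_rep = "mean"))
  })
  k <- 17
  traits <- data.frame(species = "chinense", treatment = "control", day = 1,
                       plant = seq_len(n),
                       band_k = vapply(spectra, function(s) s$values[k], 0),
                       noise = rnorm(n))
  prof <- spectral_trait_correlogram(spectra, traits, "band_k", days = 1)
  expect_equal(prof$pearson_r[k], 1, tolerance = 1e-9)
  # closed-form oracle at an arbitrary band
  x <- vapply(spectra, function(s) s$values[5], 0)
  y <- traits$band_k
  r_cf <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(prof$pearson_r[5], r_cf, tolerance = 1e-12)
  expect_equal(prof$p_value[5],
               cor.test(x, y)$p.value, tolerance = 1e-9)
  # zero-variance trait
  traits$flat <- 1
  expect_warning(pf <- spectral_trait_correlogram(spectra, traits, "flat",
                                                  days = 1),
                 "zero variance")
  expect_true(all(is.na(pf$pearson_r)))
})

test_that("a trait independent of the spectra is significant at about the alpha rate", {
  set.seed(36)
  g <- seq(400, 750, length.out = 1000)
  n <- 30
  spectra <- lapply(seq_len(n), function(i) {
    leaf_spectrum(g, runif(1000, 0.1, 0.6),
                  meta = list(species = "x", treatment = "control", day = 1,
                              plant = i, tech_rep = "mean"))
  })
  traits <- data.frame(species = "x", treatment = "control", day = 1,
                       plant = seq_len(n), indep = rnorm(n))
  prof <- spectral_trait_correlogram(spectra, traits, "indep", days = 1)
  frac_sig <- mean(prof$p_value <= 0.05)
  expect_lt(abs(frac_sig - 0.05), 0.025)
})

test_that("index-trait correlations recover construction and respect subsets", {
  set.seed(37)
  n <- 24
  chl <- runif(n, 5, 15)
  tab <- data.frame(species = "chinense",
                    treatment = rep(c("control", "cold"), n / 2),
                    day = rep(c(1, 7, 14), length.out = n),
                    plant = seq_len(n))
  idx <- rbind(
    data.frame(tab, index = "PRI", value = 0.01 * chl + rnorm(n, 0, 0.001)),
    data.frame(tab, index = "NDRE", value = rnorm(n))
  )
  traits <- data.frame(tab, chl_total = chl)
  res <- index_trait_correlation(idx, traits, traits_use = "chl_total")
  r_pri <- res$r[res$index == "PRI"]
  expect_gt(r_pri, 0.9)
  # a duplicated column correlates perfectly with itself
  traits$pri_copy <- idx$value[idx$index == "PRI"]
  res2 <- index_trait_correlation(idx, traits, traits_use = "pri_copy")
  expect_equal(res2$r[res2$index == "PRI"], 1, tolerance = 1e-9)
  # insufficient data flagged, not crashed
  idx_small <- idx[idx$index == "PRI", ][1:2, ]
  res3 <- index_trait_correlation(idx_small, traits,
                                  traits_use = "chl_total")
  expect_true(res3$insufficient)
  # subset filter keeps control + one stress only
  res4 <- index_trait_correlation(idx, traits, subset = "control+cold",
                                  traits_use = "chl_total")
  expect_equal(nrow(res4), 2)
})

test_that("salt without chlorophyll effect yields weak index-chl correlation", {
  # design where salt leaves chlorophyll untouched
  eff <- default_effect_table()
  eff <- eff[eff$species == "chinense", ]
  eff[eff$treatment == "salt",
      c("chl_mult", "caro_mult", "flav_mult", "tp_mult", "sla_mult")] <- 1
  des <- experiment_design(species = "chinense", days = c(1, 7, 14),
                           effect_table = eff, seed = 88)
  sim <- generate_experiment(des)
  keys <- vapply(sim$spectra, function(s)
    paste(s$meta$treatment, s$meta$day, s$meta$plant), "")
  plant <- lapply(split(sim$spectra, keys), average_technical_replicates)
  it <- index_table(unname(plant))
  it_mean <- aggregate(value ~ species + treatment + day + plant + index,
                       it, mean)
  r_salt <- index_trait_correlation(it_mean, sim$traits,
                                    subset = "control+salt",
                                    traits_use = "chl_total")
  r_cold <- index_trait_correlation(it_mean, sim$traits,
                                    subset = "control+cold",
                                    traits_use = "chl_total")
  ndre_salt <- abs(r_salt$r[r_salt$index == "NDRE"])
  ndre_cold <- abs(r_cold$r[r_cold$index == "NDRE"])
  expect_lt(ndre_salt, ndre_cold)
})

test_that("PRI time course separates constructed additive depressions at day 14", {
  set.seed(38)
  tr <- c("control", "salt", "cold", "cold_salt")
  depress <- c(control = 0, salt = 0.005, cold = 0.012, cold_salt = 0.03)
  rows <- list()
  for (d in c(1, 7, 14)) {
    for (t in tr) {
      eff <- if (d == 14) depress[[t]] else depress[[t]] * d / 14
      rows[[length(rows) + 1L]] <- data.frame(
        species = "chinense", treatment = t, day = d, plant = 1:4,
        index = "PRI", value = 0.04 - eff + rnorm(4, 0, 0.002))
    }
  }
  idx <- do.call(rbind, rows)
  tc <- pri_time_course(idx)
  d14 <- tc[tc$day == 14, ]
  expect_false(d14$letter[d14$treatment == "control"] ==
                 d14$letter[d14$treatment == "cold_salt"])
  # identical treatments share one letter per day
  idx0 <- idx; idx0$value <- rep(0.04, nrow(idx0))
  tc0 <- pri_time_course(idx0)
  expect_length(unique(tc0$letter[tc0$day == 7]), 1)
  expect_error(pri_time_course(idx[idx$day != 7, ]), "day\\(s\\) 7")
})
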