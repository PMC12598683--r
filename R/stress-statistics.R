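#' Gated treatment comparison with compact letter display
#'
#' Reproduces the study's statistical gate: Shapiro-Wilk normality (on
#' pooled within-group-centered residuals) and Brown-Forsythe homogeneity
#' of variance (Levene with median centering) are tested at `alpha`; if
#' both pass, a one-way ANOVA with Tukey's HSD post hoc is run, otherwise
#' Kruskal-Wallis one-way ANOVA on ranks with Dunn's test. Compact
#' significance letters are derived from the pairwise results: two groups
#' share a letter iff their pairwise difference is not significant at
#' `alpha`.
#'
#' @param values numeric measurements (one per plant).
#' @param groups treatment labels, same length.
#' @param alpha significance level for the gate, the omnibus test and the
#'   pairwise letters (default 0.05).
#' @param dunn_adjust p-value adjustment for Dunn's pairwise tests:
#'   `"none"` (default, matching the study's presentation) or
#'   `"bonferroni"`.
#' @return List of class `treatment_comparison`: `method`, `gate`
#'   (shapiro_p, levene_p, normal, homoscedastic), `omnibus_p`, `pairwise`
#'   (symmetric p-value matrix), `letters` (named character), `means`,
#'   `sds`, `n`, `alpha`.
#' @export
#' @examples
#' set.seed(1)
#' compare_treatments(rnorm(16, rep(c(0, 0, 0, 3), each = 4)),
#'                    rep(c("control", "cold", "salt", "cold_salt"), each = 4))
compare_treatments <- function(values, groups, alpha = 0.05,
                               dunn_adjust = c("none", "bonferroni")) {
  dunn_adjust <- match.arg(dunn_adjust)
  groups <- as.character(groups)
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  ok <- is.finite(values)
  values <- values[ok]; groups <- groups[ok]
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2)) {
    stop("insufficient replication: group(s) ",
         paste(names(tab)[tab < 2], collapse = ", "),
         " have fewer than 2 observations", call. = FALSE)
  }
  lev <- names(tab)
  g <- factor(groups, levels = lev)
  means <- tapply(values, g, mean)
  sds <- tapply(values, g, stats::sd)
  k <- length(lev)

  if (stats::var(values) == 0) {
    # fully degenerate data: nothing to test
    pw <- matrix(1, k, k, dimnames = list(lev, lev))
    return(structure(list(
      method = "degenerate (zero variance)",
      gate = list(shapiro_p = NA_real_, levene_p = NA_real_,
                  normal = NA, homoscedastic = NA),
      omnibus_p = 1, pairwise = pw,
      letters = stats::setNames(rep("a", k), lev),
      means = means, sds = sds, n = as.integer(tab), alpha = alpha
    ), class = "treatment_comparison"))
  }

  resid <- values - means[g]
  shapiro_p <- tryCatch(stats::shapiro.test(resid)$p.value,
                        error = function(e) 0)
  levene_p <- tryCatch(
    # tiny balanced groups can give a perfect fit on |y - median|; the
    # resulting p is NaN and the gate treats it as pass
    suppress_perfect_fit_warning(
      car::leveneTest(values ~ g, center = stats::median)[1, "Pr(>F)"]
    ),
    error = function(e) NA_real_
  )
  normal <- is.finite(shapiro_p) && shapiro_p > alpha
  homoscedastic <- !is.finite(levene_p) || levene_p > alpha

  pw <- matrix(NA_real_, k, k, dimnames = list(lev, lev))
  diag(pw) <- 1
  if (normal && homoscedastic) {
    method <- "ANOVA+Tukey"
    fit <- stats::aov(values ~ g)
    omnibus_p <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$g
    for (r in rownames(tk)) {
      pair <- strsplit(r, "-", fixed = TRUE)[[1]]
      pw[pair[1], pair[2]] <- pw[pair[2], pair[1]] <- tk[r, "p adj"]
    }
  } else {
    method <- "Kruskal-Wallis+Dunn"
    omnibus_p <- stats::kruskal.test(values, g)$p.value
    dn <- dunn_test(values, g, adjust = dunn_adjust)
    for (i in seq_len(nrow(dn))) {
      pw[dn$group1[i], dn$group2[i]] <-
        pw[dn$group2[i], dn$group1[i]] <- dn$p_value[i]
    }
  }
  letters <- compact_letters(pw <= alpha)
  structure(list(
    method = method,
    gate = list(shapiro_p = shapiro_p, levene_p = levene_p,
                normal = normal, homoscedastic = homoscedastic),
    omnibus_p = omnibus_p, pairwise = pw, letters = letters,
    means = means, sds = sds, n = as.integer(tab), alpha = alpha
  ), class = "treatment_comparison")
}

#' @export
print.treatment_comparison <- function(x, ...) {
  cat(sprintf("<treatment_comparison> %s, omnibus p = %.4g\n",
              x$method, x$omnibus_p))
  df <- data.frame(mean = round(x$means, 4), sd = round(x$sds, 4),
                   n = x$n, letter = x$letters[names(x$means)])
  print(df)
  invisible(x)
}

suppress_perfect_fit_warning <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

#' Dunn's rank-based pairwise test
#'
#' Post hoc companion of the Kruskal-Wallis test: pairwise z statistics on
#' mean ranks with the standard tie correction,
#' `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 - T) (1/n_i + 1/n_j))` with
#' `T = sum(t^3 - t) / (12 (N - 1))` over tie groups.
#'
#' @param values numeric measurements.
#' @param groups group labels.
#' @param adjust `"none"` (default) or `"bonferroni"`.
#' @return data.frame with columns group1, group2, z, p_value.
#' @export
dunn_test <- function(values, groups, adjust = c("none", "bonferroni")) {
  adjust <- match.arg(adjust)
  g <- factor(groups)
  n_all <- length(values)
  rk <- rank(values)
  rbar <- tapply(rk, g, mean)
  n <- tapply(rk, g, length)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n_all - 1))
  v0 <- n_all * (n_all + 1) / 12 - tie_term
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt(v0 * (1 / n[[a]] + 1 / n[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  if (adjust == "bonferroni") p <- pmin(1, p * length(p))
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p_value = p)
}

#' Compact letter display from a pairwise significance matrix
#'
#' Insert-and-absorb algorithm: groups sharing a letter are exactly the
#' groups whose pairwise difference is not significant. The returned
#' partition reproduces the significance matrix it was derived from.
#'
#' @param sig logical symmetric matrix with group names as dimnames;
#'   `TRUE` means significantly different. `NA` is treated as not
#'   significant.
#' @return Named character vector of letter codes.
#' @export
compact_letters <- function(sig) {
  lev <- rownames(sig)
  k <- length(lev)
  sig[is.na(sig)] <- FALSE
  # start with one class holding every group, then split on each
  # significant pair and absorb redundant classes
  classes <- list(seq_len(k))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (!sig[i, j]) next
      new_classes <- list()
      for (cl in classes) {
        if (i %in% cl && j %in% cl) {
          new_classes <- c(new_classes, list(setdiff(cl, i)),
                           list(setdiff(cl, j)))
        } else {
          new_classes <- c(new_classes, list(cl))
        }
      }
      # absorb: drop classes contained in another class
      keep <- rep(TRUE, length(new_classes))
      for (a in seq_along(new_classes)) {
        for (b in seq_along(new_classes)) {
          if (a != b && keep[b] &&
              all(new_classes[[a]] %in% new_classes[[b]]) &&
              (length(new_classes[[a]]) < length(new_classes[[b]]) ||
               a > b)) {
            keep[a] <- FALSE
            break
          }
        }
      }
      classes <- new_classes[keep]
    }
  }
  classes <- classes[order(vapply(classes, min, 0L))]
  out <- stats::setNames(rep("", k), lev)
  for (ci in seq_along(classes)) {
    for (m in classes[[ci]]) {
      out[m] <- paste0(out[m], letters[ci])
    }
  }
  out
}

#' Wavelength-wise trait correlogram
#'
#' Pearson correlation between one plant trait and the spectral value at
#' every band, across plants pooled over treatments and days (the study
#' pools days 1, 7 and 14). Spectra should be per-plant technical-replicate
#' means; raw/smoothed reflectance and first-derivative spectra give
#' complementary profiles.
#'
#' @param spectra list of per-plant [leaf_spectrum()] objects (any stage,
#'   shared grid).
#' @param traits wide trait data.frame with key columns species, treatment,
#'   day, plant (e.g. from [generate_experiment()]).
#' @param trait name of the trait column to correlate.
#' @param days measurement days to pool (default `c(1, 7, 14)`);
#'   `NULL` pools all.
#' @return data.frame of class `correlation_profile`: wavelength,
#'   pearson_r, p_value, n. A zero-variance trait yields `NA` correlations
#'   and a warning. No multiple-testing correction is applied (use
#'   [stats::p.adjust()] on `p_value` for a Benjamini-Hochberg variant).
#' @export
spectral_trait_correlogram <- function(spectra, traits, trait,
                                       days = c(1, 7, 14)) {
  if (!trait %in% names(traits)) {
    stop("trait '", trait, "' not found in the trait table", call. = FALSE)
  }
  if (!is.null(days)) {
    spectra <- Filter(function(s) s$meta$day %in% days, spectra)
  }
  if (length(spectra) < 3) {
    stop("need at least 3 plants with spectra", call. = FALSE)
  }
  grid <- stopifnot_shared_grid(spectra)
  key <- function(sp, tr, dy, pl) paste(sp, tr, dy, pl, sep = "|")
  tkey <- key(traits$species, traits$treatment, traits$day, traits$plant)
  y <- vapply(spectra, function(s) {
    m <- s$meta
    i <- match(key(m$species, m$treatment, m$day, m$plant), tkey)
    if (is.na(i)) NA_real_ else traits[[trait]][i]
  }, 0)
  keep <- is.finite(y)
  if (sum(keep) < 3) {
    stop("fewer than 3 plants have both a spectrum and trait '", trait, "'",
         call. = FALSE)
  }
  y <- y[keep]
  mat <- vapply(spectra[keep], function(s) s$values, numeric(length(grid)))
  if (stats::var(y) == 0) {
    warning("trait '", trait, "' has zero variance; correlations undefined",
            call. = FALSE)
    r <- rep(NA_real_, length(grid))
    p <- rep(NA_real_, length(grid))
  } else {
    n <- length(y)
    r <- as.numeric(stats::cor(t(mat), y))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  out <- data.frame(wavelength = grid, pearson_r = r, p_value = p,
                    n = length(y))
  class(out) <- c("correlation_profile", "data.frame")
  attr(out, "trait") <- trait
  out
}

#' Index-trait Pearson correlation matrix
#'
#' Correlates every vegetation index with every trait across plants pooled
#' over days 1/7/14, either over all treatments or restricted to control
#' plus one stress treatment (the per-treatment view of how well an index
#' tracks a stress indicator).
#'
#' @param idx_table long index table (one row per plant and index; average
#'   technical replicates first), columns species, treatment, day, plant,
#'   index, value.
#' @param traits wide trait table with key columns species, treatment,
#'   day, plant.
#' @param subset one of `"all"`, `"control+cold"`, `"control+salt"`,
#'   `"control+cold_salt"`.
#' @param traits_use trait columns to correlate; default all non-key
#'   numeric columns.
#' @param days days to pool (default `c(1, 7, 14)`).
#' @return data.frame: species, index, trait, r, p_value, n,
#'   insufficient (fewer than 3 paired observations).
#' @export
index_trait_correlation <- function(idx_table, traits, subset = "all",
                                    traits_use = NULL,
                                    days = c(1, 7, 14)) {
  subset <- match.arg(subset, c("all", "control+cold", "control+salt",
                                "control+cold_salt"))
  if (subset != "all") {
    keep_tr <- c("control", sub("^control\\+", "", subset))
    idx_table <- idx_table[idx_table$treatment %in% keep_tr, ]
    traits <- traits[traits$treatment %in% keep_tr, ]
  }
  if (!is.null(days)) {
    idx_table <- idx_table[idx_table$day %in% days, ]
    traits <- traits[traits$day %in% days, ]
  }
  key_cols <- c("species", "treatment", "day", "plant")
  if (is.null(traits_use)) {
    traits_use <- setdiff(names(traits)[vapply(traits, is.numeric, TRUE)],
                          c(key_cols, "plant", "day"))
  }
  key <- function(df) do.call(paste, c(df[key_cols], sep = "|"))
  tkey <- key(traits)
  out <- list()
  for (sp in unique(idx_table$species)) {
    sub_idx <- idx_table[idx_table$species == sp, ]
    for (ix in unique(sub_idx$index)) {
      cell <- sub_idx[sub_idx$index == ix, ]
      ti <- match(key(cell), tkey)
      for (tr_name in traits_use) {
        x <- cell$value
        y <- traits[[tr_name]][ti]
        ok <- is.finite(x) & is.finite(y)
        n <- sum(ok)
        if (n < 3 || stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
          out[[length(out) + 1L]] <- data.frame(
            species = sp, index = ix, trait = tr_name,
            r = NA_real_, p_value = NA_real_, n = n, insufficient = TRUE)
        } else {
          ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
          out[[length(out) + 1L]] <- data.frame(
            species = sp, index = ix, trait = tr_name,
            r = unname(ct$estimate), p_value = ct$p.value, n = n,
            insufficient = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' PRI time course with per-day treatment comparisons
#'
#' Applies the gated comparison ([compare_treatments()]) to the
#' photochemical reflectance index per species and day, returning group
#' means, standard deviations and compact letters: the study's view of how
#' the treatments separate over time.
#'
#' @param idx_table long index table containing a `"PRI"` index (one row
#'   per plant).
#' @param species species to analyze; default all present.
#' @param days days required in the table (error naming any missing day).
#' @param alpha significance level.
#' @return data.frame: species, day, treatment, mean, sd, n, letter,
#'   method, omnibus_p.
#' @export
pri_time_course <- function(idx_table, species = NULL,
                            days = c(1, 7, 14), alpha = 0.05) {
  pri <- idx_table[idx_table$index == "PRI", ]
  if (!nrow(pri)) stop("index table contains no PRI values", call. = FALSE)
  if (is.null(species)) species <- unique(pri$species)
  out <- list()
  for (sp in species) {
    sub <- pri[pri$species == sp, ]
    missing_days <- setdiff(days, unique(sub$day))
    if (length(missing_days)) {
      stop("PRI missing for day(s) ",
           paste(missing_days, collapse = ", "), " in species ", sp,
           call. = FALSE)
    }
    for (dy in days) {
      cell <- sub[sub$day == dy, ]
      cmp <- compare_treatments(cell$value, cell$treatment, alpha = alpha)
      lev <- names(cmp$means)
      out[[length(out) + 1L]] <- data.frame(
        species = sp, day = dy, treatment = lev,
        mean = as.numeric(cmp$means), sd = as.numeric(cmp$sds),
        n = cmp$n, letter = unname(cmp$letters[lev]),
        method = cmp$method, omnibus_p = cmp$omnibus_p)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
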