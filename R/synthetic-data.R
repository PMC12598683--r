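#' Generative leaf-optics parameters
#'
#' Parameter set for the analytic leaf reflectance model used by the
#' synthetic-data generator. The noiseless model is
#' `R(lambda) = V(lambda) + (r_nir - V(lambda)) * logistic((lambda - lambda0) / slope_s)`
#' where `V(lambda)` is the visible baseline: `r_vis_base` plus a Gaussian
#' green bump at 550 nm and a Gaussian red shoulder at 680 nm, both with
#' amplitudes that grow (saturating) with chlorophyll *deficit*
#' `max(0, 15 - chl_total)`. Chlorotic leaves therefore reflect more green
#' and more red light, and their red-edge inflection `lambda0` sits at
#' shorter wavelengths (see [chl_to_lambda0()]).
#'
#' @param chl_total total chlorophyll, mg/g DW (> 0).
#' @param caro carotenoids, mg/g DW (> 0).
#' @param flav flavonoids, mg/g DW (>= 0).
#' @param r_nir asymptotic near-infrared reflectance, fraction in (0, 1].
#' @param r_vis_base baseline visible reflectance, fraction.
#' @param green_peak_gain initial slope of the 550 nm bump amplitude per
#'   mg/g of chlorophyll deficit (amplitude saturates at deficit ~4 mg/g).
#' @param red_shoulder_gain same for the 680 nm red shoulder (saturation
#'   scale 12 mg/g).
#' @param lambda0 red-edge inflection wavelength, nm. Default `NULL` couples
#'   it to `chl_total` through [chl_to_lambda0()].
#' @param slope_s red-edge logistic scale, nm (> 0).
#' @param noise_sd multiplicative Gaussian noise standard deviation (>= 0).
#' @return A validated list of class `leaf_optics_params`.
#' @export
#' @examples
#' p <- leaf_optics_params()
#' p$lambda0  # coupled to the default chlorophyll content
leaf_optics_params <- function(chl_total = 10.9, caro = 3.1, flav = 1.9,
                               r_nir = 0.45, r_vis_base = 0.05,
                               green_peak_gain = 0.095,
                               red_shoulder_gain = 0.0183,
                               lambda0 = NULL, slope_s = 12,
                               noise_sd = 0.01) {
  if (!is.numeric(chl_total) || length(chl_total) != 1 ||
      !is.finite(chl_total)) {
    stop("non-finite or non-scalar leaf-optics parameter: chl_total",
         call. = FALSE)
  }
  if (chl_total <= 0) {
    stop("pigment contents must be positive (flav >= 0)", call. = FALSE)
  }
  if (is.null(lambda0)) lambda0 <- chl_to_lambda0(chl_total)
  p <- list(chl_total = chl_total, caro = caro, flav = flav,
            r_nir = r_nir, r_vis_base = r_vis_base,
            green_peak_gain = green_peak_gain,
            red_shoulder_gain = red_shoulder_gain,
            lambda0 = lambda0, slope_s = slope_s, noise_sd = noise_sd)
  num <- vapply(p, function(x) is.numeric(x) && length(x) == 1 &&
                  is.finite(x), TRUE)
  if (!all(num)) {
    stop("non-finite or non-scalar leaf-optics parameter: ",
         paste(names(p)[!num], collapse = ", "), call. = FALSE)
  }
  if (chl_total <= 0 || caro <= 0 || flav < 0) {
    stop("pigment contents must be positive (flav >= 0)", call. = FALSE)
  }
  if (r_nir <= 0 || r_nir > 1 || r_vis_base < 0 || r_vis_base >= r_nir) {
    stop("need 0 < r_vis_base < r_nir <= 1", call. = FALSE)
  }
  if (slope_s <= 0) stop("slope_s must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(p, class = "leaf_optics_params")
}

#' Chlorophyll to red-edge inflection coupling
#'
#' `lambda0 = lambda_ref + k * ln(chl / chl_ref)`: a relative chlorophyll
#' loss shifts the red-edge inflection left on a log scale. With the default
#' `k = 12` nm the chlorophyll reductions typical of two weeks of cold
#' stress (to ~ 0.53-0.66 of control) displace the red edge by about
#' 5-8 nm.
#'
#' @param chl total chlorophyll, mg/g DW.
#' @param lambda_ref inflection at the reference chlorophyll content, nm.
#' @param k coupling strength, nm per log-unit.
#' @param chl_ref reference chlorophyll content, mg/g DW.
#' @return Inflection wavelength in nm.
#' @export
chl_to_lambda0 <- function(chl, lambda_ref = 715, k = 12, chl_ref = 15) {
  lambda_ref + k * log(chl / chl_ref)
}

# Model shape constants (documented in the methods vignette):
# green bump centre/width, red shoulder centre/width, chlorophyll reference
# and amplitude saturation scales.
.optics_const <- list(
  green_center = 550, green_sigma = 45,
  red_center = 680, red_sigma = 8,
  chl_ref = 15, sat_green = 4, sat_red = 12
)

# Noiseless visible baseline V(lambda) for a parameter set.
visible_baseline <- function(params, wavelength) {
  k <- .optics_const
  deficit <- max(0, k$chl_ref - params$chl_total)
  a_green <- params$green_peak_gain * deficit / (1 + deficit / k$sat_green)
  a_red <- params$red_shoulder_gain * deficit / (1 + deficit / k$sat_red)
  params$r_vis_base +
    a_green * exp(-(wavelength - k$green_center)^2 / (2 * k$green_sigma^2)) +
    a_red * exp(-(wavelength - k$red_center)^2 / (2 * k$red_sigma^2))
}

#' Generate one synthetic leaf reflectance spectrum
#'
#' Evaluates the analytic leaf-optics model (see [leaf_optics_params()]) on
#' a wavelength grid and applies multiplicative Gaussian noise, clipping to
#' \[0, 1\]. Deterministic for a given seed.
#'
#' @param params a [leaf_optics_params()] object.
#' @param grid numeric wavelength grid in nm, strictly increasing, inside
#'   (300, 900) nm.
#' @param seed integer random seed for the noise draw.
#' @param meta sample key list passed to [leaf_spectrum()].
#' @return A raw-stage [leaf_spectrum()].
#' @export
#' @examples
#' s <- generate_leaf_spectrum(leaf_optics_params(noise_sd = 0), seed = 1)
#' plot(s$wavelength, s$values, type = "l", xlab = "nm", ylab = "R")
generate_leaf_spectrum <- function(params, grid = default_wavelength_grid(),
                                   seed = 1L, meta = list()) {
  if (!inherits(params, "leaf_optics_params")) {
    params <- do.call(leaf_optics_params, as.list(params))
  }
  validate_wavelength_grid(grid, min_len = 7L)
  if (params$lambda0 <= min(grid) || params$lambda0 >= max(grid)) {
    stop("lambda0 (", params$lambda0,
         " nm) must lie strictly inside the wavelength grid", call. = FALSE)
  }
  v <- visible_baseline(params, grid)
  sig <- stats::plogis((grid - params$lambda0) / params$slope_s)
  r <- v + (params$r_nir - v) * sig
  if (params$noise_sd > 0) {
    set.seed(as.integer(seed))
    r <- r * (1 + stats::rnorm(length(r), 0, params$noise_sd))
  }
  r <- pmin(pmax(r, 0), 1)
  leaf_spectrum(grid, r, meta = meta, stage = "raw")
}

#' Experiment design for the synthetic stress study
#'
#' Describes the factorial layout the generator emulates: species x
#' treatment x measurement day, with replicate plants and technical
#' spectral replicates per leaf. The default reproduces the study
#' conditions: 2 species, 4 treatments (control, cold, salt, cold_salt),
#' measurement days 1/4/7/11/14, 4 plants per cell, 3 technical replicates.
#'
#' @param species character vector of species labels.
#' @param treatments subset of `c("control", "cold", "salt", "cold_salt")`;
#'   must contain `"control"`.
#' @param days integer measurement days, ascending.
#' @param n_plants replicate plants per cell (>= 2).
#' @param n_tech technical spectral replicates per leaf.
#' @param effect_table data.frame with columns `species`, `treatment`, `day`,
#'   `chl_mult`, `caro_mult`, `flav_mult`, `tp_mult`, `sla_mult`,
#'   `lambda0_shift`: multiplicative treatment effects on the traits and an
#'   additive red-edge shift (nm) on top of the chlorophyll coupling.
#'   Control rows must be identity. Days between table rows are linearly
#'   interpolated. Default: [default_effect_table()].
#' @param seed integer random seed.
#' @return A validated list of class `experiment_design`.
#' @export
experiment_design <- function(species = c("annuum", "chinense"),
                              treatments = c("control", "cold", "salt",
                                             "cold_salt"),
                              days = c(1L, 4L, 7L, 11L, 14L),
                              n_plants = 4L, n_tech = 3L,
                              effect_table = default_effect_table(),
                              seed = 20260920L) {
  treatments <- match.arg(treatments,
                          c("control", "cold", "salt", "cold_salt"),
                          several.ok = TRUE)
  if (!"control" %in% treatments) {
    stop("the design must include a control treatment", call. = FALSE)
  }
  if (n_plants < 2) stop("n_plants must be >= 2", call. = FALSE)
  if (n_tech < 1) stop("n_tech must be >= 1", call. = FALSE)
  if (is.unsorted(days, strictly = TRUE)) {
    stop("days must be sorted strictly ascending", call. = FALSE)
  }
  needed <- c("species", "treatment", "day", "chl_mult", "caro_mult",
              "flav_mult", "tp_mult", "sla_mult", "lambda0_shift")
  missing_cols <- setdiff(needed, names(effect_table))
  if (length(missing_cols)) {
    stop("effect_table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ctrl <- effect_table[effect_table$treatment == "control", ]
  mult_cols <- c("chl_mult", "caro_mult", "flav_mult", "tp_mult", "sla_mult")
  if (nrow(ctrl) &&
      (any(abs(as.matrix(ctrl[, mult_cols]) - 1) > 1e-12) ||
       any(ctrl$lambda0_shift != 0))) {
    stop("control effects must be identity (multiplier 1, shift 0)",
         call. = FALSE)
  }
  for (sp in species) {
    for (tr in setdiff(treatments, "control")) {
      if (!any(effect_table$species == sp & effect_table$treatment == tr)) {
        stop("effect_table has no rows for design cell (", sp, ", ", tr, ")",
             call. = FALSE)
      }
    }
  }
  structure(
    list(species = species, treatments = treatments, days = as.integer(days),
         n_plants = as.integer(n_plants), n_tech = as.integer(n_tech),
         effect_table = effect_table, seed = as.integer(seed)),
    class = "experiment_design"
  )
}

#' Default treatment effect table
#'
#' Multiplicative treatment effects on chlorophyll, carotenoids, flavonoids,
#' total phenolics and specific leaf area for the two pepper species at
#' days 1, 7 and 14: the ratios of the stressed group means to the control
#' group means of the study's destructive trait tables. Cold halves
#' chlorophyll by day 14, salt slightly increases it in *C. annuum* and
#' mildly decreases it in *C. chinense*, and the combined stress is
#' intermediate. `lambda0_shift` is 0 everywhere: the red-edge displacement
#' emerges from the chlorophyll coupling of [chl_to_lambda0()].
#'
#' @return A data.frame usable as `effect_table` in [experiment_design()].
#' @export
default_effect_table <- function() {
  row <- function(sp, tr, day, chl, caro, flav, tp, sla) {
    data.frame(species = sp, treatment = tr, day = day, chl_mult = chl,
               caro_mult = caro, flav_mult = flav, tp_mult = tp,
               sla_mult = sla, lambda0_shift = 0)
  }
  rbind(
    row("annuum", "control", 1, 1, 1, 1, 1, 1),
    row("annuum", "control", 7, 1, 1, 1, 1, 1),
    row("annuum", "control", 14, 1, 1, 1, 1, 1),
    row("annuum", "cold", 1, 0.879, 0.909, 1.257, 1.274, 0.610),
    row("annuum", "cold", 7, 0.610, 0.640, 1.300, 1.078, 0.826),
    row("annuum", "cold", 14, 0.564, 0.615, 2.330, 1.724, 0.727),
    row("annuum", "salt", 1, 1.188, 1.168, 1.316, 1.270, 0.829),
    row("annuum", "salt", 7, 1.266, 1.236, 1.725, 1.514, 1.087),
    row("annuum", "salt", 14, 1.242, 1.235, 1.473, 1.642, 1.000),
    row("annuum", "cold_salt", 1, 0.980, 1.002, 1.257, 1.252, 0.780),
    row("annuum", "cold_salt", 7, 0.878, 0.890, 2.302, 1.701, 0.870),
    row("annuum", "cold_salt", 14, 0.843, 0.884, 2.412, 2.020, 0.909),
    row("chinense", "control", 1, 1, 1, 1, 1, 1),
    row("chinense", "control", 7, 1, 1, 1, 1, 1),
    row("chinense", "control", 14, 1, 1, 1, 1, 1),
    row("chinense", "cold", 1, 0.923, 0.951, 1.095, 1.074, 0.882),
    row("chinense", "cold", 7, 0.611, 0.663, 2.389, 1.295, 0.800),
    row("chinense", "cold", 14, 0.534, 0.620, 3.405, 2.812, 0.947),
    row("chinense", "salt", 1, 1.008, 0.997, 0.861, 0.812, 0.912),
    row("chinense", "salt", 7, 0.965, 0.929, 2.205, 1.860, 1.120),
    row("chinense", "salt", 14, 0.878, 0.902, 1.440, 2.641, 1.053),
    row("chinense", "cold_salt", 1, 1.214, 1.263, 0.936, 1.071, 0.794),
    row("chinense", "cold_salt", 7, 0.764, 0.798, 2.589, 1.860, 0.880),
    row("chinense", "cold_salt", 14, 0.660, 0.787, 4.612, 2.641, 1.368)
  )
}

# Interpolate effect-table multipliers to an arbitrary day (constant
# extrapolation beyond the tabulated range).
interp_effects <- function(effect_table, species, treatment, day) {
  sub <- effect_table[effect_table$species == species &
                        effect_table$treatment == treatment, ]
  if (!nrow(sub)) {
    stop("effect_table has no rows for (", species, ", ", treatment, ")",
         call. = FALSE)
  }
  sub <- sub[order(sub$day), ]
  cols <- c("chl_mult", "caro_mult", "flav_mult", "tp_mult", "sla_mult",
            "lambda0_shift")
  out <- lapply(cols, function(cl) {
    if (nrow(sub) == 1) return(sub[[cl]])
    stats::approx(sub$day, sub[[cl]], xout = day, rule = 2)$y
  })
  stats::setNames(out, cols)
}

#' Generate a full synthetic stress experiment
#'
#' For every (species, treatment, day, plant, technical replicate) cell of
#' the design, draws a plant-level trait vector (lognormal biological
#' variation around the treatment-cell mean) and generates the matching
#' reflectance spectrum, with the red-edge inflection coupled to the plant's
#' chlorophyll. Returns the spectra together with the generative
#' ground-truth trait table (long format is available through
#' [write_trait_table()]).
#'
#' @param design an [experiment_design()].
#' @param base a [leaf_optics_params()] giving the optics and control-level
#'   trait means (chl, caro, flav).
#' @param bio_cv lognormal coefficient of variation of plant-level traits.
#' @param tp_base,sla_base control-level means for total phenolics
#'   (mg/g DW) and specific leaf area (cm2/mg).
#' @param growth optional output of [generate_growth_and_color()]; if
#'   `NULL`, generated with default targets so that the trait table carries
#'   `rgr_pla` and `exg` columns.
#' @return List with `spectra` (list of raw [leaf_spectrum()]) and `traits`
#'   (wide data.frame, one row per species/treatment/day/plant).
#' @export
generate_experiment <- function(design = experiment_design(),
                                base = leaf_optics_params(),
                                bio_cv = 0.08,
                                tp_base = 7.5, sla_base = 0.25,
                                growth = NULL) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(design$seed)
  if (is.null(growth)) {
    growth <- generate_growth_and_color(design, seed = design$seed + 1L)
  }
  spectra <- list()
  traits <- list()
  spec_seed <- design$seed
  for (sp in design$species) {
    for (tr in design$treatments) {
      # plant-level biological factors persist across days
      plant_fac <- matrix(
        exp(stats::rnorm(design$n_plants * 5, 0, bio_cv)),
        nrow = design$n_plants
      )
      for (day in design$days) {
        eff <- interp_effects(design$effect_table, sp, tr, day)
        for (pl in seq_len(design$n_plants)) {
          chl <- base$chl_total * eff$chl_mult * plant_fac[pl, 1]
          caro <- base$caro * eff$caro_mult * plant_fac[pl, 2]
          flav <- base$flav * eff$flav_mult * plant_fac[pl, 3]
          tp <- tp_base * eff$tp_mult * plant_fac[pl, 4]
          sla <- sla_base * eff$sla_mult * plant_fac[pl, 5]
          lam0 <- chl_to_lambda0(chl) + eff$lambda0_shift
          p <- leaf_optics_params(
            chl_total = chl, caro = caro, flav = flav,
            r_nir = base$r_nir, r_vis_base = base$r_vis_base,
            green_peak_gain = base$green_peak_gain,
            red_shoulder_gain = base$red_shoulder_gain,
            lambda0 = lam0, slope_s = base$slope_s,
            noise_sd = base$noise_sd
          )
          for (te in seq_len(design$n_tech)) {
            spec_seed <- spec_seed + 1L
            meta <- list(species = sp, treatment = tr, day = day,
                         plant = pl, tech_rep = te)
            spectra[[length(spectra) + 1L]] <-
              generate_leaf_spectrum(p, seed = spec_seed, meta = meta)
          }
          gr <- growth[growth$species == sp & growth$treatment == tr &
                         growth$plant == pl & growth$day == day, ]
          traits[[length(traits) + 1L]] <- data.frame(
            species = sp, treatment = tr, day = day, plant = pl,
            chl_total = chl, caro = caro, flav = flav,
            chl_a_b_ratio = 6.7 * exp(stats::rnorm(1, 0, 0.03)),
            caro_chl_ratio = caro / chl,
            tp = tp, tf = flav, sla = sla,
            rgr_pla = if (nrow(gr)) gr$rgr_pla[1] else NA_real_,
            exg = if (nrow(gr)) {
              2 * gr$mean_g[1] - gr$mean_r[1] - gr$mean_b[1]
            } else NA_real_
          )
        }
      }
    }
  }
  list(spectra = spectra, traits = do.call(rbind, traits))
}

#' Invert the pigment equations to absorbances
#'
#' Solves the linear spectrophotometric system exactly so that
#' [pigment_concentrations()] applied to the result recovers the requested
#' chlorophyll a, chlorophyll b and carotenoid concentrations (to machine
#' precision). Used to build synthetic plate readings with known truth.
#'
#' @param chl_a,chl_b,caro concentrations in the measured extract, ug/mL
#'   (vectorized, all >= 0).
#' @return data.frame with columns `a470`, `a6524`, `a6652`.
#' @export
#' @examples
#' generate_absorbances(5.612, 2.587, 2)  # A665.2 = 0.5, A652.4 = 0.3
generate_absorbances <- function(chl_a, chl_b, caro) {
  if (any(!is.finite(chl_a)) || any(!is.finite(chl_b)) ||
      any(!is.finite(caro))) {
    stop("concentrations must be finite", call. = FALSE)
  }
  if (any(chl_a < 0) || any(chl_b < 0) || any(caro < 0)) {
    stop("concentrations must be >= 0", call. = FALSE)
  }
  det <- 16.72 * 34.09 - 9.16 * 15.28
  a6652 <- (34.09 * chl_a + 9.16 * chl_b) / det
  a6524 <- (15.28 * chl_a + 16.72 * chl_b) / det
  a470 <- (221 * caro + 1.63 * chl_a + 104.96 * chl_b) / 1000
  if (any(a470 < 0) || any(a6524 < 0) || any(a6652 < 0)) {
    stop("requested concentrations imply negative absorbance", call. = FALSE)
  }
  data.frame(a470 = a470, a6524 = a6524, a6652 = a6652)
}

#' Generate plant-image summary tables (growth and color)
#'
#' Produces a projected-leaf-area (PLA) time series per plant whose
#' noiseless per-interval log-growth matches the per-treatment relative
#' growth rate targets, and mean R/G/B channel values whose noiseless
#' excess greenness matches the color targets (linearly approached from a
#' common healthy starting value over the time course). A day-0 baseline
#' row is included so growth rates can be computed for the first interval.
#'
#' @param design an [experiment_design()].
#' @param rgr_targets named numeric vector, %/day per treatment.
#' @param exg_targets named numeric vector, day-14 excess greenness target
#'   per treatment (0-255 channel scale; day 0 starts at `exg_start`).
#' @param seed integer random seed.
#' @param pla0 initial projected leaf area (arbitrary units, > 0).
#' @param exg_start healthy excess greenness at day 0.
#' @param pla_noise_sd lognormal noise sd on PLA; `exg_noise_sd` additive
#'   noise sd on the green channel.
#' @param exg_noise_sd see above.
#' @return data.frame with columns species, treatment, plant, day, pla,
#'   mean_r, mean_g, mean_b, rgr_pla (log-growth rate over the interval
#'   ending at `day`, %/day; `NA` at day 0).
#' @export
generate_growth_and_color <- function(design = experiment_design(),
                                      rgr_targets = c(control = 8, cold = 2,
                                                      salt = 6,
                                                      cold_salt = 2.5),
                                      exg_targets = c(control = 90, cold = 60,
                                                      salt = 85,
                                                      cold_salt = 65),
                                      seed = design$seed + 1L,
                                      pla0 = 50, exg_start = 90,
                                      pla_noise_sd = 0.04,
                                      exg_noise_sd = 2) {
  stopifnot(inherits(design, "experiment_design"))
  missing_tr <- setdiff(design$treatments, names(rgr_targets))
  if (length(missing_tr)) {
    stop("rgr_targets missing treatments: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  missing_tr <- setdiff(design$treatments, names(exg_targets))
  if (length(missing_tr)) {
    stop("exg_targets missing treatments: ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  if (pla0 <= 0) stop("initial PLA must be > 0", call. = FALSE)
  set.seed(as.integer(seed))
  days <- c(0L, design$days)
  horizon <- max(days)
  out <- list()
  for (sp in design$species) {
    for (tr in design$treatments) {
      rgr <- rgr_targets[[tr]]
      exg_end <- exg_targets[[tr]]
      for (pl in seq_len(design$n_plants)) {
        pla_true <- pla0 * exp(rgr / 100 * days)
        pla <- pla_true * exp(stats::rnorm(length(days), 0,
                                           pla_noise_sd))
        exg_true <- exg_start + (exg_end - exg_start) * days / horizon
        mean_r <- rep(60, length(days))
        mean_b <- rep(40, length(days))
        mean_g <- (exg_true + mean_r + mean_b) / 2 +
          stats::rnorm(length(days), 0, exg_noise_sd)
        rgr_obs <- c(NA_real_,
                     100 * diff(log(pla)) / diff(days))
        out[[length(out) + 1L]] <- data.frame(
          species = sp, treatment = tr, plant = pl, day = days,
          pla = pla, mean_r = mean_r, mean_g = mean_g, mean_b = mean_b,
          rgr_pla = rgr_obs
        )
      }
    }
  }
  do.call(rbind, out)
}
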