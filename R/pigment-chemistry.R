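#' Pigment concentrations from spectrophotometric absorbances
#'
#' Converts absorbances of a methanolic leaf extract measured at 470,
#' 652.4 and 665.2 nm into chlorophyll a, chlorophyll b, total chlorophyll
#' and total carotenoid concentrations with the standard linear
#' coefficients for methanol:
#' \deqn{C_a = 16.72 A_{665.2} - 9.16 A_{652.4}}
#' \deqn{C_b = 34.09 A_{652.4} - 15.28 A_{665.2}}
#' \deqn{C_{a+b} = 1.44 A_{665.2} + 24.93 A_{652.4}}
#' \deqn{C_{x+c} = (1000 A_{470} - 1.63 C_a - 104.96 C_b) / 221}
#' The printed coefficients satisfy the identity `C_a + C_b = C_{a+b}` up
#' to rounding of the third decimal. Negative computed concentrations are
#' flagged, never silently clipped: a negative value signals an assay or
#' blank problem and clipping would bias group means.
#'
#' @param a470,a6524,a6652 absorbances (vectorized, >= 0, finite). A single
#'   data.frame with columns `a470`, `a6524`, `a6652` may be given as the
#'   first argument instead.
#' @return data.frame with columns `chl_a`, `chl_b`, `chl_total`, `caro`
#'   (ug/mL) and logical `flag_negative`.
#' @export
#' @examples
#' pigment_concentrations(0.8, 0.3, 0.5)  # chl_a 5.612, chl_b 2.587
pigment_concentrations <- function(a470, a6524 = NULL, a6652 = NULL) {
  if (is.data.frame(a470)) {
    df <- a470
    a470 <- df$a470; a6524 <- df$a6524; a6652 <- df$a6652
  }
  absorb <- c(a470, a6524, a6652)
  if (any(!is.finite(absorb))) {
    stop("absorbances must be finite", call. = FALSE)
  }
  if (any(absorb < 0)) stop("absorbances must be >= 0", call. = FALSE)
  chl_a <- 16.72 * a6652 - 9.16 * a6524
  chl_b <- 34.09 * a6524 - 15.28 * a6652
  chl_total <- 1.44 * a6652 + 24.93 * a6524
  caro <- (1000 * a470 - 1.63 * chl_a - 104.96 * chl_b) / 221
  data.frame(chl_a = chl_a, chl_b = chl_b, chl_total = chl_total,
             caro = caro,
             flag_negative = chl_a < 0 | chl_b < 0 | caro < 0)
}

#' Extraction parameters
#'
#' Mass/volume bookkeeping of the pigment and phenolic extractions: the
#' default 17.5 mg of ground leaf material in 2 mL extraction solution with
#' a 1:2 dilution before reading matches the pigment assay; the phenolic
#' assays use their own parameters (no dilution).
#'
#' @param sample_mass mg ground leaf material (> 0).
#' @param solvent_volume mL (> 0).
#' @param dilution_factor unitless (>= 1).
#' @return List of class `extraction_params`.
#' @export
extraction_params <- function(sample_mass = 17.5, solvent_volume = 2,
                              dilution_factor = 2) {
  if (!all(is.finite(c(sample_mass, solvent_volume, dilution_factor)))) {
    stop("extraction parameters must be finite", call. = FALSE)
  }
  if (sample_mass <= 0 || solvent_volume <= 0) {
    stop("sample_mass and solvent_volume must be > 0", call. = FALSE)
  }
  if (dilution_factor < 1) {
    stop("dilution_factor must be >= 1", call. = FALSE)
  }
  structure(list(sample_mass = sample_mass,
                 solvent_volume = solvent_volume,
                 dilution_factor = dilution_factor),
            class = "extraction_params")
}

#' Convert an extract concentration to a dry-weight basis
#'
#' `mg/g DW = c * solvent_volume * dilution_factor / sample_mass`
#' (ug/mL x mL / mg is numerically mg/g).
#'
#' @param conc concentration in the measured (diluted) extract, ug/mL.
#' @param e an [extraction_params()] object.
#' @return Concentration in mg per g dry weight.
#' @export
#' @examples
#' to_dry_weight_basis(10, extraction_params(20, 2, 2))  # 2 mg/g DW
to_dry_weight_basis <- function(conc, e = extraction_params()) {
  stopifnot(inherits(e, "extraction_params"))
  conc * e$solvent_volume * e$dilution_factor / e$sample_mass
}

#' Fit a linear calibration curve
#'
#' Ordinary least-squares line `absorbance = slope * concentration +
#' intercept` through standard dilutions of gallic acid (total phenolics,
#' Folin-Ciocalteu assay) or luteolin (flavonoids, aluminum chloride
#' assay).
#'
#' @param concentration standard concentrations (mg/mL), >= 3 values with
#'   >= 2 distinct levels.
#' @param absorbance measured absorbances, same length.
#' @param standard_name label, e.g. `"gallic_acid"` or `"luteolin"`.
#' @return List of class `calibration_curve` with `slope`, `intercept`,
#'   `r_squared`, `standard_name`, `n`.
#' @export
fit_calibration_curve <- function(concentration, absorbance,
                                  standard_name = "gallic_acid") {
  if (length(concentration) != length(absorbance)) {
    stop("concentration and absorbance must have equal length",
         call. = FALSE)
  }
  if (length(concentration) < 3) {
    stop("need at least 3 standards", call. = FALSE)
  }
  if (length(unique(concentration)) < 2) {
    stop("standards must span at least 2 distinct concentrations",
         call. = FALSE)
  }
  fit <- stats::lm(absorbance ~ concentration)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope <= 0) {
    stop("calibration slope must be positive; got ", format(slope),
         call. = FALSE)
  }
  r2 <- suppressWarnings(summary(fit))$r.squared  # exact lines warn in summary.lm
  structure(list(standard_name = standard_name, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2, n = length(concentration)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve: %s> A = %.4g c + %.4g (r2 = %.4f, n = %d)\n",
              x$standard_name, x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Quantify a sample in standard equivalents
#'
#' Inverts a calibration curve, `conc = (A - intercept) / slope` (after
#' optional per-sample blank subtraction), and converts to mg per g dry
#' weight with [to_dry_weight_basis()]. Negative concentrations (sample
#' absorbance below the intercept) are returned as-is with a
#' below-detection flag. The curve concentration is passed to the
#' dry-weight formula unscaled, so express the standards in ug/mL if
#' mg/g DW output is wanted.
#'
#' @param sample_abs sample absorbance(s).
#' @param curve a [fit_calibration_curve()] result.
#' @param e an [extraction_params()] object for the assay.
#' @param blank_abs per-sample blank absorbance subtracted from
#'   `sample_abs` before quantification (default 0; the flavonoid assay
#'   reads a water blank per sample).
#' @return data.frame with `equivalents_mg_g` and `below_detection`.
#' @export
quantify_equivalents <- function(sample_abs, curve,
                                 e = extraction_params(20, 2, 1),
                                 blank_abs = 0) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("invalid calibration curve (slope 0)",
                             call. = FALSE)
  conc <- (sample_abs - blank_abs - curve$intercept) / curve$slope
  mg_g <- to_dry_weight_basis(conc, e)
  data.frame(equivalents_mg_g = mg_g, below_detection = conc < 0)
}
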