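#' Leaf reflectance spectra
#'
#' A `leaf_spectrum` is the pipeline's atomic object: a wavelength grid (nm),
#' one reflectance (or first-derivative) value per band, and a sample key
#' identifying species, treatment, day, plant and technical replicate.
#' Reflectance is stored internally as a fraction of the white reference
#' (0 to 1); tables supplied in percent are auto-detected and rescaled.
#'
#' @param wavelength numeric vector of band centers in nm, strictly increasing.
#' @param values numeric vector of reflectance (fraction) or derivative values,
#'   same length as `wavelength`.
#' @param meta named list with elements `species`, `treatment`, `day`, `plant`,
#'   `tech_rep`; missing elements are filled with `NA`.
#' @param stage one of `"raw"`, `"smoothed"`, `"derivative"`.
#' @param delta_lambda nominal band interval in nm (only meaningful for
#'   derivative spectra).
#'
#' @return An object of class `leaf_spectrum`.
#' @export
#' @examples
#' g <- default_wavelength_grid()
#' s <- leaf_spectrum(g, rep(0.2, length(g)))
#' s
leaf_spectrum <- function(wavelength, values,
                          meta = list(), stage = "raw",
                          delta_lambda = NULL) {
  wavelength <- as.numeric(wavelength)
  values <- as.numeric(values)
  validate_wavelength_grid(wavelength, min_len = 1L)
  if (length(values) != length(wavelength)) {
    stop("`values` must have one entry per wavelength band (",
         length(values), " values, ", length(wavelength), " bands)",
         call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("reflectance values must be finite", call. = FALSE)
  }
  stage <- match.arg(stage, c("raw", "smoothed", "derivative"))
  if (stage != "derivative") {
    values <- normalize_reflectance_unit(values)
    if (any(values < 0 | values > 1)) {
      stop("reflectance must lie in [0, 1] after unit normalization",
           call. = FALSE)
    }
  }
  key_fields <- c("species", "treatment", "day", "plant", "tech_rep")
  full_meta <- stats::setNames(as.list(rep(NA, length(key_fields))), key_fields)
  full_meta[names(meta)] <- meta
  structure(
    list(wavelength = wavelength, values = values, meta = full_meta,
         stage = stage, delta_lambda = delta_lambda),
    class = "leaf_spectrum"
  )
}

#' @export
print.leaf_spectrum <- function(x, ...) {
  rng <- range(x$wavelength)
  cat(sprintf("<leaf_spectrum [%s]> %d bands, %.1f-%.1f nm\n",
              x$stage, length(x$wavelength), rng[1], rng[2]))
  m <- x$meta
  cat(sprintf("  sample: %s | %s | day %s | plant %s | rep %s\n",
              m$species, m$treatment, m$day, m$plant, m$tech_rep))
  invisible(x)
}

#' Default instrument wavelength grid
#'
#' The handheld leaf-clip spectroradiometer emulated by the synthetic module
#' covers 325.8 to 789.9 nm in 258 bands (nominal band interval 1.8 nm).
#'
#' @param n number of bands.
#' @param from,to grid limits in nm.
#' @return Numeric vector of band centers (nm).
#' @export
default_wavelength_grid <- function(n = 258L, from = 325.8, to = 789.9) {
  seq(from, to, length.out = n)
}

# Shared grid validator. Visible/NIR leaf spectroscopy only: reject grids
# outside (300, 900) nm, non-finite or non-increasing grids.
validate_wavelength_grid <- function(wavelength, min_len = 7L) {
  if (length(wavelength) < min_len) {
    stop("wavelength grid needs at least ", min_len, " bands", call. = FALSE)
  }
  if (!all(is.finite(wavelength))) {
    stop("wavelength grid contains non-finite values", call. = FALSE)
  }
  if (length(wavelength) > 1 && any(diff(wavelength) <= 0)) {
    stop("wavelength grid must be strictly increasing", call. = FALSE)
  }
  if (min(wavelength) <= 300 || max(wavelength) >= 900) {
    stop("wavelength grid must lie strictly inside (300, 900) nm",
         call. = FALSE)
  }
  invisible(wavelength)
}

# Percent-scale reflectance (max > 1.5) is auto-converted to fractions.
normalize_reflectance_unit <- function(values, quiet = FALSE) {
  if (length(values) && max(values, na.rm = TRUE) > 1.5) {
    if (!quiet) {
      message("reflectance looks percent-scaled (max ",
              format(max(values, na.rm = TRUE), digits = 4),
              "); dividing by 100")
    }
    values <- values / 100
  }
  values
}

# Sample key as a single string, used for grouping and table headers.
spectrum_key <- function(s, with_rep = TRUE) {
  m <- s$meta
  parts <- c(m$species, m$treatment, m$day, m$plant,
             if (with_rep) m$tech_rep)
  paste(parts, collapse = "|")
}

stopifnot_shared_grid <- function(spectra) {
  if (!length(spectra)) stop("empty spectrum collection", call. = FALSE)
  g <- spectra[[1]]$wavelength
  for (s in spectra[-1]) {
    if (length(s$wavelength) != length(g) ||
        max(abs(s$wavelength - g)) > 1e-9) {
      stop("spectra do not share a common wavelength grid", call. = FALSE)
    }
  }
  g
}
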