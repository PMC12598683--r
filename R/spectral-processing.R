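#' Three-point weighted-mean smoothing of a reflectance spectrum
#'
#' Each interior band is replaced by a weighted mean of itself and its two
#' neighbours, `R_i = 0.5 Ref_i + 0.25 Ref_{i+1} + 0.25 Ref_{i-1}`.
#' The two endpoint bands have no full neighbourhood and are copied
#' unchanged, which keeps the smoothed grid aligned with the raw grid
#' (raw and smoothed spectra are used jointly in wavelength-wise
#' correlograms).
#'
#' @param s a [leaf_spectrum()] (stage `"raw"`) or a numeric vector.
#' @return A `leaf_spectrum` with stage `"smoothed"` (or a numeric vector if
#'   a vector was supplied).
#' @export
#' @examples
#' smooth_spectrum(c(0.1, 0.2, 0.3))  # interior band is a fixed point: 0.2
smooth_spectrum <- function(s) {
  vec_in <- is.numeric(s)
  v <- if (vec_in) as.numeric(s) else s$values
  n <- length(v)
  if (n < 3) stop("smoothing needs at least 3 bands", call. = FALSE)
  if (!all(is.finite(v))) stop("non-finite reflectance", call. = FALSE)
  out <- v
  idx <- 2:(n - 1)
  out[idx] <- 0.5 * v[idx] + 0.25 * v[idx + 1] + 0.25 * v[idx - 1]
  if (vec_in) return(out)
  res <- s
  res$values <- out
  res$stage <- "smoothed"
  res
}

#' First derivative of a smoothed reflectance spectrum
#'
#' Implements the band-window derivative
#' `rho_i = ((sum_{j=i+1..i+3} R_j - sum_{j=i-3..i-1} R_j) / 3) / delta_lambda`.
#' The three forward and three backward bands form means centred 4 bands
#' apart, so on a linear ramp of slope `b` the literal formula returns `4 b`:
#' it is applied literally (matching the published processing chain) because
#' peak *positions*, the quantity of interest, are invariant to constant
#' scaling. `slope_consistent = TRUE` divides by 4 to recover the true
#' per-nm slope. Three bands at each end have no full window and are
#' dropped from the output grid.
#'
#' @param s a smoothed [leaf_spectrum()] or numeric vector.
#' @param delta_lambda nominal band interval in nm (default 1.8). Used as a
#'   constant even on slightly non-uniform grids.
#' @param slope_consistent divide by 4 so that a linear ramp returns its
#'   true slope. Default `FALSE` (literal formula).
#' @param wavelength required when `s` is a numeric vector.
#' @return A `leaf_spectrum` of stage `"derivative"` on the trimmed grid,
#'   or a plain numeric vector for vector input.
#' @export
first_derivative <- function(s, delta_lambda = 1.8, slope_consistent = FALSE,
                             wavelength = NULL) {
  if (delta_lambda <= 0) stop("delta_lambda must be > 0", call. = FALSE)
  vec_in <- is.numeric(s)
  v <- if (vec_in) as.numeric(s) else s$values
  n <- length(v)
  if (n < 7) stop("derivative needs at least 7 bands", call. = FALSE)
  idx <- 4:(n - 3)
  fwd <- v[idx + 1] + v[idx + 2] + v[idx + 3]
  bwd <- v[idx - 1] + v[idx - 2] + v[idx - 3]
  rho <- ((fwd - bwd) / 3) / delta_lambda
  if (slope_consistent) rho <- rho / 4
  if (vec_in) return(rho)
  res <- s
  res$wavelength <- s$wavelength[idx]
  res$values <- rho
  res$stage <- "derivative"
  res$delta_lambda <- delta_lambda
  res
}

#' Average technical replicates of one plant
#'
#' Per-band arithmetic mean of several spectra of the same leaf. All spectra
#' must share one wavelength grid and one (species, treatment, day, plant)
#' key; the returned spectrum carries `tech_rep = "mean"`.
#'
#' @param spectra list of [leaf_spectrum()] objects.
#' @return A single `leaf_spectrum`.
#' @export
average_technical_replicates <- function(spectra) {
  if (inherits(spectra, "leaf_spectrum")) spectra <- list(spectra)
  stopifnot_shared_grid(spectra)
  keys <- vapply(spectra, spectrum_key, "", with_rep = FALSE)
  if (length(unique(keys)) != 1) {
    stop("technical replicates span multiple plant keys: ",
         paste(unique(keys), collapse = ", "), call. = FALSE)
  }
  stages <- unique(vapply(spectra, function(s) s$stage, ""))
  if (length(stages) != 1) {
    stop("cannot average spectra at different processing stages",
         call. = FALSE)
  }
  vals <- rowMeans(vapply(spectra, function(s) s$values,
                          numeric(length(spectra[[1]]$values))))
  res <- spectra[[1]]
  res$values <- vals
  res$meta$tech_rep <- "mean"
  res
}

#' Locate the red-edge peak of a first-derivative spectrum
#'
#' The red edge is the steep reflectance rise between roughly 690 and 750 nm;
#' its inflection appears as the maximum of the first derivative. The peak is
#' located either as the argmax band inside `window` (ties broken toward the
#' lowest wavelength) or, with `interpolate = TRUE`, as the vertex of the
#' parabola through the argmax band and its two neighbours.
#'
#' @param d a derivative [leaf_spectrum()].
#' @param window numeric length-2, search window in nm. Default `c(690, 750)`.
#' @param interpolate parabolic sub-band refinement of the peak position.
#' @return List of class `red_edge_feature` with `peak_wavelength`,
#'   `peak_value`, `window`, `interpolated`, `degenerate`.
#' @export
red_edge_peak <- function(d, window = c(690, 750), interpolate = FALSE) {
  if (!inherits(d, "leaf_spectrum") || d$stage != "derivative") {
    stop("`d` must be a derivative spectrum", call. = FALSE)
  }
  in_win <- which(d$wavelength >= window[1] & d$wavelength <= window[2])
  if (length(in_win) < 3) {
    stop("red-edge window [", window[1], ", ", window[2],
         "] nm covers fewer than 3 bands of the derivative grid",
         call. = FALSE)
  }
  rho <- d$values[in_win]
  wl <- d$wavelength[in_win]
  degenerate <- diff(range(rho)) == 0
  if (degenerate) {
    warning("all derivative values equal inside the red-edge window; ",
            "degenerate peak at the lowest wavelength", call. = FALSE)
  }
  k <- which(rho == max(rho))[1]  # tie -> lowest wavelength
  peak_wl <- wl[k]
  peak_val <- rho[k]
  interpolated <- FALSE
  if (interpolate && !degenerate && k > 1 && k < length(rho)) {
    # parabola through (wl[k-1..k+1], rho[k-1..k+1]); vertex in closed form
    y1 <- rho[k - 1]; y2 <- rho[k]; y3 <- rho[k + 1]
    x1 <- wl[k - 1]; x2 <- wl[k]; x3 <- wl[k + 1]
    denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
    a <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
    b <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
    if (a < 0) {
      peak_wl <- -b / (2 * a)
      peak_val <- y2  # value at the sampled argmax band
      interpolated <- TRUE
    }
  }
  structure(
    list(peak_wavelength = peak_wl, peak_value = peak_val,
         window = window, interpolated = interpolated,
         degenerate = degenerate),
    class = "red_edge_feature"
  )
}

#' @export
print.red_edge_feature <- function(x, ...) {
  cat(sprintf("<red_edge_feature> peak %.2f nm (rho = %.4g)%s, window %g-%g nm\n",
              x$peak_wavelength, x$peak_value,
              if (x$interpolated) ", parabolic" else "",
              x$window[1], x$window[2]))
  invisible(x)
}

#' Red-edge peak shift between two groups of derivative spectra
#'
#' Averages each group's derivative spectra per band, locates the red-edge
#' peak of both mean derivatives, and returns the displacement
#' `peak(group_b) - peak(group_a)` in nm. Negative values mean group_b's
#' red edge sits at shorter wavelengths (the chlorosis direction).
#'
#' @param group_a,group_b lists of derivative [leaf_spectrum()] objects on a
#'   shared grid (e.g. control vs. a stress treatment).
#' @param window,interpolate passed to [red_edge_peak()].
#' @param per_plant if `TRUE`, peaks are located per spectrum and their group
#'   means differenced, instead of locating one peak on each group-mean
#'   derivative (the default).
#' @return Signed shift in nm.
#' @export
red_edge_shift <- function(group_a, group_b, window = c(690, 750),
                           interpolate = FALSE, per_plant = FALSE) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must contain at least one spectrum", call. = FALSE)
  }
  stopifnot_shared_grid(c(group_a, group_b))
  peak_of <- function(group) {
    if (per_plant) {
      mean(vapply(group, function(s) {
        red_edge_peak(s, window, interpolate)$peak_wavelength
      }, 0))
    } else {
      red_edge_peak(mean_spectrum(group), window, interpolate)$peak_wavelength
    }
  }
  peak_of(group_b) - peak_of(group_a)
}

# Per-band mean of a list of spectra sharing a grid; meta collapsed.
mean_spectrum <- function(spectra) {
  stopifnot_shared_grid(spectra)
  res <- spectra[[1]]
  res$values <- rowMeans(vapply(spectra, function(s) s$values,
                                numeric(length(res$values))))
  res$meta$plant <- "mean"
  res$meta$tech_rep <- "mean"
  res
}

#' Mean difference spectrum between two groups
#'
#' Computes the per-band difference `mean(group_b) - mean(group_a)` and the
#' wavelength at which its absolute value is largest (ties toward the lowest
#' wavelength). Used to ask where along the spectrum a stress treatment
#' separates most strongly from the control.
#'
#' @param group_a,group_b lists of [leaf_spectrum()] objects on a shared
#'   grid and at a shared processing stage.
#' @return List with `wavelength`, `difference`, `argmax_wavelength`,
#'   `max_abs_difference`, `degenerate`.
#' @export
difference_spectrum <- function(group_a, group_b) {
  ga <- mean_spectrum(group_a)
  gb <- mean_spectrum(group_b)
  stopifnot_shared_grid(list(ga, gb))
  d <- gb$values - ga$values
  degenerate <- all(d == 0)
  if (degenerate) {
    warning("groups are identical; difference spectrum is all zero",
            call. = FALSE)
  }
  k <- which(abs(d) == max(abs(d)))[1]
  list(wavelength = ga$wavelength, difference = d,
       argmax_wavelength = ga$wavelength[k],
       max_abs_difference = abs(d[k]), degenerate = degenerate)
}
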