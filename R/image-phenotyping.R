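#' Greenness-threshold plant segmentation
#'
#' Minimal segmenter for top-view plant images: a pixel belongs to the
#' plant iff `2G - R - B > threshold` on the 0-255 channel scale. Intended
#' as plumbing for synthetic fixtures; the pipeline's primary input is a
#' precomputed PLA/RGB summary table.
#'
#' @param image numeric array `height x width x 3` (R, G, B). Values in
#'   \[0, 1\] are rescaled to 0-255.
#' @param threshold excess-greenness cutoff (default 20).
#' @param meta optional plant key list (`species`, `treatment`, `day`,
#'   `plant`).
#' @return List with `mask` (logical matrix) and `record`: a one-row
#'   data.frame with `pla` (mask pixel count) and `mean_r`, `mean_g`,
#'   `mean_b` over the mask (NA when the mask is empty, with a warning).
#' @export
segment_plant <- function(image, threshold = 20, meta = list()) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop("image must be a height x width x 3 array", call. = FALSE)
  }
  if (max(image, na.rm = TRUE) <= 1) image <- image * 255
  r <- image[, , 1]; g <- image[, , 2]; b <- image[, , 3]
  mask <- (2 * g - r - b) > threshold
  pla <- sum(mask)
  if (pla == 0) {
    warning("empty plant mask (no pixel exceeds the greenness threshold)",
            call. = FALSE)
    rec <- data.frame(pla = 0, mean_r = NA_real_, mean_g = NA_real_,
                      mean_b = NA_real_)
  } else {
    rec <- data.frame(pla = pla, mean_r = mean(r[mask]),
                      mean_g = mean(g[mask]), mean_b = mean(b[mask]))
  }
  for (f in c("species", "treatment", "day", "plant")) {
    if (!is.null(meta[[f]])) rec[[f]] <- meta[[f]]
  }
  list(mask = mask, record = rec)
}

#' Read an RGB raster for the fallback segmenter
#'
#' Loads a PNG or TIFF image (by file extension) into the
#' `height x width x 3` array [segment_plant()] expects. Requires the
#' `png` or `tiff` package respectively.
#'
#' @param path image file.
#' @return Numeric array with values on the 0-255 scale.
#' @export
read_plant_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG images needs the 'png' package", call. = FALSE)
    }
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF images needs the 'tiff' package", call. = FALSE)
    }
    tiff::readTIFF(path)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3, drop = FALSE]
  } else {
    stop("image is not a 3-channel raster", call. = FALSE)
  }
  img * 255
}

#' Relative growth rate from projected leaf area
#'
#' `RGR = 100 * (ln PLA2 - ln PLA1) / (day2 - day1)` in percent per day.
#' The PLA unit (pixels or cm2) cancels in the log difference.
#'
#' @param days integer vector of imaging days.
#' @param pla projected leaf areas matching `days` (> 0 at the two days
#'   used).
#' @param day1,day2 the two imaging days to compare (`day2 > day1`); both
#'   must be present in `days`.
#' @return Relative growth rate in %/day.
#' @export
#' @examples
#' relative_growth_rate(c(0, 7), c(50, 100), 0, 7)  # 100*ln(2)/7 = 9.902
relative_growth_rate <- function(days, pla, day1, day2) {
  if (length(days) != length(pla)) {
    stop("days and pla must have equal length", call. = FALSE)
  }
  if (is.unsorted(days, strictly = TRUE)) {
    stop("days must be strictly increasing", call. = FALSE)
  }
  if (day2 <= day1) stop("day2 must be greater than day1", call. = FALSE)
  i1 <- match(day1, days); i2 <- match(day2, days)
  if (is.na(i1) || is.na(i2)) {
    stop("day ", if (is.na(i1)) day1 else day2,
         " not present in the growth series", call. = FALSE)
  }
  if (pla[i1] <= 0 || pla[i2] <= 0) {
    stop("PLA must be > 0 at both days", call. = FALSE)
  }
  100 * (log(pla[i2]) - log(pla[i1])) / (day2 - day1)
}

#' Excess greenness of a plant
#'
#' `ExG = 2 G - (R + B)` on raw mean channel values (0-255 digital
#' numbers, no chromatic normalization). Adding a constant to all three
#' channels leaves ExG unchanged.
#'
#' @param mean_r,mean_g,mean_b mean channel values over plant pixels, or a
#'   one-row data.frame with columns `mean_r`, `mean_g`, `mean_b` as the
#'   first argument.
#' @return Excess greenness value.
#' @export
#' @examples
#' excess_greenness(10, 50, 20)  # 70
excess_greenness <- function(mean_r, mean_g = NULL, mean_b = NULL) {
  if (is.data.frame(mean_r)) {
    df <- mean_r
    mean_r <- df$mean_r; mean_g <- df$mean_g; mean_b <- df$mean_b
  }
  if (any(!is.finite(c(mean_r, mean_g, mean_b)))) {
    stop("channel means must be finite", call. = FALSE)
  }
  2 * mean_g - (mean_r + mean_b)
}

#' Specific leaf area
#'
#' `SLA = LA / LDW` in cm2 per mg: leaf area (mean of the leaves above and
#' beneath the sampling leaf) over leaf dry weight. Lower SLA indicates
#' thicker leaves.
#'
#' @param leaf_area cm2 (> 0).
#' @param leaf_dry_weight mg (> 0).
#' @return SLA in cm2/mg.
#' @export
#' @examples
#' specific_leaf_area(100, 500)  # 0.2
specific_leaf_area <- function(leaf_area, leaf_dry_weight) {
  if (any(leaf_area <= 0) || any(leaf_dry_weight <= 0)) {
    stop("leaf area and dry weight must be > 0", call. = FALSE)
  }
  leaf_area / leaf_dry_weight
}
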