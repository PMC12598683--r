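#' Spectral reflectance index definitions
#'
#' The eight default indices (RGI, PRI, NDRE, NDVI, NDVI_green, ZMI, GM1,
#' FLAV_700_760) are loaded from a YAML registry shipped with the package,
#' so additional indices can be added without code changes: each entry has
#' a `name`, an R `formula` over band variables `R<nm>`, and the list of
#' required `bands` (nm). The FLAV constant 0.40 is interpreted on the
#' reflectance-fraction scale.
#'
#' @param path YAML registry file; default: the registry shipped in
#'   `inst/extdata/indices.yaml`.
#' @return List of index definitions (name, label, formula, bands).
#' @export
default_index_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "indices.yaml", package = "hyperleaf")
  }
  defs <- yaml::read_yaml(path)$indices
  for (d in defs) {
    vars <- all.vars(str2lang(d$formula))
    band_vars <- paste0("R", d$bands)
    if (!all(vars %in% band_vars)) {
      stop("index ", d$name, " references bands not listed in `bands`: ",
           paste(setdiff(vars, band_vars), collapse = ", "), call. = FALSE)
    }
  }
  defs
}

#' Find the grid band closest to a target wavelength
#'
#' Nominal index wavelengths (e.g. 531 nm for PRI) rarely coincide with the
#' instrument's band centers; the nearest band within `tolerance` is used
#' instead, ties broken toward the lower wavelength.
#'
#' @param grid numeric wavelength grid (nm).
#' @param target requested wavelength (nm).
#' @param tolerance maximum allowed |grid - target| in nm (default 2).
#' @param context optional label (index name) used in the error message.
#' @return Integer band index into `grid`.
#' @export
band_lookup <- function(grid, target, tolerance = 2, context = NULL) {
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  d <- abs(grid - target)
  i <- which(d == min(d))[1]  # tie -> lower wavelength (grid is ascending)
  if (d[i] > tolerance) {
    stop("no grid band within ", tolerance, " nm of ", target, " nm",
         if (!is.null(context)) paste0(" (needed by ", context, ")"),
         "; nearest is ", format(grid[i], digits = 6), " nm", call. = FALSE)
  }
  i
}

#' Compute vegetation indices from one spectrum
#'
#' Evaluates each index formula on the (smoothed) reflectance fractions at
#' the matched grid bands. A zero denominator yields `NaN` for that index
#' plus an `undefined` flag rather than an error; a band that cannot be
#' matched within `tolerance` is an error naming the index.
#'
#' @param s a [leaf_spectrum()] (smoothed stage expected; raw is accepted
#'   and used as-is).
#' @param defs index definitions, see [default_index_definitions()].
#' @param tolerance band matching tolerance in nm.
#' @return List of class `vegetation_index_set`: `values` (named numeric),
#'   `matched_bands` (named numeric, requested -> matched nm),
#'   `undefined` (character vector of index names with zero denominators),
#'   `meta` (the sample key).
#' @export
#' @examples
#' g <- default_wavelength_grid()
#' flat <- leaf_spectrum(g, rep(0.2, length(g)))
#' compute_indices(flat)$values  # PRI/NDRE/NDVI/NDVI_green 0; RGI/ZMI/GM1 1
compute_indices <- function(s, defs = default_index_definitions(),
                            tolerance = 2) {
  stopifnot(inherits(s, "leaf_spectrum"))
  if (s$stage == "derivative") {
    stop("indices are defined on reflectance, not derivative spectra",
         call. = FALSE)
  }
  values <- numeric(0)
  matched <- numeric(0)
  undefined <- character(0)
  for (d in defs) {
    env <- new.env(parent = baseenv())
    for (b in d$bands) {
      i <- band_lookup(s$wavelength, b, tolerance, context = d$name)
      assign(paste0("R", b), s$values[i], envir = env)
      matched[as.character(b)] <- s$wavelength[i]
    }
    val <- eval(str2lang(d$formula), envir = env)
    if (!is.finite(val)) {
      undefined <- c(undefined, d$name)
      val <- NaN
    }
    values[d$name] <- val
  }
  structure(
    list(values = values, matched_bands = matched,
         undefined = undefined, meta = s$meta),
    class = "vegetation_index_set"
  )
}

#' @export
print.vegetation_index_set <- function(x, ...) {
  cat("<vegetation_index_set>\n")
  print(round(x$values, 4))
  if (length(x$undefined)) {
    cat("undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Index table for a collection of spectra
#'
#' Convenience wrapper: smooths each raw spectrum, averages nothing (pass
#' technical-replicate means if desired), computes all indices and returns
#' a long data.frame.
#'
#' @param spectra list of [leaf_spectrum()] objects.
#' @param defs,tolerance passed to [compute_indices()].
#' @param smooth apply [smooth_spectrum()] first (default `TRUE`; the
#'   pipeline computes indices on smoothed spectra).
#' @return data.frame with columns species, treatment, day, plant, tech_rep,
#'   index, value.
#' @export
index_table <- function(spectra, defs = default_index_definitions(),
                        tolerance = 2, smooth = TRUE) {
  rows <- lapply(spectra, function(s) {
    if (smooth && s$stage == "raw") s <- smooth_spectrum(s)
    ix <- compute_indices(s, defs, tolerance)
    m <- s$meta
    data.frame(species = m$species, treatment = m$treatment, day = m$day,
               plant = m$plant, tech_rep = m$tech_rep,
               index = names(ix$values), value = unname(ix$values))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative index change versus control
#'
#' For each species, day and index, the percent change of each stress
#' treatment's mean index value relative to the control mean,
#' `100 * (mean(treatment) - mean(control)) / mean(control)`, with a
#' significance flag from the gated group comparison
#' ([compare_treatments()], control vs. that treatment).
#'
#' @param idx_table long index table as returned by [index_table()] (one
#'   row per plant; average technical replicates first).
#' @param alpha significance level for the comparison.
#' @return data.frame with columns species, day, index, treatment,
#'   percent_change, p_value, significant, method, undefined (control mean
#'   of 0 flags the change as undefined rather than erroring).
#' @export
relative_change_vs_control <- function(idx_table, alpha = 0.05) {
  needed <- c("species", "treatment", "day", "plant", "index", "value")
  if (!all(needed %in% names(idx_table))) {
    stop("index table must have columns ",
         paste(needed, collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (sp in unique(idx_table$species)) {
    for (day in unique(idx_table$day)) {
      sub <- idx_table[idx_table$species == sp & idx_table$day == day, ]
      for (ix in unique(sub$index)) {
        cell <- sub[sub$index == ix, ]
        ctrl <- cell$value[cell$treatment == "control"]
        if (length(ctrl) < 2) {
          stop("need >= 2 control plants for (", sp, ", day ", day, ")",
               call. = FALSE)
        }
        for (tr in setdiff(unique(cell$treatment), "control")) {
          trt <- cell$value[cell$treatment == tr]
          undefined <- mean(ctrl) == 0
          pc <- if (undefined) NA_real_ else {
            100 * (mean(trt) - mean(ctrl)) / mean(ctrl)
          }
          cmp <- tryCatch(
            compare_treatments(c(ctrl, trt),
                               rep(c("control", tr),
                                   c(length(ctrl), length(trt))),
                               alpha = alpha),
            error = function(e) NULL
          )
          out[[length(out) + 1L]] <- data.frame(
            species = sp, day = day, index = ix, treatment = tr,
            percent_change = pc,
            p_value = if (is.null(cmp)) NA_real_ else cmp$omnibus_p,
            significant = if (is.null(cmp)) NA else
              isTRUE(cmp$omnibus_p <= alpha),
            method = if (is.null(cmp)) NA_character_ else cmp$method,
            undefined = undefined
          )
        }
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
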