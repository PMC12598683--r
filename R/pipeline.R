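#' Read and write spectral tables
#'
#' Spectra travel as tab-delimited text: first column `wavelength_nm`, one
#' column per sample named `species|treatment|day|plant|rep`. Reflectance
#' in percent is auto-normalized to fractions on read (with a message).
#'
#' @param path file path.
#' @param spectra list of [leaf_spectrum()] objects on a shared grid.
#' @return `read_spectra_table`: a list of raw-stage [leaf_spectrum()];
#'   `write_spectra_table`: the path, invisibly.
#' @export
write_spectra_table <- function(spectra, path) {
  grid <- stopifnot_shared_grid(spectra)
  df <- data.frame(wavelength_nm = grid, check.names = FALSE)
  for (s in spectra) df[[spectrum_key(s)]] <- s$values
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spectra_table
#' @export
read_spectra_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stop("first column of a spectral table must be 'wavelength_nm'",
         call. = FALSE)
  }
  grid <- df[[1]]
  keys <- names(df)[-1]
  if (anyDuplicated(keys)) {
    stop("duplicate sample columns: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  }
  lapply(keys, function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    if (length(parts) != 5) {
      stop("sample column '", k,
           "' is not of the form species|treatment|day|plant|rep",
           call. = FALSE)
    }
    leaf_spectrum(grid, df[[k]],
                  meta = list(species = parts[1], treatment = parts[2],
                              day = as.numeric(parts[3]), plant = parts[4],
                              tech_rep = parts[5]))
  })
}

#' Write a long-format trait table
#'
#' Serializes a wide per-plant trait table to the pipeline's long format:
#' columns (species, treatment, day, plant, trait, value), tab-delimited.
#'
#' @param traits wide data.frame with key columns species, treatment, day,
#'   plant.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  key_cols <- c("species", "treatment", "day", "plant")
  value_cols <- setdiff(names(traits), key_cols)
  long <- do.call(rbind, lapply(value_cols, function(cl) {
    data.frame(traits[key_cols], trait = cl, value = traits[[cl]])
  }))
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Validate a delimited input table against a named schema
#'
#' Checks column presence, numeric types and duplicate sample keys before
#' any analysis stage touches the data, so format problems surface as
#' named errors instead of silent downstream `NA`s. Known schemas:
#' `"spectra"` (wide spectral table), `"traits"` (long trait table),
#' `"pla_rgb"` (plant-image summary), `"absorbance"` (plate readings with
#' columns sample, wavelength, absorbance).
#'
#' @param path file path of a tab-delimited table.
#' @param schema one of `"spectra"`, `"traits"`, `"pla_rgb"`,
#'   `"absorbance"`.
#' @return The validated data.frame (for `"spectra"`, the wide table; use
#'   [read_spectra_table()] to obtain spectrum objects).
#' @export
validate_table <- function(path, schema = c("spectra", "traits", "pla_rgb",
                                            "absorbance")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE)
  fail <- function(...) stop(schema, " table ", path, ": ", ...,
                             call. = FALSE)
  need_numeric <- function(cols) {
    for (cl in cols) {
      if (!is.numeric(df[[cl]])) fail("column '", cl, "' is not numeric")
      }
  }
  if (schema == "spectra") {
    if (names(df)[1] != "wavelength_nm") {
      fail("first column must be 'wavelength_nm'")
    }
    if (anyDuplicated(names(df))) {
      fail("duplicate sample key column(s): ",
           paste(unique(names(df)[duplicated(names(df))]), collapse = ", "))
    }
    need_numeric(names(df))
    if (is.unsorted(df$wavelength_nm, strictly = TRUE)) {
      fail("wavelength_nm must be strictly increasing")
    }
    vals <- as.matrix(df[-1])
    if (max(vals, na.rm = TRUE) > 1.5) {
      message("spectra table ", path,
              " looks percent-scaled; values will be divided by 100 on read")
    }
  } else if (schema == "traits") {
    cols <- c("species", "treatment", "day", "plant", "trait", "value")
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      fail("missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    need_numeric(c("day", "value"))
    k <- do.call(paste, df[c("species", "treatment", "day", "plant",
                             "trait")])
    if (anyDuplicated(k)) fail("duplicate (sample, trait) rows")
  } else if (schema == "pla_rgb") {
    cols <- c("species", "treatment", "plant", "day", "pla", "mean_r",
              "mean_g", "mean_b")
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      fail("missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    need_numeric(c("day", "pla", "mean_r", "mean_g", "mean_b"))
    if (any(df$pla < 0, na.rm = TRUE)) fail("negative PLA")
  } else {
    cols <- c("sample", "wavelength", "absorbance")
    missing_cols <- setdiff(cols, names(df))
    if (length(missing_cols)) {
      fail("missing column(s): ", paste(missing_cols, collapse = ", "))
    }
    need_numeric(c("wavelength", "absorbance"))
  }
  df
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. All analysis stages read
#' their parameters from this object and the full configuration is
#' serialized into the run manifest.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed driving the simulation.
#' @param design an [experiment_design()]; default built from `seed`.
#' @param spectra_path optional wide spectral table to ingest instead of
#'   simulating.
#' @param delta_lambda band interval for [first_derivative()], nm.
#' @param window red-edge search window, nm.
#' @param tolerance band matching tolerance for indices, nm.
#' @param alpha significance level of the statistics layer.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, design = NULL,
                            spectra_path = NULL, delta_lambda = 1.8,
                            window = c(690, 750), tolerance = 2,
                            alpha = 0.05) {
  if (is.null(design)) design <- experiment_design(seed = as.integer(seed))
  stopifnot(inherits(design, "experiment_design"))
  if (delta_lambda <= 0) stop("delta_lambda must be > 0", call. = FALSE)
  if (tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                     call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 design = design, spectra_path = spectra_path,
                 delta_lambda = delta_lambda, window = window,
                 tolerance = tolerance, alpha = alpha),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) spectra, average technical replicates, smooth,
#' differentiate, quantify red-edge shifts per treatment, compute
#' vegetation indices and their relative change versus control, build
#' trait correlograms and index-trait correlation matrices, and run the
#' PRI time course. Each stage writes a tab-delimited table into
#' `config$out_dir`; a manifest (YAML) records the configuration, stage
#' status and MD5 checksum of every output. Identical configuration and
#' seed reproduce identical tables; a failing stage leaves earlier outputs
#' in place and is named in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return The run manifest, invisibly (list with `config`, `stages`,
#'   `files`, `version`, `timestamp`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- list()
  files <- character(0)
  state <- new.env()
  emit <- function(name, df) {
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    files[[name]] <<- path
  }
  run_stage <- function(name, fun) {
    res <- tryCatch({
      fun()
      list(status = "ok", error = NA_character_)
    }, error = function(e) {
      list(status = "failed", error = conditionMessage(e))
    })
    stages[[name]] <<- res
    if (res$status == "failed") {
      warning("pipeline stage '", name, "' failed: ", res$error,
              call. = FALSE)
    }
    res$status == "ok"
  }

  ok <- run_stage("input", function() {
    if (is.null(config$spectra_path)) {
      sim <- generate_experiment(config$design)
      state$spectra <- sim$spectra
      state$traits <- sim$traits
      write_spectra_table(state$spectra,
                          file.path(config$out_dir, "spectra.tsv"))
      files[["spectra"]] <<- file.path(config$out_dir, "spectra.tsv")
      write_trait_table(state$traits,
                        file.path(config$out_dir, "traits.tsv"))
      files[["traits"]] <<- file.path(config$out_dir, "traits.tsv")
    } else {
      validate_table(config$spectra_path, "spectra")
      state$spectra <- read_spectra_table(config$spectra_path)
      state$traits <- NULL
    }
  })

  if (ok) ok <- run_stage("replicate_means", function() {
    sp <- state$spectra
    keys <- vapply(sp, spectrum_key, "", with_rep = FALSE)
    state$plant_spectra <- lapply(split(sp, keys),
                                  average_technical_replicates)
  })

  if (ok) ok <- run_stage("smooth_derivative", function() {
    state$smoothed <- lapply(state$plant_spectra, smooth_spectrum)
    state$deriv <- lapply(state$smoothed, first_derivative,
                          delta_lambda = config$delta_lambda)
  })

  if (ok) ok <- run_stage("red_edge", function() {
    meta_of <- function(s) s$meta
    rows <- list()
    der <- state$deriv
    cells <- unique(do.call(rbind, lapply(der, function(s) {
      data.frame(species = s$meta$species, treatment = s$meta$treatment,
                 day = s$meta$day)
    })))
    for (i in seq_len(nrow(cells))) {
      ci <- cells[i, ]
      if (ci$treatment == "control") next
      pick <- function(tr) Filter(function(s) {
        s$meta$species == ci$species && s$meta$treatment == tr &&
          s$meta$day == ci$day
      }, der)
      ctrl <- pick("control")
      trt <- pick(ci$treatment)
      if (!length(ctrl) || !length(trt)) next
      rows[[length(rows) + 1L]] <- data.frame(
        species = ci$species, treatment = ci$treatment, day = ci$day,
        shift_nm = red_edge_shift(ctrl, trt, window = config$window))
    }
    emit("red_edge_shifts", do.call(rbind, rows))
  })

  if (ok) ok <- run_stage("indices", function() {
    idx <- index_table(unname(state$plant_spectra),
                       tolerance = config$tolerance)
    state$idx <- idx
    emit("indices", idx)
    emit("index_relative_change",
         relative_change_vs_control(idx, alpha = config$alpha))
  })

  if (ok && !is.null(state$traits)) {
    ok <- run_stage("correlograms", function() {
      rows <- list()
      for (sp in unique(state$traits$species)) {
        der_sp <- Filter(function(s) s$meta$species == sp, state$deriv)
        for (tr_name in c("chl_total", "caro", "tp", "tf", "sla",
                          "rgr_pla", "exg")) {
          prof <- spectral_trait_correlogram(
            der_sp, state$traits[state$traits$species == sp, ], tr_name)
          prof$species <- sp
          prof$trait <- tr_name
          rows[[length(rows) + 1L]] <- as.data.frame(prof)
        }
      }
      emit("correlograms_derivative", do.call(rbind, rows))
      emit("index_trait_correlations",
           index_trait_correlation(state$idx, state$traits))
    })
    if (ok) run_stage("pri_time_course", function() {
      emit("pri_time_course",
           pri_time_course(state$idx, alpha = config$alpha,
                           days = sort(unique(state$idx$day))))
    })
  }

  manifest <- list(
    config = list(seed = config$seed, delta_lambda = config$delta_lambda,
                  window = config$window, tolerance = config$tolerance,
                  alpha = config$alpha,
                  simulated = is.null(config$spectra_path)),
    stages = stages,
    files = as.list(tools::md5sum(unlist(files))),
    version = as.character(utils::packageVersion("hyperleaf")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
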