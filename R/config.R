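# Flat key-value configuration files, run manifests, and the end-to-end
# characterization pipelines.

config_error <- function(...) {
  stop(errorCondition(paste0(...),
                      class = c("planarpet_config_error", "error")))
}

#' Read / write flat key-value configuration files
#'
#' The configuration dialect is one `key = value` pair per line; `#` starts
#' a comment. Values are parsed as numeric, logical (`true`/`false`), or
#' string; comma-separated values become vectors. Keys use the same names as
#' the corresponding constructor arguments ([build_detector()],
#' [detector_response()], [acquisition_windows()], ...).
#'
#' @param path file path.
#' @return `read_config`: a named list. `write_config`: `path`, invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      config_error("malformed config line (expected key = value): '", ln, "'")
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    parsed <- if (!anyNA(num)) num
              else if (all(tolower(parts) %in% c("true", "false")))
                tolower(parts) == "true"
              else parts
    out[[key]] <- parsed
  }
  out
}

#' @rdname read_config
#' @param config named list of scalar or vector values.
#' @export
write_config <- function(config, path) {
  fmt <- function(v) {
    if (is.logical(v)) v <- ifelse(v, "true", "false")
    if (is.numeric(v)) v <- formatC(v, digits = 15, format = "g")
    paste(v, collapse = ", ")
  }
  writeLines(paste(names(config), "=", vapply(config, fmt, character(1))),
             path)
  invisible(path)
}

#' Serialize a geometry, response or source to config form
#'
#' @param x a `detector_geometry`, `detector_response` or
#'   `acquisition_windows` object.
#' @return A named list of flat key-value pairs.
#' @export
as_config <- function(x) {
  flat <- unclass(x)
  flat[vapply(flat, function(v) is.atomic(v) && length(v) >= 1, logical(1))]
}

#' Run manifest
#'
#' Records everything needed to reproduce a pipeline run: the configuration
#' snapshot, the seed of every stochastic stage, the package version,
#' digests of the files written, and timestamps.
#'
#' @param config the configuration list used.
#' @param seeds named list of per-stage seeds.
#' @param files character vector of output files (digested with MD5).
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds, files = character()) {
  files <- files[file.exists(files)]
  structure(list(
    package_version = as.character(utils::packageVersion("planarpet")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    file_digests = if (length(files))
      as.list(tools::md5sum(files)) else list()
  ), class = "run_manifest")
}

default_config <- function(protocol) {
  base <- list(protocol = protocol, separation = 60, seed = 1,
               timing_window_ns = 4, energy_low = 350, energy_high = 700,
               target_center_sensitivity_percent = 3.5)
  extra <- switch(protocol,
    sensitivity = list(step_mm = 2, span_mm = 224, n_decays_per_position = 1e5),
    countrate = list(frame_interval_min = 60, frame_duration_s = 30,
                     stop_half_lives = 10, max_decays_per_frame = 3e5,
                     angle_allowance_mm = 110,
                     peak_concentration_kbq_ml = 10.5),
    resolution = list(separation = 80, n_prompts = 1e5, pixel_size_mm = 0.2,
                      n_iterations = 15, extent_xy_mm = 25.6),
    config_error("unknown protocol: ", protocol))
  modifyList(base, extra)
}

build_setup <- function(config) {
  geom <- build_detector(separation = config$separation %||% 60)
  windows <- acquisition_windows(config$timing_window_ns %||% 4,
                                 config$energy_low %||% 350,
                                 config$energy_high %||% 700)
  # efficiency is always calibrated at the 60 mm sensitivity condition
  response <- calibrate_pair_efficiency(
    build_detector(separation = 60),
    config$target_center_sensitivity_percent %||% 3.5)
  list(geom = geom, windows = windows, response = response)
}

#' Run a characterization pipeline from a configuration
#'
#' Executes one of the three measurement protocols end to end
#' (simulate, filter, rebin/reconstruct, characterize) and returns a
#' machine-readable report plus a [run_manifest()]. Protocols:
#' `"sensitivity"` (point-source X scan, sensitivity profile),
#' `"countrate"` (decaying scatter-phantom series, count-rate decomposition,
#' NECR, scatter fraction, efficiency at peak), and `"resolution"`
#' (centered point source, MLEM and back-projection PSF fits).
#'
#' @param config a configuration list, or the path of a config file with at
#'   least a `protocol` key; missing keys take protocol defaults.
#' @param out_dir optional output directory; when given, the list-mode data
#'   of the first stage, the JSON report and the manifest are written there.
#' @return A list with `report`, `manifest`, and protocol-specific objects.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$protocol)) config_error("config must name a protocol")
  config <- modifyList(default_config(config$protocol), config)
  seed <- as.integer(config$seed %||% 1)
  setup <- build_setup(config)
  files <- character()
  stage <- function(name) message(sprintf("[planarpet] stage: %s", name))

  if (config$protocol == "sensitivity") {
    stage("simulate sensitivity scan")
    acqs <- simulate_sensitivity_scan(
      setup$geom, setup$response, setup$windows,
      step = config$step_mm, span = config$span_mm,
      n_decays = config$n_decays_per_position, seed = seed)
    stage("characterize sensitivity")
    prof <- sensitivity_profile(acqs, NULL, a_cal = 89.9)
    report <- list(protocol = "sensitivity",
                   n_positions = nrow(prof$records),
                   peak_slice_sensitivity_cps_per_kbq = prof$peak_s,
                   peak_absolute_sensitivity_percent = prof$peak_abs,
                   average_absolute_sensitivity_percent = prof$average_abs)
    result <- list(profile = prof)
  } else if (config$protocol == "countrate") {
    stage("calibrate dead time")
    phantom <- nu4_scatter_phantom()
    response <- calibrate_dead_time(
      phantom, setup$geom, setup$response, setup$windows,
      peak_concentration_kbq_ml = config$peak_concentration_kbq_ml,
      seed = seed)
    stage("simulate decay series")
    frames <- simulate_decay_series(
      phantom, setup$geom, response, setup$windows,
      frame_interval = config$frame_interval_min,
      stop_half_lives = config$stop_half_lives,
      frame_duration = config$frame_duration_s,
      max_decays_per_frame = config$max_decays_per_frame,
      seed = seed + 1000L)
    stage(sprintf("angle-allowance filter (%g mm)",
                  config$angle_allowance_mm))
    filtered <- lapply(frames, apply_angle_allowance,
                       allowance = config$angle_allowance_mm)
    stage("count-rate decomposition")
    series <- countrate_decompose(filtered)
    eff <- efficiency_at_peak(series,
                              volume_ml = phantom$reporting_volume_ml)
    report <- list(protocol = "countrate",
                   n_frames = length(frames),
                   angle_allowance_mm = config$angle_allowance_mm,
                   dead_time_tau_us = response$dead_time_tau_us,
                   scatter_fraction_percent = 100 * series$scatter_fraction,
                   peak_necr_kcps = series$peak_necr_kcps,
                   concentration_at_peak_kbq_ml = series$concentration_at_peak,
                   peak_trues_kcps = series$peak_trues_kcps,
                   peak_prompt_kcps = series$peak_prompt_kcps,
                   efficiency_cps_per_mbq = eff$efficiency,
                   suv1_370mbq_kbq_ml = suv_concentration(1, 370),
                   suv1_37mbq_kbq_ml = suv_concentration(1, 37))
    result <- list(series = series, efficiency = eff, frames = frames)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      lm_path <- file.path(out_dir, "frame_001.plm")
      write_listmode(frames[[1]], lm_path)
      files <- c(files, lm_path)
    }
  } else if (config$protocol == "resolution") {
    stage("simulate point source")
    src <- point_source()
    acc <- pair_acceptance_analytic(c(0, 0, 0), setup$geom)
    n_decays <- config$n_prompts / (acc * setup$response$eta^2 * 0.45)
    acq <- simulate_acquisition(
      src, setup$geom, setup$response, setup$windows,
      duration = n_decays / (src$activity_at_start * 1000), seed = seed,
      include_randoms = FALSE, max_decays = Inf)
    grid <- recon_grid(setup$geom, extent_xy = config$extent_xy_mm,
                       pixel_size = config$pixel_size_mm)
    stage("MLEM reconstruction")
    mlem <- mlem_reconstruct(acq, grid, n_iterations = config$n_iterations)
    stage("back-projection reconstruction")
    bp <- backproject(acq, grid)
    fits <- list(
      mlem_x = fit_psf(image_profile(mlem, "x")),
      mlem_y = fit_psf(image_profile(mlem, "y")),
      mlem_z = fit_psf(image_profile(mlem, "z")),
      bp_x = fit_psf(image_profile(bp, "x"), baseline = TRUE))
    report <- list(protocol = "resolution",
                   n_prompts = nrow(acq$events),
                   mlem_fwhm_x_mm = fits$mlem_x$fwhm,
                   mlem_fwhm_y_mm = fits$mlem_y$fwhm,
                   mlem_fwhm_z_mm = fits$mlem_z$fwhm,
                   mlem_fwtm_x_mm = fits$mlem_x$fwtm,
                   backprojection_fwhm_x_mm = fits$bp_x$fwhm)
    result <- list(fits = fits, mlem = mlem, backprojection = bp)
  }

  manifest <- run_manifest(config, seeds = list(main = seed), files = files)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    report_path <- file.path(out_dir, "report.json")
    writeLines(jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA),
               report_path)
    manifest_path <- file.path(out_dir, "manifest.json")
    writeLines(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                                digits = NA), manifest_path)
  }
  c(list(report = report, manifest = manifest), result)
}
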