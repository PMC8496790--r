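#' Default run configuration
#'
#' Nested list of every tunable stage parameter, organized by stage
#' (`synthetic`, `preprocess`, `activation`, `velocity`, `regions`), plus a
#' `seed`. This is the object serialized verbatim (YAML) next to every run
#' output so that any result can be regenerated.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    synthetic = list(
      grid_rows = 100L, grid_cols = 100L, pixel_size_mm = 0.17,
      frame_rate_hz = 3000, base_speed_mps = 0.5,
      source = "left", upstroke_ms = 2, apd_ms = 50,
      noise_sd = 0.05, drift_per_s = 0.1, duration_ms = 500,
      inactive_margin_px = 0L, sc_threshold_mps = 0.2
    ),
    preprocess = list(
      kernel_size = 3L, low_hz = 0, high_hz = 100, filter_order = 4L,
      drift_order = 2L, snr_threshold = 3
    ),
    activation = list(
      method = "max_dvdt", amplitude_floor = 0.3, window_ms = NULL
    ),
    velocity = list(
      fit_radius_px = 3L, poly_order = 2L, speed_cap_mps = 2,
      gradient_floor = 1e-6
    ),
    regions = list(
      threshold_mps = 0.2, pixel_area_mm2 = NULL  # NULL = pixel_size_mm^2
    )
  )
}

#' Read / write a run configuration (YAML)
#'
#' @param path YAML file; top-level keys are the stage sections of
#'   [default_config()]. Missing keys fall back to the defaults.
#' @return `read_config`: the merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  modifyList(default_config(), user)
}

#' @rdname read_config
#' @param config configuration list to serialize.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline on a movie
#'
#' Chains preprocessing (binning, temporal filter, drift correction +
#' normalization, SNR masking), activation-time detection, conduction
#' velocity estimation and slow-conduction segmentation, and returns the
#' region report together with every intermediate map. The region-of-
#' interest denominator for percent SC is the SNR mask intersected with the
#' valid-velocity pixels. Deterministic for a given movie + config: the
#' same input yields a bit-identical report. Stage failures are re-raised
#' with the stage name prefixed.
#'
#' @param movie a raw [voltage_movie()].
#' @param config configuration list, see [default_config()].
#' @return list with `report` (a [region_report()]), `processed`
#'   ([voltage_movie()]), `mask`, `lat` (`lat_map`), `cv` (`cv_map`),
#'   `sc` (`sc_map`), `roi`, `excluded_px` (named counts of invalid-CV
#'   pixels by reason), and `config`.
#' @export
run_pipeline <- function(movie, config = default_config()) {
  stopifnot(inherits(movie, "voltage_movie"))
  config <- modifyList(default_config(), config)
  at_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  pp <- at_stage("preprocess", {
    p <- config$preprocess
    preprocess_movie(movie, kernel_size = p$kernel_size, low_hz = p$low_hz,
                     high_hz = p$high_hz, filter_order = p$filter_order,
                     drift_order = p$drift_order,
                     snr_threshold = p$snr_threshold)
  })
  lat <- at_stage("activation", {
    a <- config$activation
    local_activation_times(pp$movie, pp$mask, window_ms = a$window_ms,
                           method = a$method,
                           amplitude_floor = a$amplitude_floor)
  })
  cv <- at_stage("velocity", {
    v <- config$velocity
    cv_map(lat, fit_radius_px = v$fit_radius_px, poly_order = v$poly_order,
           speed_cap_mps = v$speed_cap_mps,
           gradient_floor = v$gradient_floor)
  })
  res <- at_stage("regions", {
    r <- config$regions
    px_area <- if (is.null(r$pixel_area_mm2)) movie$pixel_size_mm^2
               else r$pixel_area_mm2
    sc <- classify_slow(cv, threshold_mps = r$threshold_mps)
    roi <- pp$mask & cv$valid
    lab <- label_components(sc)
    list(sc = sc, roi = roi,
         report = region_report(lab, pixel_area_mm2 = px_area, roi = roi))
  })
  excl <- table(cv$reason[cv$reason != "ok"])
  list(report = res$report, processed = pp$movie, mask = pp$mask,
       lat = lat, cv = cv, sc = res$sc, roi = res$roi,
       excluded_px = stats::setNames(as.integer(excl), names(excl)),
       config = config)
}
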