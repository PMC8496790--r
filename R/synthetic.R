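#' Scene specification for synthetic optical-mapping movies
#'
#' Describes a propagating-activation scene: grid geometry, a background
#' conduction speed with optional slow patches and block segments, the pacing
#' source, the action-potential waveform, and the noise/drift model. Defaults
#' mirror a 17 mm x 17 mm field of view imaged at 3000 frames/s with
#' 100 x 100 pixels, paced from one edge of the field, which is the geometry
#' of typical atrial optical-mapping experiments.
#'
#' @param grid_rows,grid_cols pixel counts, at least 8.
#' @param pixel_size_mm pixel pitch in mm (default 0.17 = 17 mm / 100 px).
#' @param frame_rate_hz acquisition rate (default 3000 fps).
#' @param base_speed_mps background conduction speed in m/s.
#' @param patches list of patches overriding the local speed. Each patch is a
#'   list with `shape = "rect"` (`rows`, `cols`: index ranges) or
#'   `shape = "disc"` (`center` = c(row, col), `radius_px`), plus `speed_mps`.
#' @param block_segments list of line segments, each
#'   `list(from = c(row, col), to = c(row, col))`, across which activation
#'   does not propagate (implemented as effectively infinite travel cost).
#' @param source pacing origin: one of `"top"`, `"bottom"`, `"left"`,
#'   `"right"` (the whole edge is stimulated, producing a plane wave, as with
#'   a pacing wire at that edge) or a `c(row, col)` point source.
#' @param baseline_ms quiet pre-stimulus recording time before the first
#'   activation (default 10 ms); all ground-truth LATs include this offset.
#' @param upstroke_ms action-potential upstroke duration (2%-98% rise).
#' @param apd_ms plateau duration before repolarization.
#' @param noise_sd additive Gaussian noise SD, in units of the AP amplitude.
#' @param drift_per_s slope of the linear baseline drift, amplitude units per
#'   second.
#' @param duration_ms movie length; `NULL` (default) extends the movie to
#'   cover the latest activation plus the full action potential.
#' @param inactive_margin_px width of a border of non-tissue pixels carrying
#'   only noise and drift (no activation); used to exercise signal-quality
#'   masking. Default 0.
#' @param sc_threshold_mps speed below which a pixel counts as slow
#'   conduction in the ground truth (default 0.2 m/s).
#' @param seed RNG seed for noise generation.
#'
#' @return an object of class `scene_spec`.
#' @seealso [make_movie()]
#' @export
scene_spec <- function(grid_rows = 100L, grid_cols = 100L,
                       pixel_size_mm = 0.17, frame_rate_hz = 3000,
                       base_speed_mps = 0.5, patches = list(),
                       block_segments = list(), source = "left",
                       baseline_ms = 10, upstroke_ms = 2, apd_ms = 50,
                       noise_sd = 0.05, drift_per_s = 0.1,
                       duration_ms = NULL, inactive_margin_px = 0L,
                       sc_threshold_mps = 0.2, seed = 1L) {
  if (grid_rows < 8L || grid_cols < 8L)
    stop("grid must be at least 8 x 8", call. = FALSE)
  if (pixel_size_mm <= 0 || frame_rate_hz <= 0 || base_speed_mps <= 0)
    stop("pixel size, frame rate and base speed must be positive", call. = FALSE)
  for (p in patches) {
    if (is.null(p$speed_mps) || p$speed_mps <= 0)
      stop("every patch needs a positive speed_mps", call. = FALSE)
    if (!identical(p$shape, "rect") && !identical(p$shape, "disc"))
      stop("patch shape must be 'rect' or 'disc'", call. = FALSE)
  }
  if (is.character(source)) {
    if (!source %in% c("top", "bottom", "left", "right"))
      stop("edge source must be one of top/bottom/left/right", call. = FALSE)
  } else {
    source <- as.numeric(source)
    if (length(source) != 2L || source[1] < 1 || source[1] > grid_rows ||
        source[2] < 1 || source[2] > grid_cols)
      stop("point source lies outside the grid", call. = FALSE)
  }
  if (upstroke_ms <= 0 || apd_ms <= 0)
    stop("upstroke_ms and apd_ms must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(
    grid_rows = as.integer(grid_rows), grid_cols = as.integer(grid_cols),
    pixel_size_mm = pixel_size_mm, frame_rate_hz = frame_rate_hz,
    base_speed_mps = base_speed_mps, patches = patches,
    block_segments = block_segments, source = source,
    baseline_ms = baseline_ms, upstroke_ms = upstroke_ms, apd_ms = apd_ms,
    noise_sd = noise_sd, drift_per_s = drift_per_s,
    duration_ms = duration_ms,
    inactive_margin_px = as.integer(inactive_margin_px),
    sc_threshold_mps = sc_threshold_mps, seed = as.integer(seed)
  ), class = "scene_spec")
}

# Per-pixel speed field (m/s) implied by base speed + patches; block pixels
# get an effectively zero speed so the front must route around them.
scene_speed_field <- function(spec) {
  speed <- matrix(spec$base_speed_mps, spec$grid_rows, spec$grid_cols)
  for (p in spec$patches) {
    if (identical(p$shape, "rect")) {
      rows <- intersect(round(p$rows[1]):round(p$rows[2]), seq_len(spec$grid_rows))
      cols <- intersect(round(p$cols[1]):round(p$cols[2]), seq_len(spec$grid_cols))
      speed[rows, cols] <- p$speed_mps
    } else {
      rr <- row(speed) - p$center[1]
      cc <- col(speed) - p$center[2]
      speed[rr^2 + cc^2 <= p$radius_px^2] <- p$speed_mps
    }
  }
  speed
}

# Rasterize block segments onto the pixel grid (pixel centers within half a
# pixel of the segment).
block_mask <- function(spec) {
  blocked <- matrix(FALSE, spec$grid_rows, spec$grid_cols)
  for (seg in spec$block_segments) {
    from <- seg$from; to <- seg$to
    len <- max(abs(to - from))
    ts <- seq(0, 1, length.out = max(2L, ceiling(len * 4) + 1L))
    for (t in ts) {
      pt <- round(from + t * (to - from))
      if (pt[1] >= 1 && pt[1] <= spec$grid_rows &&
          pt[2] >= 1 && pt[2] <= spec$grid_cols)
        blocked[pt[1], pt[2]] <- TRUE
    }
  }
  blocked
}

source_mask <- function(spec, tissue = NULL) {
  src <- matrix(FALSE, spec$grid_rows, spec$grid_cols)
  if (is.null(tissue)) tissue <- matrix(TRUE, spec$grid_rows, spec$grid_cols)
  if (is.character(spec$source)) {
    # a pacing wire at the given edge stimulates the first tissue line
    rows <- which(rowSums(tissue) > 0); cols <- which(colSums(tissue) > 0)
    switch(spec$source,
      top    = { src[min(rows), ] <- TRUE },
      bottom = { src[max(rows), ] <- TRUE },
      left   = { src[, min(cols)] <- TRUE },
      right  = { src[, max(cols)] <- TRUE }
    )
  } else {
    src[round(spec$source[1]), round(spec$source[2])] <- TRUE
  }
  src & tissue
}

#' Solve the eikonal equation for front arrival times
#'
#' First-order upwind fast-sweeping solver for `|grad T| = 1/speed` on a
#' regular grid: the arrival time of a wavefront propagating from the source
#' pixels through a heterogeneous speed field. Travel cost per pixel is
#' `pixel_size_mm / speed` (ms when speed is in m/s = mm/ms). Pixels the
#' front cannot reach (enclosed by blocks, or zero-speed pixels) come back
#' as `Inf`.
#'
#' @param speed_mps matrix of local speeds (m/s); non-positive entries are
#'   treated as impassable.
#' @param source logical matrix marking pixels with arrival time 0, or a
#'   numeric matrix of initial arrival times (`Inf` = unknown). Supplying
#'   exact near-source times ("source factorization") removes the
#'   first-order scheme's accuracy loss around a point source.
#' @param pixel_size_mm grid spacing in mm.
#' @param tol convergence tolerance in ms.
#' @param max_cycles maximum number of 4-sweep Gauss-Seidel cycles.
#' @return matrix of arrival times in ms (`Inf` where unreached).
#' @export
solve_eikonal <- function(speed_mps, source, pixel_size_mm,
                          tol = 1e-9, max_cycles = 50L) {
  nr <- nrow(speed_mps); nc <- ncol(speed_mps)
  stopifnot(identical(dim(source), dim(speed_mps)))
  cost <- pixel_size_mm / pmax(speed_mps, 0)   # ms per pixel; Inf if speed<=0
  cost[!is.finite(cost) | speed_mps <= 0] <- Inf
  if (is.logical(source)) {
    stopifnot(any(source))
    tt <- matrix(Inf, nr, nc)
    tt[source] <- 0
  } else {
    stopifnot(any(is.finite(source)))
    tt <- source
    source <- is.finite(source)
  }
  orders <- list(
    list(seq_len(nr), seq_len(nc)),
    list(seq_len(nr), rev(seq_len(nc))),
    list(rev(seq_len(nr)), seq_len(nc)),
    list(rev(seq_len(nr)), rev(seq_len(nc)))
  )
  for (cycle in seq_len(max_cycles)) {
    delta <- 0
    for (ord in orders) {
      for (i in ord[[1]]) {
        for (j in ord[[2]]) {
          if (source[i, j]) next
          f <- cost[i, j]
          if (!is.finite(f)) next
          a <- min(if (i > 1) tt[i - 1, j] else Inf,
                   if (i < nr) tt[i + 1, j] else Inf)
          b <- min(if (j > 1) tt[i, j - 1] else Inf,
                   if (j < nc) tt[i, j + 1] else Inf)
          if (!is.finite(a) && !is.finite(b)) next
          tnew <- if (abs(a - b) >= f || !is.finite(min(a, b) + f)) {
            min(a, b) + f
          } else {
            (a + b + sqrt(2 * f * f - (a - b)^2)) / 2
          }
          if (tnew < tt[i, j]) {
            delta <- max(delta, tt[i, j] - tnew)
            tt[i, j] <- tnew
          }
        }
      }
    }
    if (delta < tol) break
  }
  tt
}

# Action-potential template: logistic upstroke whose steepest point sits at
# the activation time (the max-dV/dt convention used for LAT downstream),
# a plateau of apd_ms, then exponential recovery.
ap_trace <- function(t_ms, lat_ms, upstroke_ms, apd_ms) {
  s <- upstroke_ms / 8          # 2%-98% rise spans ~8 scale units
  v <- stats::plogis((t_ms - lat_ms) / s)
  t_rep <- lat_ms + apd_ms
  tau <- apd_ms / 4
  late <- t_ms > t_rep
  v[late] <- v[late] * exp(-(t_ms[late] - t_rep) / tau)
  v
}

#' Generate a synthetic optical-mapping movie with ground truth
#'
#' Builds the per-pixel true activation-time map by propagating a wavefront
#' through the scene's speed field (eikonal solve; block segments are
#' impassable), then emits a fluorescence movie in which every tissue pixel
#' follows an action-potential-shaped trace activated at its true LAT, with
#' linear baseline drift and additive Gaussian noise applied last.
#'
#' @param spec a [scene_spec()].
#' @return a list with components
#'   \describe{
#'     \item{movie}{a [voltage_movie()].}
#'     \item{truth}{a `ground_truth` list: `lat_ms`, `speed_mps`, `sc_mask`
#'       (true speed below `sc_threshold_mps`), `tissue` (non-margin pixels),
#'       `unreached` (tissue pixels the front never reaches, or reaches after
#'       the movie ends — flagged, never silently truncated),
#'       `component_count` and `component_areas_mm2` for the true
#'       slow-conduction regions (components of 2+ pixels, 4-connectivity),
#'       and `percent_sc` over tissue pixels.}
#'   }
#' @export
make_movie <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  speed <- scene_speed_field(spec)
  blocked <- block_mask(spec)
  speed[blocked] <- 0
  tissue <- matrix(TRUE, spec$grid_rows, spec$grid_cols)
  m <- spec$inactive_margin_px
  if (m > 0) {
    tissue[] <- FALSE
    tissue[(m + 1):(spec$grid_rows - m), (m + 1):(spec$grid_cols - m)] <- TRUE
  }
  src <- source_mask(spec, tissue)
  if (!any(src))
    stop("source lies entirely outside the tissue", call. = FALSE)
  speed_eff <- speed
  speed_eff[!tissue] <- 0
  init <- src
  if (!is.character(spec$source)) {
    # source factorization: seed exact straight-line times in a small disk
    # around a point source where the speed field is still uniform there
    sr <- round(spec$source[1]); sc_ <- round(spec$source[2])
    v0 <- speed_eff[sr, sc_]
    d_px <- sqrt((row(speed_eff) - sr)^2 + (col(speed_eff) - sc_)^2)
    disk <- d_px <= 3 & tissue & abs(speed_eff - v0) < 1e-12
    if (v0 > 0 && all(abs(speed_eff[d_px <= 4 & tissue] - v0) < 1e-12)) {
      init <- matrix(Inf, spec$grid_rows, spec$grid_cols)
      init[disk] <- d_px[disk] * spec$pixel_size_mm / v0
    }
  }
  lat <- solve_eikonal(speed_eff, init, spec$pixel_size_mm) + spec$baseline_ms

  dur <- spec$duration_ms
  if (is.null(dur)) {
    reach <- lat[is.finite(lat)]
    dur <- max(reach) + spec$upstroke_ms + spec$apd_ms + 60
  }
  nt <- max(3L, ceiling(dur / 1000 * spec$frame_rate_hz))
  t_ms <- (seq_len(nt) - 1) / spec$frame_rate_hz * 1000

  unreached <- tissue & (!is.finite(lat) | lat > dur)
  lat_out <- lat
  lat_out[!tissue | !is.finite(lat)] <- NA_real_

  data <- array(0, dim = c(spec$grid_rows, spec$grid_cols, nt))
  act <- which(tissue & is.finite(lat))
  for (idx in act) {
    data[idx + (seq_len(nt) - 1L) * length(tissue)] <-
      ap_trace(t_ms, lat[idx], spec$upstroke_ms, spec$apd_ms)
  }
  if (spec$drift_per_s != 0) {
    ramp <- spec$drift_per_s * t_ms / 1000
    data <- data + rep(ramp, each = spec$grid_rows * spec$grid_cols)
  }
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    data <- data + stats::rnorm(length(data), sd = spec$noise_sd)
  }

  speed_truth <- speed
  speed_truth[!tissue] <- NA_real_
  sc_mask <- !is.na(speed_truth) & speed_truth < spec$sc_threshold_mps
  lab <- label_components(sc_mask)
  sizes <- lab$sizes[lab$sizes > 1L]
  truth <- structure(list(
    lat_ms = lat_out, speed_mps = speed_truth, sc_mask = sc_mask,
    tissue = tissue, unreached = unreached,
    component_count = length(sizes),
    component_areas_mm2 = sizes * spec$pixel_size_mm^2,
    percent_sc = 100 * sum(sc_mask) / sum(tissue),
    sc_threshold_mps = spec$sc_threshold_mps
  ), class = "ground_truth")

  list(
    movie = voltage_movie(data, spec$frame_rate_hz, spec$pixel_size_mm),
    truth = truth
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d x %d px, %.1f%% slow (<%g m/s), %d component(s) of 2+ px\n",
    nrow(x$lat_ms), ncol(x$lat_ms), x$percent_sc, x$sc_threshold_mps,
    x$component_count
  ))
  invisible(x)
}
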