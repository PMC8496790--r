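#' Classify pixels as slow or normal conduction
#'
#' Thresholds the conduction-velocity map: a valid pixel with speed
#' strictly below `threshold_mps` is slow conduction (SC), a valid pixel at
#' or above it is normal, and invalid or unmasked pixels are excluded. The
#' default 0.2 m/s is the conventional cutoff for pro-arrhythmic slow
#' conduction in atrial tissue.
#'
#' @param cv a `cv_map` from [cv_map()].
#' @param threshold_mps SC speed threshold (default 0.2 m/s); comparison is
#'   strict (`speed < threshold`).
#' @return an `sc_map`: list with `state` (character matrix with values
#'   `"slow"`, `"normal"`, `"excluded"`) and `threshold_mps`.
#' @export
classify_slow <- function(cv, threshold_mps = 0.2) {
  stopifnot(inherits(cv, "cv_map"))
  if (!any(cv$valid)) stop("no valid pixels to classify", call. = FALSE)
  state <- matrix("excluded", nrow(cv$speed), ncol(cv$speed))
  state[cv$valid & cv$speed < threshold_mps] <- "slow"
  state[cv$valid & cv$speed >= threshold_mps] <- "normal"
  structure(list(state = state, threshold_mps = threshold_mps),
            class = "sc_map")
}

#' Label connected slow-conduction components
#'
#' Groups slow pixels into connected components using 4-connectivity:
#' pixels are neighbors through shared horizontal or vertical edges only,
#' never diagonally. Components are grown until no further neighboring
#' slow pixel is found; every slow pixel belongs to exactly one component
#' and excluded/normal pixels to none. Implemented as a two-pass union-find
#' labeling.
#'
#' @param slow logical matrix (`TRUE` = slow pixel) or an `sc_map`.
#' @return list with `labels` (integer matrix, 0 = background, 1..n =
#'   component id in scan order) and `sizes` (integer vector of component
#'   pixel counts, indexed by label).
#' @export
label_components <- function(slow) {
  if (inherits(slow, "sc_map")) slow <- slow$state == "slow"
  stopifnot(is.logical(slow), is.matrix(slow))
  nr <- nrow(slow); nc <- ncol(slow)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  nxt <- 0L
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (!slow[i, j]) next
      up <- if (i > 1L) labels[i - 1L, j] else 0L
      left <- if (j > 1L) labels[i, j - 1L] else 0L
      if (up == 0L && left == 0L) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        labels[i, j] <- nxt
      } else if (up != 0L && left != 0L) {
        ru <- find(up); rl <- find(left)
        if (ru != rl) parent[max(ru, rl)] <- min(ru, rl)
        labels[i, j] <- min(ru, rl)
      } else {
        labels[i, j] <- max(up, left)
      }
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    # renumber roots consecutively in scan order of first appearance
    remap <- integer(nxt)
    remap[unique(roots)] <- seq_along(unique(roots))
    final <- remap[roots]
    nz <- labels != 0L
    labels[nz] <- final[labels[nz]]
    sizes <- tabulate(labels[nz], nbins = max(final))
  } else {
    sizes <- integer(0)
  }
  list(labels = labels, sizes = as.integer(sizes))
}

#' Per-recording slow-conduction outcome report
#'
#' Computes the three outcome measures of a mapped recording:
#' \itemize{
#'   \item `percent_sc`: percentage of region-of-interest pixels classified
#'     slow — computed from the binary image before any component
#'     filtering, so single-pixel components contribute;
#'   \item `n_components`: number of connected SC components with more than
#'     one pixel (single-pixel components are not counted);
#'   \item `component_areas_mm2`: area of each counted component, pixel
#'     count times `pixel_area_mm2` (0.0289 mm^2 for a 17 mm / 100 px
#'     pitch), and their mean `mean_area_mm2` (NA when nothing is counted,
#'     never 0).
#' }
#'
#' @param labels result of [label_components()] (or an `sc_map`, which is
#'   labeled internally).
#' @param pixel_area_mm2 area of one pixel (default 0.0289 mm^2).
#' @param roi logical matrix of region-of-interest pixels; the percent
#'   denominator. Must contain every slow pixel.
#' @return a `region_report`: list with `percent_sc`, `n_components`,
#'   `component_areas_mm2`, `mean_area_mm2`, `pixel_area_mm2`,
#'   `n_roi_px`, `n_slow_px`.
#' @export
region_report <- function(labels, pixel_area_mm2 = 0.0289, roi) {
  if (inherits(labels, "sc_map")) labels <- label_components(labels)
  stopifnot(is.matrix(roi), is.logical(roi),
            identical(dim(roi), dim(labels$labels)))
  if (!any(roi)) stop("empty ROI", call. = FALSE)
  n_slow <- sum(labels$labels != 0L & roi)
  counted <- labels$sizes[labels$sizes > 1L]
  areas <- counted * pixel_area_mm2
  structure(list(
    percent_sc = 100 * n_slow / sum(roi),
    n_components = length(counted),
    component_areas_mm2 = areas,
    mean_area_mm2 = if (length(areas)) mean(areas) else NA_real_,
    pixel_area_mm2 = pixel_area_mm2,
    n_roi_px = sum(roi), n_slow_px = n_slow
  ), class = "region_report")
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf(
    "<region_report> %.1f%% SC of %d ROI px; %d component(s) of 2+ px, mean area %s mm^2\n",
    x$percent_sc, x$n_roi_px, x$n_components,
    if (is.na(x$mean_area_mm2)) "NA" else sprintf("%.3f", x$mean_area_mm2)))
  invisible(x)
}
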