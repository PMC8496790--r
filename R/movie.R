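#' Voltage movie container
#'
#' A `voltage_movie` holds a fluorescence time series as a numeric array of
#' dimension `rows x cols x frames` together with the acquisition geometry:
#' the frame rate in Hz and the pixel pitch in mm. Raw, filtered and
#' normalized movies share this container.
#'
#' @param data numeric array, `rows x cols x frames`, finite values.
#' @param frame_rate_hz frames per second, positive scalar.
#' @param pixel_size_mm edge length of one pixel in mm, positive scalar.
#'
#' @return an object of class `voltage_movie`.
#' @export
voltage_movie <- function(data, frame_rate_hz, pixel_size_mm) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rows x cols x frames array", call. = FALSE)
  if (dim(data)[3] < 3L)
    stop("movie must have at least 3 frames", call. = FALSE)
  if (!all(is.finite(data)))
    stop("movie contains non-finite values", call. = FALSE)
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L || frame_rate_hz <= 0)
    stop("`frame_rate_hz` must be a positive scalar", call. = FALSE)
  if (!is.numeric(pixel_size_mm) || length(pixel_size_mm) != 1L || pixel_size_mm <= 0)
    stop("`pixel_size_mm` must be a positive scalar", call. = FALSE)
  structure(
    list(data = data, frame_rate_hz = frame_rate_hz, pixel_size_mm = pixel_size_mm),
    class = "voltage_movie"
  )
}

#' @export
print.voltage_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voltage_movie> %d x %d px, %d frames @ %g fps (%.1f ms), pixel %g mm\n",
    d[1], d[2], d[3], x$frame_rate_hz, 1000 * d[3] / x$frame_rate_hz,
    x$pixel_size_mm
  ))
  invisible(x)
}

#' @export
dim.voltage_movie <- function(x) dim(x$data)

n_frames <- function(movie) dim(movie$data)[3]

movie_duration_ms <- function(movie) 1000 * n_frames(movie) / movie$frame_rate_hz

#' Time axis of a movie in milliseconds
#'
#' Frame k (1-based) is assigned time `(k - 1) / frame_rate_hz * 1000` ms,
#' i.e. the first frame is t = 0.
#'
#' @param movie a [voltage_movie()].
#' @return numeric vector of per-frame times in ms.
#' @export
movie_times_ms <- function(movie) {
  (seq_len(n_frames(movie)) - 1) / movie$frame_rate_hz * 1000
}

#' Read / write movies as multi-page TIFF stacks
#'
#' Each frame is stored as one 32-bit float TIFF page. TIFF float storage
#' is defined on \[0, 1\], so the movie is affinely mapped onto that range
#' on write; the offset/scale and the geometry (frame rate, pixel size)
#' go to a JSON sidecar `<path>.json` and the original values are restored
#' on read. If the sidecar is missing the caller must supply the geometry
#' and values are taken as stored.
#'
#' @param movie a [voltage_movie()].
#' @param path file path for the TIFF stack.
#' @return `write_movie_tiff` returns `path` invisibly; `read_movie_tiff`
#'   returns a [voltage_movie()].
#' @export
write_movie_tiff <- function(movie, path) {
  stopifnot(inherits(movie, "voltage_movie"))
  lo <- min(movie$data)
  scale <- max(movie$data) - lo
  if (scale <= 0) scale <- 1
  frames <- lapply(seq_len(n_frames(movie)),
                   function(k) (movie$data[, , k] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = movie$frame_rate_hz,
         pixel_size_mm = movie$pixel_size_mm,
         value_offset = lo, value_scale = scale),
    paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_movie_tiff
#' @param frame_rate_hz,pixel_size_mm geometry overrides used when no JSON
#'   sidecar is present next to `path`.
#' @export
read_movie_tiff <- function(path, frame_rate_hz = NULL, pixel_size_mm = NULL) {
  if (!file.exists(path))
    stop(sprintf("movie file not found: %s", path), call. = FALSE)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = FALSE),
    error = function(e) stop(sprintf("TIFF reader failed on %s: %s", path,
                                     conditionMessage(e)), call. = FALSE)
  )
  if (is.matrix(pages)) pages <- list(pages)
  sidecar <- paste0(path, ".json")
  offset <- 0; scale <- 1
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(frame_rate_hz)) frame_rate_hz <- meta$frame_rate_hz
    if (is.null(pixel_size_mm)) pixel_size_mm <- meta$pixel_size_mm
    if (!is.null(meta$value_offset)) offset <- meta$value_offset
    if (!is.null(meta$value_scale)) scale <- meta$value_scale
  }
  if (is.null(frame_rate_hz) || is.null(pixel_size_mm))
    stop("no geometry sidecar found; supply frame_rate_hz and pixel_size_mm",
         call. = FALSE)
  data <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) data[, , k] <- pages[[k]] * scale + offset
  voltage_movie(data, frame_rate_hz, pixel_size_mm)
}

#' Write a single map (LAT, speed, ...) as a CSV grid
#'
#' Undefined pixels are written as empty cells (read back as NA).
#'
#' @param map numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map, path, sep = ",", row.names = FALSE, col.names = FALSE,
                     na = "")
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                              na.strings = c("", "NA")))
}
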