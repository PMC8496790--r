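# Independent oracles and small scene builders shared across tests.

# Brute-force 4-connectivity flood fill (stack-based DFS), deliberately a
# different algorithm from the package's two-pass union-find labeling.
flood_fill_oracle <- function(slow) {
  nr <- nrow(slow); nc <- ncol(slow)
  visited <- matrix(FALSE, nr, nc)
  sizes <- integer(0)
  for (j0 in seq_len(nc)) {
    for (i0 in seq_len(nr)) {
      if (!slow[i0, j0] || visited[i0, j0]) next
      stack <- list(c(i0, j0))
      visited[i0, j0] <- TRUE
      size <- 0L
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        size <- size + 1L
        for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
          q <- p + dd
          if (q[1] >= 1 && q[1] <= nr && q[2] >= 1 && q[2] <= nc &&
              slow[q[1], q[2]] && !visited[q[1], q[2]]) {
            visited[q[1], q[2]] <- TRUE
            stack[[length(stack) + 1L]] <- q
          }
        }
      }
      sizes <- c(sizes, size)
    }
  }
  sizes
}

# Direct (triple-loop) 2-D convolution with edge replication.
conv2_oracle <- function(mat, kernel) {
  half <- (nrow(kernel) - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      acc <- 0
      for (di in -half:half) {
        for (dj in -half:half) {
          ii <- min(max(i + di, 1L), nr)
          jj <- min(max(j + dj, 1L), nc)
          acc <- acc + kernel[di + half + 1L, dj + half + 1L] * mat[ii, jj]
        }
      }
      out[i, j] <- acc
    }
  }
  out
}

# Wrap a bare LAT matrix in a lat_map for feeding cv_map directly.
as_lat_map <- function(lat_ms, pixel_size_mm = 0.17, frame_rate_hz = 3000) {
  structure(list(lat_ms = lat_ms, frame_rate_hz = frame_rate_hz,
                 pixel_size_mm = pixel_size_mm,
                 window_ms = c(0, max(lat_ms, na.rm = TRUE) + 1),
                 method = "max_dvdt"),
            class = "lat_map")
}

# Hand-built cv_map carrying given speeds (for the regions module).
as_cv_map <- function(speed, valid = !is.na(speed), pixel_size_mm = 0.17) {
  structure(list(
    vx = speed, vy = speed * 0, speed = ifelse(valid, speed, NA_real_),
    valid = valid,
    reason = ifelse(valid, "ok", "undefined_lat"),
    fit_radius_px = 3L, poly_order = 2L, speed_cap_mps = 2,
    pixel_size_mm = pixel_size_mm
  ), class = "cv_map")
}

# Small fast scene: noise-free plane wave unless overridden.
quick_scene <- function(n = 40, frame_rate_hz = 1000, noise_sd = 0,
                        drift_per_s = 0, ...) {
  scene_spec(grid_rows = n, grid_cols = n, frame_rate_hz = frame_rate_hz,
             base_speed_mps = 0.5, source = "left",
             noise_sd = noise_sd, drift_per_s = drift_per_s, ...)
}

interior_mask <- function(n, border = 4L) {
  m <- matrix(FALSE, n, n)
  m[(border + 1):(n - border), (border + 1):(n - border)] <- TRUE
  m
}
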