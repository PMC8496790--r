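#' Conduction velocity map from an activation-time surface
#'
#' Estimates the per-pixel conduction velocity by locally fitting the
#' activation surface T(x, y) with a low-order polynomial (least squares
#' over a circular pixel neighborhood) and converting its spatial gradient
#' g = grad T (ms/mm) into a velocity via the inverse-gradient identity
#' v = g / |g|^2, the standard construction for activation surfaces: the
#' wavefront moves normal to the isochrones with speed 1/|g|. With T in ms
#' and distances in mm, speeds come out directly in m/s.
#'
#' Pixel validity: a pixel is invalid when its LAT is undefined, when the
#' neighborhood holds fewer defined LATs than polynomial coefficients
#' (`underdetermined`), when the fitted gradient magnitude falls below
#' `gradient_floor` (`flat_gradient`: quasi-simultaneous activation, no
#' meaningful direction), or when the implied speed exceeds `speed_cap_mps`
#' (`implausible`). Invalid pixels are excluded from slow-conduction
#' statistics rather than classified; their counts are reported.
#'
#' @param lat a `lat_map` from [local_activation_times()].
#' @param fit_radius_px radius of the circular fit neighborhood in pixels
#'   (default 3).
#' @param poly_order polynomial order of the local surface fit, 1 or 2
#'   (default 2).
#' @param speed_cap_mps physiological upper bound on speed (default 2 m/s).
#' @param gradient_floor minimum |grad T| in ms/mm treated as a real
#'   wavefront (default 1e-6).
#' @return a `cv_map`: list with matrices `vx`, `vy`, `speed` (m/s; NA where
#'   invalid), logical `valid`, character `reason`
#'   (`"ok"`, `"undefined_lat"`, `"underdetermined"`, `"flat_gradient"`,
#'   `"implausible"`), and the fit provenance (`fit_radius_px`,
#'   `poly_order`, `speed_cap_mps`, `pixel_size_mm`).
#' @export
cv_map <- function(lat, fit_radius_px = 3L, poly_order = 2L,
                   speed_cap_mps = 2, gradient_floor = 1e-6) {
  stopifnot(inherits(lat, "lat_map"))
  if (!poly_order %in% c(1L, 2L))
    stop("poly_order must be 1 or 2", call. = FALSE)
  if (fit_radius_px < 1L)
    stop("fit_radius_px must be at least 1", call. = FALSE)
  h <- lat$pixel_size_mm
  T_ms <- lat$lat_ms
  nr <- nrow(T_ms); nc <- ncol(T_ms)

  r <- as.integer(fit_radius_px)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[offs$di^2 + offs$dj^2 <= r^2, ]
  npts <- nrow(offs)
  # x along columns, y along rows, in mm
  xs <- offs$dj * h; ys <- offs$di * h
  X <- if (poly_order == 1L) cbind(1, xs, ys)
       else cbind(1, xs, ys, xs^2, xs * ys, ys^2)
  ncoef <- ncol(X)
  # pseudo-inverse rows for the two linear coefficients (the gradient at 0)
  pinv_full <- solve(crossprod(X), t(X))[2:3, , drop = FALSE]

  # neighbor value stack: V[, k] = T shifted by offset k, NA-padded
  V <- matrix(NA_real_, nr * nc, npts)
  for (k in seq_len(npts)) {
    di <- offs$di[k]; dj <- offs$dj[k]
    src_r <- seq_len(nr) + di; src_c <- seq_len(nc) + dj
    ok_r <- src_r >= 1L & src_r <= nr; ok_c <- src_c >= 1L & src_c <= nc
    sh <- matrix(NA_real_, nr, nc)
    sh[ok_r, ok_c] <- T_ms[src_r[ok_r], src_c[ok_c]]
    V[, k] <- sh
  }

  defined <- !is.na(T_ms)
  n_avail <- rowSums(!is.na(V))
  gx <- rep(NA_real_, nr * nc); gy <- rep(NA_real_, nr * nc)
  reason <- rep("undefined_lat", nr * nc)

  full <- which(defined & n_avail == npts)
  if (length(full)) {
    G <- V[full, , drop = FALSE] %*% t(pinv_full)
    gx[full] <- G[, 1]; gy[full] <- G[, 2]
    reason[full] <- "ok"
  }
  partial <- which(defined & n_avail < npts)
  for (idx in partial) {
    keep <- !is.na(V[idx, ])
    if (sum(keep) < ncoef) { reason[idx] <- "underdetermined"; next }
    Xk <- X[keep, , drop = FALSE]
    cf <- tryCatch(qr.coef(qr(Xk), V[idx, keep]), error = function(e) NULL)
    if (is.null(cf) || any(is.na(cf[2:3]))) { reason[idx] <- "underdetermined"; next }
    gx[idx] <- cf[2]; gy[idx] <- cf[3]
    reason[idx] <- "ok"
  }

  gmag2 <- gx^2 + gy^2
  est <- reason == "ok"
  flat <- est & sqrt(gmag2) < gradient_floor
  reason[flat] <- "flat_gradient"
  speed <- ifelse(est & !flat, 1 / sqrt(gmag2), NA_real_)
  fast <- est & !flat & speed > speed_cap_mps
  reason[fast] <- "implausible"
  valid <- reason == "ok"
  speed[!valid] <- NA_real_
  vx <- ifelse(valid, gx / gmag2, NA_real_)
  vy <- ifelse(valid, gy / gmag2, NA_real_)

  if (!any(valid))
    stop("conduction velocity undefined everywhere (no valid pixel)", call. = FALSE)

  structure(list(
    vx = matrix(vx, nr, nc), vy = matrix(vy, nr, nc),
    speed = matrix(speed, nr, nc), valid = matrix(valid, nr, nc),
    reason = matrix(reason, nr, nc),
    fit_radius_px = r, poly_order = poly_order,
    speed_cap_mps = speed_cap_mps, pixel_size_mm = h
  ), class = "cv_map")
}

#' @export
print.cv_map <- function(x, ...) {
  tab <- table(x$reason)
  cat(sprintf("<cv_map> %d x %d px, %d valid; median speed %.3f m/s\n",
              nrow(x$speed), ncol(x$speed), sum(x$valid),
              stats::median(x$speed[x$valid])))
  bad <- tab[setdiff(names(tab), "ok")]
  if (length(bad))
    cat("  excluded:", paste(sprintf("%s=%d", names(bad), bad), collapse = ", "), "\n")
  invisible(x)
}
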