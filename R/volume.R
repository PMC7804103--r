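#' 3D scalar volume with physical voxel spacing
#'
#' `volume3d()` is the common currency of the imaging stages: a 3D numeric
#' array plus per-axis voxel spacing (mm) and a physical origin (mm).
#' Voxel indices are 1-based in R; the physical center of voxel
#' `(i, j, k)` is `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param values numeric 3D array.
#' @param spacing_mm positive length-3 numeric, voxel size per axis in mm.
#' @param origin_mm length-3 numeric, physical position of voxel (1,1,1).
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(values, spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  spacing_mm <- as.numeric(spacing_mm)
  origin_mm <- as.numeric(origin_mm)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stop("`spacing_mm` must be 3 strictly positive finite numbers",
         call. = FALSE)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite numbers", call. = FALSE)
  structure(list(values = values, spacing_mm = spacing_mm,
                 origin_mm = origin_mm),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(signif(x$spacing_mm, 4), collapse = "x"),
              paste(signif(x$origin_mm, 4), collapse = ", ")))
  cat(sprintf("  intensity range [%g, %g]\n",
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$values)

is_volume3d <- function(x) inherits(x, "volume3d")

#' Voxel volume in mL
#' @param vol a `volume3d` or a length-3 spacing vector.
#' @return voxel volume in millilitres (mm^3 / 1000).
#' @export
voxel_volume_ml <- function(vol) {
  sp <- if (is_volume3d(vol)) vol$spacing_mm else as.numeric(vol)
  prod(sp) / 1000
}

# Physical coordinates (mm) of all voxel centers along one axis
axis_coords <- function(vol, axis) {
  vol$origin_mm[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing_mm[axis]
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$values), dim(b$values)) &&
    all(abs(a$spacing_mm - b$spacing_mm) < tol) &&
    all(abs(a$origin_mm - b$origin_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!same_grid(a, b))
    stop("volumes are not on the same grid (shape/spacing/origin differ)",
         call. = FALSE)
  invisible(TRUE)
}

#' Trilinear interpolation of a volume at physical points
#'
#' Points outside the grid are assigned `fill`. Used by resampling and
#' rigid registration.
#'
#' @param vol a `volume3d`.
#' @param points n x 3 matrix of physical coordinates (mm).
#' @param fill value for points outside the field of view.
#' @return numeric vector of length n.
#' @keywords internal
interp_trilinear <- function(vol, points, fill = 0) {
  d <- dim(vol$values)
  # continuous 1-based voxel coordinates
  cx <- (points[, 1] - vol$origin_mm[1]) / vol$spacing_mm[1] + 1
  cy <- (points[, 2] - vol$origin_mm[2]) / vol$spacing_mm[2] + 1
  cz <- (points[, 3] - vol$origin_mm[3]) / vol$spacing_mm[3] + 1
  out <- rep(fill, nrow(points))
  inside <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
  if (!any(inside)) return(out)
  cx <- cx[inside]; cy <- cy[inside]; cz <- cz[inside]
  x0 <- pmin(floor(cx), d[1] - 1); x0 <- pmax(x0, 1)
  y0 <- pmin(floor(cy), d[2] - 1); y0 <- pmax(y0, 1)
  z0 <- pmin(floor(cz), d[3] - 1); z0 <- pmax(z0, 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  v <- vol$values
  idx <- function(i, j, k) v[cbind(i, j, k)]
  val <-
    idx(x0,     y0,     z0    ) * (1 - fx) * (1 - fy) * (1 - fz) +
    idx(x0 + 1, y0,     z0    ) * fx       * (1 - fy) * (1 - fz) +
    idx(x0,     y0 + 1, z0    ) * (1 - fx) * fy       * (1 - fz) +
    idx(x0,     y0,     z0 + 1) * (1 - fx) * (1 - fy) * fz       +
    idx(x0 + 1, y0 + 1, z0    ) * fx       * fy       * (1 - fz) +
    idx(x0 + 1, y0,     z0 + 1) * fx       * (1 - fy) * fz       +
    idx(x0,     y0 + 1, z0 + 1) * (1 - fx) * fy       * fz       +
    idx(x0 + 1, y0 + 1, z0 + 1) * fx       * fy       * fz
  out[inside] <- val
  out
}

# Nearest-neighbour interpolation at physical points (for masks)
interp_nearest <- function(vol, points, fill = 0) {
  d <- dim(vol$values)
  cx <- round((points[, 1] - vol$origin_mm[1]) / vol$spacing_mm[1] + 1)
  cy <- round((points[, 2] - vol$origin_mm[2]) / vol$spacing_mm[2] + 1)
  cz <- round((points[, 3] - vol$origin_mm[3]) / vol$spacing_mm[3] + 1)
  out <- rep(fill, nrow(points))
  inside <- cx >= 1 & cx <= d[1] & cy >= 1 & cy <= d[2] & cz >= 1 & cz <= d[3]
  out[inside] <- vol$values[cbind(cx[inside], cy[inside], cz[inside])]
  out
}

# Separable Gaussian smoothing with sigma in mm per axis; optionally
# mask-normalized (Nadaraya-Watson) so edges/foreground borders do not bleed.
gaussian_smooth <- function(vol, sigma_mm, mask = NULL) {
  v <- vol$values
  if (is.null(mask)) {
    num <- v
    den <- array(1, dim(v))
  } else {
    num <- v * mask
    den <- mask * 1.0
  }
  for (axis in 1:3) {
    s <- sigma_mm / vol$spacing_mm[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * ((-r:r) / s)^2)
    k <- k / sum(k)
    num <- convolve_axis(num, k, axis)
    den <- convolve_axis(den, k, axis)
  }
  out <- num / pmax(den, .Machine$double.eps)
  volume3d(out, vol$spacing_mm, vol$origin_mm)
}

# 1D convolution of a 3D array along an axis with zero padding
convolve_axis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
  }
  res <- array(out, dp)
  aperm(res, order(perm))
}
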