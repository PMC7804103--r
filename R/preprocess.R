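#' Bias field correction
#'
#' Removes a smooth multiplicative intensity inhomogeneity (coil/B1 bias)
#' in the spirit of N4: the log-intensity within the foreground is fitted
#' by a smooth field (mask-normalized Gaussian kernel regression at the
#' control-grid scale, iterated), the field is mean-centered over the
#' foreground so the overall intensity scale is preserved, and the image is
#' divided by its exponential. The estimated field contains no spatial
#' frequencies above the control-grid scale by construction.
#'
#' @param vol a [volume3d] with strictly positive foreground intensities.
#' @param foreground logical array of voxels to fit (default: above Otsu-like
#'   mean threshold).
#' @param control_grid_spacing_mm smoothness scale of the estimated field
#'   (mm); the Gaussian kernel sigma is half this value.
#' @param max_iters number of fit-and-remove iterations.
#' @return list with `corrected` ([volume3d]) and `field` (multiplicative
#'   bias estimate, [volume3d]).
#' @export
correct_bias <- function(vol, foreground = NULL,
                         control_grid_spacing_mm = 30, max_iters = 2) {
  stopifnot(is_volume3d(vol))
  if (is.null(foreground)) foreground <- vol$values > mean(vol$values)
  if (any(vol$values[foreground] <= 0))
    stop(paste("foreground contains nonpositive intensities;",
               "shift the image before bias correction"), call. = FALSE)
  logv <- vol$values
  logv[!foreground] <- NA
  logv[foreground] <- log(logv[foreground])
  work <- logv
  total_field <- array(0, dim(vol$values))
  sigma <- control_grid_spacing_mm / 2
  fg <- foreground * 1.0
  for (it in seq_len(max_iters)) {
    tmp <- work
    tmp[!foreground] <- 0
    sm <- gaussian_smooth(volume3d(tmp, vol$spacing_mm, vol$origin_mm),
                          sigma, mask = fg)$values
    sm <- sm - mean(sm[foreground])     # preserve global scale
    total_field <- total_field + sm
    work[foreground] <- work[foreground] - sm[foreground]
  }
  field <- exp(total_field)
  corrected <- vol$values / field
  list(corrected = volume3d(corrected, vol$spacing_mm, vol$origin_mm),
       field = volume3d(field, vol$spacing_mm, vol$origin_mm))
}

#' Landmark-based intensity standardization (Nyul)
#'
#' `nyul_fit()` learns a standard intensity scale from reference volumes:
#' for each volume the intensities at `percentile_landmarks` are computed,
#' and the standard scale is their per-landmark mean. `nyul_apply()` maps a
#' volume onto the standard scale by continuous piecewise-linear
#' interpolation between its own landmark intensities and the standard
#' values, extrapolating linearly beyond the end landmarks.
#'
#' @param reference_volumes list of [volume3d] (or numeric vectors of
#'   intensities) defining the standard scale.
#' @param percentile_landmarks increasing percentiles in `[0, 100]`;
#'   default min, deciles, max.
#' @param foreground optional list of logical arrays restricting each
#'   reference to head voxels.
#' @return `nyul_fit()` returns an `intensity_mapping`:
#'   `list(percentiles, standard_scale)`.
#' @export
nyul_fit <- function(reference_volumes,
                     percentile_landmarks = c(0, seq(10, 90, 10), 100),
                     foreground = NULL) {
  if (length(percentile_landmarks) < 2 ||
      any(diff(percentile_landmarks) <= 0))
    stop("percentile_landmarks must be >= 2 strictly increasing values",
         call. = FALSE)
  lm <- vapply(seq_along(reference_volumes), function(i) {
    v <- reference_volumes[[i]]
    x <- if (is_volume3d(v)) as.numeric(v$values) else as.numeric(v)
    if (!is.null(foreground)) x <- x[as.logical(foreground[[i]])]
    if (length(unique(x)) < 2)
      stop("degenerate reference histogram (all intensities equal)",
           call. = FALSE)
    stats::quantile(x, percentile_landmarks / 100, names = FALSE, type = 7)
  }, numeric(length(percentile_landmarks)))
  std <- rowMeans(matrix(lm, nrow = length(percentile_landmarks)))
  if (any(diff(std) <= 0))
    stop("standard scale landmarks are not strictly increasing", call. = FALSE)
  structure(list(percentiles = percentile_landmarks, standard_scale = std),
            class = "intensity_mapping")
}

#' @rdname nyul_fit
#' @param vol a [volume3d] to standardize.
#' @param mapping an `intensity_mapping` from `nyul_fit()`.
#' @param vol_foreground optional logical array for landmark estimation.
#' @export
nyul_apply <- function(vol, mapping, vol_foreground = NULL) {
  stopifnot(is_volume3d(vol), inherits(mapping, "intensity_mapping"))
  x <- as.numeric(vol$values)
  xf <- if (is.null(vol_foreground)) x else x[as.logical(vol_foreground)]
  if (length(unique(xf)) < 2)
    stop("degenerate histogram (all intensities equal)", call. = FALSE)
  src <- stats::quantile(xf, mapping$percentiles / 100, names = FALSE,
                         type = 7)
  if (any(diff(src) <= 0)) {
    # collapse duplicated landmarks (flat histogram regions)
    keep <- c(TRUE, diff(src) > 0)
    src <- src[keep]
    tgt <- mapping$standard_scale[keep]
  } else tgt <- mapping$standard_scale
  mapped <- stats::approx(src, tgt, xout = x, rule = 2)$y
  # linear extrapolation beyond the end landmarks with the end-segment slope
  k <- length(src)
  lo <- x < src[1]
  hi <- x > src[k]
  if (any(lo)) {
    s <- (tgt[2] - tgt[1]) / (src[2] - src[1])
    mapped[lo] <- tgt[1] + s * (x[lo] - src[1])
  }
  if (any(hi)) {
    s <- (tgt[k] - tgt[k - 1]) / (src[k] - src[k - 1])
    mapped[hi] <- tgt[k] + s * (x[hi] - src[k])
  }
  volume3d(array(mapped, dim(vol$values)), vol$spacing_mm, vol$origin_mm)
}

#' Resample a volume to a new voxel spacing
#'
#' The physical field of view is preserved (within one voxel). Linear
#' interpolation is used for intensity images, nearest-neighbour for masks.
#'
#' @param vol a [volume3d].
#' @param target_spacing_mm length-3 (or scalar, recycled) spacing in mm.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return a [volume3d] on the new grid.
#' @export
resample <- function(vol, target_spacing_mm, interpolation = "linear") {
  stopifnot(is_volume3d(vol))
  tsp <- rep_len(as.numeric(target_spacing_mm), 3)
  if (any(tsp <= 0)) stop("target spacing must be positive", call. = FALSE)
  extent <- dim(vol$values) * vol$spacing_mm
  nd <- pmax(1L, as.integer(round(extent / tsp)))
  if (all(abs(tsp - vol$spacing_mm) < 1e-9)) return(vol)
  # new voxel centers, aligned so both grids share the field-of-view corner
  coords <- lapply(1:3, function(a) {
    vol$origin_mm[a] - vol$spacing_mm[a] / 2 + (seq_len(nd[a]) - 0.5) * tsp[a]
  })
  pts <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]]))
  vals <- switch(interpolation,
    linear = interp_trilinear(clamp_edges(vol), pts),
    nearest = interp_nearest(vol, pts),
    stop("interpolation must be 'linear' or 'nearest'", call. = FALSE))
  volume3d(array(vals, nd), tsp,
           origin_mm = vol$origin_mm - vol$spacing_mm / 2 + tsp / 2)
}

# For linear resampling near the face of the grid the target center can sit
# outside the source voxel-center hull; clamp by edge replication pad of 1.
clamp_edges <- function(vol) {
  d <- dim(vol$values)
  v <- array(0, d + 2)
  v[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- vol$values
  v[1, , ] <- v[2, , ]; v[d[1] + 2, , ] <- v[d[1] + 1, , ]
  v[, 1, ] <- v[, 2, ]; v[, d[2] + 2, ] <- v[, d[2] + 1, ]
  v[, , 1] <- v[, , 2]; v[, , d[3] + 2] <- v[, , d[3] + 1]
  volume3d(v, vol$spacing_mm, vol$origin_mm - vol$spacing_mm)
}

#' Rigid registration of two volumes
#'
#' Estimates the 6-parameter rigid transform (rotations in radians about
#' the volume center, then translation in mm) mapping points of the fixed
#' grid into the moving volume, by maximizing normalized cross-correlation
#' with a two-level coarse-to-fine search (translation-only first, then all
#' six parameters, Nelder-Mead).
#'
#' @param moving,fixed [volume3d] objects with overlapping fields of view.
#' @param smooth_sigma_mm Gaussian pre-smoothing for a smoother cost
#'   landscape.
#' @return a `rigid_transform`: list with `rotation_rad` (3),
#'   `translation_mm` (3), `center_mm`, and `metric` (final NCC).
#' @export
register_rigid <- function(moving, fixed, smooth_sigma_mm = 2) {
  stopifnot(is_volume3d(moving), is_volume3d(fixed))
  mv <- gaussian_smooth(moving, smooth_sigma_mm)
  fx <- gaussian_smooth(fixed, smooth_sigma_mm)
  center <- fixed$origin_mm + (dim(fixed$values) - 1) * fixed$spacing_mm / 2
  coords <- lapply(1:3, function(a) axis_coords(fixed, a))
  pts <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]]))
  fvals <- as.numeric(fx$values)
  cost <- function(par) {
    mapped <- rigid_map_points(pts, par[1:3], par[4:6], center)
    mvals <- interp_trilinear(mv, mapped, fill = NA)
    ok <- !is.na(mvals)
    if (sum(ok) < 10) return(1)
    -abs(stats::cor(mvals[ok], fvals[ok]))
  }
  # stage 1: translation only
  c3 <- function(tr) cost(c(0, 0, 0, tr))
  o1 <- stats::optim(c(0, 0, 0), c3, method = "Nelder-Mead",
                     control = list(maxit = 300, reltol = 1e-8))
  # stage 2: full 6-parameter refinement
  o2 <- stats::optim(c(0, 0, 0, o1$par), cost, method = "Nelder-Mead",
                     control = list(maxit = 600, reltol = 1e-10))
  if (!o2$convergence %in% c(0, 1))
    stop("rigid registration failed to converge; final metric ",
         signif(-o2$value, 4), call. = FALSE)
  structure(list(rotation_rad = o2$par[1:3], translation_mm = o2$par[4:6],
                 center_mm = center, metric = -o2$value),
            class = "rigid_transform")
}

# map physical points through the rigid transform: rotate about center
# (R = Rz %*% Ry %*% Rx), then translate
rigid_map_points <- function(pts, rot, trans, center) {
  R <- rot_matrix(rot)
  sw <- sweep(pts, 2, center)
  out <- sw %*% t(R)
  sweep(out, 2, center + trans, `+`)
}

rot_matrix <- function(rot) {
  cx <- cos(rot[1]); sx <- sin(rot[1])
  cy <- cos(rot[2]); sy <- sin(rot[2])
  cz <- cos(rot[3]); sz <- sin(rot[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply or invert a rigid transform
#'
#' `apply_rigid()` resamples the moving volume onto the fixed grid through
#' the transform. `invert_rigid()` returns the inverse transform about the
#' same center.
#'
#' @param moving a [volume3d]; `fixed` defines the output grid.
#' @param transform a `rigid_transform`.
#' @param interpolation `"linear"` or `"nearest"`.
#' @export
apply_rigid <- function(moving, fixed, transform,
                        interpolation = "linear") {
  coords <- lapply(1:3, function(a) axis_coords(fixed, a))
  pts <- as.matrix(expand.grid(coords[[1]], coords[[2]], coords[[3]]))
  mapped <- rigid_map_points(pts, transform$rotation_rad,
                             transform$translation_mm, transform$center_mm)
  vals <- if (interpolation == "nearest") interp_nearest(moving, mapped)
          else interp_trilinear(moving, mapped)
  volume3d(array(vals, dim(fixed$values)), fixed$spacing_mm, fixed$origin_mm)
}

#' @rdname apply_rigid
#' @export
invert_rigid <- function(transform) {
  R <- rot_matrix(transform$rotation_rad)
  # inverse: x' = R^T (x - c - t) + c; recover euler angles of R^T
  Rt <- t(R)
  ry <- -asin(Rt[3, 1])
  rx <- atan2(Rt[3, 2] / cos(ry), Rt[3, 3] / cos(ry))
  rz <- atan2(Rt[2, 1] / cos(ry), Rt[1, 1] / cos(ry))
  structure(list(rotation_rad = c(rx, ry, rz),
                 translation_mm = as.numeric(-Rt %*% transform$translation_mm),
                 center_mm = transform$center_mm, metric = transform$metric),
            class = "rigid_transform")
}

#' Cross-sequence intensity matching
#'
#' Fits a linear gain/offset model on non-enhancing voxels so the
#' pre-contrast volume's mean and standard deviation over the mask match
#' the post-contrast volume's, then applies it to the whole pre-contrast
#' volume. After matching, the subtraction map is zero-mean over
#' non-enhancing tissue.
#'
#' @param t1w,t1wc co-registered [volume3d] volumes on the same grid.
#' @param nonenhancing_mask logical array of normal-tissue voxels.
#' @return list with `matched` ([volume3d]), `gain`, `offset`.
#' @export
match_intensity <- function(t1w, t1wc, nonenhancing_mask) {
  stop_if_grid_mismatch(t1w, t1wc)
  m <- as.logical(nonenhancing_mask)
  if (!any(m)) stop("non-enhancing mask is empty", call. = FALSE)
  x <- t1w$values[m]
  y <- t1wc$values[m]
  if (stats::sd(x) == 0)
    stop("zero variance in non-enhancing mask; cannot fit gain", call. = FALSE)
  gain <- stats::sd(y) / stats::sd(x)
  offset <- mean(y) - gain * mean(x)
  matched <- volume3d(t1w$values * gain + offset, t1w$spacing_mm,
                      t1w$origin_mm)
  list(matched = matched, gain = gain, offset = offset)
}

#' Subtraction enhancement map
#'
#' Voxelwise post-contrast minus (intensity-matched) pre-contrast volume.
#' Enhancement (contrast uptake) is positive by construction.
#'
#' @param t1wc,t1w_matched [volume3d] on identical grids.
#' @return a [volume3d] enhancement map.
#' @export
subtract <- function(t1wc, t1w_matched) {
  stop_if_grid_mismatch(t1wc, t1w_matched)
  volume3d(t1wc$values - t1w_matched$values, t1wc$spacing_mm,
           t1wc$origin_mm)
}
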