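#' Segment the enhancing rim from a subtraction map
#'
#' Thresholds the subtraction enhancement map, applies morphological
#' opening then closing with spherical structuring elements of physical
#' radius (implemented through the exact Euclidean distance transform, so
#' anisotropic voxels are honoured), and discards connected components
#' (26-connectivity) smaller than `min_component_ml`. An empty result is a
#' valid output and is flagged non-measurable rather than raising an error.
#'
#' @param subtraction_map a [volume3d] (T1wC minus matched T1w).
#' @param threshold intensity threshold; voxels strictly above it are
#'   candidate enhancement. No default is meaningful across scanners —
#'   choose relative to the rim contrast.
#' @param opening_radius_mm,closing_radius_mm structuring-element radii in
#'   mm (0 = skip).
#' @param min_component_ml minimum component volume in mL (0 = keep all).
#' @return an `enhancement_mask`: list with `mask` (logical array),
#'   `spacing_mm`, `measurable` flag.
#' @export
segment_enhancement <- function(subtraction_map, threshold,
                                opening_radius_mm = 0,
                                closing_radius_mm = 0,
                                min_component_ml = 0) {
  stopifnot(is_volume3d(subtraction_map), is.finite(threshold))
  m <- subtraction_map$values > threshold
  sp <- subtraction_map$spacing_mm
  if (opening_radius_mm > 0) m <- morph_open(m, sp, opening_radius_mm)
  if (closing_radius_mm > 0) m <- morph_close(m, sp, closing_radius_mm)
  if (min_component_ml > 0 && any(m)) {
    lab <- label_components(m)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes * voxel_volume_ml(sp) >= min_component_ml)
    m <- array(lab %in% keep, dim(m))
  }
  enhancement_mask(m, sp)
}

#' @rdname segment_enhancement
#' @param mask logical (or 0/1) 3D array.
#' @param spacing_mm voxel spacing in mm.
#' @export
enhancement_mask <- function(mask, spacing_mm) {
  mask <- array(as.logical(mask), dim(as.array(mask)))
  structure(list(mask = mask, spacing_mm = as.numeric(spacing_mm),
                 measurable = any(mask)),
            class = "enhancement_mask")
}

#' @export
print.enhancement_mask <- function(x, ...) {
  cat(sprintf("<enhancement_mask> %s voxels, %d foreground (%s), %.3f mL\n",
              paste(dim(x$mask), collapse = "x"), sum(x$mask),
              if (x$measurable) "measurable" else "non-measurable",
              sum(x$mask) * voxel_volume_ml(x$spacing_mm)))
  invisible(x)
}

# 26-connected component labelling
label_components <- function(mask, connectivity = 26) {
  array(.label_components_cpp(as.integer(mask), dim(mask),
                              as.integer(connectivity)), dim(mask))
}

# morphology via the exact EDT: erosion keeps voxels farther than r from
# background; dilation keeps voxels within r of foreground
morph_erode <- function(mask, spacing, r) {
  d <- edt_mm(mask, spacing)
  d > r
}
morph_dilate <- function(mask, spacing, r) {
  # pad = TRUE here: outside the grid must NOT count as mask foreground
  d <- edt_mm(!mask, spacing, pad = TRUE)
  mask | (d > 0 & d <= r)
}
morph_open <- function(mask, spacing, r)
  morph_dilate(morph_erode(mask, spacing, r), spacing, r)
morph_close <- function(mask, spacing, r)
  morph_erode(morph_dilate(mask, spacing, r), spacing, r)

# exact anisotropic EDT (mm): distance of each foreground voxel center to
# the nearest background voxel center; the grid is treated as padded by one
# layer of background so masks touching the array edge have finite distances
edt_mm <- function(mask, spacing, pad = FALSE) {
  d <- dim(mask)
  padded <- array(pad, d + 2)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask
  sq <- array(.edt_sq_cpp(as.integer(padded), dim(padded),
                          as.numeric(spacing)), dim(padded))
  sqrt(sq[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)])
}

#' Euclidean distance transform of an enhancement mask
#'
#' Exact anisotropic-spacing-aware Euclidean distance (mm) from every
#' foreground voxel center to the nearest background voxel center; zero
#' outside the mask. The array boundary counts as background (the grid is
#' implicitly padded), so a mask touching the edge still has a finite,
#' well-defined thickness.
#'
#' @param mask an `enhancement_mask` (nonempty).
#' @return a [volume3d] of distances in mm.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "enhancement_mask"))
  if (!mask$measurable) stop("empty mask has no distance transform",
                             call. = FALSE)
  volume3d(edt_mm(mask$mask, mask$spacing_mm), mask$spacing_mm)
}

#' Thickness and volume statistics of an enhancement mask
#'
#' Mean and maximum of the 3D Euclidean distance transform over the mask
#' foreground — the residual-enhancement thickness statistics — plus the
#' mask volume. Note that for a shell-shaped rim the distance transform's
#' maximum is the half-thickness of the shell (distance to the nearest of
#' the two boundaries); the statistic remains strictly monotone in the true
#' rim thickness, which is what the prognostic models use.
#'
#' @param mask an `enhancement_mask`.
#' @return a `thickness_result`: list with `mean_thickness_mm`,
#'   `max_thickness_mm`, `volume_ml`, `n_voxels`, `measurable`. For an
#'   empty mask, a non-measurable sentinel with `NA` statistics.
#' @export
thickness_stats <- function(mask) {
  stopifnot(inherits(mask, "enhancement_mask"))
  if (!mask$measurable) {
    return(structure(list(mean_thickness_mm = NA_real_,
                          max_thickness_mm = NA_real_,
                          volume_ml = 0, n_voxels = 0L, measurable = FALSE),
                     class = "thickness_result"))
  }
  dt <- distance_transform(mask)$values[mask$mask]
  structure(list(mean_thickness_mm = mean(dt),
                 max_thickness_mm = max(dt),
                 volume_ml = sum(mask$mask) * voxel_volume_ml(mask$spacing_mm),
                 n_voxels = sum(mask$mask), measurable = TRUE),
            class = "thickness_result")
}

#' @export
print.thickness_result <- function(x, ...) {
  if (!x$measurable) cat("<thickness_result> non-measurable (empty mask)\n")
  else cat(sprintf(
    "<thickness_result> mean %.2f mm, max %.2f mm, volume %.3f mL (%d voxels)\n",
    x$mean_thickness_mm, x$max_thickness_mm, x$volume_ml, x$n_voxels))
  invisible(x)
}
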