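DEFAULT_ALPS_CENTERS <- matrix(
  c(24, -12, 24,
    -28, -12, 24,
    36, -12, 24,
    -40, -12, 24),
  ncol = 3, byrow = TRUE,
  dimnames = list(NULL, c("x", "y", "z"))
)

#' Build the DTI-ALPS spherical ROI set
#'
#' Four 6-mm-diameter spheres in template (MNI) space at the level of the
#' lateral-ventricle body, two per hemisphere: a medial one over the
#' projection fibers (corona radiata, inferior-superior) and a lateral one
#' over the association fibers (superior longitudinal fasciculus,
#' anterior-posterior). Side is assigned by the sign of x (positive = right)
#' and role by |x| within a side (smaller |x| = projection).
#'
#' @param centers 4 x 3 matrix of sphere centers in template mm; the default
#'   is (24,-12,24), (-28,-12,24), (36,-12,24), (-40,-12,24).
#' @param diameter sphere diameter in mm (default 6).
#' @return object of class `alps_roi_set`: a data.frame with columns
#'   `side`, `role`, `x`, `y`, `z`, `diameter`.
#' @export
build_roi_set <- function(centers = DEFAULT_ALPS_CENTERS, diameter = 6) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) == 4, ncol(centers) == 3, diameter > 0)
  side <- ifelse(centers[, 1] >= 0, "right", "left")
  role <- rep(NA_character_, 4)
  for (s in c("left", "right")) {
    idx <- which(side == s)
    if (length(idx) != 2) {
      stop("each side must have exactly two ROIs (one projection, one association)")
    }
    ax <- abs(centers[idx, 1])
    if (ax[1] == ax[2]) stop("ROIs on side '", s, "' have duplicated |x|; roles ambiguous")
    role[idx[which.min(ax)]] <- "projection"
    role[idx[which.max(ax)]] <- "association"
  }
  rois <- data.frame(side = side, role = role,
                     x = centers[, 1], y = centers[, 2], z = centers[, 3],
                     diameter = diameter, stringsAsFactors = FALSE)
  # reject overlapping spheres (possible only with overridden geometry)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
    if (d < diameter) {
      stop(sprintf("ROIs %s-%s and %s-%s overlap (center distance %.1f mm < diameter %.1f mm)",
                   rois$side[i], rois$role[i], rois$side[j], rois$role[j], d, diameter))
    }
  }
  class(rois) <- c("alps_roi_set", "data.frame")
  rois
}

#' Rasterize a spherical ROI onto a voxel grid
#'
#' A voxel is included iff its center, mapped to template mm space, lies
#' within the sphere radius of the ROI center (no partial volumes).
#'
#' @param roi one row of an [build_roi_set()] result (or any list with
#'   `x`, `y`, `z`, `diameter`).
#' @param shape target grid shape.
#' @param affine 4x4 voxel-to-template-mm matrix for the target grid.
#' @return logical array of `shape`.
#' @export
rasterize_roi <- function(roi, shape, affine) {
  centers <- voxel_centers_mm(shape, affine)
  d2 <- (centers[, 1] - roi$x)^2 + (centers[, 2] - roi$y)^2 +
    (centers[, 3] - roi$z)^2
  sel <- d2 <= (roi$diameter / 2)^2
  if (!any(sel)) {
    stop(sprintf("ROI %s-%s at (%g, %g, %g) captures no voxel on the target grid",
                 roi$side %||% "?", roi$role %||% "?", roi$x, roi$y, roi$z))
  }
  array(sel, dim = shape)
}

# integer-mm lattice points of template space inside a sphere ROI;
# spacing 1 mm by default (the template grid used for ROI sampling)
roi_sample_points <- function(roi, spacing = 1) {
  r <- roi$diameter / 2
  gx <- seq(ceiling((roi$x - r) / spacing), floor((roi$x + r) / spacing)) * spacing
  gy <- seq(ceiling((roi$y - r) / spacing), floor((roi$y + r) / spacing)) * spacing
  gz <- seq(ceiling((roi$z - r) / spacing), floor((roi$z + r) / spacing)) * spacing
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  d2 <- (pts[, 1] - roi$x)^2 + (pts[, 2] - roi$y)^2 + (pts[, 3] - roi$z)^2
  pts[d2 <= r^2, , drop = FALSE]
}
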