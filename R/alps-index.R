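#' Compute the DTI-ALPS index
#'
#' For each hemisphere the index is the ratio
#' \deqn{ALPS = \frac{Dxx_{proj} + Dxx_{assoc}}{Dyy_{proj} + Dzz_{assoc}}}
#' of the x-diffusivity averaged over the projection- and association-fiber
#' ROIs to the diffusivity along the respective fiber tracts (inferior-
#' superior for projection, anterior-posterior for association). The mean
#' index is the average of the left and right indices.
#'
#' Two sampling paths are available. The default (`method = "template"`)
#' resamples the diffusivity maps into template space with trilinear
#' interpolation on a 1-mm lattice restricted to each sphere, matching a
#' workflow in which individual maps are registered to the template before
#' ROI extraction. `method = "native"` instead rasterizes the spheres onto
#' the native map grid through the affine and averages voxel values
#' directly. Sample points whose interpolation support includes an invalid
#' voxel (or invalid voxels, for the native path) are excluded from the
#' means and counted in the QC record.
#'
#' @param maps a [derive_maps()] result.
#' @param rois an [build_roi_set()] result.
#' @param affine 4x4 matrix mapping the maps' world space to template mm
#'   space (identity when the maps are already in template space).
#' @param method `"template"` (trilinear resampling, default) or
#'   `"native"` (voxel-center-in-sphere on the native grid).
#' @param spacing template-lattice spacing in mm for the template path.
#' @return object of class `alps_result`: list with `left`, `right`,
#'   `mean`, a per-ROI data.frame `roi_means` (mean Dxx/Dyy/Dzz, sample and
#'   invalid counts) and `qc`.
#' @export
compute_alps <- function(maps, rois, affine = diag(4),
                         method = c("template", "native"), spacing = 1) {
  stopifnot(inherits(maps, "diffusivity_maps"), inherits(rois, "alps_roi_set"))
  method <- match.arg(method)
  total <- affine %*% maps$affine          # voxel -> template mm
  shape <- dim(maps$fa)
  validnum <- array(as.numeric(maps$valid), dim = shape)
  # zero-fill invalid voxels so zero-weight neighbours cannot inject NA into
  # the interpolation; affected sample points are excluded by the validity
  # gate anyway
  zf <- function(a) { a[!maps$valid] <- 0; a }
  dxx_vol <- zf(maps$dxx); dyy_vol <- zf(maps$dyy); dzz_vol <- zf(maps$dzz)
  stats <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    if (method == "template") {
      pts <- roi_sample_points(roi, spacing = spacing)
      vox <- world_to_voxel(pts, total)
      v <- trilinear(validnum, vox, outside = 0)
      keep <- !is.na(v) & v >= 1 - 1e-12   # all 8 support voxels valid
      if (!any(keep)) {
        stop(sprintf("ROI %s-%s captures no valid sample point", roi$side, roi$role))
      }
      dxx <- trilinear(dxx_vol, vox[keep, , drop = FALSE])
      dyy <- trilinear(dyy_vol, vox[keep, , drop = FALSE])
      dzz <- trilinear(dzz_vol, vox[keep, , drop = FALSE])
      n_total <- nrow(pts); n_bad <- sum(!keep)
    } else {
      sel <- rasterize_roi(roi, shape, total)
      keep <- sel & maps$valid
      if (!any(keep)) {
        stop(sprintf("ROI %s-%s captures no valid voxel", roi$side, roi$role))
      }
      dxx <- maps$dxx[keep]; dyy <- maps$dyy[keep]; dzz <- maps$dzz[keep]
      n_total <- sum(sel); n_bad <- sum(sel & !maps$valid)
    }
    stats[[i]] <- data.frame(
      side = roi$side, role = roi$role,
      dxx = mean(dxx), dyy = mean(dyy), dzz = mean(dzz),
      n = n_total, n_invalid = n_bad, stringsAsFactors = FALSE
    )
  }
  roi_means <- do.call(rbind, stats)
  index_for <- function(s) {
    proj <- roi_means[roi_means$side == s & roi_means$role == "projection", ]
    asso <- roi_means[roi_means$side == s & roi_means$role == "association", ]
    den <- proj$dyy + asso$dzz
    if (den <= 0) {
      stop("non-physical diffusivities: Dyy-proj + Dzz-assoc <= 0 on the ",
           s, " side")
    }
    (proj$dxx + asso$dxx) / den
  }
  left <- index_for("left"); right <- index_for("right")
  structure(list(
    left = left, right = right, mean = (left + right) / 2,
    roi_means = roi_means, method = method,
    qc = list(n_invalid_total = sum(roi_means$n_invalid))
  ), class = "alps_result")
}

#' @export
print.alps_result <- function(x, ...) {
  cat(sprintf("<alps_result> left %.4f | right %.4f | mean %.4f (%s sampling)\n",
              x$left, x$right, x$mean, x$method))
  invisible(x)
}

#' Automated orientation QC of the ALPS ROIs
#'
#' Surrogate for the manual check of ROI placement against fiber-direction
#' maps: within each ROI, the fraction of voxels whose principal
#' eigenvector has its largest absolute component along the expected fiber
#' axis (projection: inferior-superior z; association:
#' anterior-posterior y). ROIs below the threshold are flagged, never
#' moved.
#'
#' @param tf a [tensor_field()].
#' @param rois an [build_roi_set()] result.
#' @param affine 4x4 world-to-template matrix (identity default).
#' @param threshold warn when the aligned fraction falls below this value
#'   (default 0.5).
#' @return data.frame with one row per ROI: `side`, `role`,
#'   `aligned_fraction`, `n`, `warn`.
#' @export
roi_orientation_qc <- function(tf, rois, affine = diag(4), threshold = 0.5) {
  stopifnot(inherits(tf, "tensor_field"), inherits(rois, "alps_roi_set"))
  tf <- tensor_eigen(tf)
  shape <- dim(tf$D)[1:3]
  total <- affine %*% tf$affine
  v1 <- tf$eig$vectors[, , 1]
  out <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    sel <- which(rasterize_roi(roi, shape, total) & tf$valid)
    expected_axis <- if (roi$role == "projection") 3L else 2L
    if (length(sel) == 0) {
      frac <- NA_real_
    } else {
      dom <- max.col(abs(v1[sel, , drop = FALSE]), ties.method = "first")
      frac <- mean(dom == expected_axis)
    }
    out[[i]] <- data.frame(side = roi$side, role = roi$role,
                           aligned_fraction = frac, n = length(sel),
                           warn = is.na(frac) || frac < threshold,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
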