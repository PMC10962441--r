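#' Generate a DWI phantom with planted diffusivities at the ALPS ROIs
#'
#' Builds a template-space phantom (identity-scaled affine, 1-mm grid by
#' default) whose four ALPS ROI neighbourhoods carry axis-aligned diagonal
#' tensors, so the downstream index has a closed-form expected value:
#' projection ROIs get diag(dxx_proj, dyy_proj, z_fill) with the dominant
#' eigenvector along the inferior-superior axis, association ROIs get
#' diag(dxx_assoc, y_fill, dzz_assoc) dominant along anterior-posterior.
#' The tensors are planted on spheres slightly larger than the ROIs so that
#' every ROI sample point (either sampling path) sees the planted constant.
#'
#' @param dxx_proj,dxx_assoc,dyy_proj,dzz_assoc planted diffusivities in
#'   mm^2/s (all > 0). Applied to both hemispheres unless overridden.
#' @param left,right optional per-side overrides: named lists with any of
#'   `dxx_proj`, `dxx_assoc`, `dyy_proj`, `dzz_assoc`.
#' @param rois ROI set (defaults to [build_roi_set()]).
#' @param voxel_size grid resolution in mm (default 1, aligned with the
#'   template lattice so trilinear resampling is exact).
#' @param plant_margin how far beyond the ROI radius the planted sphere
#'   extends, in mm (default 2).
#' @param noise,snr,seed,n_b0,directions,bvalue passed to [phantom_spec()].
#' @return list with `acq` (the acquisition), `rois` (the ROI set),
#'   `truth` (exact tensor field) and `expected` (closed-form left/right/
#'   mean indices from the planted values).
#' @export
generate_alps_phantom <- function(dxx_proj, dxx_assoc, dyy_proj, dzz_assoc,
                                  left = list(), right = list(),
                                  rois = build_roi_set(),
                                  voxel_size = 1, plant_margin = 2,
                                  noise = c("none", "rician"), snr = 30,
                                  seed = 1L, n_b0 = 8,
                                  directions = default_gradient_set(25),
                                  bvalue = 1000) {
  noise <- match.arg(noise)
  base <- list(dxx_proj = dxx_proj, dxx_assoc = dxx_assoc,
               dyy_proj = dyy_proj, dzz_assoc = dzz_assoc)
  if (any(unlist(base) <= 0)) stop("all planted diffusivities must be > 0")
  side_vals <- list(
    left = utils::modifyList(base, left),
    right = utils::modifyList(base, right)
  )
  plant_r <- rois$diameter[1] / 2 + plant_margin
  # planted spheres must stay disjoint (centers within a side are 12 mm apart)
  for (i in 1:3) for (j in (i + 1):4) {
    d <- sqrt(sum((as.numeric(rois[i, c("x", "y", "z")]) -
                     as.numeric(rois[j, c("x", "y", "z")]))^2))
    if (d < 2 * plant_r) {
      stop("planted ROI spheres overlap; reduce diameter or plant_margin")
    }
  }
  regions <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    roi <- rois[i, ]
    v <- side_vals[[roi$side]]
    if (roi$role == "projection") {
      zfill <- 1.6 * max(v$dxx_proj, v$dyy_proj)
      D <- diag(c(v$dxx_proj, v$dyy_proj, zfill))
    } else {
      yfill <- 1.6 * max(v$dxx_assoc, v$dzz_assoc)
      D <- diag(c(v$dxx_assoc, yfill, v$dzz_assoc))
    }
    regions[[i]] <- list(name = paste(roi$side, roi$role, sep = "_"),
                         center = c(roi$x, roi$y, roi$z),
                         radius = plant_r, tensor = D)
  }
  pad <- plant_r + 3
  lo <- floor(c(min(rois$x), min(rois$y), min(rois$z)) - pad)
  hi <- ceiling(c(max(rois$x), max(rois$y), max(rois$z)) + pad)
  shape <- as.integer((hi - lo) / voxel_size) + 1L
  affine <- scaled_affine(voxel_size, origin = lo)
  spec <- phantom_spec(shape = shape, voxel_size = voxel_size, affine = affine,
                       regions = regions,
                       background_tensor = diag(0.7e-3, 3),
                       bvalue = bvalue, directions = directions, n_b0 = n_b0,
                       noise = noise, snr = snr, seed = seed)
  ph <- generate_dwi_phantom(spec)
  idx <- function(v) (v$dxx_proj + v$dxx_assoc) / (v$dyy_proj + v$dzz_assoc)
  expected <- list(left = idx(side_vals$left), right = idx(side_vals$right))
  expected$mean <- (expected$left + expected$right) / 2
  list(acq = ph$acq, rois = rois, truth = ph$truth, expected = expected)
}
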