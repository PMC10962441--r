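#' Directional diffusivity and scalar maps from a tensor field
#'
#' Reads the apparent diffusivities along the image axes off the tensor
#' diagonal (Dxx: left-right, Dyy: anterior-posterior, Dzz:
#' inferior-superior, assuming RAS-oriented volumes) and derives fractional
#' anisotropy (FA), mean diffusivity (MD) and the principal eigenvector (V1)
#' from the eigendecomposition.
#'
#' @param tf a [tensor_field()].
#' @return object of class `diffusivity_maps`: list with 3-D arrays `dxx`,
#'   `dyy`, `dzz`, `fa`, `md`, a 4-D array `v1` (x, y, z, component), the
#'   `affine`, the `valid` mask and the propagated `qc` record.
#' @export
derive_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  tf <- tensor_eigen(tf)
  shape <- dim(tf$D)[1:3]
  ev <- tf$eig$values
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  md <- (l1 + l2 + l3) / 3
  ss <- l1^2 + l2^2 + l3^2
  fa <- sqrt(0.5 * ((l1 - l2)^2 + (l2 - l3)^2 + (l1 - l3)^2)) / sqrt(ss)
  fa[ss == 0] <- 0
  v1 <- tf$eig$vectors[, , 1]
  structure(list(
    dxx = array(tf$D[, , , 1], dim = shape),
    dyy = array(tf$D[, , , 2], dim = shape),
    dzz = array(tf$D[, , , 3], dim = shape),
    fa = array(fa, dim = shape),
    md = array(md, dim = shape),
    v1 = array(v1, dim = c(shape, 3)),
    affine = tf$affine,
    valid = tf$valid,
    qc = tf$qc
  ), class = "diffusivity_maps")
}

#' @export
print.diffusivity_maps <- function(x, ...) {
  d <- dim(x$fa)
  cat(sprintf("<diffusivity_maps> %d x %d x %d grid (Dxx/Dyy/Dzz/FA/MD/V1)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Median mean diffusivity within white matter
#'
#' The histogram-based conventional diffusion marker: the median of the MD
#' distribution over white-matter voxels.
#'
#' @param maps a [derive_maps()] result.
#' @param wm_mask logical/binary white-matter mask on the map grid.
#' @return median MD in mm^2/s.
#' @export
median_md <- function(maps, wm_mask) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  sel <- as.logical(wm_mask) & as.logical(maps$valid)
  if (!any(sel)) stop("white-matter mask does not intersect any valid voxel")
  median(maps$md[sel])
}

#' Simplified peak width of skeletonized mean diffusivity (PSMD)
#'
#' The spread (95th minus 5th percentile) of MD over a supplied white-matter
#' skeleton mask. Skeletonization itself is upstream; the mask is an input.
#' Percentiles use the linear-interpolation convention of
#' `stats::quantile(type = 7)`.
#'
#' @param maps a [derive_maps()] result.
#' @param skeleton_mask logical/binary skeleton mask on the map grid.
#' @return p95 - p5 of skeleton MD, in mm^2/s.
#' @export
psmd <- function(maps, skeleton_mask) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  sel <- as.logical(skeleton_mask) & as.logical(maps$valid)
  if (!any(sel)) stop("skeleton mask does not intersect any valid voxel")
  q <- quantile(maps$md[sel], c(0.05, 0.95), names = FALSE, type = 7)
  q[2] - q[1]
}
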