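`%||%` <- function(x, y) if (is.null(x)) y else x

#' Voxel-centre coordinates in world (mm) space
#'
#' NIfTI convention: the affine maps 0-based voxel indices to world mm.
#'
#' @param shape integer length-3 grid shape.
#' @param affine 4x4 voxel-to-world matrix.
#' @return matrix with one row per voxel (column-major order) and columns
#'   x, y, z in mm.
#' @keywords internal
voxel_centers_mm <- function(shape, affine) {
  idx <- as.matrix(expand.grid(
    i = seq_len(shape[1]) - 1L,
    j = seq_len(shape[2]) - 1L,
    k = seq_len(shape[3]) - 1L
  ))
  xyz1 <- cbind(idx, 1)
  out <- xyz1 %*% t(affine)
  out[, 1:3, drop = FALSE]
}

# map world-mm points (n x 3) to continuous 0-based voxel coordinates
world_to_voxel <- function(points_mm, affine) {
  inv <- solve(affine)
  xyz1 <- cbind(points_mm, 1)
  out <- xyz1 %*% t(inv)
  out[, 1:3, drop = FALSE]
}

#' Trilinear interpolation of a 3-D volume at continuous voxel coordinates
#'
#' @param vol 3-D numeric array.
#' @param vox n x 3 matrix of 0-based continuous voxel coordinates.
#' @param outside value returned for sample points outside the grid.
#' @return numeric vector of length n.
#' @keywords internal
trilinear <- function(vol, vox, outside = NA_real_) {
  dims <- dim(vol)
  n <- nrow(vox)
  out <- rep(outside, n)
  i0 <- floor(vox[, 1]); j0 <- floor(vox[, 2]); k0 <- floor(vox[, 3])
  fx <- vox[, 1] - i0; fy <- vox[, 2] - j0; fz <- vox[, 3] - k0
  ok <- i0 >= 0 & j0 >= 0 & k0 >= 0 &
    (i0 + 1) <= (dims[1] - 1) & (j0 + 1) <= (dims[2] - 1) & (k0 + 1) <= (dims[3] - 1)
  # points exactly on the upper face are still inside the grid
  hi <- vox[, 1] <= dims[1] - 1 & vox[, 2] <= dims[2] - 1 & vox[, 3] <= dims[3] - 1
  edge <- !ok & hi & i0 >= 0 & j0 >= 0 & k0 >= 0
  i0[edge] <- pmin(i0[edge], dims[1] - 2L)
  j0[edge] <- pmin(j0[edge], dims[2] - 2L)
  k0[edge] <- pmin(k0[edge], dims[3] - 2L)
  fx[edge] <- vox[edge, 1] - i0[edge]
  fy[edge] <- vox[edge, 2] - j0[edge]
  fz[edge] <- vox[edge, 3] - k0[edge]
  ok <- ok | edge
  if (!any(ok)) return(out)
  i0 <- i0[ok]; j0 <- j0[ok]; k0 <- k0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  at <- function(di, dj, dk) {
    vol[cbind(i0 + di + 1L, j0 + dj + 1L, k0 + dk + 1L)]
  }
  v <- at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[ok] <- v
  out
}

# symmetric 3x3 tensor <-> length-6 component vector (xx, yy, zz, xy, xz, yz)
tensor_to_vec <- function(D) {
  stopifnot(is.matrix(D), all(dim(D) == c(3, 3)))
  if (max(abs(D - t(D))) > 1e-12 * max(1, max(abs(D)))) {
    stop("tensor is not symmetric")
  }
  c(D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
}

vec_to_tensor <- function(v) {
  matrix(c(v[1], v[4], v[5],
           v[4], v[2], v[6],
           v[5], v[6], v[3]), 3, 3)
}

is_spd <- function(D, tol = 0) {
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol)
}

#' Diagonal voxel-to-world affine
#'
#' Convenience constructor for an axis-aligned affine with a given voxel
#' size and world-mm origin (the position of voxel (0,0,0)).
#'
#' @param voxel_size voxel edge length(s) in mm (scalar or length 3).
#' @param origin world coordinates of the first voxel center.
#' @return 4x4 matrix.
#' @export
scaled_affine <- function(voxel_size, origin = c(0, 0, 0)) {
  voxel_size <- rep_len(voxel_size, 3)
  A <- diag(c(voxel_size, 1))
  A[1:3, 4] <- origin
  A
}
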