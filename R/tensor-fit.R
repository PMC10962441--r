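#' Per-voxel diffusion tensor field
#'
#' @param D 4-D array (x, y, z, 6) of tensor components in the order
#'   xx, yy, zz, xy, xz, yz (mm^2/s).
#' @param affine 4x4 voxel-to-world matrix.
#' @param valid logical array flagging voxels with a usable fit.
#' @param qc optional list of quality-control summaries.
#' @return object of class `tensor_field`.
#' @export
tensor_field <- function(D, affine, valid, qc = list()) {
  stopifnot(length(dim(D)) == 4, dim(D)[4] == 6)
  structure(list(D = D, affine = affine, valid = valid, qc = qc,
                 eig = NULL),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  d <- dim(x$D)
  cat(sprintf("<tensor_field> %d x %d x %d grid, %d/%d valid voxels\n",
              d[1], d[2], d[3], sum(x$valid), prod(d[1:3])))
  invisible(x)
}

# eigendecomposition of every valid voxel tensor, cached on the object.
# piecewise-constant phantoms have few unique tensors, so decompose each
# unique tensor once and broadcast.
tensor_eigen <- function(tf) {
  if (!is.null(tf$eig)) return(tf)
  shape <- dim(tf$D)[1:3]
  nvox <- prod(shape)
  Dm <- matrix(tf$D, nvox, 6)
  vidx <- which(as.logical(tf$valid))
  evals <- matrix(NA_real_, nvox, 3)
  evecs <- array(NA_real_, dim = c(nvox, 3, 3))
  if (length(vidx)) {
    Dv <- Dm[vidx, , drop = FALSE]
    key <- do.call(paste, c(as.data.frame(Dv), sep = "|"))
    ukey <- !duplicated(key)
    umap <- match(key, key[ukey])
    uD <- Dv[ukey, , drop = FALSE]
    uval <- matrix(0, nrow(uD), 3)
    uvec <- array(0, dim = c(nrow(uD), 3, 3))
    for (u in seq_len(nrow(uD))) {
      e <- eigen(vec_to_tensor(uD[u, ]), symmetric = TRUE)
      uval[u, ] <- e$values            # decreasing: lambda1 >= lambda2 >= lambda3
      uvec[u, , ] <- e$vectors         # columns are eigenvectors
    }
    evals[vidx, ] <- uval[umap, , drop = FALSE]
    evecs[vidx, , ] <- uvec[umap, , , drop = FALSE]
  }
  tf$eig <- list(values = evals, vectors = evecs)
  tf
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Per voxel, minimises
#' \deqn{\sum_i (\ln S_i - \ln S_0 + b_i g_i' D g_i)^2}
#' over the six unique tensor components and \eqn{\ln S_0}, the estimator
#' used by standard single-tensor fitting tools in their default mode.
#' Signals at or below zero are raised to a configurable floor
#' (`floor_frac * S0`, per voxel) before taking logs; floored voxels are
#' counted in the QC record. Positive- and negative-polarity acquisitions
#' enter the fit as independent measurements.
#'
#' @param acq a [dwi_acquisition()].
#' @param floor_frac signal floor as a fraction of the voxel's mean b=0
#'   signal (default 1e-6).
#' @return a [tensor_field()]; voxels with an all-zero signal are flagged
#'   invalid rather than fitted. `qc$n_floored` counts voxels in which at
#'   least one measurement was floored; `qc$n_negative_eig` counts valid
#'   voxels with a negative smallest eigenvalue (reported, never clamped).
#' @export
fit_tensor <- function(acq, floor_frac = 1e-6) {
  stopifnot(inherits(acq, "dwi_acquisition"))
  shape <- dim(acq$signal)[1:3]
  nvox <- prod(shape)
  nvol <- dim(acq$signal)[4]
  S <- matrix(acq$signal, nvox, nvol)
  g <- t(acq$bvecs)
  b <- acq$bvals
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7) {
    stop("design matrix rank ", qrX$rank, " < 7: fewer than 6 independent ",
         "diffusion directions plus b=0; tensor not identifiable")
  }
  mask <- if (is.null(acq$mask)) rep(TRUE, nvox) else as.logical(acq$mask)
  if (!any(mask)) stop("brain mask is empty")
  s0 <- rowMeans(S[, b == 0, drop = FALSE])
  allzero <- rowSums(S) == 0
  fit_idx <- which(mask & !allzero)
  floor_val <- pmax(floor_frac * s0[fit_idx], .Machine$double.xmin)
  Sf <- S[fit_idx, , drop = FALSE]
  floored <- Sf < floor_val          # recycles floor_val down columns
  Sf <- pmax(Sf, floor_val)
  logS <- log(Sf)
  beta <- qr.coef(qrX, t(logS))                    # 7 x nfit
  Dmat <- matrix(NA_real_, nvox, 6)
  Dmat[fit_idx, ] <- t(beta[2:7, , drop = FALSE])
  valid <- array(FALSE, dim = shape)
  valid[fit_idx] <- TRUE
  tf <- tensor_field(array(Dmat, dim = c(shape, 6)), affine = acq$affine,
                     valid = valid)
  tf <- tensor_eigen(tf)
  neg <- sum(tf$eig$values[fit_idx, 3] < 0, na.rm = TRUE)
  tf$qc <- list(
    n_fitted = length(fit_idx),
    n_invalid = as.integer(nvox - length(fit_idx)),
    n_floored = sum(rowSums(floored) > 0),
    n_negative_eig = neg,
    floor_frac = floor_frac
  )
  tf
}
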