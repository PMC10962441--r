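#' Deterministic unit gradient direction set
#'
#' Generates `n` approximately uniformly distributed unit vectors on the
#' sphere by the golden-angle (Fibonacci) spiral. Deterministic, so the same
#' acquisition geometry is reproduced on every call.
#'
#' @param n number of base directions (default 25, the acquisition scheme
#'   emulated by the phantom generator: 25 directions at b = 1000 s/mm^2,
#'   acquired in positive and negative gradient polarity).
#' @return n x 3 matrix of unit row vectors.
#' @export
default_gradient_set <- function(n = 25) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  g <- cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  g / sqrt(rowSums(g^2))
}

#' Specification of a diffusion-weighted MRI phantom
#'
#' Defines a rectangular grid in world space, a set of geometric regions each
#' carrying a constant symmetric positive-definite diffusion tensor, the
#' diffusion encoding (b-value, base gradient directions emitted in positive
#' and negative polarity, number of b = 0 volumes) and an optional Rician
#' noise level.
#'
#' @param shape integer length-3 grid shape (voxels).
#' @param voxel_size voxel edge length(s) in mm (scalar or length 3).
#' @param affine 4x4 voxel-to-world matrix; default a scaled identity, i.e.
#'   the phantom lives directly in template space.
#' @param regions list of regions, each a list with elements `name`,
#'   `center` (mm), `radius` (mm) and `tensor` (3x3 symmetric
#'   positive-definite, mm^2/s). Alternatively a region may carry a logical
#'   `mask` array of the grid shape instead of center/radius.
#' @param background_tensor 3x3 SPD tensor filling voxels outside all
#'   regions (mm^2/s).
#' @param bvalue diffusion weighting in s/mm^2 for the weighted volumes.
#' @param directions base unit gradient directions (n x 3); each is emitted
#'   in both polarities, so the acquisition holds `2 * nrow(directions)`
#'   weighted volumes.
#' @param n_b0 number of b = 0 volumes (default 8).
#' @param s0 non-diffusion-weighted signal amplitude.
#' @param noise `"none"` or `"rician"`.
#' @param snr signal-to-noise ratio S0/sigma for Rician noise.
#' @param seed integer seed for the noise draw.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(20, 20, 20),
                         voxel_size = 2.5,
                         affine = NULL,
                         regions = list(),
                         background_tensor = diag(0.7e-3, 3),
                         bvalue = 1000,
                         directions = default_gradient_set(25),
                         n_b0 = 8,
                         s0 = 1000,
                         noise = c("none", "rician"),
                         snr = 30,
                         seed = 1L) {
  noise <- match.arg(noise)
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3, all(shape >= 1), n_b0 >= 1, s0 > 0, snr > 0)
  affine <- affine %||% scaled_affine(voxel_size)
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3)
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-9)) {
    stop("gradient directions must have unit norm (tolerance 1e-9)")
  }
  if (!is_spd(background_tensor)) stop("background tensor is not positive-definite")
  for (r in regions) {
    if (is.null(r$name)) stop("every region needs a name")
    if (!is_spd(r$tensor)) {
      stop(sprintf("region '%s': tensor is not positive-definite", r$name))
    }
    if (is.null(r$mask) && (is.null(r$center) || is.null(r$radius))) {
      stop(sprintf("region '%s': supply either a mask or center+radius", r$name))
    }
  }
  structure(
    list(shape = shape, voxel_size = rep_len(voxel_size, 3), affine = affine,
         regions = regions, background_tensor = background_tensor,
         bvalue = bvalue, directions = directions, n_b0 = as.integer(n_b0),
         s0 = s0, noise = noise, snr = snr, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Raw diffusion-weighted acquisition container
#'
#' @param signal 4-D array (x, y, z, volume), non-negative.
#' @param bvals per-volume b-values (s/mm^2).
#' @param bvecs 3 x nvol matrix of per-volume unit gradient directions
#'   (columns; zero columns for b = 0 volumes).
#' @param affine 4x4 voxel-to-world matrix.
#' @param mask optional logical brain mask.
#' @return object of class `dwi_acquisition`.
#' @export
dwi_acquisition <- function(signal, bvals, bvecs, affine, mask = NULL) {
  signal <- unclass(signal)
  stopifnot(length(dim(signal)) == 4)
  nvol <- dim(signal)[4]
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  stopifnot(length(bvals) == nvol, all(dim(bvecs) == c(3, nvol)))
  if (!any(bvals == 0)) stop("acquisition needs at least one b=0 volume")
  if (min(signal) < 0) stop("signal must be non-negative")
  dw <- bvals > 0
  nrm <- sqrt(colSums(bvecs[, dw, drop = FALSE]^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    stop("diffusion-weighted gradient directions must be unit vectors")
  }
  # collinearity check: >= 6 directions spanning the space of symmetric tensors
  g <- t(bvecs[, dw, drop = FALSE])
  gu <- unique(round(rbind(g, -g), 8))
  B <- cbind(gu[, 1]^2, gu[, 2]^2, gu[, 3]^2,
             2 * gu[, 1] * gu[, 2], 2 * gu[, 1] * gu[, 3], 2 * gu[, 2] * gu[, 3])
  if (qr(B)$rank < 6) {
    stop("fewer than 6 independent (non-collinear) diffusion directions; ",
         "the tensor is not identifiable")
  }
  structure(list(signal = signal, bvals = bvals, bvecs = bvecs,
                 affine = affine, mask = mask),
            class = "dwi_acquisition")
}

#' @export
print.dwi_acquisition <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dwi_acquisition> %d x %d x %d grid, %d volumes (%d b=0, %d weighted)\n",
              d[1], d[2], d[3], d[4], sum(x$bvals == 0), sum(x$bvals > 0)))
  invisible(x)
}

# per-voxel tensor component volume from a phantom spec (4-D array, 6 comps)
build_tensor_volume <- function(spec) {
  nvox <- prod(spec$shape)
  Dmat <- matrix(rep(tensor_to_vec(spec$background_tensor), each = nvox),
                 nrow = nvox)
  centers <- voxel_centers_mm(spec$shape, spec$affine)
  for (r in spec$regions) {
    if (!is.null(r$mask)) {
      sel <- as.logical(r$mask)
    } else {
      d2 <- (centers[, 1] - r$center[1])^2 + (centers[, 2] - r$center[2])^2 +
        (centers[, 3] - r$center[3])^2
      sel <- d2 <= r$radius^2
    }
    Dmat[sel, ] <- matrix(tensor_to_vec(r$tensor), nrow = sum(sel), ncol = 6,
                          byrow = TRUE)
  }
  Dmat
}

add_rician_noise <- function(signal, sigma) {
  n1 <- array(rnorm(length(signal), sd = sigma), dim = dim(signal))
  n2 <- array(rnorm(length(signal), sd = sigma), dim = dim(signal))
  sqrt((signal + n1)^2 + n2^2)
}

#' Generate a diffusion-weighted phantom with known tensor ground truth
#'
#' Simulates the single-tensor signal model S = S0 exp(-b g' D g) on the
#' grid and regions of a [phantom_spec()]. The base gradient table is
#' expanded into positive and negative polarity, and `n_b0` unweighted
#' volumes are prepended. Optional Rician noise (magnitude-MRI convention)
#' is applied to the noiseless signal.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `acq` (a [dwi_acquisition()]) and `truth`
#'   (a `tensor_field` holding the exact per-voxel tensors used).
#' @export
generate_dwi_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- rbind(spec$directions, -spec$directions)  # polarity expansion
  nvol <- spec$n_b0 + nrow(g)
  bvals <- c(rep(0, spec$n_b0), rep(spec$bvalue, nrow(g)))
  bvecs <- cbind(matrix(0, 3, spec$n_b0), t(g))
  Dmat <- build_tensor_volume(spec)                       # nvox x 6
  # g' D g for all voxels and weighted directions at once
  Q <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  adc <- Dmat %*% t(Q)                                    # nvox x ndir
  sig <- cbind(matrix(spec$s0, nrow(Dmat), spec$n_b0),
               spec$s0 * exp(-spec$bvalue * adc))
  signal <- array(sig, dim = c(spec$shape, nvol))
  if (spec$noise == "rician") {
    set.seed(spec$seed)
    signal <- add_rician_noise(signal, sigma = spec$s0 / spec$snr)
  }
  acq <- dwi_acquisition(signal, bvals, bvecs, spec$affine)
  truth <- tensor_field(array(Dmat, dim = c(spec$shape, 6)),
                        affine = spec$affine,
                        valid = array(TRUE, dim = spec$shape))
  list(acq = acq, truth = truth)
}
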