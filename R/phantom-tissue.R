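#' Generate a tissue-map phantom with planted PVS structure
#'
#' Builds a simple geometric "brain": an ellipsoidal brain mask split into a
#' central basal-ganglia block surrounding two box ventricles, white matter
#' around it, and a cortical gray-matter shell. CSF consists of the
#' ventricles, an extra-cerebral rim (planted in the vessel/extra-cerebral
#' exclusion mask), a few spherical lacunes, and individually planted PVS
#' voxels in the white matter and basal ganglia. The exact planted PVS
#' voxel counts per region are returned as ground truth; PVS voxels planted
#' inside an exclusion mask (e.g. the ventricles) are excluded from the
#' ground truth, since the subtraction procedure removes them.
#'
#' @param shape grid shape (default c(40, 48, 40)).
#' @param voxel_size voxel edge length in mm (default 1.1; voxel volume is
#'   `voxel_size^3`).
#' @param n_pvs_wm,n_pvs_bg number of PVS voxels planted in white matter /
#'   basal ganglia.
#' @param n_pvs_ventricle number of PVS voxels deliberately planted inside
#'   the ventricles (removed by the procedure; for testing).
#' @param n_lacunes number of spherical lacunes planted in white matter.
#' @param seed integer seed.
#' @return list with `maps` (a [tissue_maps()]) and `truth` (list with
#'   planted PVS voxel counts `n_wb`, `n_bg`, `n_wm` and
#'   `voxel_volume_mm3`).
#' @export
generate_tissue_phantom <- function(shape = c(40, 48, 40), voxel_size = 1.1,
                                    n_pvs_wm = 120, n_pvs_bg = 40,
                                    n_pvs_ventricle = 0, n_lacunes = 2,
                                    seed = 1L) {
  set.seed(seed)
  shape <- as.integer(shape)
  ctr <- (shape + 1) / 2
  idx <- as.matrix(expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                               k = seq_len(shape[3])))
  semi <- shape / 2 - 2
  r2 <- ((idx[, 1] - ctr[1]) / semi[1])^2 + ((idx[, 2] - ctr[2]) / semi[2])^2 +
    ((idx[, 3] - ctr[3]) / semi[3])^2
  brain <- array(r2 <= 1, dim = shape)
  shell <- array(r2 <= 1 & r2 > 0.72, dim = shape)       # cortical GM shell
  rim <- array(r2 > 1 & r2 <= 1.25, dim = shape)         # extra-cerebral CSF

  box <- function(lo, hi) {
    m <- array(FALSE, dim = shape)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
  off <- round(shape[1] / 8)
  vent <- box(round(ctr) + c(-off - 2, -4, -4), round(ctr) + c(-off + 2, 4, 4)) |
    box(round(ctr) + c(off - 2, -4, -4), round(ctr) + c(off + 2, 4, 4))
  vent <- vent & brain
  bg <- box(round(ctr - shape / 5), round(ctr + shape / 5)) & brain & !vent

  sphere <- function(center, radius) {
    d2 <- (idx[, 1] - center[1])^2 + (idx[, 2] - center[2])^2 +
      (idx[, 3] - center[3])^2
    array(d2 <= radius^2, dim = shape)
  }
  wm_region <- brain & !shell & !vent & !bg
  lac <- array(FALSE, dim = shape)
  if (n_lacunes > 0) {
    cand <- which(wm_region)
    for (s in seq_len(n_lacunes)) {
      cen <- idx[sample(cand, 1), ]
      lac <- lac | (sphere(cen, 2) & brain)
    }
  }

  pick <- function(pool, n) {
    pool <- which(pool)
    if (n > length(pool)) stop("not enough voxels to plant the requested PVS")
    if (n == 0) integer(0) else sample(pool, n)
  }
  pvs_wm_idx <- pick(wm_region & !lac, n_pvs_wm)
  pvs_bg_idx <- pick(bg & !lac, n_pvs_bg)
  pvs_vent_idx <- pick(vent, n_pvs_ventricle)
  planted <- array(FALSE, dim = shape)
  planted[c(pvs_wm_idx, pvs_bg_idx, pvs_vent_idx)] <- TRUE
  if (any(planted & !brain)) stop("planted PVS voxels fall outside the brain mask")

  csf <- vent | rim | lac | planted
  gm <- shell & !csf
  # the WM and BG masks are regional (SynthSeg-style) masks: they keep
  # covering voxels occupied by planted PVS, so PVS-in-region volumes are
  # well defined; lacunes are excluded from the WM region
  wm <- wm_region & !lac
  maps <- tissue_maps(gm = gm, wm = wm, csf = csf,
                      lacunes = lac, ventricles = vent, vessel_csf = rim,
                      bg = bg, voxel_volume = voxel_size^3,
                      affine = scaled_affine(voxel_size))
  truth <- list(n_wb = n_pvs_wm + n_pvs_bg,
                n_bg = n_pvs_bg, n_wm = n_pvs_wm,
                voxel_volume_mm3 = voxel_size^3)
  list(maps = maps, truth = truth)
}
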