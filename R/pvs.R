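#' Tissue-class map container
#'
#' Binary label volumes on a shared grid, as produced by an upstream
#' segmentation pipeline: gray matter, white matter, CSF, white matter
#' hyperintensities, manually delineated lacunes, ventricles, the
#' extra-cerebral / large-vessel CSF exclusion mask, and a basal-ganglia
#' region mask.
#'
#' @param gm,wm,csf,wmh,lacunes,ventricles,vessel_csf,bg binary/logical
#'   arrays on a common grid. `wmh`, `lacunes`, `ventricles`, `vessel_csf`
#'   and `bg` may be omitted (treated as empty).
#' @param voxel_volume voxel volume in mm^3.
#' @param affine optional 4x4 voxel-to-world matrix.
#' @return object of class `tissue_maps`. Note: the ventricle mask is not
#'   required to be a subset of the CSF class; the overlap is reported by
#'   [make_pvs_map()], not enforced here.
#' @export
tissue_maps <- function(gm, wm, csf, wmh = NULL, lacunes = NULL,
                        ventricles = NULL, vessel_csf = NULL, bg = NULL,
                        voxel_volume = 1, affine = NULL) {
  ref <- dim(gm)
  empty <- array(FALSE, dim = ref)
  maps <- list(gm = gm, wm = wm, csf = csf,
               wmh = wmh %||% empty, lacunes = lacunes %||% empty,
               ventricles = ventricles %||% empty,
               vessel_csf = vessel_csf %||% empty, bg = bg %||% empty)
  for (nm in names(maps)) {
    m <- maps[[nm]]
    if (!identical(dim(m), ref)) {
      stop(sprintf("map '%s' is on a different grid (%s vs %s)", nm,
                   paste(dim(m), collapse = "x"), paste(ref, collapse = "x")))
    }
    vals <- unique(as.vector(m))
    if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
      stop(sprintf("map '%s' is not binary", nm))
    }
    maps[[nm]] <- array(as.logical(m), dim = ref)
  }
  stopifnot(voxel_volume > 0)
  structure(c(maps, list(voxel_volume = voxel_volume, affine = affine)),
            class = "tissue_maps")
}

#' Construct the PVS map by subtraction from the CSF class
#'
#' Perivascular spaces share CSF-like signal, so the PVS map is derived
#' from the already-segmented CSF class by removing everything known not to
#' be PVS: manually identified lacunes, the ventricles, and the CSF
#' surrounding large vessels and outside the brain (an explicit exclusion
#' mask). Exclusion masks are combined by union, so overlapping exclusions
#' are removed once.
#'
#' @param t a [tissue_maps()] object.
#' @param review_mask optional additional exclusion mask standing in for
#'   the manual inspection step.
#' @return logical PVS array with attributes `n_voxels` and
#'   `ventricle_outside_csf` (count of ventricle voxels not in the CSF
#'   class, reported for QC).
#' @export
make_pvs_map <- function(t, review_mask = NULL) {
  stopifnot(inherits(t, "tissue_maps"))
  excl <- t$lacunes | t$ventricles | t$vessel_csf
  if (!is.null(review_mask)) {
    if (!identical(dim(review_mask), dim(t$csf))) {
      stop("map 'review_mask' is on a different grid")
    }
    excl <- excl | as.logical(review_mask)
  }
  pvs <- t$csf & !excl
  if (!any(t$csf)) warning("CSF map is empty; PVS map is empty")
  attr(pvs, "n_voxels") <- sum(pvs)
  attr(pvs, "ventricle_outside_csf") <- sum(t$ventricles & !t$csf)
  pvs
}

#' Regional PVS volumes, normalized and log-transformed
#'
#' Raw volumes are voxel counts times voxel volume, for the whole brain and
#' for the intersections with the basal-ganglia and white-matter masks.
#' Volumes are normalized by total brain volume (gray + white matter) and
#' natural-log transformed. A zero whole-brain PVS volume has no defined
#' log and raises an error (no pseudo-count is ever added); zero subregion
#' volumes yield `NA` log values with a warning, and downstream analyses
#' must handle such subjects explicitly.
#'
#' @param pvs binary PVS map (from [make_pvs_map()]).
#' @param t the [tissue_maps()] the map came from.
#' @param log whether to compute log-transformed normalized volumes.
#' @return object of class `pvs_volumes`: data.frame with one row per
#'   region (`whole_brain`, `bg`, `wm`) and columns `raw_mm3`,
#'   `normalized`, `log_normalized`, plus attribute `brain_volume_mm3`.
#' @export
pvs_volumes <- function(pvs, t, log = TRUE) {
  stopifnot(inherits(t, "tissue_maps"))
  if (!identical(dim(pvs), dim(t$csf))) stop("PVS map is on a different grid")
  pvs <- as.logical(pvs)
  vv <- t$voxel_volume
  brain_vol <- (sum(t$gm) + sum(t$wm)) * vv
  if (brain_vol <= 0) stop("brain volume (GM + WM) is zero")
  raw <- c(whole_brain = sum(pvs) * vv,
           bg = sum(pvs & t$bg) * vv,
           wm = sum(pvs & t$wm) * vv)
  normalized <- raw / brain_vol
  out <- data.frame(region = names(raw), raw_mm3 = unname(raw),
                    normalized = unname(normalized), stringsAsFactors = FALSE)
  if (log) {
    if (raw["whole_brain"] == 0) {
      stop("whole-brain PVS volume is zero: log transform undefined")
    }
    lg <- log(out$normalized)
    if (any(out$raw_mm3 == 0)) {
      warning("zero PVS volume in subregion(s): log set to NA")
      lg[out$raw_mm3 == 0] <- NA_real_
    }
    out$log_normalized <- lg
  }
  attr(out, "brain_volume_mm3") <- brain_vol
  class(out) <- c("pvs_volumes", "data.frame")
  out
}

#' Rater agreement metrics for paired PVS volume measurements
#'
#' Given two series of volumes of the same scans measured by two raters (or
#' the same rater twice), computes the standard error of measurement
#' (SD of the paired differences divided by sqrt(2)), the mean percent
#' variability (|difference| / pair mean * 100, averaged), and the
#' two-way random-effects, absolute-agreement, single-rater intraclass
#' correlation ICC(2,1).
#'
#' @param vol_a,vol_b numeric vectors of paired volumes (>= 2 pairs).
#' @return list with `sem`, `percent_variability`,
#'   `percent_variability_sd` and `icc`.
#' @export
reliability_report <- function(vol_a, vol_b) {
  stopifnot(length(vol_a) == length(vol_b))
  n <- length(vol_a)
  if (n < 2) stop("at least 2 paired observations are required")
  d <- vol_a - vol_b
  sem <- sd(d) / sqrt(2)
  pv <- abs(d) / ((vol_a + vol_b) / 2) * 100
  # ICC(2,1) from the two-way ANOVA mean squares, k = 2 raters
  k <- 2
  Y <- cbind(vol_a, vol_b)
  grand <- mean(Y)
  subj_means <- rowMeans(Y)
  rater_means <- colMeans(Y)
  msr <- k * sum((subj_means - grand)^2) / (n - 1)
  msc <- n * sum((rater_means - grand)^2) / (k - 1)
  sse <- sum((Y - outer(subj_means, rep(1, k)) -
                outer(rep(1, n), rater_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  list(sem = sem, percent_variability = mean(pv),
       percent_variability_sd = sd(pv), icc = icc)
}
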