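#' Write a diffusion acquisition as NIfTI-1 plus FSL-style bval/bvec
#'
#' @param acq a [dwi_acquisition()].
#' @param prefix output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec` (bvec rows are the x, y, z
#'   components across volumes).
#' @return the three paths, invisibly.
#' @export
write_dwi <- function(acq, prefix) {
  stopifnot(inherits(acq, "dwi_acquisition"))
  img <- RNifti::asNifti(acq$signal)
  img <- RNifti::`sform<-`(img, structure(acq$affine, code = 2L))
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  bvec <- paste0(prefix, ".bvec")
  writeLines(paste(format(acq$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval)
  writeLines(apply(acq$bvecs, 1, paste, collapse = " "), bvec)
  invisible(c(nii = nii, bval = bval, bvec = bvec))
}

#' Read a diffusion acquisition from NIfTI-1 plus bval/bvec text files
#'
#' Volumes are reoriented to RAS axis order on load so that the tensor
#' diagonal is anatomically unambiguous (x: left-right, y:
#' anterior-posterior, z: inferior-superior).
#'
#' @param nii path to the 4-D NIfTI file.
#' @param bval,bvec paths to FSL-dialect b-value / gradient files; default
#'   to `nii` with the extension swapped.
#' @return a [dwi_acquisition()].
#' @export
read_dwi <- function(nii, bval = NULL, bvec = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", nii)
  bval <- bval %||% paste0(stem, ".bval")
  bvec <- bvec %||% paste0(stem, ".bvec")
  img <- RNifti::readNifti(nii)
  if (RNifti::orientation(img) != "RAS") {
    RNifti::orientation(img) <- "RAS"
  }
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  bvals <- scan(bval, quiet = TRUE)
  bvecs <- matrix(scan(bvec, quiet = TRUE), nrow = 3, byrow = TRUE)
  dwi_acquisition(array(as.numeric(img), dim = dim(img)), bvals, bvecs,
                  affine = affine)
}

#' Write diffusivity maps as NIfTI-1 volumes plus a QC JSON
#'
#' @param maps a [derive_maps()] result.
#' @param prefix output path prefix; writes `<prefix>_dxx.nii.gz` etc. for
#'   dxx, dyy, dzz, fa, md, v1, and `<prefix>_qc.json`.
#' @return written paths, invisibly.
#' @export
write_maps <- function(maps, prefix) {
  stopifnot(inherits(maps, "diffusivity_maps"))
  paths <- character(0)
  for (nm in c("dxx", "dyy", "dzz", "fa", "md", "v1")) {
    vol <- maps[[nm]]
    vol[is.na(vol)] <- 0
    img <- RNifti::asNifti(vol)
    img <- RNifti::`sform<-`(img, structure(maps$affine, code = 2L))
    p <- paste0(prefix, "_", nm, ".nii.gz")
    RNifti::writeNifti(img, p)
    paths <- c(paths, p)
  }
  qc <- paste0(prefix, "_qc.json")
  jsonlite::write_json(maps$qc, qc, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, qc))
}

#' Read a 4x4 affine from a whitespace-delimited text file
#'
#' @param path text file with 4 rows of 4 numbers (FSL .mat style).
#' @return 4x4 numeric matrix.
#' @export
read_affine <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (!all(dim(m) == c(4, 4))) stop("affine file must contain a 4x4 matrix")
  m
}

#' Read a binary mask volume from NIfTI
#'
#' @param path NIfTI file; any nonzero voxel is TRUE.
#' @return logical array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) != 0, dim = dim(img))
}

#' @importFrom utils read.table
NULL
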