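#' Construct a Volume3D
#'
#' @param data 3D numeric array.
#' @param spacing Voxel size in mm (length 1 recycled, or length 3).
#' @param affine 4x4 voxel-to-world matrix (0-based indices, RAS+ world).
#'   Defaults to a diagonal affine built from \code{spacing} with the origin
#'   at voxel (0,0,0).
#' @param meta Named list of metadata (e.g. \code{te} in ms).
#' @return A \linkS4class{Volume3D}.
#' @export
Volume3D <- function(data, spacing = c(1, 1, 1), affine = NULL, meta = list()) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  new("Volume3D", data = data, spacing = as.numeric(spacing),
      affine = affine, meta = meta)
}

#' Construct a LabelMask
#'
#' @param data 3D array of 0/1 values.
#' @param side \code{"left"} or \code{"right"}.
#' @inheritParams Volume3D
#' @return A \linkS4class{LabelMask}.
#' @export
LabelMask <- function(data, side, spacing = c(1, 1, 1), affine = NULL,
                      meta = list()) {
  v <- Volume3D(data, spacing, affine, meta)
  new("LabelMask", v, side = side)
}

## World coordinates of 0-based voxel indices (n x 3 matrix) under an affine.
voxelToWorld <- function(idx0, affine) {
  idx0 <- rbind(t(idx0), 1)
  t(affine %*% idx0)[, 1:3, drop = FALSE]
}

## World coordinates of every in-mask voxel (n x 3, mm).
maskWorldCoords <- function(mask) {
  idx <- which(mask@data == 1, arr.ind = TRUE) - 1L
  voxelToWorld(idx, mask@affine)
}

#' Read a NIfTI-1 volume
#'
#' Reads a 3D NIfTI-1 image and normalises it to the package's internal
#' convention: data reoriented so the affine is RAS+ (world positions of the
#' voxels are unchanged), spacing taken from the header.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @param meta Extra metadata merged into the returned volume's \code{meta}.
#' @return A \linkS4class{Volume3D}.
#' @export
readVolume <- function(path, meta = list()) {
  if (!file.exists(path))
    hqStop("hippoquant_missing_file", "file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    hqStop("hippoquant_corrupt_header",
                           "cannot read NIfTI file ", path, ": ",
                           conditionMessage(e)))
  if (length(dim(img)) != 3L)
    hqStop("hippoquant_not_3d", "expected a 3D image, got ",
           length(dim(img)), "D: ", path)
  RNifti::orientation(img) <- "RAS"
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  Volume3D(array(as.numeric(img), dim = dim(img)),
           spacing = RNifti::pixdim(img)[1:3], affine = aff,
           meta = c(list(source = path), meta))
}

#' Read a NIfTI-1 hippocampal mask
#'
#' As \code{\link{readVolume}}, with values binarised at 0.5 and the side
#' recorded.
#'
#' @inheritParams readVolume
#' @param side \code{"left"} or \code{"right"}.
#' @return A \linkS4class{LabelMask}.
#' @export
readMask <- function(path, side) {
  v <- readVolume(path)
  d <- v@data
  if (!all(unique(as.vector(d)) %in% c(0, 1)))
    d <- (d > 0.5) + 0
  new("LabelMask", Volume3D(d, v@spacing, v@affine, v@meta), side = side)
}

#' Write a volume or mask as NIfTI-1
#'
#' @param v A \linkS4class{Volume3D} or \linkS4class{LabelMask}.
#' @param path Output path (\code{.nii} or \code{.nii.gz}); the directory
#'   must exist.
#' @return \code{path}, invisibly.
#' @export
writeVolume <- function(v, path) {
  if (!dir.exists(dirname(path)))
    hqStop("hippoquant_unwritable_path", "directory does not exist: ",
           dirname(path))
  img <- RNifti::asNifti(v@data)
  RNifti::pixdim(img) <- v@spacing
  RNifti::qform(img) <- structure(v@affine, code = 2L)
  RNifti::sform(img) <- structure(v@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Assert that two images live on the same grid
#'
#' Passes silently iff the array shapes are equal and the affines agree
#' element-wise within \code{tol}; symmetric in its arguments. The tolerance
#' absorbs header float noise without hiding genuine misregistration.
#'
#' @param a,b \linkS4class{Volume3D} or \linkS4class{LabelMask} objects.
#' @param tol Element-wise affine tolerance.
#' @return \code{TRUE}, invisibly, on success.
#' @export
assertSameGrid <- function(a, b, tol = 1e-5) {
  if (!identical(dim(a@data), dim(b@data)))
    hqStop("hippoquant_grid_mismatch",
           "shape mismatch: ", paste(dim(a@data), collapse = "x"), " vs ",
           paste(dim(b@data), collapse = "x"))
  if (max(abs(a@affine - b@affine)) > tol)
    hqStop("hippoquant_grid_mismatch",
           "affine mismatch: max |delta| = ",
           format(max(abs(a@affine - b@affine))))
  invisible(TRUE)
}
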