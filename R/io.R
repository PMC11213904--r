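## Thin I/O wrappers around the standard formats: PNG images, NIfTI
## volumes/time series, and stimulus-set manifests.

#' Read or write a stimulus image
#'
#' Grayscale images round-trip as matrices, colour images as H x W x 3
#' arrays, values in `[0, 1]` (8-bit PNG).
#'
#' @param path PNG file path.
#' @param img Image to write.
#' @return `read_image` returns the image; `write_image` the path.
#' @export
read_image <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  img
}

#' @rdname read_image
#' @export
write_image <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Write a voxels x time matrix as a 4-D NIfTI file
#'
#' Voxels are laid out along the first axis (n x 1 x 1 x time), which is
#' sufficient for the package's mask-vector analyses; a `vox_dim` can
#' reshape to a true 3-D grid.
#'
#' @param bold Voxels x time matrix or `ff_bold` object.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param TR Repetition time stored in the header (s).
#' @param vox_dim Optional 3-D grid `c(nx, ny, nz)` with
#'   `prod(vox_dim) == nrow(bold)`.
#' @return The path, invisibly.
#' @export
write_bold_nifti <- function(bold, path, TR = NULL, vox_dim = NULL) {
  Y <- if (is.list(bold)) bold$data else bold
  if (is.null(TR)) TR <- if (is.list(bold) && !is.null(bold$TR)) bold$TR else 2
  if (is.null(vox_dim)) vox_dim <- c(nrow(Y), 1, 1)
  if (prod(vox_dim) != nrow(Y)) stop("vox_dim does not match voxel count")
  arr <- array(Y, c(vox_dim, ncol(Y)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, TR)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D NIfTI file as a voxels x time matrix
#'
#' @param path NIfTI file path.
#' @return A list of class `ff_bold` with `data` (voxels x time) and `TR`.
#' @export
read_bold_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  dm <- dim(img)
  if (length(dm) != 4) stop("expected a 4-D volume")
  Y <- matrix(img, prod(dm[1:3]), dm[4])
  TR <- RNifti::pixdim(img)[4]
  structure(list(data = Y, TR = TR, vox_dim = dm[1:3]), class = "ff_bold")
}

#' Write a per-voxel statistical map as NIfTI
#'
#' @param values Numeric vector (one value per voxel).
#' @param path Output path.
#' @param vox_dim Optional 3-D grid.
#' @return The path, invisibly.
#' @export
write_map_nifti <- function(values, path, vox_dim = NULL) {
  if (is.null(vox_dim)) vox_dim <- c(length(values), 1, 1)
  RNifti::writeNifti(RNifti::asNifti(array(values, vox_dim)), path)
  invisible(path)
}
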