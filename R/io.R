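#' Read a 3D volume from NIfTI
#'
#' Supports `.nii` and `.nii.gz`. Voxel spacing is taken from the NIfTI
#' pixdim and the origin from the translation column of the stored transform.
#'
#' @param path file path.
#' @return A [scalar_volume()].
#' @export
read_volume <- function(path) {
  .check_nifti_ext(path)
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  data <- array(as.numeric(img), dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  org <- tryCatch(RNifti::xform(img)[1:3, 4], error = function(e) c(0, 0, 0))
  scalar_volume(data, spacing = sp, origin = as.numeric(org))
}

#' Write a 3D volume (or mask) to NIfTI
#'
#' Spacing and origin round-trip through [read_volume()]. Masks should be
#' written with `datatype = "uint8"`.
#'
#' @param volume a [scalar_volume()] or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type (e.g. `"double"`, `"uint8"`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, datatype = "double") {
  .check_nifti_ext(path)
  vol <- as_volume(volume)
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  m <- structure(m, code = 2L)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

.check_nifti_ext <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    stop("unsupported volume format for '", basename(path),
         "': supported extensions are .nii, .nii.gz")
  }
  invisible(path)
}

#' Write a binary mask to NIfTI (unsigned 8-bit, values 0/1)
#'
#' @param mask logical/binary 3D array.
#' @param path output path.
#' @param spacing,origin geometry metadata.
#' @export
write_mask <- function(mask, path, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  m <- as_mask(mask)
  write_volume(scalar_volume(array(as.numeric(m), dim(m)), spacing, origin),
               path, datatype = "uint8")
}
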