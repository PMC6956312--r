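#' 3D image volume container
#'
#' A `dear_volume` wraps a 3D scalar array of shape `n_slices x size x size`
#' together with its physical metadata. Values are either on the Hounsfield
#' scale (`units = "HU"`) or linearly mapped to `[0, 1]`
#' (`units = "normalized"`).
#'
#' @param data 3D numeric array, `n_slices x N x N`.
#' @param units `"HU"` or `"normalized"`.
#' @param pixel_size_mm in-plane pixel spacing in mm.
#' @param slice_thickness_mm slice-to-slice spacing in mm.
#' @return An object of class `dear_volume`.
#' @export
new_volume <- function(data, units = c("HU", "normalized"),
                       pixel_size_mm = 0.664, slice_thickness_mm = 1) {
  units <- match.arg(units)
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array (n_slices x N x N)")
  if (dim(data)[2] != dim(data)[3])
    stop("volume slices must be square")
  if (units == "normalized" && (min(data) < -1e-9 || max(data) > 1 + 1e-9))
    stop("normalized volumes must lie in [0, 1]")
  structure(
    list(data = data, units = units,
         pixel_size_mm = pixel_size_mm,
         slice_thickness_mm = slice_thickness_mm),
    class = "dear_volume")
}

#' @export
print.dear_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dear_volume> %d slices of %dx%d [%s], pixel %.3f mm, slice %.2f mm\n",
              d[1], d[2], d[3], x$units, x$pixel_size_mm, x$slice_thickness_mm))
  invisible(x)
}

#' Number of slices in a volume
#' @param volume a `dear_volume`.
#' @return integer slice count.
#' @export
n_slices <- function(volume) dim(volume$data)[1]

#' Write a volume to NIfTI
#'
#' Stores the volume as `.nii` / `.nii.gz` with pixel size and slice
#' thickness in the header. The array is written as `N x N x n_slices`
#' (slice index last), the usual NIfTI axis order.
#'
#' @param volume a `dear_volume`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- aperm(volume$data, c(2, 3, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(volume$pixel_size_mm, volume$pixel_size_mm,
                           volume$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file written by [write_volume_nifti()].
#' @param units unit tag to attach (the file stores only voxel data).
#' @return a `dear_volume`.
#' @export
read_volume_nifti <- function(path, units = c("HU", "normalized")) {
  units <- match.arg(units)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- aperm(array(as.numeric(img), dim = dim(img)), c(3, 1, 2))
  new_volume(arr, units = units, pixel_size_mm = pd[1],
             slice_thickness_mm = pd[3])
}
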