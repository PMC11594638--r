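#' Image volumes
#'
#' A `pvs_volume` is a plain 3D numeric array carrying its isotropic voxel
#' spacing in millimetres as the attribute `voxel_mm`. It is the common
#' carrier for T2/FLAIR intensities, vesselness maps, atlas label grids and
#' binary masks throughout the package.
#'
#' @param data A 3D numeric, integer or logical array.
#' @param voxel_mm Isotropic voxel edge length in mm (default 0.9, matching
#'   a 0.9 x 0.9 x 0.9 mm 3D T2 acquisition).
#' @return A `pvs_volume`: the array with `voxel_mm` attribute and class set.
#' @export
as_volume <- function(data, voxel_mm = 0.9) {
  if (length(dim(data)) != 3L)
    stop("volume data must be a 3D array, got ", length(dim(data)), " dims")
  if (!is.numeric(voxel_mm) || length(voxel_mm) != 1L || voxel_mm <= 0)
    stop("voxel_mm must be a single positive number")
  structure(data, voxel_mm = as.numeric(voxel_mm), class = "pvs_volume")
}

#' @rdname as_volume
#' @param x Object to query.
#' @export
voxel_mm <- function(x) {
  v <- attr(x, "voxel_mm")
  if (is.null(v)) stop("object carries no voxel_mm attribute")
  v
}

#' @export
print.pvs_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<pvs_volume %d x %d x %d @ %.3g mm, range [%.4g, %.4g]>\n",
              d[1], d[2], d[3], voxel_mm(x),
              min(x, na.rm = TRUE), max(x, na.rm = TRUE)))
  invisible(x)
}

# strip class/attrs to a bare array (RNifti and arithmetic paths)
vol_data <- function(x) {
  a <- unclass(x)
  attr(a, "voxel_mm") <- NULL
  a
}

#' Check two volumes share grid geometry
#'
#' @param a,b `pvs_volume` objects (or bare arrays with matching dims).
#' @param what Label used in the error message.
#' @return Invisibly `TRUE`; errors on mismatch.
#' @export
check_same_grid <- function(a, b, what = "volumes") {
  if (!identical(dim(a), dim(b)))
    stop(what, " are on different grids: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  va <- attr(a, "voxel_mm"); vb <- attr(b, "voxel_mm")
  if (!is.null(va) && !is.null(vb) && !isTRUE(all.equal(va, vb)))
    stop(what, " have different voxel spacing: ", va, " vs ", vb)
  invisible(TRUE)
}

#' Read / write volumes as NIfTI-1
#'
#' Thin wrappers over RNifti keeping the voxel spacing in the header's pixdim.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a `pvs_volume`; `write_volume` returns the
#'   path invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  px <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1L]
  as_volume(arr, voxel_mm = px[1])
}

#' @rdname read_volume
#' @param vol A `pvs_volume`.
#' @export
write_volume <- function(vol, path) {
  v <- voxel_mm(vol)
  img <- RNifti::asNifti(vol_data(vol))
  RNifti::pixdim(img) <- c(v, v, v)
  RNifti::writeNifti(img, path)
  invisible(path)
}
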