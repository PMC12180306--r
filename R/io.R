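#' BOLD series container
#'
#' Wraps a 4D BOLD array in time-first order `(time, x, y, z)` together with
#' the repetition time and a [volume_grid()].
#'
#' @param data 4D numeric array, time first.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param grid a [volume_grid()] whose shape matches `dim(data)[2:4]`.
#' @return an object of class `bold_series`.
#' @export
bold_series <- function(data, tr_seconds, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(dim(data)) != 4L)
    stop("BOLD data must be a 4D array (time, x, y, z)", call. = FALSE)
  if (dim(data)[1L] < 2L)
    stop("BOLD series needs at least 2 time points", call. = FALSE)
  if (!identical(as.integer(dim(data)[2:4]), grid$shape))
    stop("BOLD spatial dimensions do not match the grid", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0)
    stop("tr_seconds must be a single positive number", call. = FALSE)
  structure(list(data = data, tr_seconds = as.numeric(tr_seconds),
                 grid = grid, .cache = new.env(parent = emptyenv())),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat("<bold_series> T = ", dim(x$data)[1L], ", grid ",
      paste(x$grid$shape, collapse = " x "), ", TR = ",
      x$tr_seconds, " s\n", sep = "")
  invisible(x)
}

n_timepoints <- function(bold) dim(bold$data)[1L]

# T x V matrix view of the series (voxels in array linear order); cached on
# the object since several stages index voxel series repeatedly
bold_matrix <- function(bold) {
  if (is.null(bold$.cache$mat)) {
    d <- dim(bold$data)
    bold$.cache$mat <- matrix(bold$data, nrow = d[1L])
  }
  bold$.cache$mat
}

# time series of given voxels (coords n x 3 or linear indices) as T x n
voxel_series <- function(bold, voxels) {
  if (is.matrix(voxels)) voxels <- lin_index(bold$grid$shape, voxels)
  bold_matrix(bold)[, voxels, drop = FALSE]
}

#' Read a preprocessed 4D BOLD image with its brain mask
#'
#' Reads NIfTI files, validates that the 4D image and the 3D mask share the
#' spatial shape and affine, and returns a [bold_series()]. The repetition
#' time is taken from the NIfTI time step unless overridden.
#'
#' @param path 4D NIfTI file.
#' @param mask_path 3D binary-mask NIfTI file on the same grid.
#' @param tr_seconds optional TR override; required when the header time step
#'   is missing or non-positive.
#' @param affine_tol maximum absolute element-wise affine discrepancy.
#' @return a [bold_series()].
#' @export
read_bold <- function(path, mask_path, tr_seconds = NULL, affine_tol = 1e-3) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 4L)
    stop("expected a 4D NIfTI image, got ", length(dim(img)), "D", call. = FALSE)
  msk <- RNifti::readNifti(mask_path)
  if (length(dim(msk)) != 3L)
    stop("expected a 3D NIfTI mask, got ", length(dim(msk)), "D", call. = FALSE)
  if (!identical(dim(msk), dim(img)[1:3]))
    stop("mask shape does not match the image spatial shape", call. = FALSE)
  a_img <- unclass(RNifti::xform(img))[1:4, 1:4]
  a_msk <- unclass(RNifti::xform(msk))[1:4, 1:4]
  if (max(abs(a_img - a_msk)) > affine_tol)
    stop("mask affine does not match the image affine", call. = FALSE)
  if (is.null(tr_seconds)) {
    tr_seconds <- RNifti::pixdim(img)[4L]
    if (!is.finite(tr_seconds) || tr_seconds <= 0)
      stop("NIfTI header carries no usable TR; pass tr_seconds explicitly",
           call. = FALSE)
  }
  mv <- unique(as.vector(msk))
  if (!all(mv %in% c(0, 1)))
    stop("mask must be binary (values 0/1)", call. = FALSE)
  grid <- volume_grid(dim(img)[1:3], a_img, array(msk > 0.5, dim(msk)))
  bold_series(aperm(unclass(img)[, , , , drop = FALSE], c(4L, 1L, 2L, 3L)),
              tr_seconds, grid)
}

#' Write a 3D map as NIfTI on a grid's geometry
#'
#' @param map3d numeric 3D array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @export
write_map <- function(map3d, grid, path) {
  if (!identical(as.integer(dim(map3d)), grid$shape))
    stop("map shape does not match the grid", call. = FALSE)
  im <- RNifti::asNifti(array(as.numeric(map3d), dim(map3d)))
  im <- RNifti::`sform<-`(im, structure(grid$affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(grid$affine, code = 2L))
  RNifti::pixdim(im) <- grid$voxel_size
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Write a BOLD series as 4D NIfTI
#'
#' @param bold a [bold_series()].
#' @param path output file.
#' @export
write_bold <- function(bold, path) {
  arr <- aperm(bold$data, c(2L, 3L, 4L, 1L))
  im <- RNifti::asNifti(arr)
  im <- RNifti::`sform<-`(im, structure(bold$grid$affine, code = 2L))
  im <- RNifti::`qform<-`(im, structure(bold$grid$affine, code = 2L))
  RNifti::pixdim(im) <- c(bold$grid$voxel_size, bold$tr_seconds)
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' Read a 3D volume (mask or label image) on a known grid
#'
#' @param path NIfTI file.
#' @param grid optional [volume_grid()] to validate shape/affine against.
#' @param affine_tol affine comparison tolerance.
#' @return numeric 3D array.
#' @export
read_volume <- function(path, grid = NULL, affine_tol = 1e-3) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D NIfTI volume", call. = FALSE)
  if (!is.null(grid)) {
    if (!identical(as.integer(dim(img)), grid$shape))
      stop("volume shape does not match the grid", call. = FALSE)
    a <- unclass(RNifti::xform(img))[1:4, 1:4]
    if (max(abs(a - grid$affine)) > affine_tol)
      stop("volume affine does not match the grid", call. = FALSE)
  }
  array(as.numeric(img), dim(img))
}
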