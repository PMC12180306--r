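#' Volume grid geometry
#'
#' A `volume_grid` bundles the 3D geometry every stage of the pipeline relies
#' on: array shape, voxel size, the voxel-to-world affine, the binary brain
#' mask, and the inter-hemispheric (mid-sagittal) mirroring plane used by the
#' lateralization features. Data are assumed template-normalized, so the
#' mirroring plane is the world `x = 0` plane mapped into voxel space; for
#' non-standard grids `midline_index` can be set explicitly.
#'
#' The midline is stored as a (possibly half-integer) 1-based voxel position
#' `m` along `midline_axis`; voxel `i` mirrors to `2m - i`. When the axis has
#' odd width and `m` is an integer, the central voxel column lies on the plane
#' and belongs to neither hemisphere.
#'
#' @param shape integer triple, voxels per axis.
#' @param affine 4x4 voxel(0-based)-to-world matrix.
#' @param brain_mask logical/0-1 3D array on `shape`.
#' @param voxel_size mm triple; derived from `affine` columns when `NULL`.
#' @param midline_axis axis index (1-3) of the left-right world direction;
#'   detected from the affine's dominant first-row column when `NULL`.
#' @param midline_index half-integer 1-based voxel position of the mirroring
#'   plane; located from the affine when `NULL`.
#' @return an object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine, brain_mask, voxel_size = NULL,
                        midline_axis = NULL, midline_index = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix", call. = FALSE)
  brain_mask <- array(as.logical(brain_mask), dim(brain_mask))
  if (!identical(dim(brain_mask), shape))
    stop("brain_mask shape does not match grid shape", call. = FALSE)
  if (is.null(voxel_size))
    voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))

  if (is.null(midline_axis)) {
    xrow <- abs(affine[1L, 1:3])
    midline_axis <- which.max(xrow)
    if (xrow[midline_axis] < 2 * max(xrow[-midline_axis], 0)) {
      warning("left-right axis not clearly identified from affine; using axis 1")
      midline_axis <- 1L
    }
  }
  midline_axis <- as.integer(midline_axis)

  if (is.null(midline_index)) {
    a <- affine[1L, midline_axis]
    others <- setdiff(1:3, midline_axis)
    rest <- affine[1L, 4L] + sum(affine[1L, others] * (shape[others] - 1) / 2)
    if (abs(a) < 1e-12) {
      warning("degenerate left-right affine column; midline set to grid centre")
      m <- (shape[midline_axis] + 1) / 2
    } else {
      m <- -rest / a + 1   # 1-based voxel position where world x = 0
    }
    m <- round(2 * m) / 2  # snap to half-integer so mirroring maps voxels
    if (m < 1.5 || m > shape[midline_axis] - 0.5) {
      warning("world x = 0 plane falls outside the grid; midline set to grid centre")
      m <- round(shape[midline_axis] + 1) / 2
    }
  } else {
    m <- round(2 * midline_index) / 2
  }

  wlo <- floor(m - 0.5)                       # voxels strictly below the plane
  whi <- shape[midline_axis] - ceiling(m + 0.5) + 1
  if (abs(wlo - whi) > 1L)
    stop("midline_index does not split the axis into near-equal hemispheres",
         call. = FALSE)

  # does the low-index block carry negative (left) world x?
  left_low <- affine[1L, midline_axis] > 0

  structure(
    list(shape = shape, voxel_size = as.numeric(voxel_size), affine = affine,
         brain_mask = brain_mask, midline_axis = midline_axis,
         midline_index = m, left_low = left_low,
         .cache = new.env(parent = emptyenv())),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(x$shape, collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 3), collapse = " x "),
      " mm\n  in-mask voxels: ", sum(x$brain_mask),
      "\n  midline: axis ", x$midline_axis, " at voxel ", x$midline_index,
      " (left on ", if (x$left_low) "low" else "high", " indices)\n", sep = "")
  invisible(x)
}

# mirror voxel coordinates (n x 3 matrix, 1-based) about the midline plane
mirror_coords <- function(grid, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  coords[, grid$midline_axis] <- 2 * grid$midline_index - coords[, grid$midline_axis]
  coords
}

# hemisphere of each coordinate row: "left", "right", or "mid"
hemisphere_of <- function(grid, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  v <- coords[, grid$midline_axis]
  side <- ifelse(v < grid$midline_index, "low",
                 ifelse(v > grid$midline_index, "high", "mid"))
  low_lab <- if (grid$left_low) "left" else "right"
  high_lab <- if (grid$left_low) "right" else "left"
  out <- side
  out[side == "low"] <- low_lab
  out[side == "high"] <- high_lab
  out
}

lin_index <- function(shape, coords) {
  coords <- matrix(as.integer(round(coords)), ncol = 3L)
  coords[, 1L] + (coords[, 2L] - 1L) * shape[1L] +
    (coords[, 3L] - 1L) * shape[1L] * shape[2L]
}

in_grid <- function(shape, coords) {
  coords <- matrix(coords, ncol = 3L)
  coords[, 1L] >= 1 & coords[, 1L] <= shape[1L] &
    coords[, 2L] >= 1 & coords[, 2L] <= shape[2L] &
    coords[, 3L] >= 1 & coords[, 3L] <= shape[3L]
}

# Mirror-paired in-mask voxels: linear indices of left-hemisphere voxels and
# of their exact mirror voxels, restricted to pairs where both members are in
# the brain mask (plane voxels excluded). Order is a raster scan of the left
# hemisphere, so element i of $right is the mirror of element i of $left.
# Depends only on the grid, so the result is cached on it.
mirror_pairs <- function(grid) {
  if (!is.null(grid$.cache$mirror_pairs)) return(grid$.cache$mirror_pairs)
  grid$.cache$mirror_pairs <- mirror_pairs_build(grid)
}

mirror_pairs_build <- function(grid) {
  idx <- which(grid$brain_mask)
  if (!length(idx)) return(list(left = integer(0), right = integer(0)))
  coords <- arrayInd(idx, grid$shape)
  side <- hemisphere_of(grid, coords)
  sel <- side == "left"
  lc <- coords[sel, , drop = FALSE]
  mc <- mirror_coords(grid, lc)
  ok <- in_grid(grid$shape, mc)
  lc <- lc[ok, , drop = FALSE]
  mlin <- lin_index(grid$shape, mc[ok, , drop = FALSE])
  keep <- grid$brain_mask[mlin]
  list(left = lin_index(grid$shape, lc[keep, , drop = FALSE]),
       right = mlin[keep])
}
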