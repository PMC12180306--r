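#' Significance clusters of a component map
#'
#' Retains the connected regions of in-mask voxels exceeding the Z threshold
#' whose size is strictly greater than `min_size` ("more than 10 contiguous
#' voxels with Z > 3.1"). An empty result is allowed and flagged downstream.
#'
#' @param zmap numeric 3D array of Z-scores.
#' @param mask logical 3D brain mask.
#' @param z_thresh Z threshold (strict, default 3.1).
#' @param min_size minimum region size (strict >, default 10).
#' @param connectivity voxel connectivity, 26 (default) or 6.
#' @return logical 3D array.
#' @export
significance_clusters <- function(zmap, mask, z_thresh = 3.1, min_size = 10L,
                                  connectivity = 26L) {
  stopifnot(all(is.finite(zmap[mask])))
  supra <- mask & (zmap > z_thresh)
  if (!any(supra)) return(array(FALSE, dim(zmap)))
  lab <- label_components(supra, connectivity)
  sizes <- region_sizes(lab)
  keep <- which(sizes > min_size)
  if (!length(keep)) return(array(FALSE, dim(zmap)))
  array(lab %in% keep, dim(zmap))
}

#' Morphological opening then closing of a binary mask
#'
#' Smooths a cluster mask with a ball (default) or per-slice disk structuring
#' element of the given voxel radius. Opening removes protrusions and
#' isolated voxels; closing fills small holes.
#'
#' @param mask logical 3D array.
#' @param radius_voxels structuring-element radius in voxels (default 2).
#' @param element `"ball"` (3D, default) or `"disk"` (2D, per axial slice).
#' @return logical 3D array.
#' @export
morph_open_close <- function(mask, radius_voxels = 2, element = c("ball", "disk")) {
  element <- match.arg(element)
  offs <- if (element == "ball") ball_offsets(radius_voxels)
          else disk_offsets(radius_voxels)
  binary_close(binary_open(mask, offs), offs)
}

#' Main connected component containing (or nearest to) a centre voxel
#'
#' Returns the connected region of `mask` that contains `center`. When the
#' centre voxel is not in the mask (morphological opening can delete it), the
#' region with the smallest Euclidean voxel distance to the centre is chosen
#' (ties: larger region, then lowest lexicographic seed voxel) with a warning.
#'
#' @param mask logical 3D array (nonempty).
#' @param center voxel coordinate triple (1-based).
#' @param connectivity 26 or 6.
#' @return logical 3D array containing a single connected region.
#' @export
main_connected_component <- function(mask, center, connectivity = 26L) {
  if (!any(mask)) stop("empty mask: no cluster to select", call. = FALSE)
  lab <- label_components(mask, connectivity)
  center <- as.integer(round(center))
  if (mask[center[1L], center[2L], center[3L]]) {
    sel <- lab[center[1L], center[2L], center[3L]]
  } else {
    warning("centre voxel not in mask; selecting the nearest region")
    idx <- which(mask)
    coords <- arrayInd(idx, dim(mask))
    d2 <- (coords[, 1L] - center[1L])^2 + (coords[, 2L] - center[2L])^2 +
      (coords[, 3L] - center[3L])^2
    regs <- lab[idx]
    mind <- tapply(d2, regs, min)
    best <- as.integer(names(mind)[mind == min(mind)])
    if (length(best) > 1L) {
      sizes <- region_sizes(lab)[best]
      best <- best[sizes == max(sizes)]
      if (length(best) > 1L) {
        # lowest lexicographic seed voxel among the tied regions
        seed_key <- vapply(best, function(r) {
          rc <- coords[regs == r, , drop = FALSE]
          rc <- rc[order(rc[, 1L], rc[, 2L], rc[, 3L]), , drop = FALSE][1L, ]
          sum(rc * c(1e12, 1e6, 1))
        }, numeric(1))
        best <- best[which.min(seed_key)]
      }
    }
    sel <- best[1L]
  }
  array(lab == sel, dim(mask))
}

#' Component centre: the in-mask voxel of maximum Z
#'
#' Ties are broken by the lowest lexicographic coordinate triple.
#'
#' @param zmap numeric 3D array.
#' @param mask logical 3D array.
#' @return integer voxel coordinate triple.
#' @export
sic_center <- function(zmap, mask) {
  idx <- which(mask)
  z <- zmap[idx]
  mx <- max(z)
  cand <- arrayInd(idx[z == mx], dim(zmap))
  cand <- cand[order(cand[, 1L], cand[, 2L], cand[, 3L]), , drop = FALSE]
  as.integer(cand[1L, ])
}

# neighbourhood coordinates around a centre voxel; "cube3" is the 3x3x3 cube
# (27 voxels), "ball3" the radius-3 Euclidean ball
neighborhood_coords <- function(center, mode = c("cube3", "ball3")) {
  mode <- match.arg(mode)
  offs <- if (mode == "cube3") as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
          else ball_offsets(3)
  sweep(offs, 2L, as.integer(round(center)), "+")
}

#' Central local average time series
#'
#' Mean time series over the neighbourhood of the component centre,
#' intersected with the brain mask (voxels outside the grid or the mask are
#' dropped).
#'
#' @param bold a [bold_series()].
#' @param center voxel coordinate triple.
#' @param mode `"cube3"` (3x3x3 cube, default) or `"ball3"` (radius-3 ball).
#' @return numeric vector of length T.
#' @export
central_local_average <- function(bold, center, mode = c("cube3", "ball3")) {
  mode <- match.arg(mode)
  nb <- neighborhood_coords(center, mode)
  nb <- nb[in_grid(bold$grid$shape, nb), , drop = FALSE]
  lin <- lin_index(bold$grid$shape, nb)
  lin <- lin[bold$grid$brain_mask[lin]]
  if (!length(lin))
    stop("neighbourhood does not intersect the brain mask", call. = FALSE)
  rowMeans(voxel_series(bold, lin))
}

#' Derive the five clustering levels of a component
#'
#' Computes, in the fixed order: significance clusters (Z > `z_thresh`, size
#' > `min_size`), morphologically opened+closed clusters, the main connected
#' component containing the component centre, the central local average
#' series, and the central-voxel series. The centre is taken from the raw
#' Z-map independently of the masks. When opening annihilates all clusters
#' the largest significance cluster is used as the main cluster, with a
#' warning.
#'
#' @param bold a [bold_series()].
#' @param comp a `spatial_component` from [spatial_ica()].
#' @param z_thresh,min_size,connectivity see [significance_clusters()].
#' @param morph_radius,element see [morph_open_close()].
#' @param neighborhood see [central_local_average()].
#' @return an object of class `cluster_set` with fields `sig_mask`,
#'   `morph_mask`, `main_mask` (NULL when no significant cluster survives),
#'   `center`, `central_series`, `central_voxel_series`.
#' @export
component_clusters <- function(bold, comp, z_thresh = 3.1, min_size = 10L,
                               connectivity = 26L, morph_radius = 2,
                               element = "ball",
                               neighborhood = c("cube3", "ball3")) {
  neighborhood <- match.arg(neighborhood)
  grid <- bold$grid
  sig <- significance_clusters(comp$zmap, grid$brain_mask, z_thresh, min_size,
                               connectivity)
  center <- sic_center(comp$zmap, grid$brain_mask)
  morph <- morph_open_close(sig, morph_radius, element)
  main <- NULL
  if (any(morph)) {
    main <- suppressWarnings(main_connected_component(morph, center, connectivity))
  } else if (any(sig)) {
    warning("morphology removed all clusters; falling back to the largest ",
            "significance cluster")
    lab <- label_components(sig, connectivity)
    main <- array(lab == which.max(region_sizes(lab)), dim(sig))
  }
  structure(
    list(sig_mask = sig, morph_mask = morph, main_mask = main, center = center,
         central_series = central_local_average(bold, center, neighborhood),
         central_voxel_series = as.numeric(
           voxel_series(bold, matrix(center, 1L))),
         neighborhood = neighborhood),
    class = "cluster_set")
}
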