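#' Extract the SOZ cluster from the selected component
#'
#' The SOZ mask is the main connected component (containing, or nearest to,
#' the component centre) of the morphologically opened-and-closed
#' significance clusters of the selected component: threshold, then
#' open/close, then main component. When morphology annihilates every
#' cluster, the largest significance cluster is used instead, with a
#' warning.
#'
#' @param comp the selected `spatial_component`.
#' @param clusters its [component_clusters()].
#' @param connectivity 26 or 6.
#' @return an object of class `soz_result` with `soz_mask`, `center`, and
#'   unassessed concordance fields.
#' @export
extract_soz <- function(comp, clusters, connectivity = 26L) {
  if (!any(clusters$sig_mask))
    stop("selected component has no significance cluster", call. = FALSE)
  if (any(clusters$morph_mask)) {
    soz <- suppressWarnings(
      main_connected_component(clusters$morph_mask, clusters$center,
                               connectivity))
  } else {
    warning("morphology removed all clusters; using the largest ",
            "significance cluster as the SOZ")
    lab <- label_components(clusters$sig_mask, connectivity)
    soz <- array(lab == which.max(region_sizes(lab)), dim(clusters$sig_mask))
  }
  structure(list(component = comp$index, soz_mask = soz,
                 center = clusters$center, concordance = "not_assessed",
                 overlap_voxels = NA_integer_, dice = NA_real_),
            class = "soz_result")
}

# modal nonzero label over a mask; NA when the mask hits no labeled voxel
modal_label <- function(labels, mask) {
  v <- labels[mask]
  v <- v[v > 0]
  if (!length(v)) return(NA_integer_)
  tb <- table(v)
  as.integer(names(tb)[which.max(tb)])
}

#' Assess SOZ concordance against a resection mask
#'
#' Three levels: `full` when the SOZ overlaps the resection by at least one
#' voxel; `partial` when there is no overlap but the modal lobe label of the
#' SOZ equals that of the resection; `discordant` otherwise. The Dice
#' coefficient and overlap voxel count are recorded. With no resection mask
#' the result stays `not_assessed`.
#'
#' @param soz a [extract_soz()] result.
#' @param resection_mask logical/0-1 3D array on the SOZ grid, or `NULL`.
#' @param lobe_labels integer 3D array of lobe labels (0 = background), or
#'   `NULL` (then no `partial` level can be assigned).
#' @return the completed `soz_result`.
#' @export
assess_concordance <- function(soz, resection_mask, lobe_labels = NULL) {
  if (is.null(resection_mask)) return(soz)
  if (!identical(dim(resection_mask), dim(soz$soz_mask)))
    stop("resection mask is not on the SOZ grid", call. = FALSE)
  res <- resection_mask > 0.5
  overlap <- sum(soz$soz_mask & res)
  soz$overlap_voxels <- as.integer(overlap)
  soz$dice <- 2 * overlap / (sum(soz$soz_mask) + sum(res))
  if (overlap > 0L) {
    soz$concordance <- "full"
  } else if (!is.null(lobe_labels)) {
    if (!identical(dim(lobe_labels), dim(soz$soz_mask)))
      stop("lobe labels are not on the SOZ grid", call. = FALSE)
    l_soz <- modal_label(lobe_labels, soz$soz_mask)
    l_res <- modal_label(lobe_labels, res)
    soz$concordance <- if (!is.na(l_soz) && !is.na(l_res) && l_soz == l_res)
      "partial" else "discordant"
  } else {
    soz$concordance <- "discordant"
  }
  soz
}

#' Dice coefficient between two binary masks
#'
#' @param a,b logical/0-1 arrays of identical shape.
#' @return value in \[0, 1\]; 1 iff the masks are identical and nonempty.
#' @export
dice_coefficient <- function(a, b) {
  a <- a > 0.5
  b <- b > 0.5
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
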