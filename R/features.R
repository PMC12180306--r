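#' Outside-to-inside suprathreshold voxel ratio
#'
#' Ratio of suprathreshold voxels outside the brain mask to those inside it.
#' Artifact components (motion, pulsation, rim effects) load heavily outside
#' the parenchyma and score high; genuinely neuronal components score near
#' zero. A zero denominator yields `Inf`, which the classifier treats as an
#' automatic rejection.
#'
#' @param zmap numeric 3D array of Z-scores over the full grid.
#' @param brain_mask logical 3D array.
#' @param z_thresh Z threshold (default 3.1).
#' @return non-negative ratio (possibly `Inf`).
#' @export
outside_inside_ratio <- function(zmap, brain_mask, z_thresh = 3.1) {
  supra <- zmap > z_thresh
  n_out <- sum(supra & !brain_mask)
  n_in <- sum(supra & brain_mask)
  if (n_in == 0L) return(Inf)
  n_out / n_in
}

#' Dominant periodogram frequency of a series
#'
#' Frequency (Hz, zero bin excluded) of the maximal periodogram ordinate of
#' the mean-removed series; resolution is 1/(T*TR).
#'
#' @param series numeric vector, length >= 8.
#' @param tr_seconds sampling interval in seconds.
#' @return frequency in Hz.
#' @export
max_power_frequency <- function(series, tr_seconds) {
  if (length(series) < 8L)
    stop("series too short for a periodogram (need T >= 8)", call. = FALSE)
  if (stats::sd(series) == 0)
    stop("degenerate constant series", call. = FALSE)
  pg <- stats::spec.pgram(series, taper = 0, detrend = FALSE, demean = TRUE,
                          fast = FALSE, plot = FALSE)
  pg$freq[which.max(pg$spec)] / tr_seconds
}

#' Functional lateralization index
#'
#' One minus the absolute Pearson correlation between in-mask Z values of
#' left-hemisphere voxels and their exact mirror voxels. Mirror-symmetric
#' resting networks score near 0; one-sided (lateralized) components score
#' near 1. The absolute value makes anti-symmetric maps score 0 as well.
#'
#' @param zmap numeric 3D array.
#' @param grid a [volume_grid()].
#' @return value in \[0, 1\].
#' @export
lateralization_index <- function(zmap, grid) {
  mp <- mirror_pairs(grid)
  if (!length(mp$left))
    stop("no mirror-paired in-mask voxels", call. = FALSE)
  xl <- zmap[mp$left]
  xr <- zmap[mp$right]
  if (stats::sd(xl) == 0 || stats::sd(xr) == 0)
    stop("degenerate hemisphere array (constant values)", call. = FALSE)
  1 - abs(stats::cor(xl, xr))
}

#' Lateralization strength of the significance mask
#'
#' After removing mirrored pairs (suprathreshold voxels whose mirror voxel is
#' also suprathreshold), counts the remaining suprathreshold voxels per
#' hemisphere: `LS = |nL - nR| / (nL + nR)`. A fully one-sided mask scores 1;
#' an exactly mirror-symmetric mask leaves no non-mirrored voxels and scores
#' 0 with side `"none"`.
#'
#' @param sig_mask logical 3D significance mask.
#' @param grid a [volume_grid()].
#' @return list with `ls` in \[0, 1\] and `side` in
#'   `c("left", "right", "none")`.
#' @export
lateralization_strength <- function(sig_mask, grid) {
  idx <- which(sig_mask)
  if (!length(idx)) return(list(ls = 0, side = "none"))
  coords <- arrayInd(idx, grid$shape)
  side <- hemisphere_of(grid, coords)
  mc <- mirror_coords(grid, coords)
  ok <- in_grid(grid$shape, mc)
  mirrored <- logical(length(idx))
  mirrored[ok] <- sig_mask[lin_index(grid$shape, mc[ok, , drop = FALSE])]
  keep <- !mirrored & side != "mid"
  nl <- sum(side[keep] == "left")
  nr <- sum(side[keep] == "right")
  if (nl + nr == 0L) return(list(ls = 0, side = "none"))
  list(ls = abs(nl - nr) / (nl + nr),
       side = if (nl > nr) "left" else if (nr > nl) "right" else "none")
}

#' Local connectivity matrix of a component's main cluster
#'
#' Pearson correlations between the time series of all voxels in the main
#' cluster. Constant-series voxels are dropped with a warning; the centre row
#' is the cluster voxel at (or nearest to) the component centre.
#'
#' @param bold a [bold_series()].
#' @param main_mask logical 3D array with >= 2 voxels.
#' @param center voxel coordinate triple.
#' @return list with `r` (N x N correlation matrix), `n`, `center_row`,
#'   `voxels` (linear indices).
#' @export
local_connectivity <- function(bold, main_mask, center) {
  lin <- which(main_mask)
  if (length(lin) < 2L)
    stop("main cluster needs at least 2 voxels", call. = FALSE)
  M <- voxel_series(bold, lin)
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant voxel series dropped from the cluster")
    keep <- sds > 0
    lin <- lin[keep]
    M <- M[, keep, drop = FALSE]
    if (length(lin) < 2L)
      stop("fewer than 2 usable voxels in the cluster", call. = FALSE)
  }
  r <- stats::cor(M)
  diag(r) <- 1
  coords <- arrayInd(lin, bold$grid$shape)
  d2 <- (coords[, 1L] - center[1L])^2 + (coords[, 2L] - center[2L])^2 +
    (coords[, 3L] - center[3L])^2
  list(r = r, n = length(lin), center_row = which.min(d2), voxels = lin)
}

#' Local clustering coefficient: mean off-diagonal correlation
#'
#' Ratio of the sum of existing pairwise correlations to the number of
#' possible connections in the cluster subnetwork.
#'
#' @param conn a connectivity object from [local_connectivity()].
#' @return mean off-diagonal correlation, in \[-1, 1\].
#' @export
clustering_coefficient <- function(conn) {
  n <- conn$n
  (sum(conn$r) - n) / (n * (n - 1))
}

#' Local connectivity diversity: variance of pairwise correlations
#'
#' Unbiased sample variance of the distinct pairwise correlations (each
#' unordered pair counted once). High diversity marks heterogeneous coupling
#' inside the cluster.
#'
#' @param conn a connectivity object from [local_connectivity()].
#' @return non-negative variance.
#' @export
connectivity_diversity <- function(conn) {
  v <- conn$r[upper.tri(conn$r)]
  if (length(v) < 2L)
    stop("need at least 2 distinct voxel pairs", call. = FALSE)
  stats::var(v)
}

#' Central network strength
#'
#' Mean correlation between the centre voxel's series and every other voxel
#' of the main cluster.
#'
#' @param conn a connectivity object from [local_connectivity()].
#' @return value in \[-1, 1\].
#' @export
central_network_strength <- function(conn) {
  c_ <- conn$center_row
  mean(conn$r[c_, -c_])
}

#' Central energy of a series
#'
#' Sum of squares of the (preprocessed, unnormalized) series at the
#' component centre voxel.
#'
#' @param center_series numeric vector.
#' @return non-negative value.
#' @export
central_energy <- function(center_series) sum(center_series^2)

#' Maximum temporal-source non-Gaussianity
#'
#' Largest absolute excess kurtosis, `|E(y^4) - 3 E(y^2)^2|` with sample
#' central moments, over a set of temporal sources. Spike-like epileptic
#' activity is strongly super-Gaussian and dominates this measure.
#'
#' @param sources list of numeric vectors (unit-variance temporal sources).
#' @return non-negative value.
#' @export
max_tic_nongaussianity <- function(sources) {
  if (!length(sources))
    stop("empty source list", call. = FALSE)
  max(vapply(sources, function(y) {
    yc <- y - mean(y)
    abs(mean(yc^4) - 3 * mean(yc^2)^2)
  }, numeric(1)))
}

#' Extract the full feature vector of one component
#'
#' Assembles the nine component-level measures into a one-row tibble.
#' Components with no surviving significance cluster are flagged
#' non-candidate; their cluster-dependent features are `NA`.
#'
#' @param bold a [bold_series()].
#' @param comp a `spatial_component`.
#' @param clusters the component's [component_clusters()].
#' @param seed integer seed for the temporal ICA.
#' @param config a [pipeline_config()].
#' @return a one-row tibble.
#' @export
extract_features <- function(bold, comp, clusters, seed,
                             config = pipeline_config()) {
  grid <- bold$grid
  center <- clusters$center
  candidate <- !is.null(clusters$main_mask) && any(clusters$sig_mask)
  r_oi <- outside_inside_ratio(comp$zmap, grid$brain_mask, config$z_thresh)
  freq <- max_power_frequency(clusters$central_series, bold$tr_seconds)
  li <- lateralization_index(comp$zmap, grid)
  ls <- lateralization_strength(clusters$sig_mask, grid)
  ce <- central_energy(clusters$central_voxel_series)

  cc <- cd <- ns <- kurt <- NA_real_
  if (candidate) {
    conn <- local_connectivity(bold, clusters$main_mask, center)
    cc <- clustering_coefficient(conn)
    cd <- if (conn$n >= 3L) connectivity_diversity(conn) else NA_real_
    ns <- central_network_strength(conn)
    k <- min(5L, conn$n, n_timepoints(bold) - 1L)
    src <- temporal_ica(bold, conn$voxels, k, seed)
    kurt <- max_tic_nongaussianity(src)
  }

  tibble::tibble(
    component = comp$index,
    candidate = candidate,
    n_sig_voxels = sum(clusters$sig_mask),
    center_x = center[1L], center_y = center[2L], center_z = center[3L],
    r_oi = r_oi,
    max_power_freq = freq,
    lat_index = li,
    lat_strength = ls$ls,
    lat_side = ls$side,
    clustering_coef = cc,
    conn_diversity = cd,
    central_strength = ns,
    central_energy = ce,
    max_tic_kurtosis = kurt
  )
}
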