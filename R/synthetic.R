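#' Specification for synthetic multi-subject BOLD cohorts
#'
#' Defines the study conditions the generator emulates: a template-normalized
#' grid with an ellipsoidal brain mask, mirror-symmetric bilateral resting
#' networks with smooth band-limited signals, extracerebral rim artifacts
#' with supra-band power, a slow scanner drift, and one lateralized focal
#' epileptic source whose signal combines a low-frequency sinusoid with a
#' Poisson spike train convolved with a canonical double-gamma hemodynamic
#' response. Voxelwise mixing jitter inside the epileptic blob produces the
#' heterogeneous local connectivity the classifier expects.
#'
#' @param shape grid shape in voxels.
#' @param voxel_mm isotropic voxel size in mm.
#' @param n_time time points per subject.
#' @param tr_seconds repetition time.
#' @param n_subjects cohort size.
#' @param n_sym number of symmetric bilateral networks per subject.
#' @param n_art number of extracerebral artifact sources.
#' @param drift include a slow drift source.
#' @param noise_sd white-noise SD (source peak amplitudes are 1.5-4).
#' @param physio_sd SD of diffuse physiological noise: temporally smoothed
#'   (15 s moving average) voxel-private fluctuations over the whole brain,
#'   the spatially unstructured low-frequency background real BOLD carries.
#' @param net_amp,art_amp,drift_amp,epi_amp peak loadings of the source
#'   classes.
#' @param sym_band dominant-frequency band of the resting networks (Hz).
#' @param art_band artifact frequency band (above 0.1 Hz).
#' @param drift_freq drift frequency (below 0.01 Hz).
#' @param epi_freq_range epileptic sinusoid frequency range (Hz).
#' @param spike_rate Poisson spike rate per frame.
#' @param epi_sigma epileptic blob Gaussian width (voxels, truncated at 2
#'   sigma).
#' @param sin_weight,spike_weight relative weights of the sinusoidal and
#'   spike parts of the epileptic signal (combined to unit variance).
#' @param jitter_range voxelwise jitter-noise weight range inside the blob,
#'   relative to each voxel's shared loading.
#' @param seed master seed; subject seeds derive deterministically from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(40L, 48L, 40L), voxel_mm = 2,
                           n_time = 160L, tr_seconds = 3,
                           n_subjects = 8L, n_sym = 4L, n_art = 2L,
                           drift = TRUE, noise_sd = 1, physio_sd = 1.2,
                           net_amp = 2.5, art_amp = 3, drift_amp = 1.5,
                           epi_amp = 4,
                           sym_band = c(0.015, 0.075),
                           art_band = c(0.11, 0.15),
                           drift_freq = 0.005,
                           epi_freq_range = c(0.02, 0.04),
                           spike_rate = 0.03, epi_sigma = 3,
                           sin_weight = sqrt(0.4), spike_weight = sqrt(0.6),
                           jitter_range = c(0.6, 1.6), seed = 1L) {
  structure(as.list(environment()), class = "synthetic_spec")
}

.synth_cache <- new.env(parent = emptyenv())

# MNI-like grid: LAS affine with world x = 0 at the axis-1 centre.
# Geometry depends only on shape/voxel size, so it is memoized.
synthetic_grid <- function(spec) {
  key <- paste(c(spec$shape, spec$voxel_mm), collapse = "_")
  if (!is.null(.synth_cache[[key]])) return(.synth_cache[[key]])
  .synth_cache[[key]] <- synthetic_grid_build(spec)
}

synthetic_grid_build <- function(spec) {
  sh <- as.integer(spec$shape)
  vm <- spec$voxel_mm
  aff <- rbind(c(-vm, 0, 0, vm * (sh[1L] - 1) / 2),
               c(0, vm, 0, -vm * (sh[2L] - 1) / 2),
               c(0, 0, vm, -vm * (sh[3L] - 1) / 2),
               c(0, 0, 0, 1))
  ctr <- (sh + 1) / 2
  semi <- pmax((sh - 10) / 2, 2)
  ax <- array(seq_len(sh[1L]), sh)
  ay <- aperm(array(seq_len(sh[2L]), sh[c(2L, 1L, 3L)]), c(2L, 1L, 3L))
  az <- aperm(array(seq_len(sh[3L]), sh[c(3L, 1L, 2L)]), c(2L, 3L, 1L))
  mask <- ((ax - ctr[1L]) / semi[1L])^2 + ((ay - ctr[2L]) / semi[2L])^2 +
    ((az - ctr[3L]) / semi[3L])^2 <= 1
  volume_grid(sh, aff, mask)
}

# canonical double-gamma HRF (response peak ~6 s, undershoot ~16 s),
# sampled at the TR
hrf_kernel <- function(tr_seconds, duration = 32) {
  t <- seq(0, duration, by = tr_seconds)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

unit_sd <- function(x) {
  s <- stats::sd(x)
  if (s == 0) stop("degenerate constant signal in generator", call. = FALSE)
  (x - mean(x)) / s
}

# truncated Gaussian blob (zero beyond 2 sigma) around a voxel centre
gaussian_blob <- function(shape, center, sigma) {
  r <- ceiling(2 * sigma)
  out <- array(0, shape)
  xs <- max(1L, center[1L] - r):min(shape[1L], center[1L] + r)
  ys <- max(1L, center[2L] - r):min(shape[2L], center[2L] + r)
  zs <- max(1L, center[3L] - r):min(shape[3L], center[3L] + r)
  g <- expand.grid(x = xs, y = ys, z = zs)
  d2 <- (g$x - center[1L])^2 + (g$y - center[2L])^2 + (g$z - center[3L])^2
  v <- exp(-d2 / (2 * sigma^2))
  v[d2 > (2 * sigma)^2] <- 0
  out[cbind(g$x, g$y, g$z)] <- v
  out
}

# sample a blob centre from `eligible` voxels (logical array); error when none
sample_center <- function(eligible, what) {
  idx <- which(eligible)
  if (!length(idx))
    stop("cannot place ", what, ": no eligible voxels (mask too small?)",
         call. = FALSE)
  arrayInd(idx[sample.int(length(idx), 1L)], dim(eligible))[1L, ]
}

#' Generate one synthetic subject
#'
#' Builds BOLD = sum over sources of (spatial map x time course) + white
#' noise, deterministic given `subject_seed`, and returns the series with a
#' ground-truth record (per-source class, dominant frequency, loading map;
#' the epileptic focus mask and side).
#'
#' @param spec a [synthetic_spec()].
#' @param subject_seed integer seed for this subject.
#' @param epi_side `"left"` or `"right"`; placement side of the epileptic
#'   blob.
#' @return list with `bold` (a [bold_series()]) and `truth`.
#' @export
generate_subject <- function(spec, subject_seed,
                             epi_side = c("left", "right")) {
  epi_side <- match.arg(epi_side)
  grid <- synthetic_grid(spec)
  T_ <- spec$n_time
  sh <- grid$shape
  V <- prod(sh)
  tt <- (seq_len(T_) - 1L) * spec$tr_seconds

  geo_key <- paste(c("geo", sh, spec$voxel_mm), collapse = "_")
  if (is.null(.synth_cache[[geo_key]])) {
    .synth_cache[[geo_key]] <- list(
      hemi = array(hemisphere_of(grid, arrayInd(seq_len(V), sh)), sh),
      core = binary_erode(grid$brain_mask, ball_offsets(3)),
      shell_out = binary_dilate(grid$brain_mask, ball_offsets(3)) &
        !grid$brain_mask,
      shell_in = grid$brain_mask &
        !binary_erode(grid$brain_mask, ball_offsets(3)))
  }
  geo <- .synth_cache[[geo_key]]

  with_seed(subject_seed, {
    sources <- list()
    hemi <- geo$hemi
    core <- geo$core        # placement margin

    # Compact sources are placed without mutual overlap: overlapping
    # planted sources would be statistically dependent and not separable
    # by ICA even noiselessly. The epileptic blob is placed first because
    # its designated territory (inferior-lateral, strictly unilateral) is
    # the most constrained.
    placed <- list()     # (center, support radius) of every planted blob
    exclude_placed <- function(elig, new_r, with_mirror = FALSE,
                               rule = c("max", "sum")) {
      rule <- match.arg(rule)
      if (!length(placed)) return(elig)
      idx <- which(elig)
      if (!length(idx)) return(elig)
      coords <- arrayInd(idx, sh)
      test_sets <- list(coords)
      if (with_mirror) test_sets <- c(test_sets, list(mirror_coords(grid, coords)))
      ok <- rep(TRUE, length(idx))
      for (p in placed) for (cs in test_sets) {
        d <- sqrt((cs[, 1L] - p$ctr[1L])^2 + (cs[, 2L] - p$ctr[2L])^2 +
                    (cs[, 3L] - p$ctr[3L])^2)
        # "max": centres stay outside each other's support with a margin
        # (the residual tail overlap of truncated Gaussians is
        # negligible, and the full sum rule would make dense default
        # layouts infeasible). "sum": supports fully separated.
        lim <- if (rule == "sum") p$r + new_r + 2 else pmax(p$r, new_r) + 2
        ok <- ok & d > lim
      }
      elig[idx[!ok]] <- FALSE
      elig
    }
    # epileptic focal source: unilateral inferior-lateral blob, sinusoid +
    # HRF-convolved Poisson spike train, voxelwise mixing jitter
    esig <- spec$epi_sigma
    zc <- slice.index(core, 3L)
    elig <- core & hemi == epi_side & zc < (sh[3L] + 1) / 2 - 2 &
      abs(slice.index(core, 1L) - grid$midline_index) > 2 * esig + 0.5
    ectr <- sample_center(elig, "epileptic blob")
    placed <- list(list(ctr = ectr, r = 2 * esig))
    eblob <- gaussian_blob(sh, ectr, esig) * grid$brain_mask
    epi_mask <- eblob > 0         # truncated support (2 sigma), in-mask
    f_epi <- stats::runif(1, spec$epi_freq_range[1L], spec$epi_freq_range[2L])
    sin_part <- unit_sd(sin(2 * pi * f_epi * tt + stats::runif(1, 0, 2 * pi)))
    repeat {                      # at least 2 events so spikes carry power
      events <- stats::rpois(T_, spec$spike_rate)
      if (sum(events) >= 2L) break
    }
    spike_part <- unit_sd(stats::convolve(
      events, rev(hrf_kernel(spec$tr_seconds)), type = "open")[seq_len(T_)])
    etc <- unit_sd(spec$sin_weight * sin_part + spec$spike_weight * spike_part)
    sources[[length(sources) + 1L]] <-
      list(class = "epileptic", map = eblob * spec$epi_amp, tc = etc,
           freq = f_epi, mask = epi_mask, side = epi_side,
           center = as.integer(ectr))

    # symmetric bilateral networks: mirrored Gaussian blob pairs
    for (i in seq_len(spec$n_sym)) {
      sigma <- stats::runif(1, 2.5, 3.5)
      elig <- core & hemi == "left" &
        abs(slice.index(core, 1L) - grid$midline_index) > sigma + 1
      elig <- exclude_placed(elig, 2 * sigma, with_mirror = TRUE)
      ctr <- sample_center(elig, "symmetric network")
      mctr <- as.integer(round(mirror_coords(grid, matrix(ctr, 1L))))
      placed <- c(placed, list(list(ctr = ctr, r = 2 * sigma),
                               list(ctr = mctr, r = 2 * sigma)))
      blob <- gaussian_blob(sh, ctr, sigma)
      map <- (blob + gaussian_blob(sh, mctr, sigma)) * grid$brain_mask *
        spec$net_amp * stats::runif(1, 0.8, 1.2)
      f1 <- stats::runif(1, spec$sym_band[1L], spec$sym_band[2L])
      f2 <- stats::runif(1, spec$sym_band[1L], spec$sym_band[2L])
      tc <- unit_sd(sin(2 * pi * f1 * tt + stats::runif(1, 0, 2 * pi)) +
                      0.3 * sin(2 * pi * f2 * tt + stats::runif(1, 0, 2 * pi)))
      sources[[length(sources) + 1L]] <-
        list(class = "network", map = map, tc = tc, freq = f1)
    }

    # extracerebral artifacts: rim patches straddling the mask boundary,
    # with most loading outside the brain
    shell_out <- geo$shell_out
    shell_in <- geo$shell_in
    occupied <- array(FALSE, sh)           # support of the planted sources
    for (s in sources) occupied <- occupied | (s$map != 0)
    for (i in seq_len(spec$n_art)) {
      # prefer full support separation from every placed source (so the
      # patch keeps clear of network tails even in its neighbourhood);
      # fall back to centre separation when the rim is too crowded
      elig <- exclude_placed(shell_out, 7, rule = "sum")
      if (!any(elig)) elig <- exclude_placed(shell_out, 7)
      # flat coherent patch: rim loading with a weaker uniform bleed into
      # the boundary layer of the brain (thick enough that the bleed, not
      # the global drift field, dominates its own neighbourhood average);
      # voxels already claimed by another source are left out so the
      # planted sources stay support-disjoint, and a draw whose surviving
      # patch is too small to behave like a coherent artifact is rejected
      for (try in 1:20) {
        ctr <- sample_center(elig, "artifact patch")
        prox <- gaussian_blob(sh, ctr, 3.5)
        map <- (prox > 0.1) * (shell_out + 0.7 * shell_in) * spec$art_amp
        map[occupied] <- 0
        if (sum(map != 0) >= 60) break
        elig[ctr[1L], ctr[2L], ctr[3L]] <- FALSE
      }
      placed <- c(placed, list(list(ctr = ctr, r = 7)))
      occupied <- occupied | (map != 0)
      f <- stats::runif(1, spec$art_band[1L], spec$art_band[2L])
      tc <- unit_sd(sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) +
                      0.2 * stats::rnorm(T_))
      sources[[length(sources) + 1L]] <-
        list(class = "artifact", map = map, tc = tc, freq = f)
    }

    # slow scanner drift over a broad central profile. The profile is
    # orthogonalized against the compact sources so the planted maps are
    # uncorrelated by construction — overlap between the drift and focal
    # sources would otherwise make them statistically dependent and
    # inseparable in principle, not just in practice.
    if (isTRUE(spec$drift)) {
      dctr <- as.integer(round((sh + 1) / 2))
      dmap <- gaussian_blob(sh, dctr, 12) * grid$brain_mask * spec$drift_amp
      # zero the drift over every compact source's support: the planted
      # maps are then exactly orthogonal, so the sources stay separable,
      # without the deep negative wells a plain projection would dig at
      # the blobs (which would put the drift component's centre on
      # another source's territory)
      for (s in sources) dmap[s$map != 0] <- 0
      dtc <- unit_sd(sin(2 * pi * spec$drift_freq * tt +
                           stats::runif(1, 0, 2 * pi)))
      sources[[length(sources) + 1L]] <-
        list(class = "drift", map = dmap, tc = dtc, freq = spec$drift_freq)
    }

    # assemble: Y = sum(tc %o% map) + jitter inside the blob + white noise;
    # maps are sparse, so only their support is touched
    Y <- matrix(stats::rnorm(T_ * V, sd = spec$noise_sd), T_, V)
    for (s in sources) {
      nz <- which(s$map != 0)
      Y[, nz] <- Y[, nz] + tcrossprod(s$tc, s$map[nz])
    }
    # voxelwise mixing jitter: each blob voxel carries private broadband
    # fluctuations scaled relative to its shared loading. This spreads the
    # within-cluster correlations (high diversity, low clustering/central
    # strength). Being temporally white, the jitter projects almost
    # entirely outside the low-frequency subspace the decomposition
    # retains, so the focal source stays a single component.
    blin <- which(epi_mask)
    nb <- length(blin)
    gam <- stats::runif(nb, spec$jitter_range[1L], spec$jitter_range[2L])
    Y[, blin] <- Y[, blin] +
      matrix(stats::rnorm(T_ * nb), T_) *
      rep(gam * eblob[blin] * spec$epi_amp, each = T_)

    # diffuse physiological noise: voxel-private, temporally smoothed
    if (spec$physio_sd > 0) {
      vin <- which(grid$brain_mask)
      Wn <- matrix(stats::rnorm(T_ * length(vin)), T_)
      Sm <- Wn
      for (d in c(-2L, -1L, 1L, 2L)) {
        sh_rows <- if (d > 0) rbind(matrix(0, d, ncol(Wn)),
                                    Wn[seq_len(T_ - d), , drop = FALSE])
        else rbind(Wn[(1 - d):T_, , drop = FALSE], matrix(0, -d, ncol(Wn)))
        Sm <- Sm + sh_rows
      }
      Y[, vin] <- Y[, vin] + Sm * (spec$physio_sd / sqrt(5))
    }

    bold <- bold_series(array(Y, c(T_, sh)), spec$tr_seconds, grid)
    truth <- list(
      subject_seed = subject_seed,
      sources = lapply(sources, function(s) s[setdiff(names(s), "map")]),
      maps = lapply(sources, function(s) s$map),
      classes = vapply(sources, `[[`, character(1), "class"),
      epi_mask = epi_mask, epi_side = epi_side, epi_freq = f_epi,
      epi_center = as.integer(ectr))
    list(bold = bold, truth = truth)
  })
}

#' Generate a synthetic cohort
#'
#' Subject seeds derive deterministically from the master seed; epileptic
#' sides alternate left/right so the cohort is balanced. Optionally writes
#' one 4D NIfTI plus mask per subject and a JSON ground-truth manifest.
#'
#' @param spec a [synthetic_spec()].
#' @param out_dir optional output directory for NIfTI + manifest.
#' @return list of subjects (each `list(bold, truth)`) with a `manifest`
#'   attribute (tibble: subject, seed, epi_side, epi_freq, epi_center).
#' @export
generate_cohort <- function(spec, out_dir = NULL) {
  stopifnot(spec$n_subjects >= 2L)
  sides <- rep(c("left", "right"), length.out = spec$n_subjects)
  subjects <- lapply(seq_len(spec$n_subjects), function(i) {
    generate_subject(spec, subject_seed = spec$seed + 1013L * i,
                     epi_side = sides[i])
  })
  manifest <- tibble::tibble(
    subject = sprintf("sub%02d", seq_len(spec$n_subjects)),
    seed = spec$seed + 1013L * seq_len(spec$n_subjects),
    epi_side = sides,
    epi_freq = vapply(subjects, function(s) s$truth$epi_freq, numeric(1)),
    epi_center = vapply(subjects, function(s)
      paste(s$truth$epi_center, collapse = ","), character(1)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(subjects)) {
      write_bold(subjects[[i]]$bold,
                 file.path(out_dir, sprintf("sub%02d_bold.nii.gz", i)))
      write_map(subjects[[i]]$bold$grid$brain_mask * 1,
                subjects[[i]]$bold$grid,
                file.path(out_dir, sprintf("sub%02d_mask.nii.gz", i)))
      write_map(subjects[[i]]$truth$epi_mask * 1, subjects[[i]]$bold$grid,
                file.path(out_dir, sprintf("sub%02d_focus.nii.gz", i)))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  attr(subjects, "manifest") <- manifest
  subjects
}
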