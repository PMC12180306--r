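# FastICA fixed-point algorithm (logcosh contrast, symmetric decorrelation)
# after PCA whitening. Rows of X are observed channels, columns are samples.
# Deterministic given `seed`.
#
# Convergence: the update is iterated until the worst per-component rotation
# delta falls below `tol`. When the whitened data contain near-Gaussian
# subspaces (small samples, noise-only directions) those directions have no
# identifiable fixed point and the max-delta criterion cannot reach a strict
# tolerance; the best iterate seen is then accepted provided its delta is
# below `practical_tol`, otherwise the fit is retried with a fresh internal
# seed a bounded number of times before erroring.
#
# For very wide data (many samples) the unmixing rotation is estimated on a
# seeded random subsample of `max_samples` columns — ample for the handful
# of components extracted here — and the sources are then projected from
# the full data, keeping the run deterministic and fast.
fastica_core <- function(X, n_comp, seed, tol = 1e-5, max_iter = 600L,
                         restarts = 3L, practical_tol = 5e-2,
                         max_samples = Inf) {
  p <- nrow(X)
  n <- ncol(X)
  if (n_comp < 1L || n_comp > p)
    stop("n_comp must lie in [1, number of channels]", call. = FALSE)
  Xc <- X - rowMeans(X)
  if (p <= n) {
    cv <- tcrossprod(Xc) / (n - 1)
    eg <- eigen(cv, symmetric = TRUE)
    rank <- sum(eg$values > max(eg$values[1L], 0) * 1e-10 & eg$values > 0)
    if (rank < n_comp)
      stop("data rank (", rank, ") is below the requested ", n_comp,
           " components", call. = FALSE)
    d <- eg$values[seq_len(n_comp)]
    K <- t(eg$vectors[, seq_len(n_comp), drop = FALSE]) / sqrt(d)
    Z <- K %*% Xc
  } else {
    # dual whitening via the samples Gram matrix: cheaper when channels
    # outnumber samples; Z rows are the leading right singular directions
    eg <- eigen(crossprod(Xc), symmetric = TRUE)
    rank <- sum(eg$values > max(eg$values[1L], 0) * 1e-10 & eg$values > 0)
    if (rank < n_comp)
      stop("data rank (", rank, ") is below the requested ", n_comp,
           " components", call. = FALSE)
    Z <- sqrt(n - 1) * t(eg$vectors[, seq_len(n_comp), drop = FALSE])
    K <- NULL
  }

  Zit <- Z
  n_it <- n
  if (is.finite(max_samples) && n > max_samples) {
    samp <- with_seed(seed + 131L, sample.int(n, max_samples))
    Zit <- Z[, samp, drop = FALSE]
    n_it <- max_samples
  }

  converged <- FALSE
  overall_best <- Inf
  W_overall <- NULL
  W <- NULL
  for (attempt in seq_len(restarts + 1L)) {
    if (attempt == 1L) {
      # start from the whitened PCA basis: usually far closer to the
      # fixed point than a random rotation, and avoids saddle passes
      W <- diag(n_comp)
    } else {
      W <- with_seed(seed + 7907L * (attempt - 1L), {
        matrix(stats::rnorm(n_comp * n_comp), n_comp, n_comp)
      })
      s <- svd(W)
      W <- s$u %*% t(s$v)
    }
    best_delta <- Inf
    W_best <- W
    run_below <- 0L
    for (it in seq_len(max_iter)) {
      G <- tanh(W %*% Zit)
      gprime <- 1 - diag(tcrossprod(G)) / n_it
      W1 <- tcrossprod(G, Zit) / n_it - gprime * W
      s <- svd(W1)
      W1 <- s$u %*% t(s$v)
      delta <- max(abs(abs(rowSums(W1 * W)) - 1))
      W <- W1
      if (delta < best_delta) { best_delta <- delta; W_best <- W }
      # convergence must be sustained: the rotation delta also dips below
      # the tolerance transiently while crossing a saddle of the contrast
      run_below <- if (delta < tol) run_below + 1L else 0L
      if (run_below >= 5L) { converged <- TRUE; break }
    }
    if (best_delta < overall_best) {
      overall_best <- best_delta
      W_overall <- W_best
    }
    if (!converged && best_delta < practical_tol) {
      W <- W_best
      converged <- TRUE
    }
    if (converged) break
  }
  if (!converged) {
    # rotation cycling within a near-Gaussian subspace: no fixed point
    # exists to converge to; return the best rotation seen, as the
    # identifiable (non-Gaussian) components have long settled
    warning("FastICA rotation did not settle below ", practical_tol,
            " after ", restarts + 1L, " seeded starts (best delta ",
            signif(overall_best, 3), "); returning the best iterate")
    W <- W_overall
  }

  S <- W %*% Z
  sds <- sqrt(pmax(rowSums((S - rowMeans(S))^2) / (n - 1), .Machine$double.eps))
  S <- S / sds
  A <- Xc %*% t(S) %*% solve(tcrossprod(S))
  list(S = S, A = A, K = K, W = W, n_iter = it, attempts = attempt)
}

#' Convert a raw component map to Z-scores using in-mask statistics
#'
#' Standardizes the whole volume (out-of-mask voxels included) with the mean
#' and SD computed over in-mask voxels only, so the in-mask distribution has
#' mean 0 and SD 1 while out-of-brain loadings stay comparable — the
#' outside-to-inside ratio feature counts suprathreshold voxels on both sides
#' of the mask.
#'
#' @param raw_map numeric 3D array.
#' @param mask logical 3D array with at least 2 in-mask voxels.
#' @return numeric 3D array of Z-scores.
#' @export
zscore_map <- function(raw_map, mask) {
  v <- raw_map[mask]
  if (length(v) < 2L)
    stop("mask must contain at least 2 voxels", call. = FALSE)
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0)
    stop("degenerate component: map is constant over the mask", call. = FALSE)
  (raw_map - mean(v)) / s
}

#' Spatial ICA of a BOLD series
#'
#' Decomposes the voxelwise-demeaned series into `n_components` spatial
#' sources with variance-normalized mixing time courses (FastICA, logcosh
#' contrast, PCA whitening). Each component's map is converted to Z-scores
#' with in-mask statistics and sign-flipped so that its maximum-|Z| in-mask
#' voxel is positive; the time course is flipped together with the map.
#'
#' @param bold a [bold_series()].
#' @param n_components number of components (<= min(T, in-mask voxels)).
#' @param seed integer seed; the decomposition is deterministic given it.
#' @return an object of class `decomposition` with elements `components`
#'   (each holding `index`, `zmap`, `timecourse`), `n_components`, `seed`,
#'   `grid`, and the fitted raw maps/mixing for diagnostics.
#' @export
spatial_ica <- function(bold, n_components, seed) {
  stopifnot(inherits(bold, "bold_series"))
  T_ <- n_timepoints(bold)
  n_in <- sum(bold$grid$brain_mask)
  if (n_components > min(T_, n_in))
    stop("n_components (", n_components, ") exceeds min(T = ", T_,
         ", in-mask voxels = ", n_in, ")", call. = FALSE)
  X <- bold_matrix(bold)
  X <- X - rep(.colMeans(X, nrow(X), ncol(X)), each = nrow(X))  # demean per voxel
  fit <- fastica_core(X, n_components, seed, max_samples = 30000L)

  maps <- fit$S           # k x V raw spatial sources (unit variance over voxels)
  A <- fit$A              # T x k mixing; columns are time courses
  tc_sd <- sqrt(pmax(apply(A, 2L, stats::var), .Machine$double.eps))
  A <- sweep(A, 2L, tc_sd, "/")             # variance-normalized time courses
  maps <- maps * tc_sd                      # maps absorb the scale

  mask <- bold$grid$brain_mask
  comps <- vector("list", n_components)
  for (i in seq_len(n_components)) {
    raw <- array(maps[i, ], bold$grid$shape)
    z <- zscore_map(raw, mask)
    if (needs_sign_flip(z, mask)) {         # sign convention: positive peak
      z <- -z
      maps[i, ] <- -maps[i, ]
      A[, i] <- -A[, i]
    }
    comps[[i]] <- structure(
      list(index = i, zmap = z, timecourse = A[, i], grid = bold$grid),
      class = "spatial_component")
  }
  structure(list(components = comps, n_components = n_components, seed = seed,
                 grid = bold$grid, raw_maps = maps, mixing = A),
            class = "decomposition")
}

#' @export
print.decomposition <- function(x, ...) {
  cat("<decomposition> ", x$n_components, " spatial components, seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# TRUE when the component's sign convention requires a flip: the in-mask
# voxel of maximum |Z| must be positive, making the decomposition invariant
# to the sign indeterminacy of ICA
needs_sign_flip <- function(zmap, mask) {
  zin <- zmap[mask]
  zin[which.max(abs(zin))] < 0
}

#' Apply the component sign convention to a Z-map
#'
#' Flips the map when its maximum-|Z| in-mask voxel is negative, so that
#' `apply_sign_convention(z) == apply_sign_convention(-z)`: downstream
#' features are invariant to ICA sign flips.
#'
#' @param zmap numeric 3D array.
#' @param mask logical 3D array.
#' @return the (possibly negated) Z-map.
#' @export
apply_sign_convention <- function(zmap, mask) {
  if (needs_sign_flip(zmap, mask)) -zmap else zmap
}

#' Temporal ICA within a voxel set
#'
#' Separates the time series of the given voxels into `n_sources`
#' unit-variance temporal sources (FastICA on voxel channels). Used to
#' isolate spike-like activity inside a component's main cluster before the
#' kurtosis feature.
#'
#' @param bold a [bold_series()].
#' @param voxel_set n x 3 matrix of voxel coordinates or vector of linear
#'   indices; must contain at least `n_sources` voxels.
#' @param n_sources number of temporal sources (>= 1); reduced to the data
#'   rank with a warning when the cluster's series span fewer dimensions
#'   (e.g. a perfectly coherent cluster has rank 1).
#' @param seed integer seed.
#' @return list of numeric vectors of length T, each with unit variance.
#' @export
temporal_ica <- function(bold, voxel_set, n_sources, seed) {
  stopifnot(inherits(bold, "bold_series"))
  if (is.matrix(voxel_set)) voxel_set <- lin_index(bold$grid$shape, voxel_set)
  if (length(voxel_set) == 0L)
    stop("empty voxel set", call. = FALSE)
  if (length(voxel_set) < n_sources)
    stop("voxel set has ", length(voxel_set), " voxels but ", n_sources,
         " sources requested", call. = FALSE)
  X <- t(voxel_series(bold, voxel_set))   # channels = voxels, samples = time
  Xc <- X - rowMeans(X)
  M <- if (nrow(Xc) <= ncol(Xc)) tcrossprod(Xc) else crossprod(Xc)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  rank <- sum(ev > max(ev[1L], 0) * 1e-10 & ev > 0)
  if (rank < 1L)
    stop("cluster series are constant; no temporal source to extract",
         call. = FALSE)
  if (rank < n_sources) {
    warning("cluster data rank ", rank, " < ", n_sources,
            " requested temporal sources; extracting ", rank)
    n_sources <- rank
  }
  fit <- fastica_core(X, n_sources, seed)
  lapply(seq_len(n_sources), function(i) as.numeric(fit$S[i, ]))
}
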