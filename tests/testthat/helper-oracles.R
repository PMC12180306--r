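# Independent brute-force oracles and small fixture builders. Every oracle
# is written as plain loops/first-principles formulas, independent of the
# package's implementation paths.

# --- fixtures ---------------------------------------------------------------

# small grid with an MNI-like LAS affine: world x = 0 at the axis-1 centre
toy_grid <- function(shape = c(12L, 12L, 12L), mask = NULL, voxel = 2) {
  shape <- as.integer(shape)
  aff <- rbind(c(-voxel, 0, 0, voxel * (shape[1] - 1) / 2),
               c(0, voxel, 0, 0),
               c(0, 0, voxel, 0),
               c(0, 0, 0, 1))
  if (is.null(mask)) mask <- array(TRUE, shape)
  volume_grid(shape, aff, mask)
}

toy_bold <- function(grid, T_ = 40L, tr = 2, seed = 1) {
  withr::with_seed(seed, {
    bold_series(array(rnorm(T_ * prod(grid$shape)), c(T_, grid$shape)),
                tr, grid)
  })
}

# reduced synthetic spec for fast end-to-end tests
small_spec <- function(...) {
  args <- utils::modifyList(
    list(shape = c(34L, 40L, 34L), n_time = 100L, n_subjects = 3L,
         n_sym = 2L, n_art = 1L, epi_sigma = 2.2),
    list(...))
  do.call(synthetic_spec, args)
}

# one small analyzed cohort, computed once and shared across tests
.fit_cache <- new.env()
cached_small_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    sp <- small_spec(seed = 11L)
    subjects <- generate_cohort(sp)
    fit <- suppressWarnings(run_cohort_pipeline(
      lapply(subjects, `[[`, "bold"),
      pipeline_config(n_components = 10L, seed = sp$seed)))
    .fit_cache$fit <- fit
    .fit_cache$subjects <- subjects
  }
  list(fit = .fit_cache$fit, subjects = .fit_cache$subjects)
}

# --- oracles ----------------------------------------------------------------

# flood-fill connected-component labeling (BFS over an explicit queue)
oracle_label <- function(mask, connectivity = 26L) {
  dm <- dim(mask)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[rowSums(abs(offs)) > 0, ]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, ]
  lab <- array(0L, dm)
  cur <- 0L
  for (v in which(mask)) {
    if (lab[v] > 0L) next
    cur <- cur + 1L
    queue <- list(arrayInd(v, dm)[1, ])
    lab[v] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (r in seq_len(nrow(offs))) {
        q <- p + as.integer(offs[r, ])
        if (any(q < 1L) || any(q > dm)) next
        if (mask[q[1], q[2], q[3]] && lab[q[1], q[2], q[3]] == 0L) {
          lab[q[1], q[2], q[3]] <- cur
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  lab
}

# partition of labels (region membership as sorted voxel-index sets)
label_partition <- function(lab) {
  v <- which(lab > 0)
  unname(lapply(split(v, lab[v]), sort))
}

oracle_ball <- function(radius) {
  r <- ceiling(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  as.matrix(g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, ])
}

oracle_dilate <- function(mask, radius) {
  dm <- dim(mask)
  offs <- oracle_ball(radius)
  out <- array(FALSE, dm)
  for (v in which(mask)) {
    p <- arrayInd(v, dm)[1, ]
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (all(q >= 1L) && all(q <= dm)) out[q[1], q[2], q[3]] <- TRUE
    }
  }
  out
}

oracle_erode <- function(mask, radius) {
  dm <- dim(mask)
  offs <- oracle_ball(radius)
  out <- array(FALSE, dm)
  for (v in which(mask)) {
    p <- arrayInd(v, dm)[1, ]
    keep <- TRUE
    for (r in seq_len(nrow(offs))) {
      q <- p + offs[r, ]
      if (any(q < 1L) || any(q > dm) || !mask[q[1], q[2], q[3]]) {
        keep <- FALSE; break
      }
    }
    if (keep) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}

oracle_open_close <- function(mask, radius) {
  opened <- oracle_dilate(oracle_erode(mask, radius), radius)
  # closing on a padded copy (infinite-background semantics)
  r <- ceiling(radius)
  dm <- dim(mask)
  big <- array(FALSE, dm + 2L * r)
  big[r + seq_len(dm[1]), r + seq_len(dm[2]), r + seq_len(dm[3])] <- opened
  closed <- oracle_erode(oracle_dilate(big, radius), radius)
  closed[r + seq_len(dm[1]), r + seq_len(dm[2]), r + seq_len(dm[3])]
}

# explicit-DFT periodogram peak frequency (zero bin excluded)
oracle_peak_freq <- function(x, tr) {
  T_ <- length(x)
  xc <- x - mean(x)
  m <- floor(T_ / 2)
  power <- numeric(m)
  for (k in seq_len(m)) {
    re <- sum(xc * cos(-2 * pi * k * (0:(T_ - 1)) / T_))
    im <- sum(xc * sin(-2 * pi * k * (0:(T_ - 1)) / T_))
    power[k] <- re^2 + im^2
  }
  which.max(power) / (T_ * tr)
}

oracle_pearson <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}

# pairwise-correlation matrix by explicit loops
oracle_cor_matrix <- function(M) {
  n <- ncol(M)
  r <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) r[i, j] <- oracle_pearson(M[, i], M[, j])
  }
  r
}

oracle_mean_offdiag <- function(r) {
  n <- nrow(r); s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) s <- s + r[i, j]
  s / (n * (n - 1))
}

oracle_pair_variance <- function(r) {
  vals <- c()
  n <- nrow(r)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) vals <- c(vals, r[i, j])
  m <- mean(vals)
  sum((vals - m)^2) / (length(vals) - 1)
}

oracle_excess_kurtosis <- function(y) {
  yc <- y - mean(y)
  mean(yc^4) - 3 * mean(yc^2)^2
}

# mirror voxel of coordinate p about plane m on axis 1 (toy grids)
oracle_mirror <- function(p, m) c(2 * m - p[1], p[2], p[3])

# lateralization index by explicit pair loops (toy grid, axis-1 midline m)
oracle_li <- function(zmap, mask, m) {
  dm <- dim(zmap)
  xl <- c(); xr <- c()
  for (v in which(mask)) {
    p <- arrayInd(v, dm)[1, ]
    if (p[1] >= m) next               # low-index block only (left on LAS)
    q <- oracle_mirror(p, m)
    if (q[1] < 1 || q[1] > dm[1] || !mask[q[1], q[2], q[3]]) next
    xl <- c(xl, zmap[p[1], p[2], p[3]])
    xr <- c(xr, zmap[q[1], q[2], q[3]])
  }
  1 - abs(oracle_pearson(xl, xr))
}

# lateralization strength by explicit counting (left = high indices on LAS)
oracle_ls <- function(sig, m, left_high = TRUE) {
  dm <- dim(sig)
  nl <- 0L; nr <- 0L
  for (v in which(sig)) {
    p <- arrayInd(v, dm)[1, ]
    if (p[1] == m) next
    q <- oracle_mirror(p, m)
    mirrored <- q[1] >= 1 && q[1] <= dm[1] && sig[q[1], q[2], q[3]]
    if (mirrored) next
    is_left <- xor(p[1] < m, left_high)
    if (is_left) nl <- nl + 1L else nr <- nr + 1L
  }
  if (nl + nr == 0L) return(list(ls = 0, side = "none"))
  list(ls = abs(nl - nr) / (nl + nr),
       side = if (nl > nr) "left" else if (nr > nl) "right" else "none")
}
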