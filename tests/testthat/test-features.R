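test_that("outside-to-inside ratio counts suprathreshold voxels on both sides", {
  grid_shape <- c(10L, 10L, 10L)
  mask <- array(FALSE, grid_shape); mask[3:8, 3:8, 3:8] <- TRUE
  z <- array(0, grid_shape)
  inside <- which(mask)[1:100]
  outside <- which(!mask)[1:4]
  z[inside] <- 5; z[outside] <- 5
  expect_equal(outside_inside_ratio(z, mask), 0.04)
  z[outside] <- 0
  expect_equal(outside_inside_ratio(z, mask), 0)
  z2 <- array(0, grid_shape); z2[which(!mask)[1:3]] <- 5
  expect_identical(outside_inside_ratio(z2, mask), Inf)   # reject sentinel
})

test_that("dominant frequency finds the spectral peak, excluding the zero bin", {
  tt <- 0:199 * 3
  s <- sin(2 * pi * 0.05 * tt)
  expect_equal(max_power_frequency(s, 3), 0.05, tolerance = 1 / 600)
  s2 <- sin(2 * pi * 0.15 * tt + 0.3)
  expect_equal(max_power_frequency(s2, 3), 0.15, tolerance = 1 / 600)
  # stronger low component wins
  s3 <- 2 * sin(2 * pi * 0.02 * tt) + sin(2 * pi * 0.08 * tt)
  expect_equal(max_power_frequency(s3, 3), 0.02, tolerance = 1 / 600)
  # a large constant offset does not create a zero-frequency winner
  expect_equal(max_power_frequency(s + 100, 3), 0.05, tolerance = 1 / 600)
  expect_error(max_power_frequency(rep(1, 50), 3), "constant")
  expect_error(max_power_frequency(s[1:4], 3), "T >= 8")
})

test_that("dominant frequency matches an explicit-DFT oracle", {
  for (seed in 1:20) {
    x <- withr::with_seed(seed, as.numeric(stats::filter(
      rnorm(48), rep(1, 3), circular = TRUE)))
    expect_equal(max_power_frequency(x, 2.5), oracle_peak_freq(x, 2.5),
                 tolerance = 1e-12)
  }
})

test_that("lateralization index has the stated analytic limits", {
  grid <- toy_grid(c(12L, 10L, 10L))
  z <- withr::with_seed(21, array(rnorm(1200), grid$shape))
  zs <- z
  for (i in 1:6) zs[13 - i, , ] <- zs[i, , ]     # mirror-symmetric
  expect_equal(lateralization_index(zs, grid), 0, tolerance = 1e-12)
  za <- z
  for (i in 1:6) za[13 - i, , ] <- -za[i, , ]    # anti-symmetric: also 0
  expect_equal(lateralization_index(za, grid), 0, tolerance = 1e-12)
  # global sign flip leaves LI unchanged
  expect_equal(lateralization_index(z, grid), lateralization_index(-z, grid))
  expect_error(lateralization_index(array(0, grid$shape) + zs * 0, grid),
               "degenerate|constant")
})

test_that("independent random hemispheres give LI near 1", {
  grid <- toy_grid(c(22L, 22L, 22L))   # ~5.3k mirror pairs
  lis <- sapply(1:5, function(s) {
    z <- withr::with_seed(300 + s, array(rnorm(22^3), grid$shape))
    lateralization_index(z, grid)
  })
  expect_true(all(abs(lis - 1) < 0.05))
})

test_that("LI matches the explicit pair-loop oracle on masked grids", {
  shape <- c(10L, 8L, 8L)
  for (seed in 1:5) {
    mask <- withr::with_seed(400 + seed, array(runif(prod(shape)) < 0.7, shape))
    if (sum(mask) < 20) next
    grid <- toy_grid(shape, mask = mask)
    z <- withr::with_seed(500 + seed, array(rnorm(prod(shape)), shape))
    expect_equal(lateralization_index(z, grid),
                 oracle_li(z, mask, m = 5.5), tolerance = 1e-10)
  }
})

test_that("lateralization strength counts non-mirrored suprathreshold voxels", {
  grid <- toy_grid(c(12L, 10L, 10L))   # LAS: left = high indices
  sig <- array(FALSE, grid$shape)
  sig[9:11, 3:5, 3:5] <- TRUE          # fully one-sided (left)
  r <- lateralization_strength(sig, grid)
  expect_equal(r$ls, 1)
  expect_equal(r$side, "left")
  # mirror-symmetric mask: everything pairs off
  sym <- sig
  for (i in 1:6) sym[13 - i, , ] <- sym[i, , ] | sym[13 - i, , ]
  for (i in 1:6) sym[i, , ] <- sym[13 - i, , ]
  r2 <- lateralization_strength(sym, grid)
  expect_equal(r2$ls, 0)
  expect_equal(r2$side, "none")
  # 30 left vs 10 right non-mirrored
  mix <- array(FALSE, grid$shape)
  mix[10, 1:5, 1:6] <- TRUE            # 30 left
  mix[3, 6:7, 1:5] <- TRUE             # 10 right, mirror-disjoint
  r3 <- lateralization_strength(mix, grid)
  expect_equal(r3$ls, 0.5)
  expect_equal(r3$side, "left")
  # hemispheric swap flips the side label, not the magnitude
  swapped <- mix[12:1, , ]
  r4 <- lateralization_strength(swapped, grid)
  expect_equal(r4$ls, r3$ls)
  expect_equal(r4$side, "right")
})

test_that("LS matches the explicit counting oracle on random masks", {
  shape <- c(10L, 8L, 8L)
  grid <- toy_grid(shape)
  for (seed in 1:6) {
    sig <- withr::with_seed(600 + seed, array(runif(prod(shape)) < 0.2, shape))
    got <- lateralization_strength(sig, grid)
    want <- oracle_ls(sig, m = 5.5, left_high = TRUE)
    expect_equal(got$ls, want$ls, tolerance = 1e-12)
    expect_identical(got$side, want$side)
  }
})

test_that("local connectivity equals brute-force pairwise correlation", {
  grid <- toy_grid(c(8L, 8L, 8L))
  bold <- toy_bold(grid, T_ = 30L, seed = 31)
  mask <- array(FALSE, grid$shape); mask[2:4, 2:3, 2] <- TRUE
  conn <- local_connectivity(bold, mask, center = c(3L, 2L, 2L))
  M <- sapply(which(mask), function(v) {
    p <- arrayInd(v, grid$shape)[1, ]; bold$data[, p[1], p[2], p[3]]
  })
  expect_equal(conn$r, oracle_cor_matrix(M), tolerance = 1e-12)
  expect_equal(conn$n, 6L)
  # shared series -> all correlations 1
  s <- sin(seq_len(30))
  b2 <- bold_series(array(rep(s, 512), c(30, grid$shape)), 2, grid)
  c2 <- local_connectivity(b2, mask, c(3L, 2L, 2L))
  expect_equal(max(abs(c2$r - 1)), 0, tolerance = 1e-12)
  # independent long noise series decorrelate
  g2 <- toy_grid(c(4L, 4L, 4L))
  b3 <- toy_bold(g2, T_ = 500L, seed = 32)
  m3 <- array(FALSE, g2$shape); m3[1:2, 1, 1] <- TRUE
  c3 <- local_connectivity(b3, m3, c(1L, 1L, 1L))
  expect_lt(abs(c3$r[1, 2]), 0.1)
})

test_that("graph summaries have their analytic values and match oracles", {
  r3 <- diag(3)
  r3[1, 2] <- r3[2, 1] <- 0.5
  r3[1, 3] <- r3[3, 1] <- 0.2
  r3[2, 3] <- r3[3, 2] <- -0.1
  conn <- list(r = r3, n = 3L, center_row = 1L)
  expect_equal(clustering_coefficient(conn), 0.2)
  expect_equal(connectivity_diversity(conn), var(c(0.5, 0.2, -0.1)))
  expect_equal(central_network_strength(conn), mean(c(0.5, 0.2)))
  # pairs {0, 1}: unbiased variance 0.5
  r2 <- diag(2); conn2 <- list(r = r2, n = 2L, center_row = 1L)
  expect_error(connectivity_diversity(conn2), "pairs")
  rp <- matrix(c(1, 0, 0.5, 0, 1, 1, 0.5, 1, 1), 3)   # pair set {0, 0.5, 1}
  expect_equal(connectivity_diversity(list(r = rp, n = 3L, center_row = 1L)),
               var(c(0, 0.5, 1)))
  # all off-diagonals 1 -> CC = 1, NS = 1; all 0 -> 0
  ones <- matrix(1, 4, 4)
  expect_equal(clustering_coefficient(list(r = ones, n = 4L)), 1)
  expect_equal(central_network_strength(list(r = ones, n = 4L, center_row = 2L)), 1)
  expect_equal(clustering_coefficient(list(r = diag(4), n = 4L)), 0)
  # NS with r_ic = {0.4, 0.8, 0.0} -> 0.4
  rc <- diag(4)
  rc[1, 2:4] <- rc[2:4, 1] <- c(0.4, 0.8, 0)
  expect_equal(central_network_strength(list(r = rc, n = 4L, center_row = 1L)),
               0.4)
  # random matrices against the loop oracles
  for (seed in 1:5) {
    M <- withr::with_seed(700 + seed, matrix(rnorm(40 * 6), 40))
    r <- cor(M); conn <- list(r = r, n = 6L, center_row = 3L)
    expect_equal(clustering_coefficient(conn), oracle_mean_offdiag(r),
                 tolerance = 1e-12)
    expect_equal(connectivity_diversity(conn), oracle_pair_variance(r),
                 tolerance = 1e-12)
  }
})

test_that("central energy is the plain sum of squares", {
  expect_equal(central_energy(rep(2.5, 7)), 7 * 2.5^2)
  expect_equal(central_energy(numeric(10)), 0)
  expect_equal(central_energy(c(1, -2, 3)), 14)
  # quadratic scaling
  x <- withr::with_seed(41, rnorm(20))
  expect_equal(central_energy(3 * x), 9 * central_energy(x))
})

test_that("max temporal non-Gaussianity follows the moment formula", {
  # symmetric two-point source: excess kurtosis exactly -2, |.| = 2
  y <- rep(c(-1, 1), 50)
  expect_equal(max_tic_nongaussianity(list(y)), 2)
  # large Gaussian sample is near zero
  g <- withr::with_seed(42, rnorm(1e4))
  expect_lt(max_tic_nongaussianity(list(g)), 0.15)
  # the spiky source dominates a smooth one
  spikes <- rep(0, 1000); spikes[withr::with_seed(43, sample.int(1000, 10))] <- 6
  smooth <- sin(2 * pi * (1:1000) / 100)
  expect_equal(max_tic_nongaussianity(list(smooth, spikes)),
               abs(oracle_excess_kurtosis(spikes)), tolerance = 1e-12)
  # scale invariance on variance-normalized input is exact scale-freeness
  z <- withr::with_seed(44, rt(500, df = 5))
  expect_equal(max_tic_nongaussianity(list(z / sd(z))),
               abs(oracle_excess_kurtosis(z / sd(z))), tolerance = 1e-12)
  expect_error(max_tic_nongaussianity(list()), "empty")
})

test_that("extract_features assembles a full row and flags non-candidates", {
  res <- cached_small_fit()
  tab <- res$fit$features
  expect_true(all(c("r_oi", "max_power_freq", "lat_index", "lat_strength",
                    "clustering_coef", "conn_diversity", "central_strength",
                    "central_energy", "max_tic_kurtosis") %in% names(tab)))
  expect_true(any(!tab$candidate))     # noise components without clusters
  nc <- tab[!tab$candidate, ]
  expect_true(all(is.na(nc$clustering_coef)))
  expect_true(all(nc$n_sig_voxels == 0 |
                    is.na(nc$clustering_coef)))
  cand <- tab[tab$candidate, ]
  expect_true(all(is.finite(cand$max_tic_kurtosis)))
})
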