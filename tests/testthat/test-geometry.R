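test_that("significance clustering keeps only regions strictly above min size", {
  grid <- toy_grid(c(12L, 12L, 12L))
  z <- array(0, grid$shape)
  z[1:3, 1:2, 1:2] <- 5      # 12 voxels -> kept
  z[8:9, 8:9, 8:9] <- 5      # 8 voxels  -> dropped
  sig <- significance_clusters(z, grid$brain_mask)
  expect_equal(sum(sig), 12)
  expect_true(all(sig[1:3, 1:2, 1:2]))
  # all sub-threshold -> empty
  expect_equal(sum(significance_clusters(z * 0.5, grid$brain_mask)), 0)
  # an 11-voxel region passes the strict "> 10" rule
  z2 <- array(0, grid$shape); z2[1:11, 1, 1] <- 4
  expect_equal(sum(significance_clusters(z2, grid$brain_mask)), 11)
  z3 <- array(0, grid$shape); z3[1:10, 1, 1] <- 4
  expect_equal(sum(significance_clusters(z3, grid$brain_mask)), 0)
})

test_that("touching blobs merge into one region (flood-fill oracle)", {
  grid <- toy_grid(c(12L, 12L, 12L))
  z <- array(0, grid$shape)
  z[2:4, 2:6, 2] <- 5
  z[5:7, 6:10, 2] <- 5       # diagonal touch at (4,6)/(5,6): 26-connected
  sig <- significance_clusters(z, grid$brain_mask)
  lab <- label_components(sig)
  expect_equal(max(lab), 1L)
  expect_equal(sum(sig), 30)
})

test_that("region labeling matches an independent flood fill", {
  for (seed in 1:4) {
    mask <- withr::with_seed(seed, array(runif(12^3) < 0.25, c(12, 12, 12)))
    for (conn in c(26L, 6L)) {
      got <- label_components(mask, conn)
      want <- oracle_label(mask, conn)
      expect_identical(label_partition(got), label_partition(want))
    }
  }
})

test_that("morphological opening/closing matches the brute-force oracle", {
  # solid cube: interior preserved (the ball element only rounds corners);
  # lone voxel removed; interior hole filled by closing
  cube <- array(FALSE, c(12, 12, 12)); cube[3:9, 3:9, 3:9] <- TRUE
  oc <- morph_open_close(cube, 2)
  expect_identical(oc, oracle_open_close(cube, 2))
  expect_true(all(oc[4:8, 4:8, 4:8]))
  expect_true(all(cube[oc]))                  # opening/closing of a solid
  lone <- array(FALSE, c(12, 12, 12)); lone[6, 6, 6] <- TRUE
  expect_equal(sum(morph_open_close(lone, 2)), 0)
  holed <- cube; holed[6, 6, 6] <- FALSE
  och <- morph_open_close(holed, 2)
  expect_identical(och, oracle_open_close(holed, 2))
  # closing alone fills a 1-voxel interior hole
  closed <- binary_close(holed, ball_offsets(2))
  expect_true(closed[6, 6, 6])

  for (seed in 1:3) {
    mask <- withr::with_seed(100 + seed,
                             oracle_dilate(array(runif(10^3) < 0.04,
                                                 c(10, 10, 10)), 1.5))
    got <- morph_open_close(mask, 2)
    expect_identical(got, oracle_open_close(mask, 2))
    # idempotence on the result
    expect_identical(morph_open_close(got, 2), got)
  }
})

test_that("main connected component follows the centre, with nearest fallback", {
  mask <- array(FALSE, c(12, 12, 12))
  mask[2:4, 2:4, 2:4] <- TRUE        # blob A (27)
  mask[9:11, 9:11, 9:11] <- TRUE     # blob B (27)
  a <- main_connected_component(mask, c(3, 3, 3))
  expect_true(all(a[2:4, 2:4, 2:4]) && sum(a) == 27)
  # centre outside the mask: nearest region wins, with a warning
  expect_warning(b <- main_connected_component(mask, c(8, 8, 8)), "nearest")
  expect_true(all(b[9:11, 9:11, 9:11]) && sum(b) == 27)
  expect_error(main_connected_component(array(FALSE, c(4, 4, 4)), c(1, 1, 1)),
               "empty")
})

test_that("sic_center takes the max-Z voxel with lexicographic tie-break", {
  grid <- toy_grid(c(12L, 12L, 12L))
  z <- array(0, grid$shape)
  z[10, 11, 3] <- 7
  expect_equal(sic_center(z, grid$brain_mask), c(10L, 11L, 3L))
  z2 <- array(0, grid$shape)
  z2[3, 3, 3] <- 7; z2[2, 5, 5] <- 7
  expect_equal(sic_center(z2, grid$brain_mask), c(2L, 5L, 5L))
})

test_that("central local average equals the enumerated neighbourhood mean", {
  grid <- toy_grid(c(10L, 10L, 10L))
  bold <- toy_bold(grid, T_ = 25L, seed = 12)
  ctr <- c(5L, 6L, 4L)
  got <- central_local_average(bold, ctr)
  # brute-force: explicit 27-voxel enumeration
  acc <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1)
    acc <- acc + bold$data[, ctr[1] + dx, ctr[2] + dy, ctr[3] + dz]
  expect_equal(got, acc / 27, tolerance = 1e-12)

  # shared series passes through unchanged
  s <- sin(seq_len(25))
  bold2 <- bold_series(array(rep(s, 1000), c(25, grid$shape)), 2, grid)
  expect_equal(central_local_average(bold2, ctr), s)

  # at a mask edge only in-mask voxels are averaged
  mask <- array(FALSE, grid$shape); mask[1:5, , ] <- TRUE
  gedge <- volume_grid(grid$shape, grid$affine, mask)
  bedge <- bold_series(bold$data, 2, gedge)
  gote <- central_local_average(bedge, c(5L, 6L, 4L))
  acc <- 0
  for (dx in -1:0) for (dy in -1:1) for (dz in -1:1)
    acc <- acc + bedge$data[, 5 + dx, 6 + dy, 4 + dz]
  expect_equal(gote, acc / 18, tolerance = 1e-12)
})

test_that("significance clustering is monotone in the Z threshold", {
  grid <- toy_grid(c(12L, 12L, 12L))
  for (seed in 1:3) {
    z <- withr::with_seed(200 + seed, {
      raw <- array(rnorm(12^3), c(12, 12, 12))
      # smooth to create contiguous structure
      for (i in 1:2) raw <- (raw + oracle_dilate(raw > 0.8, 1) * 2) / 2
      raw * 3
    })
    prev <- NULL
    for (th in c(1.5, 2.5, 3.1, 4)) {
      cur <- significance_clusters(z, grid$brain_mask, z_thresh = th,
                                   min_size = 3L)
      if (!is.null(prev)) expect_true(all(prev | !cur))  # cur subset of prev
      prev <- cur
    }
  }
})

test_that("component_clusters fixes the level order and centre provenance", {
  pl_grid <- toy_grid(c(12L, 12L, 12L))
  z <- array(0, pl_grid$shape)
  z[3:7, 3:7, 3:7] <- 4 + withr::with_seed(9, array(runif(125), c(5, 5, 5)))
  z[5, 5, 5] <- 9
  comp <- structure(list(index = 1L, zmap = z,
                         timecourse = rep(0, 20), grid = pl_grid),
                    class = "spatial_component")
  bold <- toy_bold(pl_grid, T_ = 20L)
  cl <- component_clusters(bold, comp)
  expect_equal(cl$center, c(5L, 5L, 5L))
  expect_true(cl$main_mask[5, 5, 5])
  expect_equal(max(label_components(cl$main_mask)), 1L)
  expect_equal(length(cl$central_series), 20L)
  expect_equal(cl$central_voxel_series, bold$data[, 5, 5, 5])
})
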