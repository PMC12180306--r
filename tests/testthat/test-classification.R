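# minimal feature table builder: one subject row per component with all
# gated features neutral unless overridden
feature_row <- function(subject, component, candidate = TRUE,
                        r_oi = 0.1, freq = 0.05, li = 0.5, ls = 0.5,
                        cc = 0.5, cd = 0.01, ns = 0.5, ce = 100, kurt = 1) {
  tibble::tibble(subject = subject, component = as.integer(component),
                 candidate = candidate, n_sig_voxels = 50L,
                 center_x = 1L, center_y = 1L, center_z = 1L,
                 r_oi = r_oi, max_power_freq = freq, lat_index = li,
                 lat_strength = ls, lat_side = "left",
                 clustering_coef = cc, conn_diversity = cd,
                 central_strength = ns, central_energy = ce,
                 max_tic_kurtosis = kurt)
}

test_that("thresholds are mean +/- k*SD toward the expected tail", {
  tab <- dplyr::bind_rows(lapply(0:9, function(i)
    feature_row("s1", i + 1, r_oi = i)))
  thr <- suppressWarnings(compute_thresholds(tab, classification_rule()))
  row <- thr[thr$feature == "r_oi", ]
  expect_equal(row$mean, 4.5)
  expect_equal(row$sd, sd(0:9))
  expect_equal(row$threshold, 4.5 - sd(0:9))       # ~1.47: values {0,1} pass
  expect_equal(sum(tab$r_oi < row$threshold), 2)
  # "greater" features offset upward
  row_li <- thr[thr$feature == "lat_index", ]
  expect_equal(row_li$threshold, 0.5)              # zero SD -> mean
  # lenient mode offsets away from the tail
  thr_len <- suppressWarnings(
    compute_thresholds(tab, classification_rule(direction_mode = "lenient")))
  expect_equal(thr_len$threshold[thr_len$feature == "r_oi"], 4.5 + sd(0:9))
})

test_that("zero-variance features collapse to the mean with a warning", {
  tab <- withr::with_seed(1, dplyr::bind_rows(lapply(1:6, function(i)
    feature_row("s1", i, r_oi = 0.2,            # the only zero-SD feature
                li = runif(1), ls = runif(1), cc = runif(1),
                cd = runif(1), ns = runif(1)))))
  expect_warning(thr <- compute_thresholds(tab), "zero SD for feature 'r_oi'")
  expect_equal(thr$threshold[thr$feature == "r_oi"], 0.2)
})

test_that("the band gate is inclusive and the r_oi reject sentinel excludes", {
  tab <- dplyr::bind_rows(
    feature_row("s1", 1, freq = 0.05, li = 0.9, ls = 0.9, cc = 0.2,
                cd = 0.05, ns = 0.2),
    feature_row("s1", 2, freq = 0.15),             # out of band
    feature_row("s1", 3, freq = 0.01),             # boundary: in band
    feature_row("s1", 4, freq = 0.1),              # boundary: in band
    feature_row("s1", 5, freq = 0.05, r_oi = Inf), # rejected outright
    feature_row("s2", 6, freq = 0.05, li = 0.9, ls = 0.9, cc = 0.2,
                cd = 0.05, ns = 0.2))
  thr <- suppressWarnings(compute_thresholds(tab))
  cand <- filter_candidates(tab, thr, relax = FALSE)
  expect_false(2L %in% cand$component)
  expect_false(5L %in% cand$component)
  cand0 <- filter_candidates(tab, thr)
  expect_true(all(!is.na(cand0$k_used)))
  expect_false(5L %in% cand0$component)
})

test_that("candidate sets shrink monotonically as k_sd grows", {
  res <- cached_small_fit()
  tab <- res$fit$features
  thr <- suppressWarnings(compute_thresholds(tab))
  sizes <- sapply(c(0.5, 1, 1.5), function(k)
    nrow(filter_candidates(tab, thr, classification_rule(k_sd = k),
                           relax = FALSE)))
  expect_true(all(diff(sizes) <= 0))
})

test_that("selection prioritizes central energy and kurtosis by rank sum", {
  tab <- dplyr::bind_rows(
    feature_row("s1", 1, ce = 100, kurt = 5),   # CE rank 1, kurt rank 2
    feature_row("s1", 2, ce = 90, kurt = 6),    # CE rank 2, kurt rank 1
    feature_row("s1", 3, ce = 10, kurt = 1))
  cand <- tibble::tibble(subject = "s1", component = 1:3,
                         k_used = 1, band_dropped = FALSE)
  sel <- select_epileptic(cand, tab)
  expect_equal(sel$component, 2L)               # tie on rank sum -> higher kurt
  expect_equal(sel$n_candidates, 3L)
  # lexicographic mode prefers the higher CE
  sel2 <- select_epileptic(cand, tab, classification_rule(priority = "lexicographic"))
  expect_equal(sel2$component, 1L)
  # single candidate is selected directly
  sel3 <- select_epileptic(cand[1, ], tab)
  expect_equal(sel3$component, 1L)
  # no candidates -> unlocalizable
  sel4 <- select_epileptic(cand[0, ], tab)
  expect_true(is.na(sel4$component))
  expect_equal(sel4$n_candidates, 0L)
})

test_that("selection is invariant to monotone rescaling of central energy", {
  tab <- dplyr::bind_rows(lapply(1:5, function(i)
    feature_row("s1", i, ce = i * 10, kurt = 6 - i)))
  cand <- tibble::tibble(subject = "s1", component = 1:5,
                         k_used = 1, band_dropped = FALSE)
  sel_a <- select_epileptic(cand, tab)
  tab2 <- tab
  tab2$central_energy <- log(tab2$central_energy) * 1e6   # monotone map
  sel_b <- select_epileptic(cand, tab2)
  expect_equal(sel_a$component, sel_b$component)
})

test_that("thresholds ignore degenerate rows and subject/component order", {
  tab <- dplyr::bind_rows(
    lapply(1:6, function(i) feature_row("s1", i, r_oi = i / 10)),
    lapply(1:6, function(i) feature_row("s2", i, r_oi = 1 - i / 10)),
    feature_row("s1", 7, candidate = FALSE, r_oi = 1e6))
  thr <- suppressWarnings(compute_thresholds(tab))
  shuf <- withr::with_seed(1, tab[sample.int(nrow(tab)), ])
  thr2 <- suppressWarnings(compute_thresholds(shuf))
  expect_equal(thr, thr2)
  expect_lt(thr$mean[thr$feature == "r_oi"], 1)   # degenerate row excluded
})

test_that("classification of a cohort is deterministic and well-formed", {
  res <- cached_small_fit()
  fit1 <- suppressWarnings(classify_components(res$fit$features))
  fit2 <- suppressWarnings(classify_components(res$fit$features))
  expect_identical(fit1$selection, fit2$selection)
  expect_equal(nrow(fit1$selection), length(unique(res$fit$features$subject)))
  expect_true(all(table(fit1$selection$subject) == 1))
  td <- tidy(fit1)
  expect_identical(td, fit1$selection)
  gl <- glance(fit1)
  expect_equal(gl$n_subjects, nrow(fit1$selection))
})
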