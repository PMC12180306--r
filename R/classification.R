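#' Classification rule for the epileptic-component selection
#'
#' Encodes, per feature, the expected direction of the epileptic component
#' relative to the cohort: dominant frequency inside the low-frequency band;
#' outside-to-inside ratio below threshold; lateralization index and strength
#' above threshold; clustering coefficient below; connectivity diversity
#' above; central network strength below; central energy and maximum
#' temporal-source kurtosis maximized among the surviving candidates.
#'
#' Thresholds are `mean +/- k_sd * SD` of all components of all subjects,
#' offset toward the feature's expected tail (`direction_mode = "strict"`,
#' the default) or away from it (`"lenient"`).
#'
#' @param k_sd SD multiplier (default 1).
#' @param band inclusive dominant-frequency band in Hz (default 0.01-0.1).
#' @param direction_mode `"strict"` or `"lenient"` threshold offset.
#' @param priority `"rank_sum"` (default) combines the two priority features
#'   by the sum of descending ranks; `"lexicographic"` orders by central
#'   energy then kurtosis.
#' @return an object of class `classification_rule`.
#' @export
classification_rule <- function(k_sd = 1, band = c(0.01, 0.1),
                                direction_mode = c("strict", "lenient"),
                                priority = c("rank_sum", "lexicographic")) {
  structure(
    list(
      directions = tibble::tribble(
        ~feature,            ~direction,
        "max_power_freq",    "band",
        "r_oi",              "less",
        "lat_index",         "greater",
        "lat_strength",      "greater",
        "clustering_coef",   "less",
        "conn_diversity",    "greater",
        "central_strength",  "less",
        "central_energy",    "maximize",
        "max_tic_kurtosis",  "maximize"
      ),
      k_sd = k_sd, band = band,
      direction_mode = match.arg(direction_mode),
      priority = match.arg(priority)
    ),
    class = "classification_rule")
}

#' Per-feature cohort thresholds
#'
#' Computes each thresholded feature's mean and SD over all non-degenerate
#' rows (components with a surviving significance cluster) of the cohort
#' table, and the threshold at the rule's `k_sd`. Band features carry fixed
#' limits; maximize features get no threshold. A zero-SD feature collapses
#' its threshold to the mean, with a warning.
#'
#' @param table cohort feature table: one row per (subject, component), as
#'   built by [cohort_features()].
#' @param rule a [classification_rule()].
#' @return tibble with columns feature, direction, mean, sd, threshold.
#' @export
compute_thresholds <- function(table, rule = classification_rule()) {
  valid <- dplyr::filter(table, .data$candidate)
  if (nrow(valid) < 2L)
    stop("need at least 2 valid component rows for cohort statistics",
         call. = FALSE)
  dirs <- dplyr::filter(rule$directions, !.data$direction %in% c("band", "maximize"))
  out <- purrr::pmap_dfr(dirs, function(feature, direction) {
    v <- valid[[feature]]
    v <- v[is.finite(v)]
    m <- mean(v)
    s <- stats::sd(v)
    if (s == 0) warning("zero SD for feature '", feature,
                        "'; threshold equals the mean")
    tibble::tibble(feature = feature, direction = direction, mean = m, sd = s)
  })
  out$threshold <- threshold_at(out, rule$k_sd, rule$direction_mode)
  out
}

# threshold values for a stats table at multiplier k
threshold_at <- function(stats_tbl, k, mode = "strict") {
  sgn <- ifelse(stats_tbl$direction == "less", -1, 1)
  if (mode == "lenient") sgn <- -sgn
  stats_tbl$mean + sgn * k * stats_tbl$sd
}

# logical pass vector for the directional + band gates
passes_gates <- function(df, stats_tbl, k, rule, drop_band = FALSE) {
  pass <- rep(TRUE, nrow(df))
  thr <- threshold_at(stats_tbl, k, rule$direction_mode)
  for (i in seq_len(nrow(stats_tbl))) {
    v <- df[[stats_tbl$feature[i]]]
    ok <- is.finite(v) &
      if (stats_tbl$direction[i] == "less") v < thr[i] else v > thr[i]
    pass <- pass & ok
  }
  if (!drop_band) {
    f <- df$max_power_freq
    pass <- pass & is.finite(f) & f >= rule$band[1L] & f <= rule$band[2L]
  }
  pass
}

#' Filter candidate components per subject
#'
#' Applies all seven gates (band + six directional thresholds) to every
#' non-degenerate component. A subject with zero passing components has its
#' gates relaxed stepwise: `k_sd` is reduced in 0.25 steps to 0 and, if still
#' empty, the band gate is dropped last. Every relaxation is recorded in the
#' output.
#'
#' @param table cohort feature table.
#' @param thresholds output of [compute_thresholds()] (carries mean/sd).
#' @param rule a [classification_rule()].
#' @param relax apply the relaxation ladder (default). With `relax = FALSE`
#'   the gates are evaluated once at the rule's `k_sd` and a subject may
#'   end up with no candidates.
#' @return tibble of candidate rows: subject, component, k_used,
#'   band_dropped.
#' @export
filter_candidates <- function(table, thresholds, rule = classification_rule(),
                              relax = TRUE) {
  valid <- dplyr::filter(table, .data$candidate)
  ladder <- if (relax) unique(c(seq(rule$k_sd, 0, by = -0.25), 0))
            else rule$k_sd
  purrr::map_dfr(split(valid, valid$subject), function(df) {
    for (k in ladder) {
      pass <- passes_gates(df, thresholds, k, rule)
      if (any(pass))
        return(tibble::tibble(subject = df$subject[pass],
                              component = df$component[pass],
                              k_used = k, band_dropped = FALSE))
    }
    if (!relax)
      return(tibble::tibble(subject = character(0), component = integer(0),
                            k_used = numeric(0), band_dropped = logical(0)))
    pass <- passes_gates(df, thresholds, 0, rule, drop_band = TRUE)
    if (any(pass))
      return(tibble::tibble(subject = df$subject[pass],
                            component = df$component[pass],
                            k_used = 0, band_dropped = TRUE))
    tibble::tibble(subject = character(0), component = integer(0),
                   k_used = numeric(0), band_dropped = logical(0))
  })
}

#' Select the epileptic component per subject
#'
#' Among each subject's candidates, central energy and maximum
#' temporal-source kurtosis are prioritized: components are ranked on both
#' (descending) and the component minimizing the rank sum is selected; ties
#' go to the higher kurtosis, then the lower component index. With
#' `priority = "lexicographic"`, ordering is by central energy then
#' kurtosis. Subjects with no candidates are marked unlocalizable
#' (`component = NA`).
#'
#' @param candidates output of [filter_candidates()].
#' @param table cohort feature table.
#' @param rule a [classification_rule()].
#' @return tibble: subject, component, k_used, band_dropped, n_candidates.
#' @export
select_epileptic <- function(candidates, table, rule = classification_rule()) {
  subjects <- unique(table$subject)
  purrr::map_dfr(subjects, function(s) {
    cand <- dplyr::filter(candidates, .data$subject == s)
    if (!nrow(cand))
      return(tibble::tibble(subject = s, component = NA_integer_,
                            k_used = NA_real_, band_dropped = NA,
                            n_candidates = 0L))
    df <- dplyr::semi_join(
      dplyr::filter(table, .data$subject == s), cand,
      by = c("subject", "component"))
    if (rule$priority == "lexicographic") {
      ord <- order(-df$central_energy, -df$max_tic_kurtosis, df$component)
      pick <- df$component[ord[1L]]
    } else {
      rank_ce <- rank(-df$central_energy, ties.method = "min")
      rank_k <- rank(-df$max_tic_kurtosis, ties.method = "min")
      score <- rank_ce + rank_k
      ord <- order(score, -df$max_tic_kurtosis, df$component)
      pick <- df$component[ord[1L]]
    }
    tibble::tibble(subject = s, component = as.integer(pick),
                   k_used = cand$k_used[1L], band_dropped = cand$band_dropped[1L],
                   n_candidates = nrow(cand))
  })
}

#' Classify a cohort feature table
#'
#' Runs the full classification: cohort thresholds, per-subject candidate
#' filtering with the relaxation ladder, and epileptic-component selection.
#'
#' @param table cohort feature table (one row per subject x component).
#' @param rule a [classification_rule()].
#' @return an object of class `soz_classification` holding `table`, `rule`,
#'   `thresholds`, `candidates`, and `selection`.
#' @export
classify_components <- function(table, rule = classification_rule()) {
  thresholds <- compute_thresholds(table, rule)
  candidates <- filter_candidates(table, thresholds, rule)
  selection <- select_epileptic(candidates, table, rule)
  structure(list(table = table, rule = rule, thresholds = thresholds,
                 candidates = candidates, selection = selection),
            class = "soz_classification")
}

#' @export
print.soz_classification <- function(x, ...) {
  n <- nrow(x$selection)
  cat("<soz_classification> ", n, " subjects, ",
      sum(!is.na(x$selection$component)), " localized\n", sep = "")
  print(x$selection)
  invisible(x)
}

#' @rdname classify_components
#' @param x a `soz_classification`.
#' @param ... unused.
#' @export
tidy.soz_classification <- function(x, ...) x$selection

#' @rdname classify_components
#' @export
glance.soz_classification <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$selection),
    n_localized = sum(!is.na(x$selection$component)),
    n_relaxed = sum(x$selection$k_used < x$rule$k_sd, na.rm = TRUE),
    n_band_dropped = sum(x$selection$band_dropped, na.rm = TRUE),
    mean_candidates = mean(x$selection$n_candidates)
  )
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
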