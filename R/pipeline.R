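#' Pipeline configuration
#'
#' Registry of the analysis parameters. Defaults follow the method's stated
#' values: 30 components, significance threshold Z > 3.1 on clusters of more
#' than 10 contiguous voxels, a 2-voxel structuring element, a one-SD cohort
#' threshold offset, and the 0.01-0.1 Hz dominant-frequency band.
#'
#' @param n_components spatial components per subject.
#' @param z_thresh cluster Z threshold.
#' @param min_cluster minimum cluster size (strict >).
#' @param morph_radius structuring-element radius in voxels.
#' @param element `"ball"` or `"disk"` structuring element.
#' @param neighborhood central-average neighbourhood, `"cube3"` or `"ball3"`.
#' @param connectivity voxel connectivity, 26 or 6.
#' @param k_sd threshold SD multiplier.
#' @param direction_mode `"strict"` or `"lenient"` threshold offset.
#' @param priority `"rank_sum"` or `"lexicographic"` priority combination.
#' @param band dominant-frequency band (Hz, inclusive).
#' @param seed master seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_components = 30L, z_thresh = 3.1,
                            min_cluster = 10L, morph_radius = 2,
                            element = "ball",
                            neighborhood = c("cube3", "ball3"),
                            connectivity = 26L, k_sd = 1,
                            direction_mode = c("strict", "lenient"),
                            priority = c("rank_sum", "lexicographic"),
                            band = c(0.01, 0.1), seed = 1L) {
  neighborhood <- match.arg(neighborhood)
  direction_mode <- match.arg(direction_mode)
  priority <- match.arg(priority)
  structure(as.list(environment()), class = "pipeline_config")
}

rule_from_config <- function(config) {
  classification_rule(k_sd = config$k_sd, band = config$band,
                      direction_mode = config$direction_mode,
                      priority = config$priority)
}

#' Decompose one subject and extract all component features
#'
#' Runs spatial ICA, derives each component's clustering levels, and
#' extracts the nine features, returning the per-subject feature table and
#' the intermediate objects needed for SOZ extraction.
#'
#' @param bold a [bold_series()].
#' @param config a [pipeline_config()].
#' @param seed subject-level seed (defaults to `config$seed`).
#' @return list with `decomp`, `clusters` (per component), `features`
#'   (tibble with one row per component).
#' @export
analyze_subject <- function(bold, config = pipeline_config(),
                            seed = config$seed) {
  decomp <- spatial_ica(bold, config$n_components, seed)
  clusters <- vector("list", config$n_components)
  rows <- vector("list", config$n_components)
  for (i in seq_len(config$n_components)) {
    comp <- decomp$components[[i]]
    cl <- suppressWarnings(component_clusters(
      bold, comp, z_thresh = config$z_thresh, min_size = config$min_cluster,
      connectivity = config$connectivity, morph_radius = config$morph_radius,
      element = config$element, neighborhood = config$neighborhood))
    clusters[[i]] <- cl
    rows[[i]] <- suppressWarnings(
      extract_features(bold, comp, cl, seed = seed + 31L * i, config = config))
  }
  list(decomp = decomp, clusters = clusters,
       features = dplyr::bind_rows(rows))
}

#' Bind per-subject feature tables into a cohort table
#'
#' @param feature_list named list of per-subject feature tibbles (names are
#'   subject ids).
#' @return tibble with a leading `subject` column.
#' @export
cohort_features <- function(feature_list) {
  dplyr::bind_rows(feature_list, .id = "subject")
}

#' Run the full localization pipeline on a cohort
#'
#' Executes decomposition, geometry, feature extraction, cohort
#' classification, SOZ extraction, and (when resection masks are provided)
#' concordance assessment.
#'
#' @param subjects named list; each element is either a [bold_series()] or a
#'   list with elements `bold` and optionally `resection_mask`,
#'   `lobe_labels`.
#' @param config a [pipeline_config()].
#' @return an object of class `soz_cohort`: `features` (cohort table),
#'   `classification` (a `soz_classification`), `soz` (named list of
#'   `soz_result`), `summary` (tibble), `config`.
#' @export
run_cohort_pipeline <- function(subjects, config = pipeline_config()) {
  if (is.null(names(subjects)))
    names(subjects) <- sprintf("sub%02d", seq_along(subjects))
  analyses <- vector("list", length(subjects))
  names(analyses) <- names(subjects)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    bold <- if (inherits(s, "bold_series")) s else s$bold
    analyses[[i]] <- analyze_subject(bold, config,
                                     seed = config$seed + 101L * i)
  }
  table <- cohort_features(lapply(analyses, `[[`, "features"))
  classification <- classify_components(table, rule_from_config(config))

  soz <- list()
  for (i in seq_along(subjects)) {
    id <- names(subjects)[i]
    sel <- classification$selection
    comp_idx <- sel$component[sel$subject == id]
    if (!length(comp_idx) || is.na(comp_idx)) next
    res <- suppressWarnings(extract_soz(
      analyses[[i]]$decomp$components[[comp_idx]],
      analyses[[i]]$clusters[[comp_idx]], config$connectivity))
    s <- subjects[[i]]
    if (!inherits(s, "bold_series") && !is.null(s$resection_mask))
      res <- assess_concordance(res, s$resection_mask, s$lobe_labels)
    res$subject <- id
    soz[[id]] <- res
  }

  soz_tbl <- tibble::tibble(subject = character(0), soz_voxels = integer(0),
                            concordance = character(0),
                            overlap_voxels = integer(0), dice = numeric(0))
  if (length(soz))
    soz_tbl <- purrr::map_dfr(soz, function(r) tibble::tibble(
      subject = r$subject, soz_voxels = sum(r$soz_mask),
      concordance = r$concordance, overlap_voxels = r$overlap_voxels,
      dice = r$dice))
  summary <- dplyr::left_join(classification$selection, soz_tbl,
                              by = "subject")

  structure(list(features = table, classification = classification, soz = soz,
                 summary = summary, analyses = analyses, config = config),
            class = "soz_cohort")
}

#' @export
print.soz_cohort <- function(x, ...) {
  cat("<soz_cohort> ", length(x$analyses), " subjects, ",
      x$config$n_components, " components each\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @rdname run_cohort_pipeline
#' @param x a `soz_cohort`.
#' @param ... unused.
#' @export
tidy.soz_cohort <- function(x, ...) x$summary

#' @rdname run_cohort_pipeline
#' @export
glance.soz_cohort <- function(x, ...) glance(x$classification)

# index of the decomposition component best matching a planted loading map
match_component <- function(decomp, map) {
  v <- as.numeric(map)
  cors <- vapply(decomp$components, function(c_)
    abs(stats::cor(as.numeric(c_$zmap), v)), numeric(1))
  list(index = which.max(cors), cor = max(cors))
}

#' Planted-component recovery study
#'
#' Generates seeded synthetic cohorts, runs the full pipeline on each, and
#' measures whether the classifier selects the planted epileptic component
#' (identified as the decomposition component whose Z-map best correlates
#' with the planted loading map) and how well the extracted SOZ overlaps the
#' planted focus (Dice).
#'
#' @param n_cohorts number of cohorts.
#' @param spec a [synthetic_spec()] (its seed is overridden per cohort).
#' @param n_components components per subject for this study.
#' @param seed master seed.
#' @return tibble: cohort, subject, selected, planted, match_cor, recovered,
#'   dice.
#' @export
planted_recovery_study <- function(n_cohorts = 20L, spec = synthetic_spec(),
                                   n_components = 20L, seed = 1L) {
  config <- pipeline_config(n_components = n_components, seed = seed)
  purrr::map_dfr(seq_len(n_cohorts), function(cc) {
    sp <- spec
    sp$seed <- seed + 20183L * cc
    subjects <- generate_cohort(sp)
    config$seed <- sp$seed
    fit <- run_cohort_pipeline(lapply(subjects, `[[`, "bold"), config)
    purrr::map_dfr(seq_along(subjects), function(i) {
      id <- sprintf("sub%02d", i)
      truth <- subjects[[i]]$truth
      epi_map <- truth$maps[[which(truth$classes == "epileptic")]]
      m <- match_component(fit$analyses[[i]]$decomp, epi_map)
      sel <- fit$classification$selection
      selected <- sel$component[sel$subject == id]
      recovered <- length(selected) == 1L && !is.na(selected) &&
        selected == m$index
      dice <- if (!is.null(fit$soz[[id]]))
        dice_coefficient(fit$soz[[id]]$soz_mask, truth$epi_mask)
      else NA_real_
      tibble::tibble(cohort = cc, subject = id,
                     selected = if (length(selected)) selected else NA_integer_,
                     planted = m$index, match_cor = m$cor,
                     recovered = recovered, dice = dice)
    })
  })
}

#' Gate-behaviour study on noiseless cohorts
#'
#' Generates noiseless cohorts (so ICA recovery is exact), matches each
#' planted artifact and drift source to its decomposition component, and
#' checks which classifier gates exclude it: the frequency-band gate and,
#' for artifacts, the outside-to-inside ratio gate.
#'
#' @param n_cohorts number of cohorts.
#' @param spec a [synthetic_spec()]; the white and physiological noise are
#'   forced to 0 and `n_components` to the planted source count.
#' @param seed master seed.
#' @return tibble: cohort, subject, class, band_excluded, roi_excluded.
#' @export
gate_exclusion_study <- function(n_cohorts = 3L, spec = synthetic_spec(),
                                 seed = 1L) {
  spec$noise_sd <- 0
  spec$physio_sd <- 0
  spec$jitter_range <- c(0, 0)
  n_src <- spec$n_sym + spec$n_art + as.integer(isTRUE(spec$drift)) + 1L
  config <- pipeline_config(n_components = n_src, seed = seed)
  purrr::map_dfr(seq_len(n_cohorts), function(cc) {
    sp <- spec
    sp$seed <- seed + 4409L * cc
    subjects <- generate_cohort(sp)
    config$seed <- sp$seed
    fit <- run_cohort_pipeline(lapply(subjects, `[[`, "bold"), config)
    thr <- fit$classification$thresholds
    roi_thr <- thr$threshold[thr$feature == "r_oi"]
    band <- config$band
    purrr::map_dfr(seq_along(subjects), function(i) {
      id <- sprintf("sub%02d", i)
      truth <- subjects[[i]]$truth
      check <- which(truth$classes %in% c("artifact", "drift"))
      purrr::map_dfr(check, function(k) {
        m <- match_component(fit$analyses[[i]]$decomp, truth$maps[[k]])
        row <- dplyr::filter(fit$features, .data$subject == id,
                             .data$component == m$index)
        tibble::tibble(
          cohort = cc, subject = id, class = truth$classes[k],
          band_excluded = !(row$max_power_freq >= band[1L] &
                              row$max_power_freq <= band[2L]),
          roi_excluded = !is.finite(row$r_oi) | row$r_oi >= roi_thr)
      })
    })
  })
}
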