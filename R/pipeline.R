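# End-to-end orchestration: synth -> segment -> morph -> derive ->
# remodel -> stats. Image-facing stages (segmentation, morphometry) never
# see group labels; clinical labels are joined only when derived metrics
# and statistics are computed, emulating blinded measurement.

#' Pipeline run configuration
#'
#' Either a [cohort_spec()] (fully synthetic run: images are generated per
#' subject) or a path to a subject CSV (tabular-only run: derived metrics
#' and statistics on supplied measurements). Validation is fail-fast:
#' missing inputs error before any computation.
#'
#' @param cohort a [cohort_spec()], or NULL when `subjects_csv` is given.
#' @param subjects_csv path to a subject table CSV (see
#'   [generate_cohort()] for the column contract).
#' @param nomogram a [nomogram_model()].
#' @param n_fields synthetic fields per stain per subject (the reference
#'   protocol uses 9: 3 inner / 3 mid / 3 outer media; the default 3 is a
#'   budget-scaled version).
#' @param field_size field edge length, px.
#' @param field_pixel_size µm per px for synthetic fields.
#' @param exclusion_radius branch-exclusion radius for lamellar
#'   measurements, µm (0 disables skeletonization; fields are synthetic
#'   and branch-free by construction).
#' @param seed global seed; per-stage seeds are derived as
#'   `derive_seed(seed, stage_index)`.
#' @param out_dir optional directory for report CSVs.
#' @return a validated `run_config`.
#' @export
run_config <- function(cohort = NULL, subjects_csv = NULL,
                       nomogram = nomogram_model(), n_fields = 3L,
                       field_size = 128L, field_pixel_size = 1,
                       exclusion_radius = 0, seed = 1L, out_dir = NULL) {
  if (is.null(cohort) && is.null(subjects_csv))
    stopf("run_config: provide a cohort spec or a subjects_csv path")
  if (!is.null(cohort) && !inherits(cohort, "cohort_spec"))
    stopf("'cohort' must be a cohort_spec")
  if (!is.null(subjects_csv) && !file.exists(subjects_csv))
    stopf("subjects_csv '%s' does not exist", subjects_csv)
  stopifnot(inherits(nomogram, "nomogram_model"))
  check_number(n_fields, "n_fields", 1)
  check_number(field_size, "field_size", 32)
  structure(list(cohort = cohort, subjects_csv = subjects_csv,
                 nomogram = nomogram, n_fields = as.integer(n_fields),
                 field_size = as.integer(field_size),
                 field_pixel_size = field_pixel_size,
                 exclusion_radius = exclusion_radius,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(config[setdiff(names(config), "out_dir")]), tf)
  unname(tools::md5sum(tf))
}

# per-subject synthetic field spec derived from the subject's true medial
# composition: spacing follows the true lamellar metrics; elastin target
# above the lamellar band supply is delivered as intralamellar texture
subject_field_spec <- function(tr, stain_kind, config, seed) {
  tf <- c(elastin = tr$elastin_fraction, cytoplasm = tr$cytoplasm_fraction,
          collagen = tr$collagen_fraction, gag = tr$gag_fraction)
  tf <- pmin(pmax(tf, 0), 1)
  if (sum(tf) > 1) tf <- tf / sum(tf)
  ps <- config$field_pixel_size
  H <- config$field_size
  n_fit <- max(1L, floor(H * ps /
                           (tr$lamella_thickness + tr$interlamellar_distance)))
  n_lam <- min(round(tr$n_lamellae), n_fit)
  field_spec(stain_kind = stain_kind,
             image_size = c(H, H), pixel_size = ps,
             n_lamellae = n_lam,
             lamella_thickness = tr$lamella_thickness,
             interlamellar_distance = tr$interlamellar_distance,
             target_fractions = tf,
             nuclei_density = tr$smc_density,
             color_jitter_sd = 4,
             seed = seed)
}

#' Run the full pipeline
#'
#' @param config a [run_config()].
#' @return a `study_report`: list with `subjects`, `morphometry` (blinded
#'   per-subject image measurements, synthetic runs only), `derived`
#'   (per-subject derived metrics), `group_comparison`,
#'   `score_comparisons` (Kruskal-Wallis/Dunn of metrics across medial
#'   degeneration scores), `correlations`, `interrater`, `remodeling`
#'   (pre-aneurysmal predictions for the aneurysm group) and `provenance`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  # stage 1: subjects (synthetic or file)
  synth <- !is.null(config$cohort)
  cohort <- stage("cohort", {
    if (synth) {
      cs <- config$cohort
      cs$seed <- derive_seed(config$seed, 1L)
      generate_cohort(cs)
    } else {
      list(subjects = utils::read.csv(config$subjects_csv), truth = NULL)
    }
  })
  subjects <- cohort$subjects

  # stages 2-3: blinded image synthesis + measurement (synthetic runs)
  morph <- NULL
  if (synth) {
    morph <- stage("morphometry", {
      rows <- lapply(seq_len(nrow(subjects)), function(i) {
        tr <- cohort$truth[i, ]
        fseed <- derive_seed(config$seed, 100L + i)
        frs <- lapply(seq_len(config$n_fields), function(f) {
          fs <- subject_field_spec(tr, "movat", config,
                                   derive_seed(fseed, f))
          fld <- generate_stain_field(fs)
          mask <- classify_pixels(fld$image, default_palette("movat"))
          el <- matrix(as.vector(mask) ==
                         match("elastin",
                               attr(mask, "palette")$classes$role),
                       nrow(mask), ncol(mask))
          lam <- measure_lamellae(el, transect_spec(3L),
                                  pixel_size = fld$image$pixel_size,
                                  exclusion_radius = config$exclusion_radius)
          list(fr = medial_fractions(mask), lam = lam)
        })
        nres <- lapply(seq_len(config$n_fields), function(f) {
          hs <- subject_field_spec(tr, "he", config,
                                   derive_seed(fseed, 50L + f))
          fld <- generate_stain_field(hs)
          count_nuclei(fld$image)
        })
        fr <- aggregate_fields(lapply(frs, `[[`, "fr"))
        data.frame(
          id = subjects$id[i],
          elastin_fraction = fr$fractions[["elastin"]],
          cytoplasm_fraction = fr$fractions[["cytoplasm"]],
          collagen_fraction = fr$fractions[["collagen"]],
          gag_fraction = fr$fractions[["gag"]],
          unclassified_fraction = fr$unclassified_fraction,
          n_lamellae = mean(vapply(frs, function(r) r$lam$n_lamellae, 0)),
          lamella_thickness = mean(vapply(frs, function(r)
            r$lam$lamella_thickness, 0)),
          interlamellar_distance = mean(vapply(frs, function(r)
            r$lam$interlamellar_distance, 0), na.rm = TRUE),
          n_excluded = sum(vapply(frs, function(r) r$lam$n_excluded, 0L)),
          smc_density = mean(vapply(nres, function(r) r$density, 0)),
          n_fields = config$n_fields)
      })
      do.call(rbind, rows)
    })
  }

  # stage 4: derived metrics (labels joined here, after measurement)
  derived <- stage("derived", {
    d <- subjects[, c("id", "group", "age", "sex", "bsa",
                      "observed_diameter")]
    meas <- if (synth) morph else subjects
    for (col in c("elastin_fraction", "cytoplasm_fraction",
                  "collagen_fraction", "gag_fraction", "smc_density"))
      d[[col]] <- meas[[col]][match(d$id, meas$id)]
    for (col in c("intima_thickness", "media_thickness",
                  "adventitia_thickness", "lamella_thickness",
                  "interlamellar_distance"))
      d[[col]] <- subjects[[col]]
    d$expected_diameter <- expected_diameter(d, config$nomogram)
    zc <- z_score_and_class(d$observed_diameter, d$expected_diameter,
                            config$nomogram)
    d$z <- zc$z
    d$size_class <- zc$class
    d$fold_dilatation <- fold_dilatation(d$observed_diameter,
                                         d$expected_diameter)
    geom <- lapply(seq_len(nrow(d)), function(i)
      wall_geometry(d$observed_diameter[i], d$intima_thickness[i],
                    d$media_thickness[i], d$adventitia_thickness[i]))
    d$media_xsec_area <- vapply(geom, media_xsec_area, 0)
    d$smc_per_xsec <- d$smc_density * d$media_xsec_area
    for (comp in c("elastin", "cytoplasm", "collagen", "gag"))
      d[[paste0(comp, "_xsec")]] <- d[[paste0(comp, "_fraction")]] *
        d$media_xsec_area
    d
  })

  # stage 5: reverse remodeling for the aneurysm group
  remodeling <- stage("remodeling", {
    an <- derived[derived$group == "aneurysm", ]
    if (!nrow(an)) NULL else {
      rows <- lapply(seq_len(nrow(an)), function(i) {
        g <- wall_geometry(an$observed_diameter[i], an$intima_thickness[i],
                           an$media_thickness[i],
                           an$adventitia_thickness[i])
        pred <- predict_preaneurysmal(
          g, list(lamella_thickness = an$lamella_thickness[i],
                  interlamellar_distance = an$interlamellar_distance[i]),
          an$expected_diameter[i])
        data.frame(id = an$id[i],
                   observed_media = an$media_thickness[i],
                   predicted_media = pred$predicted_media_thickness,
                   predicted_lamella_thickness =
                     pred$predicted_lamella_thickness,
                   predicted_interlamellar_distance =
                     pred$predicted_interlamellar_distance,
                   scaling_factor = pred$scaling_factor,
                   area_residual = pred$area_residual)
      })
      do.call(rbind, rows)
    }
  })

  # stage 6: statistics
  stats_out <- stage("statistics", {
    num_metrics <- intersect(
      c("age", "bsa", "observed_diameter", "z", "elastin_fraction",
        "cytoplasm_fraction", "collagen_fraction", "gag_fraction",
        "smc_density", "media_thickness", "media_xsec_area",
        "smc_per_xsec", "elastin_xsec", "cytoplasm_xsec", "collagen_xsec",
        "gag_xsec"), names(derived))
    grp <- split(derived, derived$group)
    cmp <- do.call(rbind, lapply(num_metrics, function(m) {
      res <- mann_whitney(grp$nondilated[[m]], grp$aneurysm[[m]])
      data.frame(variable = m,
                 nondilated_mean = mean(grp$nondilated[[m]]),
                 aneurysm_mean = mean(grp$aneurysm[[m]]),
                 U = res$statistic, p_value = res$p_value,
                 p_label = format_p(res$p_value),
                 method = res$method)
    }))
    if ("valve" %in% names(subjects)) {
      tb <- table(subjects$valve, subjects$group)
      if (all(dim(tb) >= 2)) {
        res <- fisher_exact_rxc(contingency_table(unclass(tb)))
        cmp <- rbind(cmp, data.frame(
          variable = "bicuspid_valve", nondilated_mean = NA,
          aneurysm_mean = NA, U = NA, p_value = res$p_value,
          p_label = format_p(res$p_value), method = res$method))
      }
    }
    corr <- correlation_matrix(derived[, num_metrics])
    score_cols <- grep("^score_rater", names(subjects), value = TRUE)
    irr <- if (length(score_cols) >= 2)
      interrater_agreement(subjects[, score_cols]) else NULL
    score_cmp <- NULL
    if (length(score_cols)) {
      consensus <- round(rowMeans(subjects[, score_cols, drop = FALSE]))
      score_cmp <- lapply(
        intersect(c("media_thickness", "elastin_fraction", "smc_per_xsec"),
                  names(derived)),
        function(m) kruskal_wallis_dunn(split(derived[[m]],
                                              consensus)))
      names(score_cmp) <- intersect(
        c("media_thickness", "elastin_fraction", "smc_per_xsec"),
        names(derived))
    }
    list(group_comparison = cmp, correlations = corr, interrater = irr,
         score_comparisons = score_cmp)
  })

  report <- structure(list(
    subjects = subjects, morphometry = morph, derived = derived,
    remodeling = remodeling,
    group_comparison = stats_out$group_comparison,
    correlations = stats_out$correlations,
    interrater = stats_out$interrater,
    score_comparisons = stats_out$score_comparisons,
    provenance = list(package = "aortomorph",
                      version = as.character(utils::packageVersion("aortomorph")),
                      seed = config$seed,
                      config_hash = config_hash(config))),
    class = "study_report")
  if (!is.null(config$out_dir)) write_study_report(report, config$out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d subjects (seed %d, config %s)\n",
              nrow(x$subjects), x$provenance$seed,
              substr(x$provenance$config_hash, 1, 8)))
  cat("group comparison (head):\n")
  print(utils::head(x$group_comparison[, c("variable", "nondilated_mean",
                                           "aneurysm_mean", "p_label")], 8),
        row.names = FALSE)
  invisible(x)
}

#' Write a study report to CSV files
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df))
      utils::write.csv(df, file.path(dir, paste0(name, ".csv")),
                       row.names = FALSE)
  }
  wt(report$subjects, "subjects")
  wt(report$morphometry, "morphometry")
  wt(report$derived, "derived_metrics")
  wt(report$remodeling, "remodeling_predictions")
  wt(report$group_comparison, "group_comparison")
  if (!is.null(report$correlations))
    utils::write.csv(report$correlations$rho,
                     file.path(dir, "correlation_rho.csv"))
  wt(report$interrater, "interrater")
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
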