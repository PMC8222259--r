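# Synthetic two-group subject cohort (nondilated vs aneurysm) with known
# per-subject truth. Group effects are additive deltas on the medial
# metrics plus a multiplicative fold on aortic diameter; observed values
# add configured Gaussian noise onto the truth.

COHORT_METRICS <- c("elastin_fraction", "cytoplasm_fraction",
                    "collagen_fraction", "gag_fraction", "smc_density",
                    "media_thickness", "intima_thickness",
                    "adventitia_thickness", "lamella_thickness",
                    "interlamellar_distance", "n_lamellae")

#' Specify a synthetic subject cohort
#'
#' Defaults emulate a cohort of 17 nondilated and 18 aneurysmal ascending
#' aortas: aneurysms carry a reduced medial elastin fraction (the dilution
#' signature), unchanged SMC density, a thinner media and a 1.6-fold
#' dilated diameter relative to the nomogram expectation (safely above the
#' 1.5-fold aneurysm threshold once multiplicative noise, clipped at 2 SD,
#' is applied).
#'
#' @param n_per_group named integer counts, e.g.
#'   `c(nondilated = 17, aneurysm = 18)`.
#' @param group_effects named additive deltas applied to the aneurysm
#'   group's metric means (names among `r toString(COHORT_METRICS)`).
#' @param diameter_fold multiplicative effect on the aneurysm group's
#'   diameter relative to its nomogram expectation.
#' @param baseline named baseline (nondilated) metric means.
#' @param metric_noise_sd named observation-noise SDs per metric.
#' @param diameter_noise_sd SD of the log-scale multiplicative diameter
#'   noise (clipped at ±2 SD).
#' @param nomogram a [nomogram_model()].
#' @param age_range,bsa_range sampling ranges.
#' @param sex_male_p probability of male sex.
#' @param race_probs named sampling probabilities for race.
#' @param valve_bicuspid_p named per-group probability of bicuspid valve.
#' @param comorbidity_p named list: per-comorbidity, per-group probability.
#' @param n_raters raters scoring medial degeneration (ordinal 1-3).
#' @param rater_sd SD of rater jitter around the latent score (smaller =
#'   higher inter-rater concordance).
#' @param seed integer RNG seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_per_group = c(nondilated = 17L, aneurysm = 18L),
                        group_effects = c(elastin_fraction = -0.07,
                                          cytoplasm_fraction = 0.04,
                                          collagen_fraction = 0.02,
                                          gag_fraction = 0.01,
                                          smc_density = 0,
                                          media_thickness = -250),
                        diameter_fold = 1.6,
                        baseline = c(elastin_fraction = 0.32,
                                     cytoplasm_fraction = 0.34,
                                     collagen_fraction = 0.24,
                                     gag_fraction = 0.10,
                                     smc_density = 1500,
                                     media_thickness = 1200,
                                     intima_thickness = 100,
                                     adventitia_thickness = 500,
                                     lamella_thickness = 4,
                                     interlamellar_distance = 12,
                                     n_lamellae = 8),
                        metric_noise_sd = c(elastin_fraction = 0.04,
                                            cytoplasm_fraction = 0.04,
                                            collagen_fraction = 0.03,
                                            gag_fraction = 0.02,
                                            smc_density = 150,
                                            media_thickness = 100,
                                            intima_thickness = 20,
                                            adventitia_thickness = 80,
                                            lamella_thickness = 0.4,
                                            interlamellar_distance = 1.2,
                                            n_lamellae = 0),
                        diameter_noise_sd = 0.03,
                        nomogram = nomogram_model(),
                        age_range = c(30, 75),
                        bsa_range = c(1.6, 2.4),
                        sex_male_p = 0.7,
                        race_probs = c(caucasian = 0.6,
                                       african_american = 0.2,
                                       hispanic = 0.2),
                        valve_bicuspid_p = c(nondilated = 0.06,
                                             aneurysm = 0.5),
                        comorbidity_p = list(
                          hypertension = c(nondilated = 0.35, aneurysm = 0.67),
                          hyperlipidemia = c(nondilated = 0.12, aneurysm = 0.67),
                          diabetes = c(nondilated = 0.12, aneurysm = 0.17),
                          smoking = c(nondilated = 0.71, aneurysm = 0.39),
                          lipid_lowering = c(nondilated = 0.18, aneurysm = 0.78)),
                        n_raters = 3L,
                        rater_sd = 0.35,
                        seed = 1L) {
  stopifnot(all(c("nondilated", "aneurysm") %in% names(n_per_group)))
  n_per_group <- as.integer(n_per_group)
  names(n_per_group) <- c("nondilated", "aneurysm")
  if (any(n_per_group < 1L)) stopf("n_per_group must be >= 1")
  bad <- setdiff(names(group_effects), COHORT_METRICS)
  if (length(bad))
    stopf("unknown group_effects metric(s): %s", paste(bad, collapse = ", "))
  if (any(metric_noise_sd < 0)) stopf("metric noise SDs must be >= 0")
  check_number(diameter_fold, "diameter_fold", 0, strict_lower = TRUE)
  check_number(diameter_noise_sd, "diameter_noise_sd", 0)
  stopifnot(inherits(nomogram, "nomogram_model"))
  structure(list(n_per_group = n_per_group, group_effects = group_effects,
                 diameter_fold = diameter_fold, baseline = baseline,
                 metric_noise_sd = metric_noise_sd,
                 diameter_noise_sd = diameter_noise_sd, nomogram = nomogram,
                 age_range = age_range, bsa_range = bsa_range,
                 sex_male_p = sex_male_p, race_probs = race_probs,
                 valve_bicuspid_p = valve_bicuspid_p,
                 comorbidity_p = comorbidity_p,
                 n_raters = as.integer(n_raters), rater_sd = rater_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic subject cohort with ground truth
#'
#' @param spec a [cohort_spec()].
#' @return list with `subjects` (one row per subject: demographics,
#'   observed diameter, valve, comorbidity flags, per-rater medial
#'   degeneration scores, and noisy observed metrics) and `truth` (the true
#'   per-metric values before observation noise, plus expected diameter and
#'   the applied diameter fold).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    groups <- rep(c("nondilated", "aneurysm"), spec$n_per_group)
    n <- length(groups)
    id <- sprintf("S%03d", seq_len(n))
    age <- round(stats::runif(n, spec$age_range[1], spec$age_range[2]), 1)
    sex <- ifelse(stats::runif(n) < spec$sex_male_p, "male", "female")
    race <- names(spec$race_probs)[
      apply(stats::rmultinom(n, 1, spec$race_probs) == 1L, 2, which)]
    bsa <- round(stats::runif(n, spec$bsa_range[1], spec$bsa_range[2]), 2)

    exp_d <- expected_diameter(data.frame(age = age, sex = sex, bsa = bsa),
                               spec$nomogram)
    fold <- ifelse(groups == "aneurysm", spec$diameter_fold, 1)
    zlog <- pmin(pmax(stats::rnorm(n), -2), 2) * spec$diameter_noise_sd
    obs_d <- exp_d * fold * exp(zlog)

    truth <- data.frame(id = id, group = groups,
                        expected_diameter = exp_d,
                        diameter_fold = fold,
                        true_diameter = obs_d)
    for (m in COHORT_METRICS) {
      delta <- spec$group_effects[m]
      delta <- if (is.na(delta)) 0 else delta
      truth[[m]] <- spec$baseline[[m]] + ifelse(groups == "aneurysm",
                                                delta, 0)
    }

    subjects <- data.frame(id = id, group = groups, age = age, sex = sex,
                           race = race, bsa = bsa,
                           observed_diameter = obs_d)
    subjects$valve <- ifelse(
      stats::runif(n) < spec$valve_bicuspid_p[groups], "bicuspid",
      "tricuspid")
    for (cm in names(spec$comorbidity_p))
      subjects[[cm]] <- stats::runif(n) < spec$comorbidity_p[[cm]][groups]
    for (m in COHORT_METRICS) {
      sd_m <- spec$metric_noise_sd[m]
      sd_m <- if (is.na(sd_m)) 0 else sd_m
      v <- truth[[m]] + stats::rnorm(n, 0, sd_m)
      if (grepl("fraction", m)) v <- pmin(pmax(v, 0), 1)
      if (m %in% c("smc_density", "media_thickness", "intima_thickness",
                   "adventitia_thickness", "lamella_thickness",
                   "interlamellar_distance", "n_lamellae"))
        v <- pmax(v, 0)
      subjects[[m]] <- v
    }

    # ordinal medial degeneration scores: latent severity unrelated to
    # group (the qualitative grading does not separate the groups)
    latent <- sample.int(3L, n, replace = TRUE, prob = c(0.25, 0.35, 0.40))
    for (r in seq_len(spec$n_raters)) {
      s <- round(latent + stats::rnorm(n, 0, spec$rater_sd))
      subjects[[sprintf("score_rater%d", r)]] <- pmin(pmax(s, 1L), 3L)
    }
    list(subjects = subjects, truth = truth)
  })
}
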