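# Published contingency tables of the motivating cohort (17 nondilated vs
# 18 aneurysmal ascending aortas): categorical subject characteristics and
# the qualitative medial-degeneration scoring. Stored as counts only; the
# corresponding exact-test p-values are recomputed, never stored.

#' Printed contingency tables of the reference cohort
#'
#' Counts are (rows = categories, columns = nondilated / aneurysm). These
#' feed [fisher_exact_rxc()] as a worked-example surface: the recomputed
#' two-sided exact p-values match the published ones to 4 decimal places.
#'
#' @return named list of [contingency_table()]s.
#' @export
reference_tables <- function() {
  g <- c("nondilated", "aneurysm")
  ct <- function(counts, rows) {
    contingency_table(matrix(counts, ncol = 2, byrow = TRUE,
                             dimnames = list(rows, g)))
  }
  list(
    sex_male = ct(c(11, 16, 6, 2), c("male", "female")),
    race = ct(c(4, 0, 9, 16, 4, 2),
              c("african_american", "caucasian", "hispanic")),
    bicuspid_valve = ct(c(1, 9, 16, 9), c("bicuspid", "tricuspid")),
    valve_insufficiency = ct(c(0, 11, 17, 7), c("present", "absent")),
    valve_stenosis = ct(c(1, 4, 16, 14), c("present", "absent")),
    atherosclerosis = ct(c(5, 1, 12, 17), c("present", "absent")),
    hypertension = ct(c(6, 12, 11, 6), c("present", "absent")),
    hyperlipidemia = ct(c(2, 12, 15, 6), c("present", "absent")),
    diabetes = ct(c(2, 3, 15, 15), c("present", "absent")),
    smoking = ct(c(12, 7, 5, 11), c("present", "absent")),
    lipid_lowering = ct(c(3, 14, 14, 4), c("present", "absent")),
    beta_blockers = ct(c(5, 9, 12, 9), c("present", "absent")),
    calcium_channel_blockers = ct(c(1, 3, 16, 15), c("present", "absent")),
    acei_arb = ct(c(3, 7, 14, 11), c("present", "absent")),
    medial_degeneration = ct(c(6, 2, 4, 8, 7, 8),
                             c("mild", "moderate", "severe")),
    mucoid_intralamellar_grade = ct(c(1, 0, 9, 10, 4, 5, 3, 3),
                                    c("none", "mild", "moderate", "severe")),
    mucoid_intralamellar_distribution = ct(
      c(1, 0, 5, 2, 5, 5, 6, 11),
      c("absent", "focal", "multifocal", "extensive")),
    mucoid_translamellar_grade = ct(c(14, 9, 1, 4, 1, 4, 1, 1),
                                    c("none", "mild", "moderate", "severe")),
    mucoid_translamellar_distribution = ct(
      c(14, 9, 0, 3, 3, 6), c("absent", "focal", "multifocal")),
    elastic_thinning_grade = ct(c(0, 2, 17, 16), c("none", "mild")),
    elastic_disorganization = ct(c(11, 10, 6, 8),
                                 c("focal", "multifocal")),
    laminar_collapse_appearance = ct(c(3, 7, 14, 11), c("none", "thin")),
    laminar_collapse_distribution = ct(c(3, 7, 11, 8, 3, 3),
                                       c("absent", "focal", "multifocal")),
    medial_fibrosis_grade = ct(c(8, 9, 9, 9), c("none", "mild")))
}

#' Published group summary diameters of the reference cohort
#'
#' Mean (SD) observed and nomogram-expected external aortic diameters of
#' the aneurysm group, in cm: expected 3.5 (0.2), observed 5.2 (0.5). Used
#' in the fold-dilatation worked example (observed / expected = 1.5-fold
#' to one decimal place).
#'
#' @return named list with `expected_mean`, `expected_sd`, `observed_mean`,
#'   `observed_sd` (cm).
#' @export
reference_diameters <- function() {
  list(expected_mean = 3.5, expected_sd = 0.2,
       observed_mean = 5.2, observed_sd = 0.5)
}
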