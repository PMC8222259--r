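# Area-conservation model of medial thinning under lumen dilatation.
#
# Treat the media as an annulus of lumen radius a and thickness b. If the
# medial cross-sectional area pi*((a+b)^2 - a^2) = pi*(2ab + b^2) is
# conserved while the lumen dilates to a', the new thickness is the unique
# positive root of 2 a' b' + b'^2 = 2 a b + b^2:
#     b' = sqrt(a'^2 + 2ab + b^2) - a'.
# Inverting the map predicts the pre-aneurysmal geometry of an observed
# aneurysm had its wall components remained inert; lamellar metrics are
# scaled by the same factor as the media.

#' Annulus state of the media
#'
#' @param a lumen radius (any length unit, > 0).
#' @param b media thickness (same unit, > 0).
#' @return an `annulus_state` with the conserved quantity
#'   `Q = 2ab + b^2` (area / pi) and the thinness index `a/b`.
#' @export
annulus_state <- function(a, b) {
  check_number(a, "a", 0, strict_lower = TRUE)
  check_number(b, "b", 0, strict_lower = TRUE)
  structure(list(a = a, b = b, Q = 2 * a * b + b^2, index = a / b),
            class = "annulus_state")
}

#' Media thickness after lumen dilatation at conserved area
#'
#' @param state an [annulus_state()] (or list with `a`, `b`).
#' @param a_new new lumen radius (same unit), vectorised.
#' @return new media thickness `b_new` with the medial annulus area
#'   preserved exactly.
#' @export
thinned_thickness <- function(state, a_new) {
  if (!inherits(state, "annulus_state")) state <- annulus_state(state$a,
                                                                state$b)
  if (any(a_new <= 0)) stopf("a_new must be > 0")
  sqrt(a_new^2 + state$Q) - a_new
}

#' Thinning curves for given radius-to-thickness indices
#'
#' Tabulates b_new / b against the dilatation ratio a_new / a for media of
#' given thinness indices (a/b around 10 is typical of nondilated aortas,
#' around 20 of aneurysms).
#'
#' @param indices numeric a/b indices.
#' @param dilatation ratios a_new / a to tabulate.
#' @return data.frame with `index`, `dilatation`, `thinning`
#'   (= b_new / b).
#' @export
thinning_curve <- function(indices = c(10, 20),
                           dilatation = seq(1, 2, by = 0.05)) {
  out <- do.call(rbind, lapply(indices, function(idx) {
    st <- annulus_state(a = idx, b = 1)
    data.frame(index = idx, dilatation = dilatation,
               thinning = thinned_thickness(st, idx * dilatation))
  }))
  rownames(out) <- NULL
  out
}

#' Fold dilatation
#'
#' @param observed_diameter,expected_diameter same units; expected > 0.
#' @return observed / expected ratio.
#' @export
fold_dilatation <- function(observed_diameter, expected_diameter) {
  if (any(expected_diameter <= 0)) stopf("expected diameter must be > 0")
  observed_diameter / expected_diameter
}

#' Predict pre-aneurysmal wall geometry by reverse remodeling
#'
#' Maps an observed (aneurysmal) wall back to the geometry it would have
#' had at the nomogram-expected diameter if its components had remained
#' inert (medial area conserved). The expected lumen radius is obtained
#' self-consistently with the predicted media: with
#' `c = R_expected - intima - adventitia` and conserved `Q`, the predicted
#' thickness is `b_pred = c - sqrt(c^2 - Q)` (so that
#' `a_expected = c - b_pred` and `2 a_expected b_pred + b_pred^2 = Q`
#' exactly). Lamella thickness and interlamellar distance scale by the
#' same factor `b_pred / b_obs` as the media.
#'
#' @param geom observed [wall_geometry()].
#' @param lamellar observed [measure_lamellae()] metrics (or a list with
#'   `lamella_thickness`, `interlamellar_distance` in µm); optional.
#' @param expected_diameter_cm nomogram-expected external diameter, cm.
#' @return a `remodeling_prediction`: `predicted_media_thickness`,
#'   `predicted_lamella_thickness`, `predicted_interlamellar_distance`
#'   (µm), `predicted_lumen_radius` (µm), `scaling_factor`,
#'   `area_residual`.
#' @export
predict_preaneurysmal <- function(geom, lamellar = NULL,
                                  expected_diameter_cm) {
  stopifnot(inherits(geom, "wall_geometry"))
  check_number(expected_diameter_cm, "expected_diameter_cm", 0,
               strict_lower = TRUE)
  st <- annulus_state(geom$a, geom$media_thickness)
  cc <- expected_diameter_cm * 1e4 / 2 - geom$intima_thickness -
    geom$adventitia_thickness
  if (cc <= 0 || cc^2 < st$Q)
    stopf(paste0("expected diameter %.3g cm is infeasible for the observed",
                 " wall (media outer radius would not fit)"),
          expected_diameter_cm)
  b_pred <- cc - sqrt(cc^2 - st$Q)
  a_pred <- cc - b_pred
  sf <- b_pred / geom$media_thickness
  resid <- abs((2 * a_pred * b_pred + b_pred^2) - st$Q) / st$Q
  lt <- lamellar$lamella_thickness %||% NA_real_
  il <- lamellar$interlamellar_distance %||% NA_real_
  structure(list(predicted_media_thickness = b_pred,
                 predicted_lumen_radius = a_pred,
                 predicted_lamella_thickness = lt * sf,
                 predicted_interlamellar_distance = il * sf,
                 scaling_factor = sf,
                 area_residual = resid), class = "remodeling_prediction")
}

#' @export
print.remodeling_prediction <- function(x, ...) {
  cat(sprintf(
    "<remodeling_prediction> media %.4g um (x%.3f); lamella %.3g um; spacing %.3g um\n",
    x$predicted_media_thickness, x$scaling_factor,
    x$predicted_lamella_thickness, x$predicted_interlamellar_distance))
  invisible(x)
}
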