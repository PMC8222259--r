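# Expected aortic diameter, z-score classification and derived
# cross-sectional quantities. Expected diameters come from a linear
# nomogram in age, sex and body surface area; the shipped default
# coefficients are synthetic placeholders (clearly labelled), since real
# nomogram coefficients are configuration, not part of this package.

#' Aortic diameter nomogram
#'
#' Linear model `expected = intercept + coef_age*age + coef_sex*[male] +
#' coef_bsa*bsa` (cm), with a residual SD used for z-scores. The default
#' coefficients are synthetic: they yield plausible adult ascending-aorta
#' diameters (about 3.3-3.6 cm) but are not fitted to any population;
#' supply real published coefficients for clinical use.
#'
#' @param intercept cm.
#' @param coef_age cm per year.
#' @param coef_sex cm added for male sex.
#' @param coef_bsa cm per m².
#' @param residual_sd residual SD, cm (> 0).
#' @return a `nomogram_model` object.
#' @export
nomogram_model <- function(intercept = 1.4, coef_age = 0.008,
                           coef_sex = 0.15, coef_bsa = 0.7,
                           residual_sd = 0.3) {
  check_number(residual_sd, "residual_sd", 0, strict_lower = TRUE)
  for (nm in c("intercept", "coef_age", "coef_sex", "coef_bsa"))
    check_number(get(nm), nm)
  structure(list(intercept = intercept, coef_age = coef_age,
                 coef_sex = coef_sex, coef_bsa = coef_bsa,
                 residual_sd = residual_sd, synthetic_default =
                   missing(intercept) && missing(coef_age) &&
                   missing(coef_sex) && missing(coef_bsa)),
            class = "nomogram_model")
}

#' @rdname nomogram_model
#' @param path JSON/YAML file with keys `intercept`, `coef_age`, `coef_sex`,
#'   `coef_bsa`, `residual_sd`.
#' @export
read_nomogram <- function(path) {
  cfg <- read_config(path)
  need <- c("intercept", "coef_age", "coef_sex", "coef_bsa", "residual_sd")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stopf("nomogram file '%s': missing key(s) %s", path,
          paste(miss, collapse = ", "))
  nomogram_model(cfg$intercept, cfg$coef_age, cfg$coef_sex, cfg$coef_bsa,
                 cfg$residual_sd)
}

#' Expected aortic diameter from the nomogram
#'
#' @param subject data.frame (or list) with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `bsa` (m²); vectorised over rows.
#' @param model a [nomogram_model()].
#' @return expected diameter(s), cm.
#' @export
expected_diameter <- function(subject, model) {
  stopifnot(inherits(model, "nomogram_model"))
  for (k in c("age", "sex", "bsa"))
    if (is.null(subject[[k]]) || anyNA(subject[[k]]))
      stopf("missing covariate '%s'", k)
  male <- subject$sex == "male"
  model$intercept + model$coef_age * subject$age +
    model$coef_sex * as.numeric(male) + model$coef_bsa * subject$bsa
}

#' Aortic z-score and size class
#'
#' z = (observed - expected) / residual SD. Classes: `aneurysm` when
#' observed > 1.5 x expected; `normal` when |z| <= 2; otherwise
#' `indeterminate-dilated`.
#'
#' @param observed,expected diameters, cm (vectorised).
#' @param model a [nomogram_model()] (supplies the residual SD).
#' @return data.frame with columns `z` and `class`.
#' @export
z_score_and_class <- function(observed, expected, model) {
  stopifnot(inherits(model, "nomogram_model"))
  if (any(expected <= 0)) stopf("expected diameter must be > 0")
  z <- (observed - expected) / model$residual_sd
  cls <- ifelse(observed > 1.5 * expected, "aneurysm",
                ifelse(abs(z) <= 2, "normal", "indeterminate-dilated"))
  data.frame(z = z, class = cls)
}

#' Wall geometry of an axisymmetric aortic cross-section
#'
#' Diameters are external; the lumen radius subtracts all three layer
#' thicknesses (this convention is explicit and configurable via
#' `reference`).
#'
#' @param external_diameter cm.
#' @param intima_thickness,media_thickness,adventitia_thickness µm.
#' @param reference `"external"` (default) or `"luminal"`: which surface
#'   `external_diameter` refers to.
#' @return a `wall_geometry` object carrying radii in µm: external `R_um`,
#'   media outer `r_out`, media inner `r_in`, lumen `a`.
#' @export
wall_geometry <- function(external_diameter, intima_thickness,
                          media_thickness, adventitia_thickness,
                          reference = c("external", "luminal")) {
  reference <- match.arg(reference)
  check_number(external_diameter, "external_diameter", 0,
               strict_lower = TRUE)
  for (nm in c("intima_thickness", "media_thickness", "adventitia_thickness"))
    check_number(get(nm), nm, 0)
  wall <- intima_thickness + media_thickness + adventitia_thickness
  if (reference == "external") {
    R_um <- external_diameter * 1e4 / 2
    a <- R_um - wall
  } else {
    a <- external_diameter * 1e4 / 2
    R_um <- a + wall
  }
  if (a <= 0)
    stopf("lumen radius is not positive (%g um): wall exceeds radius", a)
  r_out <- R_um - adventitia_thickness
  r_in <- r_out - media_thickness
  structure(list(external_diameter = R_um * 2 / 1e4,
                 intima_thickness = intima_thickness,
                 media_thickness = media_thickness,
                 adventitia_thickness = adventitia_thickness,
                 R_um = R_um, r_out = r_out, r_in = r_in, a = a,
                 reference = reference),
            class = "wall_geometry")
}

#' Media cross-sectional area
#'
#' Annulus area pi (r_out^2 - r_in^2) between the media's outer and inner
#' radii, in mm².
#'
#' @param geom a [wall_geometry()].
#' @return area, mm² (0 with a warning when the media has zero thickness).
#' @export
media_xsec_area <- function(geom) {
  stopifnot(inherits(geom, "wall_geometry"))
  if (geom$media_thickness <= 0) {
    warning("media thickness is 0; cross-sectional area is 0")
    return(0)
  }
  pi * (geom$r_out^2 - geom$r_in^2) / 1e6
}

#' Per-cross-section derived quantities
#'
#' Scales medial fractions and nuclear density by the media cross-sectional
#' area: `smc_per_xsec = density * area`, `component_xsec[c] =
#' fraction[c] * area`. This is the quantity that separates dilution
#' (fraction down, amount maintained) from true loss of a component.
#'
#' @param fractions a [fraction_set()] or named numeric fractions.
#' @param density nuclei per mm².
#' @param area media cross-sectional area, mm² (> 0).
#' @return list with `smc_per_xsec` (count) and `component_xsec` (mm² per
#'   component).
#' @export
per_cross_section <- function(fractions, density, area) {
  check_number(area, "area", 0, strict_lower = TRUE)
  check_number(density, "density", 0)
  fr <- if (inherits(fractions, "fraction_set")) fractions$fractions
        else fractions
  list(smc_per_xsec = density * area, component_xsec = fr * area)
}
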