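# Synthetic full-thickness vessel rings (transverse sections): concentric
# annuli for intima, media and adventitia around a lumen, with exact layer
# radii recorded as ground truth. Used to validate layer-thickness
# measurement and the annulus-area closed form by pixel counting.

#' Specify a synthetic aortic ring image
#'
#' @param external_diameter external vessel diameter, cm.
#' @param intima_thickness,media_thickness,adventitia_thickness layer
#'   thicknesses, µm (0 renders the layer absent).
#' @param pixel_size µm per pixel.
#' @param stain_kind stain label carried by the image (default `"vvg"`).
#' @param color_jitter_sd additive Gaussian per-channel noise SD.
#' @param seed integer RNG seed (used only for jitter).
#' @return a `ring_spec` object.
#' @export
ring_spec <- function(external_diameter = 0.5,
                      intima_thickness = 100,
                      media_thickness = 1200,
                      adventitia_thickness = 500,
                      pixel_size = 4,
                      stain_kind = "vvg",
                      color_jitter_sd = 0,
                      seed = 1L) {
  check_number(external_diameter, "external_diameter", 0, strict_lower = TRUE)
  check_number(intima_thickness, "intima_thickness", 0)
  check_number(media_thickness, "media_thickness", 0)
  check_number(adventitia_thickness, "adventitia_thickness", 0)
  check_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  R_um <- external_diameter * 1e4 / 2
  wall <- intima_thickness + media_thickness + adventitia_thickness
  if (wall >= R_um)
    stopf("wall thickness (%g um) must be below the external radius (%g um)",
          wall, R_um)
  for (th in c(intima = intima_thickness, media = media_thickness,
               adventitia = adventitia_thickness)) {
    if (th > 0 && th < pixel_size)
      stopf("pixel size %g um/px too coarse: a %g um layer is under 1 px",
            pixel_size, th)
  }
  structure(list(external_diameter = external_diameter,
                 intima_thickness = intima_thickness,
                 media_thickness = media_thickness,
                 adventitia_thickness = adventitia_thickness,
                 pixel_size = pixel_size, stain_kind = stain_kind,
                 color_jitter_sd = color_jitter_sd, seed = as.integer(seed)),
            class = "ring_spec")
}

#' Generate a synthetic vessel-ring image with ground truth
#'
#' @param spec a [ring_spec()].
#' @param palette optional [stain_palette()] with classes named `intima`,
#'   `media`, `adventitia`, `background`; defaults to the built-in ring
#'   palette.
#' @return list with `image` (a [stain_image()]) and `truth` (a
#'   `ring_truth`: exact layer radii in µm, thicknesses, pixel size, and the
#'   pre-noise `label_mask` with levels background/intima/media/adventitia).
#' @export
generate_ring_image <- function(spec, palette = NULL) {
  stopifnot(inherits(spec, "ring_spec"))
  if (is.null(palette)) palette <- ring_palette()
  ps <- spec$pixel_size
  R_um <- spec$external_diameter * 1e4 / 2
  r_adv_in <- R_um - spec$adventitia_thickness
  r_med_in <- r_adv_in - spec$media_thickness
  r_int_in <- r_med_in - spec$intima_thickness   # lumen radius a
  R_px <- ceiling(R_um / ps)
  n <- 2L * (R_px + 2L) + 1L
  ctr <- (n + 1) / 2
  d <- seq_len(n) - ctr
  r2 <- outer(d^2, d^2, "+")               # squared radius in px^2
  r_um <- sqrt(r2) * ps
  labels <- matrix(0L, n, n)               # 0 background/lumen
  labels[r_um > r_int_in & r_um <= r_med_in] <- 1L  # intima
  labels[r_um > r_med_in & r_um <= r_adv_in] <- 2L  # media
  labels[r_um > r_adv_in & r_um <= R_um] <- 3L      # adventitia
  truth <- structure(list(
    external_diameter = spec$external_diameter,
    intima_thickness = spec$intima_thickness,
    media_thickness = spec$media_thickness,
    adventitia_thickness = spec$adventitia_thickness,
    pixel_size = ps,
    lumen_radius = r_int_in,
    radii = c(lumen = r_int_in, intima_out = r_med_in, media_out = r_adv_in,
              external = R_um),
    seed = spec$seed,
    label_mask = labels,
    label_levels = c("background", "intima", "media", "adventitia")),
    class = "ring_truth")

  rgbm <- as.matrix(palette$classes[, c("r", "g", "b")])
  idx <- match(c("background", "intima", "media", "adventitia"),
               palette$classes$name)
  if (anyNA(idx))
    stopf("ring palette must define classes intima/media/adventitia/background")
  px <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    lut <- rgbm[idx, ch]
    px[, , ch] <- matrix(lut[labels + 1L], n, n)
  }
  if (spec$color_jitter_sd > 0) {
    px <- with_seed(spec$seed, {
      out <- px + stats::rnorm(length(px), 0, spec$color_jitter_sd)
      out[out < 0] <- 0; out[out > 255] <- 255
      out
    })
  }
  list(image = stain_image(px, spec$stain_kind, ps), truth = truth)
}

#' @export
print.ring_truth <- function(x, ...) {
  cat(sprintf(
    "<ring_truth> D = %.3g cm; intima/media/adventitia = %g/%g/%g um at %g um/px\n",
    x$external_diameter, x$intima_thickness, x$media_thickness,
    x$adventitia_thickness, x$pixel_size))
  invisible(x)
}
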