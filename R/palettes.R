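#' Stain palettes
#'
#' A `stain_palette` maps a stain kind to a set of colour prototypes, one per
#' histological class, used both to render synthetic fields and to classify
#' pixels of stained sections. Each class has a `name`, a `role` (one of
#' `elastin`, `cytoplasm`, `collagen`, `gag`, `nucleus`, `background`) and a
#' prototype sRGB colour. `max_distance` is the CIELAB distance (Delta E)
#' beyond which a pixel is left unclassified; `white_L` is the L* luminance
#' above which a pixel is treated as background (lumen/white space)
#' regardless of prototype distance.
#'
#' Default palettes are idealisations of the standard stains: Movat
#' pentachrome renders elastin near-black, smooth-muscle cytoplasm crimson,
#' collagen yellow and glycosaminoglycans blue-green; Verhoeff (no
#' counterstain) renders elastin black on pale grey; Verhoeff-Van Gieson
#' adds a red collagen counterstain; H&E renders nuclei blue-violet on pink.
#'
#' @param stain_kind one of `"movat"`, `"verhoeff"`, `"vvg"`, `"he"`.
#' @param classes data.frame with columns `name`, `role`, `r`, `g`, `b`
#'   (sRGB in 0..255).
#' @param max_distance CIELAB Delta E classification threshold.
#' @param white_L L* threshold above which pixels are background.
#' @return an object of class `stain_palette`.
#' @export
stain_palette <- function(stain_kind, classes, max_distance = 25,
                          white_L = 92) {
  stain_kind <- match.arg(stain_kind, c("movat", "verhoeff", "vvg", "he"))
  stopifnot(is.data.frame(classes),
            all(c("name", "role", "r", "g", "b") %in% names(classes)))
  if (nrow(classes) < 2L) stopf("palette needs at least 2 classes")
  if (anyDuplicated(classes$name)) stopf("palette class names must be unique")
  roles <- c("elastin", "cytoplasm", "collagen", "gag", "nucleus",
             "background")
  if (!all(classes$role %in% roles))
    stopf("unknown palette role(s): %s",
          paste(setdiff(classes$role, roles), collapse = ", "))
  rgb <- as.matrix(classes[, c("r", "g", "b")])
  if (anyDuplicated(rgb)) stopf("palette prototype colours must be distinct")
  check_number(max_distance, "max_distance", lower = 0, strict_lower = TRUE)
  check_number(white_L, "white_L", lower = 0, upper = 100)
  structure(list(stain_kind = stain_kind, classes = classes,
                 max_distance = max_distance, white_L = white_L,
                 lab = rgb_to_lab(rgb)),
            class = "stain_palette")
}

#' @rdname stain_palette
#' @export
default_palette <- function(stain_kind) {
  stain_kind <- match.arg(stain_kind, c("movat", "verhoeff", "vvg", "he"))
  cls <- switch(stain_kind,
    movat = data.frame(
      name = c("elastin", "cytoplasm", "collagen", "gag", "nucleus",
               "background"),
      role = c("elastin", "cytoplasm", "collagen", "gag", "nucleus",
               "background"),
      r = c(30, 185, 225, 70, 75, 248),
      g = c(26, 45, 195, 170, 40, 246),
      b = c(24, 60, 60, 160, 95, 243)),
    verhoeff = data.frame(
      name = c("elastin", "tissue", "background"),
      role = c("elastin", "cytoplasm", "background"),
      r = c(22, 200, 250),
      g = c(20, 198, 250),
      b = c(20, 196, 248)),
    vvg = data.frame(
      name = c("elastin", "collagen", "background"),
      role = c("elastin", "collagen", "background"),
      r = c(22, 190, 250),
      g = c(20, 70, 250),
      b = c(20, 80, 248)),
    he = data.frame(
      name = c("nucleus", "tissue", "background"),
      role = c("nucleus", "cytoplasm", "background"),
      r = c(72, 232, 250),
      g = c(60, 165, 250),
      b = c(150, 185, 248)))
  stain_palette(stain_kind, cls)
}

# Palette used to paint concentric vessel-ring images (VVG-like): distinct
# colours per wall layer so layer boundaries are recoverable by colour.
ring_palette <- function() {
  cls <- data.frame(
    name = c("intima", "media", "adventitia", "background"),
    role = c("cytoplasm", "elastin", "collagen", "background"),
    r = c(150, 40, 200, 250),
    g = c(110, 35, 90, 250),
    b = c(130, 35, 100, 248))
  stain_palette("vvg", cls)
}

#' @export
print.stain_palette <- function(x, ...) {
  cat(sprintf("<stain_palette: %s> %d classes, max Delta E %.1f, white L* > %.0f\n",
              x$stain_kind, nrow(x$classes), x$max_distance, x$white_L))
  print(x$classes, row.names = FALSE)
  invisible(x)
}

# sRGB (0..255) -> CIELAB via grDevices; input Nx3 matrix.
rgb_to_lab <- function(m) {
  m <- matrix(as.numeric(m), ncol = 3L)
  grDevices::convertColor(m / 255, from = "sRGB", to = "Lab")
}

# Read a palette from a JSON (or YAML, if available) file of the form
# {stain_kind, max_distance, white_L, classes: [{name, role, rgb:[r,g,b]}]}
#' @rdname stain_palette
#' @param path palette file (.json, or .yaml/.yml when the yaml package is
#'   installed).
#' @export
read_palette <- function(path) {
  spec <- read_config(path)
  for (k in c("stain_kind", "classes"))
    if (is.null(spec[[k]])) stopf("palette file %s: missing key '%s'", path, k)
  cl <- spec$classes
  df <- data.frame(
    name = vapply(cl, function(x) x$name, ""),
    role = vapply(cl, function(x) x$role, ""),
    r = vapply(cl, function(x) as.numeric(x$rgb[[1]]), 0),
    g = vapply(cl, function(x) as.numeric(x$rgb[[2]]), 0),
    b = vapply(cl, function(x) as.numeric(x$rgb[[3]]), 0))
  stain_palette(spec$stain_kind, df,
                max_distance = spec$max_distance %||% 25,
                white_L = spec$white_L %||% 92)
}
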