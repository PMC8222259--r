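# Pixel classification of stained sections by nearest colour prototype in
# CIELAB, and medial area fractions. The classifier is deliberately simple
# and auditable: convert sRGB to CIELAB, assign each ROI pixel to the
# nearest palette prototype (Delta E, CIE76) unless it is farther than
# `max_distance` from all of them (unclassified), with a luminance gate
# (L* above `white_L`) that sends white/lumen pixels to background
# regardless of prototype distance.

#' Classify stain-image pixels by nearest CIELAB prototype
#'
#' @param image a [stain_image()].
#' @param palette a [stain_palette()] with matching `stain_kind`.
#' @return a `label_mask`: integer H x W matrix (0 = unclassified, i = i-th
#'   palette class), with the palette attached as attribute `"palette"`.
#' @export
classify_pixels <- function(image, palette) {
  stopifnot(inherits(image, "stain_image"), inherits(palette, "stain_palette"))
  if (image$stain_kind != palette$stain_kind)
    stopf("stain kind mismatch: image is '%s', palette is '%s'",
          image$stain_kind, palette$stain_kind)
  d <- dim(image$pixels)
  roi <- image$roi_mask %||% matrix(TRUE, d[1], d[2])
  if (!any(roi)) stopf("ROI is empty")
  flat <- cbind(as.vector(image$pixels[, , 1]),
                as.vector(image$pixels[, , 2]),
                as.vector(image$pixels[, , 3]))
  sel <- as.vector(roi)
  lab <- rgb_to_lab(flat[sel, , drop = FALSE])
  proto <- palette$lab
  k <- nrow(proto)
  d2 <- matrix(0, nrow(lab), k)
  for (j in seq_len(k)) {
    d2[, j] <- (lab[, 1] - proto[j, 1])^2 + (lab[, 2] - proto[j, 2])^2 +
      (lab[, 3] - proto[j, 3])^2
  }
  nearest <- max.col(-d2, ties.method = "first")
  mind <- sqrt(d2[cbind(seq_len(nrow(d2)), nearest)])
  nearest[mind > palette$max_distance] <- 0L
  bg <- match("background", palette$classes$role)
  if (!is.na(bg)) nearest[lab[, 1] > palette$white_L] <- bg
  labels <- matrix(0L, d[1], d[2])
  labels[roi] <- nearest
  structure(labels, palette = palette, roi = image$roi_mask,
            class = c("label_mask", class(labels)))
}

#' Medial component area fractions from a label mask
#'
#' Fractions are computed over classified, non-background ROI pixels.
#' Nucleus pixels follow `nucleus_policy` (default `"cytoplasm"`: merged
#' into cytoplasm, so Movat reports exactly the four components elastin /
#' cytoplasm / collagen / GAG). The unclassified fraction (relative to all
#' ROI pixels) is reported separately, never mixed into the component
#' denominator.
#'
#' @param mask a `label_mask` from [classify_pixels()].
#' @param nucleus_policy `"cytoplasm"` (merge into cytoplasm), `"own"`
#'   (report as its own component) or `"drop"` (exclude from denominator).
#' @return a `fraction_set`: list with `fractions` (named, summing to 1),
#'   `unclassified_fraction`, `n_pixels_roi`, `n_classified` and
#'   `denominator` metadata.
#' @export
medial_fractions <- function(mask,
                             nucleus_policy = c("cytoplasm", "own", "drop")) {
  nucleus_policy <- match.arg(nucleus_policy)
  palette <- attr(mask, "palette")
  if (is.null(palette)) stopf("mask must come from classify_pixels()")
  roi <- attr(mask, "roi")
  vals <- if (is.null(roi)) as.vector(mask) else mask[roi]
  n_roi <- length(vals)
  if (n_roi == 0L) stopf("mask is empty within the ROI")
  counts <- tabulate(vals, nbins = nrow(palette$classes))
  roles <- palette$classes$role
  n_uncl <- sum(vals == 0L)
  comp_counts <- c(elastin = 0, cytoplasm = 0, collagen = 0, gag = 0)
  nuc <- 0
  for (i in seq_along(roles)) {
    r <- roles[i]
    if (r == "background") next
    if (r == "nucleus") nuc <- nuc + counts[i]
    else comp_counts[r] <- comp_counts[r] + counts[i]
  }
  if (nucleus_policy == "cytoplasm") comp_counts["cytoplasm"] <-
      comp_counts["cytoplasm"] + nuc
  if (nucleus_policy == "own") comp_counts <- c(comp_counts, nucleus = nuc)
  denom <- sum(comp_counts)
  if (denom == 0L) stopf("no classified tissue pixels in the ROI")
  structure(list(fractions = comp_counts / denom,
                 unclassified_fraction = n_uncl / n_roi,
                 n_pixels_roi = n_roi,
                 n_classified = denom,
                 denominator = "classified non-background ROI pixels",
                 nucleus_policy = nucleus_policy),
            class = "fraction_set")
}

#' @export
print.fraction_set <- function(x, ...) {
  cat(sprintf("<fraction_set> %d ROI px, %d classified (%.1f%% unclassified)\n",
              x$n_pixels_roi, x$n_classified,
              100 * x$unclassified_fraction))
  print(round(x$fractions, 4))
  invisible(x)
}

#' Average per-field fractions into a specimen mean
#'
#' Unweighted arithmetic mean per component across fields, emulating the
#' averaging of several arbitrarily selected high-power fields per
#' specimen.
#'
#' @param per_field list of [medial_fractions()] results (or of named
#'   numeric vectors with identical names).
#' @return a `fraction_set` with the averaged fractions and `n_fields`.
#' @export
aggregate_fields <- function(per_field) {
  if (!length(per_field)) stopf("need at least one field")
  vecs <- lapply(per_field, function(f)
    if (inherits(f, "fraction_set")) f$fractions else f)
  nms <- names(vecs[[1]])
  for (v in vecs)
    if (!identical(names(v), nms))
      stopf("fields have inconsistent component sets")
  m <- colMeans(do.call(rbind, vecs))
  uncl <- mean(vapply(per_field, function(f)
    if (inherits(f, "fraction_set")) f$unclassified_fraction else NA_real_,
    0))
  structure(list(fractions = m, unclassified_fraction = uncl,
                 n_pixels_roi = sum(vapply(per_field, function(f)
                   if (inherits(f, "fraction_set")) f$n_pixels_roi else 0L,
                   0L)),
                 n_classified = NA_integer_,
                 denominator = "mean over fields",
                 n_fields = length(per_field)),
            class = "fraction_set")
}

# Per-pixel agreement between a label mask and a generator truth mask,
# compared on roles (nucleus pixels count as cytoplasm on both sides).
label_agreement <- function(mask, truth) {
  palette <- attr(mask, "palette")
  pred_role <- c("unclassified", palette$classes$role)[as.vector(mask) + 1L]
  pred_role[pred_role == "nucleus"] <- "cytoplasm"
  true_role <- truth$label_levels[as.vector(truth$label_mask)]
  true_role[true_role == "nucleus"] <- "cytoplasm"
  mean(pred_role == true_role)
}
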