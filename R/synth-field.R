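# Synthetic medial high-power fields.
#
# A field is a flat Cartesian strip: elastic lamellae are horizontal wavy
# bands of known count, thickness and spacing; interlamellar tissue is a
# blocky texture of cytoplasm / collagen / glycosaminoglycan in configured
# proportions; nuclei are rotated ellipses placed with Poisson-disk
# separation. Ground truth (realized fractions, counts, geometry) is
# recorded from the pre-noise label mask, never from the nominal spec.

FIELD_CLASSES <- c("elastin", "cytoplasm", "collagen", "gag", "nucleus",
                   "background")

#' Specify a synthetic medial field
#'
#' Defaults describe a 128 x 128 µm Movat field with 8 lamellae of 4 µm
#' thickness at 12 µm edge-to-edge spacing (an elastin area fraction of
#' exactly 0.25) and a medial nuclei density of 1500 /mm².
#'
#' @param stain_kind stain to render: `"movat"`, `"verhoeff"`, `"vvg"`,
#'   `"he"`.
#' @param image_size integer (rows, cols) in pixels.
#' @param pixel_size µm per pixel.
#' @param n_lamellae number of elastic lamellae.
#' @param lamella_thickness lamella thickness, µm.
#' @param interlamellar_distance edge-to-edge gap between lamellae, µm.
#' @param target_fractions named fractions for `elastin`, `cytoplasm`,
#'   `collagen`, `gag`; values in `[0,1]`, sum <= 1 (any remainder renders
#'   as background).
#' @param nuclei_density nuclei per mm².
#' @param nucleus_axes (major, minor) ellipse axes, µm.
#' @param waviness_amplitude sine displacement amplitude of lamellae, µm.
#' @param fragmentation_prob probability that a lamella segment carries a
#'   break (a short erased gap of `fragment_gap` µm). Breaks are sparse
#'   interruptions, so transect counts degrade gracefully rather than
#'   collapsing with the erased fraction.
#' @param color_jitter_sd additive Gaussian per-channel noise SD (0..255
#'   units), applied after label rendering.
#' @param seed integer RNG seed.
#' @param texture_block interlamellar texture block size, px.
#' @param fragment_segment length of lamella segments that independently
#'   carry at most one break, µm.
#' @param fragment_gap width of an individual break, µm.
#' @return a `field_spec` object.
#' @export
field_spec <- function(stain_kind = "movat",
                       image_size = c(256L, 256L),
                       pixel_size = 0.5,
                       n_lamellae = 8L,
                       lamella_thickness = 4,
                       interlamellar_distance = 12,
                       target_fractions = c(elastin = 0.25, cytoplasm = 0.30,
                                            collagen = 0.30, gag = 0.15),
                       nuclei_density = 1500,
                       nucleus_axes = c(12, 4),
                       waviness_amplitude = 2,
                       fragmentation_prob = 0,
                       color_jitter_sd = 0,
                       seed = 1L,
                       texture_block = 4L,
                       fragment_segment = 16,
                       fragment_gap = 2) {
  stain_kind <- match.arg(stain_kind, c("movat", "verhoeff", "vvg", "he"))
  image_size <- as.integer(image_size)
  stopifnot(length(image_size) == 2L, all(image_size >= 8L))
  check_number(pixel_size, "pixel_size", 0, strict_lower = TRUE)
  check_number(n_lamellae, "n_lamellae", 0)
  check_number(lamella_thickness, "lamella_thickness", 0, strict_lower = TRUE)
  check_number(interlamellar_distance, "interlamellar_distance", 0,
               strict_lower = TRUE)
  comp <- c("elastin", "cytoplasm", "collagen", "gag")
  if (!all(comp %in% names(target_fractions)))
    stopf("target_fractions must name %s", paste(comp, collapse = ", "))
  target_fractions <- target_fractions[comp]
  if (any(target_fractions < 0) || any(target_fractions > 1))
    stopf("target_fractions must lie in [0, 1]")
  if (sum(target_fractions) > 1 + 1e-9)
    stopf("target_fractions sum to %.3f > 1", sum(target_fractions))
  check_number(nuclei_density, "nuclei_density", 0)
  stopifnot(length(nucleus_axes) == 2L, all(nucleus_axes > 0))
  check_number(waviness_amplitude, "waviness_amplitude", 0)
  check_number(fragmentation_prob, "fragmentation_prob", 0, 1)
  check_number(color_jitter_sd, "color_jitter_sd", 0)

  spec <- list(stain_kind = stain_kind, image_size = image_size,
               pixel_size = pixel_size, n_lamellae = as.integer(n_lamellae),
               lamella_thickness = lamella_thickness,
               interlamellar_distance = interlamellar_distance,
               target_fractions = target_fractions,
               nuclei_density = nuclei_density, nucleus_axes = nucleus_axes,
               waviness_amplitude = waviness_amplitude,
               fragmentation_prob = fragmentation_prob,
               color_jitter_sd = color_jitter_sd, seed = as.integer(seed),
               texture_block = as.integer(texture_block),
               fragment_segment = fragment_segment,
               fragment_gap = fragment_gap)
  class(spec) <- "field_spec"
  validate_field_geometry(spec)
  spec
}

validate_field_geometry <- function(spec) {
  ps <- spec$pixel_size
  H <- spec$image_size[1]
  thick_px <- max(1L, round(spec$lamella_thickness / ps))
  gap_px <- max(1L, round(spec$interlamellar_distance / ps))
  period_px <- thick_px + gap_px
  n <- spec$n_lamellae
  if (n > 0L && n * period_px > H)
    stopf("image too small to hold %d lamellae: need %d rows, have %d",
          n, n * period_px, H)
  amp_px <- round(spec$waviness_amplitude / ps)
  off <- (H - n * period_px) %/% 2L + gap_px %/% 2L
  if (n > 0L && (off - amp_px < 0L ||
                 off + (n - 1L) * period_px + thick_px + amp_px > H))
    stopf("waviness amplitude %.3g um pushes lamellae outside the field",
          spec$waviness_amplitude)
  f_band <- if (n > 0L) n * thick_px / H else 0
  if (f_band > spec$target_fractions[["elastin"]] + 0.02)
    stopf(paste0("infeasible spec: lamellar geometry implies an elastin ",
                 "fraction of %.3f, above the %.3f target"),
          f_band, spec$target_fractions[["elastin"]])
  invisible(list(thick_px = thick_px, gap_px = gap_px,
                 period_px = period_px, offset = off, amp_px = amp_px,
                 band_fraction = f_band))
}

#' Generate a synthetic stain field with ground truth
#'
#' Rendering is fully deterministic for a fixed spec (including seed). The
#' returned truth is computed from the rendered pre-noise label mask.
#'
#' @param spec a [field_spec()].
#' @param palette optional [stain_palette()]; defaults to the stain's
#'   built-in palette.
#' @return list with elements `image` (a [stain_image()]) and `truth` (a
#'   `field_truth`: realized fractions, nuclei count, lamellar geometry,
#'   field area, seed, and the pre-noise `label_mask`).
#' @export
generate_stain_field <- function(spec, palette = NULL) {
  stopifnot(inherits(spec, "field_spec"))
  geo <- validate_field_geometry(spec)
  if (is.null(palette)) palette <- default_palette(spec$stain_kind)
  H <- spec$image_size[1]; W <- spec$image_size[2]
  ps <- spec$pixel_size
  with_seed(spec$seed, {
    labels <- matrix(0L, H, W)

    # 1. lamellae as horizontal wavy bands of exact per-column thickness
    n <- spec$n_lamellae
    phases <- stats::runif(max(n, 1L), 0, 2 * pi)
    if (n > 0L) {
      x <- seq_len(W)
      for (i in seq_len(n)) {
        d <- round(geo$amp_px * sin(2 * pi * x / W + phases[i]))
        top <- geo$offset + (i - 1L) * geo$period_px + 1L + d
        rows <- outer(0:(geo$thick_px - 1L), top, "+")
        labels[cbind(as.vector(rows), rep(x, each = geo$thick_px))] <- 1L
      }
    }

    # 2. fragmentation: each band segment carries a short break with
    # probability fragmentation_prob. Both the break indicator uniforms
    # and the break positions are drawn unconditionally, so the erased set
    # is nested in fragmentation_prob for a fixed seed (monotone coupling).
    seg_px <- max(1L, round(spec$fragment_segment / ps))
    gap_break_px <- max(1L, round(spec$fragment_gap / ps))
    n_seg <- ceiling(W / seg_px)
    u_frag <- matrix(stats::runif(max(n, 1L) * n_seg), max(n, 1L), n_seg)
    pos_frag <- matrix(stats::runif(max(n, 1L) * n_seg), max(n, 1L), n_seg)
    if (n > 0L && spec$fragmentation_prob > 0) {
      for (i in seq_len(n)) {
        broken <- which(u_frag[i, ] < spec$fragmentation_prob)
        if (!length(broken)) next
        erase_cols <- unlist(lapply(broken, function(s) {
          seg_start <- (s - 1L) * seg_px + 1L
          seg_len <- min(seg_px, W - seg_start + 1L)
          off <- floor(pos_frag[i, s] * max(seg_len - gap_break_px, 0L))
          cols <- seg_start + off + 0:(gap_break_px - 1L)
          cols[cols <= W]
        }))
        if (!length(erase_cols)) next
        d <- round(geo$amp_px * sin(2 * pi * erase_cols / W + phases[i]))
        top <- geo$offset + (i - 1L) * geo$period_px + 1L + d
        rows <- outer(0:(geo$thick_px - 1L), top, "+")
        labels[cbind(as.vector(rows),
                     rep(erase_cols, each = geo$thick_px))] <- 0L
      }
    }

    # 3. interlamellar texture in blocks; class shares aim at the target
    # fractions after accounting for band elastin and expected nucleus area
    area_mm2 <- H * W * ps^2 / 1e6
    n_nuclei <- round(spec$nuclei_density * area_mm2)
    nuc_px_expect <- n_nuclei * pi * prod(spec$nucleus_axes / 2) / ps^2
    s_nuc <- min(nuc_px_expect / (H * W), 0.5)
    tf <- spec$target_fractions
    q <- c(elastin = max(0, tf[["elastin"]] - geo$band_fraction),
           cytoplasm = max(0, tf[["cytoplasm"]] - s_nuc),
           collagen = tf[["collagen"]],
           gag = tf[["gag"]],
           background = max(0, 1 - sum(tf)))
    if (sum(q) <= 0) q["cytoplasm"] <- 1
    q <- q / sum(q)
    bs <- spec$texture_block
    nbr <- ceiling(H / bs); nbc <- ceiling(W / bs)
    block_cls <- matrix(
      c(1L, 2L, 3L, 4L, 6L)[
        findInterval(stats::runif(nbr * nbc), cumsum(q),
                     rightmost.closed = TRUE) + 1L],
      nbr, nbc)
    px_cls <- block_cls[cbind(rep((seq_len(H) - 1L) %/% bs + 1L, W),
                              rep((seq_len(W) - 1L) %/% bs + 1L, each = H))]
    free <- labels == 0L
    labels[free] <- px_cls[free]

    # 4. nuclei: rotated ellipses with Poisson-disk separation, placed in
    # the interlamellar tissue. A candidate whose ellipse would touch
    # lamellar elastin is rejected, so each rendered nucleus is one
    # connected blob; once dart throwing saturates (densities beyond what
    # separation allows) both constraints are relaxed and overlaps or
    # band-clipped nuclei are permitted.
    nuclei_placed <- 0L
    if (n_nuclei > 0L) {
      ra <- spec$nucleus_axes[1] / 2 / ps
      rb <- spec$nucleus_axes[2] / 2 / ps
      min_sep <- 2 * ra
      centers <- matrix(numeric(0), 0, 2)
      pixsets <- list()
      tries <- 0L; max_tries <- 40L * n_nuclei
      relax <- FALSE
      while (nrow(centers) < n_nuclei && tries < 2L * max_tries) {
        tries <- tries + 1L
        if (tries > max_tries) relax <- TRUE
        cy <- stats::runif(1, 1 + rb, H - rb)
        cx <- stats::runif(1, 1 + rb, W - rb)
        theta <- stats::runif(1, 0, pi)
        if (labels[round(cy), round(cx)] == 1L) next
        if (!relax && nrow(centers) &&
            min((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) < min_sep^2)
          next
        e <- ellipse_pixels(cy, cx, ra, rb, theta, H, W)
        on_band <- labels[e] == 1L
        if (!relax && any(on_band)) next
        centers <- rbind(centers, c(cy, cx))
        pixsets[[nrow(centers)]] <- e[!on_band, , drop = FALSE]
      }
      for (e in pixsets) labels[e] <- 5L
      nuclei_placed <- nrow(centers)
    }

    # 5. truth from the rendered pre-noise mask
    tab <- tabulate(labels, nbins = 6L)
    n_tissue <- sum(tab[1:5])
    realized <- c(elastin = tab[1], cytoplasm = tab[2] + tab[5],
                  collagen = tab[3], gag = tab[4]) / max(n_tissue, 1L)
    truth <- structure(list(
      realized_fractions = realized,
      nuclei_count = nuclei_placed,
      n_lamellae = n,
      mean_lamella_thickness = geo$thick_px * ps,
      mean_interlamellar_distance = geo$gap_px * ps,
      field_area = area_mm2,
      seed = spec$seed,
      label_mask = labels,
      label_levels = FIELD_CLASSES), class = "field_truth")

    # 6. colour rendering + truncated Gaussian jitter
    px <- render_labels(labels, palette)
    if (spec$color_jitter_sd > 0) {
      px <- px + stats::rnorm(length(px), 0, spec$color_jitter_sd)
      px[px < 0] <- 0; px[px > 255] <- 255
    }
    list(image = stain_image(px, spec$stain_kind, ps), truth = truth)
  })
}

# pixel indices (row, col) covered by a rotated ellipse
ellipse_pixels <- function(cy, cx, ra, rb, theta, H, W) {
  r0 <- max(1L, floor(cy - ra)); r1 <- min(H, ceiling(cy + ra))
  c0 <- max(1L, floor(cx - ra)); c1 <- min(W, ceiling(cx + ra))
  rr <- r0:r1; cc <- c0:c1
  dy <- rep(rr - cy, length(cc)); dx <- rep(cc - cx, each = length(rr))
  u <- (dx * cos(theta) + dy * sin(theta)) / ra
  v <- (-dx * sin(theta) + dy * cos(theta)) / rb
  inside <- u^2 + v^2 <= 1
  cbind(rep(rr, length(cc))[inside], rep(cc, each = length(rr))[inside])
}

# paint an integer label mask (codes into FIELD_CLASSES) with a palette,
# falling back along stain-appropriate roles when a palette lacks a role
render_labels <- function(labels, palette) {
  H <- nrow(labels); W <- ncol(labels)
  fallback <- list(
    elastin = c("elastin", "cytoplasm", "background"),
    cytoplasm = c("cytoplasm", "collagen", "background"),
    collagen = c("collagen", "cytoplasm", "background"),
    gag = c("gag", "cytoplasm", "collagen", "background"),
    nucleus = c("nucleus", "cytoplasm", "collagen", "background"),
    background = "background")
  px <- array(0, c(H, W, 3))
  rgbm <- as.matrix(palette$classes[, c("r", "g", "b")])
  for (code in seq_along(FIELD_CLASSES)) {
    sel <- labels == code
    if (!any(sel)) next
    role <- FIELD_CLASSES[code]
    hit <- fallback[[role]][fallback[[role]] %in% palette$classes$role][1]
    if (is.na(hit)) stopf("palette has no class usable for role '%s'", role)
    col <- rgbm[match(hit, palette$classes$role), ]
    for (ch in 1:3) {
      plane <- px[, , ch]; plane[sel] <- col[ch]; px[, , ch] <- plane
    }
  }
  px
}

#' @export
print.field_truth <- function(x, ...) {
  cat(sprintf("<field_truth> %d lamellae, %d nuclei, %.4g mm^2 (seed %d)\n",
              x$n_lamellae, x$nuclei_count, x$field_area, x$seed))
  print(round(x$realized_fractions, 4))
  invisible(x)
}
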