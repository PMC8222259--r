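# Lamellar morphometry along transects, medial nuclei counting, and
# vessel-layer thickness from ring sections.
#
# Lamellae in flat medial fields run horizontally, so transects are image
# columns (perpendicular to the lamellae). On each transect, maximal runs
# of elastin pixels are bands: runs separated by gaps no wider than
# `bridge_px` are merged (a 1 px hole does not split a band) and runs
# shorter than `min_band_px` are discarded as noise.

#' Transect specification
#'
#' @param n_transects number of evenly spaced transects (columns).
#' @param positions optional explicit column positions (overrides
#'   `n_transects`).
#' @return a `transect_spec`.
#' @export
transect_spec <- function(n_transects = 9L, positions = NULL) {
  if (is.null(positions)) check_number(n_transects, "n_transects", 1)
  structure(list(n_transects = as.integer(n_transects),
                 positions = positions), class = "transect_spec")
}

transect_columns <- function(spec, width) {
  pos <- spec$positions %||%
    round(seq(1, width, length.out = spec$n_transects + 2L)[
      -c(1L, spec$n_transects + 2L)])
  pos <- as.integer(pos)
  if (any(pos < 1L | pos > width))
    stopf("transect positions outside the image (width %d)", width)
  pos
}

# Band runs along one mask column: list of (start, length) after bridging
# gaps <= bridge_px and dropping runs < min_band_px.
column_bands <- function(col, min_band_px = 2L, bridge_px = 1L) {
  r <- rle(as.logical(col))
  # bridge: flip FALSE runs of length <= bridge_px that sit between TRUEs
  if (bridge_px > 0L && length(r$lengths) > 2L) {
    inner <- 2:(length(r$lengths) - 1L)
    flip <- inner[!r$values[inner] & r$lengths[inner] <= bridge_px]
    if (length(flip)) {
      r$values[flip] <- TRUE
      r <- rle(inverse.rle(r))
    }
  }
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_band_px
  cbind(start = starts[keep], length = r$lengths[keep])
}

#' Count elastic lamellae along transects
#'
#' @param elastin_mask logical (or 0/1) H x W matrix of elastin pixels.
#' @param spec a [transect_spec()].
#' @param pixel_size µm per pixel (unused for the count; kept for a
#'   uniform signature).
#' @param min_band_px minimum band extent, px.
#' @param bridge_px largest gap bridged within a band, px.
#' @return mean band count across transects (0 for an all-empty mask).
#' @export
count_lamellae <- function(elastin_mask, spec = transect_spec(),
                           pixel_size = 1, min_band_px = 2L,
                           bridge_px = 1L) {
  m <- as.matrix(elastin_mask) != 0
  cols <- transect_columns(spec, ncol(m))
  mean(vapply(cols, function(x)
    nrow(column_bands(m[, x], min_band_px, bridge_px)), 0L))
}

#' Measure lamellar thickness and interlamellar distance
#'
#' Band extents along each transect are converted to µm; the interlamellar
#' distance is the edge-to-edge gap between consecutive bands on the same
#' transect. Measurements falling within `exclusion_radius` of a skeleton
#' branch point (where a lamella divides or a radial strut takes off) are
#' dropped and tallied in `n_excluded`, so thickness is measured only in
#' segments without divisions.
#'
#' @inheritParams count_lamellae
#' @param pixel_size µm per pixel.
#' @param exclusion_radius radius around branch points within which
#'   measurements are discarded, µm; 0 disables branch detection.
#' @return a `lamellar_metrics` list: `n_lamellae` (mean count),
#'   `lamella_thickness` / `interlamellar_distance` (means, µm, with
#'   per-measurement vectors in `thickness_um` / `spacing_um`),
#'   `n_excluded`, and `interlamellar_defined`.
#' @export
measure_lamellae <- function(elastin_mask, spec = transect_spec(),
                             pixel_size = 1, exclusion_radius = 10,
                             min_band_px = 2L, bridge_px = 1L) {
  m <- as.matrix(elastin_mask) != 0
  if (!any(m)) stopf("elastin mask is empty")
  cols <- transect_columns(spec, ncol(m))
  branch <- if (exclusion_radius > 0) {
    branch_points(skeletonize(m))
  } else matrix(numeric(0), 0, 2)
  excl_px <- exclusion_radius / pixel_size
  thick <- numeric(0); space <- numeric(0)
  counts <- integer(0); n_excluded <- 0L
  for (x in cols) {
    b <- column_bands(m[, x], min_band_px, bridge_px)
    counts <- c(counts, nrow(b))
    if (!nrow(b)) next
    centers <- b[, "start"] + (b[, "length"] - 1) / 2
    ok <- rep(TRUE, nrow(b))
    if (nrow(branch)) {
      d2 <- outer(centers, branch[, 1], function(r, br) (r - br)^2) +
        outer(rep(x, nrow(b)), branch[, 2], function(c_, bc) (c_ - bc)^2)
      ok <- apply(d2, 1, min) > excl_px^2
    }
    n_excluded <- n_excluded + sum(!ok)
    thick <- c(thick, b[ok, "length"] * pixel_size)
    if (nrow(b) >= 2L) {
      gaps <- b[-1L, "start"] - (b[-nrow(b), "start"] +
                                   b[-nrow(b), "length"])
      gap_ok <- ok[-1L] & ok[-length(ok)]
      space <- c(space, gaps[gap_ok] * pixel_size)
    }
  }
  structure(list(
    n_lamellae = mean(counts),
    lamella_thickness = if (length(thick)) mean(thick) else NA_real_,
    interlamellar_distance = if (length(space)) mean(space) else NA_real_,
    interlamellar_defined = length(space) > 0L,
    thickness_um = thick, spacing_um = space,
    n_excluded = n_excluded,
    spacing_convention = "edge-to-edge"), class = "lamellar_metrics")
}

#' @export
print.lamellar_metrics <- function(x, ...) {
  cat(sprintf(
    "<lamellar_metrics> n = %.2f; thickness %.3g um; spacing %s um (%d excluded)\n",
    x$n_lamellae, x$lamella_thickness,
    if (x$interlamellar_defined) sprintf("%.3g", x$interlamellar_distance)
    else "undefined", x$n_excluded))
  invisible(x)
}

# ---- skeletonization (Zhang-Suen thinning) ----------------------------

# Vectorised Zhang-Suen binary thinning. Adequate for band masks of a few
# hundred pixels a side; used only to locate lamellar divisions.
skeletonize <- function(mask) {
  img <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nrow(m), ncol(m))
    rs <- (1 + max(dr, 0)):(nrow(m) + min(dr, 0))
    cs <- (1 + max(dc, 0)):(ncol(m) + min(dc, 0))
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift(img, -1, 0); p3 <- shift(img, -1, 1)
      p4 <- shift(img, 0, 1);  p5 <- shift(img, 1, 1)
      p6 <- shift(img, 1, 0);  p7 <- shift(img, 1, -1)
      p8 <- shift(img, 0, -1); p9 <- shift(img, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) +
        (p4 == 0 & p5 == 1) + (p5 == 0 & p6 == 1) +
        (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- img == 1L & bsum >= 2 & bsum <= 6 & a == 1
      if (phase == 1L)
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      else
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      if (any(cond)) {
        img[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] == 1L
}

# skeleton pixels with >= 3 of 8 neighbours are branch points;
# returns a (row, col) matrix
branch_points <- function(skel) {
  s <- matrix(0L, nrow(skel) + 2L, ncol(skel) + 2L)
  s[2:(nrow(skel) + 1L), 2:(ncol(skel) + 1L)] <- as.integer(skel)
  nb <- matrix(0L, nrow(s), ncol(s))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rs <- (1 + max(dr, 0)):(nrow(s) + min(dr, 0))
    cs <- (1 + max(dc, 0)):(ncol(s) + min(dc, 0))
    nb[rs, cs] <- nb[rs, cs] + s[rs - dr, cs - dc]
  }
  hits <- which(s == 1L & nb >= 3L, arr.ind = TRUE)
  hits - 1L  # undo the pad
}

# ---- nuclei -----------------------------------------------------------

#' Count medial nuclei on an H&E field
#'
#' Nucleus-coloured pixels are grouped into 8-connected components;
#' components with area inside `[min_area, max_area]` µm² count as one
#' nucleus. Oversized blobs (overlapping nuclei) follow `oversize_policy`:
#' `"split_by_area"` (default) counts `round(area / nominal_area)` nuclei,
#' `"count_one"` counts 1, `"exclude"` counts 0; the choice and the number
#' of affected blobs are recorded in the result. Counting all medial
#' nuclei overestimates smooth muscle cells (endothelial cells and
#' leukocytes are included), a documented property of the H&E proxy.
#'
#' @param image a [stain_image()] with `stain_kind == "he"`.
#' @param palette optional palette; defaults to the H&E palette.
#' @param min_area,max_area nucleus area bounds, µm².
#' @param nominal_area nominal single-nucleus area, µm², used by
#'   `"split_by_area"`; default is an ellipse of 12 x 4 µm axes.
#' @param oversize_policy see above.
#' @return a `nuclei_result`: `count`, `field_area` (mm²), `density`
#'   (nuclei/mm²), `n_components`, `n_oversized`, `policy`.
#' @export
count_nuclei <- function(image, palette = NULL, min_area = 4,
                         max_area = 120,
                         nominal_area = pi * 6 * 2,
                         oversize_policy = c("split_by_area", "count_one",
                                             "exclude")) {
  oversize_policy <- match.arg(oversize_policy)
  stopifnot(inherits(image, "stain_image"))
  if (image$stain_kind != "he")
    stopf("nuclei are counted on H&E fields (got '%s')", image$stain_kind)
  if (is.null(palette)) palette <- default_palette("he")
  area_mm2 <- field_area_mm2(image)
  if (area_mm2 <= 0) stopf("field area must be > 0")
  mask <- classify_pixels(image, palette)
  nuc_idx <- which(palette$classes$role == "nucleus")
  if (!length(nuc_idx)) stopf("palette has no nucleus class")
  bin <- matrix(as.vector(mask) %in% nuc_idx, nrow(mask), ncol(mask))
  comps <- connected_components(bin)
  px_area <- image$pixel_size^2
  count <- 0L; n_over <- 0L
  for (a_px in comps) {
    a <- a_px * px_area
    if (a < min_area) next
    if (a <= max_area) count <- count + 1L
    else {
      n_over <- n_over + 1L
      count <- count + switch(oversize_policy,
                              split_by_area =
                                max(1L, as.integer(round(a / nominal_area))),
                              count_one = 1L,
                              exclude = 0L)
    }
  }
  structure(list(count = count, field_area = area_mm2,
                 density = count / area_mm2,
                 n_components = length(comps), n_oversized = n_over,
                 policy = oversize_policy), class = "nuclei_result")
}

#' @export
print.nuclei_result <- function(x, ...) {
  cat(sprintf("<nuclei_result> %d nuclei in %.4g mm^2 = %.1f /mm^2 (%s)\n",
              x$count, x$field_area, x$density, x$policy))
  invisible(x)
}

# component pixel counts of a binary mask, 8-connectivity (stack-based
# flood fill; components here are nucleus-sized, so this stays cheap)
connected_components <- function(bin) {
  H <- nrow(bin); W <- ncol(bin)
  lab <- matrix(0L, H, W)
  sizes <- integer(0)
  todo <- which(bin)
  cur <- 0L
  for (p in todo) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    n_px <- 0L
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      n_px <- n_px + 1L
      r <- ((q - 1L) %% H) + 1L
      cc <- ((q - 1L) %/% H) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr < 1L || rr > H || c2 < 1L || c2 > W) next
        qq <- (c2 - 1L) * H + rr
        if (bin[qq] && lab[qq] == 0L) {
          lab[qq] <- cur
          stack <- c(stack, qq)
        }
      }
    }
    sizes <- c(sizes, n_px)
  }
  sizes
}

# ---- layer thickness from ring sections -------------------------------

#' Measure vessel layer thickness on a ring section
#'
#' Casts `n_sites` radial rays from the tissue centroid and measures, per
#' ray, the radial extent of each classified layer (intima, media,
#' adventitia), averaging across sites.
#'
#' @param image a ring [stain_image()].
#' @param n_sites number of radial measurement sites.
#' @param palette optional palette with classes named `intima`, `media`,
#'   `adventitia`; defaults to the built-in ring palette.
#' @param step ray sampling step, px.
#' @return a `wall_thickness`: `intima`, `media`, `adventitia` (mean µm),
#'   `per_site` matrix, `n_sites`.
#' @export
measure_layer_thickness <- function(image, n_sites = 3L, palette = NULL,
                                    step = 0.25) {
  stopifnot(inherits(image, "stain_image"))
  if (is.null(palette)) palette <- ring_palette()
  check_number(n_sites, "n_sites", 1)
  mask <- classify_pixels(image, palette)
  layer_idx <- match(c("intima", "media", "adventitia"),
                     palette$classes$name)
  if (anyNA(layer_idx))
    stopf("palette must define classes intima, media, adventitia")
  tissue <- which(matrix(as.vector(mask) %in% layer_idx,
                         nrow(mask), ncol(mask)), arr.ind = TRUE)
  if (!nrow(tissue)) stopf("no vessel-wall tissue found in the image")
  ctr <- colMeans(tissue)
  in_lumen <- mask[round(ctr[1]), round(ctr[2])] %in% layer_idx
  if (in_lumen)
    stopf("tissue centroid does not fall in the lumen; ring not detected")
  H <- nrow(mask); W <- ncol(mask)
  rmax <- sqrt(max((c(1, H) - ctr[1])^2)) + sqrt(max((c(1, W) - ctr[2])^2))
  angles <- (seq_len(n_sites) - 1L) * 2 * pi / n_sites
  out <- matrix(NA_real_, n_sites, 3,
                dimnames = list(NULL, c("intima", "media", "adventitia")))
  ts <- seq(0, rmax, by = step)
  for (s in seq_len(n_sites)) {
    rr <- round(ctr[1] + ts * sin(angles[s]))
    cc <- round(ctr[2] + ts * cos(angles[s]))
    keep <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
    labs <- mask[cbind(rr[keep], cc[keep])]
    tt <- ts[keep]
    for (j in 1:3) {
      hit <- which(labs == layer_idx[j])
      if (length(hit))
        out[s, j] <- (tt[max(hit)] - tt[min(hit)] + step) * image$pixel_size
      else out[s, j] <- 0
    }
  }
  if (all(out == 0))
    stopf("no layer boundaries found along any ray")
  structure(list(intima = mean(out[, "intima"]),
                 media = mean(out[, "media"]),
                 adventitia = mean(out[, "adventitia"]),
                 per_site = out, n_sites = n_sites),
            class = "wall_thickness")
}

#' @export
print.wall_thickness <- function(x, ...) {
  cat(sprintf(
    "<wall_thickness> intima %.3g / media %.3g / adventitia %.3g um (%d sites)\n",
    x$intima, x$media, x$adventitia, x$n_sites))
  invisible(x)
}
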