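# Lamellar morphometry, nuclei counting, layer thickness.

test_that("band runs per transect equal a brute-force run-length scan", {
  set.seed(42)
  for (rep in 1:20) {
    m <- matrix(runif(64 * 64) < 0.4, 64, 64)
    for (x in sample(64, 5)) {
      got <- nrow(aortomorph:::column_bands(m[, x], min_band_px = 1L,
                                            bridge_px = 0L))
      expect_identical(got, oracle_run_count(m[, x]))
    }
  }
})

test_that("unbroken synthetic bands are counted exactly; blanks give 0", {
  out <- generate_stain_field(field_spec(seed = 14))
  mask <- classify_pixels(out$image, default_palette("movat"))
  el <- elastin_mask_of(mask)
  expect_equal(count_lamellae(el, transect_spec(9)), 8)
  expect_equal(count_lamellae(matrix(FALSE, 32, 32), transect_spec(3)), 0)
})

test_that("fragmented bands stay within 1 of truth on average", {
  devs <- vapply(1:20, function(s) {
    out <- generate_stain_field(field_spec(
      image_size = c(128, 128), pixel_size = 1,
      fragmentation_prob = 0.3, seed = 300 + s))
    el <- out$truth$label_mask == 1L
    count_lamellae(el, transect_spec(9), pixel_size = 1) - 8
  }, 0)
  expect_lte(max(abs(devs)), 1)
})

test_that("lamella thickness and spacing are recovered within one pixel", {
  sp <- field_spec(seed = 23)           # 4 um bands, 12 um gaps, 0.5 um/px
  out <- generate_stain_field(sp)
  el <- out$truth$label_mask == 1L
  lm <- measure_lamellae(el, transect_spec(9), pixel_size = sp$pixel_size,
                         exclusion_radius = 0)
  expect_lte(abs(lm$lamella_thickness - 4), sp$pixel_size)
  expect_lte(abs(lm$interlamellar_distance - 12), sp$pixel_size)
  expect_true(lm$interlamellar_defined)
  # units: lengths are px * pixel_size
  lm2 <- measure_lamellae(el, transect_spec(9), pixel_size = 1,
                          exclusion_radius = 0)
  expect_equal(lm2$lamella_thickness, lm$lamella_thickness / sp$pixel_size)
  # transect order must not matter
  cols <- c(20, 60, 100)
  lm_a <- measure_lamellae(el, transect_spec(positions = cols),
                           pixel_size = 1, exclusion_radius = 0)
  lm_b <- measure_lamellae(el, transect_spec(positions = rev(cols)),
                           pixel_size = 1, exclusion_radius = 0)
  expect_equal(lm_a$lamella_thickness, lm_b$lamella_thickness)
  expect_equal(lm_a$n_lamellae, lm_b$n_lamellae)
})

test_that("single band: thickness measured, spacing flagged undefined", {
  m <- matrix(FALSE, 40, 40)
  m[18:21, ] <- TRUE
  lm <- measure_lamellae(m, transect_spec(5), pixel_size = 2,
                         exclusion_radius = 0)
  expect_equal(lm$lamella_thickness, 8)  # 4 px at 2 um/px
  expect_false(lm$interlamellar_defined)
  expect_true(is.na(lm$interlamellar_distance))
})

test_that("consistency: count x (thickness + spacing) spans the band extent", {
  sp <- field_spec(seed = 77)
  out <- generate_stain_field(sp)
  el <- out$truth$label_mask == 1L
  lm <- measure_lamellae(el, transect_spec(9), pixel_size = sp$pixel_size,
                         exclusion_radius = 0)
  extent <- lm$n_lamellae * (lm$lamella_thickness +
                               lm$interlamellar_distance)
  rendered <- sp$n_lamellae *
    (sp$lamella_thickness + sp$interlamellar_distance)
  expect_lt(abs(extent - rendered) / rendered, 0.05)
})

test_that("measurements near a rendered Y-division are excluded", {
  # two horizontal bands that merge into a Y at known coordinates
  m <- matrix(FALSE, 60, 80)
  m[20:23, ] <- TRUE                      # band A
  m[36:39, 1:40] <- TRUE                  # band B, left half only
  for (i in 0:11) {                       # oblique branch joining B to A
    m[35 - i, 40 + i + 0:1] <- TRUE
  }
  lm_excl <- measure_lamellae(m, transect_spec(positions = c(10, 44, 70)),
                              pixel_size = 1, exclusion_radius = 10)
  lm_all <- measure_lamellae(m, transect_spec(positions = c(10, 44, 70)),
                             pixel_size = 1, exclusion_radius = 0)
  expect_gt(lm_excl$n_excluded, 0)
  expect_identical(lm_all$n_excluded, 0L)
  # away from the branch the thickness is still the rendered 4 px
  expect_lte(abs(lm_excl$lamella_thickness - 4), 1)
})

test_that("nuclei are counted exactly on non-overlapping fields", {
  hs <- field_spec("he", image_size = c(300, 400), pixel_size = 1,
                   nuclei_density = 500, seed = 8,
                   lamella_thickness = 4, interlamellar_distance = 12,
                   n_lamellae = 8L)
  out <- generate_stain_field(hs)
  res <- count_nuclei(out$image)
  expect_identical(res$count, out$truth$nuclei_count)
  expect_identical(res$count, 60L)        # 500 /mm^2 x 0.12 mm^2
  expect_equal(res$density, res$count / 0.12)
  # blank field
  blank <- stain_image(array(rep(c(232, 165, 185), each = 16), c(4, 4, 3)),
                       "he", 100)
  res0 <- count_nuclei(blank)
  expect_identical(res0$count, 0L)
  expect_equal(res0$density, 0)
  expect_error(count_nuclei(generate_stain_field(field_spec(seed = 1))$image),
               "H&E")
})

test_that("oversized nucleus blobs follow the declared deterministic policy", {
  px <- array(rep(c(232, 165, 185), each = 40 * 40), c(40, 40, 3))
  img0 <- stain_image(px, "he", 1)
  pal <- default_palette("he")
  nuc <- as.numeric(pal$classes[pal$classes$role == "nucleus",
                                c("r", "g", "b")])
  # one blob of ~2 nominal nucleus areas (should split into 2)
  blob <- px
  for (ch in 1:3) blob[10:17, 10:19, ch] <- nuc[ch]   # 80 px = 80 um^2
  img <- stain_image(blob, "he", 1)
  res_split <- count_nuclei(img, max_area = 60,
                            nominal_area = 40,
                            oversize_policy = "split_by_area")
  expect_identical(res_split$count, 2L)
  expect_identical(res_split$n_oversized, 1L)
  res_one <- count_nuclei(img, max_area = 60, oversize_policy = "count_one")
  expect_identical(res_one$count, 1L)
  res_ex <- count_nuclei(img, max_area = 60, oversize_policy = "exclude")
  expect_identical(res_ex$count, 0L)
})

test_that("layer thickness is recovered within 2 px on synthetic rings", {
  sp <- ring_spec(external_diameter = 0.12, intima_thickness = 40,
                  media_thickness = 160, adventitia_thickness = 60,
                  pixel_size = 2)
  out <- generate_ring_image(sp)
  wt <- measure_layer_thickness(out$image, n_sites = 3)
  expect_lte(abs(wt$media - 160), 2 * sp$pixel_size)
  expect_lte(abs(wt$intima - 40), 2 * sp$pixel_size)
  expect_lte(abs(wt$adventitia - 60), 2 * sp$pixel_size)
  # axisymmetry: per-site spread within one pixel
  expect_lte(max(apply(wt$per_site, 2, function(v) diff(range(v)))),
             sp$pixel_size)
  # degenerate adventitia reports 0
  sp0 <- ring_spec(external_diameter = 0.1, intima_thickness = 40,
                   media_thickness = 160, adventitia_thickness = 0,
                   pixel_size = 2)
  wt0 <- measure_layer_thickness(generate_ring_image(sp0)$image, 3)
  expect_equal(wt0$adventitia, 0)
})
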