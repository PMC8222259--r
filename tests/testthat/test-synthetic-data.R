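# Synthetic-data generators: determinism, truth consistency, geometry.

test_that("noiseless field rendering preserves lamella count and fractions", {
  out <- generate_stain_field(field_spec(seed = 11))
  expect_identical(out$truth$n_lamellae, 8L)
  tf <- c(elastin = 0.25, cytoplasm = 0.30, collagen = 0.30, gag = 0.15)
  expect_true(all(abs(out$truth$realized_fractions - tf) <= 0.02))
  # truth fractions recomputed from the label mask match stored values
  tab <- tabulate(out$truth$label_mask, nbins = 6L)
  recomputed <- c(elastin = tab[1], cytoplasm = tab[2] + tab[5],
                  collagen = tab[3], gag = tab[4]) / sum(tab[1:5])
  expect_equal(out$truth$realized_fractions, recomputed)
  expect_lte(sum(out$truth$realized_fractions), 1 + 1e-12)
})

test_that("field generation is deterministic and seed-sensitive", {
  a <- generate_stain_field(field_spec(seed = 5, color_jitter_sd = 6,
                                       fragmentation_prob = 0.2))
  b <- generate_stain_field(field_spec(seed = 5, color_jitter_sd = 6,
                                       fragmentation_prob = 0.2))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$realized_fractions, b$truth$realized_fractions)
  c <- generate_stain_field(field_spec(seed = 6, color_jitter_sd = 6,
                                       fragmentation_prob = 0.2))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("infeasible field specs error before rendering", {
  expect_error(field_spec(target_fractions = c(elastin = 0.5,
                                               cytoplasm = 0.4,
                                               collagen = 0.3, gag = 0.1)),
               "sum")
  # 8 lamellae at 32 px period do not fit in 64 rows
  expect_error(field_spec(image_size = c(64, 64)), "too small")
  # lamellar supply above the elastin target
  expect_error(field_spec(target_fractions = c(elastin = 0.10,
                                               cytoplasm = 0.40,
                                               collagen = 0.35,
                                               gag = 0.15)),
               "infeasible")
})

test_that("fragmentation monotonically removes elastin at a fixed seed", {
  probs <- c(0, 0.15, 0.3, 0.6, 1)
  counts <- vapply(probs, function(p) {
    out <- generate_stain_field(field_spec(seed = 21,
                                           fragmentation_prob = p))
    sum(out$truth$label_mask == 1L)
  }, 0)
  expect_true(all(diff(counts) <= 0))
  expect_lt(counts[5], counts[1])
})

test_that("ring geometry matches the closed-form annulus within 1%", {
  sp <- ring_spec(external_diameter = 0.12, intima_thickness = 40,
                  media_thickness = 160, adventitia_thickness = 60,
                  pixel_size = 2)
  out <- generate_ring_image(sp)
  med_px <- sum(out$truth$label_mask == 2L)
  closed <- pi * (out$truth$radii[["media_out"]]^2 -
                    out$truth$radii[["intima_out"]]^2) / sp$pixel_size^2
  expect_lt(abs(med_px - closed) / closed, 0.01)
  # media band width along a horizontal radius equals thickness / px
  ctr <- (dim(out$truth$label_mask)[1] + 1) / 2
  row <- out$truth$label_mask[ctr, ctr:ncol(out$truth$label_mask)]
  expect_equal(sum(row == 2L), sp$media_thickness / sp$pixel_size,
               tolerance = 0.02)
})

test_that("degenerate and infeasible ring specs behave per contract", {
  sp <- ring_spec(external_diameter = 0.08, intima_thickness = 30,
                  media_thickness = 120, adventitia_thickness = 0,
                  pixel_size = 2)
  out <- generate_ring_image(sp)
  expect_identical(sum(out$truth$label_mask == 3L), 0L)  # adventitia absent
  expect_error(ring_spec(external_diameter = 0.05, intima_thickness = 100,
                         media_thickness = 1200,
                         adventitia_thickness = 500),
               "external radius")
  expect_error(ring_spec(external_diameter = 0.5, intima_thickness = 10,
                         media_thickness = 1200,
                         adventitia_thickness = 500, pixel_size = 20),
               "coarse")
})

test_that("cohort generator honours sizes, effects and determinism", {
  co <- generate_cohort(cohort_spec(seed = 3))
  expect_identical(nrow(co$subjects), 35L)
  expect_identical(sum(co$subjects$group == "nondilated"), 17L)
  expect_identical(sum(co$subjects$group == "aneurysm"), 18L)
  # group deltas applied exactly to the truth
  by_grp <- split(co$truth, co$truth$group)
  expect_equal(unique(by_grp$nondilated$elastin_fraction) -
                 unique(by_grp$aneurysm$elastin_fraction), 0.07)
  expect_equal(unique(by_grp$aneurysm$smc_density),
               unique(by_grp$nondilated$smc_density))
  co2 <- generate_cohort(cohort_spec(seed = 3))
  expect_identical(co$subjects, co2$subjects)
})

test_that("null cohorts give calibrated Mann-Whitney type-I error", {
  null_spec <- function(seed) {
    cohort_spec(group_effects = c(elastin_fraction = 0), seed = seed)
  }
  reject <- vapply(1:500, function(s) {
    co <- generate_cohort(null_spec(s))
    x <- split(co$subjects$elastin_fraction, co$subjects$group)
    mann_whitney(x$nondilated, x$aneurysm)$p_value < 0.05
  }, NA)
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("the configured elastin deficit is detectable (power check)", {
  hits <- vapply(1:200, function(s) {
    co <- generate_cohort(cohort_spec(
      group_effects = c(elastin_fraction = -0.07), seed = 1000 + s))
    x <- split(co$subjects$elastin_fraction, co$subjects$group)
    mann_whitney(x$nondilated, x$aneurysm)$p_value < 0.05
  }, NA)
  expect_gt(mean(hits), 0.5)
})
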