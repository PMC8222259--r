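# Nearest-prototype CIELAB classification and medial fractions.

test_that("prototype colours classify to their own class; far colours do not", {
  pal <- default_palette("movat")
  protos <- as.matrix(pal$classes[, c("r", "g", "b")])
  for (i in which(pal$classes$role != "background")) {
    px <- array(rep(protos[i, ], each = 16), c(4, 4, 3))
    img <- stain_image(px, "movat", 1)
    expect_true(all(classify_pixels(img, pal) == i), info = pal$classes$name[i])
  }
  # a mid-grey far from every prototype is unclassified everywhere
  far <- stain_image(array(128, c(4, 4, 3)), "movat", 1)
  expect_true(all(classify_pixels(far, pal) == 0L))
  # near-white goes to background regardless of distance
  white <- stain_image(array(254, c(4, 4, 3)), "movat", 1)
  bg <- match("background", pal$classes$role)
  expect_true(all(classify_pixels(white, pal) == bg))
})

test_that("classification errors on stain mismatch and empty ROI", {
  img <- stain_image(array(100, c(4, 4, 3)), "he", 1)
  expect_error(classify_pixels(img, default_palette("movat")), "mismatch")
  expect_error(stain_image(array(100, c(4, 4, 3)), "he", 1,
                           roi_mask = matrix(FALSE, 4, 4)), "empty")
})

test_that("vectorised classifier equals the exhaustive per-pixel oracle", {
  pal <- default_palette("movat")
  for (s in 1:3) {
    out <- generate_stain_field(field_spec(
      image_size = c(32, 32), pixel_size = 1, n_lamellae = 2L,
      lamella_thickness = 4, interlamellar_distance = 12,
      color_jitter_sd = 25, waviness_amplitude = 0, seed = s))
    got <- classify_pixels(out$image, pal)
    expect_identical(matrix(as.integer(got), nrow(got)),
                     oracle_classify(out$image, pal))
  }
})

test_that("noiseless Movat fields are recovered near-perfectly", {
  out <- generate_stain_field(field_spec(seed = 31))
  mask <- classify_pixels(out$image, default_palette("movat"))
  expect_gte(aortomorph:::label_agreement(mask, out$truth), 0.99)
  fr <- medial_fractions(mask)
  expect_true(all(abs(fr$fractions - out$truth$realized_fractions) <= 0.02))
  expect_equal(sum(fr$fractions), 1, tolerance = 1e-9)
})

test_that("Verhoeff elastin fraction agrees with the Movat-derived one", {
  sp_m <- field_spec(stain_kind = "movat", seed = 44)
  sp_v <- field_spec(stain_kind = "verhoeff", seed = 44)
  fr_m <- medial_fractions(classify_pixels(generate_stain_field(sp_m)$image,
                                           default_palette("movat")))
  fr_v <- medial_fractions(classify_pixels(generate_stain_field(sp_v)$image,
                                           default_palette("verhoeff")))
  expect_lte(abs(fr_v$fractions[["elastin"]] - fr_m$fractions[["elastin"]]),
             0.02)
})

test_that("recovered fractions stay within 0.05 of truth at jitter SD 8", {
  pal <- default_palette("movat")
  worst <- 0
  for (s in 1:20) {
    out <- generate_stain_field(field_spec(
      image_size = c(128, 128), pixel_size = 1, color_jitter_sd = 8,
      seed = 200 + s))
    fr <- medial_fractions(classify_pixels(out$image, pal))
    worst <- max(worst, max(abs(fr$fractions -
                                  out$truth$realized_fractions)))
  }
  expect_lte(worst, 0.05)
})

test_that("fractions are invariant to pixel order and field order", {
  out <- generate_stain_field(field_spec(seed = 9, color_jitter_sd = 5))
  mask <- classify_pixels(out$image, default_palette("movat"))
  fr <- medial_fractions(mask)
  # shuffle pixels: fractions depend only on label counts
  shuffled <- mask
  perm <- sample(length(shuffled))
  shuffled[] <- shuffled[perm]
  attr(shuffled, "palette") <- attr(mask, "palette")
  expect_equal(medial_fractions(shuffled)$fractions, fr$fractions)
  # field order is irrelevant to the specimen mean
  fs <- lapply(c(2, 9, 13), function(s)
    medial_fractions(classify_pixels(
      generate_stain_field(field_spec(seed = s))$image,
      default_palette("movat"))))
  expect_equal(aggregate_fields(fs)$fractions,
               aggregate_fields(rev(fs))$fractions)
})

test_that("aggregate_fields averages per component and checks consistency", {
  f <- function(el) c(elastin = el, cytoplasm = 1 - el)
  agg <- aggregate_fields(list(f(0.2), f(0.3), f(0.4)))
  expect_equal(unname(agg$fractions[["elastin"]]), 0.3)
  expect_identical(agg$n_fields, 3L)
  same <- replicate(9, f(0.25), simplify = FALSE)
  expect_equal(aggregate_fields(same)$fractions, f(0.25))
  expect_error(aggregate_fields(list(f(0.2), c(elastin = 0.2, gag = 0.8))),
               "inconsistent")
})

test_that("stratified 9-field sampling recovers a whole-image gradient mean", {
  # one tall field with a radial elastin gradient emulated by increasing
  # spacing: approximate by sampling 3 inner / 3 mid / 3 outer sub-fields
  out <- generate_stain_field(field_spec(
    image_size = c(288, 96), pixel_size = 1, n_lamellae = 18L,
    lamella_thickness = 4, interlamellar_distance = 12,
    waviness_amplitude = 0, fragmentation_prob = 0.25,
    target_fractions = c(elastin = 0.25, cytoplasm = 0.35, collagen = 0.28,
                         gag = 0.12), seed = 17))
  mask <- classify_pixels(out$image, default_palette("movat"))
  whole <- medial_fractions(mask)
  strata <- list(1:96, 97:192, 193:288)
  fields <- list()
  for (st in strata) for (j in 0:2) {
    sub <- mask[st, (j * 32 + 1):(j * 32 + 32)]
    attr(sub, "palette") <- attr(mask, "palette")
    fields[[length(fields) + 1L]] <- medial_fractions(sub)
  }
  agg <- aggregate_fields(fields)
  expect_true(all(abs(agg$fractions - whole$fractions) <= 0.02))
})
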