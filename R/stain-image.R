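#' Stain image container
#'
#' Holds an 8-bit RGB raster together with the physical pixel size (µm per
#' pixel), the stain kind and an optional region-of-interest mask marking
#' the medial region. All morphometric routines operate on this container.
#'
#' @param pixels numeric H x W x 3 array, channel values in 0..255.
#' @param stain_kind one of `"movat"`, `"verhoeff"`, `"vvg"`, `"he"`.
#' @param pixel_size µm per pixel, > 0.
#' @param roi_mask optional logical H x W matrix; `NULL` means whole image.
#' @return an object of class `stain_image`.
#' @export
stain_image <- function(pixels, stain_kind, pixel_size, roi_mask = NULL) {
  stain_kind <- match.arg(stain_kind, c("movat", "verhoeff", "vvg", "he"))
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stopf("'pixels' must be an H x W x 3 array")
  if (any(pixels < 0) || any(pixels > 255))
    stopf("'pixels' channel values must lie in 0..255")
  check_number(pixel_size, "pixel_size", lower = 0, strict_lower = TRUE)
  if (!is.null(roi_mask)) {
    if (!is.logical(roi_mask) || !identical(dim(roi_mask), dim(pixels)[1:2]))
      stopf("'roi_mask' must be a logical matrix matching the image")
    if (!any(roi_mask)) stopf("'roi_mask' is empty")
  }
  structure(list(pixels = pixels, stain_kind = stain_kind,
                 pixel_size = pixel_size, roi_mask = roi_mask),
            class = "stain_image")
}

#' @export
print.stain_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<stain_image: %s> %d x %d px at %.3g um/px (%.4g mm^2)%s\n",
              x$stain_kind, d[1], d[2], x$pixel_size,
              field_area_mm2(x),
              if (is.null(x$roi_mask)) "" else ", with ROI"))
  invisible(x)
}

#' @rdname stain_image
#' @param image a `stain_image`.
#' @export
field_area_mm2 <- function(image) {
  d <- dim(image$pixels)
  d[1] * d[2] * image$pixel_size^2 / 1e6
}

# ---- on-disk formats --------------------------------------------------

#' Read and write stain images
#'
#' Images are written as ASCII PPM (portable pixmap, plain text) or, when
#' the png package is installed, as PNG; either way a JSON sidecar
#' `<path>.json` carries `pixel_size`, `stain_kind` and any extra metadata
#' (seed, ground truth). Reading without a sidecar, or with a sidecar
#' missing `pixel_size` or `stain_kind`, is an error naming the missing key.
#'
#' @param image a [stain_image()].
#' @param path output path; `.ppm` or `.png`.
#' @param metadata named list merged into the sidecar.
#' @return `write_stain_image` returns `path` invisibly; `read_stain_image`
#'   returns a `stain_image` with the sidecar in attribute `"metadata"`.
#' @export
write_stain_image <- function(image, path, metadata = list()) {
  stopifnot(inherits(image, "stain_image"))
  ext <- tolower(tools::file_ext(path))
  px <- round(image$pixels)
  if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("PNG output requires the 'png' package; use .ppm instead")
    png::writePNG(px / 255, path)
  } else if (ext == "ppm") {
    write_ppm(px, path)
  } else stopf("unsupported image extension '%s' (use .ppm or .png)", ext)
  side <- c(list(pixel_size = image$pixel_size,
                 stain_kind = image$stain_kind), metadata)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stain_image
#' @export
read_stain_image <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stopf("missing sidecar '%s' for image '%s'", sidecar, path)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (k in c("pixel_size", "stain_kind"))
    if (is.null(meta[[k]]))
      stopf("sidecar '%s': missing key '%s'", sidecar, k)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stopf("reading PNG requires the 'png' package")
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) a <- a[, , 1:3, drop = FALSE]
    else a <- array(rep(a, 3L), c(dim(a), 3L))
    a * 255
  } else if (ext == "ppm") {
    read_ppm(path)
  } else stopf("unsupported image extension '%s'", ext)
  img <- stain_image(px, meta$stain_kind, meta$pixel_size)
  attr(img, "metadata") <- meta
  img
}

# ASCII ("plain", P3) PPM writer/reader: 8-bit RGB as whitespace-separated
# integers. Chosen because it is text-only and dependency-free.
write_ppm <- function(px, path) {
  d <- dim(px)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", sprintf("%d %d", d[2], d[1]), "255"), con)
  # interleave channels row-major: r g b r g b ...
  flat <- aperm(px, c(3, 2, 1))  # channel, col, row
  write(as.integer(flat), con, ncolumns = 12L)
}

read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toks[1] != "P3") stopf("'%s' is not an ASCII (P3) PPM file", path)
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  vals <- as.numeric(toks[-(1:4)])
  if (length(vals) != 3L * w * h)
    stopf("'%s': expected %d samples, found %d", path, 3L * w * h,
          length(vals))
  aperm(array(vals, c(3L, w, h)), c(3, 2, 1))
}

# ---- config files (JSON always; YAML when available) ------------------

read_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("YAML configs require the 'yaml' package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
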