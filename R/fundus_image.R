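#' Construct a fundus image
#'
#' A `fundus_image` is an `H x W x 3` integer array of RGB values in
#' `[0, 255]` together with a resolution tier and a source identifier. The
#' tiers mirror the three working resolutions of the analysis pipeline:
#' 240 (patch classification), 360 (abstract image sets) and 480
#' (component-level image sets); images at any other size carry the tier
#' `"native"`.
#'
#' @param pixels numeric or integer `H x W x 3` array (or `H x W` matrix,
#'   replicated across channels) with values in `[0, 255]`.
#' @param tier one of 240, 360, 480 or `"native"`. Defaults to the matching
#'   numeric tier when the raster is square at a tier size, else `"native"`.
#' @param source_id free-text provenance tag.
#' @return an object of class `fundus_image`.
#' @examples
#' img <- fundus_image(array(128L, dim = c(8, 8, 3)))
#' dim(img$pixels)
#' @export
fundus_image <- function(pixels, tier = NULL, source_id = "unknown") {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  if (!(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L))
    stopf("exudatekit_bad_image", "pixels must be an H x W x 3 array")
  d <- dim(pixels)
  if (d[1] < 3L || d[2] < 3L)
    stopf("exudatekit_bad_image", "image must be at least 3 x 3")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("exudatekit_bad_image", "channel values must lie in [0, 255]")
  storage.mode(pixels) <- "integer"
  if (is.null(tier)) {
    tier <- if (d[1] == d[2] && d[1] %in% c(240L, 360L, 480L)) d[1] else "native"
  }
  if (!identical(tier, "native")) {
    tier <- as.integer(tier)
    if (!tier %in% c(240L, 360L, 480L))
      stopf("exudatekit_bad_tier", "tier must be 240, 360, 480 or \"native\"")
  }
  structure(list(pixels = pixels, tier = tier, source_id = source_id),
            class = "fundus_image")
}

#' Coerce to a fundus image
#'
#' @param x a `fundus_image`, an `H x W x 3` array or an `H x W` matrix.
#' @param ... passed to [fundus_image()].
#' @return a `fundus_image`.
#' @export
as_fundus_image <- function(x, ...) {
  if (inherits(x, "fundus_image")) x else fundus_image(x, ...)
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<fundus_image %d x %d, tier %s, source \"%s\">\n",
              d[1], d[2], as.character(x$tier), x$source_id))
  invisible(x)
}

#' @export
dim.fundus_image <- function(x) dim(x$pixels)

#' Read a fundus image from disk
#'
#' PNG and JPEG are read through the `png`/`jpeg` packages when installed;
#' netpbm PPM (`P3` plain text or `P6` binary) is always available.
#'
#' @param path file path; format chosen by extension
#'   (`.png`, `.jpg`/`.jpeg`, `.ppm`).
#' @param source_id provenance tag, default the file name.
#' @return a `fundus_image`.
#' @export
read_fundus_image <- function(path, source_id = basename(path)) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stopf("exudatekit_io", "the png package is required to read %s", path)
      float_to_raster(png::readPNG(path))
    },
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stopf("exudatekit_io", "the jpeg package is required to read %s", path)
      float_to_raster(jpeg::readJPEG(path))
    },
    ppm = read_ppm(path),
    stopf("exudatekit_io", "unsupported image extension: %s", ext)
  )
  fundus_image(px, source_id = source_id)
}

#' Write a fundus image to disk
#'
#' @param img a `fundus_image` (or coercible raster).
#' @param path output path; `.png` needs the `png` package, `.ppm` is
#'   dependency free.
#' @param ... for PPM, `plain = TRUE` selects the text `P3` encoding.
#' @return `path`, invisibly.
#' @export
write_fundus_image <- function(img, path, ...) {
  img <- as_fundus_image(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = {
      if (!requireNamespace("png", quietly = TRUE))
        stopf("exudatekit_io", "the png package is required to write %s", path)
      png::writePNG(img$pixels / 255, path)
    },
    ppm = write_ppm(img$pixels, path, ...),
    stopf("exudatekit_io", "unsupported image extension: %s", ext)
  )
  invisible(path)
}

# [0,1] float array from png/jpeg -> integer raster; drops an alpha channel,
# replicates grayscale.
float_to_raster <- function(a) {
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  if (dim(a)[3] >= 3L) a <- a[, , 1:3, drop = FALSE]
  quantize255(a * 255)
}
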