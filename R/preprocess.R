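#' Smoothing kernels
#'
#' `table2_printed` is the reference 3 x 3 weight pattern used by the
#' denoising stage, stored verbatim: its entries sum to 17/16 (the
#' bottom-right weight is 1/8 where a symmetric Gaussian-like pattern would
#' have 1/16), so it brightens a constant image slightly. The default kernel
#' for [smooth_linear()] is `table2_normalized`, the same weights divided by
#' their sum, which preserves constant images exactly.
#'
#' @param weights positive 3 x 3 numeric matrix.
#' @param normalize if `TRUE`, the effective weights are rescaled to sum to 1.
#' @return a `smoothing_kernel` object.
#' @examples
#' smoothing_kernel(matrix(1, 3, 3), normalize = TRUE)
#' table2_normalized()
#' @export
smoothing_kernel <- function(weights, normalize = TRUE) {
  weights <- as.matrix(weights)
  if (!all(dim(weights) == c(3L, 3L)))
    stopf("exudatekit_bad_kernel", "smoothing kernel must be 3 x 3")
  if (anyNA(weights) || any(weights <= 0))
    stopf("exudatekit_bad_kernel", "all kernel weights must be positive")
  structure(list(weights = weights, normalize = isTRUE(normalize)),
            class = "smoothing_kernel")
}

#' @rdname smoothing_kernel
#' @export
table2_printed <- function() {
  w <- matrix(c(1/16, 1/8, 1/16,
                1/8,  1/4, 1/8,
                1/16, 1/8, 1/8), nrow = 3, byrow = TRUE)
  smoothing_kernel(w, normalize = FALSE)
}

#' @rdname smoothing_kernel
#' @export
table2_normalized <- function() {
  k <- table2_printed()
  smoothing_kernel(k$weights / sum(k$weights), normalize = TRUE)
}

effective_weights <- function(kernel) {
  if (kernel$normalize) kernel$weights / sum(kernel$weights) else kernel$weights
}

resolve_kernel <- function(kernel) {
  if (inherits(kernel, "smoothing_kernel")) return(kernel)
  if (is.character(kernel))
    return(switch(kernel,
                  table2_printed = table2_printed(),
                  table2_normalized = table2_normalized(),
                  stopf("exudatekit_bad_kernel", "unknown kernel name: %s", kernel)))
  smoothing_kernel(kernel)
}

#' Rescale a fundus image to a working resolution tier
#'
#' Deterministic bilinear resampling (half-pixel centre alignment, no corner
#' alignment) to one of the square working resolutions 240, 360 or 480.
#'
#' @param img a `fundus_image` or raster.
#' @param tier target side length; one of 240, 360, 480.
#' @return a `fundus_image` of size `tier x tier`.
#' @examples
#' img <- fundus_image(array(90L, dim = c(480, 480, 3)))
#' dim(rescale_to_tier(img, 240))
#' @export
rescale_to_tier <- function(img, tier) {
  img <- as_fundus_image(img)
  if (length(tier) != 1L || !tier %in% c(240, 360, 480))
    stopf("exudatekit_bad_tier", "tier must be one of 240, 360, 480 (got %s)",
          paste(tier, collapse = ","))
  tier <- as.integer(tier)
  out <- bilinear_resize(img$pixels, tier, tier)
  fundus_image(out, tier = tier, source_id = img$source_id)
}

# Bilinear resize of an H x W x 3 raster to oh x ow. Sampling uses
# half-pixel centres: src = (dst + 0.5) * scale - 0.5, clamped to the raster.
bilinear_resize <- function(px, oh, ow) {
  d <- dim(px); h <- d[1]; w <- d[2]
  if (oh == h && ow == w) return(px)
  sy <- (seq_len(oh) - 0.5) * h / oh - 0.5
  sx <- (seq_len(ow) - 0.5) * w / ow - 0.5
  sy <- pmin(pmax(sy, 0), h - 1)
  sx <- pmin(pmax(sx, 0), w - 1)
  y0 <- pmin(floor(sy), h - 1); y1 <- pmin(y0 + 1, h - 1)
  x0 <- pmin(floor(sx), w - 1); x1 <- pmin(x0 + 1, w - 1)
  fy <- sy - y0; fx <- sx - x0
  i0 <- as.integer(y0) + 1L; i1 <- as.integer(y1) + 1L
  j0 <- as.integer(x0) + 1L; j1 <- as.integer(x1) + 1L
  out <- array(0L, dim = c(oh, ow, 3L))
  wy0 <- 1 - fy
  wx0m <- matrix(1 - fx, nrow = oh, ncol = ow, byrow = TRUE)
  fxm <- matrix(fx, nrow = oh, ncol = ow, byrow = TRUE)
  for (k in 1:3) {
    ch <- px[, , k]
    top <- ch[i0, j0, drop = FALSE] * wx0m + ch[i0, j1, drop = FALSE] * fxm
    bot <- ch[i1, j0, drop = FALSE] * wx0m + ch[i1, j1, drop = FALSE] * fxm
    out[, , k] <- quantize255(top * wy0 + bot * fy)
  }
  out
}

#' Linear smoothing filter
#'
#' Convolves each RGB channel with a 3 x 3 positive weight window
#' (a weighted running mean). Borders are handled by edge replication so the
#' dark retinal rim is not pulled further down; results are rounded
#' half-away-from-zero and clipped to `[0, 255]`.
#'
#' @param img a `fundus_image` or raster.
#' @param kernel a [smoothing_kernel()], a kernel name
#'   (`"table2_printed"`, `"table2_normalized"`) or a 3 x 3 matrix.
#' @return the smoothed `fundus_image`.
#' @export
smooth_linear <- function(img, kernel = table2_normalized()) {
  img <- as_fundus_image(img)
  kernel <- resolve_kernel(kernel)
  # true convolution: flip the kernel so an impulse reproduces the printed
  # weight layout (the reference kernel is not symmetric)
  w <- effective_weights(kernel)[3:1, 3:1]
  px <- img$pixels
  out <- array(0L, dim = dim(px))
  for (k in 1:3) out[, , k] <- quantize255(correlate3x3(px[, , k], w))
  fundus_image(out, tier = img$tier, source_id = img$source_id)
}

# 3x3 cross-correlation with edge replication, vectorized as a weighted sum
# of shifted views of the padded matrix.
correlate3x3 <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  p <- pad_replicate(m, 1L)
  acc <- matrix(0, h, wd)
  for (dy in -1:1) for (dx in -1:1)
    acc <- acc + w[dy + 2L, dx + 2L] * p[(1:h) + 1L + dy, (1:wd) + 1L + dx, drop = FALSE]
  acc
}

#' Median filter with an optional processing mask
#'
#' Each selected pixel is replaced by the channel-wise median of its
#' `window x window` neighbourhood (edge replication at the borders). When a
#' mask is supplied, only in-mask pixels are rewritten and the window is
#' stratified to in-mask pixels, i.e. the median ignores out-of-mask
#' neighbours; this is how the pipeline confines despeckling to the yellow
#' exudate colour range.
#'
#' @param img a `fundus_image` or raster.
#' @param window odd window side length, at least 3.
#' @param mask optional `H x W` logical matrix of pixels to process; `NULL`
#'   processes the whole image.
#' @return the filtered `fundus_image`.
#' @export
median_filter <- function(img, window = 3L, mask = NULL) {
  img <- as_fundus_image(img)
  if (length(window) != 1L || window < 3L || window %% 2L == 0L)
    stopf("exudatekit_bad_window", "window must be an odd integer >= 3 (got %s)", window)
  window <- as.integer(window)
  d <- dim(img$pixels)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    dim(mask) <- d[1:2]
    if (anyNA(mask)) stopf("exudatekit_bad_mask", "mask must be logical with no NA")
  }
  px <- img$pixels
  out <- px
  r <- (window - 1L) %/% 2L
  sel <- if (is.null(mask)) rep(TRUE, d[1] * d[2]) else as.vector(mask)
  if (!any(sel)) return(img)
  keep <- if (is.null(mask)) NULL else {
    pm <- pad_replicate(mask * 1, r)
    km <- matrix(NA, sum(sel), window^2)
    idx <- 0L
    for (dy in -r:r) for (dx in -r:r) {
      idx <- idx + 1L
      km[, idx] <- pm[(1:d[1]) + r + dy, (1:d[2]) + r + dx][sel] > 0
    }
    km
  }
  for (k in 1:3) {
    p <- pad_replicate(px[, , k], r)
    vals <- matrix(0, sum(sel), window^2)
    idx <- 0L
    for (dy in -r:r) for (dx in -r:r) {
      idx <- idx + 1L
      vals[, idx] <- p[(1:d[1]) + r + dy, (1:d[2]) + r + dx][sel]
    }
    if (!is.null(keep)) vals[!keep] <- NA
    med <- apply(vals, 1L, stats::median, na.rm = TRUE)
    ch <- out[, , k]
    ch[sel] <- as.integer(round_half_away(med))
    out[, , k] <- ch
  }
  fundus_image(out, tier = img$tier, source_id = img$source_id)
}

#' Denoise a fundus image
#'
#' Linear smoothing followed by median filtering, the noise-removal pairing
#' used before segmentation. By default the median stage is restricted to the
#' yellow exudate colour range (the one colour the pipeline cares about);
#' `mask = "full"` applies it everywhere, which is the mode that repairs
#' salt-and-pepper corruption across the whole field of view.
#'
#' @param img a `fundus_image` or raster.
#' @param kernel smoothing kernel, as for [smooth_linear()].
#' @param window odd median window, as for [median_filter()].
#' @param mask `"exudate"` (default; median only on yellow-range pixels),
#'   `"full"`, or an explicit logical matrix.
#' @param spec colour range used when `mask = "exudate"`.
#' @return the denoised `fundus_image`.
#' @examples
#' img <- fundus_image(array(100L, dim = c(16, 16, 3)))
#' denoise(img, mask = "full")
#' @export
denoise <- function(img, kernel = table2_normalized(), window = 3L,
                    mask = c("exudate", "full"), spec = color_range_spec()) {
  img <- as_fundus_image(img)
  sm <- smooth_linear(img, kernel)
  m <- if (is.character(mask)) {
    switch(match.arg(mask),
           exudate = select_exudate_pixels(sm, spec),
           full = NULL)
  } else mask
  median_filter(sm, window = window, mask = m)
}
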