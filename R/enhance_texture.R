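#' 48-bin intensity histogram
#'
#' Summarizes one channel (or luminance) of a fundus image with 48
#' equal-width bins over `[0, 255]`, together with frequencies normalized by
#' the number of pixels. 48 bins keep each bin a small, distinct range of
#' pixel values while staying far coarser than the raw 256-level histogram.
#'
#' @param img a `fundus_image` or raster.
#' @param channel one of `"r"`, `"g"`, `"b"`, `"luminance"` (Rec.601 weights).
#' @return a `histogram_spec`: `n_bins`, integer `counts`, `normalized`
#'   frequencies (summing to 1), and the bin `breaks`.
#' @examples
#' h <- histogram48(fundus_image(array(10L, dim = c(4, 4, 3))))
#' which(h$counts > 0)
#' @export
histogram48 <- function(img, channel = c("luminance", "r", "g", "b")) {
  img <- as_fundus_image(img)
  channel <- match.arg(channel)
  v <- switch(channel,
              r = img$pixels[, , 1], g = img$pixels[, , 2], b = img$pixels[, , 3],
              luminance = 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
                          0.114 * img$pixels[, , 3])
  n_bins <- 48L
  bin <- pmin(floor(v * n_bins / 256), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  structure(list(n_bins = n_bins, counts = counts,
                 normalized = counts / sum(counts),
                 breaks = seq(0, 256, length.out = n_bins + 1L),
                 channel = channel),
            class = "histogram_spec")
}

#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray-level pairs at a fixed pixel
#' offset. Intensities are quantized uniformly into `levels` bins over
#' `[0, 255]` before counting.
#'
#' @param img_gray numeric `H x W` matrix of intensities in `[0, 255]`, or a
#'   `fundus_image` (converted to Rec.601 luminance).
#' @param levels number of gray levels, at least 2 (default 8).
#' @param offset integer `(dy, dx)` displacement, non-zero.
#' @param symmetric if `TRUE`, counts both the offset and its opposite.
#' @param normalize if `TRUE`, entries are divided by the total pair count.
#' @return a `glcm_matrix`: `levels`, `matrix`, `offset`, `n_pairs`.
#' @examples
#' g <- glcm(matrix(c(0, 0, 255, 255), 2, byrow = TRUE), levels = 2, offset = c(0, 1))
#' g$matrix
#' @export
glcm <- function(img_gray, levels = 8L, offset = c(0L, 1L),
                 symmetric = FALSE, normalize = FALSE) {
  if (inherits(img_gray, "fundus_image"))
    img_gray <- 0.299 * img_gray$pixels[, , 1] + 0.587 * img_gray$pixels[, , 2] +
                0.114 * img_gray$pixels[, , 3]
  img_gray <- as.matrix(img_gray)
  if (levels < 2L) stopf("exudatekit_bad_glcm", "levels must be >= 2")
  if (length(offset) != 2L || all(offset == 0L))
    stopf("exudatekit_bad_glcm", "offset must be a non-zero (dy, dx) pair")
  dy <- as.integer(offset[1]); dx <- as.integer(offset[2])
  h <- nrow(img_gray); w <- ncol(img_gray)
  if (abs(dy) >= h || abs(dx) >= w)
    stopf("exudatekit_offset_too_large",
          "offset (%d, %d) exceeds the %d x %d image", dy, dx, h, w)
  q <- pmin(floor(img_gray * levels / 256), levels - 1L)
  rows <- seq_len(h - abs(dy)); cols <- seq_len(w - abs(dx))
  r1 <- if (dy >= 0) rows else rows + abs(dy)
  c1 <- if (dx >= 0) cols else cols + abs(dx)
  from <- q[r1, c1, drop = FALSE]
  to <- q[r1 + dy, c1 + dx, drop = FALSE]
  m <- matrix(0, levels, levels)
  tab <- table(factor(from, levels = 0:(levels - 1L)),
               factor(to, levels = 0:(levels - 1L)))
  m <- m + unclass(tab)
  if (symmetric) m <- m + t(m)
  n_pairs <- sum(m)
  if (normalize) m <- m / n_pairs
  structure(list(levels = as.integer(levels), matrix = m,
                 offset = c(dy, dx), n_pairs = n_pairs,
                 symmetric = symmetric, normalized = normalize),
            class = "glcm_matrix")
}

#' Adaptive histogram equalization
#'
#' Tile-based equalization of the HSV value channel (the image is converted
#' to HSV, the value channel equalized per tile with bilinear blending of
#' tile mappings, then converted back). Tiles with a degenerate (single-bin)
#' histogram map identically, so constant images pass through unchanged.
#'
#' @param img a `fundus_image` or raster.
#' @param tiles tile grid side count, default 8 (an 8 x 8 grid).
#' @return the equalized `fundus_image`.
#' @export
ahe <- function(img, tiles = 8L) {
  img <- as_fundus_image(img)
  hsv <- rgb_to_hsv_array(img$pixels)
  v255 <- hsv[, , 3] * 255
  v_eq <- clahe_channel(v255, clip_limit = Inf, tiles = tiles)
  hsv[, , 3] <- v_eq / 255
  out <- hsv_to_rgb_array(hsv)
  fundus_image(out, tier = img$tier, source_id = img$source_id)
}

#' Contrast-limited AHE with RGB density
#'
#' CLAHE applied independently to each of the R, G and B channels ("RGB
#' density"): tile histograms are clipped at `clip_limit` times the uniform
#' bin height, the excess redistributed uniformly, and per-tile mappings
#' blended bilinearly. Working per channel keeps the yellow exudate colours
#' intact rather than collapsing them to gray or HSV value, which is what
#' makes this variant the preferred enhancement before colour-range
#' selection. As `clip_limit` approaches 0 the mapping tends to the
#' identity.
#'
#' @param img a `fundus_image` or raster.
#' @param clip_limit positive clip factor, default 2 (multiples of the
#'   uniform histogram height).
#' @param tiles tile grid side count, default 8.
#' @return the enhanced `fundus_image`.
#' @examples
#' img <- fundus_image(array(77L, dim = c(16, 16, 3)))
#' identical(clahe_rd(img)$pixels, img$pixels)
#' @export
clahe_rd <- function(img, clip_limit = 2.0, tiles = 8L) {
  img <- as_fundus_image(img)
  if (length(clip_limit) != 1L || !clip_limit > 0)
    stopf("exudatekit_bad_clip", "clip_limit must be positive")
  out <- array(0L, dim = dim(img$pixels))
  for (k in 1:3)
    out[, , k] <- quantize255(clahe_channel(img$pixels[, , k], clip_limit, tiles))
  fundus_image(out, tier = img$tier, source_id = img$source_id)
}

# CLAHE on one channel of values in [0,255]. Returns a real-valued matrix.
# clip_limit = Inf gives plain (unclipped) AHE. Tiles with a single occupied
# histogram bin use the identity mapping.
clahe_channel <- function(ch, clip_limit, tiles = 8L) {
  h <- nrow(ch); w <- ncol(ch)
  tiles <- max(1L, as.integer(tiles))
  ty <- min(tiles, h); tx <- min(tiles, w)
  # tile boundaries (approximately equal tiles covering the image)
  ybreaks <- round(seq(0, h, length.out = ty + 1L))
  xbreaks <- round(seq(0, w, length.out = tx + 1L))
  nb <- 256L
  vq <- pmin(pmax(floor(ch), 0), 255)
  maps <- array(0, dim = c(ty, tx, nb))  # mapping LUT per tile
  centres_y <- numeric(ty); centres_x <- numeric(tx)
  for (i in seq_len(ty)) {
    rows <- (ybreaks[i] + 1L):ybreaks[i + 1L]
    centres_y[i] <- mean(range(rows))
    for (j in seq_len(tx)) {
      cols <- (xbreaks[j] + 1L):xbreaks[j + 1L]
      if (i == 1L) centres_x[j] <- mean(range(cols))
      tile <- vq[rows, cols]
      hist <- tabulate(tile + 1L, nbins = nb)
      n <- sum(hist)
      if (sum(hist > 0L) <= 1L) {  # degenerate tile: identity mapping
        maps[i, j, ] <- 0:(nb - 1L)
        next
      }
      if (is.finite(clip_limit)) {
        clip <- clip_limit * n / nb
        excess <- sum(pmax(hist - clip, 0))
        hist <- pmin(hist, clip) + excess / nb
      }
      cdf <- cumsum(hist) / n
      cdf0 <- cdf[1]
      maps[i, j, ] <- if (cdf0 >= 1) 0:(nb - 1L) else
        (cdf - cdf0) / (1 - cdf0) * (nb - 1L)
    }
  }
  # bilinear blending of the four surrounding tile mappings
  yi <- findInterval(seq_len(h), centres_y)            # lower tile index (0..ty)
  xi <- findInterval(seq_len(w), centres_x)
  y0 <- pmax(yi, 1L); y1 <- pmin(yi + 1L, ty)
  x0 <- pmax(xi, 1L); x1 <- pmin(xi + 1L, tx)
  fy <- ifelse(y1 == y0, 0,
               (seq_len(h) - centres_y[y0]) / (centres_y[y1] - centres_y[y0]))
  fx <- ifelse(x1 == x0, 0,
               (seq_len(w) - centres_x[x0]) / (centres_x[x1] - centres_x[x0]))
  fy <- pmin(pmax(fy, 0), 1); fx <- pmin(pmax(fx, 0), 1)
  out <- matrix(0, h, w)
  lut_at <- function(ti, tj, rows, cols) {
    lut <- maps[ti, tj, ]
    matrix(lut[vq[rows, cols, drop = FALSE] + 1L], length(rows), length(cols))
  }
  # group rows by (y0, y1) tile pair and columns by (x0, x1) pair
  for (i in seq_len(ty)) {
    rsel <- which(y0 == i)
    if (!length(rsel)) next
    for (j in seq_len(tx)) {
      csel <- which(x0 == j)
      if (!length(csel)) next
      m00 <- lut_at(i, j, rsel, csel)
      m01 <- lut_at(i, min(j + 1L, tx), rsel, csel)
      m10 <- lut_at(min(i + 1L, ty), j, rsel, csel)
      m11 <- lut_at(min(i + 1L, ty), min(j + 1L, tx), rsel, csel)
      wy <- fy[rsel]; wx <- fx[csel]
      wxm <- matrix(wx, length(rsel), length(csel), byrow = TRUE)
      top <- m00 * (1 - wxm) + m01 * wxm
      bot <- m10 * (1 - wxm) + m11 * wxm
      out[rsel, csel] <- top * (1 - wy) + bot * wy
    }
  }
  out
}

# HSV helpers: H in [0,1), S,V in [0,1]
rgb_to_hsv_array <- function(px) {
  d <- dim(px)
  m <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(m, maxColorValue = 255)
  out <- array(0, dim = d)
  for (k in 1:3) out[, , k] <- matrix(hsv[k, ], d[1], d[2])
  out
}

hsv_to_rgb_array <- function(hsv) {
  d <- dim(hsv)
  h6 <- as.vector(hsv[, , 1]) * 6
  s <- as.vector(hsv[, , 2]); v <- as.vector(hsv[, , 3])
  i <- floor(h6) %% 6
  f <- h6 - floor(h6)
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  out <- array(0L, dim = d)
  out[, , 1] <- quantize255(matrix(r, d[1], d[2]) * 255)
  out[, , 2] <- quantize255(matrix(g, d[1], d[2]) * 255)
  out[, , 3] <- quantize255(matrix(b, d[1], d[2]) * 255)
  out
}

#' Export a histogram or GLCM to CSV
#'
#' @param x a `histogram_spec` or `glcm_matrix`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_enhance_csv <- function(x, path) {
  if (inherits(x, "histogram_spec")) {
    df <- data.frame(bin = seq_len(x$n_bins), low = x$breaks[-length(x$breaks)],
                     high = x$breaks[-1], count = x$counts,
                     normalized = x$normalized)
    utils::write.csv(df, path, row.names = FALSE)
  } else if (inherits(x, "glcm_matrix")) {
    utils::write.csv(as.data.frame(x$matrix), path, row.names = FALSE)
  } else stopf("exudatekit_bad_export", "cannot export object of class %s", class(x)[1])
  invisible(path)
}
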