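#' Exudate colour range
#'
#' Hard exudates occupy the yellow-orange band from RGB(255,128,0) to
#' RGB(255,178,102). The selection predicate is the per-channel box spanned
#' by those endpoints, widened by `tolerance` on every side: R in
#' `[255 - tol, 255]`, G in `[128 - tol, 178 + tol]`, B in `[0, 102 + tol]`.
#'
#' @param low_rgb,high_rgb endpoint colours (length-3 integer vectors); they
#'   are reordered per channel so `low <= high`.
#' @param tolerance non-negative per-channel slack, default 20.
#' @return a `color_range_spec`.
#' @examples
#' color_range_spec()
#' @export
color_range_spec <- function(low_rgb = c(255L, 128L, 0L),
                             high_rgb = c(255L, 178L, 102L),
                             tolerance = 20L) {
  low <- pmin(low_rgb, high_rgb)
  high <- pmax(low_rgb, high_rgb)
  if (any(low < 0) || any(high > 255))
    stopf("exudatekit_bad_spec", "colour endpoints must lie in [0, 255]")
  if (tolerance < 0) stopf("exudatekit_bad_spec", "tolerance must be >= 0")
  structure(list(low_rgb = as.integer(low), high_rgb = as.integer(high),
                 tolerance = as.integer(tolerance)),
            class = "color_range_spec")
}

#' @export
print.color_range_spec <- function(x, ...) {
  cat(sprintf("<color_range_spec RGB(%s) .. RGB(%s) +/- %d>\n",
              paste(x$low_rgb, collapse = ","),
              paste(x$high_rgb, collapse = ","), x$tolerance))
  invisible(x)
}

#' Select candidate exudate pixels by colour
#'
#' @param img a `fundus_image` or raster.
#' @param spec a [color_range_spec()].
#' @return logical `H x W` matrix; `TRUE` where every channel lies within the
#'   widened box. An all-`FALSE` mask is a valid outcome.
#' @examples
#' img <- fundus_image(array(rep(c(255L, 136L, 0L), each = 25), dim = c(5, 5, 3)))
#' sum(select_exudate_pixels(img))
#' @export
select_exudate_pixels <- function(img, spec = color_range_spec()) {
  img <- as_fundus_image(img)
  lo <- pmax(spec$low_rgb - spec$tolerance, 0L)
  hi <- pmin(spec$high_rgb + spec$tolerance, 255L)
  px <- img$pixels
  px[, , 1] >= lo[1] & px[, , 1] <= hi[1] &
    px[, , 2] >= lo[2] & px[, , 2] <= hi[2] &
    px[, , 3] >= lo[3] & px[, , 3] <= hi[3]
}

#' Extract connected lesion regions from a binary mask
#'
#' Groups `TRUE` pixels into 8-connected components, drops components below
#' `min_pixels`, and annotates each surviving component with its fitted
#' ellipse, area `pi * a * b`, mean colour (when the source image is given)
#' and hard/soft label.
#'
#' @param mask logical `H x W` matrix.
#' @param min_pixels minimum component size, default 5 (ellipse fitting needs
#'   at least 5 pixels).
#' @param img optional source `fundus_image` for mean-colour annotation.
#' @return list of `exudate_region` objects (possibly empty).
#' @export
extract_regions <- function(mask, min_pixels = 5L, img = NULL) {
  mask <- as.matrix(mask)
  labels <- label_components(mask)
  n <- max(labels)
  if (n == 0L) return(list())
  if (!is.null(img)) img <- as_fundus_image(img)
  out <- list()
  for (lab in seq_len(n)) {
    idx <- which(labels == lab)
    if (length(idx) < min_pixels) next
    rows <- ((idx - 1L) %% nrow(mask)) + 1L
    cols <- ((idx - 1L) %/% nrow(mask)) + 1L
    mean_rgb <- if (is.null(img)) c(NA_real_, NA_real_, NA_real_) else
      vapply(1:3, function(k) mean(img$pixels[, , k][idx]), numeric(1))
    reg <- exudate_region(rows, cols, mean_rgb)
    out[[length(out) + 1L]] <- reg
  }
  out
}

# Two-pass style connected-component labelling (8-connectivity) via
# breadth-first flooding over the mask.
label_components <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  labels <- matrix(0L, h, w)
  cur <- 0L
  stack <- integer(h * w)
  todo <- which(mask)
  for (start in todo) {
    if (labels[start] != 0L) next
    cur <- cur + 1L
    top <- 1L
    stack[1L] <- start
    labels[start] <- cur
    while (top > 0L) {
      p <- stack[top]
      top <- top - 1L
      r <- ((p - 1L) %% h) + 1L
      cl <- ((p - 1L) %/% h) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr >= 1L && rr <= h && cc >= 1L && cc <= w) {
          q <- (cc - 1L) * h + rr
          if (mask[q] && labels[q] == 0L) {
            labels[q] <- cur
            top <- top + 1L
            stack[top] <- q
          }
        }
      }
    }
  }
  labels
}

#' Construct an exudate region from pixel coordinates
#'
#' @param rows,cols pixel coordinates (1-based) of the component.
#' @param mean_rgb mean colour of the component, or `NA`s when unknown.
#' @return an `exudate_region` with the second-moment ellipse
#'   (`cx, cy, a, b, theta`, `a >= b`), `area = pi * a * b`, and `kind`
#'   from [classify_exudate_type()] when the colour is known.
#' @export
exudate_region <- function(rows, cols, mean_rgb = c(NA_real_, NA_real_, NA_real_)) {
  if (!length(rows)) stopf("exudatekit_empty_region", "region has no pixels")
  ell <- fit_ellipse_points(rows, cols)
  reg <- structure(list(rows = as.integer(rows), cols = as.integer(cols),
                        n_pixels = length(rows), ellipse = ell,
                        area = unname(pi * ell["a"] * ell["b"]),
                        mean_rgb = as.numeric(mean_rgb), kind = NA_character_),
                   class = "exudate_region")
  if (!anyNA(mean_rgb)) reg$kind <- classify_exudate_type(reg)
  reg
}

#' @export
print.exudate_region <- function(x, ...) {
  cat(sprintf("<exudate_region %d px, centre (%.1f, %.1f), a=%.2f b=%.2f, area %.1f, kind %s>\n",
              x$n_pixels, x$ellipse["cx"], x$ellipse["cy"],
              x$ellipse["a"], x$ellipse["b"], x$area, x$kind))
  invisible(x)
}

#' Fit the second-moment ellipse of a region
#'
#' The ellipse of inertia of the pixel set: centre at the centroid, axis
#' directions from the eigenvectors of the coordinate covariance, and
#' semi-axes `2 * sqrt(eigenvalue)` -- the scaling under which a uniformly
#' filled ellipse recovers its own semi-axes. Degenerate (collinear) sets get
#' a minor semi-axis floored at half a pixel.
#'
#' @param region an `exudate_region`.
#' @return named vector `c(cx, cy, a, b, theta)` with `a >= b > 0`; `theta`
#'   is the major-axis angle in radians measured from the column (x) axis.
#' @examples
#' reg <- exudate_region(rep(1:5, 5), rep(1:5, each = 5))
#' fit_ellipse(reg)
#' @export
fit_ellipse <- function(region) {
  if (!inherits(region, "exudate_region"))
    stopf("exudatekit_bad_region", "fit_ellipse expects an exudate_region")
  region$ellipse
}

fit_ellipse_points <- function(rows, cols) {
  # x = column, y = row: image convention with theta measured from the x axis
  x <- cols; y <- rows
  cx <- mean(x); cy <- mean(y)
  n <- length(x)
  # population covariance + 1/12 pixel-quantization variance keeps single
  # pixels and thin lines away from zero-width ellipses
  vxx <- sum((x - cx)^2) / n + 1 / 12
  vyy <- sum((y - cy)^2) / n + 1 / 12
  vxy <- sum((x - cx) * (y - cy)) / n
  tr <- vxx + vyy
  det <- vxx * vyy - vxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, 0)
  a <- 2 * sqrt(l1)
  b <- max(2 * sqrt(l2), 0.5)
  theta <- if (abs(vxy) < 1e-12 && vxx >= vyy) 0 else atan2(l1 - vxx, vxy)
  c(cx = cx, cy = cy, a = a, b = b, theta = theta)
}

#' Largest elliptical region
#'
#' Scans a region list for the region of maximal ellipse area; ties are
#' broken by larger pixel count, then by the lowest (row, col) centroid so
#' the choice is deterministic.
#'
#' @param regions non-empty list of `exudate_region`s.
#' @return the maximal `exudate_region`.
#' @export
find_max_elliptical_region <- function(regions) {
  if (!length(regions))
    stopf("exudatekit_empty_regions", "region list is empty")
  best <- regions[[1L]]
  for (r in regions[-1L]) {
    if (r$area > best$area ||
        (r$area == best$area && r$n_pixels > best$n_pixels) ||
        (r$area == best$area && r$n_pixels == best$n_pixels &&
         (r$ellipse["cy"] < best$ellipse["cy"] ||
          (r$ellipse["cy"] == best$ellipse["cy"] && r$ellipse["cx"] < best$ellipse["cx"]))))
      best <- r
  }
  best
}

#' Severity assessment from the maximal lesion
#'
#' A candidate is flagged as a medical emergency when the maximal elliptical
#' lesion area strictly exceeds the severity threshold (by default 1% of the
#' field-of-view disc area, see [severity_threshold()]).
#'
#' @param region the maximal `exudate_region`.
#' @param threshold_area positive area threshold in square pixels.
#' @return a `severity_result` with `max_region`, `threshold_area` and the
#'   logical `emergency`.
#' @examples
#' reg <- exudate_region(rep(1:6, 6), rep(1:6, each = 6))
#' assess_severity(reg, threshold_area = 5)
#' @export
assess_severity <- function(region, threshold_area) {
  if (length(threshold_area) != 1L || !is.finite(threshold_area) || threshold_area <= 0)
    stopf("exudatekit_bad_threshold", "threshold_area must be a positive scalar")
  structure(list(max_region = region, threshold_area = threshold_area,
                 emergency = region$area > threshold_area),
            class = "severity_result")
}

#' @export
print.severity_result <- function(x, ...) {
  cat(sprintf("<severity_result area %.1f vs threshold %.1f: %s>\n",
              x$max_region$area, x$threshold_area,
              if (x$emergency) "EMERGENCY" else "below threshold"))
  invisible(x)
}

#' Default severity threshold for an image
#'
#' The minimal concerning lesion size is taken as a fraction (default 1%) of
#' the circular field-of-view area for a square image of side `size`
#' (disc radius `0.48 * size`, matching the synthetic generator's geometry).
#'
#' @param size image side length in pixels.
#' @param fraction fraction of the FOV disc area.
#' @return area threshold in square pixels.
#' @export
severity_threshold <- function(size, fraction = 0.01) {
  fraction * pi * (0.48 * size)^2
}

#' Classify a region as hard or soft exudate
#'
#' Hard exudates are dense and saturated yellow (negligible blue); soft
#' exudates (cotton-wool spots) are whitish pale yellow and may carry a
#' slight blue tinge. The rule: hard iff mean blue is at most `blue_cut` and
#' the colour is saturated (`(max - min) / max` above `sat_cut`); anything
#' paler, bluer or grayer is soft.
#'
#' @param region an `exudate_region` with known `mean_rgb`.
#' @param blue_cut blue-channel ceiling for hard exudates, default 80.
#' @param sat_cut minimum saturation for hard exudates, default 0.3.
#' @return `"hard"` or `"soft"`.
#' @export
classify_exudate_type <- function(region, blue_cut = 80, sat_cut = 0.3) {
  rgb <- region$mean_rgb
  if (anyNA(rgb))
    stopf("exudatekit_no_color", "region has no mean colour; pass img to extract_regions")
  mx <- max(rgb)
  sat <- if (mx <= 0) 0 else (mx - min(rgb)) / mx
  if (rgb[3] <= blue_cut && sat > sat_cut) "hard" else "soft"
}

#' Canny edge mask
#'
#' Optional refinement stage: Sobel gradients on the green channel after
#' Gaussian smoothing, non-maximum suppression and hysteresis thresholding at
#' fractions of the maximum gradient magnitude. Exudate masks may be
#' intersected with a dilation of these edges to keep only colour detections
#' with edge support.
#'
#' @param img a `fundus_image` or raster.
#' @param sigma Gaussian pre-smoothing standard deviation, default 1.
#' @param low,high hysteresis thresholds as fractions of the maximum gradient
#'   magnitude, defaults 0.1 and 0.2.
#' @return logical `H x W` edge mask.
#' @export
canny_edges <- function(img, sigma = 1.0, low = 0.1, high = 0.2) {
  img <- as_fundus_image(img)
  g <- img$pixels[, , 2] / 255
  g <- gaussian_blur(g, sigma)
  sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE)
  sy <- t(sx)
  gx <- correlate3x3(g, sx)
  gy <- correlate3x3(g, sy)
  mag <- sqrt(gx^2 + gy^2)
  if (max(mag) == 0) return(matrix(FALSE, nrow(g), ncol(g)))
  # non-maximum suppression along the quantized gradient direction
  ang <- atan2(gy, gx)
  sector <- (round(ang / (pi / 4)) %% 4)
  h <- nrow(g); w <- ncol(g)
  pm <- pad_replicate(mag, 1L)
  shift <- function(dy, dx) pm[(1:h) + 1L + dy, (1:w) + 1L + dx, drop = FALSE]
  nms <- (sector == 0 & mag >= shift(0, -1) & mag >= shift(0, 1)) |
         (sector == 1 & mag >= shift(-1, 1) & mag >= shift(1, -1)) |
         (sector == 2 & mag >= shift(-1, 0) & mag >= shift(1, 0)) |
         (sector == 3 & mag >= shift(-1, -1) & mag >= shift(1, 1))
  strong <- nms & mag >= high * max(mag)
  weak <- nms & mag >= low * max(mag)
  # hysteresis: keep weak-edge components that touch a strong edge
  labels <- label_components(weak)
  keep <- unique(labels[strong & labels > 0L])
  weak & labels %in% keep
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- k / sum(k)
  p <- pad_replicate(m, r)
  h <- nrow(m); w <- ncol(m)
  tmp <- matrix(0, h, w + 2L * r)
  for (i in seq_along(k)) tmp <- tmp + k[i] * p[(1:h) + r + (i - r - 1L), , drop = FALSE]
  out <- matrix(0, h, w)
  for (i in seq_along(k)) out <- out + k[i] * tmp[, (1:w) + r + (i - r - 1L), drop = FALSE]
  out
}

#' Serialize regions to JSON
#'
#' @param regions list of `exudate_region`s.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_regions_json <- function(regions, path) {
  recs <- lapply(regions, function(r) list(
    cx = unname(r$ellipse["cx"]), cy = unname(r$ellipse["cy"]),
    a = unname(r$ellipse["a"]), b = unname(r$ellipse["b"]),
    theta = unname(r$ellipse["theta"]), area = unname(r$area),
    n_pixels = r$n_pixels, mean_rgb = r$mean_rgb, kind = r$kind))
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
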