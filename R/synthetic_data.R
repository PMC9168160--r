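#' Synthetic fundus configuration
#'
#' The stated world of the generator: a reddish-brown circular retina on a
#' black surround, a bright optic disc, dark curved vessels, `n_hard`
#' saturated-yellow hard-exudate ellipses with colours drawn uniformly from
#' the detection colour box (R = 255, G 128-178, B 0-102), `n_soft`
#' whitish-yellow soft blobs with a blue component of 150-210, plus additive
#' Gaussian grain and salt-and-pepper corruption applied only after ground
#' truth is recorded.
#'
#' @param seed integer seed; every random choice in the generator flows from
#'   it, no global RNG state is consumed or left behind.
#' @param size square canvas side, at least 64 (default 256).
#' @param n_hard,n_soft exudate counts, default 4 and 2.
#' @param hard_color_range list with `g` and `b` ranges for hard colours.
#' @param soft_blue_range blue-channel range of soft exudates.
#' @param noise list with `gaussian_sigma` (default 2, mild sensor grain)
#'   and `salt_pepper_fraction` (default 0.002).
#' @param vessel_count number of vessels, default 5.
#' @param optic_disc draw the optic disc, default `TRUE`.
#' @return a `synth_config`.
#' @export
synth_config <- function(seed = 1L, size = 256L, n_hard = 4L, n_soft = 2L,
                         hard_color_range = list(g = c(128L, 178L), b = c(0L, 102L)),
                         soft_blue_range = c(150L, 210L),
                         noise = list(gaussian_sigma = 2, salt_pepper_fraction = 0.002),
                         vessel_count = 5L, optic_disc = TRUE) {
  if (size < 64L) stopf("exudatekit_bad_config", "size must be >= 64")
  if (n_hard < 0L || n_soft < 0L || vessel_count < 0L)
    stopf("exudatekit_bad_config", "counts must be >= 0")
  structure(list(seed = as.integer(seed), size = as.integer(size),
                 n_hard = as.integer(n_hard), n_soft = as.integer(n_soft),
                 hard_color_range = hard_color_range,
                 soft_blue_range = soft_blue_range,
                 noise = noise, vessel_count = as.integer(vessel_count),
                 optic_disc = isTRUE(optic_disc)),
            class = "synth_config")
}

#' Generate a synthetic fundus image with ground truth
#'
#' @param cfg a [synth_config()].
#' @return list with `image` (a `fundus_image`) and `truth`: `exudate_mask`
#'   (logical raster covering both exudate kinds), `hard_mask`, `soft_mask`,
#'   and `region_records`, a data.frame (cx, cy, a, b, theta, kind, area)
#'   sorted by area descending. Deterministic given `cfg$seed`.
#' @examples
#' out <- generate_fundus(synth_config(seed = 3, size = 96, n_hard = 2))
#' sum(out$truth$exudate_mask) > 0
#' @export
generate_fundus <- function(cfg = synth_config()) {
  with_seed(cfg$seed, generate_fundus_impl(cfg))
}

generate_fundus_impl <- function(cfg) {
  s <- cfg$size
  cx0 <- (s + 1) / 2; cy0 <- (s + 1) / 2
  R <- 0.48 * s
  xm <- matrix(rep(seq_len(s), each = s), s, s)   # column coordinate
  ym <- matrix(rep(seq_len(s), s), s, s)          # row coordinate
  r2 <- (xm - cx0)^2 + (ym - cy0)^2
  fov <- r2 <= R^2
  shade <- 1 - 0.30 * r2 / R^2
  base <- c(168, 72, 46)
  px <- array(0, dim = c(s, s, 3L))
  for (k in 1:3) {
    ch <- base[k] * shade + matrix(runif(s * s, -6, 6), s, s)
    ch[!fov] <- 0
    px[, , k] <- ch
  }
  disc_c <- c(cx0 + 0.36 * R, cy0 - 0.05 * R)  # (x, y)
  disc_r <- 0.07 * s
  if (cfg$optic_disc) {
    d2 <- (xm - disc_c[1])^2 + (ym - disc_c[2])^2
    dm <- d2 <= disc_r^2
    edge <- pmax(1 - d2 / disc_r^2, 0)^0.3
    disc_col <- c(236, 214, 168)
    for (k in 1:3) {
      ch <- px[, , k]
      ch[dm] <- ch[dm] * (1 - edge[dm]) + disc_col[k] * edge[dm]
      px[, , k] <- ch
    }
  }
  # vessels: quadratic curves radiating from the disc centre
  vcol <- c(92, 30, 26)
  for (v in seq_len(cfg$vessel_count)) {
    ang <- runif(1, 0, 2 * pi)
    bend <- runif(1, -0.8, 0.8)
    thick <- runif(1, 1.0, 2.0)
    t <- seq(0, 1, length.out = 4L * s)
    len <- runif(1, 0.8, 1.3) * R
    xa <- disc_c[1] + cos(ang) * t * len + cos(ang + pi / 2) * bend * len * t^2
    ya <- disc_c[2] + sin(ang) * t * len + sin(ang + pi / 2) * bend * len * t^2
    keep <- (xa - cx0)^2 + (ya - cy0)^2 <= (0.97 * R)^2
    xa <- xa[keep]; ya <- ya[keep]
    for (dy in -2:2) for (dx in -2:2) {
      if (dx^2 + dy^2 > thick^2) next
      ri <- pmin(pmax(round(ya) + dy, 1), s)
      ci <- pmin(pmax(round(xa) + dx, 1), s)
      idx <- (ci - 1L) * s + ri
      for (k in 1:3) {
        ch <- px[, , k]
        ch[idx] <- vcol[k]
        px[, , k] <- ch
      }
    }
  }
  # exudates: non-overlapping ellipses inside the FOV, clear of the disc
  kinds <- c(rep("hard", cfg$n_hard), rep("soft", cfg$n_soft))
  placed <- data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
                       b = numeric(0), theta = numeric(0), kind = character(0),
                       area = numeric(0))
  hard_mask <- matrix(FALSE, s, s); soft_mask <- matrix(FALSE, s, s)
  amax <- max(6, 0.05 * s)
  for (kind in kinds) {
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      a <- runif(1, 6, amax)
      b <- runif(1, 0.55 * a, a)
      theta <- runif(1, 0, pi)
      rc <- runif(1, 0, 0.80 * R - a)
      ac <- runif(1, 0, 2 * pi)
      ex <- cx0 + rc * cos(ac); ey <- cy0 + rc * sin(ac)
      if (cfg$optic_disc &&
          sqrt((ex - disc_c[1])^2 + (ey - disc_c[2])^2) < disc_r + a + 3) next
      if (nrow(placed) &&
          any(sqrt((placed$cx - ex)^2 + (placed$cy - ey)^2) < placed$a + a + 3)) next
      ok <- TRUE
      break
    }
    if (!ok)
      stopf("exudatekit_placement",
            "could not place a %s exudate without overlap after 100 attempts", kind)
    col <- if (kind == "hard") {
      c(255,
        round(runif(1, cfg$hard_color_range$g[1], cfg$hard_color_range$g[2])),
        round(runif(1, cfg$hard_color_range$b[1], cfg$hard_color_range$b[2])))
    } else {
      c(250, round(runif(1, 235, 250)),
        round(runif(1, cfg$soft_blue_range[1], cfg$soft_blue_range[2])))
    }
    u <- (xm - ex) * cos(theta) + (ym - ey) * sin(theta)
    w <- -(xm - ex) * sin(theta) + (ym - ey) * cos(theta)
    inside <- (u / a)^2 + (w / b)^2 <= 1
    for (k in 1:3) {
      ch <- px[, , k]
      ch[inside] <- col[k]
      px[, , k] <- ch
    }
    if (kind == "hard") hard_mask <- hard_mask | inside else soft_mask <- soft_mask | inside
    placed <- rbind(placed, data.frame(cx = ex, cy = ey, a = a, b = b,
                                       theta = theta, kind = kind,
                                       area = pi * a * b))
  }
  # noise last, after ground truth is frozen
  sg <- cfg$noise$gaussian_sigma
  if (sg > 0) for (k in 1:3) px[, , k] <- px[, , k] + matrix(rnorm(s * s, 0, sg), s, s)
  f <- cfg$noise$salt_pepper_fraction
  if (f > 0) {
    n_bad <- round(f * s * s)
    if (n_bad > 0) {
      idx <- sample.int(s * s, n_bad)
      val <- sample(c(0, 255), n_bad, replace = TRUE)
      for (k in 1:3) {
        ch <- px[, , k]
        ch[idx] <- val
        px[, , k] <- ch
      }
    }
  }
  img <- fundus_image(quantize255(px), source_id = sprintf("synth-seed%d", cfg$seed))
  ord <- order(placed$area, decreasing = TRUE)
  list(image = img,
       truth = list(exudate_mask = hard_mask | soft_mask,
                    hard_mask = hard_mask, soft_mask = soft_mask,
                    region_records = placed[ord, , drop = FALSE]))
}

#' Generate a balanced labelled patch dataset
#'
#' Plants one structure per grid cell on a retina-textured canvas and crops
#' one patch per cell, so patches never share pixels and the class balance is
#' exact. Classes: `hard_exudate` (yellow ellipse in the hard colour box),
#' `soft_exudate` (whitish-yellow, blue tinge), `other_lesion`
#' (hemorrhage-like dark red blob) and `background` (bare retina texture).
#' Canvas noise follows `cfg$noise` and is applied before cropping (ground
#' truth colours are recorded first).
#'
#' @param cfg a [synth_config()]; `cfg$size` is the canvas side and must be
#'   large enough to host `4 * n_per_class` cells.
#' @param patch_size patch side, at least 16 (default 48).
#' @param n_per_class patches per class, default 50.
#' @return a `patch_dataset`: `x` (list of rasters), `labels` (factor),
#'   `masks` (list of logical structure masks), `boxes` (data.frame of patch
#'   bounding boxes on the canvas), `struct_rgb` (planted colours).
#' @export
generate_patch_dataset <- function(cfg = synth_config(), patch_size = 48L,
                                   n_per_class = 50L) {
  if (patch_size < 16L) stopf("exudatekit_bad_config", "patch_size must be >= 16")
  with_seed(cfg$seed + 1L, generate_patch_impl(cfg, as.integer(patch_size),
                                               as.integer(n_per_class)))
}

generate_patch_impl <- function(cfg, patch_size, n_per_class) {
  cell <- patch_size + 4L
  per_side <- cfg$size %/% cell
  n_need <- 4L * n_per_class
  if (per_side^2 < n_need)
    stopf("exudatekit_capacity",
          "canvas of size %d holds %d patches of size %d; %d requested",
          cfg$size, per_side^2, patch_size, n_need)
  s <- per_side * cell
  base <- c(168, 72, 46)
  px <- array(0, dim = c(s, s, 3L))
  for (k in 1:3) px[, , k] <- base[k] + matrix(runif(s * s, -8, 8), s, s)
  classes <- patch_classes()
  labels <- sample(rep(classes, n_per_class))
  cells <- sample.int(per_side^2, n_need)
  xm <- matrix(rep(seq_len(s), each = s), s, s)
  ym <- matrix(rep(seq_len(s), s), s, s)
  mask_all <- matrix(FALSE, s, s)
  boxes <- data.frame(row0 = integer(n_need), col0 = integer(n_need),
                      size = patch_size)
  struct_rgb <- matrix(NA_real_, n_need, 3L)
  for (i in seq_len(n_need)) {
    cell_r <- (cells[i] - 1L) %/% per_side
    cell_c <- (cells[i] - 1L) %% per_side
    row0 <- cell_r * cell + 3L   # patch occupies rows row0..row0+patch-1
    col0 <- cell_c * cell + 3L
    boxes$row0[i] <- row0; boxes$col0[i] <- col0
    lab <- labels[i]
    if (lab == "background") next
    ecx <- col0 + (patch_size - 1) / 2
    ecy <- row0 + (patch_size - 1) / 2
    a <- runif(1, 6, max(8, patch_size / 5))
    b <- runif(1, 0.55 * a, a)
    theta <- runif(1, 0, pi)
    col <- switch(lab,
      hard_exudate = c(255,
        round(runif(1, cfg$hard_color_range$g[1], cfg$hard_color_range$g[2])),
        round(runif(1, cfg$hard_color_range$b[1], cfg$hard_color_range$b[2]))),
      soft_exudate = c(250, round(runif(1, 235, 250)),
        round(runif(1, cfg$soft_blue_range[1], cfg$soft_blue_range[2]))),
      other_lesion = c(128, round(runif(1, 16, 34)), round(runif(1, 18, 38))))
    struct_rgb[i, ] <- col
    u <- (xm - ecx) * cos(theta) + (ym - ecy) * sin(theta)
    w <- -(xm - ecx) * sin(theta) + (ym - ecy) * cos(theta)
    inside <- (u / a)^2 + (w / b)^2 <= 1
    for (k in 1:3) {
      ch <- px[, , k]
      ch[inside] <- col[k]
      px[, , k] <- ch
    }
    mask_all <- mask_all | inside
  }
  sg <- cfg$noise$gaussian_sigma
  if (sg > 0) for (k in 1:3) px[, , k] <- px[, , k] + matrix(rnorm(s * s, 0, sg), s, s)
  f <- cfg$noise$salt_pepper_fraction
  if (f > 0) {
    n_bad <- round(f * s * s)
    if (n_bad > 0) {
      idx <- sample.int(s * s, n_bad)
      val <- sample(c(0, 255), n_bad, replace = TRUE)
      for (k in 1:3) { ch <- px[, , k]; ch[idx] <- val; px[, , k] <- ch }
    }
  }
  px <- quantize255(px)
  xs <- vector("list", n_need); masks <- vector("list", n_need)
  for (i in seq_len(n_need)) {
    rs <- boxes$row0[i]:(boxes$row0[i] + patch_size - 1L)
    cs <- boxes$col0[i]:(boxes$col0[i] + patch_size - 1L)
    xs[[i]] <- px[rs, cs, , drop = FALSE]
    masks[[i]] <- mask_all[rs, cs]
  }
  structure(list(x = xs, labels = factor(labels, levels = classes),
                 masks = masks, boxes = boxes, struct_rgb = struct_rgb,
                 patch_size = patch_size),
            class = "patch_dataset")
}

#' @export
print.patch_dataset <- function(x, ...) {
  cat(sprintf("<patch_dataset %d patches of %d x %d: %s>\n",
              length(x$x), x$patch_size, x$patch_size,
              paste(sprintf("%s=%d", names(table(x$labels)), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
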