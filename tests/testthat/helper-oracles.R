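# Independent brute-force oracles. These deliberately use the most direct
# (slow) formulation of each operation and share no code with the package.

# true 3x3 convolution (kernel flipped) with edge replication
oracle_convolve3 <- function(m, w) {
  h <- nrow(m); wd <- ncol(m)
  out <- matrix(0, h, wd)
  for (r in seq_len(h)) for (c in seq_len(wd)) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1) {
      rr <- min(max(r + dy, 1), h)
      cc <- min(max(c + dx, 1), wd)
      acc <- acc + w[2 - dy, 2 - dx] * m[rr, cc]
    }
    out[r, c] <- acc
  }
  out
}

# per-window sort-and-pick-middle median with edge replication
oracle_median <- function(m, window, mask = NULL) {
  h <- nrow(m); wd <- ncol(m)
  r0 <- (window - 1) / 2
  out <- m
  for (r in seq_len(h)) for (c in seq_len(wd)) {
    if (!is.null(mask) && !mask[r, c]) next
    vals <- c()
    for (dy in -r0:r0) for (dx in -r0:r0) {
      rr <- min(max(r + dy, 1), h)
      cc <- min(max(c + dx, 1), wd)
      if (is.null(mask) || mask[rr, cc]) vals <- c(vals, m[rr, cc])
    }
    sv <- sort(vals)
    n <- length(sv)
    med <- if (n %% 2 == 1) sv[(n + 1) / 2] else (sv[n / 2] + sv[n / 2 + 1]) / 2
    out[r, c] <- sign(med) * floor(abs(med) + 0.5)
  }
  out
}

# connected components by iterative min-label propagation (8-connectivity)
oracle_component_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  lab[mask] <- seq_len(sum(mask))
  repeat {
    changed <- FALSE
    for (r in seq_len(h)) for (c in seq_len(w)) {
      if (!mask[r, c]) next
      for (dy in -1:1) for (dx in -1:1) {
        rr <- r + dy; cc <- c + dx
        if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] &&
            lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  length(unique(lab[mask]))
}

# nested-loop pair counting for the co-occurrence matrix
oracle_glcm <- function(m, levels, offset) {
  q <- pmin(floor(m * levels / 256), levels - 1)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, levels, levels)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    rr <- r + offset[1]; cc <- c + offset[2]
    if (rr >= 1 && rr <= h && cc >= 1 && cc <= w)
      out[q[r, c] + 1, q[rr, cc] + 1] <- out[q[r, c] + 1, q[rr, cc] + 1] + 1
  }
  out
}

# direct per-pixel bilinear resampler, half-pixel centre convention
oracle_bilinear <- function(px, oh, ow) {
  d <- dim(px); h <- d[1]; w <- d[2]
  out <- array(0L, dim = c(oh, ow, 3))
  for (k in 1:3) for (i in seq_len(oh)) for (j in seq_len(ow)) {
    sy <- min(max((i - 0.5) * h / oh - 0.5, 0), h - 1)
    sx <- min(max((j - 0.5) * w / ow - 0.5, 0), w - 1)
    y0 <- floor(sy); x0 <- floor(sx)
    y1 <- min(y0 + 1, h - 1); x1 <- min(x0 + 1, w - 1)
    fy <- sy - y0; fx <- sx - x0
    v <- px[y0 + 1, x0 + 1, k] * (1 - fy) * (1 - fx) +
         px[y0 + 1, x1 + 1, k] * (1 - fy) * fx +
         px[y1 + 1, x0 + 1, k] * fy * (1 - fx) +
         px[y1 + 1, x1 + 1, k] * fy * fx
    out[i, j, k] <- as.integer(min(max(floor(abs(v) + 0.5) * sign(v), 0), 255))
  }
  out
}

# sequential reference for the geometric-mean pReLU
oracle_gmpr <- function(x, slope = 0.01) {
  p1 <- NA; p2 <- NA
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    if (x[i] > 0) {
      out[i] <- x[i]
      p2 <- p1; p1 <- x[i]
    } else if (!is.na(p1) && !is.na(p2)) {
      out[i] <- sqrt(p1 * p2)
    } else {
      out[i] <- slope * x[i]
    }
  }
  out
}

# convenience: random test raster
random_raster <- function(h, w, seed) {
  set.seed(seed)
  array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3))
}

table8_path <- function() system.file("extdata", "table8_bins.csv", package = "exudatekit")
table9_path <- function() system.file("extdata", "table9_bins.csv", package = "exudatekit")
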