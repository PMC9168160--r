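pixel_img <- function(rgb, n = 5) {
  px <- array(0L, dim = c(n, n, 3))
  for (k in 1:3) px[, , k] <- as.integer(rgb[k])
  fundus_image(px)
}

test_that("select_exudate_pixels accepts the range endpoints and rejects black", {
  spec <- color_range_spec()
  expect_true(all(select_exudate_pixels(pixel_img(c(255, 128, 0)), spec)))
  expect_true(all(select_exudate_pixels(pixel_img(c(255, 178, 102)), spec)))
  expect_false(any(select_exudate_pixels(pixel_img(c(0, 0, 0)), spec)))
  # empty mask is a valid outcome, not an error
  expect_identical(sum(select_exudate_pixels(pixel_img(c(10, 200, 240)), spec)), 0L)
})

test_that("mask cardinality is monotone in tolerance", {
  px <- random_raster(40, 40, 17)
  img <- fundus_image(px)
  sizes <- vapply(c(0L, 10L, 20L, 40L, 80L), function(tol)
    sum(select_exudate_pixels(img, color_range_spec(tolerance = tol))), numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("extract_regions matches hand counts and the flood-fill oracle", {
  m <- matrix(FALSE, 20, 20)
  m[3:7, 3:7] <- TRUE
  regs <- extract_regions(m)
  expect_length(regs, 1L)
  expect_identical(regs[[1]]$n_pixels, 25L)

  m[12:15, 12:16] <- TRUE
  expect_length(extract_regions(m), 2L)

  set.seed(31)
  for (i in 1:5) {
    blob <- matrix(runif(30 * 30) < 0.35, 30, 30)
    got <- length(extract_regions(blob, min_pixels = 1L))
    expect_identical(got, oracle_component_count(blob))
  }
})

test_that("every region's pixels satisfy the colour predicate of its mask", {
  res <- generate_fundus(synth_config(seed = 23, size = 128))
  mask <- select_exudate_pixels(res$image)
  regs <- extract_regions(mask, img = res$image)
  for (r in regs)
    expect_true(all(mask[cbind(r$rows, r$cols)]))
})

test_that("fit_ellipse recovers circles and rasterized ellipses", {
  xm <- matrix(rep(1:61, each = 61), 61, 61)
  ym <- matrix(rep(1:61, 61), 61, 61)
  # filled circle radius 20
  circ <- (xm - 31)^2 + (ym - 31)^2 <= 20^2
  reg <- extract_regions(circ)[[1]]
  e <- fit_ellipse(reg)
  expect_equal(unname(e["a"]), 20, tolerance = 0.10)
  expect_equal(unname(e["b"]), 20, tolerance = 0.10)
  expect_equal(unname(reg$area), pi * 400, tolerance = 0.15)

  # axis-aligned ellipse a=20, b=10: recovered ratio 2 within 10%
  ell <- ((xm - 31) / 20)^2 + ((ym - 31) / 10)^2 <= 1
  e2 <- fit_ellipse(extract_regions(ell)[[1]])
  expect_equal(unname(e2["a"] / e2["b"]), 2, tolerance = 0.10)
  expect_lt(abs(e2["theta"]), 0.1)  # major axis along x

  # area formula: pi * a * b
  reg3 <- exudate_region(rep(1:5, 5), rep(1:5, each = 5))
  expect_equal(unname(reg3$area), pi * reg3$ellipse["a"] * reg3$ellipse["b"],
               ignore_attr = TRUE)

  # degenerate collinear set: minor axis floored, area positive
  line <- exudate_region(rep(4L, 9), 1:9)
  expect_gte(unname(line$ellipse["b"]), 0.5)
  expect_gt(line$area, 0)
})

test_that("find_max_elliptical_region picks the maximum and matches a linear scan", {
  sq <- function(r0, c0, n) {
    m <- matrix(FALSE, 40, 40)
    m[r0:(r0 + n - 1), c0:(c0 + n - 1)] <- TRUE
    extract_regions(m)[[1]]
  }
  regions <- list(sq(1, 1, 3), sq(1, 1, 7), sq(1, 1, 5))
  expect_identical(find_max_elliptical_region(regions)$n_pixels, 49L)
  expect_identical(find_max_elliptical_region(regions[2]), regions[[2]])
  expect_error(find_max_elliptical_region(list()), class = "exudatekit_empty_regions")

  set.seed(77)
  pool <- lapply(1:100, function(i)
    exudate_region(sample(1:50, 8, replace = TRUE), sample(1:50, 8, replace = TRUE)))
  areas <- vapply(pool, function(r) r$area, numeric(1))
  expect_equal(find_max_elliptical_region(pool)$area, pool[[which.max(areas)]]$area)
})

test_that("assess_severity uses a strict comparison and is monotone in threshold", {
  reg <- exudate_region(rep(1:4, 4), rep(1:4, each = 4))
  reg$area <- 10
  expect_true(assess_severity(reg, 5)$emergency)
  reg$area <- 5
  expect_false(assess_severity(reg, 5)$emergency)
  expect_error(assess_severity(reg, 0), class = "exudatekit_bad_threshold")

  set.seed(12)
  lesions <- lapply(1:30, function(i) {
    r <- exudate_region(sample(1:30, 12, replace = TRUE), sample(1:30, 12, replace = TRUE))
    r
  })
  thresholds <- c(1, 5, 10, 20, 50, 100)
  counts <- vapply(thresholds, function(th)
    sum(vapply(lesions, function(r) assess_severity(r, th)$emergency, logical(1))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("classify_exudate_type separates hard, soft and gray means", {
  mk <- function(rgb) {
    r <- exudate_region(1:6, rep(3L, 6), mean_rgb = rgb)
    r
  }
  expect_identical(classify_exudate_type(mk(c(255, 136, 0))), "hard")
  expect_identical(classify_exudate_type(mk(c(255, 255, 204))), "soft")
  expect_identical(classify_exudate_type(mk(c(120, 120, 120))), "soft")
  expect_error(classify_exudate_type(exudate_region(1:6, rep(3L, 6))),
               class = "exudatekit_no_color")
})

test_that("canny_edges outlines a bright blob and respects thresholds", {
  px <- array(30L, dim = c(40, 40, 3))
  xm <- matrix(rep(1:40, each = 40), 40, 40)
  ym <- matrix(rep(1:40, 40), 40, 40)
  blob <- (xm - 20)^2 + (ym - 20)^2 <= 8^2
  for (k in 1:3) { ch <- px[, , k]; ch[blob] <- 220L; px[, , k] <- ch }
  edges <- canny_edges(fundus_image(px))
  expect_gt(sum(edges), 0)
  d2 <- (xm - 20)^2 + (ym - 20)^2
  expect_true(all(abs(sqrt(d2[edges]) - 8) < 3))
  # constant image: no edges
  expect_identical(sum(canny_edges(fundus_image(array(9L, dim = c(20, 20, 3))))), 0L)
})

test_that("regions serialize to JSON and read back", {
  res <- generate_fundus(synth_config(seed = 2, size = 128))
  regs <- extract_regions(select_exudate_pixels(res$image), img = res$image)
  f <- tempfile(fileext = ".json")
  write_regions_json(regs, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_identical(nrow(back), length(regs))
  expect_equal(back$area[1], regs[[1]]$area)
  unlink(f)
})
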