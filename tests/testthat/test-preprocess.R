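test_that("fundus_image validates its invariants", {
  expect_s3_class(fundus_image(array(0L, dim = c(3, 3, 3))), "fundus_image")
  expect_error(fundus_image(array(-1L, dim = c(4, 4, 3))), class = "exudatekit_bad_image")
  expect_error(fundus_image(array(300L, dim = c(4, 4, 3))), class = "exudatekit_bad_image")
  expect_error(fundus_image(array(0L, dim = c(2, 5, 3))), class = "exudatekit_bad_image")
  expect_error(fundus_image(array(0L, dim = c(4, 4, 3)), tier = 100), class = "exudatekit_bad_tier")
  expect_identical(fundus_image(array(5L, dim = c(360, 360, 3)))$tier, 360L)
})

test_that("table2 kernels match the printed weight pattern", {
  w <- table2_printed()$weights
  expect_equal(w, matrix(c(1/16, 1/8, 1/16, 1/8, 1/4, 1/8, 1/16, 1/8, 1/8),
                         nrow = 3, byrow = TRUE))
  expect_equal(sum(w), 17 / 16)
  expect_equal(sum(effective_weights <- table2_normalized()$weights), 1)
  expect_error(smoothing_kernel(matrix(1, 2, 2)), class = "exudatekit_bad_kernel")
  expect_error(smoothing_kernel(matrix(c(-1, rep(1, 8)), 3, 3)),
               class = "exudatekit_bad_kernel")
})

test_that("rescale_to_tier: identity, constant, and bilinear oracle", {
  img360 <- fundus_image(random_raster(360, 360, 1))
  expect_identical(rescale_to_tier(img360, 360)$pixels, img360$pixels)

  const <- fundus_image(array(77L, dim = c(480, 480, 3)))
  down <- rescale_to_tier(const, 240)
  expect_true(all(down$pixels == 77L))
  expect_identical(dim(down$pixels), c(240L, 240L, 3L))

  expect_error(rescale_to_tier(const, 100), class = "exudatekit_bad_tier")

  # checkerboard (and a random raster) against the per-pixel oracle
  cb <- array(0L, dim = c(16, 16, 3))
  cb[, , 1] <- cb[, , 2] <- cb[, , 3] <-
    255L * ((outer(1:16, 1:16, "+") %% 2L))
  for (px in list(cb, random_raster(16, 12, 2))) {
    got <- exudatekit:::bilinear_resize(px, 8L, 8L)
    expect_identical(got, oracle_bilinear(px, 8, 8))
  }
})

test_that("rescale round trip preserves a constant image exactly", {
  const <- fundus_image(array(201L, dim = c(480, 480, 3)))
  back <- exudatekit:::bilinear_resize(rescale_to_tier(const, 240)$pixels, 480L, 480L)
  expect_true(all(back == 201L))
})

test_that("smooth_linear: constant, impulse, and brute-force oracle", {
  const <- fundus_image(array(123L, dim = c(8, 8, 3)))
  expect_identical(smooth_linear(const)$pixels, const$pixels)

  # impulse response reproduces the printed (un-normalized) weights
  imp <- array(0L, dim = c(9, 9, 3))
  imp[5, 5, ] <- 255L
  out <- smooth_linear(fundus_image(imp), table2_printed())$pixels
  expect_identical(out[4:6, 4:6, 1],
                   matrix(as.integer(round(255 * table2_printed()$weights)),
                          3, byrow = FALSE))

  set.seed(42)
  px <- random_raster(16, 16, 42)
  k <- matrix(runif(9, 0.05, 1), 3, 3)
  got <- smooth_linear(fundus_image(px), smoothing_kernel(k, normalize = TRUE))$pixels
  kn <- k / sum(k)
  for (ch in 1:3) {
    want <- oracle_convolve3(px[, , ch], kn)
    want <- pmin(pmax(sign(want) * floor(abs(want) + 0.5), 0), 255)
    expect_equal(got[, , ch], matrix(as.integer(want), 16, 16))
  }
  expect_error(smooth_linear(const, smoothing_kernel(matrix(1, 3, 3))[1]),
               class = "exudatekit_bad_kernel")
})

test_that("normalized smoothing preserves the interior mean within rounding", {
  px <- random_raster(32, 32, 7)
  sm <- smooth_linear(fundus_image(px))$pixels
  for (ch in 1:3)
    expect_lt(abs(mean(sm[5:28, 5:28, ch]) - mean(px[3:30, 3:30, ch])), 2)
})

test_that("median_filter: trivial cases and sorting oracle, with and without mask", {
  const <- fundus_image(array(200L, dim = c(8, 8, 3)))
  expect_identical(median_filter(const, 3)$pixels, const$pixels)

  salt <- array(0L, dim = c(7, 7, 3))
  salt[4, 4, ] <- 255L
  expect_true(all(median_filter(fundus_image(salt), 3)$pixels == 0L))

  expect_error(median_filter(const, 4), class = "exudatekit_bad_window")
  expect_error(median_filter(const, 1), class = "exudatekit_bad_window")

  px <- random_raster(12, 12, 3)
  got <- median_filter(fundus_image(px), 3)$pixels
  for (ch in 1:3)
    expect_equal(got[, , ch], matrix(as.integer(oracle_median(px[, , ch], 3)), 12, 12))

  # stratified (masked) median: only in-mask pixels change, window restricted
  set.seed(9)
  mask <- matrix(runif(144) < 0.4, 12, 12)
  gotm <- median_filter(fundus_image(px), 3, mask = mask)$pixels
  for (ch in 1:3)
    expect_equal(gotm[, , ch],
                 matrix(as.integer(oracle_median(px[, , ch], 3, mask)), 12, 12))
  expect_identical(gotm[, , 1][!mask], px[, , 1][!mask])
})

test_that("median_filter never invents channel values and is idempotent on constants", {
  px <- random_raster(10, 10, 5)
  out <- median_filter(fundus_image(px), 3)$pixels
  for (ch in 1:3)
    expect_true(all(out[, , ch] %in% px[, , ch]))
  const <- fundus_image(array(9L, dim = c(6, 6, 3)))
  expect_identical(median_filter(median_filter(const, 3), 3)$pixels, const$pixels)
})

test_that("denoise composes smoothing and median filtering", {
  px <- random_raster(12, 12, 8)
  img <- fundus_image(px)
  expect_identical(denoise(img, mask = "full")$pixels,
                   median_filter(smooth_linear(img), 3)$pixels)
  const <- fundus_image(array(50L, dim = c(8, 8, 3)))
  expect_identical(denoise(const, mask = "full")$pixels, const$pixels)
})

test_that("denoise reduces the error of a salt-and-pepper corrupted image", {
  clean <- array(0L, dim = c(64, 64, 3))
  for (k in 1:3) clean[, , k] <- as.integer(round(outer(1:64, 1:64,
      function(r, c) 80 + 60 * sin(r / 9) * cos(c / 11))))
  set.seed(21)
  noisy <- clean
  bad <- sample(64 * 64, 300)
  val <- sample(c(0L, 255L), 300, replace = TRUE)
  for (k in 1:3) { ch <- noisy[, , k]; ch[bad] <- val; noisy[, , k] <- ch }
  den <- denoise(fundus_image(noisy), mask = "full")$pixels
  mae <- function(a, b) mean(abs(as.numeric(a) - as.numeric(b)))
  expect_lt(mae(den, clean), mae(noisy, clean))
})

test_that("PPM round trip is lossless for P6 and P3", {
  px <- random_raster(9, 7, 13)
  img <- fundus_image(px)
  for (plain in c(FALSE, TRUE)) {
    f <- tempfile(fileext = ".ppm")
    write_fundus_image(img, f, plain = plain)
    back <- read_fundus_image(f)
    expect_identical(back$pixels, img$pixels)
    unlink(f)
  }
})
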