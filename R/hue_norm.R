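#' Green/red hue-ratio field of a fundus image
#'
#' Hue is taken as the per-pixel ratio of the green to the red channel,
#' `H(i,j) = X_g(i,j) / X_r(i,j)`, with channels first scaled to `[0, 1]`.
#' Pixels whose scaled red value does not exceed the threshold `rT` are
#' excluded (marked invalid) so the ratio never divides by a near-zero red
#' signal; `rT = 0.1` keeps genuinely dark pixels out of the average.
#'
#' @param img a `fundus_image` or raster.
#' @param rT positive red-channel threshold on the `[0, 1]` scale.
#' @return a `hue_field` with elements `H` (ratio matrix, `NA` where
#'   invalid), `valid_mask`, `rT`, `H_des` slot left `NA`, and `Hc_average`,
#'   the mean ratio over valid pixels.
#' @examples
#' img <- fundus_image(array(rep(c(100L, 50L, 0L), each = 9), dim = c(3, 3, 3)))
#' compute_hue(img)$Hc_average  # 0.5
#' @export
compute_hue <- function(img, rT = 0.1) {
  img <- as_fundus_image(img)
  if (length(rT) != 1L || !is.finite(rT) || rT <= 0)
    stopf("exudatekit_bad_rT", "rT must be a positive scalar")
  r <- img$pixels[, , 1] / 255
  g <- img$pixels[, , 2] / 255
  valid <- r > rT
  if (!any(valid))
    stopf("exudatekit_no_red_signal",
          "no red signal: no pixel has red channel above rT = %g", rT)
  H <- matrix(NA_real_, nrow(r), ncol(r))
  H[valid] <- g[valid] / r[valid]
  structure(list(H = H, valid_mask = valid, rT = rT,
                 Hc_average = mean(H[valid])),
            class = "hue_field")
}

#' @export
print.hue_field <- function(x, ...) {
  cat(sprintf("<hue_field %d x %d, %d valid px, Hc_average = %.4f, rT = %g>\n",
              nrow(x$H), ncol(x$H), sum(x$valid_mask), x$Hc_average, x$rT))
  invisible(x)
}

#' Equalize the average hue ratio of an image
#'
#' Iteratively rescales the green channel until the mean green/red ratio over
#' valid pixels matches the target `H_des` (default 0.5160, the common
#' operating point that makes images taken under different illuminants
#' comparable). Each iteration multiplies the green channel of valid pixels by
#' `H_des / Hc_average` and requantizes; absent clipping this converges in a
#' single step, and quantization residuals wash out over the remaining
#' iterations. Red and blue channels are never modified, and invalid (dark
#' red) pixels receive no correction.
#'
#' @param img a `fundus_image` or raster with at least one valid pixel.
#' @param H_des positive target mean hue ratio.
#' @param tol convergence tolerance on `|Hc_average - H_des|`.
#' @param max_iter iteration cap.
#' @param rT red threshold passed to [compute_hue()].
#' @return the adjusted `fundus_image`.
#' @examples
#' img <- fundus_image(array(rep(c(180L, 120L, 40L), each = 64),
#'                           dim = c(8, 8, 3)))
#' out <- equalize_hue(img)
#' compute_hue(out)$Hc_average
#' @export
equalize_hue <- function(img, H_des = 0.5160, tol = 1e-3, max_iter = 50L,
                         rT = 0.1) {
  img <- as_fundus_image(img)
  if (length(H_des) != 1L || !is.finite(H_des) || H_des <= 0)
    stopf("exudatekit_bad_target", "H_des must be a positive scalar")
  px <- img$pixels
  g0 <- px[, , 2] / 255
  # the multiplicative correction accumulates on the original (unquantized)
  # green channel: applying it to the requantized channel instead can stall,
  # since a sub-half-level update rounds away and the iteration fixes itself
  # at the wrong average
  scale <- 1
  for (it in seq_len(max_iter)) {
    hf <- compute_hue(fundus_image(px, tier = img$tier, source_id = img$source_id), rT = rT)
    if (abs(hf$Hc_average - H_des) <= tol)
      return(fundus_image(px, tier = img$tier, source_id = img$source_id))
    scale <- scale * H_des / hf$Hc_average
    g <- g0
    g[hf$valid_mask] <- pmin(pmax(g0[hf$valid_mask] * scale, 0), 1)
    px[, , 2] <- quantize255(g * 255)
  }
  hf <- compute_hue(fundus_image(px), rT = rT)
  if (abs(hf$Hc_average - H_des) <= tol)
    return(fundus_image(px, tier = img$tier, source_id = img$source_id))
  stop(errorCondition(
    sprintf("hue equalization did not converge in %d iterations (last Hc_average = %.6f)",
            max_iter, hf$Hc_average),
    class = c("exudatekit_no_convergence", "exudatekit_error"),
    last_Hc_average = hf$Hc_average))
}
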