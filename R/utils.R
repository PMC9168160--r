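# Shared numeric helpers. Rounding is half-away-from-zero (not R's banker
# rounding) so that channel quantization is symmetric around zero after
# arithmetic on [0,255] rasters.

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

clip255 <- function(x) pmin(pmax(x, 0), 255)

# quantize a real-valued raster back to the integer [0,255] contract
quantize255 <- function(x) {
  y <- round_half_away(x)
  storage.mode(y) <- "integer"
  pmin(pmax(y, 0L), 255L)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All package randomness funnels through this so no global state leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Pad a matrix by `p` pixels of edge replication on every side.
pad_replicate <- function(m, p) {
  ri <- c(rep(1L, p), seq_len(nrow(m)), rep(nrow(m), p))
  ci <- c(rep(1L, p), seq_len(ncol(m)), rep(ncol(m), p))
  m[ri, ci, drop = FALSE]
}

stopf <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "exudatekit_error")))
}
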