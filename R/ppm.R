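# Minimal netpbm PPM support (P3 plain text, P6 binary, maxval 255).
# Kept dependency free so image round trips work without the png package.

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P3", "P6"))
    stopf("exudatekit_io", "not a P3/P6 PPM file: %s", path)

  # header tokens (width, height, maxval) with '#' comments allowed
  tokens <- character(0)
  buf <- character(0)
  in_comment <- FALSE
  while (length(tokens) < 3L) {
    ch <- rawToChar(readBin(con, "raw", 1L))
    if (length(ch) == 0L || ch == "")
      stopf("exudatekit_io", "truncated PPM header: %s", path)
    if (in_comment) {
      if (ch == "\n") in_comment <- FALSE
    } else if (ch == "#") {
      in_comment <- TRUE
    } else if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2]); maxval <- as.integer(tokens[3])
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval <= 0L || maxval > 255L)
    stopf("exudatekit_io", "unsupported PPM header in %s", path)

  n <- 3L * w * h
  vals <- if (magic == "P6") {
    as.integer(readBin(con, "raw", n))
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE, comment.char = "#")
    if (length(v) < n) stopf("exudatekit_io", "truncated P3 payload in %s", path)
    v
  }
  if (length(vals) < n) stopf("exudatekit_io", "truncated PPM payload in %s", path)
  if (maxval != 255L) vals <- as.integer(round_half_away(vals * 255 / maxval))
  # PPM is row-major, channel-interleaved
  px <- array(0L, dim = c(h, w, 3L))
  m <- matrix(vals, nrow = 3L)
  for (k in 1:3) px[, , k] <- matrix(m[k, ], nrow = h, byrow = TRUE)
  px
}

write_ppm <- function(pixels, path, plain = FALSE) {
  d <- dim(pixels)
  h <- d[1]; w <- d[2]
  inter <- integer(3L * w * h)
  for (k in 1:3) inter[seq(k, by = 3L, length.out = w * h)] <- as.integer(t(pixels[, , k]))
  if (plain) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P3", paste(w, h), "255"), con)
    writeLines(paste(inter, collapse = " "), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P6\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(inter), con)
  }
  invisible(path)
}
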