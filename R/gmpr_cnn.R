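#' Geometric-mean parametric ReLU
#'
#' A parametric ReLU variant in which the parameter is derived from the data
#' stream itself. Scanning a sequence of pre-activations in order: positive
#' values pass through unchanged (and update the running pair of the last two
#' positive values); a non-positive value is replaced by the geometric mean
#' `sqrt(p1 * p2)` of the last two positives when both have been seen, and
#' otherwise falls back to leaky behaviour with a tiny slope (default 0.01).
#' The geometric-mean substitute always lies between the two positives it
#' interpolates, so the activation never extrapolates.
#'
#' @param x numeric vector of pre-activations, scanned left to right.
#' @param fallback_slope leak slope used before two positives have been seen.
#' @return numeric vector of activations, same length as `x`.
#' @examples
#' gmpr_prelu(c(4, 9, -1))   # -> 4 9 6
#' gmpr_prelu(c(-5))         # -> -0.05 (no positive history yet)
#' @export
gmpr_prelu <- function(x, fallback_slope = 0.01) {
  if (!length(x)) return(numeric(0))
  if (anyNA(x) || any(is.nan(x)))
    stopf("exudatekit_nan_input", "gmpr_prelu input contains NA/NaN")
  gmpr_forward(x, fallback_slope)$y
}

# Vectorized forward pass; also returns the local gradient mask used in
# backprop (1 on positives, fallback_slope on leaky positions, 0 where the
# geometric-mean substitution applies -- the substitute is treated as a
# constant w.r.t. x).
gmpr_forward <- function(x, fallback_slope = 0.01) {
  pos <- x > 0
  y <- x
  grad <- as.numeric(pos)
  if (!all(pos)) {
    cnt <- cumsum(pos)           # positives seen up to and including here
    pos_idx <- which(pos)
    neg_idx <- which(!pos)
    k <- cnt[neg_idx]            # positives seen strictly before (x<=0 here)
    gm <- k >= 2L
    if (any(gm)) {
      i1 <- pos_idx[k[gm]]
      i2 <- pos_idx[k[gm] - 1L]
      y[neg_idx[gm]] <- sqrt(x[i1] * x[i2])
    }
    if (any(!gm)) {
      y[neg_idx[!gm]] <- fallback_slope * x[neg_idx[!gm]]
      grad[neg_idx[!gm]] <- fallback_slope
    }
  }
  list(y = y, grad = grad)
}

#' CNN configuration
#'
#' The patch classifier: four convolution blocks (3 x 3 convolution with 16
#' feature maps, optional normalization, activation, 2 x 2 max pooling),
#' a 256-unit fully connected layer and a 4-way softmax head. The reference
#' input size is 240 x 240; the desk-scale default is 48 x 48. Input sizes
#' not divisible by 2^4 are zero-padded up to the next multiple.
#'
#' @param input_size square input side, default 48 (reference 240).
#' @param conv_layers number of conv blocks, default 4.
#' @param feature_maps maps per conv layer, default 16.
#' @param pool_kernel max-pool side, default 2.
#' @param fc_units fully connected width, default 256.
#' @param n_classes output classes, default 4.
#' @param activation `"gmpr_prelu"` (default) or `"relu"`.
#' @param use_norm_layers per-map standardization before the activation,
#'   default `TRUE` (speeds convergence).
#' @param fallback_slope leak slope for [gmpr_prelu()].
#' @return a `cnn_config`.
#' @export
cnn_config <- function(input_size = 48L, conv_layers = 4L, feature_maps = 16L,
                       pool_kernel = 2L, fc_units = 256L, n_classes = 4L,
                       activation = c("gmpr_prelu", "relu"),
                       use_norm_layers = TRUE, fallback_slope = 0.01) {
  activation <- match.arg(activation)
  vals <- c(input_size, conv_layers, feature_maps, pool_kernel, fc_units, n_classes)
  if (any(vals < 1))
    stopf("exudatekit_bad_config", "all architecture counts must be positive")
  structure(list(input_size = as.integer(input_size),
                 conv_layers = as.integer(conv_layers),
                 feature_maps = as.integer(feature_maps),
                 pool_kernel = as.integer(pool_kernel),
                 fc_units = as.integer(fc_units),
                 n_classes = as.integer(n_classes),
                 activation = activation,
                 use_norm_layers = isTRUE(use_norm_layers),
                 fallback_slope = fallback_slope),
            class = "cnn_config")
}

#' Class labels of the default four-way patch problem
#' @return character vector of the four class names.
#' @export
patch_classes <- function() c("hard_exudate", "soft_exudate", "other_lesion", "background")

#' Build (initialize) the patch classifier
#'
#' He-uniform initialization of all convolution and fully connected weights,
#' deterministic in `seed`. Geometry (layer sizes, pooling indices) is
#' precomputed here so forward passes are pure matrix work.
#'
#' @param cfg a [cnn_config()].
#' @param seed integer RNG seed for the initialization.
#' @return a `cnn_model`.
#' @examples
#' m <- build_model(cnn_config(input_size = 16L), seed = 1)
#' count_parameters(m)
#' @export
build_model <- function(cfg = cnn_config(), seed = 1L) {
  stride <- cfg$pool_kernel^cfg$conv_layers
  padded <- as.integer(ceiling(cfg$input_size / stride) * stride)
  sizes <- padded / cfg$pool_kernel^(0:cfg$conv_layers)
  chans <- c(3L, rep(cfg$feature_maps, cfg$conv_layers))
  with_seed(seed, {
    conv <- vector("list", cfg$conv_layers)
    for (l in seq_len(cfg$conv_layers)) {
      fan_in <- 9L * chans[l]
      lim <- sqrt(6 / fan_in)
      conv[[l]] <- list(
        W = matrix(runif(fan_in * chans[l + 1L], -lim, lim), fan_in, chans[l + 1L]),
        b = numeric(chans[l + 1L]))
    }
    d_flat <- as.integer(sizes[cfg$conv_layers + 1L]^2 * cfg$feature_maps)
    lim1 <- sqrt(6 / d_flat)
    lim2 <- sqrt(6 / cfg$fc_units)
    fc1 <- list(W = matrix(runif(d_flat * cfg$fc_units, -lim1, lim1), d_flat, cfg$fc_units),
                b = numeric(cfg$fc_units))
    fc2 <- list(W = matrix(runif(cfg$fc_units * cfg$n_classes, -lim2, lim2),
                           cfg$fc_units, cfg$n_classes),
                b = numeric(cfg$n_classes))
  })
  geom <- lapply(seq_len(cfg$conv_layers), function(l) {
    s <- as.integer(sizes[l])
    list(size = s,
         im2col = make_im2col_index(s, s),
         interior = interior_index(s, s),
         pool = make_pool_index(s, s, cfg$pool_kernel))
  })
  structure(list(cfg = cfg, padded = padded, conv = conv, fc1 = fc1, fc2 = fc2,
                 geom = geom, classes = patch_classes()[seq_len(cfg$n_classes)]),
            class = "cnn_model")
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model %dx%d input, %d conv layers x %d maps, fc %d, %d classes, %s, %s params>\n",
              x$cfg$input_size, x$cfg$input_size, x$cfg$conv_layers,
              x$cfg$feature_maps, x$cfg$fc_units, x$cfg$n_classes,
              x$cfg$activation, format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Trainable parameter count
#' @param model a `cnn_model`.
#' @return integer number of weights and biases.
#' @export
count_parameters <- function(model) {
  n <- sum(vapply(model$conv, function(l) length(l$W) + length(l$b), numeric(1)))
  n + length(model$fc1$W) + length(model$fc1$b) +
    length(model$fc2$W) + length(model$fc2$b)
}

# --- geometry helpers: pixel vectors are in row-major scan order ----------

# index matrix (h*w x 9) into the zero-padded (h+2)(w+2) row-major flat,
# giving the 3x3 neighbourhood of every output pixel
make_im2col_index <- function(h, w) {
  pw <- w + 2L
  out <- matrix(0L, h * w, 9L)
  rc <- expand.grid(c = seq_len(w), r = seq_len(h))  # row-major order
  r <- rc$r; c <- rc$c
  k <- 0L
  for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    out[, k] <- (r + dy - 1L) * pw + (c + dx - 1L) + 1L
  }
  out
}

# positions of the interior pixels inside the padded flat
interior_index <- function(h, w) {
  pw <- w + 2L
  rc <- expand.grid(c = seq_len(w), r = seq_len(h))
  rc$r * pw + rc$c + 1L
}

# (h/p * w/p x p^2) index matrix into the row-major input pixel flat
make_pool_index <- function(h, w, p) {
  oh <- h %/% p; ow <- w %/% p
  rc <- expand.grid(c = seq_len(ow), r = seq_len(oh))
  out <- matrix(0L, oh * ow, p * p)
  k <- 0L
  for (dy in seq_len(p)) for (dx in seq_len(p)) {
    k <- k + 1L
    out[, k] <- ((rc$r - 1L) * p + dy - 1L) * w + (rc$c - 1L) * p + dx
  }
  out
}

# activation dispatch on a (npix x maps) matrix, column = feature map,
# rows already in row-major scan order
activate <- function(z, cfg) {
  if (cfg$activation == "relu") {
    y <- pmax(z, 0)
    return(list(y = y, grad = (z > 0) * 1))
  }
  y <- z; grad <- z
  for (m in seq_len(ncol(z))) {
    fw <- gmpr_forward(z[, m], cfg$fallback_slope)
    y[, m] <- fw$y
    grad[, m] <- fw$grad
  }
  list(y = y, grad = grad)
}

# per-map standardization: y = (z - mu) / sqrt(var + eps), per column
norm_forward <- function(z, eps = 1e-5) {
  mu <- colMeans(z)
  zc <- sweep(z, 2L, mu)
  s <- sqrt(colMeans(zc^2) + eps)
  list(y = sweep(zc, 2L, s, "/"), s = s)
}

norm_backward <- function(dy, y, s) {
  m1 <- colMeans(dy)
  m2 <- colMeans(dy * y)
  sweep(dy - matrix(m1, nrow(dy), ncol(dy), byrow = TRUE) -
          y * matrix(m2, nrow(dy), ncol(dy), byrow = TRUE), 2L, s, "/")
}

# forward one sample; x is (npix x 3) in [0,1]-centred units, row-major.
# Returns class probabilities plus the per-layer cache for backprop.
cnn_forward <- function(model, x, keep_cache = FALSE) {
  cfg <- model$cfg
  cache <- list()
  a <- x
  for (l in seq_len(cfg$conv_layers)) {
    g <- model$geom[[l]]
    npad <- (g$size + 2L)^2
    xpad <- matrix(0, npad, ncol(a))
    xpad[g$interior, ] <- a
    cols <- NULL
    for (ch in seq_len(ncol(a)))
      cols <- cbind(cols, matrix(xpad[, ch][g$im2col], nrow(g$im2col), 9L))
    z <- cols %*% model$conv[[l]]$W
    z <- sweep(z, 2L, model$conv[[l]]$b, "+")
    nrm <- NULL
    if (cfg$use_norm_layers) {
      nrm <- norm_forward(z)
      zn <- nrm$y
    } else zn <- z
    act <- activate(zn, cfg)
    # max pool
    pid <- g$pool
    pooled <- act$y[pid[, 1L], , drop = FALSE]
    argmax <- matrix(pid[, 1L], nrow(pid), ncol(pooled))
    for (k in 2:ncol(pid)) {
      cand <- act$y[pid[, k], , drop = FALSE]
      better <- cand > pooled
      pooled[better] <- cand[better]
      am <- matrix(pid[, k], nrow(pid), ncol(pooled))
      argmax[better] <- am[better]
    }
    if (keep_cache)
      cache[[l]] <- list(cols = cols, norm = nrm, act_y = act$y,
                         act_grad = act$grad, argmax = argmax,
                         n_in = nrow(a), c_in = ncol(a))
    a <- pooled
  }
  flat <- as.vector(a)
  h1 <- as.vector(flat %*% model$fc1$W) + model$fc1$b
  act1 <- if (cfg$activation == "relu") list(y = pmax(h1, 0), grad = (h1 > 0) * 1)
          else gmpr_forward(h1, cfg$fallback_slope)
  logits <- as.vector(act1$y %*% model$fc2$W) + model$fc2$b
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  list(probs = p, flat = flat, act1 = act1, cache = cache,
       pooled_dim = dim(a))
}

# accumulate gradients for one sample given the forward cache
cnn_backward <- function(model, fwd, dlogits, grads) {
  cfg <- model$cfg
  grads$fc2$W <- grads$fc2$W + outer(fwd$act1$y, dlogits)
  grads$fc2$b <- grads$fc2$b + dlogits
  dh1 <- as.vector(model$fc2$W %*% dlogits) * fwd$act1$grad
  grads$fc1$W <- grads$fc1$W + outer(fwd$flat, dh1)
  grads$fc1$b <- grads$fc1$b + dh1
  da <- matrix(as.vector(model$fc1$W %*% dh1), fwd$pooled_dim[1], fwd$pooled_dim[2])
  for (l in rev(seq_len(cfg$conv_layers))) {
    g <- model$geom[[l]]
    cc <- fwd$cache[[l]]
    # unpool: route gradient to the argmax positions
    dact <- matrix(0, nrow(cc$act_y), ncol(cc$act_y))
    for (m in seq_len(ncol(dact)))
      dact[cc$argmax[, m], m] <- dact[cc$argmax[, m], m] + da[, m]
    dz <- dact * cc$act_grad
    if (cfg$use_norm_layers)
      dz <- norm_backward(dz, cc$norm$y, cc$norm$s)
    grads$conv[[l]]$W <- grads$conv[[l]]$W + t(cc$cols) %*% dz
    grads$conv[[l]]$b <- grads$conv[[l]]$b + colSums(dz)
    if (l > 1L) {
      dcols <- dz %*% t(model$conv[[l]]$W)
      npad <- (g$size + 2L)^2
      dxpad <- matrix(0, npad, cc$c_in)
      iv <- as.vector(g$im2col)
      for (ch in seq_len(cc$c_in)) {
        block <- dcols[, (ch - 1L) * 9L + (1:9), drop = FALSE]
        acc <- rowsum(as.vector(block), group = iv)
        dxpad[as.integer(rownames(acc)), ch] <- acc[, 1L]
      }
      da <- dxpad[g$interior, , drop = FALSE]
    }
  }
  grads
}

zero_grads <- function(model) {
  list(conv = lapply(model$conv, function(l) list(W = l$W * 0, b = l$b * 0)),
       fc1 = list(W = model$fc1$W * 0, b = model$fc1$b * 0),
       fc2 = list(W = model$fc2$W * 0, b = model$fc2$b * 0))
}

# patch raster (h x w x 3, [0,255]) -> centred (npix x 3) row-major matrix,
# zero-padded to the model's padded input size
prepare_patch <- function(model, patch) {
  if (inherits(patch, "fundus_image")) patch <- patch$pixels
  d <- dim(patch)
  if (length(d) != 3L || d[3] != 3L || d[1] != model$cfg$input_size || d[2] != model$cfg$input_size)
    stopf("exudatekit_bad_patch",
          "patch must be %d x %d x 3 (got %s)", model$cfg$input_size,
          model$cfg$input_size, paste(d, collapse = " x "))
  p <- model$padded
  canvas <- array(0, dim = c(p, p, 3L))
  canvas[seq_len(d[1]), seq_len(d[2]), ] <- patch / 255 - 0.5
  out <- matrix(0, p * p, 3L)
  for (k in 1:3) out[, k] <- as.vector(t(canvas[, , k]))  # row-major scan
  out
}

#' Train the patch classifier
#'
#' Mini-batch Adam on softmax cross-entropy. Deterministic given `seed`
#' (which drives shuffling only; the initialization seed is fixed at
#' [build_model()] time). Emits a per-epoch trace of mean loss and training
#' accuracy, the curve pair usually plotted against epochs.
#'
#' @param model a `cnn_model`.
#' @param patches a `patch_dataset` (see [generate_patch_dataset()]) or a
#'   list with elements `x` (list of `h x w x 3` rasters) and `labels`.
#' @param epochs number of passes over the data.
#' @param seed RNG seed for shuffling.
#' @param lr Adam learning rate.
#' @param batch_size mini-batch size.
#' @return list with `model` (trained) and `trace`
#'   (data.frame: epoch, loss, accuracy).
#' @export
train_model <- function(model, patches, epochs = 15L, seed = 7L,
                        lr = 1e-3, batch_size = 32L) {
  labels <- as.character(patches$labels)
  if (length(unique(labels)) < 2L)
    stopf("exudatekit_single_class", "training data contains a single class")
  unknown <- setdiff(unique(labels), model$classes)
  if (length(unknown))
    stopf("exudatekit_bad_labels", "labels not in model classes: %s",
          paste(unknown, collapse = ", "))
  y <- match(labels, model$classes)
  n <- length(y)
  xs <- lapply(patches$x, function(p) prepare_patch(model, p))
  mstate <- zero_grads(model); vstate <- zero_grads(model)
  t_step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  trace <- data.frame(epoch = integer(0), loss = numeric(0), accuracy = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- with_seed(seed * 1000L + ep, sample.int(n))
    tot_loss <- 0; tot_correct <- 0L
    for (bs in split(ord, ceiling(seq_along(ord) / batch_size))) {
      grads <- zero_grads(model)
      for (i in bs) {
        fwd <- cnn_forward(model, xs[[i]], keep_cache = TRUE)
        p <- fwd$probs
        tot_loss <- tot_loss - log(max(p[y[i]], 1e-12))
        pred <- which.max(p)  # which.max takes the lowest index on ties
        if (pred == y[i]) tot_correct <- tot_correct + 1L
        dlogits <- p
        dlogits[y[i]] <- dlogits[y[i]] - 1
        grads <- cnn_backward(model, fwd, dlogits / length(bs), grads)
      }
      t_step <- t_step + 1L
      upd <- function(w, g, m, v) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^t_step)
        vh <- v / (1 - beta2^t_step)
        list(w = w - lr * mh / (sqrt(vh) + eps), m = m, v = v)
      }
      for (l in seq_along(model$conv)) {
        for (nm in c("W", "b")) {
          u <- upd(model$conv[[l]][[nm]], grads$conv[[l]][[nm]],
                   mstate$conv[[l]][[nm]], vstate$conv[[l]][[nm]])
          model$conv[[l]][[nm]] <- u$w
          mstate$conv[[l]][[nm]] <- u$m; vstate$conv[[l]][[nm]] <- u$v
        }
      }
      for (fc in c("fc1", "fc2")) for (nm in c("W", "b")) {
        u <- upd(model[[fc]][[nm]], grads[[fc]][[nm]],
                 mstate[[fc]][[nm]], vstate[[fc]][[nm]])
        model[[fc]][[nm]] <- u$w
        mstate[[fc]][[nm]] <- u$m; vstate[[fc]][[nm]] <- u$v
      }
    }
    trace <- rbind(trace, data.frame(epoch = ep, loss = tot_loss / n,
                                     accuracy = tot_correct / n))
  }
  list(model = model, trace = trace)
}

#' Classify a patch
#'
#' @param model a trained `cnn_model`.
#' @param patch `input_size x input_size x 3` raster (or `fundus_image`).
#' @return list with `label` (argmax class; ties resolved to the lowest
#'   class index) and the softmax `probs` vector.
#' @export
predict_patch <- function(model, patch) {
  x <- prepare_patch(model, patch)
  p <- cnn_forward(model, x)$probs
  names(p) <- model$classes
  list(label = model$classes[which.max(p)], probs = p)
}

#' Split a patch dataset into train/validation/test subsets
#'
#' Stratified by class so each subset keeps the class balance. The default
#' fractions are 70/15/15; the upstream experiment's printed split counts
#' are internally inconsistent, so the fractions are configurable instead of
#' fixed.
#'
#' @param patches a `patch_dataset` (or list with `x` and `labels`).
#' @param fractions length-3 numeric summing to 1: train, validation, test.
#' @param seed RNG seed for the shuffle.
#' @return named list of three datasets (`train`, `validation`, `test`),
#'   each with `x` and `labels`.
#' @export
split_dataset <- function(patches, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8 || any(fractions < 0))
    stopf("exudatekit_bad_split", "fractions must be 3 non-negative values summing to 1")
  labels <- as.character(patches$labels)
  take <- function(ds, idx) list(x = ds$x[idx], labels = patches$labels[idx])
  parts <- list(train = integer(0), validation = integer(0), test = integer(0))
  with_seed(seed, {
    for (cl in unique(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      n_tr <- round(fractions[1] * n)
      n_va <- round(fractions[2] * n)
      parts$train <- c(parts$train, idx[seq_len(n_tr)])
      parts$validation <- c(parts$validation, idx[n_tr + seq_len(min(n_va, n - n_tr))])
      parts$test <- c(parts$test, idx[setdiff(seq_len(n), seq_len(n_tr + n_va))])
    }
  })
  lapply(parts, function(idx) take(patches, idx))
}

#' Save or load a trained model
#'
#' Models are plain R lists; persistence is R serialization.
#'
#' @param model a `cnn_model`.
#' @param path file path.
#' @return `save_model` returns `path` invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cnn_model"))
    stopf("exudatekit_bad_model", "%s does not contain a cnn_model", path)
  m
}

#' Write a training trace to CSV
#' @param trace the `trace` data.frame from [train_model()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}
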