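#' Configuration of the miniature residual encoder-decoder
#'
#' The trainable "collaborator" model is a deliberately small 2-level
#' encoder-decoder with residual blocks and an additive skip connection,
#' producing per-voxel class scores over (background, NCR, ED, ET). It is a
#' desk-scale analogue of the residual U-Nets used for full-resolution brain
#' tumor segmentation: one residual block per level, 2x2 mean-pool
#' downsampling, nearest-neighbor upsampling, and a 1x1 output convolution.
#'
#' @param width Channels per hidden layer (positive integer, default 4).
#' @param n_channels Input channels (default 4: T1, T1-Gd, T2, FLAIR).
#' @param geometry 2-D grid shape with even dims >= 4 (default `c(32, 32)`).
#' @param seed Initialization seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(width = 4L, n_channels = 4L, geometry = c(32, 32),
                         seed = 1L) {
  width <- as.integer(width)
  if (width < 1) stop("width must be >= 1")
  if (length(geometry) != 2L) {
    stop("incompatible geometry: the trainable model is 2-D")
  }
  if (any(geometry %% 2 != 0) || any(geometry < 4)) {
    stop("incompatible geometry: dims must be even and >= 4 for pooling")
  }
  structure(list(width = width, n_channels = as.integer(n_channels),
                 n_classes = 4L, geometry = as.integer(geometry),
                 seed = as.integer(seed)),
            class = "model_config")
}

model_layout <- function(config) {
  w <- config$width
  ci <- config$n_channels
  nc <- config$n_classes
  list(
    enc_conv   = c(3L, 3L, ci, w), enc_b      = w,
    enc_res    = c(3L, 3L, w, w),  enc_res_b  = w,
    bott_res   = c(3L, 3L, w, w),  bott_res_b = w,
    dec_res    = c(3L, 3L, w, w),  dec_res_b  = w,
    out_conv   = c(w, nc),         out_b      = nc
  )
}

#' Build an initialized parameter vector
#'
#' Model parameters live in a single flat numeric vector plus a layout (ordered
#' tensor names and shapes), the object exchanged between simulated
#' collaborators and the aggregator. Any two vectors built from the same config
#' can be combined linearly and folded back losslessly. Initialization is
#' He-scaled Gaussian for convolution kernels and zero for biases,
#' deterministic in `config$seed`.
#'
#' @param config A [model_config()].
#' @return An object of class `model_params` with fields `values` (flat numeric
#'   vector), `layout`, and `config`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  layout <- model_layout(config)
  values <- with_stream(derive_seed(config$seed, "init"), {
    unlist(lapply(names(layout), function(nm) {
      shp <- layout[[nm]]
      if (length(shp) == 1L) {
        numeric(shp) # bias
      } else {
        fan_in <- prod(shp[-length(shp)])
        stats::rnorm(prod(shp), 0, sqrt(2 / fan_in))
      }
    }), use.names = FALSE)
  })
  new_model_params(values, layout, config)
}

new_model_params <- function(values, layout, config) {
  structure(list(values = values, layout = layout, config = config),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", length(x$values), " parameters, width ",
      x$config$width, ", grid ", paste(x$config$geometry, collapse = "x"),
      "\n", sep = "")
  invisible(x)
}

# Fold the flat vector into named tensors.
fold_params <- function(params) {
  layout <- params$layout
  sizes <- vapply(layout, prod, numeric(1))
  stopifnot(length(params$values) == sum(sizes))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  tensors <- vector("list", length(layout))
  names(tensors) <- names(layout)
  for (i in seq_along(layout)) {
    v <- params$values[starts[i]:ends[i]]
    shp <- layout[[i]]
    tensors[[i]] <- if (length(shp) == 1L) v else array(v, dim = shp)
  }
  tensors
}

# Flatten named tensors back to a vector in layout order.
unfold_params <- function(tensors, layout) {
  unlist(lapply(names(layout), function(nm) as.vector(tensors[[nm]])),
         use.names = FALSE)
}

#' Sizes of the tensors in a parameter layout
#'
#' @param params A `model_params`.
#' @return Named integer vector: number of scalars per tensor, in layout order.
#' @export
layout_sizes <- function(params) {
  vapply(params$layout, function(shp) as.integer(prod(shp)), integer(1))
}

# ---- network primitives (2-D, channels-last arrays HxWxC) ------------------

conv3 <- function(x, W, b) {
  dims <- dim(x)
  H <- dims[1]; Wd <- dims[2]; ci <- dims[3]; co <- dim(W)[4]
  xp <- array(0, dim = c(H + 2L, Wd + 2L, ci))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  out <- array(0, dim = c(H, Wd, co))
  for (oc in seq_len(co)) {
    acc <- matrix(b[oc], H, Wd)
    for (ic in seq_len(ci)) {
      for (di in 1:3) {
        for (dj in 1:3) {
          wgt <- W[di, dj, ic, oc]
          if (wgt != 0) {
            acc <- acc + wgt * xp[di:(di + H - 1), dj:(dj + Wd - 1), ic]
          }
        }
      }
    }
    out[, , oc] <- acc
  }
  out
}

conv3_input_grad <- function(g, W) {
  dims <- dim(g)
  H <- dims[1]; Wd <- dims[2]; co <- dims[3]; ci <- dim(W)[3]
  gxp <- array(0, dim = c(H + 2L, Wd + 2L, ci))
  for (ic in seq_len(ci)) {
    acc <- matrix(0, H + 2L, Wd + 2L)
    for (oc in seq_len(co)) {
      gg <- g[, , oc]
      for (di in 1:3) {
        for (dj in 1:3) {
          wgt <- W[di, dj, ic, oc]
          if (wgt != 0) {
            acc[di:(di + H - 1), dj:(dj + Wd - 1)] <-
              acc[di:(di + H - 1), dj:(dj + Wd - 1)] + wgt * gg
          }
        }
      }
    }
    gxp[, , ic] <- acc
  }
  gxp[2:(H + 1), 2:(Wd + 1), , drop = FALSE]
}

conv3_weight_grad <- function(x, g) {
  dims <- dim(x)
  H <- dims[1]; Wd <- dims[2]; ci <- dims[3]; co <- dim(g)[3]
  xp <- array(0, dim = c(H + 2L, Wd + 2L, ci))
  xp[2:(H + 1), 2:(Wd + 1), ] <- x
  gW <- array(0, dim = c(3L, 3L, ci, co))
  gb <- numeric(co)
  for (oc in seq_len(co)) {
    gg <- g[, , oc]
    gb[oc] <- sum(gg)
    for (ic in seq_len(ci)) {
      for (di in 1:3) {
        for (dj in 1:3) {
          gW[di, dj, ic, oc] <-
            sum(xp[di:(di + H - 1), dj:(dj + Wd - 1), ic] * gg)
        }
      }
    }
  }
  list(W = gW, b = gb)
}

pool2 <- function(x) {
  d <- dim(x)
  (x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
   x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
   x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]) / 4
}

up2 <- function(x) {
  d <- dim(x)
  out <- array(0, dim = c(2L * d[1], 2L * d[2], d[3]))
  ri <- rep(seq_len(d[1]), each = 2)
  ci <- rep(seq_len(d[2]), each = 2)
  out[, , ] <- x[ri, ci, , drop = FALSE]
  out
}

# Per-case, per-channel z-score normalization, the standard input transform
# of segmentation pipelines; makes training robust to site intensity shifts.
znorm_image <- function(x) {
  for (ch in seq_len(dim(x)[3])) {
    v <- x[, , ch]
    x[, , ch] <- (v - mean(v)) / (stats::sd(v) + 1e-8)
  }
  x
}

# Forward pass; returns logits and, optionally, the cache for backprop.
# Input images are z-scored per channel before entering the network.
model_forward <- function(tensors, x, keep_cache = FALSE) {
  x <- znorm_image(x)
  a0 <- conv3(x, tensors$enc_conv, tensors$enc_b)
  x0 <- pmax(a0, 0)
  a1 <- conv3(x0, tensors$enc_res, tensors$enc_res_b)
  x1 <- pmax(x0 + a1, 0)
  d <- pool2(x1)
  a2 <- conv3(d, tensors$bott_res, tensors$bott_res_b)
  bt <- pmax(d + a2, 0)
  u <- up2(bt)
  s <- u + x1
  a3 <- conv3(s, tensors$dec_res, tensors$dec_res_b)
  y <- pmax(s + a3, 0)
  d2 <- dim(y)
  ymat <- matrix(y, ncol = d2[3])
  zmat <- ymat %*% tensors$out_conv
  zmat <- sweep(zmat, 2, tensors$out_b, `+`)
  z <- array(zmat, dim = c(d2[1], d2[2], ncol(zmat)))
  if (!keep_cache) return(list(logits = z))
  list(logits = z,
       cache = list(x = x, x0 = x0, x1 = x1, d = d, bt = bt, s = s, y = y))
}

# Backward pass from dLoss/dlogits; returns gradients as a tensor list.
model_backward <- function(tensors, cache, gz) {
  dz <- dim(gz)
  gzmat <- matrix(gz, ncol = dz[3])
  ymat <- matrix(cache$y, ncol = dim(cache$y)[3])
  g_out_conv <- t(ymat) %*% gzmat
  g_out_b <- colSums(gzmat)
  gy <- array(gzmat %*% t(tensors$out_conv), dim = dim(cache$y))

  g_pre3 <- gy * (cache$y > 0)
  gw3 <- conv3_weight_grad(cache$s, g_pre3)
  gs <- g_pre3 + conv3_input_grad(g_pre3, tensors$dec_res)

  gu <- gs
  d <- dim(gu)
  gbt <- (gu[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
          gu[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE] +
          gu[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE] +
          gu[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE])

  g_pre2 <- gbt * (cache$bt > 0)
  gw2 <- conv3_weight_grad(cache$d, g_pre2)
  gd <- g_pre2 + conv3_input_grad(g_pre2, tensors$bott_res)
  gx1 <- gs + up2(gd) / 4 # skip branch + pool branch

  g_pre1 <- gx1 * (cache$x1 > 0)
  gw1 <- conv3_weight_grad(cache$x0, g_pre1)
  gx0 <- g_pre1 + conv3_input_grad(g_pre1, tensors$enc_res)

  g_a0 <- gx0 * (cache$x0 > 0)
  gw0 <- conv3_weight_grad(cache$x, g_a0)

  list(enc_conv = gw0$W, enc_b = gw0$b,
       enc_res = gw1$W, enc_res_b = gw1$b,
       bott_res = gw2$W, bott_res_b = gw2$b,
       dec_res = gw3$W, dec_res_b = gw3$b,
       out_conv = g_out_conv, out_b = g_out_b)
}

# ---- loss: cross-entropy + soft Dice (1:1), per-voxel multiclass ------------

model_classes <- c(0L, 1L, 2L, 4L)

softmax3 <- function(z) {
  nk <- dim(z)[3]
  zmax <- z[, , 1]
  for (k in 2:nk) zmax <- pmax(zmax, z[, , k])
  e <- z
  tot <- array(0, dim = dim(z)[1:2])
  for (k in 1:nk) {
    e[, , k] <- exp(z[, , k] - zmax)
    tot <- tot + e[, , k]
  }
  for (k in 1:nk) e[, , k] <- e[, , k] / tot
  e
}

onehot_labels <- function(labels, n_classes = 4L) {
  cls <- match(labels$values, model_classes)
  t <- array(0, dim = c(dim(labels$values), n_classes))
  for (k in seq_len(n_classes)) {
    t[, , k] <- as.numeric(cls == k)
  }
  t
}

# Loss and dLoss/dlogits for one case. Cross-entropy plus (1 - mean soft Dice
# over the three foreground classes), equal weighting.
seg_loss <- function(logits, target, with_grad = FALSE, eps = 1) {
  nk <- dim(logits)[3]
  zmax <- logits[, , 1]
  for (k in 2:nk) zmax <- pmax(zmax, logits[, , k])
  tot <- array(0, dim = dim(logits)[1:2])
  for (k in 1:nk) tot <- tot + exp(logits[, , k] - zmax)
  p <- logits
  for (k in 1:nk) p[, , k] <- exp(logits[, , k] - zmax) / tot
  nvox <- prod(dim(p)[1:2])
  # cross-entropy through the log-softmax identity, stable under saturation
  logtot <- log(tot)
  ce <- 0
  for (k in 1:nk) {
    ce <- ce - sum(target[, , k] * (logits[, , k] - zmax - logtot))
  }
  ce <- ce / nvox

  fg <- 2:4
  S <- P <- Tt <- numeric(4)
  for (k in fg) {
    S[k] <- sum(p[, , k] * target[, , k])
    P[k] <- sum(p[, , k])
    Tt[k] <- sum(target[, , k])
  }
  dice_k <- (2 * S[fg] + eps) / (P[fg] + Tt[fg] + eps)
  loss <- ce + (1 - mean(dice_k))
  if (!with_grad) return(list(loss = loss))

  gp <- array(0, dim = dim(p))
  for (j in seq_along(fg)) {
    k <- fg[j]
    denom <- (P[k] + Tt[k] + eps)
    gp[, , k] <- -(2 * target[, , k] * denom - (2 * S[k] + eps)) / denom^2 / 3
  }
  # through softmax: dL/dz_k = p_k (g_k - sum_j g_j p_j), plus the CE shortcut
  dot <- array(0, dim = dim(p)[1:2])
  for (k in 1:4) dot <- dot + gp[, , k] * p[, , k]
  gz <- array(0, dim = dim(p))
  for (k in 1:4) {
    gz[, , k] <- p[, , k] * (gp[, , k] - dot) + (p[, , k] - target[, , k]) / nvox
  }
  list(loss = loss, grad = gz)
}

#' Predict a label map from a trained model
#'
#' Runs the forward pass and takes the per-voxel argmax over the four classes,
#' mapped back to the \{0, 1, 2, 4\} label convention. The special
#' [oracle_model()] returns the case's reference labels (used to test metric
#' and ranking code independently of training).
#'
#' @param params A `model_params` or `oracle_model`.
#' @param case A case (list with `image` and `labels`) as produced by
#'   [generate_site()].
#' @return A [label_map()].
#' @export
predict_labels <- function(params, case) {
  if (inherits(params, "oracle_model")) {
    return(case$labels)
  }
  tensors <- fold_params(params)
  z <- model_forward(tensors, case$image)$logits
  cls <- max.col(matrix(z, ncol = dim(z)[3]), ties.method = "first")
  label_map(array(model_classes[cls], dim = dim(z)[1:2]))
}

#' A perfect-oracle stand-in model
#'
#' Behaves like a model whose predictions equal the reference labels of every
#' case. Useful for testing metrics, convergence scoring and ranking without
#' training a real model.
#'
#' @return An object of classes `oracle_model` and `model_params`.
#' @export
oracle_model <- function() {
  structure(list(values = numeric(0), layout = list(), config = NULL),
            class = c("oracle_model", "model_params"))
}
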