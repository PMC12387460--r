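# Minimal CPU neural-network kernel: layers as mutable environments holding
# parameter arrays, gradients and caches; forward/backward via S3 dispatch.
# Activations are stored channel-fastest as [C, H, W, N] so that per-channel
# broadcasting is plain vector recycling and im2col feeds a single BLAS GEMM.
# Everything here is validated against finite-difference gradients in the
# test suite.

new_nn_layer <- function(class, fields = list()) {
  e <- new.env(parent = emptyenv())
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  if (is.null(e$shapes)) e$shapes <- list()
  if (is.null(e$modules)) e$modules <- list()
  e$params <- list()
  e$grads <- list()
  class(e) <- c(class, "nn_layer")
  e
}

nn_forward <- function(layer, x, training = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dout) UseMethod("nn_backward")

# All param-bearing layer environments in a module tree.
nn_collect <- function(layer) {
  out <- list()
  if (inherits(layer, "nn_layer")) {
    if (length(layer$shapes) > 0) out <- list(layer)
    for (m in layer$modules) out <- c(out, nn_collect(m))
  } else if (is.list(layer)) {
    for (m in layer) out <- c(out, nn_collect(m))
  }
  out
}

nn_param_count <- function(layer) {
  sum(vapply(nn_collect(layer), function(l) {
    sum(vapply(l$shapes, prod, numeric(1)))
  }, numeric(1)))
}

# Materialize parameter arrays for every layer (consumes the active RNG
# stream, so wrap in with_seed for determinism).
nn_materialize <- function(layer) {
  for (l in nn_collect(layer)) {
    if (isTRUE(l$materialized)) next
    l$params <- l$init_fn(l)
    l$materialized <- TRUE
  }
  invisible(layer)
}

nn_zero_grads <- function(layer) {
  for (l in nn_collect(layer)) {
    l$grads <- lapply(l$params, function(p) array(0, dim = dim_or_len(p)))
  }
  invisible(layer)
}

dim_or_len <- function(p) if (is.null(dim(p))) length(p) else dim(p)

kaiming_uniform <- function(shape, fan_in) {
  b <- sqrt(6 / fan_in)
  array(runif(prod(shape), -b, b), dim = shape)
}

# ---- sequential container ---------------------------------------------------

nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1 && is.list(layers[[1]]) && !inherits(layers[[1]], "nn_layer")) {
    layers <- layers[[1]]
  }
  new_nn_layer("nn_sequential", list(modules = layers))
}

#' @export
nn_forward.nn_sequential <- function(layer, x, training = FALSE) {
  for (m in layer$modules) x <- nn_forward(m, x, training)
  x
}

#' @export
nn_backward.nn_sequential <- function(layer, dout) {
  for (m in rev(layer$modules)) dout <- nn_backward(m, dout)
  dout
}

# ---- convolution ------------------------------------------------------------

nn_conv <- function(c_in, c_out, k, stride = 1, pad = (k - 1) %/% 2,
                    bias = FALSE) {
  shapes <- list(W = c(c_in * k * k, c_out))
  if (bias) shapes$b <- c_out
  new_nn_layer("nn_conv", list(
    c_in = c_in, c_out = c_out, k = k, stride = stride, pad = pad,
    use_bias = bias, shapes = shapes, idx_cache = list(),
    init_fn = function(l) {
      p <- list(W = kaiming_uniform(l$shapes$W, fan_in = l$c_in * l$k * l$k))
      if (l$use_bias) p$b <- numeric(l$c_out)
      p
    }
  ))
}

conv_geometry <- function(h, w, k, stride, pad) {
  h <- unname(h); w <- unname(w)
  c(ho = (h + 2 * pad - k) %/% stride + 1L,
    wo = (w + 2 * pad - k) %/% stride + 1L)
}

# im2col linear index for one sample of a padded [C, Hp, Wp] array; rows are
# ordered channel-fastest then kernel row then kernel column, matching the
# weight storage.
im2col_index <- function(c_in, hp, wp, k, stride, ho, wo) {
  rvec <- as.vector(outer(outer(seq_len(c_in), (0:(k - 1)) * c_in, "+"),
                          (0:(k - 1)) * c_in * hp, "+"))
  cvec <- as.vector(outer((0:(ho - 1)) * stride * c_in,
                          (0:(wo - 1)) * stride * c_in * hp, "+"))
  outer(rvec, cvec, "+")
}

pad_chw <- function(x, pad, fill = 0) {
  if (pad == 0) return(x)
  d <- dim(x)
  xp <- array(fill, dim = c(d[1], d[2] + 2 * pad, d[3] + 2 * pad, d[4]))
  xp[, pad + seq_len(d[2]), pad + seq_len(d[3]), ] <- x
  xp
}

#' @export
nn_forward.nn_conv <- function(layer, x, training = FALSE) {
  d <- dim(x)
  stopifnot(d[1] == layer$c_in)
  n <- d[4]
  g <- conv_geometry(d[2], d[3], layer$k, layer$stride, layer$pad)
  xp <- pad_chw(x, layer$pad)
  dp <- dim(xp)
  key <- paste(dp, collapse = "x")
  idx <- layer$idx_cache[[key]]
  if (is.null(idx)) {
    idx1 <- im2col_index(layer$c_in, dp[2], dp[3], layer$k, layer$stride,
                         g["ho"], g["wo"])
    per <- dp[1] * dp[2] * dp[3]
    idx <- rep(as.vector(idx1), times = n) +
      rep((0:(n - 1)) * per, each = length(idx1))
    layer$idx_cache[[key]] <- idx
  }
  patches <- matrix(xp[idx], nrow = layer$c_in * layer$k * layer$k)
  out <- crossprod(layer$params$W, patches)
  if (layer$use_bias) out <- out + layer$params$b
  dim(out) <- c(layer$c_out, unname(g["ho"]), unname(g["wo"]), n)
  if (training) {
    layer$cache <- list(patches = patches, in_dim = d, padded_dim = dp, geom = g)
  }
  out
}

#' @export
nn_backward.nn_conv <- function(layer, dout) {
  cc <- layer$cache
  n <- cc$in_dim[4]
  dmat <- matrix(dout, nrow = layer$c_out)
  layer$grads$W <- tcrossprod(cc$patches, dmat)
  if (layer$use_bias) layer$grads$b <- rowSums(dmat)
  dpatches <- layer$params$W %*% dmat
  k <- layer$k; s <- layer$stride; c_in <- layer$c_in
  ho <- cc$geom["ho"]; wo <- cc$geom["wo"]
  dxp <- array(0, dim = cc$padded_dim)
  for (kw in seq_len(k)) {
    wpos <- kw + s * (0:(wo - 1))
    for (kh in seq_len(k)) {
      block <- ((kw - 1) * k + (kh - 1)) * c_in + seq_len(c_in)
      part <- dpatches[block, , drop = FALSE]
      dim(part) <- c(c_in, ho, wo, n)
      hpos <- kh + s * (0:(ho - 1))
      dxp[, hpos, wpos, ] <- dxp[, hpos, wpos, , drop = FALSE] + part
    }
  }
  layer$cache <- NULL
  p <- layer$pad
  if (p > 0) {
    dxp <- dxp[, p + seq_len(cc$in_dim[2]), p + seq_len(cc$in_dim[3]), ,
               drop = FALSE]
  }
  dim(dxp) <- cc$in_dim
  dxp
}

# ---- batch normalization ----------------------------------------------------

nn_batchnorm <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_nn_layer("nn_batchnorm", list(
    channels = channels, eps = eps, momentum = momentum,
    running_mean = numeric(channels), running_var = rep(1, channels),
    shapes = list(gamma = channels, beta = channels),
    init_fn = function(l) list(gamma = rep(1, l$channels),
                               beta = numeric(l$channels))
  ))
}

#' @export
nn_forward.nn_batchnorm <- function(layer, x, training = FALSE) {
  d <- dim(x)
  if (training) {
    xm <- matrix(x, nrow = d[1])
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
      layer$momentum * mu
    layer$running_var <- (1 - layer$momentum) * layer$running_var +
      layer$momentum * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  istd <- 1 / sqrt(v + layer$eps)
  xhat <- (x - mu) * istd # channel-fastest recycling
  out <- xhat * layer$params$gamma + layer$params$beta
  dim(out) <- d
  if (training) layer$cache <- list(xhat = xhat, istd = istd, d = d)
  out
}

#' @export
nn_backward.nn_batchnorm <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$d
  m <- prod(d) / d[1]
  dm <- matrix(dout, nrow = d[1])
  xh <- matrix(cc$xhat, nrow = d[1])
  layer$grads$gamma <- rowSums(dm * xh)
  layer$grads$beta <- rowSums(dm)
  mean_d <- rowMeans(dm)
  mean_dx <- rowMeans(dm * xh)
  dx <- (layer$params$gamma * cc$istd) *
    (dout - mean_d - cc$xhat * mean_dx)
  dim(dx) <- d
  layer$cache <- NULL
  dx
}

# ---- relu -------------------------------------------------------------------

nn_relu <- function() new_nn_layer("nn_relu", list())

#' @export
nn_forward.nn_relu <- function(layer, x, training = FALSE) {
  mask <- x > 0
  if (training) layer$cache <- mask
  x * mask
}

#' @export
nn_backward.nn_relu <- function(layer, dout) {
  dx <- dout * layer$cache
  layer$cache <- NULL
  dx
}

# ---- max pooling ------------------------------------------------------------

nn_maxpool <- function(k = 3, stride = 2, pad = 1) {
  new_nn_layer("nn_maxpool", list(k = k, stride = stride, pad = pad))
}

#' @export
nn_forward.nn_maxpool <- function(layer, x, training = FALSE) {
  d <- dim(x)
  g <- conv_geometry(d[2], d[3], layer$k, layer$stride, layer$pad)
  xp <- pad_chw(x, layer$pad, fill = -Inf)
  k <- layer$k; s <- layer$stride
  best <- array(-Inf, dim = c(d[1], unname(g["ho"]), unname(g["wo"]), d[4]))
  arg <- array(1L, dim = dim(best))
  for (kw in seq_len(k)) {
    wpos <- kw + s * (0:(g["wo"] - 1))
    for (kh in seq_len(k)) {
      hpos <- kh + s * (0:(g["ho"] - 1))
      slice <- xp[, hpos, wpos, , drop = FALSE]
      dim(slice) <- dim(best)
      upd <- slice > best
      best[upd] <- slice[upd]
      arg[upd] <- (kw - 1L) * k + kh
    }
  }
  if (training) {
    layer$cache <- list(arg = arg, in_dim = d, padded_dim = dim(xp), geom = g)
  }
  best
}

#' @export
nn_backward.nn_maxpool <- function(layer, dout) {
  cc <- layer$cache
  k <- layer$k; s <- layer$stride
  dxp <- array(0, dim = cc$padded_dim)
  for (kw in seq_len(k)) {
    wpos <- kw + s * (0:(cc$geom["wo"] - 1))
    for (kh in seq_len(k)) {
      hpos <- kh + s * (0:(cc$geom["ho"] - 1))
      contrib <- dout * (cc$arg == (kw - 1L) * k + kh)
      dxp[, hpos, wpos, ] <- dxp[, hpos, wpos, , drop = FALSE] + contrib
    }
  }
  p <- layer$pad
  if (p > 0) {
    dxp <- dxp[, p + seq_len(cc$in_dim[2]), p + seq_len(cc$in_dim[3]), ,
               drop = FALSE]
  }
  dim(dxp) <- cc$in_dim
  layer$cache <- NULL
  dxp
}

# ---- global average pooling: [C,H,W,N] -> [C,N] -----------------------------

nn_gap <- function() new_nn_layer("nn_gap", list())

gap_forward_raw <- function(x) {
  d <- dim(x)
  hw <- d[2] * d[3]
  xt <- aperm(array(x, dim = c(d[1], hw, d[4])), c(1, 3, 2))
  rowSums(xt, dims = 2) / hw
}

#' @export
nn_forward.nn_gap <- function(layer, x, training = FALSE) {
  if (training) layer$cache <- dim(x)
  gap_forward_raw(x)
}

gap_backward_raw <- function(dout, d) {
  hw <- d[2] * d[3]
  dxt <- array(rep(as.vector(dout) / hw, times = hw), dim = c(d[1], d[4], hw))
  dx <- aperm(dxt, c(1, 3, 2))
  dim(dx) <- d
  dx
}

#' @export
nn_backward.nn_gap <- function(layer, dout) {
  d <- layer$cache
  layer$cache <- NULL
  gap_backward_raw(dout, d)
}

# ---- linear (on [features, N] matrices) -------------------------------------

nn_linear <- function(n_in, n_out, bias = TRUE) {
  shapes <- list(W = c(n_out, n_in))
  if (bias) shapes$b <- n_out
  new_nn_layer("nn_linear", list(
    n_in = n_in, n_out = n_out, use_bias = bias, shapes = shapes,
    init_fn = function(l) {
      p <- list(W = kaiming_uniform(l$shapes$W, fan_in = l$n_in))
      if (l$use_bias) p$b <- numeric(l$n_out)
      p
    }
  ))
}

#' @export
nn_forward.nn_linear <- function(layer, x, training = FALSE) {
  x <- as.matrix(x)
  out <- layer$params$W %*% x
  if (layer$use_bias) out <- out + layer$params$b
  if (training) layer$cache <- x
  out
}

#' @export
nn_backward.nn_linear <- function(layer, dout) {
  layer$grads$W <- tcrossprod(dout, layer$cache)
  if (layer$use_bias) layer$grads$b <- rowSums(dout)
  dx <- crossprod(layer$params$W, dout)
  layer$cache <- NULL
  dx
}

# ---- softmax + cross-entropy ------------------------------------------------

softmax_cols <- function(logits) {
  z <- logits - apply(logits, 2, max)[col(logits)]
  ez <- exp(z)
  ez / rep(colSums(ez), each = nrow(ez))
}

# labels: integer vector in 1..K; returns list(loss, probs, dlogits)
softmax_ce <- function(logits, labels) {
  n <- ncol(logits)
  p <- softmax_cols(logits)
  ix <- cbind(labels, seq_len(n))
  pick <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(pick, 1e-12)))
  dl <- p
  dl[ix] <- dl[ix] - 1
  list(loss = loss, probs = p, dlogits = dl / n)
}

# ---- Adam optimizer ---------------------------------------------------------

adam_state <- function(model, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  list(layers = nn_collect(model), lr = lr, beta1 = beta1, beta2 = beta2,
       eps = eps, weight_decay = weight_decay, t = 0, m = list(), v = list())
}

adam_step <- function(opt, lr = NULL) {
  if (is.null(lr)) lr <- opt$lr
  opt$t <- opt$t + 1
  b1 <- opt$beta1; b2 <- opt$beta2
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  for (i in seq_along(opt$layers)) {
    l <- opt$layers[[i]]
    key <- as.character(i)
    if (is.null(opt$m[[key]])) {
      opt$m[[key]] <- lapply(l$params, function(p) p * 0)
      opt$v[[key]] <- lapply(l$params, function(p) p * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      if (is.null(g)) next
      g <- g + opt$weight_decay * l$params[[nm]]
      opt$m[[key]][[nm]] <- b1 * opt$m[[key]][[nm]] + (1 - b1) * g
      opt$v[[key]][[nm]] <- b2 * opt$v[[key]][[nm]] + (1 - b2) * g * g
      mh <- opt$m[[key]][[nm]] / bc1
      vh <- opt$v[[key]][[nm]] / bc2
      l$params[[nm]] <- l$params[[nm]] - lr * mh / (sqrt(vh) + opt$eps)
    }
  }
  opt
}

# ---- finite-difference gradient check (test helper) -------------------------

numeric_grad <- function(fn, x, h = 1e-5) {
  g <- array(0, dim = dim_or_len(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (fn(xp) - fn(xm)) / (2 * h)
  }
  g
}
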