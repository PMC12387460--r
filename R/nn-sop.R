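# Differentiable second-order pooling for the network internals.
#
# Forward: center features, trace-normalize the covariance, run the coupled
# Newton-Schulz iteration, post-compensate by sqrt(tr C). Two routes compute
# the same quantity:
#   direct: iterate on the d x d normalized covariance (used when N >= d);
#   gram:   when the number of spatial positions N is smaller than d, iterate
#           on the N x N normalized Gram matrix G = B^T B (B the centered,
#           scaled features) and reconstruct the square root as
#           sqrt(tr C) * B * G^(-1/2) * B^T, using the M-iterate of the
#           coupled scheme (which converges to G^(-1/2)).
# Backward: hand-derived matrix-product chain rule through every step,
# validated by finite differences in the tests.

SOP_TRACE_EPS <- 1e-12

ns_iterate_raw <- function(a, n_iter) {
  d <- nrow(a)
  id <- diag(d)
  ys <- vector("list", n_iter + 1)
  ms <- vector("list", n_iter + 1)
  ys[[1]] <- a
  ms[[1]] <- id
  if (n_iter > 0) {
    for (i in seq_len(n_iter)) {
      t3 <- 3 * id - ms[[i]] %*% ys[[i]]
      ys[[i + 1]] <- ys[[i]] %*% t3 / 2
      ms[[i + 1]] <- t3 %*% ms[[i]] / 2
    }
  }
  list(ys = ys, ms = ms)
}

# Backward through the coupled iteration. g_y / g_m are gradients w.r.t. the
# final Y_n / M_n; returns gradient w.r.t. Y_0 (= the normalized input).
ns_backward_raw <- function(it, g_y, g_m = NULL) {
  n <- length(it$ys) - 1
  if (is.null(g_m)) g_m <- matrix(0, nrow(g_y), ncol(g_y))
  if (n == 0) return(g_y)
  for (i in n:1) {
    a <- it$ys[[i]]; b <- it$ms[[i]]
    ta <- t(a); tb <- t(b)
    new_gy <- 1.5 * g_y - 0.5 * (g_y %*% ta %*% tb + tb %*% ta %*% g_y) -
      0.5 * tb %*% g_m %*% tb
    new_gm <- 1.5 * g_m - 0.5 * (g_m %*% tb %*% ta + ta %*% tb %*% g_m) -
      0.5 * ta %*% g_y %*% ta
    g_y <- new_gy
    g_m <- new_gm
  }
  g_y # gradient w.r.t. Y_0; M_0 = I carries no gradient
}

# Forward SOP transform of one feature matrix [d, N]; returns the
# post-compensated square root S [d, d] plus a cache for the backward pass.
sop_fwd <- function(fmat, n_iter = 5) {
  d <- nrow(fmat)
  n <- ncol(fmat)
  fc <- fmat - rowMeans(fmat)
  tr <- sum(fc * fc) / n
  if (!is.finite(tr) || tr <= SOP_TRACE_EPS) {
    return(list(S = matrix(0, d, d), cache = list(degenerate = TRUE, d = d, n = n)))
  }
  use_gram <- n < d
  if (use_gram) {
    bhat <- fc / sqrt(n * tr)
    ghat <- crossprod(bhat)
    it <- ns_iterate_raw(ghat, n_iter)
    minv <- it$ms[[n_iter + 1]]
    msym <- (minv + t(minv)) / 2
    bm <- bhat %*% msym
    s <- sqrt(tr) * tcrossprod(bm, bhat)
    cache <- list(degenerate = FALSE, route = "gram", fc = fc, tr = tr,
                  n = n, bhat = bhat, it = it, msym = msym)
  } else {
    chat <- tcrossprod(fc) / (n * tr)
    it <- ns_iterate_raw(chat, n_iter)
    y <- it$ys[[n_iter + 1]]
    s <- sqrt(tr) * y
    cache <- list(degenerate = FALSE, route = "direct", fc = fc, tr = tr,
                  n = n, chat = chat, it = it, y = y)
  }
  list(S = s, cache = cache)
}

# Backward: gradient of a scalar loss w.r.t. the input feature matrix, given
# the gradient ds w.r.t. the emitted S.
sop_bwd <- function(cache, ds) {
  if (isTRUE(cache$degenerate)) {
    return(matrix(0, cache$d, cache$n))
  }
  tr <- cache$tr
  n <- cache$n
  fc <- cache$fc
  st <- sqrt(tr)
  if (cache$route == "direct") {
    y <- cache$y
    g_y <- st * ds
    dt <- 0.5 / st * sum(ds * y)
    dchat <- ns_backward_raw(cache$it, g_y)
    dfc <- (dchat + t(dchat)) %*% fc / (n * tr)
    dt <- dt - sum(dchat * cache$chat) / tr
  } else {
    bhat <- cache$bhat
    msym <- cache$msym
    bm <- bhat %*% msym
    dt <- 0.5 / st * sum(ds * tcrossprod(bm, bhat))
    dmsym <- st * crossprod(bhat, ds) %*% bhat
    dm <- (dmsym + t(dmsym)) / 2
    dbhat <- st * (ds + t(ds)) %*% bm
    dghat <- ns_backward_raw(cache$it, g_y = matrix(0, n, n), g_m = dm)
    dbhat <- dbhat + bhat %*% (dghat + t(dghat))
    dt <- dt - 0.5 / tr * sum(dbhat * bhat)
    dfc <- dbhat / sqrt(n * tr)
  }
  dfc <- dfc + dt * 2 * fc / n
  dfc - rowMeans(dfc)
}

# ---- SOP vectorization layer: [C,H,W,N] -> [C^2, N] -------------------------

nn_sop_vec <- function(n_iter = 5) {
  new_nn_layer("nn_sop_vec", list(n_iter = n_iter))
}

#' @export
nn_forward.nn_sop_vec <- function(layer, x, training = FALSE) {
  d <- dim(x)
  ch <- d[1]; nb <- d[4]
  out <- matrix(0, ch * ch, nb)
  caches <- if (training) vector("list", nb) else NULL
  for (i in seq_len(nb)) {
    fmat <- matrix(x[, , , i], nrow = ch)
    r <- sop_fwd(fmat, layer$n_iter)
    out[, i] <- as.vector(r$S)
    if (training) caches[[i]] <- r$cache
  }
  if (training) layer$cache <- list(caches = caches, in_dim = d)
  out
}

#' @export
nn_backward.nn_sop_vec <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$in_dim
  ch <- d[1]
  dx <- array(0, dim = d)
  for (i in seq_len(d[4])) {
    ds <- matrix(dout[, i], ch, ch)
    dfm <- sop_bwd(cc$caches[[i]], ds)
    dx[, , , i] <- array(dfm, dim = d[1:3])
  }
  layer$cache <- NULL
  dx
}

# ---- broadcast helpers ------------------------------------------------------

# multiply x [C,H,W,N] by per-(channel, sample) scales s [C,N]
scale_cn <- function(x, s) {
  d <- dim(x)
  hw <- d[2] * d[3]
  sarr <- aperm(array(s, dim = c(d[1], d[4], hw)), c(1, 3, 2))
  dim(sarr) <- d
  x * sarr
}

# sum over spatial of x*y per (channel, sample): returns [C, N]
reduce_cn <- function(x) {
  d <- dim(x)
  gap_forward_raw(x) * (d[2] * d[3])
}

# ---- SE module (network version, with backprop) -----------------------------

nn_se_module <- function(channels, reduction = 16) {
  hidden <- max(channels %/% reduction, 1L)
  new_nn_layer("nn_se_module", list(
    channels = channels, hidden = hidden,
    shapes = list(W1 = c(hidden, channels), W2 = c(channels, hidden)),
    init_fn = function(l) list(
      W1 = kaiming_uniform(l$shapes$W1, fan_in = l$channels),
      W2 = kaiming_uniform(l$shapes$W2, fan_in = l$hidden)
    )
  ))
}

#' @export
nn_forward.nn_se_module <- function(layer, x, training = FALSE) {
  z <- gap_forward_raw(x)                      # [C, N]
  h <- layer$params$W1 %*% z
  hm <- h > 0
  h <- h * hm
  s <- sigmoid(layer$params$W2 %*% h)          # [C, N]
  out <- scale_cn(x, s)
  if (training) layer$cache <- list(x = x, z = z, h = h, hm = hm, s = s)
  out
}

#' @export
nn_backward.nn_se_module <- function(layer, dout) {
  cc <- layer$cache
  d <- dim(cc$x)
  ds <- reduce_cn(dout * cc$x)                 # [C, N]
  dx <- scale_cn(dout, cc$s)
  dsig <- ds * cc$s * (1 - cc$s)
  layer$grads$W2 <- tcrossprod(dsig, cc$h)
  dh <- crossprod(layer$params$W2, dsig) * cc$hm
  layer$grads$W1 <- tcrossprod(dh, cc$z)
  dz <- crossprod(layer$params$W1, dh)
  dx + gap_backward_raw(dz, d)
  }

# ---- intermediate DFE module ------------------------------------------------
# Gates between a second-order branch (per-channel energies diag(S^1/2)
# broadcast as channel scales) and a squeeze-excitation branch, per sample.

nn_dfe_intermediate <- function(channels, tau = 0.5, mode = "hard",
                                se_reduction = 16, n_iter = 5) {
  se <- nn_se_module(channels, se_reduction)
  new_nn_layer("nn_dfe", list(
    channels = channels, tau = tau, mode = mode, n_iter = n_iter,
    reg_coeff = 0, # set by the trainer: lambda / n_gates
    modules = list(se = se),
    shapes = list(W_d = c(channels, channels), b_d = channels),
    # zero init: balanced start, alpha = 0.5 exactly
    init_fn = function(l) list(W_d = matrix(0, l$channels, l$channels),
                               b_d = numeric(l$channels))
  ))
}

#' @export
nn_forward.nn_dfe <- function(layer, x, training = FALSE) {
  d <- dim(x)
  ch <- d[1]; nb <- d[4]
  z_desc <- gap_forward_raw(x)                         # [C, N]
  zg <- layer$params$W_d %*% z_desc + layer$params$b_d # [C, N]
  alpha <- sigmoid(colMeans(zg))                       # [N]
  soft <- identical(layer$mode, "soft")
  use_sop <- if (soft) rep(TRUE, nb) else alpha > layer$tau
  se_out <- nn_forward(layer$modules$se, x, training)
  out <- array(0, dim = d)
  sop_caches <- vector("list", nb)
  qs <- vector("list", nb)
  for (i in seq_len(nb)) {
    a <- alpha[i]
    xi <- x[, , , i, drop = FALSE]
    if (use_sop[i]) {
      r <- sop_fwd(matrix(xi, nrow = ch), layer$n_iter)
      q <- diag(r$S)
      sop_caches[[i]] <- r$cache
      qs[[i]] <- q
      scaled <- xi * as.numeric(q)
      out[, , , i] <- if (soft) {
        a * scaled + (1 - a) * se_out[, , , i, drop = FALSE]
      } else {
        a * scaled + (1 - a) * xi
      }
    } else {
      out[, , , i] <- (1 - a) * se_out[, , , i, drop = FALSE] + a * xi
    }
  }
  layer$last_alpha <- alpha
  if (training) {
    layer$cache <- list(x = x, d = d, alpha = alpha, use_sop = use_sop,
                        se_out = se_out, sop_caches = sop_caches, qs = qs,
                        z_desc = z_desc, soft = soft)
  }
  out
}

#' @export
nn_backward.nn_dfe <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$d
  ch <- d[1]; nb <- d[4]
  dx <- array(0, dim = d)
  dse <- array(0, dim = d)
  dalpha <- numeric(nb)
  for (i in seq_len(nb)) {
    a <- cc$alpha[i]
    gi <- dout[, , , i, drop = FALSE]
    xi <- cc$x[, , , i, drop = FALSE]
    if (cc$use_sop[i]) {
      q <- cc$qs[[i]]
      scaled <- xi * as.numeric(q)
      other <- if (cc$soft) cc$se_out[, , , i, drop = FALSE] else xi
      dalpha[i] <- sum(gi * (scaled - other))
      # through the scaled term
      dxi <- a * gi * as.numeric(q)
      dq <- a * rowSums(matrix(gi * xi, nrow = ch))
      ds <- matrix(0, ch, ch)
      diag(ds) <- dq
      dfm <- sop_bwd(cc$sop_caches[[i]], ds)
      dxi <- dxi + array(dfm, dim = dim(xi))
      if (cc$soft) {
        dse[, , , i] <- (1 - a) * gi
      } else {
        dxi <- dxi + (1 - a) * gi
      }
      dx[, , , i] <- dx[, , , i, drop = FALSE] + dxi
    } else {
      hi <- cc$se_out[, , , i, drop = FALSE]
      dalpha[i] <- sum(gi * (xi - hi))
      dse[, , , i] <- (1 - a) * gi
      dx[, , , i] <- dx[, , , i, drop = FALSE] + a * gi
    }
  }
  # balance regularizer: d/dalpha of (reg_coeff / N) * sum (alpha - 0.5)^2
  if (layer$reg_coeff != 0) {
    dalpha <- dalpha + (layer$reg_coeff / nb) * 2 * (cc$alpha - 0.5)
  }
  dx <- dx + nn_backward(layer$modules$se, dse)
  dzbar <- dalpha * cc$alpha * (1 - cc$alpha)
  dzg <- matrix(rep(dzbar / ch, each = ch), nrow = ch)
  layer$grads$W_d <- tcrossprod(dzg, cc$z_desc)
  layer$grads$b_d <- rowSums(dzg)
  dz_desc <- crossprod(layer$params$W_d, dzg)
  dx <- dx + gap_backward_raw(dz_desc, d)
  layer$cache <- NULL
  dx
}

# ---- classification head ----------------------------------------------------
# Parallel paths after the final feature map H (already SE-refined upstream):
#   SOP path:   1x1 conv reduction (+BN+ReLU) -> S^(1/2) -> flatten  [dd^2, N]
#   descriptor: GAP -> excitation e = sigmoid(W2 relu(W1 s)) -> e * s
#               -> learned linear lift to dd^2                       [dd^2, N]
# fused by the gate alpha = sigmoid(mean(W_dh s + b_dh)) per sample:
#   soft (default): alpha * v_sop + (1 - alpha) * v_se
#   hard: same combination on the SOP branch, pure v_se on the SENet branch.

nn_head <- function(channels, sop_dim, se_reduction = 16, tau = 0.5,
                    mode = "soft", n_iter = 5) {
  hidden <- max(channels %/% se_reduction, 1L)
  new_nn_layer("nn_head", list(
    channels = channels, sop_dim = sop_dim, hidden = hidden,
    tau = tau, mode = mode, reg_coeff = 0,
    modules = list(
      reduce = nn_conv(channels, sop_dim, k = 1, stride = 1, pad = 0),
      reduce_bn = nn_batchnorm(sop_dim),
      reduce_relu = nn_relu(),
      sop = nn_sop_vec(n_iter),
      lift = nn_linear(channels, sop_dim^2, bias = TRUE)
    ),
    shapes = list(W1e = c(hidden, channels), W2e = c(channels, hidden),
                  W_dh = c(channels, channels), b_dh = channels),
    init_fn = function(l) list(
      W1e = kaiming_uniform(l$shapes$W1e, fan_in = l$channels),
      W2e = kaiming_uniform(l$shapes$W2e, fan_in = l$hidden),
      W_dh = matrix(0, l$channels, l$channels),
      b_dh = numeric(l$channels)
    )
  ))
}

#' @export
nn_forward.nn_head <- function(layer, x, training = FALSE) {
  d <- dim(x)
  ch <- d[1]; nb <- d[4]
  s_c <- gap_forward_raw(x)                              # [C, N]
  # gate
  zg <- layer$params$W_dh %*% s_c + layer$params$b_dh
  alpha <- sigmoid(colMeans(zg))
  soft <- identical(layer$mode, "soft")
  use_sop <- if (soft) rep(TRUE, nb) else alpha > layer$tau
  # descriptor path
  h1 <- layer$params$W1e %*% s_c
  hm <- h1 > 0
  h1 <- h1 * hm
  e <- sigmoid(layer$params$W2e %*% h1)
  g <- e * s_c
  v_se <- nn_forward(layer$modules$lift, g, training)    # [dd^2, N]
  # SOP path (always computed in soft mode; cheap via the Gram route)
  r <- nn_forward(layer$modules$reduce, x, training)
  r <- nn_forward(layer$modules$reduce_bn, r, training)
  r <- nn_forward(layer$modules$reduce_relu, r, training)
  v_sop <- nn_forward(layer$modules$sop, r, training)    # [dd^2, N]
  out <- matrix(0, layer$sop_dim^2, nb)
  for (i in seq_len(nb)) {
    a <- alpha[i]
    out[, i] <- if (use_sop[i]) {
      a * v_sop[, i] + (1 - a) * v_se[, i]
    } else {
      v_se[, i]
    }
  }
  layer$last_alpha <- alpha
  if (training) {
    layer$cache <- list(d = d, s_c = s_c, alpha = alpha, use_sop = use_sop,
                        h1 = h1, hm = hm, e = e, v_se = v_se, v_sop = v_sop,
                        soft = soft)
  }
  out
}

#' @export
nn_backward.nn_head <- function(layer, dout) {
  cc <- layer$cache
  d <- cc$d
  ch <- d[1]; nb <- d[4]
  dv_sop <- matrix(0, nrow(dout), nb)
  dv_se <- matrix(0, nrow(dout), nb)
  dalpha <- numeric(nb)
  for (i in seq_len(nb)) {
    a <- cc$alpha[i]
    gi <- dout[, i]
    if (cc$use_sop[i]) {
      dalpha[i] <- sum(gi * (cc$v_sop[, i] - cc$v_se[, i]))
      dv_sop[, i] <- a * gi
      dv_se[, i] <- (1 - a) * gi
    } else {
      dv_se[, i] <- gi
    }
  }
  if (layer$reg_coeff != 0) {
    dalpha <- dalpha + (layer$reg_coeff / nb) * 2 * (cc$alpha - 0.5)
  }
  # SOP path
  dr <- nn_backward(layer$modules$sop, dv_sop)
  dr <- nn_backward(layer$modules$reduce_relu, dr)
  dr <- nn_backward(layer$modules$reduce_bn, dr)
  dx <- nn_backward(layer$modules$reduce, dr)
  # descriptor path
  dg <- nn_backward(layer$modules$lift, dv_se)           # [C, N]
  de <- dg * cc$s_c
  ds_c <- dg * cc$e
  dsig <- de * cc$e * (1 - cc$e)
  layer$grads$W2e <- tcrossprod(dsig, cc$h1)
  dh1 <- crossprod(layer$params$W2e, dsig) * cc$hm
  layer$grads$W1e <- tcrossprod(dh1, cc$s_c)
  ds_c <- ds_c + crossprod(layer$params$W1e, dh1)
  # gate
  dzbar <- dalpha * cc$alpha * (1 - cc$alpha)
  dzg <- matrix(rep(dzbar / ch, each = ch), nrow = ch)
  layer$grads$W_dh <- tcrossprod(dzg, cc$s_c)
  layer$grads$b_dh <- rowSums(dzg)
  ds_c <- ds_c + crossprod(layer$params$W_dh, dzg)
  dx <- dx + gap_backward_raw(ds_c, d)
  layer$cache <- NULL
  dx
}
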