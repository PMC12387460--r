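# Squeeze-and-excitation channel attention on [C, H, W] feature maps.

#' Construct excitation weights for an SE block
#'
#' Two fully connected layers with a reduction bottleneck: `W1` maps the
#' length-`C` channel descriptor to `max(floor(C / r), 1)` hidden units
#' (ReLU), `W2` maps back to `C` (sigmoid). Kaiming-uniform fan-in
#' initialization, no biases by default.
#'
#' @param channels number of channels C
#' @param reduction_ratio bottleneck reduction r (default 16)
#' @param bias include bias vectors (default FALSE)
#' @param seed integer seed for reproducible initialization
#' @return object of class `excitation_weights`
#' @export
make_excitation_weights <- function(channels, reduction_ratio = 16,
                                    bias = FALSE, seed = 1) {
  stopifnot(channels >= 1, reduction_ratio >= 1)
  hidden <- max(channels %/% reduction_ratio, 1L)
  with_seed(seed, {
    b1 <- sqrt(6 / channels) # kaiming-uniform bound, fan-in
    w1 <- matrix(runif(hidden * channels, -b1, b1), hidden, channels)
    b2 <- sqrt(6 / hidden)
    w2 <- matrix(runif(channels * hidden, -b2, b2), channels, hidden)
    structure(list(
      W1 = w1, W2 = w2,
      b1 = if (bias) numeric(hidden) else NULL,
      b2 = if (bias) numeric(channels) else NULL,
      reduction_ratio = reduction_ratio
    ), class = "excitation_weights")
  })
}

#' Squeeze: global average pooling to a channel descriptor
#'
#' `z_c` is the arithmetic mean of channel `c` over all spatial positions.
#'
#' @param x `[C, H, W]` feature map array
#' @return numeric vector of length C (class `channel_descriptor`)
#' @export
squeeze_gap <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3) {
    stop_lungsop("lungsop_shape_mismatch", "feature map must be a [C, H, W] array")
  }
  z <- rowMeans(matrix(x, nrow = dim(x)[1]))
  structure(z, class = "channel_descriptor")
}

#' Excitation: channel scores from the squeezed descriptor
#'
#' `s = sigmoid(W2 relu(W1 z))`; every score is strictly inside (0, 1).
#'
#' @param z channel descriptor (length-C numeric)
#' @param w `excitation_weights`
#' @return numeric vector of length C with entries in (0, 1)
#' @export
excitation <- function(z, w) {
  stopifnot(inherits(w, "excitation_weights"))
  z <- as.numeric(z)
  if (length(z) != ncol(w$W1)) {
    stop_lungsop("lungsop_shape_mismatch",
                 sprintf("descriptor length %d != W1 input width %d",
                         length(z), ncol(w$W1)))
  }
  h <- as.numeric(w$W1 %*% z)
  if (!is.null(w$b1)) h <- h + w$b1
  h <- relu(h)
  s <- as.numeric(w$W2 %*% h)
  if (!is.null(w$b2)) s <- s + w$b2
  sigmoid(s)
}

#' Recalibrate a feature map with channel attention scores
#'
#' Multiplies channel `c` elementwise by the scalar `s_c`.
#'
#' @param x `[C, H, W]` feature map array
#' @param s numeric vector of length C
#' @return recalibrated `[C, H, W]` array
#' @export
recalibrate <- function(x, s) {
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[1] != length(s)) {
    stop_lungsop("lungsop_shape_mismatch",
                 "channel count of map and score vector must match")
  }
  # channel is the fastest-varying dimension, so plain recycling applies s_c
  out <- x * as.numeric(s)
  dim(out) <- dim(x)
  out
}

#' Full squeeze-and-excitation block
#'
#' `se_block(x, w) = recalibrate(x, excitation(squeeze_gap(x), w))`.
#' Shape-preserving and norm-nonincreasing (all gains lie in (0, 1)).
#'
#' @inheritParams recalibrate
#' @param w `excitation_weights`
#' @return `[C, H, W]` array
#' @export
se_block <- function(x, w) {
  recalibrate(x, excitation(squeeze_gap(x), w))
}
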