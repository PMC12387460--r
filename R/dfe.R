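# Dynamic feature enhancement: a learned scalar gate alpha in (0, 1) that
# selects (hard mode) or blends (soft mode) the second-order pooling branch
# and the squeeze-excitation branch, plus the (alpha - 1/2)^2 balance
# regularizer added to the training loss.

#' Construct gate parameters for a DFE instance
#'
#' @param channels channel count C of the gated feature map
#' @param tau branch threshold, strictly inside (0, 1); default 0.5
#' @param mode `"hard"` (branch selection) or `"soft"` (convex blend)
#' @param reg_weight weight lambda of the balance regularizer (default 0.01)
#' @param W_d optional `C x C` weight matrix (default all zeros: balanced
#'   start, `alpha = 0.5`)
#' @param b_d optional length-C bias (default zeros)
#' @return object of class `gate_params`
#' @export
gate_params <- function(channels, tau = 0.5, mode = c("hard", "soft"),
                        reg_weight = 0.01, W_d = NULL, b_d = NULL) {
  mode <- match.arg(mode)
  if (!(tau > 0 && tau < 1)) {
    stop_lungsop("lungsop_config_error", "tau must lie strictly inside (0, 1)")
  }
  stopifnot(reg_weight >= 0, channels >= 1)
  if (is.null(W_d)) W_d <- matrix(0, channels, channels)
  if (is.null(b_d)) b_d <- numeric(channels)
  if (!all(dim(W_d) == c(channels, channels)) || length(b_d) != channels) {
    stop_lungsop("lungsop_shape_mismatch", "W_d must be C x C and b_d length C")
  }
  structure(list(W_d = W_d, b_d = b_d, tau = tau, mode = mode,
                 reg_weight = reg_weight, channels = channels),
            class = "gate_params")
}

#' Evaluate the DFE gate on a channel descriptor
#'
#' Computes `z = W_d s_c + b_d`, reduces by the arithmetic mean, and applies
#' the sigmoid: `alpha = sigmoid(mean(z))`. The branch is `"sop"` iff
#' `alpha > tau` (strict); the regularizer is `(alpha - 0.5)^2`.
#'
#' @param s_c channel descriptor (length-C numeric)
#' @param p `gate_params`
#' @return object of class `gate_decision` with fields `alpha`, `branch`,
#'   `regularizer`
#' @export
gate <- function(s_c, p) {
  stopifnot(inherits(p, "gate_params"))
  s_c <- as.numeric(s_c)
  if (length(s_c) != p$channels) {
    stop_lungsop("lungsop_shape_mismatch",
                 sprintf("descriptor length %d != gate width %d",
                         length(s_c), p$channels))
  }
  z <- as.numeric(p$W_d %*% s_c) + p$b_d
  # numerical guard: keep alpha strictly inside (0, 1) even when the
  # sigmoid saturates past double precision
  alpha <- min(max(sigmoid(mean(z)), 1e-12), 1 - 1e-12)
  structure(list(
    alpha = alpha,
    branch = if (alpha > p$tau) "sop" else "senet",
    regularizer = (alpha - 0.5)^2
  ), class = "gate_decision")
}

#' Hard-mode DFE application
#'
#' Applies the branch recorded in the gate decision. On the SOP branch, an
#' intermediate placement supplies `sop_diag` (the diagonal of the pooled
#' square root, i.e. per-channel second-order energy) and the output is the
#' shape-preserving `alpha * (diag %*% h) + (1 - alpha) * h`; a head
#' placement supplies `sop_vec` (the flattened square root) with `h` the
#' matching projected descriptor vector, giving
#' `alpha * sop_vec + (1 - alpha) * h`. On the SENet branch the output is the
#' convex combination `(1 - alpha) * senet_out + alpha * h`.
#'
#' @param h the pre-enhancement features (array or vector, branch-dependent)
#' @param d a `gate_decision`
#' @param sop_vec flattened second-order descriptor (head placement)
#' @param sop_diag per-channel second-order energies (intermediate placement)
#' @param senet_out recalibrated features, same shape as `h`
#' @return enhanced features, same shape as the selected branch output
#' @export
dfe_apply_hard <- function(h, d, sop_vec = NULL, sop_diag = NULL,
                           senet_out = NULL) {
  stopifnot(inherits(d, "gate_decision"))
  a <- d$alpha
  if (d$branch == "sop") {
    if (!is.null(sop_diag)) {
      if (!is.array(h) || dim(h)[1] != length(sop_diag)) {
        stop_lungsop("lungsop_shape_mismatch", "sop_diag length must match channels")
      }
      scaled <- h * as.numeric(sop_diag)
      dim(scaled) <- dim(h)
      return(a * scaled + (1 - a) * h)
    }
    if (!is.null(sop_vec)) {
      hv <- as.numeric(h)
      if (length(hv) != length(sop_vec)) {
        stop_lungsop("lungsop_shape_mismatch", "sop_vec and h lengths differ")
      }
      return(a * as.numeric(sop_vec) + (1 - a) * hv)
    }
    stop_lungsop("lungsop_missing_branch_input",
                 "gate selected the SOP branch but no SOP input was supplied")
  }
  if (is.null(senet_out)) {
    stop_lungsop("lungsop_missing_branch_input",
                 "gate selected the SENet branch but senet_out was not supplied")
  }
  if (!identical(dim(senet_out), dim(h)) || length(senet_out) != length(h)) {
    stop_lungsop("lungsop_shape_mismatch", "senet_out shape must equal h shape")
  }
  (1 - a) * senet_out + a * h
}

#' Soft-mode DFE application
#'
#' Elementwise convex combination `alpha * s_sqrt_vec + (1 - alpha) *
#' h_prime_vec` of the flattened second-order descriptor and the projected
#' channel-attention descriptor.
#'
#' @param s_sqrt_vec numeric vector (SOP branch)
#' @param h_prime_vec numeric vector of equal length (SENet branch)
#' @param alpha blend weight in \[0, 1\]
#' @return numeric vector
#' @export
dfe_apply_soft <- function(s_sqrt_vec, h_prime_vec, alpha) {
  if (length(s_sqrt_vec) != length(h_prime_vec)) {
    stop_lungsop("lungsop_shape_mismatch", "branch vectors must have equal length")
  }
  alpha * as.numeric(s_sqrt_vec) + (1 - alpha) * as.numeric(h_prime_vec)
}

#' Balance regularizer over a batch of gate decisions
#'
#' `lambda * mean((alpha_i - 0.5)^2)`, added to the training loss (never
#' multiplied into the features).
#'
#' @param decisions list of `gate_decision` objects (or numeric alphas)
#' @param reg_weight nonnegative lambda
#' @return nonnegative scalar
#' @export
dfe_regularization_loss <- function(decisions, reg_weight = 0.01) {
  stopifnot(reg_weight >= 0)
  if (length(decisions) == 0) return(0)
  alphas <- vapply(decisions, function(d) {
    if (inherits(d, "gate_decision")) d$alpha else as.numeric(d)
  }, numeric(1))
  reg_weight * mean((alphas - 0.5)^2)
}
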