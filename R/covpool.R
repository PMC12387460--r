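# Second-order (covariance) pooling numerics.
#
# A feature map X in R^{C x H x W} is flattened to F in R^{d x N} (d = C,
# N = H*W), its channel covariance C = (1/N) sum_j (f_j - mu)(f_j - mu)^T is
# computed, trace-normalized for convergence, pushed through the coupled
# Newton-Schulz square-root iteration, and rescaled by sqrt(tr C) so the
# result approximates the square root of the original covariance.

#' Flatten the spatial dimensions of a feature map
#'
#' Reshapes a `[C, H, W]` feature map into a `d x N` matrix (d = C,
#' N = H*W) whose column `j` is the channel vector at the j-th spatial
#' location in row-major order (the width index varies fastest).
#'
#' @param x numeric array of dimension `c(C, H, W)`
#' @return an object of class `flattened_features`: a list with elements
#'   `matrix` (`d x N`) and `n` (number of spatial locations).
#' @export
#' @examples
#' x <- array(1:8, dim = c(2, 2, 2))
#' flatten_spatial(x)$matrix
flatten_spatial <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3) {
    stop_lungsop("lungsop_shape_mismatch", "feature map must be a [C, H, W] array")
  }
  stopifnot_finite(x, "feature map")
  d <- dim(x)
  ch <- d[1]; h <- d[2]; w <- d[3]
  # row-major spatial order: column j = (h-1)*W + w
  m <- t(matrix(aperm(x, c(3, 2, 1)), nrow = w * h, ncol = ch))
  structure(list(matrix = m, n = h * w), class = "flattened_features")
}

as_feature_matrix <- function(f) {
  if (inherits(f, "flattened_features")) f$matrix else as.matrix(f)
}

#' Channel covariance of flattened features
#'
#' Computes `C = (1/N) * sum_j (f_j - mu)(f_j - mu)^T` where `mu` is the mean
#' column. Equivalent to the matrix form `F I-bar F^T` with the centering
#' matrix `I-bar = (1/N)(I - (1/N) J J^T)`.
#'
#' @param f a `flattened_features` object or a plain `d x N` matrix
#' @return an object of class `covariance_descriptor`: list with `matrix`
#'   (`d x d`, symmetric PSD) and `trace_pre_norm` (its trace).
#' @export
compute_covariance <- function(f) {
  m <- as_feature_matrix(f)
  n <- ncol(m)
  stopifnot(n >= 1)
  fc <- m - rowMeans(m)
  cv <- tcrossprod(fc) / n
  cv <- (cv + t(cv)) / 2 # enforce exact symmetry
  structure(list(matrix = cv, trace_pre_norm = sum(diag(cv))),
            class = "covariance_descriptor")
}

#' Trace pre-normalization of a covariance descriptor
#'
#' Rescales the matrix to unit trace (`C-hat = C / tr(C)`), preserving the
#' original trace in `trace_pre_norm` for later post-compensation.
#'
#' @param c_desc a `covariance_descriptor`
#' @param eps degeneracy threshold on the trace (default `1e-12`)
#' @return a `covariance_descriptor` with unit-trace `matrix`
#' @export
trace_normalize <- function(c_desc, eps = 1e-12) {
  stopifnot(inherits(c_desc, "covariance_descriptor"))
  tr <- sum(diag(c_desc$matrix))
  if (!is.finite(tr) || tr <= eps) {
    stop_lungsop("lungsop_degenerate_input",
                 sprintf("covariance trace %.3g below threshold %.3g", tr, eps))
  }
  structure(list(matrix = c_desc$matrix / tr, trace_pre_norm = tr),
            class = "covariance_descriptor")
}

#' Coupled Newton-Schulz square-root iteration
#'
#' Approximates the square root of a (trace-normalized) symmetric PSD matrix
#' `A` by the multiplication-only coupled iteration
#' `Y_n = Y_{n-1} (3 I - M_{n-1} Y_{n-1}) / 2`,
#' `M_n = (3 I - M_{n-1} Y_{n-1}) M_{n-1} / 2`,
#' started at `Y_0 = A`, `M_0 = I`. `Y_n -> A^(1/2)` and `M_n -> A^(-1/2)`
#' when the spectrum lies in (0, 2); trace normalization guarantees this for
#' PSD inputs. Five iterations are the standard operating point.
#'
#' @param c_hat a `covariance_descriptor` with trace approximately 1
#' @param n_iter number of coupled updates (default 5); 0 returns `Y_0`
#' @return an object of class `sqrt_iterates`: list with `Y`, `M_aux`,
#'   `n_iter`, and the relative residual `residual`
#'   (`||Y Y - A||_F / ||A||_F`). A `lungsop_not_converged` warning (not an
#'   error) is raised when the residual exceeds 0.05.
#' @export
newton_schulz_sqrt <- function(c_hat, n_iter = 5) {
  stopifnot(inherits(c_hat, "covariance_descriptor"), n_iter >= 0)
  a <- c_hat$matrix
  d <- nrow(a)
  y <- a
  m <- diag(d)
  if (n_iter > 0) {
    for (i in seq_len(n_iter)) {
      t3 <- 3 * diag(d) - m %*% y
      y <- y %*% t3 / 2
      m <- t3 %*% m / 2
      y <- (y + t(y)) / 2
      m <- (m + t(m)) / 2
    }
  }
  na <- fro_norm(a)
  res <- if (na > 0) fro_norm(y %*% y - a) / na else 0
  if (n_iter > 0 && res > 0.05) {
    warn_lungsop("lungsop_not_converged",
                 sprintf("Newton-Schulz residual %.3g > 0.05 after %d iterations",
                         res, n_iter))
  }
  structure(list(Y = y, M_aux = m, n_iter = n_iter, residual = res),
            class = "sqrt_iterates")
}

#' Post-compensation of the normalized square root
#'
#' Restores the scale of the original covariance: because
#' `C-hat^(1/2) = C^(1/2) / sqrt(tr C)`, the compensated output is
#' `M = sqrt(tr C) * Y_N`, approximating the square root of the
#' un-normalized covariance.
#'
#' @param y a `sqrt_iterates` object (or plain matrix)
#' @param trace_pre_norm nonnegative trace of the original covariance
#' @return numeric `d x d` matrix
#' @export
post_compensate <- function(y, trace_pre_norm) {
  stopifnot(trace_pre_norm >= 0)
  ym <- if (inherits(y, "sqrt_iterates")) y$Y else as.matrix(y)
  sqrt(trace_pre_norm) * ym
}

#' Matrix power through eigendecomposition (oracle)
#'
#' Computes `C^alpha = U diag(lambda_i^alpha) U^T` with negative eigenvalues
#' clamped to zero before powering. Serves as the exact oracle against which
#' the Newton-Schulz iteration is validated.
#'
#' @param c_desc a `covariance_descriptor` or symmetric matrix
#' @param exponent positive real exponent (0.5 for the square root)
#' @return numeric `d x d` matrix
#' @export
matrix_power_eig <- function(c_desc, exponent = 0.5) {
  stopifnot(exponent > 0)
  m <- if (inherits(c_desc, "covariance_descriptor")) c_desc$matrix else as.matrix(c_desc)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)^exponent
  out <- e$vectors %*% (lam * t(e$vectors))
  (out + t(out)) / 2
}

#' End-to-end second-order pooling
#'
#' Composition flatten -> covariance -> trace normalization -> Newton-Schulz
#' -> post-compensation. A degenerate (zero-variance) input yields the zero
#' matrix with a `lungsop_degenerate_input` warning rather than an error, so
#' the pooled path never aborts mid-training.
#'
#' @param x `[C, H, W]` feature map array
#' @param n_iter Newton-Schulz iterations (default 5)
#' @return symmetric `C x C` matrix approximating the covariance square root
#' @export
second_order_pool <- function(x, n_iter = 5) {
  f <- flatten_spatial(x)
  cv <- compute_covariance(f)
  ch <- tryCatch(trace_normalize(cv), lungsop_degenerate_input = function(e) NULL)
  if (is.null(ch)) {
    warn_lungsop("lungsop_degenerate_input",
                 "degenerate (zero-trace) covariance; returning zero matrix")
    return(matrix(0, nrow(cv$matrix), ncol(cv$matrix)))
  }
  y <- newton_schulz_sqrt(ch, n_iter = n_iter)
  m <- post_compensate(y, ch$trace_pre_norm)
  (m + t(m)) / 2
}

#' Vectorize a pooled second-order descriptor
#'
#' @param m symmetric matrix
#' @param mode `"full"` for the length-`C^2` row-major flatten (default) or
#'   `"upper"` for the length-`C(C+1)/2` row-major upper triangle
#' @return numeric vector
#' @export
sop_vectorize <- function(m, mode = c("full", "upper")) {
  mode <- match.arg(mode)
  m <- as.matrix(m)
  if (max(abs(m - t(m))) > 1e-5) {
    warn_lungsop("lungsop_asymmetry", "input to sop_vectorize is not symmetric")
  }
  if (mode == "full") {
    as.vector(t(m)) # row-major
  } else {
    tm <- t(m)
    tm[lower.tri(tm, diag = TRUE)] # row-major upper triangle
  }
}
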