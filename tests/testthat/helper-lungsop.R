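# Shared test fixtures and independent oracles. Everything here is built in
# code at test time; no binary fixtures.

ns <- asNamespace("lungsop")

rel_fro <- function(a, b) {
  norm(a - b, "F") / max(norm(b, "F"), 1e-300)
}

max_abs_diff <- function(a, b) max(abs(as.vector(a) - as.vector(b)))

# Random symmetric PSD matrix with unit trace and bounded condition number,
# built from a seeded random orthogonal basis and a log-spaced spectrum.
random_psd_unit_trace <- function(d, cond = 100, seed = 1) {
  lungsop:::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(d * d), d, d)))
    lam <- exp(seq(log(1), log(1 / cond), length.out = d))
    m <- q %*% (lam * t(q))
    m <- (m + t(m)) / 2
    m / sum(diag(m))
  })
}

as_cov_desc <- function(m, trace_pre_norm = sum(diag(m))) {
  structure(list(matrix = m, trace_pre_norm = trace_pre_norm),
            class = "covariance_descriptor")
}

# Scalar oracle of the coupled Newton-Schulz recursion: for A = a*I the
# iterates stay multiples of I, obeying y_n = y_{n-1} (3 - m_{n-1} y_{n-1})/2,
# m_n = (3 - m_{n-1} y_{n-1}) m_{n-1}/2 with y_0 = a, m_0 = 1.
scalar_ns <- function(a, n_iter) {
  y <- a; m <- 1
  if (n_iter > 0) {
    for (i in seq_len(n_iter)) {
      t3 <- 3 - m * y
      y_new <- y * t3 / 2
      m <- t3 * m / 2
      y <- y_new
    }
  }
  y
}

# Largest-remainder apportionment oracle (independent re-derivation used to
# pin stratified_split's documented rounding rule).
largest_remainder_oracle <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  frac <- raw - base
  left <- n - sum(base)
  ord <- order(-frac, seq_along(frac))
  add <- rep(0, length(fractions))
  if (left > 0) add[ord[seq_len(left)]] <- 1
  base + add
}

# Mann-Whitney U AUC oracle: P(score_pos > score_neg) + 0.5 P(tie).
mann_whitney_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]
  sn <- scores[!is_pos]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

small_phantom_set <- function(n_per_class = 4, size = 32, seed = 9) {
  generate_dataset(c(benign = n_per_class, malignant = n_per_class,
                     normal = n_per_class), seed = seed, size = size)
}

# Three-stage literal backbone: at 32 px input the final map is 2x2, so the
# head covariance keeps rank > 0 (the four-stage net at 32 px ends at 1x1,
# which degenerates the second-order head to zero by construction).
tiny_model_config <- function(...) {
  model_config(width_multiplier = 0.125, input_size = 32, sop_dim = 16,
               three_stage = TRUE, ...)
}
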