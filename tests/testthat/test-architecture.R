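# Model assembly, reference builders, parameter counting, determinism.

test_that("residual_block with zeroed transform is the identity", {
  b <- make_bottleneck(4, 2, 4, stride = 1, seed = 1, zero_init = TRUE)
  x <- lungsop:::with_seed(2, array(abs(rnorm(4 * 6 * 6)), dim = c(4, 6, 6)))
  out <- residual_block(x, b)
  # transform contributes only BN beta (zero) -> relu(x) = x for x >= 0
  expect_equal(out, x, tolerance = 1e-12)
})

test_that("bottleneck geometry follows the standard ResNet rules", {
  b1 <- make_bottleneck(16, 4, 16, stride = 1, seed = 1)
  x <- lungsop:::with_seed(3, array(rnorm(16 * 8 * 8), dim = c(16, 8, 8)))
  expect_identical(dim(residual_block(x, b1)), c(16L, 8L, 8L))
  # stride-2 transition halves spatial dims and changes width
  b2 <- make_bottleneck(16, 8, 32, stride = 2, seed = 1)
  expect_identical(dim(residual_block(x, b2)), c(32L, 4L, 4L))
})

test_that("forward pass yields normalized, order-preserving probabilities", {
  cfg <- tiny_model_config()
  model <- build_lung_se_sop(cfg, seed = 5)
  x <- lungsop:::with_seed(6, array(runif(32 * 32 * 3), dim = c(32, 32, 3)))
  probs <- classify(model, x)
  expect_identical(dim(probs), c(3L, 3L))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-6)
  expect_true(all(probs >= 0))
  # identical inputs -> identical outputs in eval mode
  expect_identical(classify(model, x), probs)
  # batches preserve order
  p1 <- classify(model, x[, , 1])
  expect_equal(as.numeric(p1), as.numeric(probs[1, ]), tolerance = 1e-12)
  expect_error(classify(model, matrix(0, 16, 16)),
               class = "lungsop_shape_mismatch")
})

test_that("construction is deterministic given the seed", {
  cfg <- tiny_model_config()
  checksum <- function(m) {
    sum(vapply(lungsop:::nn_collect(m$parts), function(l) {
      sum(vapply(l$params, function(p) sum(as.numeric(p)^3), numeric(1)))
    }, numeric(1)))
  }
  m1 <- build_lung_se_sop(cfg, seed = 42)
  m2 <- build_lung_se_sop(cfg, seed = 42)
  m3 <- build_lung_se_sop(cfg, seed = 43)
  expect_identical(checksum(m1), checksum(m2))
  expect_false(identical(checksum(m1), checksum(m3)))
})

test_that("count_parameters handles simple closed-form cases", {
  lin <- lungsop:::nn_linear(10, 3)
  expect_identical(count_parameters(list(lin))$exact, 33)
  expect_identical(count_parameters(list())$exact, 0)
})

test_that("reference builders match published parameter counts", {
  r50 <- build_resnet50_baseline(1000)
  expect_equal(count_parameters(r50)$exact, 25557032)
  expect_equal(count_parameters(r50)$millions, 25.6)
  vgg <- build_vgg16_reference(1000)
  expect_equal(count_parameters(vgg)$exact, 138357544)
  expect_equal(count_parameters(vgg)$millions, 138.4)
  # VGG16 configuration D has 13 convolutional layers
  convs <- Filter(function(l) inherits(l, "nn_conv"),
                  lungsop:::nn_collect(vgg$parts))
  expect_length(convs, 13)
  # head-size arithmetic: 1000-class vs 3-class ResNet50
  r3 <- build_resnet50_baseline(3)
  expect_equal(count_parameters(r50)$exact - count_parameters(r3)$exact,
               997 * (2048 + 1))
})

test_that("ablation lattice is shape-correct with increasing parameter counts", {
  w <- 0.125
  mk <- function(...) tiny_model_config(...)
  cfgs <- list(
    base = mk(use_se = FALSE, use_sop = FALSE, use_dfe = FALSE),
    se = mk(use_se = TRUE, use_sop = FALSE, use_dfe = FALSE),
    sesop = mk(use_se = TRUE, use_sop = TRUE, use_dfe = FALSE),
    full = mk()
  )
  counts <- numeric(0)
  x <- lungsop:::with_seed(7, array(runif(32 * 32 * 2), dim = c(32, 32, 2)))
  for (nm in names(cfgs)) {
    m <- build_lung_se_sop(cfgs[[nm]], seed = 1)
    counts <- c(counts, count_parameters(m)$exact)
    p <- classify(m, x)
    expect_identical(dim(p), c(2L, 3L))
    expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
  }
  expect_true(all(diff(counts) > 0))
})

test_that("resnet50 baseline forward contract holds (scaled width)", {
  m <- build_resnet50_baseline(5, width_multiplier = 0.125, materialize = TRUE,
                               seed = 2)
  x <- lungsop:::with_seed(8, array(runif(3 * 224 * 224), dim = c(3, 224, 224, 1)))
  out <- lungsop:::model_forward(m, x, training = FALSE)
  expect_identical(dim(out$logits), c(5L, 1L))
})

test_that("checkpoints round-trip through save/load", {
  cfg <- tiny_model_config()
  m <- build_lung_se_sop(cfg, seed = 9)
  x <- lungsop:::with_seed(10, array(runif(32 * 32 * 2), dim = c(32, 32, 2)))
  p0 <- classify(m, x)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(classify(m2, x), p0, tolerance = 1e-12)
  unlink(path)
})

test_that("one optimizer step leaves no dead parameter groups", {
  cfg <- tiny_model_config(dfe_mode = "soft")
  m <- build_lung_se_sop(cfg, seed = 11)
  x <- lungsop:::with_seed(12, array(runif(3 * 32 * 32 * 8), dim = c(3, 32, 32, 8)))
  y <- rep(1:3, length.out = 8)
  out <- lungsop:::model_forward(m, x, training = TRUE)
  ce <- lungsop:::softmax_ce(out$logits, y)
  lungsop:::nn_zero_grads(m$parts)
  for (g in lungsop:::model_gates(m)) g$reg_coeff <- 0.01 / 3
  lungsop:::model_backward(m, ce$dlogits)
  norms <- vapply(lungsop:::nn_collect(m$parts), function(l) {
    sum(vapply(l$grads, function(g) sum(abs(as.numeric(g))), numeric(1)))
  }, numeric(1))
  expect_true(all(norms > 0))
})
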