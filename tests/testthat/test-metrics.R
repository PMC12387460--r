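# Confusion matrix, one-vs-rest reductions, ROC/AUC, bootstrap CIs, t-test.

test_that("confusion counts truths against predictions", {
  cm <- confusion(c("b", "b", "m"), c("b", "m", "m"), c("b", "m"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                   dimnames = list(true = c("b", "m"),
                                                   pred = c("b", "m"))))
  # permutation invariance
  perm <- c(3, 1, 2)
  cm2 <- confusion(c("b", "b", "m")[perm], c("b", "m", "m")[perm], c("b", "m"))
  expect_equal(unclass(cm), unclass(cm2))
  # perfect predictions give a diagonal matrix with supports on the diagonal
  y <- rep(c("b", "m"), c(4, 6))
  cmp <- confusion(y, y, c("b", "m"))
  expect_equal(unclass(cmp), diag(c(4L, 6L)), ignore_attr = TRUE)
  expect_error(confusion("b", "z", c("b", "m")), class = "lungsop_unknown_label")
})

test_that("per_class_metrics applies the one-vs-rest formulas exactly", {
  cm <- matrix(c(5, 1, 0,
                 2, 6, 1,
                 0, 1, 7), 3, 3, byrow = TRUE,
               dimnames = list(true = c("a", "b", "c"),
                               pred = c("a", "b", "c")))
  m <- per_class_metrics(cm)
  # class a: TP=5, FN=1, FP=2, TN=15
  expect_equal(m$a$recall, 5 / 6)
  expect_equal(m$a$precision, 5 / 7)
  expect_equal(m$a$f1, 2 * (5 / 7) * (5 / 6) / (5 / 7 + 5 / 6))
  expect_equal(m$a$accuracy, (5 + 15) / 23)
  expect_equal(m$a$support, 6)
  # harmonic identity and micro accuracy for every class
  total <- sum(cm)
  for (cl in names(m)) {
    mm <- m[[cl]]
    if (mm$precision + mm$recall > 0) {
      expect_equal(mm$f1, 2 * mm$precision * mm$recall /
                            (mm$precision + mm$recall))
    }
    expect_true(mm$accuracy >= 0 && mm$accuracy <= 1)
  }
  # perfect class: precision = recall = 1 -> f1 = 1
  cm_perfect <- diag(c(3L, 4L))
  dimnames(cm_perfect) <- list(true = c("x", "y"), pred = c("x", "y"))
  expect_equal(per_class_metrics(cm_perfect)$x$f1, 1)
  # one-vs-rest accuracy >= recall when TN > 0 (numeric check, not assumed)
  expect_gte(m$a$accuracy, m$a$recall)
})

test_that("zero-denominator convention yields 0 with a flag", {
  cm <- matrix(c(0L, 2L, 0L, 3L), 2, 2,
               dimnames = list(true = c("a", "b"), pred = c("a", "b")))
  m <- per_class_metrics(cm)
  expect_equal(m$a$precision, 0)
  expect_equal(m$a$recall, 0)
  expect_equal(m$a$f1, 0)
  expect_true(m$a$zero_denominator)
})

test_that("ROC endpoints, monotonicity and the rank-statistic oracle hold", {
  # perfectly separated
  y <- rep(c("p", "n"), c(5, 5))
  s <- cbind(p = c(0.9, 0.8, 0.85, 0.95, 0.7, 0.2, 0.1, 0.3, 0.15, 0.05))
  r <- roc_one_vs_rest(s, y, "p")
  expect_equal(r$auc, 1)
  # label-independent scores
  s2 <- cbind(p = rep(0.5, 10))
  expect_equal(roc_one_vs_rest(s2, y, "p")$auc, 0.5)
  # Mann-Whitney oracle on a random 50-sample case
  set.seed(77)
  y3 <- sample(c("p", "n"), 50, replace = TRUE, prob = c(0.4, 0.6))
  s3 <- cbind(p = runif(50) + 0.3 * (y3 == "p"))
  r3 <- roc_one_vs_rest(s3, y3, "p")
  expect_lt(abs(r3$auc - mann_whitney_auc(s3[, "p"], y3 == "p")), 1e-10)
  # endpoints and monotonicity
  expect_equal(r3$points$fpr[1], 0)
  expect_equal(r3$points$tpr[1], 0)
  expect_equal(r3$points$fpr[nrow(r3$points)], 1)
  expect_equal(r3$points$tpr[nrow(r3$points)], 1)
  expect_true(all(diff(r3$points$tpr) >= -1e-12))
  expect_true(all(diff(r3$points$fpr) >= -1e-12))
  expect_error(roc_one_vs_rest(s3, rep("p", 50), "p"),
               class = "lungsop_single_class_input")
})

test_that("bootstrap CI is seeded, nested across levels, and sane", {
  set.seed(5)
  y <- sample(c("a", "b"), 60, replace = TRUE)
  pred <- ifelse(runif(60) < 0.8, y, sample(c("a", "b"), 60, replace = TRUE))
  acc <- function(yt, yp) mean(yt == yp)
  ci1 <- bootstrap_ci(acc, y, pred, n_boot = 500, seed = 3)
  ci2 <- bootstrap_ci(acc, y, pred, n_boot = 500, seed = 3)
  expect_identical(ci1, ci2)
  # degenerate: all correct on every resample
  cid <- bootstrap_ci(acc, y, y, n_boot = 200, seed = 1)
  expect_equal(cid$lower, 1)
  expect_equal(cid$upper, 1)
  # nesting: wider level contains narrower level
  ci90 <- bootstrap_ci(acc, y, pred, n_boot = 1000, level = 0.90, seed = 7)
  ci99 <- bootstrap_ci(acc, y, pred, n_boot = 1000, level = 0.99, seed = 7)
  expect_lte(ci99$lower, ci90$lower)
  expect_gte(ci99$upper, ci90$upper)
  # interval contains the point estimate over seeded runs
  for (s in 1:25) {
    ci <- bootstrap_ci(acc, y, pred, n_boot = 1000, seed = s)
    expect_lte(ci$lower, ci$point + 1e-12)
    expect_gte(ci$upper, ci$point - 1e-12)
  }
})

test_that("paired t-test matches the reference implementation", {
  a <- c(1.0, 2.1, 3.2, 4.4, 5.1)
  b <- c(0.8, 1.7, 3.4, 4.0, 4.6)
  got <- paired_ttest(a, b)
  ref <- t.test(a, b, paired = TRUE)
  expect_equal(got$t_statistic, unname(ref$statistic))
  expect_equal(got$p_two_tailed, ref$p.value)
  expect_equal(got$mean_diff, unname(ref$estimate))
  expect_equal(got$ci_95_of_diff, as.numeric(ref$conf.int))
  # identical vectors degenerate
  expect_error(paired_ttest(a, a), class = "lungsop_degenerate_variance")
  # constant difference with shrinking jitter: p -> 0
  ps <- vapply(c(0.1, 0.01, 0.001), function(j) {
    bb <- a - 1 + j * c(1, -1, 1, -1, 1)
    paired_ttest(a, bb)$p_two_tailed
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("eval_report assembles, serializes and round-trips", {
  set.seed(9)
  cls <- c("benign", "malignant", "normal")
  y <- sample(cls, 45, replace = TRUE)
  probs <- matrix(runif(45 * 3), 45, 3)
  probs <- probs / rowSums(probs)
  # bias towards the truth so the report is non-trivial
  probs[cbind(seq_len(45), match(y, cls))] <-
    probs[cbind(seq_len(45), match(y, cls))] + 1
  probs <- probs / rowSums(probs)
  rep <- eval_report(y, probs, cls, n_boot = 50, seed = 2)
  expect_s3_class(rep, "eval_report")
  expect_equal(sum(rep$cm), 45)
  expect_equal(rep$accuracy, sum(diag(unclass(rep$cm))) / 45)
  expect_true(!is.null(rep$roc$benign_vs_malignant))
  for (nm in names(rep$cis)) {
    ci <- rep$cis[[nm]]
    expect_lte(ci$lower, ci$point + 1e-12)
    expect_gte(ci$upper, ci$point - 1e-12)
  }
  # JSON round trip
  path <- tempfile(fileext = ".json")
  report_to_json(rep, path)
  back <- report_from_json(path)
  expect_equal(back$accuracy, rep$accuracy)
  expect_equal(matrix(unlist(back$confusion$counts), 3, 3),
               unclass(rep$cm), ignore_attr = TRUE)
  # CSV emission
  outdir <- file.path(tempdir(), "report-csv")
  files <- report_to_csv(rep, outdir)
  expect_true(all(file.exists(files)))
  unlink(path); unlink(outdir, recursive = TRUE)
})
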