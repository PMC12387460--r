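# Evaluation battery: confusion matrix, one-vs-rest per-class metrics,
# ROC/AUC by threshold sweep, stratified percentile-bootstrap confidence
# intervals, and the classical paired two-tailed t-test.

#' Multiclass confusion matrix
#'
#' `counts[i, j]` is the number of samples with true class `i` predicted as
#' class `j` (rows = truth, columns = prediction).
#'
#' @param y_true,y_pred character vectors of equal length with labels drawn
#'   from `class_names`
#' @param class_names ordered class labels
#' @return object of class `confusion_matrix` (an integer matrix with
#'   dimnames)
#' @export
confusion <- function(y_true, y_pred, class_names) {
  if (length(y_true) != length(y_pred)) {
    stop_lungsop("lungsop_shape_mismatch", "y_true and y_pred lengths differ")
  }
  bad <- setdiff(unique(c(y_true, y_pred)), class_names)
  if (length(bad)) {
    stop_lungsop("lungsop_unknown_label",
                 sprintf("labels not in class_names: %s", paste(bad, collapse = ", ")))
  }
  tt <- table(factor(y_true, levels = class_names),
              factor(y_pred, levels = class_names))
  cm <- matrix(as.integer(tt), nrow = length(class_names),
               dimnames = list(true = class_names, pred = class_names))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Per-class one-vs-rest metrics from a confusion matrix
#'
#' For each class c: `TP = cm[c, c]`, `FN` = rest of row c, `FP` = rest of
#' column c, `TN` = remainder; then precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, `F1 = 2PR/(P+R)`, one-vs-rest accuracy
#' `(TP+TN)/(TP+TN+FP+FN)`. Zero denominators yield 0 with
#' `zero_denominator = TRUE` flagged.
#'
#' @param cm a `confusion_matrix` (or plain square matrix with dimnames)
#' @return named list, one `class_metrics` entry per class
#' @export
per_class_metrics <- function(cm) {
  cm <- unclass(cm)
  classes <- rownames(cm)
  total <- sum(cm)
  out <- lapply(seq_along(classes), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    safe <- function(num, den) if (den > 0) num / den else 0
    precision <- safe(tp, tp + fp)
    recall <- safe(tp, tp + fn)
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    structure(list(
      precision = precision, recall = recall, f1 = f1,
      accuracy = safe(tp + tn, total), support = tp + fn,
      zero_denominator = (tp + fp == 0) || (tp + fn == 0)
    ), class = "class_metrics")
  })
  names(out) <- classes
  out
}

#' One-vs-rest ROC curve and AUC
#'
#' Threshold sweep over the probability assigned to the positive class;
#' points are sorted by FPR with the (0,0) and (1,1) endpoints included and
#' AUC computed by the trapezoid rule.
#'
#' @param scores `n x K` matrix of class probabilities with column names
#' @param y_true character vector of true labels
#' @param class the positive class
#' @return list with `points` (data frame fpr/tpr/threshold) and `auc`
#' @export
roc_one_vs_rest <- function(scores, y_true, class) {
  scores <- as.matrix(scores)
  s <- if (!is.null(colnames(scores))) scores[, class] else scores[, 1]
  pos <- y_true == class
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop_lungsop("lungsop_single_class_input",
                 "ROC requires both positive and negative samples")
  }
  ord <- order(s, decreasing = TRUE)
  sp <- s[ord]; yp <- pos[ord]
  tp <- cumsum(yp); fp <- cumsum(!yp)
  keep <- c(sp[-1] != sp[-length(sp)], TRUE) # last index of each threshold
  tpr <- c(0, tp[keep] / n1, 1)
  fpr <- c(0, fp[keep] / n0, 1)
  thr <- c(Inf, sp[keep], -Inf)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr, threshold = thr), auc = auc)
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples cases with replacement within each true class, recomputes the
#' metric on every resample, and reports the percentile interval at the
#' requested level. Deterministic given the seed.
#'
#' @param metric_fn function `(y_true, y_pred_or_scores) -> scalar`
#' @param y_true true labels
#' @param y_pred_or_scores predictions (vector) or score matrix (rows =
#'   samples)
#' @param n_boot number of resamples (default 2000)
#' @param level confidence level (default 0.95)
#' @param seed RNG seed
#' @return list with `lower`, `upper`, `level`, `point`
#' @export
bootstrap_ci <- function(metric_fn, y_true, y_pred_or_scores, n_boot = 2000,
                         level = 0.95, seed = 1) {
  n <- length(y_true)
  stopifnot(n >= 10)
  is_mat <- is.matrix(y_pred_or_scores)
  pick <- function(idx) {
    if (is_mat) y_pred_or_scores[idx, , drop = FALSE] else y_pred_or_scores[idx]
  }
  by_class <- split(seq_len(n), y_true)
  stats <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(by_class, function(ix) {
        ix[sample.int(length(ix), length(ix), replace = TRUE)]
      }), use.names = FALSE)
      metric_fn(y_true[idx], pick(idx))
    }, numeric(1))
  })
  qs <- stats::quantile(stats, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, na.rm = TRUE)
  list(lower = qs[1], upper = qs[2], level = level,
       point = metric_fn(y_true, pick(seq_len(n))))
}

#' Classical paired two-tailed t-test
#'
#' t statistic on the paired differences with `n - 1` degrees of freedom and
#' a two-tailed p value; also returns the mean difference and its 95% CI.
#'
#' @param values_a,values_b paired numeric vectors of equal length >= 2
#' @return list with `t_statistic`, `p_two_tailed`, `mean_diff`,
#'   `ci_95_of_diff`
#' @export
paired_ttest <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    stop_lungsop("lungsop_shape_mismatch", "need equal-length vectors, n >= 2")
  }
  d <- values_a - values_b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (!is.finite(sd_d) || sd_d == 0) {
    stop_lungsop("lungsop_degenerate_variance",
                 "paired differences have zero variance")
  }
  se <- sd_d / sqrt(n)
  tstat <- mean(d) / se
  p <- 2 * stats::pt(-abs(tstat), df = n - 1)
  tcrit <- stats::qt(0.975, df = n - 1)
  list(t_statistic = tstat, p_two_tailed = p, mean_diff = mean(d),
       ci_95_of_diff = c(mean(d) - tcrit * se, mean(d) + tcrit * se))
}

#' Full evaluation report
#'
#' Confusion matrix, per-class one-vs-rest metrics, per-class ROC/AUC (plus
#' the benign-vs-malignant binary restriction when both classes are
#' present), micro accuracy, and bootstrap CIs for overall accuracy and
#' per-class recall.
#'
#' @param y_true true labels
#' @param probs `n x K` probability matrix with class-name columns
#' @param class_names ordered class labels
#' @param n_boot bootstrap resamples for the CIs (default 200 for routine
#'   evaluation; raise to 2000 for publication-grade intervals)
#' @param level CI level
#' @param seed bootstrap seed
#' @return object of class `eval_report`
#' @export
eval_report <- function(y_true, probs, class_names, n_boot = 200,
                        level = 0.95, seed = 1) {
  probs <- as.matrix(probs)
  colnames(probs) <- class_names
  y_pred <- class_names[max.col(probs, ties.method = "first")]
  cm <- confusion(y_true, y_pred, class_names)
  pcm <- per_class_metrics(cm)
  roc <- list()
  for (cl in class_names) {
    roc[[cl]] <- tryCatch(roc_one_vs_rest(probs, y_true, cl),
                          lungsop_single_class_input = function(e) NULL)
  }
  if (all(c("benign", "malignant") %in% class_names)) {
    sub <- y_true %in% c("benign", "malignant")
    if (length(unique(y_true[sub])) == 2) {
      roc[["benign_vs_malignant"]] <-
        roc_one_vs_rest(probs[sub, , drop = FALSE], y_true[sub], "malignant")
    }
  }
  micro_acc <- sum(diag(unclass(cm))) / sum(cm)
  cis <- list()
  if (length(y_true) >= 10) { # bootstrap requires n >= 10
    cis$accuracy <- bootstrap_ci(function(yt, yp) mean(yt == yp),
                                 y_true, y_pred, n_boot, level, seed)
    for (cl in class_names) {
      cis[[paste0("recall_", cl)]] <- bootstrap_ci(
        function(yt, yp) {
          den <- sum(yt == cl)
          if (den == 0) return(NA_real_)
          sum(yt == cl & yp == cl) / den
        },
        y_true, y_pred, n_boot, level, seed
      )
    }
  }
  structure(list(cm = cm, per_class = pcm, roc = roc, accuracy = micro_acc,
                 cis = cis, n = length(y_true)),
            class = "eval_report")
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `eval_report`
#' @param path optional output file; if NULL the JSON string is returned
#' @return the JSON string (invisibly when written to file)
#' @export
report_to_json <- function(report, path = NULL) {
  x <- list(
    confusion = list(class_names = rownames(report$cm),
                     counts = unclass(report$cm)),
    per_class = lapply(report$per_class, function(m) unclass(m)),
    roc = lapply(report$roc, function(r) {
      if (is.null(r)) NULL else list(auc = r$auc, points = r$points)
    }),
    accuracy = report$accuracy,
    cis = report$cis,
    n = report$n
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Read back a serialized evaluation report
#'
#' @param path JSON file written by [report_to_json()]
#' @return list mirroring the report structure
#' @export
report_from_json <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}

#' Write the tabular parts of a report as CSV
#'
#' @param report an `eval_report`
#' @param dir output directory
#' @return invisibly, the vector of files written
#' @export
report_to_csv <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f <- file.path(dir, "confusion_matrix.csv")
  utils::write.csv(unclass(report$cm), f)
  files <- c(files, f)
  tab <- do.call(rbind, lapply(names(report$per_class), function(cl) {
    m <- report$per_class[[cl]]
    data.frame(class = cl, precision = m$precision, recall = m$recall,
               f1 = m$f1, accuracy = m$accuracy, support = m$support)
  }))
  f <- file.path(dir, "per_class_metrics.csv")
  utils::write.csv(tab, f, row.names = FALSE)
  files <- c(files, f)
  for (cl in names(report$roc)) {
    if (is.null(report$roc[[cl]])) next
    f <- file.path(dir, sprintf("roc_%s.csv", cl))
    utils::write.csv(report$roc[[cl]]$points, f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
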