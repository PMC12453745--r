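# Evaluation harness: confusion metrics, ROC / precision-recall curves,
# portion learning curves, paired t-tests against a fixed baseline, and
# permutation Shapley attribution.

#' Confusion counts and standard classification metrics
#'
#' @param y_true,y_pred 0/1 vectors of equal length.
#' @return List with `counts` (tp, fp, tn, fn), `accuracy`, `precision`,
#'   `recall`, `f1`, `misclassification_percent` (continuous) and
#'   `misclassification_percent_rounded` (nearest integer percent).
#'   Precision/recall/F1 are 0 when their denominator is 0.
#' @examples
#' confusion_and_metrics(c(1, 0, 1, 0), c(1, 0, 0, 0))
#' @export
confusion_and_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_feba("length mismatch")
  if (!length(y_true)) stop_feba("empty input")
  stopifnot(is_binary_labels(y_true), is_binary_labels(y_pred))
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fn <- sum(y_true == 1 & y_pred == 0)
  total <- tp + fp + tn + fn
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  mis <- 100 * (fp + fn) / total
  list(counts = list(tp = tp, fp = fp, tn = tn, fn = fn),
       accuracy = (tp + tn) / total,
       precision = precision, recall = recall, f1 = f1,
       misclassification_percent = mis,
       misclassification_percent_rounded = as.integer(round_half_up(mis)))
}

trapezoid_auc <- function(x, y) {
  o <- order(x)
  sum(diff(x[o]) * (head(y[o], -1) + y[o][-1]) / 2)
}

#' ROC and precision-recall curves with trapezoidal AUC
#'
#' A full threshold sweep over the unique scores (plus sentinels), emitting
#' curve points and trapezoid AUCs. Higher scores must indicate class 1.
#'
#' @param y_true 0/1 vector with both classes present.
#' @param scores Numeric ranking scores.
#' @return List of two curve blocks, `roc` (`x` = FPR, `y` = TPR) and `pr`
#'   (`x` = recall, `y` = precision), each with `thresholds` and `auc`.
#' @export
roc_pr_curves <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores), is_binary_labels(y_true))
  n1 <- sum(y_true == 1)
  n0 <- sum(y_true == 0)
  if (n1 == 0 || n0 == 0) stop_feba("both classes required")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tp <- vapply(thr, function(t) sum(scores >= t & y_true == 1), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & y_true == 0), numeric(1))
  tpr <- tp / n1
  fpr <- fp / n0
  prec <- ifelse(tp + fp > 0, tp / (tp + fp), 1)
  roc <- list(thresholds = thr, x = fpr, y = tpr,
              auc = trapezoid_auc(fpr, tpr))
  pr <- list(thresholds = thr, x = tpr, y = prec,
             auc = trapezoid_auc(tpr, prec))
  list(roc = roc, pr = pr)
}

stratified_sample <- function(y, frac) {
  idx1 <- which(y == 1)
  idx0 <- which(y == 0)
  k1 <- max(1L, round(frac * length(idx1)))
  k0 <- max(1L, round(frac * length(idx0)))
  sort(c(sample(idx1, k1), sample(idx0, k0)))
}

#' Portion-based learning curve by repeated stratified resampling
#'
#' For each requested data portion, `k` seeded stratified resamples draw
#' that fraction of the data as a training set, fit the supplied pipeline,
#' and evaluate accuracy on the held-out remainder; per-portion mean and
#' standard deviation are reported for plotting.
#'
#' @param fit_fun `function(X, y)` returning a model.
#' @param predict_fun `function(model, X)` returning 0/1 labels.
#' @param dem A labeled `feba_dem` (or a matrix with `y` supplied).
#' @param y Labels when `dem` is a bare matrix.
#' @param portions Training fractions (default `c(0.2, 0.4, 0.6, 0.8)`).
#' @param k Resamples per portion (default 10).
#' @param seed Base seed.
#' @return Data frame with `portion`, `mean_accuracy`, `sd_accuracy`, `k`.
#' @export
learning_curve_cv <- function(fit_fun, predict_fun, dem, y = NULL,
                              portions = c(0.2, 0.4, 0.6, 0.8), k = 10L,
                              seed = 1L) {
  if (inherits(dem, "feba_dem")) {
    X <- dem$X
    y <- y %||% dem$labels
  } else X <- as.matrix(dem)
  stopifnot(!is.null(y), all(portions > 0 & portions < 1), k >= 1L)
  portions <- sort(portions)
  out <- lapply(seq_along(portions), function(pi) {
    p <- portions[pi]
    acc <- vapply(seq_len(k), function(r) {
      tr <- with_seed(derive_seed(seed, pi * 1000L + r),
                      stratified_sample(y, p))
      te <- setdiff(seq_along(y), tr)
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L) {
        stop_feba("degenerate fold at portion %.0f%%", 100 * p)
      }
      model <- fit_fun(X[tr, , drop = FALSE], y[tr])
      mean(predict_fun(model, X[te, , drop = FALSE]) == y[te])
    }, numeric(1))
    data.frame(portion = p, mean_accuracy = mean(acc),
               sd_accuracy = stats::sd(acc), k = k)
  })
  do.call(rbind, out)
}

#' Paired t-test of metric samples against a fixed baseline
#'
#' The paired design against a constant reduces to a one-sample t-test on
#' the differences `metric - baseline` (mathematically identical). Returns
#' the two-sided p, Cohen's d (mean difference / sd), and the 95% CI of the
#' mean difference. With zero variance, `p = 1` when the mean difference is
#' also zero, otherwise `p = 0` with a `degenerate` flag (the machine floor
#' for a constant nonzero difference).
#'
#' @param metric_samples Numeric vector (>= 2 values), on the same scale as
#'   `baseline` (e.g. percentages).
#' @param baseline Constant to compare against (default 80).
#' @return List with `t`, `p`, `cohens_d`, `ci` (95% for the mean
#'   difference), `mean_difference`, `degenerate`.
#' @export
paired_t_test <- function(metric_samples, baseline = 80.0) {
  x <- as.numeric(metric_samples)
  if (length(x) < 2L) stop_feba("need at least 2 samples")
  d <- x - baseline
  md <- mean(d)
  s <- stats::sd(d)
  n <- length(d)
  if (s == 0) {
    if (md == 0) {
      return(list(t = 0, p = 1, cohens_d = 0, ci = c(0, 0),
                  mean_difference = 0, degenerate = FALSE))
    }
    return(list(t = sign(md) * Inf, p = 0, cohens_d = sign(md) * Inf,
                ci = c(md, md), mean_difference = md, degenerate = TRUE))
  }
  tt <- stats::t.test(d, mu = 0)
  list(t = unname(tt$statistic), p = tt$p.value, cohens_d = md / s,
       ci = unname(tt$conf.int), mean_difference = md, degenerate = FALSE)
}

# All 2^d feature subsets of 1..d as a list (d <= 20 guard upstream).
all_subsets <- function(d) {
  out <- list(integer(0))
  for (j in seq_len(d)) out <- c(out, lapply(out, function(s) c(s, j)))
  out
}

shapley_exact <- function(f, x, baseline) {
  d <- length(x)
  phi <- numeric(d)
  subsets <- all_subsets(d)
  vals <- vapply(subsets, function(S) {
    z <- baseline
    z[S] <- x[S]
    f(matrix(z, 1L))
  }, numeric(1))
  key <- vapply(subsets, function(S) paste(S, collapse = ","), character(1))
  vmap <- stats::setNames(vals, key)
  for (j in seq_len(d)) {
    for (si in seq_along(subsets)) {
      S <- subsets[[si]]
      if (j %in% S) next
      s <- length(S)
      wgt <- factorial(s) * factorial(d - s - 1L) / factorial(d)
      withj <- sort(c(S, j))
      phi[j] <- phi[j] +
        wgt * (vmap[[paste(withj, collapse = ",")]] - vals[si])
    }
  }
  phi
}

shapley_sampled <- function(f, x, baseline, n_samples, seed) {
  d <- length(x)
  phi <- numeric(d)
  with_seed(seed, {
    for (r in seq_len(n_samples)) {
      perm <- sample.int(d)
      z <- baseline
      prev <- f(matrix(z, 1L))
      for (j in perm) {
        z[j] <- x[j]
        cur <- f(matrix(z, 1L))
        phi[j] <- phi[j] + (cur - prev)
        prev <- cur
      }
    }
  })
  phi / n_samples
}

#' Permutation Shapley feature attribution
#'
#' Attributes a model's score for an instance to its features by Shapley
#' values over feature coalitions, with absent features imputed from a
#' baseline (by default the column means of `X`). Exact subset enumeration
#' is used for `d <= exact_limit` (default 10); above that, a seeded
#' permutation-sampling estimate. Positive attribution pushes the score
#' toward label 1. Exact-mode attributions satisfy efficiency:
#' they sum to `f(x) - f(baseline)`.
#'
#' @param f Scoring function: `function(X_matrix) -> numeric` (e.g. a
#'   wrapper around [predict_weak()] or [predict_vote()] scores).
#' @param X Numeric background matrix (defines the baseline).
#' @param instance Row to explain (numeric vector; default the first row
#'   of `X`).
#' @param n_samples Permutations for the sampled estimator (default 200).
#' @param seed Seed for the sampled estimator.
#' @param exact_limit Dimension bound for exact enumeration.
#' @return Numeric vector of signed per-feature attributions.
#' @export
permutation_attribution <- function(f, X, instance = NULL, n_samples = 200L,
                                    seed = 1L, exact_limit = 10L) {
  X <- as.matrix(X)
  if (!nrow(X)) stop_feba("X must be non-empty")
  x <- instance %||% X[1L, ]
  stopifnot(length(x) == ncol(X))
  baseline <- colMeans(X)
  if (ncol(X) <= exact_limit) {
    shapley_exact(f, x, baseline)
  } else {
    shapley_sampled(f, x, baseline, n_samples, seed)
  }
}
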