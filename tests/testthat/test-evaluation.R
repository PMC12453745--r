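test_that("confusion metrics match hand arithmetic", {
  y <- c(rep(1, 5), rep(0, 5))
  p <- c(1, 1, 1, 0, 0, 0, 0, 0, 0, 1)
  m <- confusion_and_metrics(y, p)
  expect_equal(m$counts, list(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$precision, 0.75)
  expect_equal(m$recall, 0.6)
  expect_equal(m$accuracy, 0.7)
  perfect <- confusion_and_metrics(y, y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$misclassification_percent, 0)
  expect_error(confusion_and_metrics(y, p[-1]), "length")
})

test_that("metric identities hold on random confusion tables", {
  for (s in 1:1000) {
    cnt <- feba:::with_seed(s, sample.int(50, 4, replace = TRUE))
    y <- c(rep(1, cnt[1]), rep(0, cnt[2]), rep(0, cnt[3]), rep(1, cnt[4]))
    p <- c(rep(1, cnt[1]), rep(1, cnt[2]), rep(0, cnt[3]), rep(0, cnt[4]))
    m <- confusion_and_metrics(y, p)
    expect_equal(m$accuracy, (cnt[1] + cnt[3]) / sum(cnt))
    if (m$precision + m$recall > 0) {
      expect_equal(m$f1,
                   2 * m$precision * m$recall / (m$precision + m$recall))
    }
  }
})

test_that("ROC endpoints behave and random scores sit near 0.5", {
  y <- rep(c(0, 1), each = 50)
  perfect <- seq_along(y) / length(y)
  expect_equal(roc_pr_curves(y, perfect)$roc$auc, 1)
  expect_equal(roc_pr_curves(y, 1 - perfect)$roc$auc, 0)
  yr <- rep(c(0, 1), 5000)
  sc <- feba:::with_seed(101, runif(10000))
  expect_equal(roc_pr_curves(yr, sc)$roc$auc, 0.5, tolerance = 0.02)
  expect_error(roc_pr_curves(rep(1, 4), 1:4), "both classes")
})

test_that("trapezoid ROC AUC agrees with pROC on a shared dataset", {
  skip_if_not_installed("pROC")
  y <- rep(c(0, 1), each = 40)
  sc <- feba:::with_seed(5, rnorm(80, mean = y))
  ours <- roc_pr_curves(y, sc)$roc$auc
  ref <- as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("learning curves are sorted, disjoint and reproducible", {
  gm <- generate_feature_matrix(matrix_spec(n = 300, d = 4, seed = 31,
                                            n_informative = 2))
  fit <- function(X, y) fit_weak_learner(weak_learner_spec("linear", seed = 1),
                                         X, y)
  prd <- function(m, X) as.integer(predict_weak(m, X) >= 0.5)
  c1 <- learning_curve_cv(fit, prd, gm$dem, k = 3, seed = 2)
  c2 <- learning_curve_cv(fit, prd, gm$dem, k = 3, seed = 2)
  expect_identical(c1, c2)
  expect_identical(c1$portion, c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(diff(c1$mean_accuracy) > -0.2))  # broadly non-degrading
  expect_true(all(c1$sd_accuracy >= 0))
})

test_that("train and test rows of a resample are disjoint and cover all", {
  y <- rep(c(0, 1), each = 20)
  tr <- feba:::with_seed(3, feba:::stratified_sample(y, 0.4))
  te <- setdiff(seq_along(y), tr)
  expect_length(intersect(tr, te), 0)
  expect_setequal(c(tr, te), seq_along(y))
  expect_equal(length(tr), 16)
})

test_that("the paired t-test against a constant matches the textbook formula", {
  flat <- paired_t_test(c(80, 80, 80), baseline = 80)
  expect_equal(flat$t, 0)
  expect_equal(flat$p, 1)
  # {90, 92, 94} vs 80: d = (10, 12, 14), mean 12, sd 2, se = 2/sqrt(3)
  res <- paired_t_test(c(90, 92, 94), baseline = 80)
  t_hand <- 12 / (2 / sqrt(3))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * stats::pt(-t_hand, df = 2), tolerance = 1e-12)
  expect_equal(res$cohens_d, 6)
  # degenerate: constant nonzero difference
  deg <- paired_t_test(c(90, 90), baseline = 80)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
})

test_that("the 95% CI excludes zero exactly when p < 0.05", {
  for (s in 1:200) {
    x <- feba:::with_seed(s, rnorm(6, mean = 81, sd = 3))
    r <- paired_t_test(x, baseline = 80)
    expect_identical(r$p < 0.05, r$ci[1] > 0 || r$ci[2] < 0)
  }
})

test_that("attribution of an additive model recovers its coefficients", {
  f <- function(X) 1 + 2 * X[, 1] - 3 * X[, 2]
  X <- feba:::with_seed(4, matrix(rnorm(40), 20, 2))
  phi <- permutation_attribution(f, X, instance = X[3, ])
  base <- colMeans(X)
  expect_equal(phi, c(2 * (X[3, 1] - base[1]), -3 * (X[3, 2] - base[2])),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("constant features receive zero attribution; symmetry holds", {
  f <- function(X) X[, 1] + X[, 2]
  X <- cbind(rep(1, 10), rep(1, 10), rnorm(10))
  phi <- permutation_attribution(function(Z) f(Z), X,
                                 instance = c(1, 1, 0))
  expect_equal(phi[1], 0)
  expect_equal(phi[2], 0)
  expect_equal(phi[1], phi[2])  # symmetric twins
})
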