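test_that("tree importance isolates the separating feature", {
  n <- 100
  y <- rep(c(0L, 1L), each = n / 2)
  X <- feba:::with_seed(7, cbind(
    noise1 = rnorm(n), perfect = y + 0, noise2 = rnorm(n),
    const = rep(1, n)))
  imp <- fit_tree_importance(X, y)
  expect_equal(sum(imp), 1)
  expect_identical(unname(which.max(imp)), 2L)
  expect_identical(unname(imp["const"]), 0)
})

test_that("single-class labels give zero importances with a warning", {
  X <- matrix(rnorm(40), 20, 2)
  expect_warning(imp <- fit_tree_importance(X, rep(1L, 20)), "single-class")
  expect_identical(unname(imp), c(0, 0))
})

test_that("tree agrees with rpart on the primary split variable", {
  skip_if_not_installed("rpart")
  gm <- generate_feature_matrix(matrix_spec(n = 300, d = 6, n_informative = 1,
                                            mean_shift = 2, seed = 21))
  imp <- fit_tree_importance(gm$dem$X, gm$dem$labels)
  fit <- rpart::rpart(y ~ ., data.frame(gm$dem$X, y = factor(gm$dem$labels)),
                      method = "class",
                      control = rpart::rpart.control(maxsurrogate = 0,
                                                     cp = 0.01))
  expect_identical(names(which.max(imp)),
                   as.character(fit$frame$var[1]))
  expect_identical(unname(which.max(imp)), gm$informative)
})

test_that("tree predictions separate a clean split", {
  y <- rep(c(0L, 1L), each = 30)
  X <- cbind(f = ifelse(y == 1, 2, -2))
  fit <- fit_tree_importance(X, y, return_tree = TRUE)
  expect_equal(predict_tree(fit$tree, X), as.numeric(y))
})

test_that("RFE keeps everything when the target equals the dimension", {
  gm <- generate_feature_matrix(matrix_spec(n = 100, d = 5, seed = 2,
                                            n_informative = 2))
  sel <- rfe_select(gm$dem, n_target = 5)
  expect_identical(sel$optimized$selected, 1:5)
  expect_length(sel$ranking$eliminated, 0)
  expect_error(rfe_select(gm$dem, n_target = 6), "n_target")
})

test_that("RFE bookkeeping: partition, no reappearance, exact target size", {
  gm <- generate_feature_matrix(matrix_spec(n = 300, d = 25, seed = 3,
                                            n_informative = 4,
                                            mean_shift = 1.5))
  sel <- rfe_select(gm$dem, n_target = 6)
  r <- sel$ranking
  expect_identical(dim(r$scores), c(10L, 25L))
  expect_length(intersect(r$eliminated, r$selected), 0)
  expect_setequal(c(r$eliminated, r$selected), 1:25)
  expect_length(sel$optimized$selected, 6L)
  # eliminated features carry no scores in later iterations
  elim_iter <- apply(r$scores, 2L, function(col) {
    runs <- which(!is.na(col))
    if (!length(runs)) 0L else max(runs)
  })
  for (j in seq_len(25)) {
    pos <- match(j, r$eliminated)
    if (!is.na(pos) && elim_iter[j] > 0L) {
      after <- r$scores[seq_len(10) > elim_iter[j], j]
      expect_true(all(is.na(after)))
    }
  }
  # recovers the planted signal
  expect_true(all(gm$informative %in% sel$optimized$selected))
})

test_that("rank scores live in 0..3 while a feature survives", {
  gm <- generate_feature_matrix(matrix_spec(n = 200, d = 12, n_informative = 4, seed = 5))
  r <- rfe_select(gm$dem, n_target = 4)$ranking
  vals <- r$scores[!is.na(r$scores)]
  expect_true(all(vals %in% 0:3))
})

test_that("feature CSV round trip is bit-exact", {
  gm <- generate_feature_matrix(matrix_spec(n = 100, d = 5, n_informative = 2, seed = 4))
  path <- withr::local_tempfile(fileext = ".csv")
  export_feature_csv(gm$dem, path)
  expect_length(readLines(path), 101L)
  back <- read_feature_csv(path)
  expect_identical(back$X, gm$dem$X)
  expect_identical(back$ids, gm$dem$ids)
  expect_identical(back$labels, gm$dem$labels)
  # single-feature export keeps id + feature + label
  one <- doc_embedding_matrix(gm$dem$X[, 1, drop = FALSE], gm$dem$ids,
                              labels = gm$dem$labels)
  export_feature_csv(one, path)
  expect_identical(strsplit(readLines(path, n = 1), ",")[[1]],
                   c("id", "f_0", "label"))
})

test_that("ranking CSV has iteration rows and blank cells", {
  gm <- generate_feature_matrix(matrix_spec(n = 150, d = 8, n_informative = 3, seed = 6))
  sel <- rfe_select(gm$dem, n_target = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  export_ranking_csv(sel$ranking, path)
  tab <- read.csv(path, check.names = FALSE)
  expect_identical(nrow(tab), 10L)
  expect_identical(names(tab)[1], "iteration")
})
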