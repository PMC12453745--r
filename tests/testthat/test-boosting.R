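test_that("initial weights are all ones", {
  expect_identical(init_weights(4), c(1, 1, 1, 1))
  expect_identical(init_weights(1), 1)
  expect_error(init_weights(0), "positive")
})

test_that("misclassified samples gain +1, others are untouched", {
  expect_identical(update_weights(c(1, 1, 1), 3L), c(1, 1, 2))
  expect_identical(update_weights(c(1, 1, 1), integer(0)), c(1, 1, 1))
  w <- update_weights(update_weights(c(1, 1), 1L), 1L)
  expect_identical(w, c(3, 1))
  expect_error(update_weights(c(1, 1), 5L), "out of range")
})

test_that("weak learners fit and differentiate deterministically", {
  dem <- separable_dem(60)
  spec <- weak_learner_spec("linear", seed = 4)
  m1 <- fit_weak_learner(spec, dem$X, dem$labels)
  m2 <- fit_weak_learner(spec, dem$X, dem$labels)
  expect_identical(m1$params, m2$params)
  expect_equal(as.integer(predict_weak(m1, dem$X) >= 0.5), dem$labels)
  g <- input_gradient(m1, dem$X, dem$labels)
  expect_identical(dim(g), dim(dem$X))
  expect_true(all(is.finite(g)))
  # mlp kind trains too
  mm <- fit_weak_learner(weak_learner_spec("mlp", seed = 4), dem$X, dem$labels)
  expect_gt(mean(as.integer(predict_weak(mm, dem$X) >= 0.5) == dem$labels),
            0.9)
})

test_that("a separable problem yields a perfect single-learner ensemble", {
  dem <- separable_dem(80)
  parts <- feba:::split_three(dem$labels, 0.25, 0.25, seed = 1)
  tr <- feba:::subset_dem(dem, parts$train)
  va <- feba:::subset_dem(dem, parts$val)
  ens <- train_ensemble(tr, va, list(weak_learner_spec("linear", seed = 2)))
  expect_length(ens$learners, 1)
  pred <- predict_vote(ens, tr)
  expect_identical(pred$labels, tr$labels)
  expect_identical(pred$confidence, rep(1, nrow(tr$X)))
  # no misclassification on the training set, so no weight moved
  expect_identical(ens$final_weights, rep(1, nrow(tr$X)))
})

test_that("an unreachable threshold raises the empty-ensemble error", {
  dem <- separable_dem(40)
  parts <- feba:::split_three(dem$labels, 0.25, 0.25, seed = 1)
  expect_error(
    train_ensemble(feba:::subset_dem(dem, parts$train),
                   feba:::subset_dem(dem, parts$val),
                   list(weak_learner_spec("linear", seed = 2)),
                   threshold = 1.0),
    "empty ensemble")
})

test_that("sample weights grow exactly on misclassified training rows", {
  gm <- generate_feature_matrix(matrix_spec(n = 200, d = 6, n_informative = 2,
                                            mean_shift = 1, seed = 8))
  parts <- feba:::split_three(gm$dem$labels, 0.2, 0.2, seed = 8)
  tr <- feba:::subset_dem(gm$dem, parts$train)
  va <- feba:::subset_dem(gm$dem, parts$val)
  ens <- train_ensemble(tr, va, learner_roster(2, seed = 8))
  expect_true(all(ens$final_weights >= 1))
  expect_true(any(ens$final_weights > 1))   # imperfect learners exist
  expect_identical(nrow(ens$history), 4L)
  expect_true(all(ens$vote_weights > 0.5 & ens$vote_weights <= 1))
})

test_that("weighted majority voting matches hand sums and tie rule", {
  # weights {+: 0.9}, {-: 0.4}, {-: 0.4} -> + wins 0.9 vs 0.8
  v <- vote_from_predictions(matrix(c(1, 0, 0), 1), c(0.9, 0.4, 0.4))
  expect_identical(v$labels, 1L)
  expect_equal(v$confidence, 0.9 / 1.7)
  # two equal learners disagreeing -> tie resolves to 0
  t <- vote_from_predictions(matrix(c(1, 0), 1), c(0.7, 0.7))
  expect_identical(t$labels, 0L)
  expect_equal(t$confidence, 0.5)
})

test_that("ensemble training and prediction are fully reproducible", {
  gm <- generate_feature_matrix(matrix_spec(n = 150, d = 5, n_informative = 2, seed = 12))
  parts <- feba:::split_three(gm$dem$labels, 0.2, 0.2, seed = 12)
  tr <- feba:::subset_dem(gm$dem, parts$train)
  va <- feba:::subset_dem(gm$dem, parts$val)
  te <- feba:::subset_dem(gm$dem, parts$test)
  e1 <- train_ensemble(tr, va, learner_roster(2, seed = 3))
  e2 <- train_ensemble(tr, va, learner_roster(2, seed = 3))
  expect_identical(e1$vote_weights, e2$vote_weights)
  expect_identical(e1$final_weights, e2$final_weights)
  expect_identical(predict_vote(e1, te), predict_vote(e2, te))
})

test_that("the boosted vote outperforms the typical weak learner", {
  # the vote should lift the ensemble above the mean held-out accuracy of
  # its accepted members (the boosting claim, measured member-by-member)
  hits <- vapply(1:5, function(s) {
    g <- generate_corpus(corpus_spec(seed = s))
    res <- run_pipeline(g$docs, pipeline_config(seed = s))
    opt <- res$selection$optimized$dem
    te <- feba:::subset_dem(opt, res$split$test)
    ens_acc <- mean(predict_vote(res$ensemble, te)$labels == te$labels)
    member_acc <- vapply(res$ensemble$learners, function(m) {
      mean(as.integer(predict_weak(m, te$X) >= 0.5) == te$labels)
    }, numeric(1))
    ens_acc >= mean(member_acc) - 1e-9
  }, logical(1))
  expect_gte(sum(hits), 4L)
})
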