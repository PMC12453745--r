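test_that("the sign rule matches hand computation, sign(0) = 0", {
  x <- matrix(0, 1, 3)
  g <- matrix(c(0.3, -2, 0), 1, 3)
  p <- perturbation(0.05)
  expect_equal(fgsm_perturb(x, g, p), matrix(c(0.05, -0.05, 0), 1, 3))
  expect_identical(fgsm_perturb(x, g, perturbation(0)), x)
  expect_error(fgsm_perturb(x, matrix(0, 2, 3), p), "shapes")
})

test_that("perturbations respect the L-infinity budget on random batches", {
  p <- perturbation(0.05)
  for (s in 1:25) {
    X <- feba:::with_seed(s, matrix(rnorm(80), 8, 10))
    G <- feba:::with_seed(s + 100, matrix(rnorm(80), 8, 10))
    batch <- adversarial_batch(X, G, p)
    expect_lte(max(abs(batch$perturbed - X)), 0.05 + 1e-15)
    expect_equal(max(abs(batch$perturbed - X)), 0.05)  # some entry saturates
    expect_equal(batch$combined, X + batch$perturbed)
  }
})

test_that("the dual loss combines linearly in lambda", {
  expect_equal(combined_loss(0.3, 0.5, perturbation(0.05, 0)), 0.3)
  expect_equal(combined_loss(0.7, 0.7, perturbation(0.05, 1)), 1.4)
  expect_equal(combined_loss(0.3, 0.5, perturbation(0.05, 0.5)), 0.55)
})

test_that("epsilon zero makes defended training identical to undefended", {
  gm <- generate_feature_matrix(matrix_spec(n = 150, d = 6, n_informative = 2, seed = 17))
  parts <- feba:::split_three(gm$dem$labels, 0.2, 0.2, seed = 17)
  tr <- feba:::subset_dem(gm$dem, parts$train)
  va <- feba:::subset_dem(gm$dem, parts$val)
  te <- feba:::subset_dem(gm$dem, parts$test)
  specs <- learner_roster(1, seed = 6)
  plain <- train_ensemble(tr, va, specs)
  defended <- adversarial_train(tr, va, specs, p = perturbation(0, 1))
  expect_identical(lapply(defended$learners, `[[`, "params"),
                   lapply(plain$learners, `[[`, "params"))
  expect_identical(predict_vote(defended, te), predict_vote(plain, te))
})

test_that("a margin wider than epsilon cannot be attacked", {
  dem <- separable_dem(60, gap = 1)
  parts <- feba:::split_three(dem$labels, 0.25, 0.25, seed = 2)
  ens <- train_ensemble(feba:::subset_dem(dem, parts$train),
                        feba:::subset_dem(dem, parts$val),
                        list(weak_learner_spec("linear", seed = 2)))
  rep_ <- attack_evaluate(ens, dem, p = perturbation(0.05))
  expect_equal(rep_$clean$accuracy, 1)
  expect_equal(rep_$attacked$accuracy, 1)
})

test_that("a zero-epsilon attack leaves the metrics unchanged", {
  gm <- generate_feature_matrix(matrix_spec(n = 120, d = 5, n_informative = 2, seed = 19))
  parts <- feba:::split_three(gm$dem$labels, 0.2, 0.2, seed = 19)
  ens <- train_ensemble(feba:::subset_dem(gm$dem, parts$train),
                        feba:::subset_dem(gm$dem, parts$val),
                        learner_roster(1, seed = 9))
  rep_ <- attack_evaluate(ens, gm$dem, p = perturbation(0))
  expect_identical(rep_$clean, rep_$attacked)
  expect_true(all(rep_$confidence$clean$bin_low >= 0.5))
  expect_identical(sum(rep_$confidence$attacked$count), nrow(gm$dem$X))
})

test_that("attack reports carry confidence histograms over [0.5, 1]", {
  gm <- generate_feature_matrix(matrix_spec(n = 100, d = 4, n_informative = 2, seed = 23,
                                            mean_shift = 0.5))
  parts <- feba:::split_three(gm$dem$labels, 0.2, 0.2, seed = 23)
  ens <- train_ensemble(feba:::subset_dem(gm$dem, parts$train),
                        feba:::subset_dem(gm$dem, parts$val),
                        learner_roster(2, seed = 2))
  rep_ <- attack_evaluate(ens, gm$dem, p = perturbation(0.05))
  h <- rep_$confidence$attacked
  expect_equal(h$bin_low[1], 0.5)
  expect_equal(h$bin_high[nrow(h)], 1)
  expect_identical(sum(h$count), nrow(gm$dem$X))
})
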