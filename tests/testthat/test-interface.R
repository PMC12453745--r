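test_that("corpus JSONL and CSV round-trip with validation", {
  docs <- data.frame(id = c("a", "b", "c"),
                     text = c("one", "two", "three"),
                     label = c(0L, 1L, NA), stringsAsFactors = FALSE)
  jl <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(vapply(seq_len(3), function(i) {
    rec <- list(id = docs$id[i], text = docs$text[i])
    if (!is.na(docs$label[i])) rec$label <- docs$label[i]
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE))
  }, character(1)), jl)
  back <- load_corpus(jl)
  expect_identical(back$id, docs$id)
  expect_identical(back$text, docs$text)
  expect_identical(back$label, docs$label)
  cs <- withr::local_tempfile(fileext = ".csv")
  write.csv(docs, cs, row.names = FALSE)
  expect_identical(load_corpus(cs)$text, docs$text)
})

test_that("malformed corpora are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c('{"id":"a","text":"x"}', '{"id":"a","text":"y"}'), f)
  expect_error(load_corpus(f), "duplicate id: a")
  writeLines(c('{"id":"a","text":"x","label":2}'), f)
  expect_error(load_corpus(f), "label must be 0 or 1")
  writeLines(c('{"id":"a","text":"x"}', '{"id":"b"}'), f)
  expect_error(load_corpus(f), "missing text field at line 2")
  writeLines(c('{"id":"a","text":"x"}', "{not json"), f)
  expect_error(load_corpus(f), "line 2")
})

test_that("bag-of-words counts match hand tallies", {
  cp <- tiny_corpus(list(c("sad", "sad", "rain"), c("rain", "happy")),
                    labels = c(1, 0))
  bow <- bow_matrix(cp)
  expect_setequal(bow$feature_names, c("sad", "rain", "happy"))
  expect_equal(bow$X[1, "sad"], 2, ignore_attr = TRUE)
  expect_equal(bow$X[2, "sad"], 0, ignore_attr = TRUE)
  expect_equal(bow$X[2, "happy"], 1, ignore_attr = TRUE)
  cap <- bow_matrix(cp, top_v = 2)
  expect_identical(ncol(cap$X), 2L)
})

test_that("pipeline configs hash deterministically and reject unknowns", {
  c1 <- pipeline_config(seed = 2)
  c2 <- pipeline_config(seed = 2)
  c3 <- pipeline_config(seed = 3)
  expect_identical(c1$hash, c2$hash)
  expect_false(identical(c1$hash, c3$hash))
  expect_error(pipeline_config(bogus_key = 1), "unknown config keys")
})

test_that("YAML configs resolve against the same defaults", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("seed: 2", "n_target: 12", "adversarial: true"), f)
  cfg <- pipeline_config_from_yaml(f)
  expect_identical(cfg$n_target, 12L)
  expect_true(cfg$adversarial)
  expect_identical(cfg$hash, pipeline_config(seed = 2L, n_target = 12L,
                                             adversarial = TRUE)$hash)
  writeLines("bogus: 1", f)
  expect_error(pipeline_config_from_yaml(f), "unknown config keys")
})

test_that("the end-to-end run writes parseable, reproducible artifacts", {
  g <- generate_corpus(corpus_spec(n_docs = 200, seed = 4))
  cfg <- pipeline_config(seed = 4, embed_dim = 16, n_target = 8,
                         learners_per_kind = 1, epochs = 60,
                         encoder = "mean")
  out <- withr::local_tempdir()
  r1 <- run_pipeline(g$docs, cfg, out_dir = out)
  expect_true(file.exists(file.path(out, "optimized.csv")))
  expect_true(file.exists(file.path(out, "ranking.csv")))
  met <- jsonlite::fromJSON(file.path(out, "metrics.json"))
  expect_identical(met$config_hash, cfg$hash)
  expect_identical(met$schema_version, "1.0")
  back <- read_feature_csv(file.path(out, "optimized.csv"))
  expect_identical(back$X, r1$selection$optimized$dem$X)
  r2 <- run_pipeline(g$docs, cfg)
  expect_identical(r1$metrics$test, r2$metrics$test)
  expect_identical(ncol(r1$selection$optimized$dem$X), 8L)
})

test_that("the baseline comparison reports every family on both feature sets", {
  gm <- generate_feature_matrix(matrix_spec(n = 120, d = 6, seed = 15,
                                            mean_shift = 1.5,
                                            n_informative = 3))
  bow_like <- gm$dem
  opt_like <- doc_embedding_matrix(gm$dem$X[, 1:3], gm$dem$ids,
                                   labels = gm$dem$labels)
  cmp <- compare_baselines(bow_like, opt_like, seed = 2)
  expect_identical(nrow(cmp), 10L)
  expect_setequal(unique(cmp$family), c("svm", "knn", "rf", "nb", "lr"))
  expect_true(all(cmp$accuracy >= 0 & cmp$accuracy <= 1))
})
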