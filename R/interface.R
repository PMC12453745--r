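# Orchestration: corpus I/O, bag-of-words baseline features, the end-to-end
# pipeline runner, and the baseline-classifier comparison harness.

#' Load a labeled corpus from JSONL or CSV
#'
#' JSONL: one object per line with keys `id`, `text` and optional `label`.
#' CSV: columns `id`, `text`, optional `label`. Records are validated:
#' duplicate ids and labels outside \{0, 1\} are rejected with the offending
#' id / line number.
#'
#' @param path File path.
#' @param format `"jsonl"` or `"csv"`; guessed from the extension by default.
#' @return Data frame with columns `id`, `text`, `label` (`NA` if absent).
#' @export
load_corpus <- function(path, format = c("auto", "jsonl", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_feba("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else
      "jsonl"
  }
  if (format == "csv") {
    tab <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
    if (!all(c("id", "text") %in% names(tab))) {
      stop_feba("csv must have columns id,text[,label]")
    }
    docs <- data.frame(id = as.character(tab$id), text = tab$text,
                       label = if ("label" %in% names(tab)) tab$label else
                         NA_integer_,
                       stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    recs <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop_feba(
                        "malformed JSON at line %d: %s", i, conditionMessage(e)))
      if (is.null(rec$text)) stop_feba("missing text field at line %d", i)
      if (is.null(rec$id)) stop_feba("missing id field at line %d", i)
      lab <- rec$label
      if (is.null(lab) || !length(lab)) lab <- NA
      list(id = as.character(rec$id), text = as.character(rec$text),
           label = as.numeric(lab))
    })
    docs <- data.frame(id = vapply(recs, `[[`, character(1), "id"),
                       text = vapply(recs, `[[`, character(1), "text"),
                       label = vapply(recs, `[[`, numeric(1), "label"),
                       stringsAsFactors = FALSE)
  }
  if (anyDuplicated(docs$id)) {
    stop_feba("duplicate id: %s", docs$id[duplicated(docs$id)][1])
  }
  bad <- !is.na(docs$label) & !docs$label %in% c(0, 1)
  if (any(bad)) stop_feba("label must be 0 or 1 (id %s)", docs$id[bad][1])
  docs$label <- as.integer(docs$label)
  docs
}

#' Write a tokenized corpus as JSONL
#'
#' One object per line with `id`, `tokens` (array) and `label`.
#'
#' @param corpus A `feba_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  stopifnot(inherits(corpus, "feba_corpus"))
  lines <- vapply(seq_along(corpus$id), function(i) {
    as.character(jsonlite::toJSON(
      list(id = corpus$id[i], tokens = corpus$tokens[[i]],
           label = corpus$label[i]),
      auto_unbox = TRUE, null = "null", na = "null"))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Bag-of-words count features
#'
#' Token-count matrix over the `top_v` most frequent corpus tokens — the
#' standard comparator feature set for the optimized features.
#'
#' @param corpus A `feba_corpus`.
#' @param top_v Vocabulary cap (default 1000).
#' @return A `feba_dem` of counts with tokens as feature names.
#' @export
bow_matrix <- function(corpus, top_v = 1000L) {
  toks <- unlist(corpus$tokens, use.names = FALSE)
  if (!length(toks)) stop_feba("empty corpus")
  tab <- sort(table(toks), decreasing = TRUE)
  vocab <- names(tab)[seq_len(min(top_v, length(tab)))]
  vocab <- sort(vocab)
  idx <- stats::setNames(seq_along(vocab), vocab)
  X <- matrix(0L, length(corpus$id), length(vocab))
  for (i in seq_along(corpus$tokens)) {
    ii <- idx[corpus$tokens[[i]]]
    ii <- ii[!is.na(ii)]
    if (length(ii)) {
      t2 <- table(ii)
      X[i, as.integer(names(t2))] <- as.integer(t2)
    }
  }
  doc_embedding_matrix(X, corpus$id, labels = corpus$label,
                       feature_names = vocab)
}

stratified_split <- function(y, test_frac, seed) {
  te <- with_seed(seed, stratified_sample(y, test_frac))
  list(train = setdiff(seq_along(y), te), test = te)
}

#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end run; unknown names are
#' rejected. The resolved configuration is hashed (md5) and stamped into
#' every artifact the run writes.
#'
#' @param ... Overrides of the defaults (see the source for the full set:
#'   seeds, embedding dimension and window, RFE target and iterations, tree
#'   depth, learner roster size, acceptance threshold, epsilon, lambda,
#'   validation/test fractions, encoder, BOW cap).
#' @return A `feba_config` with a `hash` field.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L, do_stem = FALSE, encoder = "concat",
    embed_dim = 80L, window = 5L, min_count = 1L,
    n_target = 20L, rfe_iterations = 10L,
    tree_max_depth = 10L, tree_min_split = 5L,
    learners_per_kind = 3L, learner_kinds = c("mlp", "linear"),
    epochs = 200L, learning_rate = 0.05, hidden = 8L,
    threshold = 0.5, adversarial = FALSE, epsilon = 0.05, lambda = 1.0,
    val_frac = 0.2, test_frac = 0.2, bow_top_v = 1000L)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) stop_feba("unknown config keys: %s",
                                 paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, overrides)
  cfg$hash <- hash_config(cfg)
  structure(cfg, class = "feba_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file holds any subset of the [pipeline_config()] keys; unknown keys
#' are rejected, missing ones take their defaults.
#'
#' @param path YAML file path.
#' @return A `feba_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_feba("file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' @export
print.feba_config <- function(x, ...) {
  cat(sprintf("<feba_config> seed %d, encoder %s, d = %d -> %d features, %s (hash %s)\n",
              x$seed, x$encoder, x$embed_dim, x$n_target,
              if (x$adversarial) sprintf("defended (eps = %g)", x$epsilon)
              else "undefended", substr(x$hash, 1, 8)))
  invisible(x)
}

split_three <- function(y, val_frac, test_frac, seed) {
  te <- with_seed(derive_seed(seed, 71L), stratified_sample(y, test_frac))
  rest <- setdiff(seq_along(y), te)
  va_rel <- with_seed(derive_seed(seed, 72L),
                      stratified_sample(y[rest], val_frac / (1 - test_frac)))
  va <- rest[va_rel]
  list(train = setdiff(rest, va), val = va, test = te)
}

subset_dem <- function(dem, idx) {
  doc_embedding_matrix(dem$X[idx, , drop = FALSE], dem$ids[idx],
                       labels = dem$labels[idx],
                       feature_names = dem$feature_names)
}

#' Run the full pipeline end to end
#'
#' Stages: preprocessing, embedding (+ sentiment features), RFE feature
#' selection, train/validation/test split, boosted-ensemble training
#' (defended when `cfg$adversarial`), and evaluation (confusion metrics,
#' ROC/PR AUC, FGSM attack report). When `out_dir` is given, the optimized
#' feature CSV, the RFE ranking CSV, a model summary and a metrics JSON —
#' each stamped with the config hash — are written there.
#'
#' @param docs Raw corpus data frame (`id`, `text`, `label`), e.g. from
#'   [generate_corpus()] or [load_corpus()].
#' @param cfg A [pipeline_config()].
#' @param out_dir Optional artifact directory.
#' @return A list with the fitted objects and a `metrics` block.
#' @export
run_pipeline <- function(docs, cfg = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "feba_config"))
  corpus <- prep_corpus(docs, do_stem = cfg$do_stem)
  vocab <- build_vocab(corpus, min_count = cfg$min_count)
  emb <- train_word_embeddings(corpus, vocab, d = cfg$embed_dim,
                               window = cfg$window, seed = cfg$seed)
  dem <- embed_corpus(corpus, emb, encoder = cfg$encoder, seed = cfg$seed)
  dem <- add_sentiment_features(dem, corpus)
  sel <- rfe_select(dem,
                    cfg = tree_config(cfg$tree_max_depth, cfg$tree_min_split,
                                      seed = cfg$seed),
                    n_iterations = cfg$rfe_iterations,
                    n_target = min(cfg$n_target, ncol(dem$X)))
  opt <- sel$optimized$dem
  parts <- split_three(opt$labels, cfg$val_frac, cfg$test_frac, cfg$seed)
  specs <- learner_roster(cfg$learners_per_kind, cfg$learner_kinds,
                          seed = cfg$seed, hidden = cfg$hidden,
                          learning_rate = cfg$learning_rate,
                          epochs = cfg$epochs)
  p <- perturbation(cfg$epsilon, cfg$lambda)
  ens <- train_ensemble(subset_dem(opt, parts$train),
                        subset_dem(opt, parts$val), specs,
                        threshold = cfg$threshold,
                        adversarial = if (cfg$adversarial) p else NULL)
  test <- subset_dem(opt, parts$test)
  pred <- predict_vote(ens, test)
  metrics <- confusion_and_metrics(test$labels, pred$labels)
  curves <- roc_pr_curves(test$labels, pred$score)
  attack <- attack_evaluate(ens, test, p = p)
  result <- list(config = cfg, corpus = corpus, embeddings = emb,
                 features = dem, selection = sel, ensemble = ens,
                 split = parts,
                 metrics = list(test = metrics,
                                roc_auc = curves$roc$auc,
                                pr_auc = curves$pr$auc,
                                attack = attack))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    export_feature_csv(sel$optimized, file.path(out_dir, "optimized.csv"))
    export_ranking_csv(sel$ranking, file.path(out_dir, "ranking.csv"))
    report <- list(schema_version = "1.0", config_hash = cfg$hash,
                   seed = cfg$seed,
                   test_accuracy = metrics$accuracy,
                   test_f1 = metrics$f1,
                   roc_auc = curves$roc$auc, pr_auc = curves$pr$auc,
                   clean_attacked = list(
                     clean = attack$clean$accuracy,
                     attacked = attack$attacked$accuracy),
                   learner_history = ens$history)
    jsonlite::write_json(report, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

baseline_families <- function() c("svm", "knn", "rf", "nb", "lr")

fit_predict_baseline <- function(family, Xtr, ytr, Xte, seed = 1L) {
  ytr_f <- factor(ytr, levels = c(0, 1))
  switch(family,
    svm = {
      scl <- apply(Xtr, 2L, stats::sd) > 0   # constant columns break scaling
      m <- e1071::svm(x = Xtr, y = ytr_f, kernel = "radial", scale = scl)
      as.integer(as.character(predict(m, Xte)))
    },
    knn = {
      as.integer(as.character(
        with_seed(seed, class::knn(Xtr, Xte, cl = ytr_f, k = 5L))))
    },
    rf = {
      m <- with_seed(seed, randomForest::randomForest(
        x = Xtr, y = ytr_f, ntree = 200L))
      as.integer(as.character(predict(m, Xte)))
    },
    nb = {
      m <- e1071::naiveBayes(x = as.data.frame(Xtr), y = ytr_f)
      as.integer(as.character(predict(m, as.data.frame(Xte))))
    },
    lr = {
      spec <- weak_learner_spec("linear", seed = seed)
      m <- fit_weak_learner(spec, Xtr, ytr)
      as.integer(predict_weak(m, Xte) >= 0.5)
    },
    stop_feba("unknown baseline family: %s", family))
}

#' Compare baseline classifiers on optimized features vs bag-of-words
#'
#' Trains each baseline family (margin: SVM; neighbor: kNN; tree ensemble:
#' random forest; probabilistic: naive Bayes; linear: logistic regression)
#' on both feature sets with a shared stratified train/test split, and
#' reports per-family test accuracy.
#'
#' @param bow A labeled `feba_dem` of bag-of-words counts.
#' @param optimized A labeled `feba_dem` of optimized features (same rows).
#' @param families Subset of `c("svm","knn","rf","nb","lr")`.
#' @param test_frac Held-out fraction (default 0.3).
#' @param seed Split/model seed.
#' @return Data frame with `family`, `featureset`, `accuracy`.
#' @export
compare_baselines <- function(bow, optimized,
                              families = baseline_families(),
                              test_frac = 0.3, seed = 1L) {
  stopifnot(inherits(bow, "feba_dem"), inherits(optimized, "feba_dem"),
            identical(bow$labels, optimized$labels))
  y <- bow$labels
  sp <- stratified_split(y, test_frac, derive_seed(seed, 5L))
  rows <- list()
  for (fam in families) {
    for (fs in c("bow", "optimized")) {
      dem <- if (fs == "bow") bow else optimized
      pred <- fit_predict_baseline(fam, dem$X[sp$train, , drop = FALSE],
                                   y[sp$train],
                                   dem$X[sp$test, , drop = FALSE],
                                   seed = derive_seed(seed, 100L))
      rows[[length(rows) + 1L]] <- data.frame(
        family = fam, featureset = fs,
        accuracy = mean(pred == y[sp$test]))
    }
  }
  do.call(rbind, rows)
}
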