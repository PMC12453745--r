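# Decision-tree importance scoring and recursive feature elimination (RFE).
#
# The tree is a CART-style binary classifier grown on Gini impurity; feature
# importance is the normalized total impurity decrease attributed to each
# feature over all splits. RFE repeatedly fits the tree, bins surviving
# importances into quartile rank scores {0,1,2,3}, eliminates the rank-0
# features (at minimum the single lowest-importance one, so progress is
# guaranteed), and stops when the surviving set reaches the target size.
# All ties break toward the lower column index, deterministically.

#' Decision-tree configuration
#'
#' @param max_depth Maximum tree depth (default 10).
#' @param min_samples_split Minimum node size eligible for splitting
#'   (default 5).
#' @param seed Integer recorded for provenance (the fit is deterministic).
#' @return A `feba_tree_config`.
#' @export
tree_config <- function(max_depth = 10L, min_samples_split = 5L, seed = 1L) {
  stopifnot(max_depth >= 1L, min_samples_split >= 2L)
  structure(list(max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 seed = as.integer(seed)),
            class = "feba_tree_config")
}

gini_node <- function(n1, n) {
  p <- n1 / n
  2 * p * (1 - p)
}

# Best Gini split of one node; vectorized over thresholds per feature.
best_split <- function(X, y, idx) {
  n <- length(idx)
  n1 <- sum(y[idx])
  g_parent <- gini_node(n1, n)
  best <- list(gain = 0, feature = NA_integer_, threshold = NA_real_)
  for (j in seq_len(ncol(X))) {
    x <- X[idx, j]
    o <- order(x, method = "radix")
    xs <- x[o]
    ys <- y[idx][o]
    k <- seq_len(n - 1L)
    valid <- xs[k] < xs[k + 1L]
    if (!any(valid)) next
    cum1 <- cumsum(ys)[k]
    nl <- k
    nr <- n - k
    gl <- 1 - (cum1 / nl)^2 - ((nl - cum1) / nl)^2
    gr <- 1 - ((n1 - cum1) / nr)^2 - ((nr - n1 + cum1) / nr)^2
    gain <- g_parent - (nl * gl + nr * gr) / n
    gain[!valid] <- -Inf
    kk <- which.max(gain)                 # first max: lowest threshold wins
    if (gain[kk] > best$gain + 1e-12) {   # strict: lower feature index wins
      best <- list(gain = gain[kk], feature = j,
                   threshold = (xs[kk] + xs[kk + 1L]) / 2)
    }
  }
  best
}

grow_tree <- function(X, y, idx, depth, cfg, state) {
  n <- length(idx)
  n1 <- sum(y[idx])
  leaf <- function() list(leaf = TRUE, pred = as.integer(n1 * 2 > n),
                          prob = n1 / n, n = n)
  if (depth >= cfg$max_depth || n < cfg$min_samples_split ||
      n1 == 0L || n1 == n) {
    return(leaf())
  }
  sp <- best_split(X, y, idx)
  if (is.na(sp$feature) || sp$gain <= 1e-12) return(leaf())
  state$importance[sp$feature] <- state$importance[sp$feature] +
    (n / state$n_total) * sp$gain
  left <- idx[X[idx, sp$feature] <= sp$threshold]
  right <- idx[X[idx, sp$feature] > sp$threshold]
  list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
       n = n, prob = n1 / n,
       left = grow_tree(X, y, left, depth + 1L, cfg, state),
       right = grow_tree(X, y, right, depth + 1L, cfg, state))
}

#' Fit a Gini decision tree and return feature importances
#'
#' Importance of feature `j` is the total node-weighted Gini impurity
#' decrease over all splits on `j`, normalized to sum to 1 (all-zero when the
#' tree makes no split). A single-class response yields all-zero importances
#' with a warning.
#'
#' @param X Numeric n x d matrix.
#' @param y 0/1 response vector of length n.
#' @param cfg A [tree_config()].
#' @param return_tree Also return the fitted tree (for prediction)?
#' @return Numeric d-vector of importances (sums to 1 when any split
#'   occurred), or a list `(importance, tree)` when `return_tree = TRUE`.
#' @export
fit_tree_importance <- function(X, y, cfg = tree_config(),
                                return_tree = FALSE) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), is_binary_labels(y))
  if (nrow(X) < cfg$min_samples_split) {
    stop_feba("need at least min_samples_split = %d samples",
              cfg$min_samples_split)
  }
  state <- new.env()
  state$importance <- numeric(ncol(X))
  state$n_total <- nrow(X)
  if (length(unique(y)) < 2L) {
    warning("single-class response: no split possible, importances all zero")
    tree <- list(leaf = TRUE, pred = as.integer(y[1]), prob = mean(y),
                 n = nrow(X))
  } else {
    tree <- grow_tree(X, y, seq_len(nrow(X)), 0L, cfg, state)
  }
  imp <- state$importance
  if (sum(imp) > 0) imp <- imp / sum(imp)
  names(imp) <- colnames(X)
  if (return_tree) list(importance = imp, tree = tree) else imp
}

#' Predict class probabilities from a fitted Gini tree
#'
#' @param tree The `tree` component returned by
#'   `fit_tree_importance(..., return_tree = TRUE)`.
#' @param X Numeric matrix with the columns the tree was grown on.
#' @return Numeric vector of P(label = 1).
#' @export
predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  one <- function(node, xrow) {
    while (!node$leaf) {
      node <- if (xrow[node$feature] <= node$threshold) node$left else
        node$right
    }
    node$prob
  }
  vapply(seq_len(nrow(X)), function(i) one(tree, X[i, ]), numeric(1))
}

quartile_rank_scores <- function(imp) {
  br <- stats::quantile(imp, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  rowSums(outer(imp, br, `>`))
}

#' Recursive feature elimination to an optimized feature set
#'
#' Per iteration: fit the Gini tree on the surviving features, bin surviving
#' importances into quartile rank scores 0-3, and eliminate the rank-0
#' features (at minimum the single lowest-importance feature; never more
#' than would undershoot `n_target`). Iterating stops when the surviving set
#' reaches `n_target` or iterations are exhausted, after which the surviving
#' set is truncated to exactly `n_target` by final importance order.
#'
#' @param x A labeled `feba_dem`, or a numeric matrix (then `y` is required).
#' @param y 0/1 labels when `x` is a bare matrix.
#' @param cfg A [tree_config()]; defaults to depth 10, min split 5.
#' @param n_iterations Maximum RFE iterations (default 10).
#' @param n_target Number of features to keep.
#' @return List with `optimized` (a `feba_ofs`) and `ranking` (a
#'   `feba_ranking`: per-iteration score matrix with `NA` after elimination,
#'   elimination order, selected set).
#' @export
rfe_select <- function(x, y = NULL, cfg = tree_config(),
                       n_iterations = 10L, n_target) {
  if (inherits(x, "feba_dem")) {
    X <- x$X
    y <- y %||% x$labels
    ids <- x$ids
  } else {
    X <- as.matrix(x)
    ids <- rownames(X) %||% as.character(seq_len(nrow(X)))
  }
  d <- ncol(X)
  if (is.null(y)) stop_feba("labels required for feature selection")
  if (n_target < 1L || n_target > d) {
    stop_feba("n_target must be in [1, %d]", d)
  }
  feature_names <- colnames(X) %||% paste0("f_", seq_len(d) - 1L)
  surv <- seq_len(d)
  eliminated <- integer(0)
  scores <- matrix(NA_real_, n_iterations, d,
                   dimnames = list(NULL, feature_names))
  last_imp <- NULL
  for (it in seq_len(n_iterations)) {
    if (length(surv) <= n_target) break
    imp <- fit_tree_importance(X[, surv, drop = FALSE], y, cfg)
    last_imp <- stats::setNames(imp, NULL)
    sc <- quartile_rank_scores(imp)
    scores[it, surv] <- sc
    cand <- which(sc == 0)
    if (!length(cand)) cand <- order(imp, seq_along(imp))[1L]
    cand <- cand[order(imp[cand], cand)]          # lowest importance first
    n_drop <- min(length(cand), length(surv) - n_target)
    n_drop <- max(n_drop, 0L)
    if (n_drop == 0L) break
    drop_local <- cand[seq_len(n_drop)]
    eliminated <- c(eliminated, surv[drop_local])
    surv <- surv[-drop_local]
  }
  if (length(surv) > n_target) {
    imp <- fit_tree_importance(X[, surv, drop = FALSE], y, cfg)
    keep_local <- sort(order_desc_stable(imp)[seq_len(n_target)])
    drop_local <- setdiff(seq_along(surv), keep_local)
    drop_local <- drop_local[order(imp[drop_local], drop_local)]
    eliminated <- c(eliminated, surv[drop_local])
    surv <- surv[keep_local]
  }
  ranking <- structure(list(scores = scores, eliminated = eliminated,
                            selected = surv,
                            n_iterations = as.integer(n_iterations),
                            feature_names = feature_names),
                       class = "feba_ranking")
  dem <- doc_embedding_matrix(X[, surv, drop = FALSE], ids,
                              labels = if (inherits(x, "feba_dem")) x$labels
                                       else as.integer(y),
                              feature_names = feature_names[surv])
  optimized <- structure(list(dem = dem, selected = surv, ranking = ranking),
                         class = "feba_ofs")
  list(optimized = optimized, ranking = ranking)
}

#' @export
print.feba_ofs <- function(x, ...) {
  cat(sprintf("<feba_ofs> %d documents x %d selected features\n",
              nrow(x$dem$X), length(x$selected)))
  invisible(x)
}

#' @export
print.feba_ranking <- function(x, ...) {
  cat(sprintf("<feba_ranking> %d iterations x %d features; %d eliminated, %d selected\n",
              nrow(x$scores), ncol(x$scores), length(x$eliminated),
              length(x$selected)))
  invisible(x)
}

fmt_num <- function(v) sprintf("%.17g", v)

#' Write a feature matrix to CSV (lossless round trip)
#'
#' Header `id,<feature names...>,label`; numeric cells are written with 17
#' significant digits so a read-back reproduces the matrix bit-exactly.
#'
#' @param fs A `feba_ofs` or `feba_dem`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_feature_csv()]
#' @export
export_feature_csv <- function(fs, path) {
  dem <- if (inherits(fs, "feba_ofs")) fs$dem else fs
  stopifnot(inherits(dem, "feba_dem"))
  lab <- dem$labels %||% rep(NA_integer_, nrow(dem$X))
  header <- paste(c("id", dem$feature_names, "label"), collapse = ",")
  rows <- vapply(seq_len(nrow(dem$X)), function(i) {
    paste(c(dem$ids[i], fmt_num(dem$X[i, ]), lab[i]), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a feature matrix written by [export_feature_csv()]
#'
#' @param path CSV path with header `id,<features...>,label`.
#' @return A `feba_dem`.
#' @export
read_feature_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(tab)[1] == "id", names(tab)[ncol(tab)] == "label")
  feat <- names(tab)[-c(1, ncol(tab))]
  X <- as.matrix(tab[, feat, drop = FALSE])
  labels <- if (all(is.na(tab$label))) NULL else as.integer(tab$label)
  doc_embedding_matrix(X, tab$id, labels = labels, feature_names = feat)
}

#' Write an RFE ranking table to CSV
#'
#' Rows are iterations, columns feature names; blank cells mark features
#' already eliminated in that iteration (or iterations not run).
#'
#' @param ranking A `feba_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_ranking_csv <- function(ranking, path) {
  stopifnot(inherits(ranking, "feba_ranking"))
  tab <- as.data.frame(ranking$scores)
  tab <- cbind(iteration = seq_len(nrow(tab)), tab)
  write.csv(tab, path, row.names = FALSE, na = "")
  invisible(path)
}
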