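# Word embeddings and per-document vectors.
#
# Embeddings are trained spectrally: a symmetric windowed co-occurrence
# matrix is transformed to positive pointwise mutual information (PPMI) and
# factorized by truncated SVD; word vectors are U_k * sqrt(S_k) with
# sign-fixed singular vectors. This factorization is the classical spectral
# counterpart of skip-gram negative sampling and is exactly deterministic,
# which the pipeline's reproducibility contract relies on.

#' Construct a document-embedding matrix
#'
#' The universal numeric container of the pipeline: one row per document,
#' one column per feature, with optional 0/1 labels.
#'
#' @param X Numeric matrix (n x d), finite entries.
#' @param ids Character vector of document ids (length n).
#' @param labels Optional 0/1 integer vector (length n).
#' @param feature_names Character vector of d feature names.
#' @return An object of class `feba_dem`.
#' @export
doc_embedding_matrix <- function(X, ids,
                                 labels = NULL,
                                 feature_names = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_names)) {
    feature_names <- paste0("f_", seq_len(ncol(X)) - 1L)
  }
  ids <- as.character(ids)
  stopifnot(length(ids) == nrow(X), length(feature_names) == ncol(X))
  if (!all(is.finite(X))) stop_feba("embedding matrix has non-finite entries")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    stopifnot(length(labels) == nrow(X))
    if (!all(labels %in% c(0L, 1L) | is.na(labels))) {
      stop_feba("labels must be 0 or 1")
    }
  }
  dimnames(X) <- list(ids, feature_names)
  structure(list(ids = ids, X = X, labels = labels,
                 feature_names = feature_names),
            class = "feba_dem")
}

#' @export
print.feba_dem <- function(x, ...) {
  cat(sprintf("<feba_dem> %d documents x %d features%s\n",
              nrow(x$X), ncol(x$X),
              if (is.null(x$labels)) " (unlabeled)" else
                sprintf(" (labels: %d/%d positive)",
                        sum(x$labels == 1L, na.rm = TRUE), length(x$labels))))
  invisible(x)
}

#' @export
dim.feba_dem <- function(x) dim(x$X)

#' Build a frequency-thresholded vocabulary
#'
#' @param corpus A `feba_corpus` from [prep_corpus()] (or any list with a
#'   `tokens` list-column).
#' @param min_count Minimum corpus frequency for a token to enter the
#'   vocabulary (>= 1).
#' @return A `feba_vocab`: `tokens` (indexed order), `index` (token -> 1-based
#'   position), `counts`, `min_count`.
#' @export
build_vocab <- function(corpus, min_count = 1L) {
  stopifnot(min_count >= 1L)
  toks <- unlist(corpus$tokens, use.names = FALSE)
  if (!length(corpus$tokens) || !length(toks)) stop_feba("empty corpus")
  tab <- table(toks)
  keep <- tab[tab >= min_count]
  keep <- keep[order(names(keep))]  # deterministic order
  tokens <- names(keep)
  structure(list(tokens = tokens,
                 index = stats::setNames(seq_along(tokens), tokens),
                 counts = as.integer(keep),
                 min_count = as.integer(min_count)),
            class = "feba_vocab")
}

#' @export
print.feba_vocab <- function(x, ...) {
  cat(sprintf("<feba_vocab> %d tokens (min_count = %d)\n",
              length(x$tokens), x$min_count))
  invisible(x)
}

co_occurrence_matrix <- function(corpus, vocab, window) {
  V <- length(vocab$tokens)
  if (V > 4000L) {
    stop_feba("vocabulary too large for dense co-occurrence (%d tokens); raise min_count", V)
  }
  idx <- vocab$index
  pair_a <- vector("list", length(corpus$tokens))
  pair_b <- pair_a
  for (di in seq_along(corpus$tokens)) {
    ii <- unname(idx[corpus$tokens[[di]]])
    ii <- ii[!is.na(ii)]
    n <- length(ii)
    if (n < 2L) next
    offs <- seq_len(min(window, n - 1L))
    pair_a[[di]] <- unlist(lapply(offs, function(o) ii[seq_len(n - o)]))
    pair_b[[di]] <- unlist(lapply(offs, function(o) ii[seq.int(o + 1L, n)]))
  }
  a <- unlist(pair_a); b <- unlist(pair_b)
  C <- matrix(0, V, V)
  if (length(a)) {
    lin <- c((b - 1) * V + a, (a - 1) * V + b)  # symmetric
    tt <- table(lin)
    C[as.numeric(names(tt))] <- as.numeric(tt)
  }
  C
}

#' Train word embeddings on a token corpus
#'
#' Fits d-dimensional word vectors by PPMI + truncated SVD of the windowed
#' co-occurrence matrix. The fit is exactly deterministic: singular vector
#' signs are fixed so that the largest-magnitude loading of each component is
#' positive. The `seed` is recorded in the training metadata for provenance
#' (no randomness is consumed by the spectral fit).
#'
#' @param corpus A `feba_corpus`.
#' @param vocab Vocabulary from [build_vocab()] over the same corpus.
#' @param d Embedding dimension (default 80).
#' @param window Symmetric co-occurrence window (default 5 tokens).
#' @param seed Integer recorded in metadata.
#' @return A `feba_word_embeddings`: `matrix` (|V| x d, rownames = tokens),
#'   plus training metadata.
#' @export
train_word_embeddings <- function(corpus, vocab, d = 80L, window = 5L,
                                  seed = 1L) {
  if (d < 2L) stop_feba("embedding dimension must be >= 2")
  stopifnot(inherits(vocab, "feba_vocab"), window >= 1L)
  C <- co_occurrence_matrix(corpus, vocab, window)
  total <- sum(C)
  V <- nrow(C)
  W <- matrix(0, V, d)
  if (total > 0) {
    rs <- rowSums(C)
    rs[rs == 0] <- 1  # isolated tokens keep a zero vector
    P <- C / total
    pr <- rs / total
    ppmi <- log(pmax(P, .Machine$double.xmin) / outer(pr, pr))
    ppmi[C == 0] <- 0
    ppmi <- pmax(ppmi, 0)
    k <- min(d, V)
    dec <- svd(ppmi, nu = k, nv = 0)
    U <- dec$u
    for (j in seq_len(k)) {       # sign fix: dominant loading positive
      i_star <- which.max(abs(U[, j]))
      if (U[i_star, j] < 0) U[, j] <- -U[, j]
    }
    W[, seq_len(k)] <- U %*% diag(sqrt(dec$d[seq_len(k)]), k)
  }
  rownames(W) <- vocab$tokens
  colnames(W) <- paste0("f_", seq_len(d) - 1L)
  structure(list(matrix = W, d = as.integer(d), window = as.integer(window),
                 seed = as.integer(seed), method = "ppmi-svd"),
            class = "feba_word_embeddings")
}

#' @export
print.feba_word_embeddings <- function(x, ...) {
  cat(sprintf("<feba_word_embeddings> |V| = %d, d = %d (window %d, %s)\n",
              nrow(x$matrix), x$d, x$window, x$method))
  invisible(x)
}

#' Embed one document as the mean of its token vectors
#'
#' Mean pooling is order-invariant; documents with no in-vocabulary token map
#' to the zero vector and carry `attr(, "oov") = TRUE` so row alignment with
#' labels is preserved instead of dropping the document.
#'
#' @param tokens Character vector of normalized tokens (one document).
#' @param emb A `feba_word_embeddings`.
#' @return Numeric d-vector with attribute `oov`.
#' @export
embed_document <- function(tokens, emb) {
  stopifnot(inherits(emb, "feba_word_embeddings"))
  hit <- tokens[tokens %in% rownames(emb$matrix)]
  if (!length(hit)) {
    v <- numeric(emb$d)
    attr(v, "oov") <- TRUE
    return(v)
  }
  v <- colMeans(emb$matrix[hit, , drop = FALSE])
  attr(v, "oov") <- FALSE
  v
}

#' Embed a corpus into a document-embedding matrix
#'
#' Two encoders share the same contract: `"mean"` pools token vectors by
#' unweighted mean; `"contextual"` runs the token sequence through the
#' package's self-attention layer (seeded random Q/K/V projections, see
#' [init_attention()]) and mean-pools the attended values — a lightweight
#' contextual encoder with no pretrained weights. `"concat"` concatenates
#' both feature blocks.
#'
#' @param corpus A `feba_corpus`.
#' @param emb A `feba_word_embeddings`.
#' @param encoder `"mean"`, `"contextual"` or `"concat"`.
#' @param hidden_dim Attention output width for the contextual encoder.
#' @param seed Seed for the attention projections.
#' @return A `feba_dem` with an `oov` attribute (logical per-document flags).
#' @export
embed_corpus <- function(corpus, emb, encoder = c("mean", "contextual", "concat"),
                         hidden_dim = 64L, seed = 1L) {
  encoder <- match.arg(encoder)
  n <- length(corpus$id)
  mean_X <- t(vapply(corpus$tokens, function(tk) {
    v <- embed_document(tk, emb)
    c(as.numeric(v), as.numeric(attr(v, "oov")))
  }, numeric(emb$d + 1L)))
  oov <- mean_X[, emb$d + 1L] > 0
  mean_X <- mean_X[, seq_len(emb$d), drop = FALSE]
  colnames(mean_X) <- paste0("f_", seq_len(emb$d) - 1L)
  X <- mean_X
  if (encoder != "mean") {
    params <- init_attention(emb$d, hidden_dim, seed = seed)
    ctx <- matrix(0, n, hidden_dim)
    for (i in seq_len(n)) {
      tk <- corpus$tokens[[i]]
      tk <- tk[tk %in% rownames(emb$matrix)]
      if (length(tk)) {
        ctx[i, ] <- attend(emb$matrix[tk, , drop = FALSE], params)$attended
      }
    }
    colnames(ctx) <- paste0("c_", seq_len(hidden_dim) - 1L)
    X <- if (encoder == "contextual") ctx else cbind(mean_X, ctx)
  }
  dem <- doc_embedding_matrix(X, corpus$id, labels = corpus$label)
  attr(dem, "oov") <- oov
  dem
}

#' Within- and between-class embedding similarity
#'
#' Mean pairwise cosine similarity within each label group and across groups.
#' Class-separated corpora should show higher within-class than between-class
#' similarity. Pair enumeration is exhaustive up to `max_exact` documents and
#' a seeded uniform subsample above.
#'
#' @param dem A labeled `feba_dem`.
#' @param max_exact Exhaustive-enumeration cap (default 2000 documents).
#' @param seed Seed for subsampling beyond the cap.
#' @return List with `within_0`, `within_1`, `between` mean cosines and the
#'   number of zero-norm documents excluded.
#' @export
group_similarity <- function(dem, max_exact = 2000L, seed = 1L) {
  stopifnot(inherits(dem, "feba_dem"))
  if (is.null(dem$labels) || anyNA(dem$labels)) stop_feba("labels required")
  X <- dem$X
  y <- dem$labels
  if (nrow(X) > max_exact) {
    keep <- with_seed(seed, sort(sample.int(nrow(X), max_exact)))
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  nrm <- sqrt(rowSums(X^2))
  ok <- nrm > 0
  X <- X[ok, , drop = FALSE] / nrm[ok]
  y <- y[ok]
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L) {
    stop_feba("need at least 2 documents per class")
  }
  S <- tcrossprod(X)
  mean_block <- function(a, b) {
    if (identical(a, b)) {
      s <- S[a, a, drop = FALSE]
      mean(s[upper.tri(s)])
    } else {
      mean(S[a, b, drop = FALSE])
    }
  }
  i0 <- which(y == 0L); i1 <- which(y == 1L)
  list(within_0 = mean_block(i0, i0),
       within_1 = mean_block(i1, i1),
       between = mean_block(i0, i1),
       n_zero_excluded = sum(!ok))
}
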