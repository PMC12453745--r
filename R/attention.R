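# Scaled dot-product self-attention over token-embedding sequences.
#
# Attention weights are row-softmax(Q K' / sqrt(hidden_dim)) with Q = X Wq,
# K = X Wk, V = X Wv; the attended document vector is the mean over token
# positions of the weighted values. Per-dimension signed importance is the
# centered input-space difference between the attention-weighted token
# mixture and the uniform token mean: positive entries mark input dimensions
# the attention emphasizes, negative entries dimensions it down-weights, and
# the vector is exactly zero under uniform attention.

#' Initialize self-attention projections
#'
#' Draws the query/key/value projection matrices from a seeded symmetric
#' zero-mean distribution (scaled Gaussian, sd `1/sqrt(input_dim)`).
#' Parameters are used untrained by default; the projections act as a seeded
#' random feature map.
#'
#' @param input_dim Width of the token embeddings (default 300).
#' @param hidden_dim Attention output width (default 128).
#' @param seed Integer seed.
#' @return A `feba_attention` parameter set with `Wq`, `Wk`, `Wv`.
#' @export
init_attention <- function(input_dim = 300L, hidden_dim = 128L, seed = 1L) {
  if (input_dim < 1L || hidden_dim < 1L) {
    stop_feba("input_dim and hidden_dim must be positive")
  }
  mats <- with_seed(seed, lapply(1:3, function(i) {
    matrix(rnorm(input_dim * hidden_dim, sd = 1 / sqrt(input_dim)),
           input_dim, hidden_dim)
  }))
  structure(list(Wq = mats[[1]], Wk = mats[[2]], Wv = mats[[3]],
                 input_dim = as.integer(input_dim),
                 hidden_dim = as.integer(hidden_dim),
                 seed = as.integer(seed)),
            class = "feba_attention")
}

#' @export
print.feba_attention <- function(x, ...) {
  cat(sprintf("<feba_attention> input_dim = %d, hidden_dim = %d (seed %d)\n",
              x$input_dim, x$hidden_dim, x$seed))
  invisible(x)
}

row_softmax <- function(S) {
  m <- apply(S, 1L, max)
  E <- exp(S - m)
  E / rowSums(E)
}

#' Apply self-attention to a token-embedding sequence
#'
#' @param tokens_X Numeric T x input_dim matrix (one row per token).
#' @param params A `feba_attention` parameter set.
#' @return A `feba_attention_output`: `weights` (T x T, row-stochastic),
#'   `attended` (hidden_dim vector, mean-pooled weighted values) and
#'   `importance` (input_dim signed vector, see [feature_importance()]).
#' @export
attend <- function(tokens_X, params) {
  stopifnot(inherits(params, "feba_attention"))
  tokens_X <- as.matrix(tokens_X)
  if (ncol(tokens_X) != params$input_dim) {
    stop_feba("tokens_X has %d columns, expected input_dim = %d",
              ncol(tokens_X), params$input_dim)
  }
  if (nrow(tokens_X) < 1L) stop_feba("need at least one token")
  Q <- tokens_X %*% params$Wq
  K <- tokens_X %*% params$Wk
  V <- tokens_X %*% params$Wv
  S <- tcrossprod(Q, K) / sqrt(params$hidden_dim)
  W <- row_softmax(S)
  attended <- colMeans(W %*% V)
  # importance in input space: attention token mixture minus uniform mean
  mix <- colMeans(W)                       # column means of weights sum to 1
  importance <- as.numeric(crossprod(tokens_X, mix)) - colMeans(tokens_X)
  structure(list(weights = W, attended = attended, importance = importance),
            class = "feba_attention_output")
}

#' Signed per-dimension feature importance from attention
#'
#' The attention weight matrix is collapsed to a token mixture (its column
#' means, a probability vector); the importance of input dimension `j` is the
#' mixture-weighted mean of that dimension over tokens minus its uniform
#' mean. Exactly zero when attention is uniform. Positive entries mark
#' dimensions attention emphasizes; negative entries mark down-weighted,
#' noise-like dimensions.
#'
#' @inheritParams attend
#' @return Numeric input_dim signed vector.
#' @export
feature_importance <- function(tokens_X, params) {
  attend(tokens_X, params)$importance
}
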