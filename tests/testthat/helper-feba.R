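# Shared fixture builders. Everything is generated in code, seeded.

tiny_corpus <- function(tokens_list, labels = NULL) {
  n <- length(tokens_list)
  structure(list(id = sprintf("t%02d", seq_len(n)),
                 tokens = tokens_list,
                 label = if (is.null(labels)) rep(NA_integer_, n) else
                   as.integer(labels)),
            class = "feba_corpus")
}

# Identity-projection attention parameters for hand-computable examples.
identity_attention <- function(d) {
  structure(list(Wq = diag(d), Wk = diag(d), Wv = diag(d),
                 input_dim = as.integer(d), hidden_dim = as.integer(d),
                 seed = 0L),
            class = "feba_attention")
}

zero_qk_attention <- function(d) {
  structure(list(Wq = matrix(0, d, d), Wk = matrix(0, d, d), Wv = diag(d),
                 input_dim = as.integer(d), hidden_dim = as.integer(d),
                 seed = 0L),
            class = "feba_attention")
}

# A linearly separable labeled matrix with margin `gap` on one feature.
separable_dem <- function(n = 40L, gap = 1, seed = 1L) {
  y <- rep(c(0L, 1L), length.out = n)
  X <- feba:::with_seed(seed, cbind(
    sig = ifelse(y == 1L, gap, -gap) + 0,
    noise = rnorm(n, sd = 0.5)))
  doc_embedding_matrix(X, sprintf("d%03d", seq_len(n)), labels = y)
}

small_lexicon <- function(classes, probs) {
  tokens <- names(classes)
  structure(list(class = stats::setNames(as.integer(classes), tokens),
                 prob = stats::setNames(as.numeric(probs), tokens),
                 default_class = 2L, default_prob = 0.5),
            class = "feba_lexicon")
}
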