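# Probabilistic sentiment scoring on the 5-point scale
# (0 = very negative, 1 = negative, 2 = neutral, 3 = positive,
# 4 = very positive). Each word carries a (class, probability) pair from a
# packaged lexicon; a sentence score is the left-branching binary
# combination of adjacent pairs, recorded as a combination trace. The
# combination rule is a probability-weighted mean of classes with
# round-half-up, and the combined probability is the mean of the children's
# probabilities (bounded and symmetric).

#' Load a sentiment lexicon
#'
#' @param path CSV with columns `token`, `class` (0-4), `prob` ((0, 1]);
#'   defaults to the packaged affect lexicon (~200 lemmatized terms).
#' @param default_class Class for out-of-lexicon tokens (neutral 2).
#' @param default_prob Probability for out-of-lexicon tokens.
#' @return A `feba_lexicon`.
#' @export
load_sentiment_lexicon <- function(path = NULL, default_class = 2L,
                                   default_prob = 0.5) {
  if (is.null(path)) path <- feba_file("sentiment_lexicon.csv")
  tab <- read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  stopifnot(all(c("token", "class", "prob") %in% names(tab)))
  if (!all(tab$class %in% 0:4)) stop_feba("lexicon classes must be in 0..4")
  if (!all(tab$prob > 0 & tab$prob <= 1)) {
    stop_feba("lexicon probabilities must be in (0, 1]")
  }
  stopifnot(default_class %in% 0:4, default_prob > 0, default_prob <= 1)
  structure(list(class = stats::setNames(as.integer(tab$class), tab$token),
                 prob = stats::setNames(as.numeric(tab$prob), tab$token),
                 default_class = as.integer(default_class),
                 default_prob = as.numeric(default_prob)),
            class = "feba_lexicon")
}

#' @export
print.feba_lexicon <- function(x, ...) {
  cat(sprintf("<feba_lexicon> %d terms (default class %d, prob %.2f)\n",
              length(x$class), x$default_class, x$default_prob))
  invisible(x)
}

# Round half away from zero: deterministic across platforms, unlike the
# IEEE round-half-even of base round().
round_half_up <- function(x) floor(x + 0.5)

#' Sentiment (class, probability) of a single word
#'
#' Lexicon entry if present, otherwise the neutral fallback
#' `(default_class, default_prob)`.
#'
#' @param token A single token string.
#' @param lex A `feba_lexicon`.
#' @return List with `class` (integer 0-4) and `prob`.
#' @export
score_word <- function(token, lex) {
  stopifnot(inherits(lex, "feba_lexicon"))
  cl <- lex$class[token]
  if (length(token) != 1L || is.na(token) || !nzchar(token) || is.na(cl)) {
    return(list(class = lex$default_class, prob = lex$default_prob))
  }
  list(class = unname(cl), prob = unname(lex$prob[token]))
}

combine_sentiment <- function(left, right) {
  p_sum <- left$prob + right$prob
  cls <- as.integer(round_half_up(
    (left$prob * left$class + right$prob * right$class) / p_sum))
  list(class = cls, prob = p_sum / 2)
}

#' Sentence sentiment by recursive binary combination
#'
#' Folds the per-word (class, probability) pairs left-to-right: each step
#' combines the running pair with the next word's pair using a
#' probability-weighted class mean (round half up) and the mean of the two
#' probabilities. The full combination trace is returned (length
#' `n_tokens - 1`), mirroring a left-branching binary tree over the
#' sentence.
#'
#' @param tokens Non-empty character vector of tokens.
#' @param lex A `feba_lexicon`.
#' @return A `feba_sentiment`: `class` (0-4), `prob` ((0, 1]) and
#'   `node_trace` (list of `(left, right, combined)` triples).
#' @examples
#' lex <- load_sentiment_lexicon()
#' score_sentence(c("sad", "alone"), lex)$class
#' @export
score_sentence <- function(tokens, lex) {
  stopifnot(inherits(lex, "feba_lexicon"))
  if (!length(tokens)) stop_feba("cannot score an empty token list")
  acc <- score_word(tokens[1L], lex)
  trace <- vector("list", length(tokens) - 1L)
  for (i in seq_len(length(tokens) - 1L)) {
    nxt <- score_word(tokens[i + 1L], lex)
    comb <- combine_sentiment(acc, nxt)
    trace[[i]] <- list(left = acc, right = nxt, combined = comb)
    acc <- comb
  }
  structure(list(class = acc$class, prob = acc$prob, node_trace = trace),
            class = "feba_sentiment")
}

#' @export
print.feba_sentiment <- function(x, ...) {
  lab <- c("very negative", "negative", "neutral", "positive",
           "very positive")[x$class + 1L]
  cat(sprintf("<feba_sentiment> class %d (%s), prob %.3f, %d combinations\n",
              x$class, lab, x$prob, length(x$node_trace)))
  invisible(x)
}

#' Append sentence-sentiment features to a document-embedding matrix
#'
#' Adds two columns, `sent_class` (0-4) and `sent_prob`, computed per
#' document with [score_sentence()]. Documents with no tokens receive the
#' neutral fallback.
#'
#' @param dem A `feba_dem` whose rows align with `corpus`.
#' @param corpus The `feba_corpus` the matrix was embedded from.
#' @param lex A `feba_lexicon` (default packaged).
#' @return A `feba_dem` with two extra feature columns.
#' @export
add_sentiment_features <- function(dem, corpus,
                                   lex = load_sentiment_lexicon()) {
  stopifnot(inherits(dem, "feba_dem"), identical(dem$ids, corpus$id))
  sc <- vapply(corpus$tokens, function(tk) {
    if (!length(tk)) {
      c(lex$default_class, lex$default_prob)
    } else {
      s <- score_sentence(tk, lex)
      c(s$class, s$prob)
    }
  }, numeric(2))
  X <- cbind(dem$X, sent_class = sc[1L, ], sent_prob = sc[2L, ])
  doc_embedding_matrix(X, dem$ids, labels = dem$labels)
}
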