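# Seeded generators for labeled short-text corpora and numeric feature
# matrices with the statistical structure the pipeline assumes: two classes
# with class-informative vocabulary (emission odds differing by a
# configurable effect size), plus label-preserving synonym substitution,
# sarcasm-like opposite-polarity markers, emoji tokens, and raw-text noise
# (mentions, URLs, hashtags, contractions) that exercises the cleaning
# rules. Everything is driven by base R's Mersenne-Twister under an
# explicit seed, so output is bit-identical across runs and platforms.

negative_informative <- c(
  "sad", "hopeless", "tired", "alone", "empty", "worthless", "cry", "pain",
  "dark", "broken", "miserable", "lonely", "depressed", "anxious",
  "exhausted", "numb", "despair", "hurt", "guilt", "fear", "sleepless",
  "insomnia", "grief", "sorrow", "gloom", "helpless", "trapped", "useless",
  "upset", "worried", "struggle", "suffer", "ache", "weak", "drained",
  "bitter", "panic", "dread", "shame", "regret")

positive_informative <- c(
  "happy", "love", "great", "wonderful", "excited", "joy", "fun",
  "beautiful", "grateful", "hopeful", "calm", "proud", "smile", "friend",
  "sunny", "amazing", "awesome", "fantastic", "cheer", "delight", "laugh",
  "peace", "bless", "kind", "warm", "glad", "lucky", "pleasant", "bright",
  "excellent", "terrific", "thankful", "win", "celebrate", "enjoy",
  "inspire", "relaxed", "satisfied", "content", "sweet")

neutral_vocab <- c(
  "day", "time", "work", "home", "people", "thing", "today", "week",
  "school", "coffee", "music", "game", "movie", "book", "phone", "weather",
  "morning", "night", "dinner", "lunch", "street", "city", "car", "dog",
  "cat", "tree", "rain", "sun", "talk", "walk", "run", "play", "watch",
  "read", "write", "make", "take", "see", "come", "stay", "room", "desk",
  "train", "bus", "park", "shop", "store", "photo", "video", "song")

neg_emoji <- c("\U0001F622", "\U0001F62D", "\U0001F61E", "\U0001F494",
               "\U0001F614")
pos_emoji <- c("\U0001F600", "\U0001F60A", "\U0001F60D", "\U0001F604",
               "\U0001F389")

pad_vocab <- function(base, n, prefix) {
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("%s%03d", prefix, seq_len(n - length(base))))
}

#' Specification of a synthetic labeled short-text corpus
#'
#' Defaults are the package's reference study conditions: 2,000 documents,
#' balanced classes, 40 informative tokens per class (plus 800 shared neutral tokens) at effect size 2
#' log-odds, mean document length 12 tokens, 10% synonym substitution,
#' 10% sarcasm-marker noise and 10% emoji insertion.
#'
#' @param n_docs Number of documents (>= 2).
#' @param class_balance Proportion of class-1 (depressed-style) documents.
#' @param n_informative Informative tokens per class.
#' @param n_neutral Shared neutral tokens.
#' @param effect_size Log-odds difference of informative-token emission
#'   between classes (>= 0).
#' @param doc_length_mean Mean token count (truncated Poisson, minimum 3).
#' @param synonym_rate Per-occurrence probability that an informative token
#'   is replaced by its mapped synonym.
#' @param sarcasm_rate Per-document probability of injecting
#'   opposite-polarity marker tokens (labels unchanged).
#' @param emoji_rate Per-document probability of inserting a class-polarity
#'   emoji.
#' @param seed Integer seed.
#' @return A `feba_corpus_spec`.
#' @export
corpus_spec <- function(n_docs = 2000L, class_balance = 0.5,
                        n_informative = 40L, n_neutral = 800L,
                        effect_size = 2.0, doc_length_mean = 12,
                        synonym_rate = 0.1, sarcasm_rate = 0.1,
                        emoji_rate = 0.1, seed = 1L) {
  stopifnot(n_docs >= 2L, class_balance > 0, class_balance < 1,
            n_informative >= 1L, n_neutral >= 1L, effect_size >= 0,
            doc_length_mean >= 3,
            synonym_rate >= 0, synonym_rate <= 1,
            sarcasm_rate >= 0, sarcasm_rate <= 1,
            emoji_rate >= 0, emoji_rate <= 1)
  structure(as.list(environment()), class = "feba_corpus_spec")
}

default_synonym_map <- function(tokens) {
  packaged <- read.csv(feba_file("synonyms.csv"), stringsAsFactors = FALSE)
  map <- stats::setNames(packaged$synonym, packaged$token)
  missing <- setdiff(tokens, names(map))
  if (length(missing)) {
    map <- c(map, stats::setNames(paste0(missing, "ish"), missing))
  }
  map[tokens]
}

#' Generate a synthetic labeled short-text corpus
#'
#' Documents are drawn from class-conditional token mixtures: informative
#' tokens of a document's own class have emission odds larger by
#' `effect_size` (log scale) than in the other class; neutral tokens are
#' emitted equally. Raw-text noise (mentions, URLs, hashtags, contractions)
#' is added so the texts exercise the cleaning rules. Ground-truth metadata
#' records the informative vocabularies, the synonym map, and per-document
#' noise annotations.
#'
#' @param spec A [corpus_spec()].
#' @return List with `docs` (data frame `id`, `text`, `label`) and `truth`
#'   (informative vocab per class, synonym map, annotations).
#' @export
generate_corpus <- function(spec = corpus_spec()) {
  stopifnot(inherits(spec, "feba_corpus_spec"))
  neg <- pad_vocab(negative_informative, spec$n_informative, "dep")
  pos <- pad_vocab(positive_informative, spec$n_informative, "pos")
  neu <- pad_vocab(neutral_vocab, spec$n_neutral, "word")
  syn_map <- default_synonym_map(c(neg, pos))
  vocab <- c(neg, pos, neu)
  w_base <- rep(1, length(vocab))
  boost <- exp(spec$effect_size)
  w1 <- w_base; w1[seq_along(neg)] <- boost                    # class 1
  w0 <- w_base; w0[length(neg) + seq_along(pos)] <- boost      # class 0
  n1 <- round(spec$class_balance * spec$n_docs)
  labels <- c(rep(1L, n1), rep(0L, spec$n_docs - n1))
  with_seed(spec$seed, {
    labels <- sample(labels)
    texts <- character(spec$n_docs)
    n_syn <- integer(spec$n_docs)
    sarcasm <- logical(spec$n_docs)
    emoji <- character(spec$n_docs)
    for (i in seq_len(spec$n_docs)) {
      len <- max(3L, rpois(1L, spec$doc_length_mean))
      wts <- if (labels[i] == 1L) w1 else w0
      toks <- sample(vocab, len, replace = TRUE, prob = wts)
      own <- if (labels[i] == 1L) neg else pos
      is_inf <- toks %in% own
      swap <- is_inf & runif(len) < spec$synonym_rate
      toks[swap] <- unname(syn_map[toks[swap]])
      n_syn[i] <- sum(swap)
      if (runif(1) < spec$sarcasm_rate) {
        sarcasm[i] <- TRUE
        opp <- if (labels[i] == 1L) pos else neg
        toks <- append(toks, c("yeah", "right", sample(opp, 2L)),
                       after = sample.int(length(toks), 1L))
      }
      if (runif(1) < spec$emoji_rate) {
        pool <- if (labels[i] == 1L) neg_emoji else pos_emoji
        emoji[i] <- sample(pool, 1L)
        toks <- c(toks, emoji[i])
      }
      txt <- paste(toks, collapse = " ")
      if (runif(1) < 0.15) txt <- paste("@friend", txt)
      if (runif(1) < 0.10) txt <- paste(txt, "http://t.co/xyz")
      if (runif(1) < 0.10) {
        tag <- sample(c(own, neu), 1L)
        txt <- paste0(txt, " #", tag)
      }
      if (runif(1) < 0.15) {
        txt <- paste(sample(c("i'm", "can't", "don't", "they've"), 1L), txt)
      }
      texts[i] <- txt
    }
  })
  docs <- data.frame(id = sprintf("doc%05d", seq_len(spec$n_docs)),
                     text = texts, label = labels,
                     stringsAsFactors = FALSE)
  truth <- list(informative = list(class1 = neg, class0 = pos),
                neutral = neu,
                synonym_map = syn_map,
                annotations = data.frame(id = docs$id, n_synonym = n_syn,
                                         sarcasm = sarcasm, emoji = emoji,
                                         stringsAsFactors = FALSE))
  list(docs = docs, truth = truth)
}

#' Specification of a synthetic numeric feature matrix
#'
#' Defaults are the reference signal-recovery design: 1,000 samples,
#' 80 features of which 10 informative with a one-standard-deviation class
#' mean shift.
#'
#' @param n Samples.
#' @param d Features.
#' @param n_informative Number of informative features (<= d).
#' @param mean_shift Class-1 mean shift on informative features.
#' @param noise_sd Noise standard deviation (> 0).
#' @param seed Integer seed.
#' @return A `feba_matrix_spec`.
#' @export
matrix_spec <- function(n = 1000L, d = 80L, n_informative = 10L,
                        mean_shift = 1.0, noise_sd = 1.0, seed = 1L) {
  stopifnot(n >= 2L, d >= 1L, n_informative >= 0L, n_informative <= d,
            noise_sd > 0)
  structure(as.list(environment()), class = "feba_matrix_spec")
}

#' Generate a synthetic labeled feature matrix
#'
#' Class-0 rows are `Normal(0, noise_sd^2)` in every dimension; class-1 rows
#' are shifted by `mean_shift` on the informative dimensions only. Classes
#' are exactly balanced and shuffled.
#'
#' @param spec A [matrix_spec()].
#' @return List with `dem` (a labeled `feba_dem`) and `informative`
#'   (ground-truth informative column indices).
#' @export
generate_feature_matrix <- function(spec = matrix_spec()) {
  stopifnot(inherits(spec, "feba_matrix_spec"))
  with_seed(spec$seed, {
    n1 <- floor(spec$n / 2)
    y <- sample(c(rep(1L, n1), rep(0L, spec$n - n1)))
    X <- matrix(rnorm(spec$n * spec$d, sd = spec$noise_sd), spec$n, spec$d)
    informative <- sort(sample.int(spec$d, spec$n_informative))
    X[y == 1L, informative] <- X[y == 1L, informative] + spec$mean_shift
  })
  dem <- doc_embedding_matrix(X, sprintf("s%05d", seq_len(spec$n)),
                              labels = y)
  list(dem = dem, informative = informative)
}
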