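# Text preprocessing: deterministic cleaning, normalization and tokenization
# of raw short posts. The canonical stage order is
#   emoji_to_text -> expand_contractions -> clean_text -> tokenize_normalize
# (emoji names and contraction expansions must survive punctuation stripping).

#' Packaged contraction table
#'
#' English contraction surface forms and their expansions, used by
#' [expand_contractions()]. Shipped with the package so preprocessing never
#' requires a download.
#'
#' @return A data frame with columns `contraction` and `expansion`.
#' @export
default_contractions <- function() {
  read.csv(feba_file("contractions.csv"), stringsAsFactors = FALSE,
           encoding = "UTF-8")
}

#' Packaged English stop-word list
#'
#' @return Character vector of lowercase stop words. Negation words
#'   (`not`, `no`, `never`, `nor`) are present in the list but are retained
#'   at tokenization time through the negation whitelist, because polarity
#'   carries signal in depression-style text.
#' @export
default_stopwords <- function() {
  readLines(feba_file("stopwords.txt"), encoding = "UTF-8", warn = FALSE)
}

#' Packaged curse-word list
#'
#' Curse words convey strong emotion and frustration and are deliberately
#' retained during stop-word removal. The list is user-extensible: pass your
#' own vector to [tokenize_normalize()].
#'
#' @return Character vector of lowercase curse words.
#' @export
default_cursewords <- function() {
  readLines(feba_file("cursewords.txt"), encoding = "UTF-8", warn = FALSE)
}

#' Packaged emoji-name table
#'
#' @return Data frame with columns `emoji` (the character) and `name`
#'   (a lowercase word phrase).
#' @export
default_emoji_names <- function() {
  read.csv(feba_file("emoji_names.csv"), stringsAsFactors = FALSE,
           encoding = "UTF-8")
}

#' Tokens retained despite appearing in the stop-word list
#' @return Character vector of negation tokens.
#' @export
negation_whitelist <- function() c("not", "no", "never", "nor")

#' Clean a raw text string
#'
#' Removes URLs, `@usernames`, e-mail addresses and HTML-like markup, strips
#' punctuation and special characters, lowers case and collapses whitespace.
#' Hashtags lose their `#`; single-word tags keep the remaining word while
#' multi-word (underscored) tags are dropped entirely.
#'
#' A total function: any string (including `""`) maps to a cleaned string,
#' and the map is idempotent.
#'
#' @param text Character vector of raw texts.
#' @return Character vector of cleaned lowercase texts.
#' @examples
#' clean_text("@user I feel so sad http://t.co/x #sad")
#' @export
clean_text <- function(text) {
  stopifnot(is.character(text))
  x <- tolower(text)
  x <- gsub("<[^>]+>", " ", x)                                  # markup
  x <- gsub("(https?://\\S+|www\\.\\S+)", " ", x, perl = TRUE)  # urls
  x <- gsub("[[:alnum:]._%+-]+@[[:alnum:].-]+\\.[[:alpha:]]{2,}", " ", x)
  x <- gsub("@\\w+", " ", x, perl = TRUE)                       # usernames
  x <- gsub("#\\w*_\\w*", " ", x, perl = TRUE)                  # multi-word tags
  x <- gsub("#(\\w+)", "\\1", x, perl = TRUE)                   # keep tag word
  x <- gsub("[^\\p{L}\\p{N}\\s]", " ", x, perl = TRUE)          # punctuation
  x <- gsub("\\s+", " ", x, perl = TRUE)
  trimws(x)
}

#' Expand contractions to their full forms
#'
#' Replaces every whole-token occurrence of a contraction surface form
#' (e.g. `"They've"`) with its expansion (`"They have"`). Matching is
#' case-insensitive; an initial capital is preserved on the expansion.
#' Typographic apostrophes are normalized to `'` before lookup.
#'
#' @param text Character vector.
#' @param table Data frame with columns `contraction`, `expansion`
#'   (default: packaged table).
#' @return Character vector with contractions expanded.
#' @examples
#' expand_contractions("They've been down")
#' @export
expand_contractions <- function(text, table = default_contractions()) {
  stopifnot(is.character(text),
            all(c("contraction", "expansion") %in% names(table)))
  map <- stats::setNames(table$expansion, tolower(table$contraction))
  vapply(text, function(s) {
    s <- gsub("’", "'", s)
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    out <- vapply(toks, function(tk) {
      core <- gsub("^[^[:alpha:]']+|[^[:alpha:]']+$", "", tk)
      hit <- map[tolower(core)]
      if (!nzchar(core) || is.na(hit)) return(tk)
      rep_txt <- unname(hit)
      if (substr(core, 1, 1) %in% LETTERS) {
        substr(rep_txt, 1, 1) <- toupper(substr(rep_txt, 1, 1))
      }
      sub(core, rep_txt, tk, fixed = TRUE)
    }, character(1))
    paste(out, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Replace emoji by their textual names
#'
#' Each emoji known to the name table is replaced in place by its lowercase
#' name phrase; emoji absent from the table are removed. Non-emoji text is
#' unchanged apart from whitespace normalization around replacements.
#'
#' @param text Character vector.
#' @param names Data frame with columns `emoji`, `name` (default packaged).
#' @return Character vector.
#' @examples
#' emoji_to_text("sad \U0001F622")
#' @export
emoji_to_text <- function(text, names = default_emoji_names()) {
  stopifnot(is.character(text), all(c("emoji", "name") %in% base::names(names)))
  x <- text
  for (i in seq_len(nrow(names))) {
    x <- gsub(names$emoji[i], paste0(" ", names$name[i], " "), x, fixed = TRUE)
  }
  # drop unknown emoji / pictographs (common unicode emoji blocks);
  # the class is built from literal characters so PCRE compiles it in
  # UTF-8 mode
  rng <- function(a, b) paste0(intToUtf8(a), "-", intToUtf8(b))
  emoji_class <- paste0("[", rng(0x1F000, 0x1FAFF), rng(0x2600, 0x27BF),
                        rng(0x2B00, 0x2BFF), rng(0xFE00, 0xFE0F),
                        rng(0x2190, 0x21FF), intToUtf8(0x200D), "]")
  x <- gsub(emoji_class, "", x, perl = TRUE)
  trimws(gsub("\\s+", " ", x, perl = TRUE))
}

# Rule-based English lemmatizer: small exception map plus ordered
# inflectional suffix rules with consonant-undoubling and e-restoration.
# Deliberately lightweight; imperfect stems are acceptable as long as they
# are deterministic and consistent corpus-wide.
lemma_exceptions <- c(felt = "feel", men = "man", women = "woman",
                      children = "child", feet = "foot", mice = "mouse",
                      teeth = "tooth", lives = "life", leaves = "leaf")

lemmatize_token <- function(tok) {
  n <- nchar(tok)
  if (n < 4L) return(tok)
  hit <- lemma_exceptions[tok]
  if (!is.na(hit)) return(unname(hit))
  e_restore <- c("s", "z", "c", "v", "u", "g")
  undouble <- function(stem) {
    m <- nchar(stem)
    last <- substr(stem, m, m)
    prev <- substr(stem, m - 1L, m - 1L)
    if (m >= 3L && last == prev && !last %in% c("l", "s", "z", "e")) {
      substr(stem, 1L, m - 1L)
    } else stem
  }
  if (n > 4L && endsWith(tok, "ies")) return(paste0(substr(tok, 1, n - 3), "y"))
  if (n > 4L && endsWith(tok, "ied")) return(paste0(substr(tok, 1, n - 3), "y"))
  if (n > 4L && grepl("(ches|shes|xes|zes|sses)$", tok)) {
    return(substr(tok, 1, n - 2))
  }
  if (n > 5L && endsWith(tok, "ing")) {
    stem <- undouble(substr(tok, 1, n - 3))
    if (nchar(stem) >= 3L && substr(stem, nchar(stem), nchar(stem)) %in% e_restore) {
      stem <- paste0(stem, "e")
    }
    return(stem)
  }
  if (n > 4L && endsWith(tok, "ed")) {
    stem <- undouble(substr(tok, 1, n - 2))
    if (nchar(stem) >= 3L && substr(stem, nchar(stem), nchar(stem)) %in% e_restore) {
      stem <- paste0(stem, "e")
    }
    return(stem)
  }
  if (endsWith(tok, "s") && !grepl("(ss|us|is)$", tok)) {
    return(substr(tok, 1, n - 1))
  }
  tok
}

stem_token <- function(tok) {
  for (suf in c("fulness", "ousness", "iveness", "ness", "ment", "ful",
                "less", "ably", "ibly", "ally", "ly")) {
    if (nchar(tok) >= nchar(suf) + 3L && endsWith(tok, suf)) {
      return(substr(tok, 1, nchar(tok) - nchar(suf)))
    }
  }
  tok
}

#' Tokenize and normalize a cleaned text
#'
#' Whitespace tokenization followed by stop-word removal (curse words and
#' negation tokens are exempt), rule lemmatization, and optional suffix
#' stemming. Input is expected to have already passed through
#' [emoji_to_text()], [expand_contractions()] and [clean_text()].
#'
#' Stemming after lemmatization is largely redundant for this pipeline and is
#' therefore opt-in (`do_stem = FALSE` by default).
#'
#' @param text A single cleaned string.
#' @param stopwords Character vector of stop words.
#' @param cursewords Character vector of tokens exempt from stop-word removal.
#' @param do_stem Apply the suffix stemmer after lemmatization?
#' @param negations Additional exempt tokens (default [negation_whitelist()]).
#' @return Character vector of normalized tokens (possibly empty).
#' @examples
#' tokenize_normalize("i am not happy")
#' @export
tokenize_normalize <- function(text,
                               stopwords = default_stopwords(),
                               cursewords = default_cursewords(),
                               do_stem = FALSE,
                               negations = negation_whitelist()) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  if (!length(toks)) return(character(0))
  keep <- !(toks %in% stopwords) | toks %in% cursewords | toks %in% negations
  toks <- toks[keep]
  toks <- vapply(toks, lemmatize_token, character(1), USE.NAMES = FALSE)
  if (isTRUE(do_stem)) {
    toks <- vapply(toks, stem_token, character(1), USE.NAMES = FALSE)
  }
  toks[nzchar(toks)]
}

#' Preprocess a raw corpus into token form
#'
#' Runs the full deterministic preprocessing pipeline over a raw corpus:
#' emoji-to-text, contraction expansion, cleaning, then tokenization with
#' stop-word removal and lemmatization.
#'
#' @param docs Data frame with columns `id`, `text` and optionally `label`
#'   (0/1), e.g. from [load_corpus()] or [generate_corpus()].
#' @param do_stem Opt-in suffix stemming (see [tokenize_normalize()]).
#' @param stopwords,cursewords,contractions,emoji_names Overrides for the
#'   packaged resources.
#' @return A `feba_corpus`: list with `id` (character), `tokens` (list of
#'   character vectors) and `label` (integer, `NA` when absent).
#' @examples
#' docs <- data.frame(id = "a", text = "They've been so sad", label = 1)
#' prep_corpus(docs)$tokens[[1]]
#' @export
prep_corpus <- function(docs, do_stem = FALSE,
                        stopwords = default_stopwords(),
                        cursewords = default_cursewords(),
                        contractions = default_contractions(),
                        emoji_names = default_emoji_names()) {
  stopifnot(is.data.frame(docs), all(c("id", "text") %in% names(docs)))
  ids <- as.character(docs$id)
  if (anyDuplicated(ids)) {
    stop_feba("duplicate document id: %s", ids[duplicated(ids)][1])
  }
  label <- if ("label" %in% names(docs)) as.integer(docs$label) else
    rep(NA_integer_, nrow(docs))
  if (any(!is.na(label) & !label %in% c(0L, 1L))) {
    stop_feba("label must be 0 or 1")
  }
  txt <- emoji_to_text(as.character(docs$text), emoji_names)
  txt <- expand_contractions(txt, contractions)
  txt <- clean_text(txt)
  tokens <- lapply(txt, tokenize_normalize, stopwords = stopwords,
                   cursewords = cursewords, do_stem = do_stem)
  structure(list(id = ids, tokens = tokens, label = label),
            class = "feba_corpus")
}

#' @export
print.feba_corpus <- function(x, ...) {
  nlab <- sum(!is.na(x$label))
  cat(sprintf("<feba_corpus> %d documents (%d labeled), median length %d tokens\n",
              length(x$id), nlab,
              as.integer(stats::median(lengths(x$tokens)))))
  invisible(x)
}

#' @export
length.feba_corpus <- function(x) length(x$id)
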