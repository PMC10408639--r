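## Four-step preprocessing: clean -> tokenize -> stopwords -> normalize.
## Tweets are short, noisy documents; each step is total (never errors on
## odd input) and the chain is idempotent on its own output.

# Emoji and pictograph codepoints are matched by Unicode block ranges
# (misc symbols, dingbats, emoticons, transport, supplemental pictographs,
# regional indicators, variation selectors, zero-width joiner).
.emoji_pattern <- paste0(
  "[",
  "☀-➿",
  "️‍⭐⭕⬛⬜〰〽㊗㊙",
  "\U0001F000-\U0001F02F",
  "\U0001F0A0-\U0001F0FF",
  "\U0001F100-\U0001F1FF",
  "\U0001F200-\U0001F2FF",
  "\U0001F300-\U0001F5FF",
  "\U0001F600-\U0001F64F",
  "\U0001F680-\U0001F6FF",
  "\U0001F700-\U0001F77F",
  "\U0001F900-\U0001F9FF",
  "\U0001FA00-\U0001FAFF",
  "]"
)

#' Clean raw tweet text
#'
#' Step 1 of the preprocessing chain: removes URLs (`http`/`https`,
#' bare `t.co` and `www.` forms) and emoji, strips the `@` from user
#' mentions and the `#` from hashtags (the token body is kept, since
#' hashtag bodies such as "hpm" carry topical vocabulary), and collapses
#' whitespace.
#'
#' @param text Character vector of raw tweet texts.
#' @return Character vector of cleaned texts.
#' @examples
#' clean_text("see https://t.co/abc \U0001F600 palliative care")
#' @export
clean_text <- function(text) {
  text <- as.character(text)
  text[is.na(text)] <- ""
  text <- gsub("(?i)\\bhttps?://\\S+", " ", text, perl = TRUE)
  text <- gsub("(?i)\\b(?:t\\.co|www\\.)\\S+", " ", text, perl = TRUE)
  text <- gsub(.emoji_pattern, " ", text, perl = TRUE)
  text <- gsub("[@#](\\w)", "\\1", text, perl = TRUE)
  text <- gsub("\\s+", " ", text, perl = TRUE)
  trimws(text)
}

#' Tokenize cleaned text
#'
#' Step 2: lowercases and splits on whitespace and punctuation. Tokens
#' shorter than `min_len` characters and purely numeric tokens are dropped
#' (alphanumerics like "covid19" are kept); both rules are configurable.
#'
#' @param text Character scalar of cleaned text.
#' @param min_len Minimum token length retained (default 2).
#' @param drop_numeric Drop purely numeric tokens (default TRUE).
#' @return Character vector of tokens (possibly empty).
#' @examples
#' tokenize("End-of-life care!")
#' @export
tokenize <- function(text, min_len = 2L, drop_numeric = TRUE) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(character(0))
  toks <- strsplit(tolower(text), "[^[:alnum:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  toks <- toks[nchar(toks) >= min_len]
  if (drop_numeric) toks <- toks[!grepl("^[0-9]+$", toks)]
  toks
}

#' Remove stopwords
#'
#' Step 3: order-preserving removal of tokens exactly matching the
#' stoplist.
#'
#' @param tokens Character vector of tokens.
#' @param stoplist Character vector of stopwords
#'   (default [default_stopwords()]).
#' @return Filtered token vector.
#' @export
remove_stopwords <- function(tokens, stoplist = default_stopwords()) {
  if (length(stoplist) == 0L) stop("stoplist must be nonempty")
  tokens[!(tokens %in% stoplist)]
}

# Irregular noun forms handled before the suffix rules.
.irregular_lemmas <- c(
  men = "man", women = "woman", children = "child", people = "people",
  feet = "foot", teeth = "tooth", geese = "goose", mice = "mouse",
  lives = "life", wives = "wife", knives = "knife", leaves = "leaf",
  selves = "self", shelves = "shelf", halves = "half",
  news = "news", series = "series", species = "species",
  analyses = "analysis", crises = "crisis", diagnoses = "diagnosis"
)

lemmatize_one <- function(tok) {
  hit <- .irregular_lemmas[tok]
  if (!is.na(hit)) return(unname(hit))
  n <- nchar(tok)
  # -ies -> -y (babies -> baby), but not short words like "ties"
  if (n > 4L && endsWith(tok, "ies")) return(paste0(substr(tok, 1, n - 3L), "y"))
  # -sses/-shes/-ches/-xes/-zes -> drop "es"
  if (n > 4L && grepl("(ss|sh|ch|x|z)es$", tok)) return(substr(tok, 1, n - 2L))
  # plain plural -s, but keep -ss, -us, -is
  if (n > 3L && endsWith(tok, "s") && !grepl("(ss|us|is)$", tok))
    return(substr(tok, 1, n - 1L))
  tok
}

stem_one <- function(tok) {
  n <- nchar(tok)
  if (n > 5L && endsWith(tok, "ing")) return(substr(tok, 1, n - 3L))
  if (n > 4L && endsWith(tok, "ed")) return(substr(tok, 1, n - 2L))
  if (n > 4L && endsWith(tok, "ly")) return(substr(tok, 1, n - 2L))
  lemmatize_one(tok)
}

#' Normalize tokens to root forms
#'
#' Step 4: maps each token to its canonical root form. The default
#' `"lemma"` normalizer is a noun-default lemmatizer (an irregular-form
#' table plus plural suffix rules; verbs in non-noun inflections such as
#' "died" pass through, matching noun-default part-of-speech treatment).
#' `"stem"` additionally strips common verbal/adverbial suffixes
#' (-ing, -ed, -ly); `"none"` is the identity. Unknown tokens always pass
#' through unchanged; the mapping is 1-to-1 and idempotent.
#'
#' @param tokens Character vector of tokens.
#' @param method One of `"lemma"`, `"stem"`, `"none"`.
#' @return Character vector of normalized tokens, same length as input.
#' @examples
#' normalize_tokens(c("nurses", "died"))
#' @export
normalize_tokens <- function(tokens, method = c("lemma", "stem", "none")) {
  method <- match.arg(method)
  if (length(tokens) == 0L) return(character(0))
  switch(method,
         none  = tokens,
         lemma = vapply(tokens, lemmatize_one, character(1), USE.NAMES = FALSE),
         stem  = vapply(tokens, stem_one, character(1), USE.NAMES = FALSE))
}

#' Full preprocessing chain for one document
#'
#' Applies the four steps in their fixed order:
#' clean, tokenize, stopword removal, normalization.
#'
#' @param text Raw tweet text (scalar).
#' @inheritParams tokenize
#' @inheritParams remove_stopwords
#' @param normalizer Normalization method, see [normalize_tokens()].
#' @return Character vector of canonical terms.
#' @export
preprocess_text <- function(text, stoplist = default_stopwords(),
                            normalizer = "lemma", min_len = 2L,
                            drop_numeric = TRUE) {
  toks <- tokenize(clean_text(text), min_len = min_len,
                   drop_numeric = drop_numeric)
  toks <- remove_stopwords(toks, stoplist)
  normalize_tokens(toks, normalizer)
}

#' Preprocess a tweet corpus into tokenized documents
#'
#' @param tweets Tweet data frame as returned by [load_tweets()] (columns
#'   `id` and `text`).
#' @inheritParams preprocess_text
#' @param drop_empty Drop documents with no surviving tokens (default TRUE).
#' @return Named list of token vectors, names are tweet ids.
#' @export
preprocess_corpus <- function(tweets, stoplist = default_stopwords(),
                              normalizer = "lemma", min_len = 2L,
                              drop_numeric = TRUE, drop_empty = TRUE) {
  stopifnot(is.data.frame(tweets), all(c("id", "text") %in% names(tweets)))
  docs <- lapply(tweets$text, preprocess_text, stoplist = stoplist,
                 normalizer = normalizer, min_len = min_len,
                 drop_numeric = drop_numeric)
  names(docs) <- tweets$id
  if (drop_empty) docs <- docs[lengths(docs) > 0L]
  docs
}
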