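## Synthetic tweet corpora with planted topics. The generator emulates the
## regime of the real collection — short English documents, a small
## fraction carrying a PEoLC filter term, free-text profile locations
## resolvable to US/GB/CA (or not), timestamps spanning Oct 2020-Mar 2021
## around the vaccination changepoint — while giving every tweet a known
## generating topic so downstream recovery can be scored.

.synth_locations <- list(
  US = c("New York, NY", "Boston, Massachusetts", "Chicago, Illinois",
         "Seattle, WA", "Austin, Texas", "Denver, Colorado", "USA"),
  GB = c("London, England", "Manchester, UK", "Glasgow, Scotland",
         "Cardiff, Wales", "Leeds, United Kingdom", "Bristol, UK"),
  CA = c("Toronto, Ontario", "Vancouver, BC", "Montreal, Quebec",
         "Calgary, Alberta", "Winnipeg, Manitoba", "Canada")
)
.synth_unresolvable <- c("somewhere on earth", "the moon", "", "planet blue",
                         "in my garden")
.synth_noise_urls <- c("https://t.co/ab12cd", "https://example.org/x",
                       "http://news.example.com/story")
.synth_noise_emoji <- c("\U0001F600", "\U0001F49C", "\U0001F64F", "❤")
.synth_noise_stopwords <- c("the", "and", "with", "this", "or")

#' Specify a planted topic
#'
#' @param topic_id Integer topic identifier.
#' @param vocabulary Character vector of at least 5 nonempty lowercase
#'   terms.
#' @param term_weights Probability vector over `vocabulary` (default
#'   uniform); must sum to 1.
#' @return An object of class `topic_spec`.
#' @export
topic_spec <- function(topic_id, vocabulary,
                       term_weights = rep(1 / length(vocabulary),
                                          length(vocabulary))) {
  if (length(vocabulary) < 5L)
    stop("topic_spec: vocabulary must contain at least 5 terms")
  if (any(!nzchar(vocabulary)) || any(vocabulary != tolower(vocabulary)))
    stop("topic_spec: vocabulary terms must be nonempty lowercase strings")
  if (length(term_weights) != length(vocabulary))
    stop("topic_spec: term_weights length must match vocabulary")
  if (abs(sum(term_weights) - 1) > 1e-9)
    stop("topic_spec: term_weights must sum to 1")
  structure(list(topic_id = as.integer(topic_id), vocabulary = vocabulary,
                 term_weights = term_weights),
            class = "topic_spec")
}

#' Generate planted-topic vocabularies
#'
#' Builds `k` topic vocabularies of `vocab_size` synthetic terms each,
#' sharing a common pool of `round(overlap * vocab_size)` terms
#' (cross-topic vocabulary overlap); the remainder is disjoint across
#' topics. Terms are synthetic lowercase strings checked to contain no
#' PEoLC filter term as a substring, so the keyword filter can never fire
#' on topic vocabulary.
#'
#' @param k Number of topics.
#' @param vocab_size Terms per topic (default 40).
#' @param overlap Proportion of shared cross-topic vocabulary in
#'   \[0, 1\] (default 0).
#' @param seed Integer seed.
#' @return List of `k` [topic_spec()] objects.
#' @export
make_topic_specs <- function(k, vocab_size = 40L, overlap = 0, seed = 1L) {
  stopifnot(k >= 1L, vocab_size >= 5L, overlap >= 0, overlap <= 1)
  n_shared <- round(overlap * vocab_size)
  n_own <- vocab_size - n_shared
  filters <- tolower(peolc_terms())
  withr::with_seed(as.integer(seed), {
    need <- n_shared + k * n_own
    pool <- character(0)
    while (length(pool) < need) {
      cand <- vapply(seq_len(need * 2L), function(i) {
        paste0(paste(sample(letters, 6, replace = TRUE), collapse = ""),
               sample(0:9, 1))
      }, character(1))
      cand <- unique(c(pool, cand))
      cand <- cand[!vapply(cand, function(w)
        any(vapply(filters, grepl, logical(1), x = w, fixed = TRUE)),
        logical(1))]
      pool <- cand
    }
    pool <- pool[seq_len(need)]
  })
  shared <- if (n_shared > 0L) pool[seq_len(n_shared)] else character(0)
  rest <- pool[setdiff(seq_along(pool), seq_len(n_shared))]
  lapply(seq_len(k), function(i) {
    own <- rest[((i - 1L) * n_own + 1L):(i * n_own)]
    topic_spec(i, sort(c(shared, own)))
  })
}

#' Specify a synthetic corpus
#'
#' Defaults mirror the regime of the source collection: three countries
#' with probabilities proportional to their observed PEoLC tweet volumes
#' (4133 US, 2923 UK, 895 Canada), the October 2020 to March 2021
#' collection window, the US vaccination start (2020-12-10) as
#' changepoint, and a 0.02% PEoLC fraction.
#'
#' @param topics List of [topic_spec()] objects.
#' @param n_tweets Number of tweets to generate.
#' @param peolc_fraction Probability that a tweet receives one verbatim
#'   PEoLC filter term (default 2e-04, the real stream's share).
#' @param overlap Cross-topic vocabulary overlap actually used to build
#'   `topics` (recorded for reference; default 0).
#' @param countries Named numeric vector of country probabilities
#'   (must sum to 1). An `""` name denotes unresolvable locations.
#' @param date_range Length-2 POSIXct/character vector (start, end).
#' @param changepoint Timestamp within `date_range`.
#' @param tokens_per_tweet Integer (min, max) tokens drawn per tweet.
#' @param noise_fraction Fraction of tweets additionally given a URL, an
#'   emoji and stopwords to exercise preprocessing (default 0.2).
#' @param seed Integer seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(topics, n_tweets,
                        peolc_fraction = 2e-4,
                        overlap = 0,
                        countries = c(US = 4133, GB = 2923, CA = 895) / 7951,
                        date_range = c("2020-10-01", "2021-03-30"),
                        changepoint = "2020-12-10",
                        tokens_per_tweet = c(8L, 25L),
                        noise_fraction = 0.2,
                        seed = 1L) {
  stopifnot(is.list(topics), length(topics) >= 1L)
  if (!all(vapply(topics, inherits, logical(1), "topic_spec")))
    stop("corpus_spec: topics must be a list of topic_spec objects")
  if (n_tweets < 0L) stop("corpus_spec: n_tweets must be >= 0")
  if (peolc_fraction < 0 || peolc_fraction > 1)
    stop("corpus_spec: peolc_fraction must be in [0, 1]")
  if (abs(sum(countries) - 1) > 1e-9)
    stop("corpus_spec: country probabilities must sum to 1")
  date_range <- as.POSIXct(paste(as.character(date_range)), tz = "UTC")
  if (length(date_range) != 2L || date_range[1] >= date_range[2])
    stop("corpus_spec: date_range must be an increasing (start, end) pair")
  changepoint <- as.POSIXct(as.character(changepoint), tz = "UTC")
  if (changepoint < date_range[1] || changepoint > date_range[2])
    stop("corpus_spec: changepoint must lie within date_range")
  if (tokens_per_tweet[1] > tokens_per_tweet[2] || tokens_per_tweet[1] < 1L)
    stop("corpus_spec: tokens_per_tweet must satisfy 1 <= min <= max")
  structure(list(topics = topics, n_tweets = as.integer(n_tweets),
                 peolc_fraction = peolc_fraction, overlap = overlap,
                 countries = countries, date_range = date_range,
                 changepoint = changepoint,
                 tokens_per_tweet = as.integer(tokens_per_tweet),
                 noise_fraction = noise_fraction, seed = as.integer(seed)),
            class = "corpus_spec")
}

#' Generate a synthetic tweet corpus with ground-truth topics
#'
#' Each tweet is assigned a topic uniformly at random; its text is a
#' space-joined sample (with replacement, by `term_weights`) from that
#' topic's vocabulary. With probability `peolc_fraction` one verbatim
#' PEoLC filter term is inserted at a random position. Timestamps are
#' uniform over `date_range`; profile locations are drawn from a small
#' list of gazetteer-resolvable strings per country (or unresolvable
#' strings for the `""` country). A `noise_fraction` share of tweets
#' additionally carries a URL, an emoji and a few stopwords so that the
#' preprocessing stages have something to remove.
#'
#' @param spec A [corpus_spec()].
#' @return A list with `tweets` (data frame: `id`, `text`, `created_at`,
#'   `user_location`, `lang`, `country` (the generating country, NA for
#'   unresolvable), `peolc` (logical: filter term inserted)) and `truth`
#'   (data frame: `id`, `topic_id`).
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  n <- spec$n_tweets
  empty_tweets <- data.frame(id = character(0), text = character(0),
                             created_at = as.POSIXct(character(0), tz = "UTC"),
                             user_location = character(0), lang = character(0),
                             country = character(0), peolc = logical(0))
  empty_truth <- data.frame(id = character(0), topic_id = integer(0))
  if (n == 0L) return(list(tweets = empty_tweets, truth = empty_truth))
  k <- length(spec$topics)
  filters <- peolc_terms()
  withr::with_seed(spec$seed, {
    topic_of <- sample.int(k, n, replace = TRUE)
    len <- sample(seq(spec$tokens_per_tweet[1], spec$tokens_per_tweet[2]),
                  n, replace = TRUE)
    has_peolc <- stats::runif(n) < spec$peolc_fraction
    noisy <- stats::runif(n) < spec$noise_fraction
    ts <- spec$date_range[1] +
      stats::runif(n) * as.numeric(difftime(spec$date_range[2],
                                            spec$date_range[1], units = "secs"))
    cn <- names(spec$countries)
    ctry <- cn[sample.int(length(cn), n, replace = TRUE,
                          prob = spec$countries)]
    texts <- character(n)
    locs <- character(n)
    for (i in seq_len(n)) {
      tp <- spec$topics[[topic_of[i]]]
      toks <- sample(tp$vocabulary, len[i], replace = TRUE,
                     prob = tp$term_weights)
      if (has_peolc[i]) {
        pos <- sample.int(length(toks) + 1L, 1L)
        toks <- append(toks, sample(filters, 1L), after = pos - 1L)
      }
      if (noisy[i]) {
        extras <- c(sample(.synth_noise_urls, 1L),
                    sample(.synth_noise_emoji, 1L),
                    sample(.synth_noise_stopwords, 2L))
        for (x in extras)
          toks <- append(toks, x, after = sample.int(length(toks) + 1L, 1L) - 1L)
      }
      texts[i] <- paste(toks, collapse = " ")
      locs[i] <- if (nzchar(ctry[i]))
        sample(.synth_locations[[ctry[i]]], 1L)
      else sample(.synth_unresolvable, 1L)
    }
  })
  ids <- sprintf("t%07d", seq_len(n))
  tweets <- data.frame(id = ids, text = texts,
                       created_at = as.POSIXct(ts, tz = "UTC"),
                       user_location = locs, lang = "en",
                       country = ifelse(nzchar(ctry), ctry, NA_character_),
                       peolc = has_peolc, stringsAsFactors = FALSE)
  truth <- data.frame(id = ids,
                      topic_id = vapply(spec$topics, `[[`,
                                        integer(1), "topic_id")[topic_of])
  list(tweets = tweets, truth = truth)
}

#' Write a synthetic corpus and its ground truth to disk
#'
#' The corpus is written as JSON-lines (fields `id_str`, `full_text`,
#' `created_at` in the Twitter v1.1 format, `user.location`, `lang`); the
#' ground truth as a 2-column CSV (`id`, `topic_id`).
#'
#' @param corpus Result of [generate_corpus()].
#' @param jsonl Path for the tweet JSONL.
#' @param truth_csv Optional path for the ground-truth CSV.
#' @return Invisibly, `jsonl`.
#' @export
write_corpus <- function(corpus, jsonl, truth_csv = NULL) {
  write_tweets(corpus$tweets, jsonl)
  if (!is.null(truth_csv))
    utils::write.csv(corpus$truth, truth_csv, row.names = FALSE)
  invisible(jsonl)
}
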