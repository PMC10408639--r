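## Corpus construction: load tweet JSONL, keep English posts, apply the
## PEoLC keyword filter, resolve free-text profile locations to countries,
## and split by country / month / pre-post vaccination period.

#' Load tweets from a JSON-lines file
#'
#' Reads one tweet object per line (fields `id_str`, `full_text`,
#' `created_at`, `user$location`, `lang`). Records that are malformed JSON,
#' lack a required field, carry an unparseable timestamp, or are not
#' English-language (`lang != "en"`) are skipped and tallied in the
#' diagnostics.
#'
#' @param path Path to a JSONL file.
#' @return A list with elements `tweets` (data frame with columns `id`,
#'   `text`, `created_at` (POSIXct UTC), `user_location`, `lang`,
#'   `country` (NA until assigned)) and `diagnostics` (named counts:
#'   `n_lines`, `n_loaded`, `n_malformed`, `n_bad_date`, `n_non_english`).
#' @export
load_tweets <- function(path) {
  if (!file.exists(path)) stop("cannot read tweet file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]

  n_malformed <- 0L; n_bad_date <- 0L; n_non_english <- 0L
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) NULL)
    if (is.null(obj) || !is.list(obj)) { n_malformed <- n_malformed + 1L; next }
    id   <- obj[["id_str"]]
    text <- if (!is.null(obj[["full_text"]])) obj[["full_text"]] else obj[["text"]]
    ts   <- obj[["created_at"]]
    lang <- obj[["lang"]]
    loc  <- obj[["user"]][["location"]]
    if (is.null(loc)) loc <- obj[["user.location"]]
    if (is.null(loc) || is.na(loc)) loc <- ""
    if (is.null(id) || is.null(text) || is.null(ts) || is.null(lang) ||
        is.na(id) || is.na(text) || !nzchar(id)) {
      n_malformed <- n_malformed + 1L; next
    }
    if (!identical(as.character(lang), "en")) { n_non_english <- n_non_english + 1L; next }
    when <- parse_tweet_time(as.character(ts))
    if (is.na(when)) { n_bad_date <- n_bad_date + 1L; next }
    recs[[i]] <- data.frame(id = as.character(id), text = as.character(text),
                            created_at = when,
                            user_location = as.character(loc),
                            lang = as.character(lang), country = NA_character_,
                            stringsAsFactors = FALSE)
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (length(recs) == 0L) stop("no well-formed tweet records in ", path)
  tweets <- do.call(rbind, recs)
  rownames(tweets) <- NULL
  attr(tweets$created_at, "tzone") <- "UTC"
  list(tweets = tweets,
       diagnostics = c(n_lines = length(lines), n_loaded = nrow(tweets),
                       n_malformed = n_malformed, n_bad_date = n_bad_date,
                       n_non_english = n_non_english))
}

#' Write tweets to a JSON-lines file
#'
#' @param tweets Tweet data frame (see [load_tweets()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(tweets))) {
    obj <- list(id_str = tweets$id[i], full_text = tweets$text[i],
                created_at = format_tweet_time(tweets$created_at[i]),
                user = list(location = tweets$user_location[i]),
                lang = tweets$lang[i])
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Match text against the PEoLC search filter
#'
#' Returns `TRUE` where the lowercased text contains at least one filter
#' term as a case-insensitive substring. Substring (not token-boundary)
#' matching is used deliberately: the filter mixes hashtags (`#eol`),
#' fused forms (`pallcare`) and multiword phrases (`palliative care`),
#' and substring matching covers all three uniformly.
#'
#' @param text Character vector of raw tweet texts.
#' @param terms Filter terms (default the shipped PEoLC list,
#'   [peolc_terms()]).
#' @return Logical vector.
#' @examples
#' match_peolc("Our palliative care team is hiring")
#' match_peolc("COVID cases are rising again")
#' @export
match_peolc <- function(text, terms = peolc_terms()) {
  if (length(terms) == 0L) stop("filter term list must be nonempty")
  if (any(!nzchar(terms))) stop("filter term list contains an empty term")
  terms <- unique(tolower(terms))
  low <- tolower(as.character(text))
  hit <- rep(FALSE, length(low))
  for (tm in terms) {
    rest <- !hit
    if (!any(rest)) break
    hit[rest] <- grepl(tm, low[rest], fixed = TRUE)
  }
  hit
}

#' Filter a corpus to PEoLC-related tweets
#'
#' @param tweets Tweet data frame.
#' @param terms Filter terms, see [match_peolc()].
#' @param dedupe Drop exact text duplicates, keeping the earliest
#'   (default FALSE: retweets and duplicates are retained).
#' @return Filtered tweet data frame.
#' @export
filter_peolc <- function(tweets, terms = peolc_terms(), dedupe = FALSE) {
  out <- tweets[match_peolc(tweets$text, terms), , drop = FALSE]
  if (dedupe && nrow(out) > 0L) {
    out <- out[order(out$created_at), , drop = FALSE]
    out <- out[!duplicated(out$text), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

.gazetteer_cache <- new.env(parent = emptyenv())

.load_gazetteer <- function() {
  if (is.null(.gazetteer_cache$gz)) {
    gz <- utils::read.csv(cooc_extdata("gazetteer.csv"), stringsAsFactors = FALSE)
    gz$case_sensitive <- as.logical(gz$case_sensitive)
    .gazetteer_cache$gz <- gz
  }
  .gazetteer_cache$gz
}

#' Resolve a free-text profile location to a country
#'
#' Gazetteer lookup covering country names and common abbreviations,
#' capitals and major cities, US state names and postal abbreviations, UK
#' nations, and Canadian provinces with postal abbreviations. Entries are
#' matched on word boundaries; two-letter postal abbreviations match only
#' in upper case (so "on" the preposition never means Ontario). The
#' ambiguous abbreviation "CA" (California vs Canada) is excluded from the
#' gazetteer. Hits pointing at different countries yield `NA` (the
#' conflict rule), as does no hit at all.
#'
#' @param user_location Character vector of free-text profile locations.
#' @return Character vector of ISO 3166-1 alpha-2 codes or `NA`.
#' @examples
#' assign_country("Toronto, Ontario")   # "CA"
#' assign_country("London / New York")  # NA: conflicting countries
#' @export
assign_country <- function(user_location) {
  gz <- .load_gazetteer()
  loc <- as.character(user_location)
  n <- length(loc)
  if (n == 0L) return(character(0))
  ok <- !is.na(loc) & nzchar(trimws(loc))
  low <- tolower(loc)
  # per-location set of countries hit; vectorized over locations per entry
  hit <- matrix(FALSE, nrow = n, ncol = 3,
                dimnames = list(NULL, c("US", "GB", "CA")))
  for (j in seq_len(nrow(gz))) {
    pat <- paste0("\\b", gz$name[j], "\\b")
    subj <- if (gz$case_sensitive[j]) loc else low
    hit[, gz$country[j]] <- hit[, gz$country[j]] | (ok & grepl(pat, subj, perl = TRUE))
  }
  nhit <- rowSums(hit)
  out <- rep(NA_character_, n)
  one <- which(nhit == 1)
  if (length(one)) out[one] <- colnames(hit)[max.col(hit[one, , drop = FALSE])]
  out
}

#' Assign countries to a whole corpus
#'
#' @param tweets Tweet data frame.
#' @return The data frame with its `country` column filled in.
#' @export
assign_countries <- function(tweets) {
  tweets$country <- assign_country(tweets$user_location)
  tweets
}

#' Split one country's tweets into pre/post vaccination periods
#'
#' Records with `created_at` strictly before `start_date` 00:00 UTC go to
#' `pre`; the start date itself belongs to `post` ("after the start"
#' includes the start day). Shares are computed half-up from the counts.
#'
#' @param tweets Tweet data frame with `country` assigned.
#' @param country ISO 3166-1 alpha-2 code.
#' @param start_date Vaccination program start date (`Date` or string).
#' @param digits Decimal places for the reported percentages (default 2).
#' @return An object of class `period_split`: list with `country`,
#'   `start_date`, `pre`, `post` (tweet data frames), and `summary`
#'   (data frame of period, count, percent).
#' @export
partition_by_period <- function(tweets, country, start_date, digits = 2L) {
  start_date <- as.Date(start_date)
  cutoff <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  sel <- tweets[!is.na(tweets$country) & tweets$country == country, , drop = FALSE]
  if (nrow(sel) == 0L)
    warning("no records for country ", country)
  pre  <- sel[sel$created_at <  cutoff, , drop = FALSE]
  post <- sel[sel$created_at >= cutoff, , drop = FALSE]
  rownames(pre) <- rownames(post) <- NULL
  total <- nrow(sel)
  pct <- if (total > 0L) percent_of(c(nrow(pre), nrow(post)), total, digits)
         else c(NA_real_, NA_real_)
  structure(list(country = country, start_date = start_date,
                 pre = pre, post = post,
                 summary = data.frame(period = c("pre", "post"),
                                      count = c(nrow(pre), nrow(post)),
                                      percent = pct)),
            class = "period_split")
}

#' @export
print.period_split <- function(x, ...) {
  cat(sprintf("Pre/post split for %s at %s\n", x$country,
              format(x$start_date)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Monthly tweet counts and per-country proportions
#'
#' Tabulates tweets by calendar month, overall and per country (countries
#' other than `countries` are pooled as `"other"`, as are unresolved
#' locations). Per-month country proportions sum to 1.
#'
#' @param tweets Tweet data frame.
#' @param countries Countries reported individually
#'   (default `c("US","GB","CA")`).
#' @return Data frame with columns `year`, `month`, `country`, `count`,
#'   `proportion`.
#' @export
monthly_counts <- function(tweets, countries = c("US", "GB", "CA")) {
  if (nrow(tweets) == 0L)
    return(data.frame(year = integer(0), month = integer(0),
                      country = character(0), count = integer(0),
                      proportion = numeric(0)))
  lt <- as.POSIXlt(tweets$created_at, tz = "UTC")
  year <- lt$year + 1900L
  month <- lt$mon + 1L
  ctry <- ifelse(is.na(tweets$country) | !(tweets$country %in% countries),
                 "other", tweets$country)
  tab <- as.data.frame(table(year = year, month = month, country = ctry),
                       stringsAsFactors = FALSE)
  names(tab)[4] <- "count"
  tab <- tab[tab$count > 0L, , drop = FALSE]
  tab$year <- as.integer(tab$year); tab$month <- as.integer(tab$month)
  tab <- tab[order(tab$year, tab$month, tab$country), , drop = FALSE]
  mtot <- stats::ave(tab$count, tab$year, tab$month, FUN = sum)
  tab$proportion <- tab$count / mtot
  rownames(tab) <- NULL
  tab
}
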