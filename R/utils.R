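#' @keywords internal
"_PACKAGE"

## Month/day abbreviations are fixed English strings so that parsing and
## formatting of tweet timestamps never depend on the session locale.
.month_abb <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")
.day_abb <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")

#' Parse tweet creation timestamps
#'
#' Parses the classic Twitter API v1.1 `created_at` format
#' (`"Wed Oct 07 20:19:24 +0000 2020"`) into POSIXct in UTC. ISO 8601
#' strings (`"2020-10-07T20:19:24Z"` or `"2020-10-07 20:19:24"`) are also
#' accepted. Unparseable input yields `NA`.
#'
#' @param x Character vector of timestamp strings.
#' @return POSIXct vector in UTC, `NA` where unparseable.
#' @export
parse_tweet_time <- function(x) {
  out <- rep(as.POSIXct(NA, tz = "UTC"), length(x))
  if (length(x) == 0L) return(out)
  x <- as.character(x)

  m <- regmatches(x, regexec(
    "^[A-Za-z]{3} ([A-Za-z]{3}) (\\d{2}) (\\d{2}):(\\d{2}):(\\d{2}) \\+0000 (\\d{4})$",
    x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    g <- m[[i]]
    if (length(g) == 7L) {
      mon <- match(g[2], .month_abb)
      if (is.na(mon)) next
      iso <- sprintf("%s-%02d-%s %s:%s:%s", g[7], mon, g[3], g[4], g[5], g[6])
      out[i] <- as.POSIXct(iso, tz = "UTC")
    } else {
      iso <- sub("T", " ", sub("Z$", "", x[i]))
      val <- tryCatch(
        as.POSIXct(iso, tz = "UTC",
                   tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d")),
        error = function(e) NA)
      if (!is.na(val)) out[i] <- val
    }
  }
  out
}

#' Format timestamps in the Twitter API v1.1 style
#'
#' Inverse of [parse_tweet_time()]: renders POSIXct values as
#' `"EEE MMM dd HH:mm:ss +0000 yyyy"` with fixed English month and weekday
#' abbreviations, independent of the session locale.
#'
#' @param x POSIXct vector.
#' @return Character vector.
#' @export
format_tweet_time <- function(x) {
  x <- as.POSIXct(x, tz = "UTC")
  lt <- as.POSIXlt(x, tz = "UTC")
  sprintf("%s %s %02d %02d:%02d:%02d +0000 %d",
          .day_abb[lt$wday + 1L], .month_abb[lt$mon + 1L], lt$mday,
          lt$hour, lt$min, floor(lt$sec), lt$year + 1900L)
}

#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (half-up), the convention used for the reported percentages. Base
#' `round()` rounds half-to-even, which would turn e.g. 0.125 into 0.12.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a total
#'
#' Computes `count / total * 100` rounded half-up, the arithmetic used for
#' every reported share in the pipeline (pre/post splits, geographic
#' coverage, category proportions).
#'
#' @param count Numerator count(s).
#' @param total Denominator total.
#' @param digits Decimal places (default 2).
#' @return Numeric percentage(s).
#' @export
percent_of <- function(count, total, digits = 2L) {
  stopifnot(total > 0)
  round_half_up(count / total * 100, digits)
}

cooc_extdata <- function(file) {
  path <- system.file("extdata", file, package = "cooctopics")
  if (path == "") stop("resource not found: ", file)
  path
}

#' The PEoLC search-filter terms
#'
#' Returns the curated list of palliative and end-of-life care (PEoLC)
#' search-filter terms, verbatim as published (60 entries, one duplicated),
#' used to identify PEoLC-related tweets within a COVID-19 tweet stream.
#'
#' @return Character vector of filter terms.
#' @export
peolc_terms <- function() {
  readLines(cooc_extdata("peolc_filter_terms.txt"), encoding = "UTF-8")
}

#' Default English stopword list
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  readLines(cooc_extdata("stopwords_en.txt"), encoding = "UTF-8")
}
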