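## Turn a partitioned term network into human-readable topic summaries:
## ranked keywords per community, representative documents, and a
## pre/post-period comparison that flags emergent and vanished topics.
## Topic labels are deliberately left to the analyst; only keywords and
## exemplars are produced.

#' Rank a community's keywords
#'
#' Scores each term of a community by its within-community weighted
#' degree: the sum of its PMI edge weights to neighbors in the same
#' community. Alternative `score = "df"` ranks by raw document frequency.
#'
#' @param network A `cooccurrence_network`.
#' @param partition A `community_partition` covering the network.
#' @param community Community id.
#' @param k Number of keywords returned (clamped to community size).
#' @param score `"degree"` (within-community weighted degree, default) or
#'   `"df"`.
#' @return An object of class `topic_summary`: list with `community`,
#'   `size` and `keywords` (data frame `term`, `score`, sorted by
#'   decreasing score, ties lexicographic).
#' @export
rank_keywords <- function(network, partition, community, k = 20L,
                          score = c("degree", "df")) {
  score <- match.arg(score)
  assignment <- partition$assignment
  if (!(community %in% assignment))
    stop("unknown community id: ", community)
  members <- names(assignment)[assignment == community]
  if (score == "degree") {
    sc <- stats::setNames(numeric(length(members)), members)
    e <- network$edges
    internal <- e$term1 %in% members & e$term2 %in% members
    for (r in which(internal)) {
      sc[e$term1[r]] <- sc[e$term1[r]] + e$weight[r]
      sc[e$term2[r]] <- sc[e$term2[r]] + e$weight[r]
    }
  } else {
    sc <- stats::setNames(as.numeric(network$nodes$df[
      match(members, network$nodes$term)]), members)
  }
  ord <- order(-sc, members)
  kk <- min(k, length(members))
  structure(list(community = community, size = length(members),
                 keywords = data.frame(term = members[ord][seq_len(kk)],
                                       score = as.numeric(sc[ord][seq_len(kk)]),
                                       stringsAsFactors = FALSE)),
            class = "topic_summary")
}

#' @export
print.topic_summary <- function(x, ...) {
  cat(sprintf("topic_summary: community %s, %d terms; top keywords: %s\n",
              x$community, x$size,
              paste(utils::head(x$keywords$term, 8), collapse = ", ")))
  invisible(x)
}

#' Summarize every community of a partition
#'
#' @inheritParams rank_keywords
#' @return List of `topic_summary` objects, one per community, ordered by
#'   community id.
#' @export
summarize_topics <- function(network, partition, k = 20L,
                             score = "degree") {
  ids <- sort(unique(partition$assignment))
  lapply(ids, function(cid)
    rank_keywords(network, partition, cid, k = k, score = score))
}

#' Select representative documents for a topic
#'
#' Picks the `r` documents containing the largest number of the
#' community's top-10 keywords (distinct keywords present; ties broken by
#' earlier timestamp, then id). Documents matching no keyword are never
#' returned.
#'
#' @param docs Named list of token vectors ([preprocess_corpus()]).
#' @param summary A `topic_summary`.
#' @param r Number of representatives requested.
#' @param timestamps Optional named POSIXct vector (document id -> time)
#'   for tie-breaking.
#' @return Character vector of up to `r` document ids with attribute
#'   `match_counts`.
#' @export
select_representatives <- function(docs, summary, r = 3L,
                                   timestamps = NULL) {
  stopifnot(r >= 1L, inherits(summary, "topic_summary"))
  top10 <- utils::head(summary$keywords$term, 10L)
  counts <- vapply(docs, function(tk) sum(top10 %in% tk), integer(1))
  keep <- counts > 0L
  if (!any(keep)) return(character(0))
  ids <- names(docs)[keep]
  counts <- counts[keep]
  tb <- if (!is.null(timestamps)) as.numeric(timestamps[ids]) else
    rep(0, length(ids))
  ord <- order(-counts, tb, ids)
  sel <- ids[ord][seq_len(min(r, length(ids)))]
  structure(sel, match_counts = as.integer(counts[ord][seq_along(sel)]))
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Compare topic summaries across two periods
#'
#' Greedy maximum-Jaccard matching of pre- to post-period communities on
#' their top-`top` keyword sets: repeatedly pair the globally most
#' similar remaining pre/post communities until the best similarity drops
#' below `threshold`. Unmatched post communities are reported as
#' `"emergent"`, unmatched pre communities as `"vanished"` — the
#' structural signature of a topic (such as vaccination) entering the
#' discussion only after the changepoint.
#'
#' @param pre_summaries,post_summaries Lists of `topic_summary` objects.
#' @param top Number of top keywords compared (default 20).
#' @param threshold Minimum Jaccard similarity to call a match
#'   (default 0.1).
#' @return Data frame with columns `pre_community`, `post_community`,
#'   `jaccard`, `status` (`"matched"`, `"emergent"`, `"vanished"`).
#' @export
compare_periods <- function(pre_summaries, post_summaries, top = 20L,
                            threshold = 0.1) {
  stopifnot(length(pre_summaries) >= 1L, length(post_summaries) >= 1L)
  kw <- function(s) utils::head(s$keywords$term, top)
  pre_kw <- lapply(pre_summaries, kw)
  post_kw <- lapply(post_summaries, kw)
  sim <- outer(seq_along(pre_kw), seq_along(post_kw),
               Vectorize(function(i, j) jaccard(pre_kw[[i]], post_kw[[j]])))
  pre_ids <- vapply(pre_summaries, `[[`, numeric(1), "community")
  post_ids <- vapply(post_summaries, `[[`, numeric(1), "community")
  rows <- list()
  open <- sim
  while (any(open >= threshold)) {
    idx <- which(open == max(open), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    rows[[length(rows) + 1L]] <-
      data.frame(pre_community = pre_ids[idx[1]],
                 post_community = post_ids[idx[2]],
                 jaccard = sim[idx[1], idx[2]], status = "matched")
    open[idx[1], ] <- -1
    open[, idx[2]] <- -1
  }
  matched_pre <- vapply(rows, function(r) r$pre_community, numeric(1))
  matched_post <- vapply(rows, function(r) r$post_community, numeric(1))
  for (j in seq_along(post_ids))
    if (!(post_ids[j] %in% matched_post))
      rows[[length(rows) + 1L]] <-
        data.frame(pre_community = NA_real_, post_community = post_ids[j],
                   jaccard = if (length(pre_kw))
                     max(sim[, j]) else 0,
                   status = "emergent")
  for (i in seq_along(pre_ids))
    if (!(pre_ids[i] %in% matched_pre))
      rows[[length(rows) + 1L]] <-
        data.frame(pre_community = pre_ids[i], post_community = NA_real_,
                   jaccard = max(sim[i, ]), status = "vanished")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render topic summaries as a Markdown table
#'
#' Produces a compact Markdown report (one row per community: size, top
#' keywords, representative document ids) mirroring the usual
#' topic/keywords/examples layout of topic-model result tables.
#'
#' @param summaries List of `topic_summary` objects.
#' @param docs Optional tokenized documents for representative selection.
#' @param timestamps Optional named POSIXct vector for tie-breaking.
#' @param r Representatives per topic (default 2).
#' @return Character vector of Markdown lines.
#' @export
render_topic_table <- function(summaries, docs = NULL, timestamps = NULL,
                               r = 2L) {
  lines <- c("| Topic | Size | Keywords | Representative ids |",
             "|---|---|---|---|")
  for (s in summaries) {
    reps <- if (!is.null(docs))
      paste(select_representatives(docs, s, r, timestamps), collapse = ", ")
    else ""
    lines <- c(lines, sprintf(
      "| %s | %d | %s | %s |", s$community, s$size,
      paste(utils::head(s$keywords$term, 10), collapse = ", "), reps))
  }
  lines
}
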