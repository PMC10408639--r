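## End-to-end convenience layer: filter -> preprocess -> network ->
## Louvain -> summaries, plus document-level community assignment and the
## purity score used to evaluate planted-topic recovery on synthetic
## corpora.

#' Run the full topic-detection pipeline
#'
#' Applies the PEoLC keyword filter, the four-step preprocessing chain,
#' co-occurrence counting, PMI network construction and Louvain community
#' detection, returning every intermediate product.
#'
#' @param tweets Tweet data frame (columns `id`, `text`, `created_at`,
#'   ...).
#' @param terms Filter terms (default [peolc_terms()]); `NULL` skips the
#'   keyword filter.
#' @param top_n,min_co Network construction parameters, see
#'   [build_network()].
#' @param seed Louvain shuffle seed (default 0).
#' @param normalizer Token normalization method (default `"lemma"`).
#' @param keywords_k Keywords ranked per topic (default 20).
#' @return List with `tweets` (filtered), `docs`, `stats`, `network`,
#'   `partition`, `summaries`.
#' @export
run_topic_pipeline <- function(tweets, terms = peolc_terms(), top_n = 150L,
                               min_co = 2L, seed = 0L,
                               normalizer = "lemma", keywords_k = 20L) {
  if (!is.null(terms)) tweets <- filter_peolc(tweets, terms)
  if (nrow(tweets) == 0L) stop("no tweets left after keyword filtering")
  docs <- preprocess_corpus(tweets, normalizer = normalizer)
  stats <- count_cooccurrence(docs)
  network <- suppressWarnings(build_network(stats, top_n = top_n,
                                            min_co = min_co))
  partition <- louvain_partition(network, seed = seed)
  summaries <- summarize_topics(network, partition, k = keywords_k)
  list(tweets = tweets, docs = docs, stats = stats, network = network,
       partition = partition, summaries = summaries)
}

#' Assign documents to detected communities
#'
#' Maps each tokenized document to the community holding the plurality of
#' its tokens that are network nodes (ties: smallest community id).
#' Documents with no tokens in the network get `NA`.
#'
#' @param docs Named list of token vectors.
#' @param partition A `community_partition`.
#' @return Named integer vector (document id -> community id, `NA` where
#'   unassignable).
#' @export
assign_docs_to_communities <- function(docs, partition) {
  assignment <- partition$assignment
  vapply(docs, function(tk) {
    hit <- assignment[tk[tk %in% names(assignment)]]
    if (length(hit) == 0L) return(NA_integer_)
    tab <- table(hit)
    min(as.integer(names(tab)[tab == max(tab)]))  # tie: smallest id
  }, integer(1))
}

#' Purity of detected communities against planted topics
#'
#' For clustered documents, purity is `sum_c max_t |c intersect t| / N`:
#' each detected document cluster votes for its majority planted topic
#' and purity is the fraction of documents covered by those majorities.
#' Documents that could not be assigned to any community are excluded
#' from `N` (their count is reported in the `n_unassigned` attribute).
#'
#' @param doc_communities Named vector (document id -> community), as from
#'   [assign_docs_to_communities()].
#' @param truth Data frame (`id`, `topic_id`) from [generate_corpus()].
#' @return Purity in \[0, 1\], with attributes `n` (documents scored) and
#'   `n_unassigned`.
#' @export
partition_purity <- function(doc_communities, truth) {
  ids <- names(doc_communities)
  topic <- truth$topic_id[match(ids, truth$id)]
  ok <- !is.na(doc_communities) & !is.na(topic)
  n <- sum(ok)
  if (n == 0L) stop("no documents could be scored against ground truth")
  tab <- table(doc_communities[ok], topic[ok])
  structure(sum(apply(tab, 1, max)) / n, n = n,
            n_unassigned = sum(!ok))
}

#' Write a topic report as JSON
#'
#' Serializes partition quality, per-community keywords and
#' representative document ids to a JSON file.
#'
#' @param result A [run_topic_pipeline()] result.
#' @param path Output path.
#' @param r Representatives per topic (default 3).
#' @return Invisibly, `path`.
#' @export
write_topic_report <- function(result, path, r = 3L) {
  ts <- stats::setNames(result$tweets$created_at, result$tweets$id)
  topics <- lapply(result$summaries, function(s) {
    list(community = s$community, size = s$size,
         keywords = s$keywords,
         representatives = as.character(
           select_representatives(result$docs, s, r, ts)))
  })
  jsonlite::write_json(
    list(modularity = result$partition$modularity,
         n_communities = result$partition$n_communities,
         topics = topics),
    path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}
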