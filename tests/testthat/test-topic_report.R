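mk_summary <- function(community, terms, scores = rev(seq_along(terms))) {
  structure(list(community = community, size = length(terms),
                 keywords = data.frame(term = terms, score = scores,
                                       stringsAsFactors = FALSE)),
            class = "topic_summary")
}

test_that("keyword ranking scores within-community weighted degree", {
  tri <- two_triangles()
  part <- louvain_partition(tri, seed = 0)
  s0 <- rank_keywords(tri, part, 0, k = 3)
  expect_equal(s0$size, 3L)
  expect_setequal(s0$keywords$term, c("a", "b", "c"))
  # each triangle node touches two unit internal edges -> score 2, ties lexicographic
  expect_equal(s0$keywords$score, rep(2, 3))
  expect_identical(s0$keywords$term, c("a", "b", "c"))

  # hand-summed incident weights on a weighted fixture
  net <- network_from_edges(data.frame(
    term1 = c("a", "a", "b", "c"), term2 = c("b", "c", "c", "d"),
    weight = c(3, 1, 2, 5)))
  part2 <- community_partition(stats::setNames(c(0, 0, 0, 1),
                                               c("a", "b", "c", "d")))
  s <- rank_keywords(net, part2, 0, k = 3)
  # internal sums: b = 3+2, a = 3+1, c = 1+2 (the c-d edge is external)
  expect_identical(s$keywords$term, c("b", "a", "c"))
  expect_equal(s$keywords$score, c(5, 4, 3))
  expect_error(rank_keywords(net, part2, 9), "unknown community")

  # k larger than the community: clamp; singleton community scores 0
  s1 <- rank_keywords(net, part2, 1, k = 10)
  expect_identical(s1$keywords$term, "d")
  expect_equal(s1$keywords$score, 0)
})

test_that("keyword ranking sorts by score with lexicographic ties", {
  net <- network_from_edges(data.frame(
    term1 = c("x", "y"), term2 = c("y", "z"), weight = 1))
  part <- community_partition(stats::setNames(c(0, 0, 0), c("x", "y", "z")))
  s <- rank_keywords(net, part, 0, k = 3)
  expect_identical(s$keywords$term, c("y", "x", "z"))  # y=2; x=z=1 tie
})

test_that("representative selection orders by keyword coverage then time", {
  summ <- mk_summary(0, c("vaccine", "hospice", "staff", "nurse", "care"))
  docs <- list(
    rich = c("vaccine", "hospice", "staff", "nurse", "care"),
    mid = c("vaccine", "hospice", "other"),
    late_mid = c("staff", "nurse", "filler"),
    none = c("unrelated", "tokens"))
  ts <- stats::setNames(as.POSIXct(c("2020-12-01", "2020-11-01", "2020-10-01",
                                     "2020-09-01"), tz = "UTC"),
                        names(docs))
  sel <- select_representatives(docs, summ, r = 3, timestamps = ts)
  expect_identical(as.character(sel[1]), "rich")
  # tie between mid (2 hits) and late_mid (2 hits): earlier timestamp first
  expect_identical(as.character(sel[2:3]), c("late_mid", "mid"))
  expect_false("none" %in% sel)
  expect_identical(select_representatives(list(a = "zz"), summ, r = 2),
                   character(0))
})

test_that("period comparison matches identical sides and flags disjoint ones", {
  pre <- list(mk_summary(0, letters[1:5]), mk_summary(1, letters[6:10]))
  cmp <- compare_periods(pre, pre)
  expect_true(all(cmp$status == "matched"))
  expect_true(all(cmp$jaccard == 1))

  post <- c(pre, list(mk_summary(2, paste0("new", 1:5))))
  cmp2 <- compare_periods(pre, post)
  expect_equal(sum(cmp2$status == "emergent"), 1L)
  expect_equal(cmp2$post_community[cmp2$status == "emergent"], 2)
  # every community appears exactly once across categories
  expect_setequal(cmp2$pre_community[!is.na(cmp2$pre_community)], c(0, 1))
  expect_setequal(cmp2$post_community[!is.na(cmp2$post_community)], c(0, 1, 2))

  # swapping pre and post swaps emergent and vanished
  cmp3 <- compare_periods(post, pre)
  expect_equal(sum(cmp3$status == "vanished"), 1L)
  expect_equal(cmp3$pre_community[cmp3$status == "vanished"], 2)
})

test_that("summaries render as a Markdown table", {
  tri <- two_triangles()
  part <- louvain_partition(tri, seed = 0)
  lines <- render_topic_table(summarize_topics(tri, part))
  expect_match(lines[1], "^\\| Topic ")
  expect_length(lines, 4L)  # header, rule, two communities
})

test_that("an end-to-end pre/post corpus flags exactly the post-only topic", {
  specs4 <- make_topic_specs(4, vocab_size = 30, overlap = 0, seed = 31)
  pre_spec <- corpus_spec(specs4[1:3], n_tweets = 900, peolc_fraction = 1,
                          date_range = c("2020-10-01", "2020-12-09"),
                          changepoint = "2020-12-09", seed = 31)
  post_spec <- corpus_spec(specs4, n_tweets = 1200, peolc_fraction = 1,
                           date_range = c("2020-12-10", "2021-03-30"),
                           changepoint = "2020-12-10", seed = 32)
  pre <- run_topic_pipeline(generate_corpus(pre_spec)$tweets, top_n = 120)
  post_corp <- generate_corpus(post_spec)
  post <- run_topic_pipeline(post_corp$tweets, top_n = 120)
  cmp <- compare_periods(pre$summaries, post$summaries)
  expect_equal(sum(cmp$status == "emergent"), 1L)
  # the emergent community's keywords come from the post-only planted topic
  emergent_id <- cmp$post_community[cmp$status == "emergent"]
  kw <- post$summaries[[which(vapply(post$summaries, `[[`, numeric(1),
                                     "community") == emergent_id)]]$keywords$term
  expect_gt(mean(kw %in% specs4[[4]]$vocabulary), 0.8)
})

test_that("representatives on synthetic data carry the community's topic", {
  specs <- make_topic_specs(3, vocab_size = 30, overlap = 0, seed = 41)
  corp <- generate_corpus(corpus_spec(specs, n_tweets = 900,
                                      peolc_fraction = 1, seed = 41))
  res <- run_topic_pipeline(corp$tweets, top_n = 90)
  dc <- assign_docs_to_communities(res$docs, res$partition)
  for (s in res$summaries) {
    rep1 <- select_representatives(res$docs, s, r = 1)
    if (length(rep1) == 0) next
    # majority planted topic of the community
    ids <- names(dc)[!is.na(dc) & dc == s$community]
    topics <- corp$truth$topic_id[match(ids, corp$truth$id)]
    maj <- as.integer(names(which.max(table(topics))))
    expect_equal(corp$truth$topic_id[corp$truth$id == as.character(rep1)], maj)
  }
})

test_that("topic reports serialize to JSON", {
  specs <- make_topic_specs(2, vocab_size = 20, seed = 51)
  corp <- generate_corpus(corpus_spec(specs, n_tweets = 400,
                                      peolc_fraction = 1, seed = 51))
  res <- run_topic_pipeline(corp$tweets, top_n = 60)
  path <- withr::local_tempfile(fileext = ".json")
  write_topic_report(res, path)
  rep <- jsonlite::read_json(path)
  expect_equal(rep$n_communities, length(rep$topics))
  expect_true(all(vapply(rep$topics, function(t) length(t$keywords) > 0,
                         logical(1))))
})
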