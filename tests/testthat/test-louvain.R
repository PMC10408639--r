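test_that("modularity matches hand-derived fixture values", {
  tri <- two_triangles()
  one <- stats::setNames(rep(0L, 6), letters[1:6])
  expect_equal(modularity_q(tri, one), 0, tolerance = 1e-15)

  split2 <- stats::setNames(c(0L, 0L, 0L, 1L, 1L, 1L), letters[1:6])
  expect_equal(modularity_q(tri, split2), 0.5, tolerance = 1e-12)

  se <- network_from_edges(data.frame(term1 = "a", term2 = "b", weight = 1))
  expect_equal(modularity_q(se, stats::setNames(c(0L, 1L), c("a", "b"))),
               -0.5, tolerance = 1e-15)

  expect_error(modularity_q(tri, stats::setNames(0L, "a")), "missing nodes")
})

test_that("modularity agrees with a naive double-loop on varied graphs", {
  nets <- list(two_triangles(), four_clique(), planted_two_community())
  for (seed in 1:10) {
    g <- withr::with_seed(seed, {
      n <- sample(4:8, 1)
      p <- t(utils::combn(letters[1:n], 2))
      keep <- stats::runif(nrow(p)) < 0.6
      if (!any(keep)) keep[1] <- TRUE
      data.frame(term1 = p[keep, 1], term2 = p[keep, 2],
                 weight = stats::runif(sum(keep), 0.1, 3))
    })
    nets[[length(nets) + 1L]] <- network_from_edges(g)
  }
  for (net in nets) {
    terms <- net$nodes$term
    for (seed in 1:5) {
      assignment <- withr::with_seed(seed * 131L, {
        stats::setNames(sample.int(3, length(terms), replace = TRUE), terms)
      })
      expect_equal(modularity_q(net, assignment),
                   naive_modularity(net, assignment), tolerance = 1e-12)
    }
  }
})

test_that("louvain recovers planted structure and matches exhaustive search", {
  tri <- two_triangles()
  p <- louvain_partition(tri, seed = 0)
  expect_equal(p$modularity, 0.5, tolerance = 1e-12)
  expect_equal(p$n_communities, 2L)
  expect_identical(canon_partition(p$assignment),
                   canon_partition(stats::setNames(c(1, 1, 1, 2, 2, 2),
                                                   letters[1:6])))
  ex <- best_partition_exhaustive(tri)
  expect_equal(p$modularity, ex$q, tolerance = 1e-12)

  pl <- planted_two_community()
  pp <- louvain_partition(pl, seed = 0)
  exp <- best_partition_exhaustive(pl)
  expect_equal(pp$modularity, exp$q, tolerance = 1e-12)
  expect_identical(canon_partition(pp$assignment),
                   canon_partition(exp$assignment))
})

test_that("a clique collapses to a single community", {
  p <- louvain_partition(four_clique(), seed = 0)
  expect_equal(p$n_communities, 1L)
  expect_equal(p$modularity, 0, tolerance = 1e-15)
})

test_that("louvain never exceeds the exhaustive optimum on random graphs", {
  for (seed in 1:8) {
    net <- withr::with_seed(seed + 500L, {
      n <- sample(5:7, 1)
      p <- t(utils::combn(letters[1:n], 2))
      keep <- stats::runif(nrow(p)) < 0.5
      if (sum(keep) < 2) keep[1:2] <- TRUE
      network_from_edges(data.frame(term1 = p[keep, 1], term2 = p[keep, 2],
                                    weight = stats::runif(sum(keep), 0.5, 2)))
    })
    lv <- louvain_partition(net, seed = 1)
    ex <- best_partition_exhaustive(net)
    expect_lte(lv$modularity, ex$q + 1e-12)
    # and the greedy result is at least as good as staying in singletons
    singles <- stats::setNames(seq_along(net$nodes$term), net$nodes$term)
    expect_gte(lv$modularity, modularity_q(net, singles) - 1e-12)
  }
})

test_that("a fixed seed reproduces the partition; relabeling is equivariant", {
  net <- withr::with_seed(77L, {
    p <- t(utils::combn(letters[1:8], 2))
    keep <- stats::runif(nrow(p)) < 0.5
    network_from_edges(data.frame(term1 = p[keep, 1], term2 = p[keep, 2],
                                  weight = stats::runif(sum(keep), 0.5, 2)))
  })
  a <- louvain_partition(net, seed = 3)
  b <- louvain_partition(net, seed = 3)
  expect_identical(a, b)

  # rename nodes in place (stored order unchanged): identical relabeled result
  ren <- net
  map <- stats::setNames(paste0("n_", ren$nodes$term), ren$nodes$term)
  ren$nodes$term <- unname(map[ren$nodes$term])
  ren$edges$term1 <- unname(map[ren$edges$term1])
  ren$edges$term2 <- unname(map[ren$edges$term2])
  names(ren$degree) <- unname(map[names(ren$degree)])
  c <- louvain_partition(ren, seed = 3)
  expect_identical(unname(c$assignment[map[names(a$assignment)]]),
                   unname(a$assignment))
})

test_that("edge cases error cleanly and Q stays within its bounds", {
  iso <- network_from_edges(data.frame(term1 = "a", term2 = "b", weight = 1))
  iso$edges <- iso$edges[0, ]
  expect_error(louvain_partition(iso), "no edges")
  for (seed in 1:6) {
    net <- withr::with_seed(seed + 900L, {
      p <- t(utils::combn(letters[1:6], 2))
      keep <- stats::runif(nrow(p)) < 0.6
      if (!any(keep)) keep[1] <- TRUE
      network_from_edges(data.frame(term1 = p[keep, 1], term2 = p[keep, 2],
                                    weight = stats::runif(sum(keep), 0.1, 2)))
    })
    q <- louvain_partition(net, seed = 0)$modularity
    expect_gte(q, -0.5)
    expect_lt(q, 1)
  }
})

test_that("the package optimizer agrees with an independent implementation", {
  # igraph's Louvain serves purely as the cross-check: on graphs with clear
  # planted structure both optimizers must land on the same partition.
  make_planted <- function(sizes, p_in = 1, w_in = 2, w_out = 0.2, seed = 1L) {
    nodes <- paste0("v", seq_len(sum(sizes)))
    block <- rep(seq_along(sizes), sizes)
    p <- t(utils::combn(nodes, 2))
    b1 <- block[match(p[, 1], nodes)]
    b2 <- block[match(p[, 2], nodes)]
    withr::with_seed(seed, {
      keep_in <- b1 == b2 & stats::runif(nrow(p)) < p_in
      keep_out <- b1 != b2 & stats::runif(nrow(p)) < 0.15
    })
    keep <- keep_in | keep_out
    network_from_edges(data.frame(
      term1 = p[keep, 1], term2 = p[keep, 2],
      weight = ifelse(b1[keep] == b2[keep], w_in, w_out)))
  }
  for (seed in 1:3) {
    net <- make_planted(c(5, 5, 4), seed = seed)
    ours <- louvain_partition(net, seed = 0)
    g <- as_igraph(net)
    ig <- withr::with_seed(1L, igraph::cluster_louvain(g))
    q_ig <- igraph::modularity(g, igraph::membership(ig),
                               weights = igraph::E(g)$weight)
    expect_equal(ours$modularity, q_ig, tolerance = 1e-9)
    expect_identical(
      canon_partition(ours$assignment[igraph::V(g)$name]),
      canon_partition(as.integer(igraph::membership(ig))))
  }
})

test_that("partitions export to CSV with run metadata", {
  p <- louvain_partition(two_triangles(), seed = 0)
  csv <- withr::local_tempfile(fileext = ".csv")
  meta <- withr::local_tempfile(fileext = ".json")
  write_partition(p, csv, meta)
  tab <- utils::read.csv(csv)
  expect_equal(nrow(tab), 6L)
  md <- jsonlite::read_json(meta)
  expect_equal(md$n_communities, 2L)
  expect_equal(md$modularity, 0.5, tolerance = 1e-12)
})
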