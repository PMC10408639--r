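# Independent oracles and graph fixtures used across the suite. These are
# deliberately naive re-derivations (double loops, brute-force counts,
# exhaustive enumeration) kept separate from the package's own code paths.

# Brute-force document-frequency / co-document counts from raw docs.
brute_vocab_counts <- function(docs) {
  docs <- lapply(docs, unique)
  terms <- sort(unique(unlist(docs)))
  df <- sapply(terms, function(w) sum(vapply(docs, function(d) w %in% d,
                                             logical(1))))
  pairs <- if (length(terms) >= 2) utils::combn(terms, 2) else
    matrix(character(0), nrow = 2)
  codf <- if (ncol(pairs)) apply(pairs, 2, function(p)
    sum(vapply(docs, function(d) all(p %in% d), logical(1)))) else numeric(0)
  list(n = length(docs), terms = terms, df = df, pairs = pairs, codf = codf)
}

# Direct PMI evaluation from raw counts.
brute_pmi <- function(n, df1, df2, co) {
  if (co == 0) return(-Inf)
  log((co / n) / ((df1 / n) * (df2 / n)))
}

# Naive double-loop Newman modularity over ordered pairs (A_ii = 0).
naive_modularity <- function(network, assignment) {
  terms <- network$nodes$term
  nn <- length(terms)
  A <- matrix(0, nn, nn, dimnames = list(terms, terms))
  for (r in seq_len(nrow(network$edges))) {
    i <- network$edges$term1[r]; j <- network$edges$term2[r]
    A[i, j] <- A[i, j] + network$edges$weight[r]
    A[j, i] <- A[j, i] + network$edges$weight[r]
  }
  k <- rowSums(A)
  m <- sum(A) / 2
  q <- 0
  for (i in seq_len(nn)) for (j in seq_len(nn)) {
    if (assignment[terms[i]] == assignment[terms[j]])
      q <- q + A[i, j] - k[i] * k[j] / (2 * m)
  }
  unname(q / (2 * m))
}

# All set partitions of n elements as restricted-growth strings.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxid) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in seq_len(maxid + 1L)) rec(c(prefix, v), max(maxid, v))
  }
  rec(integer(0), 0L)
  out
}

# Exhaustive maximum-modularity search (feasible for <= 8 nodes).
best_partition_exhaustive <- function(network) {
  terms <- network$nodes$term
  best_q <- -Inf; best <- NULL
  for (p in all_partitions(length(terms))) {
    names(p) <- terms
    q <- naive_modularity(network, p)
    if (q > best_q) { best_q <- q; best <- p }
  }
  list(q = best_q, assignment = best)
}

# Canonical relabeling so partitions can be compared independent of ids.
canon_partition <- function(assignment) {
  as.integer(match(assignment, unique(assignment)))
}

# Fixture graphs.
two_triangles <- function() {
  network_from_edges(data.frame(
    term1 = c("a", "a", "b", "d", "d", "e"),
    term2 = c("b", "c", "c", "e", "f", "f"), weight = 1))
}

four_clique <- function() {
  p <- t(utils::combn(letters[1:4], 2))
  network_from_edges(data.frame(term1 = p[, 1], term2 = p[, 2], weight = 1))
}

# Two planted 4-node communities joined by one weak bridge.
planted_two_community <- function() {
  e <- rbind(
    t(utils::combn(c("a", "b", "c", "d"), 2)),
    t(utils::combn(c("e", "f", "g", "h"), 2)))
  df <- data.frame(term1 = e[, 1], term2 = e[, 2], weight = 2)
  rbind_edge <- data.frame(term1 = "d", term2 = "e", weight = 0.5)
  network_from_edges(rbind(df, rbind_edge))
}

# Seeded random micro-corpus (<= 10 docs over <= 6 terms).
random_micro_corpus <- function(seed) {
  withr::with_seed(seed, {
    nterm <- sample(2:6, 1)
    terms <- letters[seq_len(nterm)]
    ndoc <- sample(2:10, 1)
    docs <- lapply(seq_len(ndoc), function(i)
      sample(terms, sample(seq_len(nterm), 1), replace = TRUE))
    names(docs) <- paste0("d", seq_len(ndoc))
    docs
  })
}
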