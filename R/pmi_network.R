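## Term co-occurrence statistics and the PMI-weighted network.
##
## Occurrence is binary per document: a term repeated within one tweet
## counts once, so df/n and codf/n are empirical probabilities of a term
## (pair) appearing in a tweet. Two terms co-occurring in a tweet get a
## link weighted by pointwise mutual information,
##   pmi(w1, w2) = ln( P(w1 w2) / (P(w1) P(w2)) ),
## which corrects raw co-frequency for the marginal popularity of each
## term. Only positive-PMI links (association above independence) are
## retained, so that modularity on the weighted graph is well defined.

#' Count per-document term occurrences and co-occurrences
#'
#' @param docs Named list of token character vectors (one per document),
#'   as returned by [preprocess_corpus()].
#' @return An object of class `vocab_stats`: list with `n` (number of
#'   documents), `df` (named integer vector of document frequencies,
#'   sorted by decreasing df then term), and `co` (sparse symmetric
#'   matrix of pair co-document counts, zero diagonal).
#' @examples
#' count_cooccurrence(list(d1 = c("a", "b"), d2 = "a", d3 = c("b", "a", "a")))
#' @export
count_cooccurrence <- function(docs) {
  if (!is.list(docs) || length(docs) == 0L)
    stop("docs must be a nonempty list of token vectors")
  docs <- lapply(docs, unique)
  terms <- sort(unique(unlist(docs, use.names = FALSE)))
  if (length(terms) == 0L) stop("docs contain no tokens")
  n <- length(docs)
  lens <- lengths(docs)
  x <- Matrix::sparseMatrix(
    i = rep.int(seq_len(n), lens),
    j = match(unlist(docs, use.names = FALSE), terms),
    x = 1, dims = c(n, length(terms)),
    dimnames = list(NULL, terms))
  co <- Matrix::crossprod(x)            # co[i, j] = docs containing both
  df <- as.integer(Matrix::diag(co))
  names(df) <- terms
  Matrix::diag(co) <- 0
  co <- Matrix::drop0(co)
  ord <- order(-df, terms)
  structure(list(n = n, df = df[ord], co = co[ord, ord, drop = FALSE]),
            class = "vocab_stats")
}

#' @export
print.vocab_stats <- function(x, ...) {
  cat(sprintf("vocab_stats: %d documents, %d terms, %d co-occurring pairs\n",
              x$n, length(x$df), Matrix::nnzero(x$co) / 2))
  invisible(x)
}

codf <- function(stats, w1, w2) {
  as.numeric(stats$co[w1, w2])
}

#' Pointwise mutual information of a term pair
#'
#' Evaluates `ln( (codf/n) / ((df1/n) * (df2/n)) )` from binary
#' per-document counts (natural log). A pair that never co-occurs scores
#' `-Inf`, so it can never form a link.
#'
#' @param w1,w2 Terms (must occur in the corpus).
#' @param stats A `vocab_stats` object.
#' @return Numeric PMI weight.
#' @examples
#' s <- count_cooccurrence(list(c("a", "b"), c("a", "b"), "a", "a"))
#' pmi("a", "b", s)  # ln 2
#' @export
pmi <- function(w1, w2, stats) {
  stopifnot(inherits(stats, "vocab_stats"))
  if (!(w1 %in% names(stats$df)) || !(w2 %in% names(stats$df)))
    stop("unknown term: ", if (w1 %in% names(stats$df)) w2 else w1)
  p12 <- codf(stats, w1, w2) / stats$n
  if (p12 == 0) return(-Inf)
  p1 <- stats$df[[w1]] / stats$n
  p2 <- stats$df[[w2]] / stats$n
  log(p12 / (p1 * p2))
}

#' Build the PMI-weighted co-occurrence network
#'
#' Selects the `top_n` highest-document-frequency terms (ties broken
#' lexicographically) as nodes and links those pairs that co-occur in at
#' least `min_co` documents with positive PMI. Nodes left without any
#' link are retained and flagged as isolated. Fewer than 76 surviving
#' nodes triggers a warning, since smaller networks give unstable
#' community structure.
#'
#' @param stats A `vocab_stats` object.
#' @param top_n Number of top-df terms used as nodes (default 150;
#'   clamped to the vocabulary size).
#' @param min_co Minimum pair co-document count for a link (default 2).
#' @return An object of class `cooccurrence_network`: list with `nodes`
#'   (data frame: `term`, `df`, `degree`, `isolated`), `edges` (data
#'   frame: `term1`, `term2`, `count`, `weight`, with `term1 < term2`),
#'   `m` (total weight, half the sum of the weighted adjacency), and
#'   `degree` (named vector of weighted degrees).
#' @export
build_network <- function(stats, top_n = 150L, min_co = 2L) {
  stopifnot(inherits(stats, "vocab_stats"), top_n >= 1L, min_co >= 1L)
  terms <- names(stats$df)            # already ordered by -df, term
  if (length(terms) == 0L) stop("no terms available for network nodes")
  keep <- terms[seq_len(min(top_n, length(terms)))]
  co <- as.matrix(stats$co[keep, keep, drop = FALSE])

  tri <- which(co >= min_co, arr.ind = TRUE)
  tri <- tri[tri[, 1] < tri[, 2], , drop = FALSE]
  if (nrow(tri) == 0L)
    stop("no edges at min_co = ", min_co,
         "; lower min_co or raise top_n to retain links")
  cnt <- as.numeric(co[tri])
  df1 <- stats$df[keep[tri[, 1]]]
  df2 <- stats$df[keep[tri[, 2]]]
  w <- log((cnt / stats$n) / ((df1 / stats$n) * (df2 / stats$n)))
  pos <- w > 0
  if (!any(pos))
    stop("no edges with positive PMI at min_co = ", min_co,
         "; lower min_co or raise top_n to retain links")
  edges <- data.frame(term1 = keep[tri[pos, 1]], term2 = keep[tri[pos, 2]],
                      count = cnt[pos], weight = w[pos],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$term1, edges$term2), , drop = FALSE]
  rownames(edges) <- NULL

  deg <- stats::setNames(numeric(length(keep)), keep)
  for (k in seq_len(nrow(edges))) {
    deg[edges$term1[k]] <- deg[edges$term1[k]] + edges$weight[k]
    deg[edges$term2[k]] <- deg[edges$term2[k]] + edges$weight[k]
  }
  nodes <- data.frame(term = keep, df = as.integer(stats$df[keep]),
                      degree = as.numeric(deg), isolated = deg == 0,
                      stringsAsFactors = FALSE, row.names = NULL)
  if (nrow(nodes) < 76L)
    warning("network has ", nrow(nodes),
            " nodes; co-occurrence topic analysis is recommended for >75 nodes")
  structure(list(nodes = nodes, edges = edges, m = sum(edges$weight),
                 degree = deg),
            class = "cooccurrence_network")
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf(
    "cooccurrence_network: %d nodes (%d isolated), %d edges, total weight m = %.4f\n",
    nrow(x$nodes), sum(x$nodes$isolated), nrow(x$edges), x$m))
  invisible(x)
}

#' Build a weighted network directly from an edge table
#'
#' Constructs a `cooccurrence_network` from explicit edges, bypassing the
#' corpus statistics. Useful for scoring hand-made or externally built
#' weighted graphs with [modularity_q()] and [louvain_partition()].
#'
#' @param edges Data frame with columns `term1`, `term2` and optionally
#'   `weight` (default 1) and `count`.
#' @param nodes Optional character vector of node names (defaults to the
#'   nodes appearing in `edges`; extra names become isolated nodes).
#' @return A `cooccurrence_network`.
#' @export
network_from_edges <- function(edges, nodes = NULL) {
  stopifnot(all(c("term1", "term2") %in% names(edges)))
  if (is.null(edges$weight)) edges$weight <- 1
  if (is.null(edges$count)) edges$count <- NA_real_
  if (any(edges$term1 == edges$term2)) stop("self-loops are not allowed")
  if (any(edges$weight <= 0)) stop("edge weights must be positive")
  swap <- edges$term1 > edges$term2
  tmp <- edges$term1[swap]
  edges$term1[swap] <- edges$term2[swap]
  edges$term2[swap] <- tmp
  if (anyDuplicated(paste(edges$term1, edges$term2)))
    stop("duplicate edges")
  edges <- edges[order(edges$term1, edges$term2),
                 c("term1", "term2", "count", "weight")]
  rownames(edges) <- NULL
  terms <- if (is.null(nodes)) sort(unique(c(edges$term1, edges$term2)))
           else nodes
  deg <- stats::setNames(numeric(length(terms)), terms)
  for (k in seq_len(nrow(edges))) {
    deg[edges$term1[k]] <- deg[edges$term1[k]] + edges$weight[k]
    deg[edges$term2[k]] <- deg[edges$term2[k]] + edges$weight[k]
  }
  structure(list(nodes = data.frame(term = terms, df = NA_integer_,
                                    degree = as.numeric(deg),
                                    isolated = deg == 0,
                                    stringsAsFactors = FALSE),
                 edges = edges, m = sum(edges$weight), degree = deg),
            class = "cooccurrence_network")
}

#' Convert a co-occurrence network to an igraph object
#'
#' @param network A `cooccurrence_network`.
#' @return An undirected weighted [igraph::graph] with vertex attributes
#'   `df` and edge attributes `weight`, `count`.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  g <- igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                     vertices = network$nodes)
  g
}

#' Export a network as GraphML and a weighted edge list
#'
#' @param network A `cooccurrence_network`.
#' @param graphml Optional path for GraphML output.
#' @param edgelist Optional path for a 3-column tab-separated edge list
#'   (term1, term2, weight).
#' @param nodes Optional path for a node table CSV (term, df, degree).
#' @return Invisibly, the network.
#' @export
write_network <- function(network, graphml = NULL, edgelist = NULL,
                          nodes = NULL) {
  if (!is.null(graphml))
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
  if (!is.null(edgelist))
    utils::write.table(network$edges[, c("term1", "term2", "weight")],
                       edgelist, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(nodes))
    utils::write.csv(network$nodes, nodes, row.names = FALSE)
  invisible(network)
}
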