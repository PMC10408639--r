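## Newman modularity and the two-phase Louvain optimizer for the weighted
## undirected term network. Both are implemented here directly (no graph
## library backs them): modularity is the quality score
##   Q = (1/2m) * sum_ij [ A_ij - k_i k_j / (2m) ] * delta(c_i, c_j)
## over ordered pairs (A_ii = 0 at the term-network level), and Louvain
## greedily maximizes it by local node moves followed by community
## aggregation, stopping when no move or level improves Q.

#' Community partition of a term network
#'
#' Constructor used by [louvain_partition()]; also useful for scoring a
#' hand-made partition with [modularity_q()].
#'
#' @param assignment Named integer vector: term -> community id. Ids are
#'   renumbered to contiguous integers starting at 0.
#' @param modularity Optional Q value.
#' @param levels Number of aggregation levels used (informational).
#' @param seed,tolerance Optimizer settings (informational).
#' @return An object of class `community_partition`.
#' @export
community_partition <- function(assignment, modularity = NA_real_,
                                levels = NA_integer_, seed = NA_integer_,
                                tolerance = NA_real_) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be a named vector (term -> community id)")
  ids <- match(assignment, sort(unique(as.integer(assignment)))) - 1L
  names(ids) <- names(assignment)
  structure(list(assignment = ids, modularity = modularity,
                 n_communities = length(unique(ids)), levels = levels,
                 seed = seed, tolerance = tolerance),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community_partition: %d terms in %d communities, Q = %s\n",
              length(x$assignment), x$n_communities,
              ifelse(is.na(x$modularity), "NA",
                     sprintf("%.4f", x$modularity))))
  invisible(x)
}

# Internal weighted-graph form used by the optimizer: integer edge ends
# (i < j), edge weights, per-node self-loop weights (appear during
# aggregation; 0 at the term level).
.as_lgraph <- function(network) {
  stopifnot(inherits(network, "cooccurrence_network"))
  terms <- network$nodes$term
  list(n = length(terms), names = terms,
       ei = match(network$edges$term1, terms),
       ej = match(network$edges$term2, terms),
       ew = network$edges$weight,
       self = numeric(length(terms)))
}

.lgraph_degrees <- function(g) {
  k <- numeric(g$n)
  for (e in seq_along(g$ew)) {
    k[g$ei[e]] <- k[g$ei[e]] + g$ew[e]
    k[g$ej[e]] <- k[g$ej[e]] + g$ew[e]
  }
  k + 2 * g$self
}

.lgraph_m <- function(g) sum(g$ew) + sum(g$self)

# Q of a membership vector (integer, length g$n) on the internal graph.
# Community degree totals are accumulated from edges (doubling internal
# contributions) rather than from per-node degrees, so that the all-nodes-
# in-one-community partition yields Q = 0 exactly, not up to rounding.
.lgraph_modularity <- function(g, memb) {
  m <- .lgraph_m(g)
  if (m <= 0) stop("network total weight m must be positive")
  same <- memb[g$ei] == memb[g$ej]
  within <- sum(g$ew[same]) + sum(g$self)
  ids <- sort(unique(memb))
  ci <- match(memb[g$ei], ids)
  cj <- match(memb[g$ej], ids)
  cv <- match(memb, ids)
  ktot <- vapply(seq_along(ids), function(cc) {
    internal <- ci == cc & cj == cc
    boundary <- xor(ci == cc, cj == cc)
    2 * sum(g$ew[internal]) + sum(g$ew[boundary]) + 2 * sum(g$self[cv == cc])
  }, numeric(1))
  within / m - sum((ktot / (2 * m))^2)
}

#' Newman modularity of a partition
#'
#' Evaluates Q for a weighted undirected co-occurrence network under a
#' community assignment covering every node.
#'
#' @param network A `cooccurrence_network`.
#' @param partition A `community_partition`, or a named vector
#'   term -> community id.
#' @return The modularity Q (a number in \[-0.5, 1)).
#' @export
modularity_q <- function(network, partition) {
  assignment <- if (inherits(partition, "community_partition"))
    partition$assignment else partition
  g <- .as_lgraph(network)
  idx <- match(g$names, names(assignment))
  if (anyNA(idx))
    stop("partition is missing nodes: ",
         paste(utils::head(g$names[is.na(idx)], 5), collapse = ", "))
  memb <- as.integer(assignment[idx])
  .lgraph_modularity(g, memb)
}

# One Louvain level: local moves until no move gains more than tol.
# Returns the (non-renumbered) membership vector.
.louvain_one_level <- function(g, order, tol) {
  m <- .lgraph_m(g)
  k <- .lgraph_degrees(g)
  memb <- seq_len(g$n)
  # adjacency lists
  nbr <- vector("list", g$n)
  nw <- vector("list", g$n)
  for (e in seq_along(g$ew)) {
    i <- g$ei[e]; j <- g$ej[e]
    nbr[[i]] <- c(nbr[[i]], j); nw[[i]] <- c(nw[[i]], g$ew[e])
    nbr[[j]] <- c(nbr[[j]], i); nw[[j]] <- c(nw[[j]], g$ew[e])
  }
  comm_tot <- k  # per-community total degree, indexed by community id
                 # (ids stay within 1..n, the initial singleton labels)
  repeat {
    moved <- FALSE
    for (i in order) {
      ci <- memb[i]
      # remove i from its community
      comm_tot[ci] <- comm_tot[ci] - k[i]
      # links from i to each neighboring community
      cand <- memb[nbr[[i]]]
      kin <- if (length(cand)) tapply(nw[[i]], cand, sum) else numeric(0)
      comms <- as.integer(names(kin))
      if (!(ci %in% comms)) { comms <- c(comms, ci); kin <- c(kin, 0) }
      gain <- kin / m - comm_tot[comms] * k[i] / (2 * m^2)
      best <- max(gain)
      pick <- comms[gain >= best - 0]       # exact max set
      pick <- min(pick)                      # tie-break: smallest id
      old_gain <- gain[match(ci, comms)]
      target <- if (best - old_gain > tol) pick else ci
      memb[i] <- target
      comm_tot[target] <- comm_tot[target] + k[i]
      if (target != ci) moved <- TRUE
    }
    if (!moved) break
  }
  memb
}

# Aggregate communities into super-nodes.
.lgraph_aggregate <- function(g, memb) {
  ids <- sort(unique(memb))
  new <- match(memb, ids)
  nn <- length(ids)
  self <- numeric(nn)
  for (v in seq_len(g$n)) self[new[v]] <- self[new[v]] + g$self[v]
  ew_map <- new.env(parent = emptyenv())
  for (e in seq_along(g$ew)) {
    a <- new[g$ei[e]]; b <- new[g$ej[e]]
    if (a == b) {
      self[a] <- self[a] + g$ew[e]
    } else {
      key <- paste(min(a, b), max(a, b))
      ew_map[[key]] <- (if (is.null(ew_map[[key]])) 0 else ew_map[[key]]) + g$ew[e]
    }
  }
  keys <- ls(ew_map)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, " "))
    ei <- as.integer(parts[, 1]); ej <- as.integer(parts[, 2])
    ew <- vapply(keys, function(kk) ew_map[[kk]], numeric(1), USE.NAMES = FALSE)
  } else {
    ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  }
  list(graph = list(n = nn, names = as.character(seq_len(nn)),
                    ei = ei, ej = ej, ew = ew, self = self),
       map = new)
}

#' Louvain community detection
#'
#' Two-phase greedy modularity maximization. Phase 1 starts from
#' singleton communities and sweeps the nodes in a seed-shuffled order,
#' moving each node to the neighboring community with the largest
#' modularity gain (ties: smallest community id); sweeps repeat until no
#' move gains more than `tolerance`. Phase 2 aggregates communities into
#' super-nodes (internal weight becomes a self-loop) and repeats. The
#' iteration stops automatically when a whole level yields no modularity
#' improvement, so the number of communities (topics) emerges from the
#' optimization rather than being chosen by the user.
#'
#' @param network A `cooccurrence_network` with at least one edge.
#' @param seed Integer seed for the node-visit shuffle (default 0); fixed
#'   seed gives identical output across runs.
#' @param tolerance Minimum Q gain counted as an improvement
#'   (default 1e-12).
#' @return A [community_partition()] with the node-level assignment, its
#'   modularity Q, and the number of aggregation levels used.
#' @export
louvain_partition <- function(network, seed = 0L, tolerance = 1e-12) {
  g <- .as_lgraph(network)
  if (length(g$ew) == 0L) stop("network has no edges; cannot detect communities")
  node_map <- seq_len(g$n)  # original node -> current super-node
  levels <- 0L
  q_prev <- .lgraph_modularity(g, seq_len(g$n))
  withr::with_seed(as.integer(seed), {
    repeat {
      levels <- levels + 1L
      ord <- sample.int(g$n)
      memb <- .louvain_one_level(g, ord, tolerance)
      q_new <- .lgraph_modularity(g, memb)
      agg <- .lgraph_aggregate(g, memb)
      node_map <- agg$map[node_map]
      if (q_new - q_prev <= tolerance || agg$graph$n == g$n) {
        q_prev <- max(q_prev, q_new)
        break
      }
      q_prev <- q_new
      g <- agg$graph
    }
  })
  terms <- network$nodes$term
  assignment <- stats::setNames(node_map, terms)
  # contiguous ids from 0, ordered by first appearance in node order
  ids <- unique(assignment)
  assignment <- match(assignment, ids) - 1L
  names(assignment) <- terms
  part <- community_partition(assignment, levels = levels,
                              seed = as.integer(seed), tolerance = tolerance)
  part$modularity <- modularity_q(network, part)
  part
}

#' Write a partition to CSV plus a run-metadata JSON
#'
#' @param partition A `community_partition`.
#' @param csv Path for the term/community CSV.
#' @param meta Optional path for run metadata JSON (Q, number of
#'   communities, levels, seed, tolerance).
#' @return Invisibly, the partition.
#' @export
write_partition <- function(partition, csv, meta = NULL) {
  utils::write.csv(data.frame(term = names(partition$assignment),
                              community = as.integer(partition$assignment)),
                   csv, row.names = FALSE)
  if (!is.null(meta))
    jsonlite::write_json(list(modularity = partition$modularity,
                              n_communities = partition$n_communities,
                              levels = partition$levels,
                              seed = partition$seed,
                              tolerance = partition$tolerance),
                         meta, auto_unbox = TRUE, digits = NA)
  invisible(partition)
}
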