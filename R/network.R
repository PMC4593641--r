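#' @include AllClasses.R
NULL

#' Keep only the strongest interactions
#'
#' Retains the `ceiling(fraction * nEdges)` highest-weight edges; all edges
#' tied with the cutoff weight are kept, so the result can slightly exceed
#' that count but never depends on input order. Nodes left without edges
#' stay in the network as isolates.
#'
#' @param net a [GeneNetwork-class].
#' @param fraction fraction of edges to keep, in (0, 1]. The default 0.05
#'   keeps the top 5% of interactions.
#' @return a filtered [GeneNetwork-class] over the same node set.
#' @export
filterTopEdges <- function(net, fraction = 0.05) {
  stopifnot(is(net, "GeneNetwork"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]")
  e <- net@edges
  if (!nrow(e)) return(net)
  k <- ceiling(fraction * nrow(e))
  cutoff <- sort(e$weight, decreasing = TRUE)[k]
  e2 <- e[e$weight >= cutoff, , drop = FALSE]
  rownames(e2) <- NULL
  new("GeneNetwork", nodes = net@nodes, edges = e2,
      maxWeight = max(e2$weight))
}

#' Edge weight to Dijkstra distance
#'
#' d = max_w / w: the strongest interaction in the network has distance 1
#' and weaker interactions are proportionally farther.
#'
#' @param w positive edge weight(s).
#' @param max_w the maximum edge weight of the whole (filtered) network.
#' @return distance(s) >= 1.
#' @export
edgeDistance <- function(w, max_w) {
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  if (!is.finite(max_w) || max_w <= 0) stop("max_w must be positive")
  if (any(w > max_w)) stop("w cannot exceed max_w")
  max_w / w
}

# Internal: igraph view of a GeneNetwork with distance edge attribute.
asIgraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net@edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = net@nodes))
  igraph::E(g)$weight <- net@edges$weight
  igraph::E(g)$dist <- edgeDistance(net@edges$weight, net@maxWeight)
  g
}

#' Cut out the Dijkstra neighborhood of a query gene
#'
#' Selects the `k_sub` genes closest to the query by shortest-path distance
#' over [edgeDistance()] lengths (fewer when the connected component is
#' smaller), keeps the edges among them, and attaches a sink node to every
#' member that lost at least one connection in the cut; the member-sink edge
#' weight is the summed weight of that member's removed connections. The
#' sink models leakage toward the rest of the network; it is never ranked
#' and never contributes features.
#'
#' Distance ties at the neighborhood boundary are broken by lexicographic
#' gene identifier. A query absent from every edge yields a subnetwork of
#' just the query (no sink).
#'
#' @param net a filtered [GeneNetwork-class].
#' @param query a gene in `net`.
#' @param k_sub neighborhood size; default 30.
#' @return an unranked [QuerySubnetwork-class].
#' @export
buildSubnetwork <- function(net, query, k_sub = 30L) {
  stopifnot(is(net, "GeneNetwork"))
  if (!query %in% net@nodes) stop("query gene not in network: ", query)
  touches <- net@edges$from == query | net@edges$to == query
  if (!any(touches)) {
    return(new("QuerySubnetwork", query = query, members = query,
               sink = character(0),
               edges = data.frame(from = character(), to = character(),
                                  weight = numeric()),
               distances = stats::setNames(0, query),
               maxWeight = net@maxWeight,
               walkProbabilities = numeric(0), ranks = integer(0)))
  }
  g <- asIgraph(net)
  d <- igraph::distances(g, v = query, weights = igraph::E(g)$dist)[1L, ]
  d <- d[is.finite(d)]
  nb <- d[names(d) != query]
  nb <- nb[order(nb, names(nb), method = "radix")]
  keep <- names(nb)[seq_len(min(k_sub, length(nb)))]
  members <- c(query, keep)
  e <- net@edges
  inm <- e$from %in% members & e$to %in% members
  kept <- e[inm, , drop = FALSE]
  cut <- e[xor(e$from %in% members, e$to %in% members), , drop = FALSE]
  sink <- character(0)
  if (nrow(cut)) {
    sink <- ".sink"
    boundary <- ifelse(cut$from %in% members, cut$from, cut$to)
    lost <- rowsum(cut$weight, boundary)
    kept <- rbind(kept, data.frame(from = rownames(lost), to = sink,
                                   weight = as.numeric(lost[, 1L])))
  }
  rownames(kept) <- NULL
  new("QuerySubnetwork", query = query, members = members, sink = sink,
      edges = kept,
      distances = stats::setNames(c(0, unname(nb[keep])), c(query, keep)),
      maxWeight = net@maxWeight,
      walkProbabilities = numeric(0), ranks = integer(0))
}

#' Rank subnetwork neighbors by a random walk
#'
#' Runs a random walk with restart at the query over the subnetwork
#' (sink included): p <- alpha * e_query + (1 - alpha) * t(P) p with P the
#' row-normalized edge weights, iterated until the L1 change falls below
#' `tol`. The restart makes the stationary distribution unique and centered
#' on the query. Non-query, non-sink members are then ranked 1, 2, ... by
#' descending probability; the query's own rank is 0 by convention. Ties
#' are broken by ascending Dijkstra distance, then gene identifier.
#'
#' @param sub an unranked [QuerySubnetwork-class] with at least one
#'   non-query member.
#' @param alpha restart probability, in (0, 1); default 0.5.
#' @param tol L1 convergence tolerance; default 1e-9.
#' @param max_iter iteration cap; exceeding it is an error, not a silent
#'   approximate result.
#' @return the subnetwork with `walkProbabilities` and `ranks` filled.
#' @export
randomWalkRanks <- function(sub, alpha = 0.5, tol = 1e-9, max_iter = 10000L) {
  stopifnot(is(sub, "QuerySubnetwork"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  others <- setdiff(sub@members, sub@query)
  if (!length(others)) stop("subnetwork has no non-query member to rank")
  nodes <- c(sub@members, sub@sink)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(sub@edges))) {
    a <- sub@edges$from[i]; b <- sub@edges$to[i]; w <- sub@edges$weight[i]
    W[a, b] <- W[a, b] + w
    W[b, a] <- W[b, a] + w
  }
  deg <- rowSums(W)
  P <- W / ifelse(deg > 0, deg, 1)          # dangling rows stay zero
  restart <- as.numeric(nodes == sub@query)
  p <- restart
  for (it in seq_len(max_iter)) {
    # dangling mass restarts at the query as well
    p_new <- alpha * restart + (1 - alpha) *
      (as.numeric(crossprod(P, p)) + sum(p[deg == 0]) * restart)
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
    if (it == max_iter)
      stop("random walk failed to converge within ", max_iter,
           " iterations (last L1 change ", format(delta), ")")
  }
  names(p) <- nodes
  ord <- order(-p[others], sub@distances[others], others, method = "radix")
  ranks <- stats::setNames(seq_along(others), others[ord])
  sub@walkProbabilities <- p
  sub@ranks <- ranks[others]   # named by gene, values 1..k
  validObject(sub)
  sub
}

#' Rank-independent neighbor weight from Dijkstra distance
#'
#' w(query, neighbor) = max_w / d(query, neighbor): neighbors reached
#' through strong interactions get weights close to the network's maximum
#' weight, distant neighbors proportionally less.
#'
#' @param sub a [QuerySubnetwork-class].
#' @param neighbor a non-query member of `sub`.
#' @return a positive number.
#' @export
neighborWeight <- function(sub, neighbor) {
  stopifnot(is(sub, "QuerySubnetwork"))
  if (!neighbor %in% setdiff(sub@members, sub@query))
    stop("gene is not a neighbor in this subnetwork: ", neighbor)
  d <- sub@distances[[neighbor]]
  if (!is.finite(d)) stop("neighbor has no finite distance: ", neighbor)
  sub@maxWeight / d
}

#' Build and rank a query subnetwork in one call
#'
#' Convenience wrapper: [buildSubnetwork()] then [randomWalkRanks()] (the
#' walk is skipped when the query has no neighbors).
#'
#' @inheritParams buildSubnetwork
#' @inheritParams randomWalkRanks
#' @return a [QuerySubnetwork-class], ranked when it has neighbors.
#' @export
geneSubnetwork <- function(net, query, k_sub = 30L, alpha = 0.5,
                           tol = 1e-9, max_iter = 10000L) {
  sub <- buildSubnetwork(net, query, k_sub = k_sub)
  if (length(sub@members) > 1L)
    sub <- randomWalkRanks(sub, alpha = alpha, tol = tol, max_iter = max_iter)
  sub
}
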