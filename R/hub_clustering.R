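#' Select hub nodes of a network
#'
#' Hubs are the nodes whose degree is strictly greater than the empirical
#' `percentile` quantile of the degree multiset. The quantile is computed by
#' the nearest-rank method: the value at rank `ceiling(percentile * |V|)`
#' in the ascending sorted degree list. Ties at the threshold are excluded.
#' If no node exceeds the threshold (e.g. a single node dominates the rank
#' position), the single maximum-degree node is returned as a fallback and
#' a message is emitted.
#'
#' @param net A [ppi_network].
#' @param percentile Degree quantile in `(0, 1)`; default `0.95`.
#' @return Character vector of hub node IDs, sorted by degree (descending),
#'   then node ID (ascending).
#' @export
select_hubs <- function(net, percentile = 0.95) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(net$nodes) == 0) abort("cannot select hubs of an empty network")
  if (percentile <= 0 || percentile >= 1) abort("percentile must be in (0, 1)")
  d <- node_degrees(net)
  sorted <- sort(unname(d))
  thr <- sorted[ceiling(percentile * length(sorted))]
  hubs <- names(d)[d > thr]
  if (length(hubs) == 0) {
    top <- max(d)
    hubs <- sort(names(d)[d == top])[1]
    inform(sprintf(
      "no node exceeds the %g-quantile degree threshold (%d); falling back to top-degree node %s",
      percentile, thr, hubs))
  }
  hubs[order(-d[hubs], hubs)]
}

#' Partition a network into hub-centred clusters
#'
#' Runs multi-source Dijkstra from the hubs with edge length `-log(p)` and
#' assigns every node to the cluster of its nearest hub. Distance ties are
#' broken by hub order in `hubs`; every hub belongs to its own cluster.
#' Nodes unreachable from every hub are reported as `unassigned` and take
#' no part in later alignment stages.
#'
#' @param net A [ppi_network].
#' @param hubs Character vector of hub node IDs (all present in `net`),
#'   typically from [select_hubs()].
#' @return An object of class `hub_clustering`: list with `hubs`,
#'   `assignment` (tibble `node`, `hub`, `distance`) and `unassigned`
#'   (character vector).
#' @export
assign_to_clusters <- function(net, hubs) {
  stopifnot(inherits(net, "ppi_network"))
  if (length(hubs) == 0) abort("`hubs` must be nonempty")
  missing <- setdiff(hubs, net$nodes)
  if (length(missing)) {
    abort(sprintf("hub(s) not in network: %s", paste(missing, collapse = ", ")))
  }
  g <- as_igraph(net)
  dmat <- igraph::distances(g, v = hubs, to = igraph::V(g),
                            weights = igraph::E(g)$length,
                            algorithm = "dijkstra")
  # rows = hubs (in input order), columns = nodes; which.min takes the
  # first minimising hub, i.e. the stated tie-break
  best <- apply(dmat, 2, which.min)
  bestd <- dmat[cbind(best, seq_len(ncol(dmat)))]
  nodes <- colnames(dmat)
  reachable <- is.finite(bestd)
  assignment <- tibble(node = nodes[reachable],
                       hub = hubs[best[reachable]],
                       distance = bestd[reachable])
  # a hub tied at distance 0 with an earlier hub still owns itself
  hub_rows <- match(hubs, assignment$node)
  assignment$hub[hub_rows] <- hubs
  assignment$distance[hub_rows] <- 0
  unassigned <- sort(nodes[!reachable])
  if (length(unassigned)) {
    inform(sprintf("%d node(s) unreachable from every hub are left unassigned",
                   length(unassigned)))
  }
  assignment <- arrange(assignment, .data$node)
  structure(list(hubs = hubs, assignment = assignment, unassigned = unassigned),
            class = "hub_clustering")
}

#' Extract the clusters of a hub clustering
#'
#' @param clustering A `hub_clustering` from [assign_to_clusters()].
#' @return Named list (one element per hub, in hub order) of character
#'   vectors of member nodes.
#' @export
cluster_members <- function(clustering) {
  stopifnot(inherits(clustering, "hub_clustering"))
  out <- setNames(vector("list", length(clustering$hubs)), clustering$hubs)
  sp <- split(clustering$assignment$node, clustering$assignment$hub)
  for (h in names(sp)) out[[h]] <- sort(sp[[h]])
  out
}

#' @export
print.hub_clustering <- function(x, ...) {
  sizes <- table(x$assignment$hub)[x$hubs]
  cat(sprintf("<hub_clustering> %d hubs, %d assigned nodes, %d unassigned\n",
              length(x$hubs), nrow(x$assignment), length(x$unassigned)))
  cat("cluster sizes:", paste(sprintf("%s=%d", x$hubs, sizes), collapse = ", "),
      "\n")
  invisible(x)
}
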