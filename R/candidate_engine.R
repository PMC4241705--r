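#' Scoring and pruning parameters for the candidate engine
#'
#' @param alpha Weight in `[0, 1]` balancing conserved-edge degrees against
#'   interaction probabilities in the structural score; `alpha = 1` scores
#'   pure degree structure, `alpha = 0` pure probability.
#' @param beam_width Maximum number of candidates retained per collection
#'   after each merge (`Inf` disables pruning).
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(alpha = 0.5, beam_width = 100) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    abort("`alpha` must lie in [0, 1]")
  }
  if (!is.numeric(beam_width) || beam_width < 1) {
    abort("`beam_width` must be a positive integer (or Inf)")
  }
  structure(list(alpha = alpha, beam_width = beam_width),
            class = "scoring_params")
}

# ---- candidate / collection representations -------------------------------
# A candidate is a local alignment: an injective map from a set of network-1
# vertices onto network-2 vertices, with cached node and structural scores.
# Internally: list(mapping = named chr (names sorted), ns, ss).

as_candidate <- function(x) {
  if (is.list(x) && !is.null(x$mapping)) return(x)
  if (is.character(x) && !is.null(names(x))) {
    m <- x[order(names(x))]
    if (anyDuplicated(unname(m))) abort("candidate mapping must be injective")
    return(list(mapping = m, ns = NA_real_, ss = NA_real_))
  }
  abort("a candidate is a named character vector (g1 vertex -> g2 vertex)")
}

map_string <- function(mapping) {
  paste0(names(mapping), "->", unname(mapping), collapse = ";")
}

new_collection <- function(g1_vertices, candidates) {
  structure(list(g1_vertices = sort(g1_vertices), candidates = candidates),
            class = "candidate_collection")
}

#' @export
print.candidate_collection <- function(x, ...) {
  cat(sprintf("<candidate_collection> size %d {%s}, cardinality %d\n",
              length(x$g1_vertices), paste(x$g1_vertices, collapse = ","),
              length(x$candidates)))
  if (length(x$candidates)) {
    top <- x$candidates[[1]]
    cat(sprintf("top candidate: %s (node %.4g, structural %.4g)\n",
                map_string(top$mapping), top$ns, top$ss))
  }
  invisible(x)
}

#' Turn a candidate collection into a tibble
#'
#' @param x A `candidate_collection`.
#' @param ... Unused.
#' @return A tibble with one row per candidate: `mapping` (string form),
#'   `node_score`, `structural_score`.
#' @method tidy candidate_collection
#' @export
tidy.candidate_collection <- function(x, ...) {
  tibble(mapping = vapply(x$candidates, function(c) map_string(c$mapping), ""),
         node_score = vapply(x$candidates, function(c) c$ns, 0),
         structural_score = vapply(x$candidates, function(c) c$ss, 0))
}

# ---- scoring --------------------------------------------------------------

#' Node score of a candidate
#'
#' Sum of the BLAST bit scores of all mapped vertex pairs. Additive under
#' merging of disjoint candidates.
#'
#' @param candidate Named character vector (or candidate object) mapping
#'   network-1 vertices to network-2 vertices.
#' @param scores A [score_table].
#' @return Nonnegative number; 0 for the empty candidate.
#' @export
node_score <- function(candidate, scores) {
  m <- as_candidate(candidate)$mapping
  if (length(m) == 0) return(0)
  sum(score_lookup(scores, names(m), unname(m)))
}

#' Conserved edges at a vertex of a candidate
#'
#' Counts the neighbours `u` of `v` inside the candidate's network-1 vertex
#' set such that the edge `(v, u)` exists in network 1 and the edge between
#' their images exists in network 2.
#'
#' @param candidate Candidate mapping (see [node_score()]).
#' @param v A network-1 vertex of the candidate.
#' @param g1,g2 The two [ppi_network]s.
#' @return Integer count.
#' @export
conserved_edge_count <- function(candidate, v, g1, g2) {
  m <- as_candidate(candidate)$mapping
  if (!v %in% names(m)) abort(sprintf("vertex %s is not in the candidate", v))
  P1 <- prob_matrix(g1); P2 <- prob_matrix(g2)
  others <- setdiff(names(m), v)
  if (length(others) == 0) return(0L)
  sum(P1[v, others] > 0 & P2[m[[v]], m[others]] > 0)
}

# structural score on precomputed probability matrices
structural_impl <- function(mapping, P1, P2, alpha) {
  if (length(mapping) < 2) return(0)
  V <- names(mapping); U <- unname(mapping)
  A1 <- P1[V, V, drop = FALSE]
  A2 <- P2[U, U, drop = FALSE]
  cons <- A1 > 0 & A2 > 0
  if (!any(cons)) return(0)
  f <- rowSums(cons)
  ff <- outer(f, f)
  # R's 0^0 == 1, so alpha = 0 and alpha = 1 degenerate cleanly
  sum(ff[cons]^alpha * (A1[cons] * A2[cons])^(1 - alpha))
}

#' Structural score of a candidate
#'
#' Rewards conserved edges, weighting each ordered conserved pair
#' `(v, u)` by `(f(v) f(u))^alpha * (P1(v,u) P2(M(v),M(u)))^(1-alpha)`,
#' where `f` counts conserved edges at a vertex (a bridge-importance
#' weight) and the probability factor is the geometric evidence that the
#' interaction exists in both networks. Terms where either edge is absent
#' contribute 0; `0^0` is taken as 1.
#'
#' @inheritParams conserved_edge_count
#' @param alpha Degree-vs-probability weight in `[0, 1]`.
#' @return Nonnegative number; 0 iff the candidate conserves no edge.
#' @export
structural_score <- function(candidate, g1, g2, alpha = 0.5) {
  m <- as_candidate(candidate)$mapping
  structural_impl(m, prob_matrix(g1), prob_matrix(g2), alpha)
}

# ---- seeds ----------------------------------------------------------------

#' Build size-one candidate collections for a cluster
#'
#' For every cluster vertex with at least one positively scored partner in
#' network 2, creates a collection holding one size-1 candidate per
#' partner. Vertices with no partner produce no collection.
#'
#' @param cluster_nodes Character vector of network-1 vertices.
#' @param scores A [score_table].
#' @return List of `candidate_collection`s, in sorted vertex order, each
#'   sorted by (node score desc, structural score desc).
#' @export
seed_collections <- function(cluster_nodes, scores) {
  if (length(cluster_nodes) == 0) abort("cluster must be nonempty")
  nodes <- sort(unique(as.character(cluster_nodes)))
  out <- list()
  skipped <- 0L
  for (v in nodes) {
    partners <- score_partners(scores, v)
    if (length(partners) == 0) { skipped <- skipped + 1L; next }
    partners <- partners[order(-partners, names(partners))]
    cands <- purrr::map2(names(partners), unname(partners), function(u, s) {
      list(mapping = setNames(u, v), ns = s, ss = 0)
    })
    out[[length(out) + 1L]] <- new_collection(v, cands)
  }
  if (skipped > 0) {
    inform(sprintf("%d cluster vertex(es) have no scored partner and were skipped",
                   skipped))
  }
  out
}

# ---- combining pattern ----------------------------------------------------

# reciprocal-length matrix: 1 / (-log p) where an edge exists, else 0;
# p == 1 gives Inf (zero-length edge)
recip_matrix <- function(net) {
  P <- prob_matrix(net)
  R <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  e <- P > 0
  R[e] <- 1 / (-log(P[e]))
  R
}

collection_distance_impl <- function(Vi, Vj, R) {
  s <- sum(R[Vi, Vj, drop = FALSE])
  if (s == 0) return(Inf)
  if (is.infinite(s)) return(0)
  (length(Vi) + length(Vj)) / s
}

#' Connectivity distance between two candidate collections
#'
#' The merge-order distance: `(|Vi| + |Vj|) / sum(a(v,u) / e(v,u))` over
#' vertex pairs across the two network-1 vertex sets, where `a` indicates
#' an edge and `e = -log p` is its length. No connecting edge gives
#' `Inf`; any connecting edge of probability 1 gives 0.
#'
#' @param cc_i,cc_j `candidate_collection`s with disjoint vertex sets.
#' @param g1 The network the vertex sets live in.
#' @return Nonnegative number or `Inf`.
#' @export
collection_distance <- function(cc_i, cc_j, g1) {
  if (length(intersect(cc_i$g1_vertices, cc_j$g1_vertices))) {
    abort("collections must have disjoint vertex sets")
  }
  collection_distance_impl(cc_i$g1_vertices, cc_j$g1_vertices,
                           recip_matrix(g1))
}

# agglomerate vertex sets under the collection distance; returns nested tree
build_pattern_impl <- function(sets, R) {
  active <- purrr::map(seq_along(sets), function(i) {
    list(set = sets[[i]],
         tree = list(leaf = TRUE, index = i, members = sets[[i]]))
  })
  while (length(active) > 1) {
    k <- length(active)
    best <- NULL
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        d <- collection_distance_impl(active[[i]]$set, active[[j]]$set, R)
        m1 <- min(active[[i]]$set); m2 <- min(active[[j]]$set)
        key <- c(min(m1, m2), max(m1, m2))
        better <-
          is.null(best) ||
          d < best$d ||
          (d == best$d && (key[1] < best$key[1] ||
                             (key[1] == best$key[1] && key[2] < best$key[2])))
        if (better) best <- list(i = i, j = j, d = d, key = key)
      }
    }
    merged <- list(
      set = sort(c(active[[best$i]]$set, active[[best$j]]$set)),
      tree = list(leaf = FALSE,
                  left = active[[best$i]]$tree,
                  right = active[[best$j]]$tree,
                  members = sort(c(active[[best$i]]$set,
                                   active[[best$j]]$set))))
    active <- c(active[-c(best$i, best$j)], list(merged))
  }
  active[[1]]$tree
}

#' Hierarchical combining pattern over seed collections
#'
#' Agglomerates the seed collections by repeatedly merging the pair at
#' minimal [collection_distance()] (recomputed exactly on the union vertex
#' sets), producing the rooted binary merge tree that guides the candidate
#' merge order. Distance ties break lexicographically on the smallest
#' member IDs of the two sets; infinitely distant pairs merge last under
#' the same tie-break, so the tree always completes.
#'
#' @param seeds List of `candidate_collection`s (disjoint vertex sets).
#' @param g1 The clustered [ppi_network].
#' @return A `combining_pattern`: nested list with fields `leaf`,
#'   `members`, and (`index`) for leaves or (`left`, `right`) internally.
#' @export
build_combining_pattern <- function(seeds, g1) {
  if (length(seeds) == 0) abort("need at least one seed")
  sets <- purrr::map(seeds, "g1_vertices")
  tree <- build_pattern_impl(sets, recip_matrix(g1))
  structure(tree, class = "combining_pattern")
}

# ---- merging --------------------------------------------------------------

collection_image_matrix <- function(cc, g2_nodes) {
  k <- length(cc$candidates)
  M <- matrix(FALSE, k, length(g2_nodes))
  for (i in seq_len(k)) {
    M[i, match(unname(cc$candidates[[i]]$mapping), g2_nodes)] <- TRUE
  }
  M
}

sort_candidates <- function(cands) {
  if (length(cands) <= 1) return(cands)
  ns <- vapply(cands, function(c) c$ns, 0)
  ss <- vapply(cands, function(c) c$ss, 0)
  ms <- vapply(cands, function(c) map_string(c$mapping), "")
  cands[order(-ns, -ss, ms)]
}

top_key <- function(cc) {
  if (length(cc$candidates) == 0) return(c(-Inf, -Inf))
  c(cc$candidates[[1]]$ns, cc$candidates[[1]]$ss)
}

merge_collections_impl <- function(cc_i, cc_j, ctx, params) {
  if (length(intersect(cc_i$g1_vertices, cc_j$g1_vertices))) {
    abort("collections must have disjoint vertex sets")
  }
  ci <- cc_i$candidates; cj <- cc_j$candidates
  Mi <- collection_image_matrix(cc_i, ctx$g2_nodes)
  Mj <- collection_image_matrix(cc_j, ctx$g2_nodes)
  overlap <- Mi %*% t(Mj)           # counts of shared network-2 images
  valid <- which(overlap == 0, arr.ind = TRUE)
  if (nrow(valid) == 0) {
    # every pairing reuses a network-2 vertex: adopt the stronger parent
    ki <- top_key(cc_i); kj <- top_key(cc_j)
    keep_i <- ki[1] > kj[1] || (ki[1] == kj[1] && ki[2] >= kj[2])
    inform(sprintf("merge {%s} x {%s}: all pairings conflict; keeping parent {%s}",
                   paste(cc_i$g1_vertices, collapse = ","),
                   paste(cc_j$g1_vertices, collapse = ","),
                   paste((if (keep_i) cc_i else cc_j)$g1_vertices,
                         collapse = ",")))
    return(if (keep_i) cc_i else cc_j)
  }
  ns_i <- vapply(ci, function(c) c$ns, 0)
  ns_j <- vapply(cj, function(c) c$ns, 0)
  ns_all <- ns_i[valid[, 1]] + ns_j[valid[, 2]]   # node score is additive
  beam <- params$beam_width
  # structural scores are only needed for candidates that can reach the
  # beam: primary key is the node score, so shortlist by it first
  if (is.finite(beam) && length(ns_all) > beam) {
    thr <- sort(ns_all, decreasing = TRUE)[beam]
    short <- which(ns_all >= thr)
  } else {
    short <- seq_along(ns_all)
  }
  cands <- purrr::map(short, function(s) {
    m <- c(ci[[valid[s, 1]]]$mapping, cj[[valid[s, 2]]]$mapping)
    m <- m[order(names(m))]
    list(mapping = m, ns = ns_all[s],
         ss = structural_impl(m, ctx$P1, ctx$P2, params$alpha))
  })
  cands <- sort_candidates(cands)
  if (is.finite(beam) && length(cands) > beam) cands <- cands[seq_len(beam)]
  new_collection(c(cc_i$g1_vertices, cc_j$g1_vertices), cands)
}

#' Merge two candidate collections
#'
#' Forms the union candidate of every pair of member candidates whose
#' network-2 images are disjoint (preserving injectivity), scores them, and
#' prunes to the beam width. If every pairing conflicts, the
#' lexicographically higher-scoring parent collection is adopted unchanged
#' (logged), so a poison pair cannot erase a whole subtree.
#'
#' @param cc_i,cc_j `candidate_collection`s with disjoint network-1 vertex
#'   sets.
#' @param g1,g2 The two [ppi_network]s.
#' @param scores A [score_table] (used for node scores of the parents when
#'   missing).
#' @param params A [scoring_params].
#' @return A `candidate_collection`.
#' @export
merge_collections <- function(cc_i, cc_j, g1, g2, scores,
                              params = scoring_params()) {
  ctx <- list(P1 = prob_matrix(g1), P2 = prob_matrix(g2),
              g2_nodes = g2$nodes)
  merge_collections_impl(cc_i, cc_j, ctx, params)
}

#' Prune a candidate collection to the beam width
#'
#' Candidates are ordered by node score (descending), then structural score
#' (descending), then the string form of the mapping (ascending, a
#' deterministic tie-break); the first `beam_width` are kept.
#'
#' @param cc A `candidate_collection`.
#' @param params A [scoring_params].
#' @return The pruned `candidate_collection`.
#' @export
prune_collection <- function(cc, params = scoring_params()) {
  cands <- sort_candidates(cc$candidates)
  if (is.finite(params$beam_width) && length(cands) > params$beam_width) {
    cands <- cands[seq_len(params$beam_width)]
  }
  new_collection(cc$g1_vertices, cands)
}

# ---- per-cluster driver ---------------------------------------------------

eval_pattern <- function(tree, seeds, ctx, params) {
  if (isTRUE(tree$leaf)) return(seeds[[tree$index]])
  merge_collections_impl(eval_pattern(tree$left, seeds, ctx, params),
                         eval_pattern(tree$right, seeds, ctx, params),
                         ctx, params)
}

#' Align one hub cluster against the second network
#'
#' Runs the candidate engine for a single cluster: seed collections, the
#' hierarchical combining pattern, and a post-order beam-pruned merge of
#' the tree, yielding the cluster's final candidate collection. The result
#' may cover fewer vertices than the cluster when some vertices have no
#' scored partner or all pairings at a merge conflict.
#'
#' @param cluster Character vector of network-1 vertices (one hub cluster).
#' @param g1,g2 The two [ppi_network]s.
#' @param scores A [score_table].
#' @param params A [scoring_params].
#' @return A `candidate_collection` (empty if no cluster vertex has any
#'   scored partner).
#' @export
align_hub_cluster <- function(cluster, g1, g2, scores,
                              params = scoring_params()) {
  ctx <- list(P1 = prob_matrix(g1), P2 = prob_matrix(g2),
              g2_nodes = g2$nodes)
  align_hub_cluster_impl(cluster, ctx, scores, params)
}

align_hub_cluster_impl <- function(cluster, ctx, scores, params) {
  seeds <- seed_collections(cluster, scores)
  if (length(seeds) == 0) {
    inform("no cluster vertex has a scored partner; empty collection")
    return(new_collection(character(), list()))
  }
  seeds <- purrr::map(seeds, prune_collection, params = params)
  if (length(seeds) == 1) return(seeds[[1]])
  R <- matrix(0, nrow(ctx$P1), ncol(ctx$P1), dimnames = dimnames(ctx$P1))
  e <- ctx$P1 > 0
  R[e] <- 1 / (-log(ctx$P1[e]))
  tree <- build_pattern_impl(purrr::map(seeds, "g1_vertices"), R)
  eval_pattern(tree, seeds, ctx, params)
}
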