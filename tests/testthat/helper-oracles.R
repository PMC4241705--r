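# Independent brute-force oracles. These deliberately avoid the package's
# internal code paths: plain loops, direct edge lookups, exhaustive search.

# --- shortest paths: Floyd-Warshall on -log(p) ------------------------------
oracle_all_pairs <- function(net) {
  ids <- net$nodes
  n <- length(ids)
  D <- matrix(Inf, n, n, dimnames = list(ids, ids))
  diag(D) <- 0
  for (k in seq_len(nrow(net$edges))) {
    i <- net$edges$node1[k]; j <- net$edges$node2[k]
    len <- -log(net$edges$prob[k])
    D[i, j] <- min(D[i, j], len)
    D[j, i] <- min(D[j, i], len)
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

# --- maximum-weight bipartite matching by exhaustive assignment -------------
# W: weight matrix, 0 = absent edge. With nonnegative weights the optimum is
# attained by some full injection of the smaller side (0-weight assignments
# are equivalent to leaving a vertex unmatched), so enumerating injections
# is exhaustive.
oracle_matching_weight <- function(W) {
  if (nrow(W) > ncol(W)) W <- t(W)
  nr <- nrow(W); nc <- ncol(W)
  best <- 0
  rec <- function(row, used, acc) {
    if (row > nr) {
      if (acc > best) best <<- acc
      return(invisible())
    }
    for (col in which(!used)) {
      used[col] <- TRUE
      rec(row + 1, used, acc + W[row, col])
      used[col] <- FALSE
    }
  }
  rec(1, rep(FALSE, nc), 0)
  best
}

# --- maximum-weight DMatching by branch on first active vertex --------------
# edges: data.frame(left, right, weight). A solution is a vertex-disjoint set
# of single edges (matches) and length-2 paths (one-to-two matches).
oracle_dmatching_weight <- function(edges) {
  m <- nrow(edges)
  if (m == 0) return(0)
  memo <- new.env(parent = emptyenv())
  rec <- function(alive) {
    if (!any(alive)) return(0)
    key <- paste(which(alive), collapse = ",")
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    i0 <- which(alive)[1]
    v <- edges$left[i0]                      # branch on this left vertex
    inc <- which(alive & edges$left == v)
    # option: v stays unmatched
    rest <- alive; rest[inc] <- FALSE
    best <- rec(rest)
    for (i in inc) {
      u <- edges$right[i]
      # match (v, u)
      rest <- alive & edges$left != v & edges$right != u
      best <- max(best, edges$weight[i] + rec(rest))
      # dmatch centred at v: second incident edge j
      for (j in inc[inc != i]) {
        u2 <- edges$right[j]
        rest <- alive & edges$left != v &
          edges$right != u & edges$right != u2
        best <- max(best, edges$weight[i] + edges$weight[j] + rec(rest))
      }
      # dmatch centred at u: edge (v,u) plus (v2, u)
      others <- which(alive & edges$right == u & edges$left != v)
      for (j in others) {
        v2 <- edges$left[j]
        rest <- alive & edges$right != u &
          edges$left != v & edges$left != v2
        best <- max(best, edges$weight[i] + edges$weight[j] + rec(rest))
      }
    }
    memo[[key]] <- best
    best
  }
  rec(rep(TRUE, m))
}

# --- structural score straight from the definition --------------------------
oracle_structural <- function(mapping, g1, g2, alpha) {
  has_edge <- function(net, a, b) {
    any((net$edges$node1 == a & net$edges$node2 == b) |
          (net$edges$node1 == b & net$edges$node2 == a))
  }
  edge_p <- function(net, a, b) {
    hit <- (net$edges$node1 == a & net$edges$node2 == b) |
      (net$edges$node1 == b & net$edges$node2 == a)
    net$edges$prob[hit][1]
  }
  V <- names(mapping)
  f <- sapply(V, function(v) {
    others <- setdiff(V, v)
    if (length(others) == 0) return(0)
    sum(vapply(others, function(u) {
      has_edge(g1, v, u) && has_edge(g2, mapping[[v]], mapping[[u]])
    }, logical(1)))
  })
  total <- 0
  for (v in V) {
    for (u in setdiff(V, v)) {
      if (has_edge(g1, v, u) && has_edge(g2, mapping[[v]], mapping[[u]])) {
        total <- total + (f[[v]] * f[[u]])^alpha *
          (edge_p(g1, v, u) * edge_p(g2, mapping[[v]], mapping[[u]]))^(1 - alpha)
      }
    }
  }
  total
}

# --- exhaustive local alignment search --------------------------------------
# Best (node_score, structural_score) over ALL injective positive-score
# mappings of every subset of `cluster` into g2 (the naive dynamic program
# run to completion at tiny scale).
oracle_best_alignment <- function(cluster, g1, g2, scores, alpha) {
  cluster <- sort(cluster)
  best <- c(ns = -Inf, ss = -Inf)
  rec <- function(i, mapping) {
    if (i > length(cluster)) {
      if (length(mapping) == 0) return(invisible())
      ns <- sum(score_lookup(scores, names(mapping), unname(mapping)))
      ss <- oracle_structural(mapping, g1, g2, alpha)
      if (ns > best[["ns"]] ||
            (ns == best[["ns"]] && ss > best[["ss"]])) {
        best <<- c(ns = ns, ss = ss)
      }
      return(invisible())
    }
    v <- cluster[i]
    rec(i + 1, mapping)                       # leave v unaligned
    partners <- scores$pairs[scores$pairs$id1 == v, , drop = FALSE]
    for (k in seq_len(nrow(partners))) {
      u <- partners$id2[k]
      if (!u %in% unname(mapping)) {
        m2 <- c(mapping, stats::setNames(u, v))
        rec(i + 1, m2)
      }
    }
  }
  rec(1, stats::setNames(character(), character()))
  best
}
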