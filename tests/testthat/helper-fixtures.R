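# small builders used across the suite

net_from <- function(..., nodes = NULL, species = "") {
  # net_from("a b 0.5", "b c 0.9")
  rows <- strsplit(c(...), "[ \t]+")
  df <- tibble::tibble(
    node1 = vapply(rows, `[`, "", 1),
    node2 = vapply(rows, `[`, "", 2),
    prob = vapply(rows, function(r) {
      if (length(r) >= 3) as.numeric(r[3]) else 1
    }, 0))
  ppi_network(df, nodes = nodes, species = species)
}

scores_from <- function(...) {
  rows <- strsplit(c(...), "[ \t]+")
  score_table(tibble::tibble(
    id1 = vapply(rows, `[`, "", 1),
    id2 = vapply(rows, `[`, "", 2),
    score = vapply(rows, function(r) as.numeric(r[3]), 0)))
}

# Erdos-Renyi-ish random network with probabilities in [0.5, 1]
random_net <- function(n, p_edge = 0.5, prefix = "v", species = "") {
  ids <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  edges <- tibble::tibble(node1 = pairs[1, keep], node2 = pairs[2, keep],
                          prob = stats::runif(sum(keep), 0.5, 1))
  ppi_network(edges, nodes = ids, species = species)
}

# random cross-network score table over the two node sets
random_scores <- function(ids1, ids2, density = 0.6, max_score = 100) {
  grid <- expand.grid(id1 = ids1, id2 = ids2, stringsAsFactors = FALSE)
  keep <- stats::runif(nrow(grid)) < density
  grid <- grid[keep, , drop = FALSE]
  grid$score <- stats::runif(nrow(grid), 1, max_score)
  score_table(grid)
}

# random small candidate (injective mapping with positive scores)
random_candidate <- function(g1_ids, g2_ids, scores, size) {
  v <- sample(g1_ids, size)
  repeat {
    u <- sample(g2_ids, size)
    if (all(score_lookup(scores, v, u) > 0)) break
  }
  stats::setNames(u, v)
}
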