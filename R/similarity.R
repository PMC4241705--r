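#' Candidate support index
#'
#' Inverts a set of final candidate collections into an index from mapped
#' protein pairs `(v, u)` to the candidates that map `v` onto `u`.
#'
#' @param final_ccs List of `candidate_collection`s (the per-cluster final
#'   collections).
#' @return An object of class `candidate_support`: list with `index`
#'   (named list: pair key -> list of candidate mappings) and `pairs`
#'   (tibble `left`, `right`, `n_support`).
#' @export
collect_support <- function(final_ccs) {
  env <- new.env(parent = emptyenv())
  for (cc in final_ccs) {
    for (cand in cc$candidates) {
      m <- cand$mapping
      keys <- pair_key(names(m), unname(m))
      for (k in keys) {
        env[[k]] <- c(env[[k]], list(m))
      }
    }
  }
  keys <- sort(ls(env))
  idx <- setNames(lapply(keys, function(k) env[[k]]), keys)
  split_keys <- strsplit(keys, "\r", fixed = TRUE)
  pairs <- tibble(left = vapply(split_keys, `[`, "", 1),
                  right = vapply(split_keys, `[`, "", 2),
                  n_support = lengths(idx))
  structure(list(index = idx, pairs = pairs), class = "candidate_support")
}

support_for <- function(support, v, u) {
  support$index[[pair_key(v, u)]]
}

#' Node similarity of a supported pair
#'
#' BLAST bit score of the pair multiplied by the number of final candidates
#' supporting it.
#'
#' @param v,u Proteins of network 1 and network 2.
#' @param support A [collect_support()] index; the pair must be supported.
#' @param scores A [score_table].
#' @return Positive number.
#' @export
node_sim <- function(v, u, support, scores) {
  cands <- support_for(support, v, u)
  if (is.null(cands)) abort(sprintf("pair (%s, %s) has no supporting candidate", v, u))
  score_lookup(scores, v, u) * length(cands)
}

#' Conserved-neighbourhood similarity of a supported pair
#'
#' Sums, over every supporting candidate, the bit scores of the images of
#' the network-1 neighbours of `v` that lie inside the candidate.
#'
#' @inheritParams node_sim
#' @param g1 The first [ppi_network].
#' @return Nonnegative number.
#' @export
neighborhoods_sim <- function(v, u, support, g1, scores) {
  cands <- support_for(support, v, u)
  if (is.null(cands)) abort(sprintf("pair (%s, %s) has no supporting candidate", v, u))
  nb <- neighbour_list(g1)[[v]]
  if (is.null(nb)) return(0)
  tot <- 0
  for (m in cands) {
    inside <- intersect(nb, names(m))
    if (length(inside)) {
      tot <- tot + sum(score_lookup(scores, inside, unname(m[inside])))
    }
  }
  tot
}

#' Construct a similarity bipartite graph from an edge table
#'
#' Mainly useful to resume the matching stage from a dumped edge list (see
#' [write_intermediates()]).
#'
#' @param edges Data frame with columns `left` (network-1 protein),
#'   `right` (network-2 protein) and `weight` (positive).
#' @param stage `"isbg"` (initial) or `"simg"` (reduced; vertex degrees
#'   must then be at most 3).
#' @param left_nodes,right_nodes Optional protein universes; default to
#'   the proteins seen in `edges`.
#' @return A `similarity_graph`.
#' @export
similarity_graph <- function(edges, stage = c("isbg", "simg"),
                             left_nodes = NULL, right_nodes = NULL) {
  stage <- match.arg(stage)
  edges <- as_tibble(edges)[, c("left", "right", "weight")]
  edges$left <- as.character(edges$left)
  edges$right <- as.character(edges$right)
  edges$weight <- as.numeric(edges$weight)
  if (any(edges$weight <= 0)) abort("similarity weights must be positive")
  if (anyDuplicated(pair_key(edges$left, edges$right))) {
    abort("duplicate edges in similarity graph")
  }
  if (stage == "simg" && nrow(edges)) {
    deg <- c(table(edges$left), table(edges$right))
    if (max(deg) > 3) abort("a reduced similarity graph has vertex degrees <= 3")
  }
  new_similarity_graph(edges,
                       left_nodes %||% sort(unique(edges$left)),
                       right_nodes %||% sort(unique(edges$right)), stage)
}

new_similarity_graph <- function(edges, left_nodes, right_nodes, stage) {
  edges <- arrange(as_tibble(edges), .data$left, .data$right)
  structure(list(edges = edges, left_nodes = left_nodes,
                 right_nodes = right_nodes, stage = stage),
            class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat(sprintf("<similarity_graph:%s> %d edges over %d + %d proteins\n",
              x$stage, nrow(x$edges), length(x$left_nodes),
              length(x$right_nodes)))
  invisible(x)
}

#' Build the initial similarity bipartite graph
#'
#' One weighted edge per protein pair mapped by at least one final
#' candidate. The weight is `node_sim + neighborhoods_sim / |C|` where
#' `|C|` is the number of supporting candidates: the pair's bit score
#' amplified by its candidate support, plus its mean per-candidate
#' conserved-neighbourhood similarity. Unsupported pairs carry no edge.
#'
#' @param final_ccs List of final `candidate_collection`s.
#' @param g1,g2 The two [ppi_network]s.
#' @param scores A [score_table].
#' @return A `similarity_graph` with `stage = "isbg"`.
#' @export
build_isbg <- function(final_ccs, g1, g2, scores) {
  nb <- neighbour_list(g1)
  cnt <- new.env(parent = emptyenv())
  nsum <- new.env(parent = emptyenv())
  for (cc in final_ccs) {
    for (cand in cc$candidates) {
      m <- cand$mapping
      svec <- setNames(score_lookup(scores, names(m), unname(m)), names(m))
      for (v in names(m)) {
        k <- pair_key(v, m[[v]])
        inside <- intersect(nb[[v]], names(m))
        contrib <- if (length(inside)) sum(svec[inside]) else 0
        cnt[[k]] <- (cnt[[k]] %||% 0L) + 1L
        nsum[[k]] <- (nsum[[k]] %||% 0) + contrib
      }
    }
  }
  keys <- sort(ls(cnt))
  if (length(keys) == 0) {
    return(new_similarity_graph(
      tibble(left = character(), right = character(), weight = numeric()),
      g1$nodes, g2$nodes, "isbg"))
  }
  split_keys <- strsplit(keys, "\r", fixed = TRUE)
  left <- vapply(split_keys, `[`, "", 1)
  right <- vapply(split_keys, `[`, "", 2)
  n_c <- vapply(keys, function(k) as.numeric(cnt[[k]]), 0)
  nsums <- vapply(keys, function(k) nsum[[k]], 0)
  weight <- unname(score_lookup(scores, left, right) * n_c + nsums / n_c)
  new_similarity_graph(tibble(left = left, right = right, weight = weight),
                       g1$nodes, g2$nodes, "isbg")
}

#' Maximum-weight bipartite matching
#'
#' Finds a matching of maximum total weight in a sparse weighted bipartite
#' graph (unmatched vertices allowed, absent edges never matched). Backed
#' by igraph's exact weighted bipartite matching.
#'
#' @param weights A data frame with columns `left`, `right`, `weight`
#'   (positive), or a weight matrix (rows = left, columns = right, 0 = no
#'   edge).
#' @return A tibble of matched pairs `left`, `right`, `weight`.
#' @export
hungarian_max_matching <- function(weights) {
  if (is.matrix(weights)) {
    ln <- rownames(weights) %||% paste0("r", seq_len(nrow(weights)))
    rn <- colnames(weights) %||% paste0("c", seq_len(ncol(weights)))
    idx <- which(weights > 0, arr.ind = TRUE)
    weights <- tibble(left = ln[idx[, 1]], right = rn[idx[, 2]],
                      weight = weights[idx])
  }
  weights <- as_tibble(weights)[, c("left", "right", "weight")]
  if (nrow(weights) == 0) {
    return(tibble(left = character(), right = character(), weight = numeric()))
  }
  if (any(weights$weight <= 0)) abort("matching weights must be positive")
  weights <- arrange(weights, .data$left, .data$right)
  lv <- sort(unique(weights$left))
  rv <- sort(unique(weights$right))
  vert <- data.frame(name = c(paste0("L\r", lv), paste0("R\r", rv)),
                     type = rep(c(FALSE, TRUE), c(length(lv), length(rv))))
  ed <- data.frame(from = paste0("L\r", weights$left),
                   to = paste0("R\r", weights$right),
                   weight = weights$weight)
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = vert)
  m <- igraph::max_bipartite_match(g, types = igraph::V(g)$type,
                                   weights = igraph::E(g)$weight,
                                   eps = 1e-10)$matching
  matched <- unname(m[paste0("L\r", lv)])
  ok <- !is.na(matched)
  out <- tibble(left = lv[ok], right = sub("^R\r", "", matched[ok]))
  out <- left_join(out, weights, by = c("left", "right"))
  arrange(out, .data$left, .data$right)
}

#' Reduce the ISBG to the final similarity bipartite graph
#'
#' Duplicates each network-1 vertex (carrying identical edge weights) and
#' runs maximum-weight matching, merging each duplicate's match back onto
#' its original (matching `M1`: network-1 degrees <= 2, network-2 degrees
#' <= 1); repeats symmetrically for network 2 (`M2`); the final graph is
#' the union of `M1` and `M2` with the original ISBG weights. Every vertex
#' of the result has degree at most 3, which shrinks the search space of
#' the one-to-two matching stage while preserving its optima.
#'
#' @param isbg A `similarity_graph` with `stage = "isbg"`.
#' @return A `similarity_graph` with `stage = "simg"`.
#' @export
build_sim_graph <- function(isbg) {
  stopifnot(inherits(isbg, "similarity_graph"))
  if (isbg$stage != "isbg") abort("input must be an ISBG-stage graph")
  e <- isbg$edges
  if (nrow(e) == 0) {
    return(new_similarity_graph(e, isbg$left_nodes, isbg$right_nodes, "simg"))
  }
  dup_tag <- "\rdup"
  left_dup <- bind_rows(e, mutate(e, left = paste0(.data$left, dup_tag)))
  m1 <- hungarian_max_matching(left_dup) |>
    mutate(left = sub(paste0(dup_tag, "$"), "", .data$left)) |>
    distinct(.data$left, .data$right)
  right_dup <- bind_rows(e, mutate(e, right = paste0(.data$right, dup_tag)))
  m2 <- hungarian_max_matching(right_dup) |>
    mutate(right = sub(paste0(dup_tag, "$"), "", .data$right)) |>
    distinct(.data$left, .data$right)
  un <- distinct(bind_rows(m1, m2), .data$left, .data$right) |>
    left_join(e, by = c("left", "right"))
  deg <- c(table(un$left), table(un$right))
  if (length(deg) && max(deg) > 3) {
    abort("internal error: reduced similarity graph has a vertex of degree > 3")
  }
  new_similarity_graph(un, isbg$left_nodes, isbg$right_nodes, "simg")
}

#' Weight of a one-to-two match
#'
#' @param d A list with elements `center` (protein ID), `partners`
#'   (character vector of length 2 from the opposite side) and `side`
#'   (`"left"` if the centre lies in network 1, `"right"` otherwise).
#' @param simg A `similarity_graph`.
#' @return Sum of the two edge weights; error if either edge is absent.
#' @export
dmatch_weight <- function(d, simg) {
  stopifnot(inherits(simg, "similarity_graph"))
  e <- simg$edges
  w <- vapply(d$partners, function(p) {
    hit <- if (identical(d$side, "right")) {
      e$weight[e$left == p & e$right == d$center]
    } else {
      e$weight[e$left == d$center & e$right == p]
    }
    if (length(hit) == 0) {
      abort(sprintf("edge (%s, %s) not present in the similarity graph",
                    d$center, p))
    }
    hit[1]
  }, 0)
  sum(w)
}

#' Greedy extraction of the final alignment
#'
#' From the reduced similarity graph: (i) every edge whose two endpoints
#' both have degree 1 becomes a match immediately; (ii) every degree-2
#' vertex contributes one potential one-to-two match and every degree-3
#' vertex three; (iii) potential one-to-two matches are sorted by weight
#' (descending, deterministic tie-breaks) and accepted greedily, deleting
#' all edges incident to their three vertices; (iv) surviving single edges
#' are then matched one-to-one in descending weight order.
#'
#' @param simg A `similarity_graph` with `stage = "simg"`.
#' @return A [ppi_alignment].
#' @export
greedy_final_alignment <- function(simg) {
  stopifnot(inherits(simg, "similarity_graph"))
  if (simg$stage != "simg") abort("input must be a reduced (simg-stage) graph")
  e <- simg$edges
  empty <- ppi_alignment(tibble(type = character(), g1_members = character(),
                                g2_members = character(), weight = numeric()))
  if (nrow(e) == 0) return(empty)
  degL <- table(e$left); degR <- table(e$right)
  dl <- as.integer(degL[e$left]); dr <- as.integer(degR[e$right])
  alive <- rep(TRUE, nrow(e))
  records <- list()

  # (i) isolated 1-1 edges
  imm <- which(dl == 1 & dr == 1)
  for (i in imm) {
    records[[length(records) + 1L]] <-
      tibble(type = "match", g1_members = e$left[i], g2_members = e$right[i],
             weight = e$weight[i])
    alive[i] <- FALSE
  }

  # (ii) potential one-to-two matches from degree-2/3 vertices of each side
  pot <- list()
  add_pot <- function(center, side, partners, eidx) {
    combs <- utils::combn(seq_along(partners), 2)
    for (k in seq_len(ncol(combs))) {
      sel <- combs[, k]
      p <- partners[sel]
      o <- order(p)
      pot[[length(pot) + 1L]] <<- list(
        center = center, side = side, partners = p[o], eidx = eidx[sel][o],
        weight = sum(e$weight[eidx[sel]]))
    }
  }
  for (v in names(degL)[degL %in% c(2L, 3L)]) {
    idx <- which(e$left == v)
    add_pot(v, "left", e$right[idx], idx)
  }
  for (u in names(degR)[degR %in% c(2L, 3L)]) {
    idx <- which(e$right == u)
    add_pot(u, "right", e$left[idx], idx)
  }

  # (iii) greedy selection, heaviest first
  if (length(pot)) {
    w <- vapply(pot, function(p) p$weight, 0)
    cen <- vapply(pot, function(p) p$center, "")
    sid <- vapply(pot, function(p) p$side, "")
    p1 <- vapply(pot, function(p) p$partners[1], "")
    p2 <- vapply(pot, function(p) p$partners[2], "")
    pot <- pot[order(-w, cen, sid, p1, p2)]
    for (p in pot) {
      if (!all(alive[p$eidx])) next
      if (p$side == "left") {
        g1m <- p$center; g2m <- paste(p$partners, collapse = ",")
        dead <- e$left == p$center | e$right %in% p$partners
      } else {
        g1m <- paste(p$partners, collapse = ","); g2m <- p$center
        dead <- e$right == p$center | e$left %in% p$partners
      }
      records[[length(records) + 1L]] <-
        tibble(type = "dmatch", g1_members = g1m, g2_members = g2m,
               weight = p$weight)
      alive[dead] <- FALSE
    }
  }

  # (iv) leftover single edges, heaviest first, endpoint-disjoint
  left_used <- character(); right_used <- character()
  rest <- which(alive)
  rest <- rest[order(-e$weight[rest], e$left[rest], e$right[rest])]
  for (i in rest) {
    if (e$left[i] %in% left_used || e$right[i] %in% right_used) next
    records[[length(records) + 1L]] <-
      tibble(type = "match", g1_members = e$left[i], g2_members = e$right[i],
             weight = e$weight[i])
    left_used <- c(left_used, e$left[i])
    right_used <- c(right_used, e$right[i])
  }

  if (length(records) == 0) return(empty)
  ppi_alignment(bind_rows(records))
}
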