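#' Generate a synthetic network pair with planted orthology
#'
#' Builds a first network by preferential attachment grown from a small
#' fully connected core (so that genuine hubs exist), then a second network
#' as a relabelled copy with edges independently retained and probabilities
#' jittered, plus a similarity score table concentrated on the planted
#' ortholog pairs with optional low-score noise, and an ortholog-group
#' mapping assigning each planted pair its own group.
#'
#' Edge probabilities of network 1 are uniform on `[0.5, 1]`; network-2
#' probabilities are jittered by up to ±0.1 and clamped to `(0, 1]`. True
#' pairs receive bit scores uniform on `[50, 200]`; spurious pairs appear
#' independently at rate `score_noise_rate` with scores uniform on
#' `[1, 40]` — the two bands are disjoint so that recovery experiments
#' probe the aligner, not the generator. All randomness derives from
#' `seed`; identical arguments give identical output.
#'
#' @param n Number of proteins per network (>= 4).
#' @param hub_fraction Relative size of the fully connected seed core the
#'   preferential attachment grows from (default 0.05).
#' @param edge_keep Probability that each network-1 edge survives in
#'   network 2, in `(0, 1]`.
#' @param score_noise_rate Rate at which non-ortholog cross-network pairs
#'   receive a (low) similarity score, in `[0, 1)`.
#' @param seed Integer random seed.
#' @return An object of class `synthetic_pair`: list with [ppi_network]s
#'   `g1`, `g2`, a [score_table] `scores`, `truth` (tibble `g1`, `g2` of
#'   planted ortholog pairs), `ko` (a [ko_mapping] over both networks) and
#'   `seed`.
#' @export
generate_pair <- function(n, hub_fraction = 0.05, edge_keep = 1,
                          score_noise_rate = 0.05, seed = 1L) {
  if (!is.numeric(n) || n < 4) abort("`n` must be >= 4")
  if (hub_fraction <= 0 || hub_fraction > 0.5) {
    abort("`hub_fraction` must be in (0, 0.5]")
  }
  if (edge_keep <= 0 || edge_keep > 1) abort("`edge_keep` must be in (0, 1]")
  if (score_noise_rate < 0 || score_noise_rate >= 1) {
    abort("`score_noise_rate` must be in [0, 1)")
  }
  n <- as.integer(n)
  withr::with_seed(as.integer(seed), {
    core <- max(2L, as.integer(ceiling(hub_fraction * n)))
    g <- igraph::sample_pa(n, power = 1, m = 2, directed = FALSE,
                           start.graph = igraph::make_full_graph(core))
    ids1 <- sprintf("p%04d", seq_len(n))
    ids2 <- sprintf("q%04d", seq_len(n))
    el <- igraph::as_edgelist(g, names = FALSE)
    e1 <- tibble(node1 = ids1[el[, 1]], node2 = ids1[el[, 2]],
                 prob = runif(nrow(el), 0.5, 1))
    g1 <- ppi_network(e1, nodes = ids1, species = "sp1")
    keep <- runif(nrow(el)) <= edge_keep
    e2 <- tibble(node1 = ids2[el[keep, 1]], node2 = ids2[el[keep, 2]],
                 prob = pmin(1, pmax(1e-6,
                                     e1$prob[keep] + runif(sum(keep), -0.1, 0.1))))
    g2 <- ppi_network(e2, nodes = ids2, species = "sp2")
    truth <- tibble(g1 = ids1, g2 = ids2)
    true_scores <- tibble(id1 = ids1, id2 = ids2,
                          score = runif(n, 50, 200))
    cross <- tidyr::expand_grid(id1 = ids1, id2 = ids2) |>
      filter(.data$id1 != sub("^q", "p", .data$id2))
    noisy <- cross[runif(nrow(cross)) < score_noise_rate, , drop = FALSE]
    noisy$score <- runif(nrow(noisy), 1, 40)
    scores <- score_table(bind_rows(true_scores, noisy))
    ko <- ko_mapping(tibble(
      protein = c(ids1, ids2),
      group = rep(sprintf("K%05d", seq_len(n)), 2)))
    structure(list(g1 = g1, g2 = g2, scores = scores, truth = truth,
                   ko = ko, seed = as.integer(seed)),
              class = "synthetic_pair")
  })
}

#' Self-alignment validation fixture
#'
#' A [generate_pair()] call with `edge_keep = 1` and a 5% score-noise
#' rate: network 2 is an isomorphic relabelled copy, so the planted
#' mapping is the unambiguous optimum and recovery can be measured.
#'
#' @param n Number of proteins per network (>= 4).
#' @param seed Integer random seed.
#' @return A `synthetic_pair`.
#' @export
self_alignment_fixture <- function(n, seed = 1L) {
  generate_pair(n, edge_keep = 1, score_noise_rate = 0.05, seed = seed)
}

#' Write the five files of a synthetic pair
#'
#' Writes `g1.tsv`, `g2.tsv` (edge lists), `scores.tsv`, `truth.tsv` and
#' `ko.tsv` into a directory.
#'
#' @param pair A `synthetic_pair`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "synthetic_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_network(pair$g1, file.path(dir, "g1.tsv"))
  write_network(pair$g2, file.path(dir, "g2.tsv"))
  sc <- as.data.frame(pair$scores$pairs)
  sc$score <- format(sc$score, digits = 15, trim = TRUE, scientific = FALSE)
  write.table(sc, file.path(dir, "scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(pair$truth), file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(as.data.frame(pair$ko$mapping), file.path(dir, "ko.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Fraction of planted ortholog pairs recovered by an alignment
#'
#' A planted pair counts as recovered when its two proteins share an
#' alignment record (as a match, or together inside a one-to-two match).
#'
#' @param alignment A [ppi_alignment].
#' @param truth Tibble with columns `g1`, `g2` (planted pairs).
#' @return Fraction in `[0, 1]`.
#' @export
recovery_rate <- function(alignment, truth) {
  if (nrow(truth) == 0) abort("`truth` is empty")
  pairs <- alignment_pairs(alignment)
  hit <- pair_key(truth$g1, truth$g2) %in% pair_key(pairs$g1, pairs$g2)
  mean(hit)
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("<synthetic_pair> n=%d, seed=%d; |E1|=%d, |E2|=%d, %d scored pairs\n",
              nrow(x$truth), x$seed, nrow(x$g1$edges), nrow(x$g2$edges),
              nrow(x$scores$pairs)))
  invisible(x)
}
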