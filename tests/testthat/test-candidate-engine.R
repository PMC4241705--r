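test_that("seed collections hold one size-1 candidate per scored partner", {
  sc <- scores_from("b1 b2 50", "b1 c2 10", "c1 c2 20")
  expect_message(seeds <- seed_collections(c("b1", "c1", "x"), sc),
                 "no scored partner")
  expect_length(seeds, 2)
  cc_b <- seeds[[1]]
  expect_equal(cc_b$g1_vertices, "b1")
  expect_length(cc_b$candidates, 2)
  # node score of a seed is its bit score; best partner first
  expect_equal(cc_b$candidates[[1]]$ns, 50)
  expect_equal(unname(cc_b$candidates[[1]]$mapping), "b2")
})

test_that("collection distance follows the reciprocal-length formula", {
  g <- net_from(sprintf("a b %.10f", exp(-1)), "b c 0.5")
  cc <- function(v) pinalign:::new_collection(v, list())
  # single connecting edge of length 1: (1+1)/1 = 2
  expect_equal(collection_distance(cc("a"), cc("b"), g), 2, tolerance = 1e-9)
  # no connecting edge
  expect_equal(collection_distance(cc("a"), cc("c"), g), Inf)
  # probability-1 edge has zero length: distance 0
  g1 <- net_from("a b 1")
  expect_equal(collection_distance(cc("a"), cc("b"), g1), 0)
  expect_error(collection_distance(cc("a"), cc("a"), g), "disjoint")
})

test_that("combining pattern merges closest pairs first with ID tie-breaks", {
  g <- net_from("a b 0.5", "b c 0.5")
  sc <- scores_from("a x 1", "b y 1", "c z 1")
  seeds <- seed_collections(c("a", "b", "c"), sc)
  tree <- build_combining_pattern(seeds, g)
  # d({a},{b}) == d({b},{c}): tie-break picks {a},{b}; root adds {c}
  expect_false(tree$leaf)
  expect_equal(tree$members, c("a", "b", "c"))
  first <- if (length(tree$left$members) == 2) tree$left else tree$right
  expect_equal(first$members, c("a", "b"))

  # degenerate patterns
  expect_equal(build_combining_pattern(seeds[1], g)$members, "a")
  two <- build_combining_pattern(seeds[1:2], g)
  expect_false(two$leaf)
  expect_equal(two$members, c("a", "b"))
})

test_that("merging keeps only injective pairings and adds node scores", {
  g1 <- net_from("b c 0.5")
  g2 <- net_from("b2 c2 0.5")
  sc <- scores_from("b b2 50", "b c2 10", "c c2 20")
  seeds <- seed_collections(c("b", "c"), sc)
  merged <- merge_collections(seeds[[1]], seeds[[2]], g1, g2, sc)
  # (b->c2, c->c2) conflicts; only (b->b2, c->c2) survives
  expect_length(merged$candidates, 1)
  m <- merged$candidates[[1]]
  expect_equal(m$mapping, c(b = "b2", c = "c2"))
  expect_equal(m$ns, 50 + 20)
  expect_error(merge_collections(seeds[[1]], seeds[[1]], g1, g2, sc),
               "disjoint")
})

test_that("fully conflicting merges adopt the higher-scoring parent", {
  g1 <- net_from("a b 0.5")
  g2 <- net_from("x y 0.5")
  sc <- scores_from("a x 50", "b x 10")
  seeds <- seed_collections(c("a", "b"), sc)
  expect_message(kept <- merge_collections(seeds[[1]], seeds[[2]], g1, g2, sc),
                 "conflict")
  expect_equal(kept$g1_vertices, "a")
  expect_equal(kept$candidates[[1]]$ns, 50)
})

test_that("node score sums bit scores over the mapping", {
  sc <- scores_from("a x 60", "b y 40")
  expect_equal(node_score(c(a = "x"), sc), 60)
  expect_equal(node_score(c(a = "x", b = "y"), sc), 100)
  expect_equal(node_score(setNames(character(), character()), sc), 0)
})

test_that("conserved edge counts match the definition", {
  g1 <- net_from("a b 0.9")
  g2 <- net_from("ap bp 0.8")
  cand <- c(a = "ap", b = "bp")
  expect_equal(conserved_edge_count(cand, "a", g1, g2), 1)
  g2miss <- net_from("ap cp 0.8", nodes = "bp")
  expect_equal(conserved_edge_count(cand, "a", g1, g2miss), 0)
  # fully conserved triangle: two conserved edges at every vertex
  t1 <- net_from("a b 0.9", "b c 0.9", "a c 0.9")
  t2 <- net_from("ap bp 0.9", "bp cp 0.9", "ap cp 0.9")
  tri <- c(a = "ap", b = "bp", c = "cp")
  for (v in c("a", "b", "c")) {
    expect_equal(conserved_edge_count(tri, v, t1, t2), 2)
  }
  expect_error(conserved_edge_count(cand, "z", g1, g2), "not in the candidate")
})

test_that("structural score matches direct substitution and the oracle", {
  # one conserved edge with p1 = p2 = 1: both ordered pairs give 1
  g1 <- net_from("a b 1")
  g2 <- net_from("ap bp 1")
  cand <- c(a = "ap", b = "bp")
  for (alpha in c(0, 0.3, 1)) {
    expect_equal(structural_score(cand, g1, g2, alpha), 2)
  }
  # alpha = 1 drops the probability factor
  g1w <- net_from("a b 0.5")
  g2w <- net_from("ap bp 0.25")
  expect_equal(structural_score(cand, g1w, g2w, alpha = 1), 2)
  expect_equal(structural_score(cand, g1w, g2w, alpha = 0), 2 * 0.5 * 0.25)
  # no conserved edges -> 0
  g2n <- net_from("ap cp 0.5", nodes = "bp")
  expect_equal(structural_score(cand, g1w, g2n, alpha = 0.5), 0)

  set.seed(7)
  for (rep in 1:20) {
    n1 <- random_net(5, 0.6, prefix = "v")
    n2 <- random_net(6, 0.6, prefix = "u")
    size <- sample(2:4, 1)
    mp <- setNames(sample(n2$nodes, size), sample(n1$nodes, size))
    alpha <- runif(1)
    expect_equal(structural_score(mp, n1, n2, alpha),
                 oracle_structural(mp, n1, n2, alpha), tolerance = 1e-10)
  }
})

test_that("structural score is invariant under vertex relabelling", {
  set.seed(11)
  n1 <- random_net(5, 0.7, prefix = "v")
  n2 <- random_net(5, 0.7, prefix = "u")
  mp <- setNames(sample(n2$nodes, 4), sample(n1$nodes, 4))
  base <- structural_score(mp, n1, n2, 0.4)
  # relabel network-1 vertices
  relab <- setNames(paste0("w", seq_along(n1$nodes)), n1$nodes)
  n1r <- ppi_network(tibble::tibble(node1 = relab[n1$edges$node1],
                                    node2 = relab[n1$edges$node2],
                                    prob = n1$edges$prob),
                     nodes = unname(relab))
  mpr <- setNames(unname(mp), relab[names(mp)])
  expect_equal(structural_score(mpr, n1r, n2, 0.4), base, tolerance = 1e-12)
})

test_that("pruning sorts by node score, then structural, then mapping", {
  mk <- function(mapping, ns, ss) list(mapping = mapping, ns = ns, ss = ss)
  cc <- pinalign:::new_collection("a", list(
    mk(c(a = "x"), 10, 0), mk(c(a = "y"), 20, 0)))
  kept <- prune_collection(cc, scoring_params(beam_width = 1))
  expect_equal(unname(kept$candidates[[1]]$mapping), "y")

  cc2 <- pinalign:::new_collection("a", list(
    mk(c(a = "x"), 10, 0), mk(c(a = "y"), 10, 2)))
  kept2 <- prune_collection(cc2, scoring_params(beam_width = 1))
  expect_equal(unname(kept2$candidates[[1]]$mapping), "y")

  # within beam: unchanged cardinality
  expect_length(prune_collection(cc2, scoring_params(beam_width = 5))$candidates, 2)
})

test_that("aligning a cluster of identical networks recovers the identity", {
  g <- net_from("a b 0.8", "b c 0.7")
  sc <- scores_from("a a 100", "b b 100", "c c 100",
                    "a b 5", "b c 5", "c a 5")
  cc <- align_hub_cluster(c("a", "b", "c"), g, g, sc)
  expect_equal(cc$g1_vertices, c("a", "b", "c"))
  top <- cc$candidates[[1]]
  expect_equal(top$mapping, c(a = "a", b = "b", c = "c"))
  # 1-node cluster degenerates to its pruned seed collection
  one <- align_hub_cluster("a", g, g, sc)
  expect_equal(one$g1_vertices, "a")
  expect_equal(unname(one$candidates[[1]]$mapping), "a")
})

test_that("node-score additivity holds under merging of disjoint candidates", {
  set.seed(13)
  ids1 <- sprintf("v%02d", 1:8); ids2 <- sprintf("u%02d", 1:10)
  sc <- random_scores(ids1, ids2, density = 1)
  for (rep in 1:200) {
    v <- sample(ids1, 4)
    u <- sample(ids2, 4)
    c1 <- setNames(u[1:2], v[1:2])
    c2 <- setNames(u[3:4], v[3:4])
    expect_identical(node_score(c(c1, c2), sc),
                     node_score(c1, sc) + node_score(c2, sc))
  }
})

test_that("adding a conserved edge never decreases the structural score", {
  set.seed(17)
  for (rep in 1:50) {
    n1 <- random_net(6, 0.5, prefix = "v")
    n2 <- random_net(6, 0.5, prefix = "u")
    size <- sample(3:5, 1)
    mp <- setNames(sample(n2$nodes, size), sample(n1$nodes, size))
    alpha <- runif(1)
    base <- structural_score(mp, n1, n2, alpha)
    # add one currently unconserved in-candidate edge to both networks
    V <- names(mp)
    pairs <- t(utils::combn(V, 2))
    P1 <- pinalign:::prob_matrix(n1); P2 <- pinalign:::prob_matrix(n2)
    open <- which(!(P1[pairs] > 0 & P2[cbind(mp[pairs[, 1]], mp[pairs[, 2]])] > 0))
    if (length(open) == 0) next
    k <- sample(open, 1)
    v1 <- pairs[k, 1]; v2 <- pairs[k, 2]
    add_edge <- function(net, a, b) {
      if (pinalign:::prob_matrix(net)[a, b] > 0) return(net)
      ppi_network(dplyr::bind_rows(net$edges,
                                   tibble::tibble(node1 = a, node2 = b,
                                                  prob = runif(1, 0.5, 1))),
                  nodes = net$nodes)
    }
    n1b <- add_edge(n1, v1, v2)
    n2b <- add_edge(n2, mp[[v1]], mp[[v2]])
    expect_gte(structural_score(mp, n1b, n2b, alpha) - base, -1e-12)
  }
})
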