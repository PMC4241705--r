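mk_cc <- function(vertices, mappings) {
  pinalign:::new_collection(vertices, lapply(mappings, function(m) {
    list(mapping = m[order(names(m))], ns = 0, ss = 0)
  }))
}

test_that("candidate support counts supporting candidates per pair", {
  ccs <- list(mk_cc(c("a1", "b1"), list(c(a1 = "a2", b1 = "b2"),
                                        c(a1 = "c2", b1 = "b2"))))
  sup <- collect_support(ccs)
  n <- setNames(sup$pairs$n_support, paste(sup$pairs$left, sup$pairs$right))
  expect_equal(n[["b1 b2"]], 2L)
  expect_equal(n[["a1 a2"]], 1L)
  expect_equal(n[["a1 c2"]], 1L)
  expect_false("a1 b2" %in% names(n))
})

test_that("node and neighbourhood similarities follow their definitions", {
  g1 <- net_from("a b 0.8")
  sc <- scores_from("a ap 60", "b bp 40")
  ccs <- list(mk_cc(c("a", "b"), list(c(a = "ap", b = "bp"))))
  sup <- collect_support(ccs)
  expect_equal(node_sim("a", "ap", sup, sc), 60)
  # neighbour b of a lies inside the candidate: contributes score(b, bp)
  expect_equal(neighborhoods_sim("a", "ap", sup, g1, sc), 40)
  # no in-candidate neighbours -> 0
  lone <- net_from("a z 0.5", nodes = "b")
  expect_equal(neighborhoods_sim("a", "ap", sup, lone, sc), 0)
  # two supporting candidates each contribute
  ccs2 <- list(mk_cc(c("a", "b"), list(c(a = "ap", b = "bp"))),
               mk_cc(c("a", "b"), list(c(a = "ap", b = "bp"))))
  sup2 <- collect_support(ccs2)
  expect_equal(node_sim("a", "ap", sup2, sc), 120)
  expect_equal(neighborhoods_sim("a", "ap", sup2, g1, sc), 80)
  expect_error(node_sim("a", "zz", sup, sc), "no supporting candidate")
})

test_that("ISBG weights amplify support and average neighbourhoods", {
  g1 <- net_from("a b 0.8")
  g2 <- net_from("ap bp 0.8")
  sc <- scores_from("a ap 60", "b bp 40")
  # two identical supporting candidates: |C| = 2
  ccs <- list(mk_cc(c("a", "b"), list(c(a = "ap", b = "bp"))),
              mk_cc(c("a", "b"), list(c(a = "ap", b = "bp"))))
  isbg <- build_isbg(ccs, g1, g2, sc)
  w <- setNames(isbg$edges$weight, paste(isbg$edges$left, isbg$edges$right))
  # node_sim 120 plus mean neighbourhood (80 / 2)
  expect_equal(w[["a ap"]], 120 + 40)
  # single isolated-vertex candidate: weight is the plain bit score
  lone <- list(mk_cc("a", list(c(a = "ap"))))
  isbg2 <- build_isbg(lone, net_from("a b 0.5"), g2, sc)
  expect_equal(isbg2$edges$weight, 60)
  # unsupported pairs carry no edge
  expect_false("b bp" %in% paste(isbg2$edges$left, isbg2$edges$right))
  expect_equal(isbg2$stage, "isbg")
})

test_that("bipartite matching is maximum-weight and handles degenerate input", {
  W <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("x", "y", "z")))
  diag(W) <- 10
  m <- hungarian_max_matching(W)
  expect_equal(m$right[match(c("a", "b", "c"), m$left)], c("x", "y", "z"))
  expect_equal(sum(m$weight), 30)

  m2 <- hungarian_max_matching(tibble::tibble(
    left = c("a", "a"), right = c("x", "y"), weight = c(5, 7)))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$right, "y")

  expect_equal(nrow(hungarian_max_matching(
    tibble::tibble(left = character(), right = character(),
                   weight = numeric()))), 0)
})

test_that("matching total equals the exhaustive optimum on random matrices", {
  set.seed(5)
  for (rep in 1:40) {
    nr <- sample(1:6, 1); nc <- sample(1:6, 1)
    W <- matrix(sample(0:30, nr * nc, replace = TRUE), nr, nc,
                dimnames = list(sprintf("r%d", 1:nr), sprintf("c%d", 1:nc)))
    got <- sum(hungarian_max_matching(W)$weight)
    expect_equal(got, oracle_matching_weight(W))
  }
})

test_that("the reduced similarity graph keeps matching structure", {
  # already a perfect identity-dominant matching: reduction returns it
  e <- tibble::tibble(left = c("a", "b"), right = c("x", "y"),
                      weight = c(10, 9))
  simg <- build_sim_graph(similarity_graph(e, "isbg"))
  expect_equal(simg$stage, "simg")
  expect_equal(dplyr::arrange(simg$edges, left), dplyr::arrange(e, left))

  # one left vertex, two partners: duplication keeps both edges
  e2 <- tibble::tibble(left = "a", right = c("x", "y"), weight = c(5, 7))
  simg2 <- build_sim_graph(similarity_graph(e2, "isbg"))
  expect_equal(nrow(simg2$edges), 2)

  # empty input
  e0 <- tibble::tibble(left = character(), right = character(),
                       weight = numeric())
  expect_equal(nrow(build_sim_graph(similarity_graph(e0, "isbg"))$edges), 0)
  expect_error(build_sim_graph(simg2), "ISBG")
})

test_that("every vertex of a reduced graph has degree at most three", {
  set.seed(23)
  for (rep in 1:30) {
    nl <- sample(2:5, 1); nr <- sample(2:5, 1)
    grid <- expand.grid(left = sprintf("l%d", 1:nl),
                        right = sprintf("r%d", 1:nr),
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < 0.6, , drop = FALSE]
    if (nrow(grid) == 0) next
    grid$weight <- runif(nrow(grid), 0.5, 10)
    simg <- build_sim_graph(similarity_graph(grid, "isbg"))
    if (nrow(simg$edges) == 0) next
    deg <- c(table(simg$edges$left), table(simg$edges$right))
    expect_lte(max(deg), 3)
  }
})

test_that("dmatch weights sum their two edges and require both", {
  simg <- similarity_graph(tibble::tibble(
    left = c("a", "a"), right = c("x", "y"), weight = c(5, 7)), "simg")
  expect_equal(dmatch_weight(list(center = "a", partners = c("x", "y"),
                                  side = "left"), simg), 12)
  expect_error(dmatch_weight(list(center = "a", partners = c("x", "z"),
                                  side = "left"), simg), "not present")
  rsimg <- similarity_graph(tibble::tibble(
    left = c("a", "b"), right = c("x", "x"), weight = c(3, 3)), "simg")
  expect_equal(dmatch_weight(list(center = "x", partners = c("a", "b"),
                                  side = "right"), rsimg), 6)
})

test_that("greedy extraction applies the degree rules", {
  # single isolated edge: a match
  s1 <- similarity_graph(tibble::tibble(left = "a", right = "x", weight = 5),
                         "simg")
  a1 <- greedy_final_alignment(s1)
  expect_equal(a1$type, "match")
  expect_equal(a1$weight, 5)

  # path x - a - y: one dmatch through the centre
  s2 <- similarity_graph(tibble::tibble(
    left = c("a", "a"), right = c("x", "y"), weight = c(5, 7)), "simg")
  a2 <- greedy_final_alignment(s2)
  expect_equal(a2$type, "dmatch")
  expect_equal(a2$g2_members, "x,y")
  expect_equal(a2$weight, 12)

  # degree-3 centre: heaviest pair wins, third partner left out
  s3 <- similarity_graph(tibble::tibble(
    left = "a", right = c("x", "y", "z"), weight = c(5, 7, 2)), "simg")
  a3 <- greedy_final_alignment(s3)
  expect_equal(nrow(a3), 1)
  expect_equal(a3$g2_members, "x,y")
  expect_equal(a3$weight, 12)
})

test_that("greedy output is consistent and never beats the exhaustive optimum", {
  set.seed(29)
  for (rep in 1:20) {
    nl <- sample(2:5, 1); nr <- sample(2:5, 1)
    grid <- expand.grid(left = sprintf("l%d", 1:nl),
                        right = sprintf("r%d", 1:nr),
                        stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < 0.5, , drop = FALSE]
    if (nrow(grid) == 0) next
    grid$weight <- runif(nrow(grid), 0.5, 10)
    simg <- build_sim_graph(similarity_graph(grid, "isbg"))
    al <- greedy_final_alignment(simg)
    if (nrow(al) == 0) next
    # no protein reused across records (validated by the constructor) and
    # record weights equal the sum of their member edge weights
    wlookup <- setNames(simg$edges$weight,
                        paste(simg$edges$left, simg$edges$right))
    pr <- alignment_pairs(al)
    for (r in seq_len(nrow(al))) {
      members <- pr[pr$record == r, ]
      expect_equal(sum(wlookup[paste(members$g1, members$g2)]), al$weight[r])
    }
    expect_lte(sum(al$weight),
               oracle_dmatching_weight(as.data.frame(simg$edges)) + 1e-9)
  }
})
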