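make_net <- function(edges, nodes = NULL) {
  nodes <- nodes %||% sort(unique(c(edges$from, edges$to)))
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = data.frame(name = nodes))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("shortest paths minimize inverse-weight cost deterministically", {
  tri <- make_net(data.frame(from = c("A", "A", "C"),
                             to = c("B", "C", "B"),
                             weight = c(1, 10, 10)))
  # direct A-B costs 1; A-C-B costs 0.1 + 0.1 = 0.2
  expect_equal(shortest_path(tri, "A", "B"), c("A", "C", "B"))
  expect_equal(shortest_path(tri, "A", "A"), "A")

  two <- make_net(data.frame(from = "A", to = "B", weight = 1),
                  nodes = c("A", "B", "Z"))
  expect_error(shortest_path(two, "A", "Z"),
               class = "fibropath_no_path")
})

test_that("shortest paths equal brute-force enumeration on small graphs", {
  set.seed(31)
  for (rep in 1:25) {
    gr <- random_weighted_graph(sample(4:6, 1), p_edge = 0.5)
    g <- edges_to_igraph(gr)
    ends <- sample(gr$nodes, 2)
    want <- oracle_shortest_path(gr$edges, gr$nodes, ends[1], ends[2])
    got <- shortest_path(g, ends[1], ends[2])
    expect_equal(got, want)
  }
})

test_that("guided target selection follows strength and membership rules", {
  gm <- igraph::graph_from_data_frame(
    data.frame(from = c("g1", "g2"), to = c("x1", "x2"),
               weight = c(3, 1)), directed = FALSE)
  membership <- list(g1 = "P1", g2 = "P2")
  set.seed(5)
  draws <- select_target_guided(gm, membership, n = 10000)
  p1 <- mean(draws == "P1")
  # strengths 3:1; binomial 3 sigma around 0.75 at n = 1e4 is +/- 0.013
  expect_lt(abs(p1 - 0.75), 0.015)

  # single gene, single pathway: always that pathway
  solo <- igraph::make_graph(c("g1", "g2"), directed = FALSE)
  expect_equal(unique(select_target_guided(solo, list(g1 = "PX"), n = 50)),
               "PX")

  # two memberships split evenly
  set.seed(6)
  halves <- select_target_guided(solo, list(g1 = c("PA", "PB")), n = 10000)
  expect_lt(abs(mean(halves == "PA") - 0.5), 0.02)

  expect_error(select_target_guided(solo, list(zz = "PX")), "no gene")
})

test_that("walks are reproducible, conservative and count visits correctly", {
  pw <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g3", "g4"))
  net <- build_pathway_network(pw)
  one <- run_pathwalks(net, n_iterations = 1, mode = "random", seed = 2)
  # one iteration records at least the target visit; origin not counted
  expect_gte(one$total_times_walked, 1)
  expect_equal(sum(one$times_walked), one$total_times_walked)

  a <- run_pathwalks(net, n_iterations = 500, mode = "random", seed = 9)
  b <- run_pathwalks(net, n_iterations = 500, mode = "random", seed = 9)
  expect_identical(a, b)
  expect_equal(sum(a$times_walked / a$total_times_walked), 1)
})

test_that("uniform guidance on a cycle gives uniform visit frequencies", {
  k <- 8
  ids <- sprintf("C%d", seq_len(k))
  pw <- lapply(seq_len(k), function(i)
    c(sprintf("s%d", i), sprintf("s%d", i %% k + 1)))
  names(pw) <- ids
  net <- build_pathway_network(pw)  # ring, all edge weights 1
  wc <- run_pathwalks(net, n_iterations = 2e4, mode = "random", seed = 3)
  freq <- wc$times_walked / wc$total_times_walked
  expect_lt(max(abs(freq - 1 / k)), 0.02)  # vertex-transitive symmetry
})

test_that("planted gene-map guidance elevates the planted pathway", {
  pw <- list(P1 = c("a1", "a2"), P2 = c("a2", "b1"), P3 = c("b1", "c1"),
             P4 = c("c1", "d1"), P5 = c("d1", "a1"))
  net <- build_pathway_network(pw)
  gm <- igraph::graph_from_data_frame(
    data.frame(from = "a1", to = "a2", weight = 1), directed = FALSE)
  membership <- list(a1 = "P1", a2 = "P1")
  g <- run_pathwalks(net, gm, membership, n_iterations = 5000,
                     mode = "guided", seed = 4)
  r <- run_pathwalks(net, n_iterations = 5000, mode = "random", seed = 4)
  f_g <- g$times_walked / g$total_times_walked
  f_r <- r$times_walked / r$total_times_walked
  expect_gt(f_g["P1"], f_r["P1"])
})

test_that("random-mode visits correlate with topology scores", {
  set.seed(41)
  b <- generate_bundle(seed = 41, n_genes = 500, n_pathways = 25,
                       n_planted = 2, n_drugs = 12, n_failed = 3)
  net <- build_pathway_network(b$pathways)
  wc <- run_pathwalks(net, n_iterations = 2e4, mode = "random", seed = 41)
  tp <- topology_profile(net)
  score <- tp$betweenness + tp$strength
  rho <- cor(as.numeric(wc$times_walked[tp$pathway]), score,
             method = "spearman")
  expect_gt(rho, 0)
})

test_that("top pathways use ceiling counts and id tie-breaks", {
  wc <- structure(list(times_walked = stats::setNames(rep(5L, 10),
                                                      sprintf("P%02d", 10:1)),
                       total_times_walked = 50L),
                  class = "walk_counts")
  expect_equal(top_pathways(wc, frac = 0.25),
               c("P01", "P02", "P03"))  # all tied: lexical order

  wc2 <- structure(list(times_walked = c(A = 10L, B = 5L, C = 1L, D = 0L),
                        total_times_walked = 16L),
                   class = "walk_counts")
  expect_equal(top_pathways(wc2, frac = 0.5), c("A", "B"))
  expect_length(top_pathways(wc2, frac = 0.05), 1)
})

test_that("walks are confined to the largest component and report exclusions", {
  pw <- list(A = c("g1", "g2"), B = c("g2", "g3"), C = c("g3", "g1"),
             lone1 = c("z1", "z2"), lone2 = c("z2", "z3"))
  net <- build_pathway_network(pw)
  wc <- run_pathwalks(net, n_iterations = 200, mode = "random", seed = 5)
  expect_setequal(wc$excluded, c("lone1", "lone2"))
  expect_equal(unname(wc$times_walked[c("lone1", "lone2")]), c(0L, 0L))
  expect_setequal(names(wc$times_walked), names(pw))
})

test_that("pathway membership inversion is faithful", {
  mem <- membership_from_pathways(list(P1 = c("a", "b"), P2 = c("b", "c")))
  expect_equal(sort(mem$b), c("P1", "P2"))
  expect_equal(mem$a, "P1")
  expect_equal(mem$c, "P2")
})
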