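test_that("degree distribution matches direct counts", {
  dd <- degree_distribution(star_net(5))
  expect_equal(dd$counts, c("1" = 5L, "5" = 1L))
  expect_equal(sum(dd$counts), dd$n_nodes)
  empty <- build_network(data.frame(protein_a = character(),
                                    protein_b = character(),
                                    interaction_id = character()))
  expect_equal(length(degree_distribution(empty)$counts), 0)
  # on the DIP fixture (loops off) the hub is rvs167
  net <- dip_net()
  g <- as_igraph(net, loops = FALSE)
  deg <- igraph::degree(g)
  expect_equal(names(which.max(deg)), "rvs167")
  dd1 <- degree_distribution(net, count_self_loops = FALSE)
  expect_equal(max(as.integer(names(dd1$counts))), max(deg))
  # a self-loop adds 2 to the degree when counted
  loopnet <- build_network(data.frame(protein_a = c("a", "a"),
                                      protein_b = c("a", "b"),
                                      interaction_id = c("L1", "L2")))
  expect_equal(names(degree_distribution(loopnet, TRUE)$counts), c("1", "3"))
})

test_that("scale-free decision separates the DIP fixture from BA graphs", {
  fit <- is_scale_free(dip_net())
  expect_false(fit$decided_scale_free)
  expect_match(fit$rationale, "not scale-free")
  # single-valued degree distribution: no tail to fit
  expect_false(is_scale_free(complete_net(25))$decided_scale_free)
  # preferential attachment at scale is recognised
  ba <- generate_ba_graph(2000, 2, seed = 7)
  expect_true(is_scale_free(ba)$decided_scale_free)
  # below the criterion's minimum size the decision is "not assessable"
  small <- is_scale_free(triangle_net())
  expect_true(is.na(small$decided_scale_free))
  # determinism
  expect_identical(is_scale_free(ba)$gamma, is_scale_free(ba)$gamma)
})

test_that("edge betweenness agrees with the path-enumeration oracle", {
  p <- path_net(c("a", "b", "c"))
  sc <- edge_betweenness_scores(p)
  expect_equal(sc$score[sc$a == "a"], 2)
  expect_equal(sc$score[sc$b == "c"], 2)
  tri <- edge_betweenness_scores(triangle_net())
  expect_true(all(tri$score == tri$score[1]))
  for (seed in 1:6) {
    net <- random_net(5 + (seed %% 4), 0.45, seed)
    got <- edge_betweenness_scores(net)
    want <- oracle_edge_betweenness(net)
    expect_equal(stats::setNames(got$score, paste(got$a, got$b, sep = "\t")),
                 want[paste(got$a, got$b, sep = "\t")], tolerance = 1e-9)
  }
})

test_that("total betweenness equals the sum of pairwise shortest-path lengths", {
  for (seed in 7:10) {
    net <- random_net(7, 0.4, seed)
    g <- as_igraph(net, loops = FALSE)
    d <- igraph::distances(g)
    d <- d[upper.tri(d)]
    expect_equal(sum(edge_betweenness_scores(net)$score),
                 sum(d[is.finite(d)]), tolerance = 1e-9)
  }
})

test_that("clustering coefficient matches the triple-counting oracle", {
  expect_equal(unname(clustering_coefficient(triangle_net())), rep(1, 3))
  star <- clustering_coefficient(star_net(4))
  expect_equal(unname(star["hub"]), 0)
  for (seed in 1:5) {
    net <- random_net(5, 0.5, seed)
    expect_equal(clustering_coefficient(net),
                 oracle_clustering_coefficient(net), tolerance = 1e-12)
  }
  cc <- clustering_coefficient(dip_net())
  expect_true(all(cc >= 0 & cc <= 1))
})

test_that("combined score is the geometric mean of normalised measures", {
  # recompute by hand on a fixed 6-node fixture
  net <- random_net(6, 0.5, 42)
  bt <- edge_betweenness_scores(net)
  cc <- clustering_coefficient(net)
  n01 <- function(x) if (diff(range(x)) == 0) rep(0, length(x)) else
    (x - min(x)) / diff(range(x))
  want <- sqrt(n01(bt$score) * n01(unname((cc[bt$a] + cc[bt$b]) / 2)))
  got <- combined_topological_score(net)
  expect_equal(got$score, want, tolerance = 1e-12)
  expect_equal(attr(got, "score_kind"), "combined")
  # an edge with zero on either measure is zero combined
  expect_true(all(got$score[bt$score == min(bt$score)] == 0))
})

test_that("k-core matches the peeling oracle and is bounded by max degree", {
  k4 <- kcore_number(complete_net(4))
  expect_equal(k4$k, 3)
  expect_equal(length(k4$members), 4)
  expect_equal(kcore_number(path_net(letters[1:5]))$k, 1)
  expect_equal(kcore_number(build_network(data.frame(
    protein_a = character(), protein_b = character(),
    interaction_id = character())))$k, 0)
  for (seed in 1:6) {
    net <- random_net(6 + (seed %% 3), 0.4, seed)
    got <- kcore_number(net)
    want <- oracle_kcore(net)
    expect_equal(got$k, want$k)
    expect_equal(got$members, want$members)
    expect_lte(got$k, max(igraph::degree(as_igraph(net))))
  }
})
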