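test_that("the packaged DIP table parses to 90 records over 34 proteins", {
  f <- system.file("extdata", "dip_yeast_subnet.tsv", package = "complexpert")
  rec <- parse_interaction_table(f)
  expect_equal(nrow(rec), 90)
  expect_equal(length(unique(c(rec$protein_a, rec$protein_b))), 34)
  expect_equal(length(unique(rec$interaction_id)), 90)
})

test_that("parser handles degenerate and dialect variations", {
  expect_equal(nrow(parse_interaction_table("")), 0)
  rec <- parse_interaction_table("x\tx\tID1")
  expect_equal(rec$protein_a, "x")
  expect_equal(rec$protein_b, "x")
  # leading row-number column and header are auto-detected; ids lower-cased
  txt <- "#\tProtein_A\tProtein_B\tPPI_ID\n1\tAct1\tAbp1\tDIP-1\n2\tApp1 \tabp1\tDIP-2"
  rec <- parse_interaction_table(txt)
  expect_equal(rec$protein_a, c("act1", "app1"))
  expect_equal(rec$protein_b, c("abp1", "abp1"))
  expect_error(parse_interaction_table("a\tb\tID1\nbroken_row"), "line 2")
  expect_error(parse_interaction_table("a\tb\tID1\nc\td\tID1"), "duplicate")
})

test_that("build_network merges duplicate pairs and applies the loop policy", {
  net <- dip_net()
  expect_equal(n_nodes(net), 34)
  expect_equal(n_edges(net), 90)
  expect_equal(n_edges(dip_net(self_loop_policy = "drop")), 80)
  # (a,b) and (b,a) merge into one edge with both ids
  rec <- data.frame(protein_a = c("a", "b"), protein_b = c("b", "a"),
                    interaction_id = c("I1", "I2"), stringsAsFactors = FALSE)
  m <- build_network(rec)
  expect_equal(n_edges(m), 1)
  expect_setequal(m$edges$ids[[1]], c("I1", "I2"))
  expect_equal(n_nodes(build_network(rec[0, ])), 0)
})

test_that("node set always equals the distinct identifiers of the records", {
  for (seed in 1:5) {
    net <- random_net(8, 0.4, seed)
    rec <- parse_interaction_table(export_network(net, "tsv"))
    rebuilt <- build_network(rec)
    expect_setequal(rebuilt$nodes, unique(c(rec$protein_a, rec$protein_b)))
  }
})

test_that("core annotation yields the expected fraction and warns on unknown ids", {
  net <- dip_net()
  expect_true(is.na(core_fraction(net)))  # unknown until a list is supplied
  net67 <- annotate_core(net, dip_core_ids())
  expect_equal(sum(net67$edges$core), 67)
  expect_equal(core_fraction(net67), 67 / 90, tolerance = 1e-12)
  net0 <- annotate_core(net, character())
  expect_equal(core_fraction(net0), 0)
  all_ids <- unlist(net$edges$ids)
  expect_equal(core_fraction(annotate_core(net, all_ids)), 1)
  expect_warning(annotate_core(net, c(all_ids[1], "DIP-NOPE")), "not present")
})

test_that("diff_networks reports exact deltas and swaps on argument reversal", {
  net <- annotate_core(dip_net(), dip_core_ids())
  d0 <- diff_networks(net, net)
  expect_equal(nrow(d0$added_edges), 0)
  expect_equal(nrow(d0$removed_edges), 0)
  aug <- apply_additions(net, data.frame(a = "aip1", b = "app1"))
  d <- diff_networks(net, aug)
  expect_equal(nrow(d$added_edges), 1)
  expect_equal(nrow(d$removed_edges), 0)
  rev <- diff_networks(aug, net)
  expect_equal(rev$added_edges, d$removed_edges)
  expect_equal(rev$removed_edges, d$added_edges)
  # removing 3 edges of which 2 core is counted correctly
  core_edges <- net$edges[net$edges$core, c("a", "b")][1:2, ]
  noncore_edge <- net$edges[!net$edges$core, c("a", "b")][1, ]
  cut <- remove_edges(net, rbind(core_edges, noncore_edge))
  expect_equal(diff_networks(net, cut)$removed_core_count, 2)
})

test_that("TSV export round-trips the network exactly", {
  net <- dip_net()
  rebuilt <- build_network(parse_interaction_table(export_network(net, "tsv")))
  expect_equal(rebuilt$nodes, net$nodes)
  expect_equal(rebuilt$edges$a, net$edges$a)
  expect_equal(rebuilt$edges$b, net$edges$b)
  expect_equal(rebuilt$edges$ids, net$edges$ids)
})

test_that("SIF and GraphML exports have the expected shape", {
  net <- make_net(c("a", "b", "b", "c"))
  sif <- export_network(net, "sif")
  expect_equal(strsplit(sif, "\n")[[1]], c("a pp b", "b pp c"))
  gml <- export_network(net, "graphml")
  expect_match(gml, "graphml", fixed = TRUE)
  expect_error(export_network(net, "xyz"))
})

test_that("export with a clustering produces a node-attribute companion table", {
  prot <- dip_net()$nodes
  cl <- new_clustering(split(prot[1:29], rep(1:5, c(3, 7, 15, 2, 2))))
  out <- export_network(dip_net(), "sif", clustering = cl)
  expect_equal(nrow(out$node_attributes), 29)
  expect_equal(length(unique(out$node_attributes$cluster)), 5)
})
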