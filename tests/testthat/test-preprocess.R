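test_that("defective-clique completion finds the missing edge of a near-clique", {
  k4_minus <- make_net(c("n1", "n3", "n1", "n4", "n2", "n3", "n2", "n4", "n3", "n4"))
  pred <- predict_false_negatives(k4_minus, defective_clique_params(2))
  expect_equal(pred$a, "n1")
  expect_equal(pred$b, "n2")
  expect_equal(pred$completed_clique, 4)
  # complete graphs have no non-adjacent pairs
  expect_equal(nrow(predict_false_negatives(complete_net(6),
                                            defective_clique_params(1))), 0)
  expect_error(defective_clique_params(0), "min_common")
})

test_that("the suggested parameter yields exactly one completion on the DIP network", {
  net <- dip_net()
  lam <- suggest_defective_clique_param(net)
  pred <- predict_false_negatives(net, defective_clique_params(lam, max_predictions = 1))
  expect_equal(nrow(pred), 1)
  aug <- apply_additions(net, pred)
  expect_equal(n_edges(aug), 91)
  expect_equal(n_nodes(aug), 34)
  empty <- build_network(data.frame(protein_a = character(),
                                    protein_b = character(),
                                    interaction_id = character()))
  expect_equal(suggest_defective_clique_param(empty), 1L)
  expect_equal(suggest_defective_clique_param(complete_net(10)), lam)
})

test_that("predictions are valid and monotone in min_common", {
  for (seed in 1:5) {
    net <- random_net(8 + (seed %% 3), 0.45, seed)
    prev <- NULL
    for (lam in 1:4) {
      pred <- predict_false_negatives(net, defective_clique_params(lam))
      keys <- if (nrow(pred)) paste(pred$a, pred$b) else character()
      # never an existing edge, and the common clique really exists
      existing <- paste(net$edges$a, net$edges$b)
      expect_length(intersect(keys, existing), 0)
      for (i in seq_len(nrow(pred))) {
        expect_true(oracle_has_common_clique(net, pred$a[i], pred$b[i], lam))
      }
      # raising min_common never enlarges the prediction set
      if (!is.null(prev)) expect_true(all(keys %in% prev))
      prev <- keys
    }
  }
})

test_that("perturbed planted cliques are re-predicted", {
  # delete one edge inside a 6-clique embedded in sparse background noise
  cl <- utils::combn(paste0("c", 1:6), 2)
  pairs <- c(as.vector(cl), "c1", "x1", "x1", "x2", "c4", "x3")
  net <- make_net(pairs)
  cut <- remove_edges(net, data.frame(a = "c2", b = "c5"))
  pred <- predict_false_negatives(cut, defective_clique_params(4))
  expect_equal(nrow(pred), 1)
  expect_equal(c(pred$a, pred$b), c("c2", "c5"))
})

test_that("apply_additions synthesises PRED ids and rejects existing edges", {
  net <- dip_net()
  aug <- apply_additions(net, data.frame(a = "aip1", b = "app1"))
  expect_equal(n_edges(aug), 91)
  keys <- function(x) paste(x$edges$a, x$edges$b)
  new_edge <- aug$edges[!(keys(aug) %in% keys(net)), ]
  expect_equal(new_edge$ids[[1]], "PRED-1")
  d <- diff_networks(net, aug)
  expect_equal(nrow(d$added_edges), 1)
  expect_identical(apply_additions(net, data.frame(a = character(), b = character())),
                   net)
  expect_error(apply_additions(net, data.frame(a = "act1", b = "abp1")), "exists")
})

test_that("false-positive flagging follows the policy and the score order", {
  expect_equal(nrow(flag_false_positives(
    path_net(c("a", "b", "c", "d")),
    fp_filter_policy("betweenness", top_k = 0))), 0)
  fl <- flag_false_positives(path_net(c("a", "b", "c", "d")),
                             fp_filter_policy("betweenness", top_k = 1))
  expect_equal(c(fl$a, fl$b), c("b", "c"))
  # default policy on the completed DIP network flags exactly 3 edges
  aug <- fn_completed_net()
  fl3 <- flag_false_positives(aug)
  expect_equal(nrow(fl3), 3)
  expect_true(all(diff(fl3$score) <= 0))
  # threshold selection agrees with rank selection at the implied cutoff
  bythr <- flag_false_positives(aug, fp_filter_policy("betweenness",
                                                      threshold = min(fl3$score) - 1e-9))
  expect_setequal(paste(bythr$a, bythr$b), paste(fl3$a, fl3$b))
  # protect_core spares core-flagged edges from removal
  net_core <- annotate_core(dip_net(), dip_core_ids())
  core_keys <- paste(net_core$edges$a, net_core$edges$b)[net_core$edges$core]
  prot <- flag_false_positives(net_core, fp_filter_policy("betweenness", top_k = 5,
                                                          protect_core = TRUE))
  expect_length(intersect(paste(prot$a, prot$b), core_keys), 0)
  expect_error(fp_filter_policy("betweenness", top_k = 1, threshold = 2))
})

test_that("edge removal keeps isolated nodes and validates inputs", {
  aug <- fn_completed_net()
  fl <- flag_false_positives(aug)
  red <- remove_edges(aug, fl)
  expect_equal(n_edges(red), 88)
  expect_equal(n_nodes(red), 34)
  expect_identical(remove_edges(aug, fl[0, ]), aug)
  allgone <- remove_edges(aug, aug$edges[, c("a", "b")])
  expect_equal(n_edges(allgone), 0)
  expect_equal(n_nodes(allgone), 34)
  expect_error(remove_edges(aug, data.frame(a = "zz", b = "qq")), "not present")
})

test_that("core preservation audit warns exactly when core edges are removed", {
  net <- annotate_core(dip_net(), dip_core_ids())
  aug <- apply_additions(net, predict_false_negatives(
    net, defective_clique_params(max_predictions = 1)))
  flagged <- flag_false_positives(aug)
  red <- remove_edges(aug, flagged)
  audit <- core_preservation_audit(aug, red)
  expect_equal(audit$verdict, "warn")
  expect_equal(audit$core_removed, 2)
  # pure addition is ok
  expect_equal(core_preservation_audit(net, aug)$verdict, "ok")
  # removing only non-core edges is ok
  noncore <- net$edges[!net$edges$core, c("a", "b")][1:2, ]
  expect_equal(core_preservation_audit(net, remove_edges(net, noncore))$verdict, "ok")
  # unknown core flags: not assessable
  expect_equal(core_preservation_audit(dip_net(), red)$verdict, "not assessable")
})

test_that("flag -> remove -> audit composes to the diff_networks delta", {
  net <- annotate_core(dip_net(), dip_core_ids())
  fl <- flag_false_positives(net, fp_filter_policy("betweenness", top_k = 4))
  red <- remove_edges(net, fl)
  audit <- core_preservation_audit(net, red)
  d <- diff_networks(net, red)
  expect_equal(audit$delta$removed_edges, d$removed_edges)
  expect_equal(audit$delta$added_edges, d$added_edges)
  expect_equal(audit$core_removed, d$removed_core_count)
})
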