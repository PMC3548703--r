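scenario_net <- function() annotate_core(dip_net(), dip_core_ids())

test_that("fact assertion is idempotent and keyed by predicate and slots", {
  wm <- list()
  wm <- assert_fact(wm, fact("network", nodes = 34, edges = 90))
  wm <- assert_fact(wm, fact("network", nodes = 34, edges = 90))
  expect_length(wm, 1)
  wm <- assert_fact(wm, fact("network", nodes = 34, edges = 91))
  expect_length(wm, 2)
  expect_error(fact("x", 1), "named")
})

test_that("the knowledge base has the six-module tree with three inactive leaves", {
  kb <- build_complex_extraction_kb()
  expect_length(kb$modules, 6)
  expect_equal(sum(!vapply(kb$modules, `[[`, logical(1), "active")), 3)
  roots <- Filter(function(m) is.null(m$parent), kb$modules)
  expect_length(roots, 1)
  expect_equal(roots[[1]]$name, "PPI Complex Extraction")
  # every parent link resolves within the registry
  for (m in kb$modules) {
    if (!is.null(m$parent)) expect_true(m$parent %in% names(kb$modules))
  }
  # every rule belongs to exactly one registered module
  for (r in kb$rules) expect_true(r$module %in% names(kb$modules))
})

test_that("inference fires the narrated rules on matching memory", {
  kb <- build_complex_extraction_kb()
  st <- kdss_init(kb, scenario_net())
  st$memory <- assert_fact(st$memory, fact("scale_free", value = FALSE))
  out <- run_inference(kb, st)
  subjects <- vapply(out$suggestions, `[[`, "", "subject")
  expect_equal(subjects, "preprocess-network")
  # high core fraction: FN addition suggested, FP deletion suppressed
  st2 <- out$state
  st2$focus <- "Complex Preprocessing"
  st2$memory <- assert_fact(st2$memory, fact("core_fraction", value = 67 / 90))
  out2 <- run_inference(kb, st2)
  subjects2 <- vapply(out2$suggestions, `[[`, "", "subject")
  expect_true("add-fn-ppis" %in% subjects2)
  expect_false("delete-fp-ppis" %in% subjects2)
  # low core fraction fires the deletion rule instead
  st3 <- kdss_init(kb, scenario_net())
  st3$focus <- "Complex Preprocessing"
  st3$memory <- assert_fact(st3$memory, fact("core_fraction", value = 0.4))
  out3 <- run_inference(kb, st3)
  expect_true("delete-fp-ppis" %in% vapply(out3$suggestions, `[[`, "", "subject"))
  # MCL proposed once preprocessing is done
  st4 <- kdss_init(kb, scenario_net())
  st4$focus <- "Complex Clustering"
  st4$memory <- assert_fact(st4$memory, fact("preprocessed", value = TRUE))
  out4 <- run_inference(kb, st4)
  mclsugg <- out4$suggestions[[1]]
  expect_equal(mclsugg$subject, "mcl")
  expect_match(mclsugg$rationale, "fastest")
  expect_equal(mclsugg$proposed_params$inflation, 2.2)
})

test_that("refraction: a rule never fires twice on the same match", {
  kb <- build_complex_extraction_kb()
  st <- kdss_init(kb, scenario_net())
  st$memory <- assert_fact(st$memory, fact("scale_free", value = FALSE))
  out1 <- run_inference(kb, st)
  out2 <- run_inference(kb, out1$state)
  expect_length(out2$suggestions, 0)
})

test_that("only rules of the focused module fire", {
  kb <- build_complex_extraction_kb()
  st <- kdss_init(kb, scenario_net())
  # core_fraction present, but focus is at the root: R2 must not fire
  st$memory <- assert_fact(st$memory, fact("core_fraction", value = 0.9))
  out <- run_inference(kb, st)
  expect_false("add-fn-ppis" %in% vapply(out$suggestions, `[[`, "", "subject"))
  st$focus <- "unknown-module"
  expect_error(run_inference(kb, st), "focus")
})

test_that("tool ranking is cost-ascending and purpose-scoped", {
  kb <- build_complex_extraction_kb()
  fp <- rank_tools(kb$tools, "delete-fp")
  expect_length(fp, 3)
  expect_equal(fp[[1]]$name, "betweenness-centrality")
  fn <- rank_tools(kb$tools, "add-fn")
  expect_length(fn, 1)
  expect_equal(fn[[1]]$name, "detect-defective-cliques")
  one <- rank_tools(list(tool_spec("t", "p", 1)), "p")
  expect_equal(one[[1]]$name, "t")
  expect_error(rank_tools(kb$tools, "no-such-purpose"), "no-such-purpose")
})

test_that("execute_tool validates parameters and asserts result facts", {
  kb <- build_complex_extraction_kb()
  st <- kdss_init(kb, scenario_net())
  st2 <- execute_tool(st, kb$tools[["detect-defective-cliques"]], list())
  expect_equal(wm_value(st2$memory, "network", "edges"), 91)
  expect_equal(n_edges(st2$net), 91)
  # schema violation: error, state untouched
  expect_error(execute_tool(st, kb$tools[["mcl"]], list(bogus = 1)), "bogus")
  # runner failure is recorded as a fact, memory otherwise unchanged
  boom <- tool_spec("boom", "p", 1, runner = function(state, params) stop("nope"))
  st3 <- execute_tool(st, boom, list())
  expect_equal(n_edges(st3$net), 90)
  expect_true(any(vapply(st3$memory, function(f) f$predicate == "tool_failed",
                         logical(1))))
})

test_that("checkpoint and rollback are exact inverses and idempotent", {
  kb <- build_complex_extraction_kb()
  st <- kdss_init(kb, scenario_net())
  st$memory <- assert_fact(st$memory, fact("scale_free", value = FALSE))
  st <- checkpoint(st, "before mutation")
  snap_mem <- st$memory
  snap_net <- st$net
  st <- execute_tool(st, kb$tools[["detect-defective-cliques"]], list())
  st$memory <- assert_fact(st$memory, fact("extra", value = 1))
  st2 <- rollback(st, "cp1")
  expect_identical(st2$memory, snap_mem)
  expect_identical(st2$net, snap_net)
  st3 <- rollback(st2, "cp1")
  expect_identical(st3$memory, st2$memory)
  expect_identical(st3$net, st2$net)
  expect_error(rollback(st, "cp99"), "unknown checkpoint")
  # the abandoned branch stays visible in the trace
  expect_true(any(vapply(st2$trace$nodes, function(n) n$status == "abandoned",
                         logical(1))))
})

test_that("trace exports round-trip and keep the three-layer structure", {
  empty <- export_trace(kdss_init(build_complex_extraction_kb(),
                                  scenario_net())$trace, "json")
  expect_true(jsonlite::validate(empty))
  sc <- run_scenario(scenario_net())
  j <- export_trace(sc$trace, "json")
  rt <- import_trace_json(j)
  expect_identical(export_trace(rt, "json"), j)
  layers <- vapply(sc$trace$nodes, `[[`, 0L, "layer")
  expect_setequal(unique(layers), c(0L, 1L, 2L))
  # every tool node sits inside a strategy inside a module
  for (n in sc$trace$nodes) {
    if (n$layer == 2L) {
      expect_false(is.na(n$strategy))
      expect_true(n$module %in% c("Complex Preprocessing", "Complex Clustering",
                                  "PPI Complex Extraction"))
    }
  }
  dot <- export_trace(sc$trace, "dot")
  expect_match(dot, "cluster_", fixed = TRUE)
  gml <- export_trace(sc$trace, "graphml")
  expect_match(gml, "graphml", fixed = TRUE)
})

test_that("accept-all replays the narrated decision sequence", {
  sc <- run_scenario(scenario_net())
  subjects <- vapply(sc$suggestions, `[[`, "", "subject")
  expect_equal(subjects[1:3],
               c("preprocess-network", "add-fn-ppis", "detect-defective-cliques"))
  expect_false("delete-fp-ppis" %in% subjects)
  expect_equal(sc$tool_sequence,
               c("detect-defective-cliques", "mcl", "cytoscape-export"))
  expect_equal(n_edges(sc$networks$fn_completed), 91)
  mods <- unique(vapply(sc$trace$nodes, `[[`, "", "module"))
  expect_true(all(c("PPI Complex Extraction", "Complex Preprocessing",
                    "Complex Clustering") %in% mods))
})

test_that("the override branch audits core loss, warns, and rolls back", {
  sc <- run_scenario(scenario_net(),
                     decisions = c("accept", "accept", "accept",
                                   "override:delete-fp-ppis", "accept",
                                   "rollback", "accept", "accept", "accept"))
  expect_true("betweenness-centrality" %in% sc$tool_sequence)
  expect_equal(sc$state$last_audit$verdict, "warn")
  expect_equal(sc$state$last_audit$core_removed, 2)
  subjects <- vapply(sc$suggestions, `[[`, "", "subject")
  expect_true("change-strategy-or-parameters" %in% subjects)
  # rollback resumed the FN branch: final network is the 91-edge one
  expect_equal(n_edges(sc$net), 91)
  expect_false(is.null(sc$clustering))
  # both strategies appear in the trace, the FP branch marked abandoned
  labels <- vapply(sc$trace$nodes, `[[`, "", "label")
  expect_true("Add FN PPIs" %in% labels)
  expect_true("Delete FP PPIs" %in% labels)
  expect_true(any(vapply(sc$trace$nodes, function(n) n$status == "abandoned",
                         logical(1))))
})
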