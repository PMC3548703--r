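# The complex-extraction knowledge base: the module tree, the narrated
# rule set (R1..R6 plus a focus-activation rule) and the tool registry
# with runners bound to the package's algorithms.

#' Build the protein-complex-extraction knowledge base
#'
#' Six decision modules in a tree: the root supervises two active children
#' (preprocessing and clustering); three further specialised modules are
#' registered as inactive placeholders with empty rule sets. Rules encode
#' the expert guidance: a non-scale-free input network triggers
#' preprocessing advice (R1); a curated-core fraction above the assumed
#' high-throughput false-positive rate favours false-negative addition over
#' edge deletion (R2/R2'); chosen strategies are matched to the
#' cheapest-ranked tool with proposed parameters (R4); deleting core
#' interactions raises a warning (R5); once preprocessed, MCL is proposed
#' for clustering with species defaults (R3); a finished clustering
#' triggers visualisation export (R6).
#'
#' @param species Species tag used for clustering parameter defaults.
#' @return A knowledge base: list with `modules`, `rules`, `tools`,
#'   `strategies`, `species`.
#' @export
build_complex_extraction_kb <- function(species = "S.cerevisiae") {
  modules <- list(
    "PPI Complex Extraction" = decision_module("PPI Complex Extraction"),
    "Complex Preprocessing" = decision_module("Complex Preprocessing",
                                              parent = "PPI Complex Extraction"),
    "Complex Clustering" = decision_module("Complex Clustering",
                                           parent = "PPI Complex Extraction"),
    "Interaction Identification" = decision_module("Interaction Identification",
                                                   parent = "Complex Preprocessing",
                                                   active = FALSE),
    "Cluster Comparison" = decision_module("Cluster Comparison",
                                           parent = "Complex Clustering",
                                           active = FALSE),
    "Cluster Identification" = decision_module("Cluster Identification",
                                               parent = "Complex Clustering",
                                               active = FALSE)
  )

  tools <- list(
    "detect-defective-cliques" = tool_spec(
      "detect-defective-cliques", solves = "add-fn", cost_rank = 1,
      param_schema = c("min_common", "max_predictions"),
      runner = run_detect_defective_cliques,
      description = paste("Predicts missing interactions by completing",
                          "near-cliques lacking exactly one edge;",
                          "conservative, adds few edges.")),
    "betweenness-centrality" = tool_spec(
      "betweenness-centrality", solves = "delete-fp", cost_rank = 1,
      param_schema = c("top_k", "threshold", "protect_core"),
      runner = function(state, params) run_fp_filter(state, params, "betweenness",
                                                     "Betweenness Centrality"),
      description = paste("Removes highest-betweenness edges, which bridge",
                          "distant regions and are enriched in false",
                          "positives; lowest computational cost.")),
    "clustering-coefficient" = tool_spec(
      "clustering-coefficient", solves = "delete-fp", cost_rank = 2,
      param_schema = c("top_k", "threshold", "protect_core"),
      runner = function(state, params) run_fp_filter(state, params,
                                                     "clustering-coefficient",
                                                     "Clustering Coefficient"),
      description = "Removes edges whose endpoints share few neighbours."),
    "combined-topological-score" = tool_spec(
      "combined-topological-score", solves = "delete-fp", cost_rank = 3,
      param_schema = c("top_k", "threshold", "protect_core"),
      runner = function(state, params) run_fp_filter(state, params, "combined",
                                                     "Combined Topological Score"),
      description = paste("Geometric mean of centrality and clustering",
                          "coefficient after normalisation; dearest of the",
                          "three purification tools.")),
    "mcl" = tool_spec(
      "mcl", solves = "clustering", cost_rank = 1,
      param_schema = c("inflation", "expansion", "add_self_loops",
                       "prune_threshold", "max_iter", "convergence_tol"),
      runner = run_mcl_tool,
      description = paste("Flow-simulation clustering; fast, works well on",
                          "dense graphs, robust to noise.")),
    "rnsc" = tool_spec(
      "rnsc", solves = "clustering", cost_rank = 2,
      param_schema = c("seed", "restarts", "tabu_length",
                       "diversification_period", "max_no_improve",
                       "initial_clusters"),
      runner = run_rnsc_tool,
      description = paste("Cost-based local search; precision/recall close",
                          "to MCL on noisy or purified networks, slower.")),
    "mcode" = tool_spec(
      "mcode", solves = "clustering", cost_rank = 3,
      param_schema = c("vwp", "haircut", "fluff", "fluff_density"),
      runner = run_mcode_tool,
      description = paste("Local-density complex detection; sensitive to",
                          "noise, benefits most from preprocessing.")),
    "cytoscape-export" = tool_spec(
      "cytoscape-export", solves = "visualisation", cost_rank = 1,
      param_schema = c("format"),
      runner = run_export_tool,
      description = "Writes the clustered network as SIF plus a node-attribute table.")
  )

  rules <- list(
    R1 = kdss_rule("R1", "PPI Complex Extraction", 100,
      when = function(wm) {
        isFALSE(wm_value(wm, "scale_free", "value")) && !wm_has(wm, "preprocessed")
      },
      then = function(mt, wm) list(suggestions = list(suggestion(
        "strategy", "preprocess-network",
        rationale = paste("the input network is not scale-free, unlike most",
                          "cellular interaction networks; preprocessing can",
                          "change its geometry by correcting false-positive",
                          "or false-negative interactions"),
        fired_by = "R1", activates = "Complex Preprocessing")))),
    R2 = kdss_rule("R2", "Complex Preprocessing", 90,
      when = function(wm) {
        cf <- wm_value(wm, "core_fraction", "value")
        !is.null(cf) && cf > HIGH_THROUGHPUT_FP_RATE
      },
      then = function(mt, wm) {
        cf <- wm_value(wm, "core_fraction", "value")
        list(suggestions = list(suggestion(
          "strategy", "add-fn-ppis",
          rationale = sprintf(
            paste("%.0f%% of interactions are manually curated core",
                  "interactions, above the ~%.0f%% false-positive rate of",
                  "high-throughput screens; deleting edges would risk core",
                  "interactions, so adding missing interactions is preferred"),
            100 * cf, 100 * HIGH_THROUGHPUT_FP_RATE),
          fired_by = "R2",
          pros_cons = "pro: preserves curated interactions; con: may add spurious edges")))
      }),
    R2prime = kdss_rule("R2prime", "Complex Preprocessing", 90,
      when = function(wm) {
        cf <- wm_value(wm, "core_fraction", "value")
        !is.null(cf) && cf <= HIGH_THROUGHPUT_FP_RATE
      },
      then = function(mt, wm) {
        cf <- wm_value(wm, "core_fraction", "value")
        list(suggestions = list(suggestion(
          "strategy", "delete-fp-ppis",
          rationale = sprintf(
            paste("only %.0f%% of interactions are curated, consistent with",
                  "a high false-positive load; removing suspect edges is",
                  "preferred"), 100 * cf),
          fired_by = "R2prime")))
      }),
    R4 = kdss_rule("R4", "Complex Preprocessing", 80,
      when = function(wm) {
        chosen <- Filter(function(f) f$predicate == "strategy_chosen" &&
                           f$slots$strategy %in% c("add-fn-ppis", "delete-fp-ppis"), wm)
        lapply(unname(chosen), function(f) list(strategy = f$slots$strategy))
      },
      then = function(mt, wm) {
        purpose <- if (mt$strategy == "add-fn-ppis") "add-fn" else "delete-fp"
        ranked <- rank_tools(tools, purpose, "cost")
        best <- ranked[[1]]
        params <- if (purpose == "add-fn") {
          list(min_common = DEFAULT_MIN_COMMON,
               max_predictions = DEFAULT_MAX_PREDICTIONS)
        } else {
          list(top_k = DEFAULT_BC_TOP_K)
        }
        list(suggestions = list(suggestion(
          "tool", best$name,
          rationale = sprintf(
            "%s ranked first by computational cost among %d tool(s) for purpose '%s'",
            best$name, length(ranked), purpose),
          fired_by = "R4", pros_cons = best$description,
          proposed_params = params)))
      }),
    R5 = kdss_rule("R5", "Complex Preprocessing", 95,
      when = function(wm) {
        cr <- wm_value(wm, "audit", "core_removed")
        !is.null(cr) && cr > 0
      },
      then = function(mt, wm) {
        cr <- wm_value(wm, "audit", "core_removed")
        list(suggestions = list(suggestion(
          "parameter", "change-strategy-or-parameters",
          rationale = sprintf(
            paste("%d core interaction(s) have been deleted; moving core",
                  "interactions is lethal for biological networks, so the",
                  "strategy and/or its parameters should be reconsidered"), cr),
          fired_by = "R5")))
      }),
    R3 = kdss_rule("R3", "Complex Clustering", 90,
      when = function(wm) isTRUE(wm_value(wm, "preprocessed", "value")),
      then = function(mt, wm) {
        p <- suggest_clustering_params(NULL, "mcl", species)
        list(suggestions = list(suggestion(
          "tool", "mcl",
          rationale = paste("the network has been preprocessed; MCODE is",
                            "sensitive to noise while MCL and RNSC perform",
                            "similarly on noisy or purified networks, and MCL",
                            "is the fastest and works well with dense graphs;",
                            "standard parameters for this species are available"),
          fired_by = "R3", pros_cons = tools[["mcl"]]$description,
          proposed_params = list(inflation = p$inflation))))
      }),
    Rfocus = kdss_rule("Rfocus-clustering", "PPI Complex Extraction", 60,
      when = function(wm) {
        isTRUE(wm_value(wm, "preprocessed", "value")) && !wm_has(wm, "clustered")
      },
      then = function(mt, wm) list(activate = "Complex Clustering")),
    R6 = kdss_rule("R6", "PPI Complex Extraction", 50,
      when = function(wm) isTRUE(wm_value(wm, "clustered", "value")),
      then = function(mt, wm) list(suggestions = list(suggestion(
        "tool", "cytoscape-export",
        rationale = "clustering finished: visualise the clustered network",
        fired_by = "R6", proposed_params = list(format = "sif")))))
  )

  list(modules = modules, rules = rules, tools = tools,
       strategies = c("preprocess-network", "add-fn-ppis", "delete-fp-ppis"),
       species = species)
}

# ---- tool runners -----------------------------------------------------

net_state_label <- function(net) {
  sprintf("PPIN: %d proteins, %d interactions", n_nodes(net), n_edges(net))
}

network_facts <- function(net) {
  facts <- list(fact("network", nodes = n_nodes(net), edges = n_edges(net),
                     source = "tool-result"))
  cf <- core_fraction(net)
  if (!is.na(cf)) {
    facts <- c(facts, list(fact("core_count", value = sum(net$edges$core),
                                source = "tool-result")))
  }
  facts
}

run_detect_defective_cliques <- function(state, params) {
  p <- defective_clique_params(
    min_common = params$min_common %||% DEFAULT_MIN_COMMON,
    max_predictions = params$max_predictions %||% DEFAULT_MAX_PREDICTIONS)
  pred <- predict_false_negatives(state$net, p)
  net2 <- apply_additions(state$net, pred)
  state$net <- net2
  state$networks$fn_completed <- net2
  state$trace <- trace_add(state$trace, 0, net_state_label(net2), state$focus)
  list(state = state,
       facts = c(network_facts(net2),
                 list(fact("preprocessed", value = TRUE, source = "tool-result"),
                      fact("fn_added", value = nrow(pred), source = "tool-result"))),
       label = "Detect Defective Cliques", result = pred)
}

run_fp_filter <- function(state, params, score_kind, label) {
  policy <- if (!is.null(params$threshold)) {
    fp_filter_policy(score_kind, threshold = params$threshold,
                     protect_core = params$protect_core %||% FALSE)
  } else {
    fp_filter_policy(score_kind, top_k = params$top_k %||% DEFAULT_BC_TOP_K,
                     protect_core = params$protect_core %||% FALSE)
  }
  before <- state$net
  flagged <- flag_false_positives(before, policy)
  net2 <- remove_edges(before, flagged)
  audit <- core_preservation_audit(before, net2)
  state$net <- net2
  state$networks$fp_filtered <- net2
  state$last_audit <- audit
  state$trace <- trace_add(state$trace, 0, net_state_label(net2), state$focus)
  facts <- c(network_facts(net2),
             list(fact("preprocessed", value = TRUE, source = "tool-result")))
  if (audit$verdict != "not assessable") {
    facts <- c(facts, list(fact("audit", core_removed = audit$core_removed,
                                verdict = audit$verdict, source = "tool-result")))
  }
  list(state = state, facts = facts, label = label, result = audit)
}

run_mcl_tool <- function(state, params) {
  defaults <- mcl_params()
  p <- utils::modifyList(unclass(defaults), params)
  mp <- mcl_params(p$inflation, p$expansion, p$add_self_loops,
                   p$prune_threshold, p$max_iter, p$convergence_tol)
  cl <- mcl(state$net, mp)
  state$clustering <- cl
  state$trace <- trace_add(state$trace, 0,
                           sprintf("clustering: %d clusters", length(cl$clusters)),
                           state$focus)
  list(state = state,
       facts = list(fact("clustered", value = TRUE, source = "tool-result"),
                    fact("n_clusters", value = length(cl$clusters),
                         source = "tool-result")),
       label = "MCL Clustering", result = cl)
}

run_rnsc_tool <- function(state, params) {
  if (is.null(params$seed)) stop("rnsc requires a seed parameter")
  p <- rnsc_params(initial_clusters = params$initial_clusters %||% "random",
                   tabu_length = params$tabu_length %||% 3L,
                   diversification_period = params$diversification_period %||% 20L,
                   max_no_improve = params$max_no_improve %||% 30L,
                   restarts = params$restarts %||% DEFAULT_RNSC_RESTARTS,
                   seed = params$seed)
  cl <- rnsc(state$net, p)
  state$clustering <- cl
  state$trace <- trace_add(state$trace, 0,
                           sprintf("clustering: %d clusters", length(cl$clusters)),
                           state$focus)
  list(state = state,
       facts = list(fact("clustered", value = TRUE, source = "tool-result"),
                    fact("n_clusters", value = length(cl$clusters),
                         source = "tool-result")),
       label = "RNSC Clustering", result = cl)
}

run_mcode_tool <- function(state, params) {
  p <- mcode_params(vwp = params$vwp %||% DEFAULT_MCODE_VWP,
                    haircut = params$haircut %||% TRUE,
                    fluff = params$fluff %||% FALSE,
                    fluff_density = params$fluff_density %||% 0.5)
  res <- mcode(state$net, p)
  state$mcode <- res
  state$trace <- trace_add(state$trace, 0,
                           sprintf("complexes: %d", length(res$complexes)),
                           state$focus)
  list(state = state,
       facts = list(fact("clustered", value = TRUE, source = "tool-result"),
                    fact("n_clusters", value = length(res$complexes),
                         source = "tool-result")),
       label = "MCODE Complex Detection", result = res)
}

run_export_tool <- function(state, params) {
  fmt <- params$format %||% "sif"
  out <- export_network(state$net, fmt, clustering = state$clustering)
  state$export <- out
  state$trace <- trace_add(state$trace, 0, sprintf("export (%s)", fmt), state$focus)
  list(state = state,
       facts = list(fact("exported", value = TRUE, source = "tool-result")),
       label = "Cytoscape export", result = out)
}

# ---- scenario driver --------------------------------------------------

#' Replay the complex-extraction scenario
#'
#' Runs the full decision loop on a network: input analysis (size, core
#' fraction, scale-free test), rule-driven strategy and tool suggestions,
#' scripted or accept-all user decisions, tool execution with fact
#' feedback, module focus management, checkpoints on overrides, and the
#' three-layer workflow trace.
#'
#' Decisions are an injectable source so the interactive system can be
#' replayed deterministically: each element answers one pending suggestion
#' (or continue prompt) in order. Supported directives: `"accept"`,
#' `"reject"`, `"override:<strategy-or-tool>"`, `"rollback"` (to the most
#' recent checkpoint) or `"rollback:<id>"`. When the list is exhausted,
#' remaining suggestions are accepted.
#'
#' @param net A `ppin`, or a path to an edge-list TSV.
#' @param core_ids Optional character vector (or file path) of core
#'   interaction ids; required for the core-fraction rules to fire.
#' @param decisions `"accept-all"` or a character vector of directives.
#' @param species Species tag for parameter defaults.
#' @param annotations Optional [annotation_map()] (or TSV path): when
#'   given, cluster enrichment is computed on the final clustering.
#' @param alpha Enrichment reporting cutoff.
#' @return A `kdss_scenario`: list with `state`, `trace`, `suggestions`
#'   (every suggestion in firing order), `tool_sequence`, `clustering`,
#'   `net`, `networks`, `enrichment` (or `NULL`).
#' @export
run_scenario <- function(net, core_ids = NULL, decisions = "accept-all",
                         species = "S.cerevisiae", annotations = NULL,
                         alpha = 0.01) {
  if (is.character(net)) net <- build_network(parse_interaction_table(net))
  if (is.character(core_ids) && length(core_ids) == 1 && file.exists(core_ids)) {
    core_ids <- read_core_ids(core_ids)
  }
  if (!is.null(core_ids)) net <- annotate_core(net, core_ids)
  if (is.character(annotations)) annotations <- read_annotation_map(annotations)

  kb <- build_complex_extraction_kb(species)
  state <- kdss_init(kb, net)

  accept_all <- identical(decisions, "accept-all")
  queue <- if (accept_all) character() else decisions
  next_decision <- function() {
    if (accept_all || length(queue) == 0) return("accept")
    d <- queue[1]
    queue <<- queue[-1]
    d
  }

  # input analysis
  state$trace <- trace_add(state$trace, 0, net_state_label(net), state$focus)
  state$memory <- assert_fact(state$memory,
                              fact("network", nodes = n_nodes(net),
                                   edges = n_edges(net), source = "analysis"))
  cf <- core_fraction(net)
  if (!is.na(cf)) {
    state$memory <- assert_fact(state$memory,
                                fact("core_fraction", value = cf, source = "analysis"))
  }
  sf <- is_scale_free(net)
  if (!is.na(sf$decided_scale_free)) {
    state$memory <- assert_fact(state$memory,
                                fact("scale_free", value = sf$decided_scale_free,
                                     source = "analysis"))
  }

  all_suggestions <- list()
  tool_sequence <- character()

  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 200L) stop("scenario did not terminate")
    prev_focus <- state$focus
    inf <- run_inference(kb, state)
    state <- inf$state
    suggs <- inf$suggestions
    if (length(suggs) == 0) {
      if (state$focus != prev_focus) next  # a rule just shifted focus: run the child's rules
      if (state$focus == "PPI Complex Extraction") break
      # focused child module has nothing left: offer to conclude it
      sugg <- suggestion("strategy", "continue",
                         rationale = sprintf("%s has no further advice: conclude it and return focus to the parent module",
                                             state$focus),
                         fired_by = "module-completion")
      choice <- next_decision()
      all_suggestions[[length(all_suggestions) + 1L]] <- sugg
      if (identical(choice, "accept")) {
        state$decisions[[length(state$decisions) + 1L]] <-
          list(suggestion = sugg, choice = choice)
        parent <- kb$modules[[state$focus]]$parent
        state$focus_stack <- utils::head(state$focus_stack, -1L)
        state$focus <- parent
      } else {
        state <- handle_decision(state, sugg, choice, kb)
        st <- state$scheduled; state$scheduled <- NULL
        if (!is.null(st)) {
          state <- execute_tool(state, kb$tools[[st$name]], st$params)
          tool_sequence <- c(tool_sequence, st$name)
        }
      }
      next
    }
    for (sugg in suggs) {
      all_suggestions[[length(all_suggestions) + 1L]] <- sugg
      choice <- next_decision()
      state <- handle_decision(state, sugg, choice, kb)
      st <- state$scheduled; state$scheduled <- NULL
      if (!is.null(st)) {
        state <- execute_tool(state, kb$tools[[st$name]], st$params)
        tool_sequence <- c(tool_sequence, st$name)
      }
    }
  }

  enr <- NULL
  if (!is.null(annotations) && !is.null(state$clustering)) {
    enr <- best_term_per_cluster(state$clustering, annotations, alpha)
  }
  structure(list(state = state, trace = state$trace,
                 suggestions = all_suggestions, tool_sequence = tool_sequence,
                 clustering = state$clustering, net = state$net,
                 networks = state$networks, enrichment = enr,
                 scale_free = sf),
            class = "kdss_scenario")
}

# Apply one decision directive; tool executions are deferred to the driver
# through state$scheduled.
handle_decision <- function(state, sugg, choice, kb) {
  if (grepl("^rollback", choice)) {
    id <- sub("^rollback:?", "", choice)
    if (!nzchar(id)) id <- names(state$checkpoints)[length(state$checkpoints)]
    state$decisions[[length(state$decisions) + 1L]] <-
      list(suggestion = sugg, choice = choice, checkpoint = id)
    return(rollback(state, id))
  }
  state <- decide(state, sugg, choice, kb)
  if (identical(choice, "accept") && sugg$kind == "tool") {
    state$scheduled <- list(name = sugg$subject, params = sugg$proposed_params)
  } else if (grepl("^override:", choice)) {
    alt <- sub("^override:", "", choice)
    if (alt %in% names(kb$tools)) {
      state$scheduled <- list(name = alt, params = list())
    }
  }
  state
}

#' @export
print.kdss_scenario <- function(x, ...) {
  cat("complex-extraction scenario run\n")
  cat(sprintf("  tools executed: %s\n", paste(x$tool_sequence, collapse = " -> ")))
  cat(sprintf("  final network: %d proteins, %d interactions\n",
              n_nodes(x$net), n_edges(x$net)))
  if (!is.null(x$clustering)) {
    cat(sprintf("  clusters: %d (+%d singletons)\n",
                length(x$clustering$clusters), length(x$clustering$singletons)))
  }
  invisible(x)
}
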