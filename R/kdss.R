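# Forward-chaining production core: explicit working memory, salience
# ordering, refraction. Rule and fact counts are tiny, so no pattern
# network is used; determinism and checkpointability dominate.

#' Create a fact
#'
#' @param predicate Fact name.
#' @param ... Named slot values.
#' @param source Who asserted it: `"user"`, `"analysis"` or `"tool-result"`.
#' @return A `kdss_fact`.
#' @export
fact <- function(predicate, ..., source = "analysis") {
  slots <- list(...)
  if (length(slots) > 0 && (is.null(names(slots)) || any(!nzchar(names(slots))))) {
    stop("all fact slots must be named")
  }
  structure(list(predicate = predicate, slots = slots, source = source),
            class = "kdss_fact")
}

fact_key <- function(f) {
  s <- f$slots[order(names(f$slots))]
  paste(f$predicate,
        paste(names(s), vapply(s, function(v) paste(format(v), collapse = "|"), ""),
              sep = "=", collapse = ";"),
        sep = ":")
}

#' Assert a fact into working memory
#'
#' Working memory is a named list keyed by the fact's canonical
#' (predicate, slots) form; asserting an already-present fact is a no-op,
#' so assertion is idempotent.
#'
#' @param memory Named list of facts (may be empty `list()`).
#' @param f A [fact()].
#' @return The updated memory.
#' @export
assert_fact <- function(memory, f) {
  stopifnot(inherits(f, "kdss_fact"))
  key <- fact_key(f)
  if (!is.null(memory[[key]])) return(memory)
  memory[[key]] <- f
  memory
}

#' Read a slot from working memory
#'
#' Returns the value of `slot` in the most recently asserted fact with the
#' given predicate, or `NULL` when no such fact exists.
#'
#' @param memory Working memory (named fact list).
#' @param predicate Fact name to look up.
#' @param slot Slot name.
#' @export
wm_value <- function(memory, predicate, slot) {
  hits <- Filter(function(f) f$predicate == predicate, memory)
  if (length(hits) == 0) return(NULL)
  hits[[length(hits)]]$slots[[slot]]
}

wm_has <- function(memory, predicate) {
  any(vapply(memory, function(f) f$predicate == predicate, logical(1)))
}

#' Define a production rule
#'
#' @param id Rule identifier, unique within the knowledge base.
#' @param module Name of the single decision module owning the rule.
#' @param salience Priority; higher fires first (ties break on id).
#' @param when Function(memory) returning a list of matches (one list per
#'   distinct match, possibly empty `list()`), or `TRUE`/`FALSE` for
#'   rules with a single trivial binding.
#' @param then Function(match, memory) returning a list with any of:
#'   `suggestions` (list of [suggestion()]), `facts` (list of [fact()]),
#'   `activate` (child module name to shift focus to).
#' @export
kdss_rule <- function(id, module, salience, when, then) {
  structure(list(id = id, module = module, salience = salience,
                 when = when, then = then),
            class = "kdss_rule")
}

#' Create a suggestion
#'
#' The unit of advice the reasoner hands to the user: a strategy to follow,
#' a tool to run, or a parameter/warning notice, with the firing rule and a
#' rationale attached.
#'
#' @param kind `"strategy"`, `"tool"` or `"parameter"`.
#' @param subject What is being proposed (strategy or tool name).
#' @param rationale Non-empty text citing why the rule fired.
#' @param fired_by Id of the firing rule.
#' @param pros_cons Optional advantages/drawbacks text.
#' @param proposed_params Named list of proposed parameter values.
#' @param activates Optional module the acceptance hands focus to.
#' @export
suggestion <- function(kind, subject, rationale, fired_by, pros_cons = "",
                       proposed_params = list(), activates = NULL) {
  stopifnot(kind %in% c("strategy", "tool", "parameter"), nzchar(rationale))
  structure(list(kind = kind, subject = subject, rationale = rationale,
                 pros_cons = pros_cons, proposed_params = proposed_params,
                 fired_by = fired_by, activates = activates),
            class = "kdss_suggestion")
}

#' @export
print.kdss_suggestion <- function(x, ...) {
  cat(sprintf("[%s] %s (rule %s): %s\n", x$kind, x$subject, x$fired_by, x$rationale))
  invisible(x)
}

#' Define a tool specification
#'
#' Realises the solver/tool side of the data-problem-solver registry: what
#' purpose the tool serves, its relative computational cost rank (used for
#' "lowest cost" ranking), the parameters it accepts and the function that
#' runs it.
#'
#' @param name Unique tool name.
#' @param solves Purpose tag (e.g. `"add-fn"`, `"delete-fp"`,
#'   `"clustering"`, `"visualisation"`).
#' @param cost_rank Ordinal cost within the purpose (1 = cheapest).
#' @param param_schema Character vector of accepted parameter names.
#' @param runner Function(state, params) returning
#'   `list(state = ..., facts = list(...), label = ...)`.
#' @param description Pros/cons text surfaced with suggestions.
#' @export
tool_spec <- function(name, solves, cost_rank, param_schema = character(),
                      runner = NULL, description = "") {
  structure(list(name = name, solves = solves, cost_rank = cost_rank,
                 param_schema = param_schema, runner = runner,
                 description = description),
            class = "kdss_tool_spec")
}

#' Rank the tools serving a purpose
#'
#' @param specs List of [tool_spec()] objects.
#' @param purpose Purpose tag to match.
#' @param criterion `"cost"` (ascending cost rank; stable for ties) or
#'   `"default"` (registry order).
#' @return The matching specs in rank order.
#' @export
rank_tools <- function(specs, purpose, criterion = c("cost", "default")) {
  criterion <- match.arg(criterion)
  hits <- Filter(function(s) s$solves == purpose, specs)
  if (length(hits) == 0) stop(sprintf("no tool in the registry solves purpose '%s'", purpose))
  if (criterion == "cost") {
    hits <- hits[order(vapply(hits, `[[`, numeric(1), "cost_rank"))]
  }
  hits
}

#' Build a decision-module registry
#'
#' @param name Module name.
#' @param parent Parent module name (`NULL` for the root).
#' @param active Whether the module carries rules in this scenario;
#'   inactive modules are registered placeholders that keep the module
#'   tree faithful.
#' @export
decision_module <- function(name, parent = NULL, active = TRUE) {
  structure(list(name = name, parent = parent, active = active),
            class = "kdss_module")
}

#' Run one forward-chaining inference pass
#'
#' Fires every rule of the focused module whose precondition matches, once
#' per distinct match (refraction: a rule never fires twice on the same
#' match, across passes). Rules fire in salience-descending order, ties
#' broken by rule id; fired actions may assert facts (visible to
#' lower-salience rules in the same pass), propose suggestions, or shift
#' focus to a child module, which ends the pass.
#'
#' @param kb Knowledge base from [build_complex_extraction_kb()] (or any
#'   list with `modules` and `rules`).
#' @param state Engine state (list with `memory`, `focus`, `fired`, ...).
#'   See [kdss_init()].
#' @return List with `suggestions` (ordered) and the updated `state`.
#' @export
run_inference <- function(kb, state) {
  if (is.null(state$focus) || !state$focus %in% names(kb$modules)) {
    stop("no decision module has focus")
  }
  rules <- Filter(function(r) r$module == state$focus, kb$rules)
  ord <- order(-vapply(rules, `[[`, numeric(1), "salience"),
               vapply(rules, `[[`, "", "id"))
  rules <- rules[ord]
  suggestions <- list()
  for (r in rules) {
    res <- r$when(state$memory)
    matches <- if (isTRUE(res)) list(list()) else if (is.logical(res) || is.null(res)) list() else res
    for (mt in matches) {
      h <- paste(r$id, paste(deparse(mt), collapse = ""), sep = "#")
      if (h %in% state$fired) next
      state$fired <- c(state$fired, h)
      act <- r$then(mt, state$memory)
      for (f in act$facts %||% list()) state$memory <- assert_fact(state$memory, f)
      for (s in act$suggestions %||% list()) suggestions[[length(suggestions) + 1L]] <- s
      if (!is.null(act$activate)) {
        state$focus_stack <- c(state$focus_stack, state$focus)
        state$focus <- act$activate
        return(list(suggestions = suggestions, state = state))
      }
    }
  }
  list(suggestions = suggestions, state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- workflow trace ---------------------------------------------------

new_trace <- function() {
  list(nodes = list(), edges = list(), counter = 0L,
       cursor = list("0" = NULL, "1" = NULL, "2" = NULL))
}

trace_add <- function(trace, layer, label, module, strategy = NA_character_,
                      status = "done") {
  trace$counter <- trace$counter + 1L
  id <- sprintf("n%d", trace$counter)
  trace$nodes[[id]] <- list(id = id, label = label, layer = as.integer(layer),
                            module = module, strategy = strategy,
                            status = status)
  prev <- trace$cursor[[as.character(layer)]]
  if (!is.null(prev)) {
    trace$edges[[length(trace$edges) + 1L]] <- list(from = prev, to = id)
  }
  trace$cursor[[as.character(layer)]] <- id
  trace
}

#' Export a workflow trace
#'
#' The trace is a three-layer DAG: layer 0 holds object-level data states,
#' layer 1 the strategies grouped inside their decision-module boundaries,
#' layer 2 the executed tools; directed edges follow the execution
#' timeline within each layer. JSON is the canonical round-trippable form
#' (fields serialised in fixed order); GraphML and DOT exports target
#' graph viewers, the DOT form grouping nodes by module boundary.
#'
#' @param trace A trace (from [run_scenario()]'s result or [kdss_init()]).
#' @param format `"json"`, `"graphml"` or `"dot"`.
#' @return Character scalar with the serialised trace.
#' @export
export_trace <- function(trace, format = c("json", "graphml", "dot")) {
  format <- match.arg(format)
  nodes <- unname(lapply(trace$nodes, function(n) {
    n[sort(names(n))]
  }))
  nodes <- nodes[order(vapply(nodes, function(n) as.integer(sub("^n", "", n$id)), 0L))]
  edges <- trace$edges
  if (format == "json") {
    return(jsonlite::toJSON(list(edges = edges, nodes = nodes),
                            auto_unbox = TRUE, pretty = TRUE, null = "null"))
  }
  if (format == "graphml") {
    esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", gsub(">", "&gt;", x)))
    lines <- c(
      '<?xml version="1.0" encoding="UTF-8"?>',
      '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
      '  <key id="label" for="node" attr.name="label" attr.type="string"/>',
      '  <key id="layer" for="node" attr.name="layer" attr.type="int"/>',
      '  <key id="module" for="node" attr.name="module" attr.type="string"/>',
      '  <key id="strategy" for="node" attr.name="strategy" attr.type="string"/>',
      '  <key id="status" for="node" attr.name="status" attr.type="string"/>',
      '  <graph edgedefault="directed">')
    for (n in nodes) {
      lines <- c(lines, sprintf('    <node id="%s">', n$id),
                 sprintf('      <data key="label">%s</data>', esc(n$label)),
                 sprintf('      <data key="layer">%d</data>', n$layer),
                 sprintf('      <data key="module">%s</data>', esc(n$module)),
                 sprintf('      <data key="strategy">%s</data>',
                         if (is.na(n$strategy)) "" else esc(n$strategy)),
                 sprintf('      <data key="status">%s</data>', esc(n$status)),
                 '    </node>')
    }
    for (e in edges) {
      lines <- c(lines, sprintf('    <edge source="%s" target="%s"/>', e$from, e$to))
    }
    lines <- c(lines, '  </graph>', '</graphml>')
    return(paste0(paste(lines, collapse = "\n"), "\n"))
  }
  # dot: module boundaries as clusters
  mods <- unique(vapply(nodes, `[[`, "", "module"))
  lines <- c("digraph workflow {", "  rankdir=LR;")
  for (i in seq_along(mods)) {
    lines <- c(lines, sprintf('  subgraph cluster_%d {', i),
               sprintf('    label="%s";', mods[i]))
    for (n in nodes) {
      if (n$module != mods[i]) next
      shape <- c("ellipse", "box", "box")[n$layer + 1L]
      style <- if (n$status == "abandoned") ', style=dashed' else ''
      lines <- c(lines, sprintf('    %s [label="%s", shape=%s%s];',
                                n$id, n$label, shape, style))
    }
    lines <- c(lines, "  }")
  }
  for (e in edges) lines <- c(lines, sprintf("  %s -> %s;", e$from, e$to))
  lines <- c(lines, "}")
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Import a JSON workflow trace
#'
#' Inverse of [export_trace()] for the JSON format; exporting an imported
#' trace reproduces the document.
#'
#' @param json Character scalar produced by `export_trace(trace, "json")`.
#' @return A trace object.
#' @export
import_trace_json <- function(json) {
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  trace <- new_trace()
  for (n in doc$nodes) {
    n$layer <- as.integer(n$layer)
    if (is.null(n$strategy)) n$strategy <- NA_character_
    trace$nodes[[n$id]] <- n[c("id", "label", "layer", "module", "strategy", "status")]
  }
  trace$edges <- lapply(doc$edges, function(e) list(from = e$from, to = e$to))
  ids <- vapply(doc$nodes, `[[`, "", "id")
  trace$counter <- if (length(ids)) max(as.integer(sub("^n", "", ids))) else 0L
  for (ly in c("0", "1", "2")) {
    lnodes <- Filter(function(n) n$layer == as.integer(ly), trace$nodes)
    if (length(lnodes)) {
      last <- lnodes[[which.max(vapply(lnodes, function(n) as.integer(sub("^n", "", n$id)), 0L))]]
      trace$cursor[[ly]] <- last$id
    }
  }
  trace
}

# ---- engine state, checkpoints, execution -----------------------------

#' Initialise engine state for a knowledge base
#'
#' @param kb A knowledge base (see [build_complex_extraction_kb()]).
#' @param net The input `ppin`.
#' @return A state list: working `memory`, refraction record `fired`,
#'   current `focus` and `focus_stack`, the evolving network `net`, named
#'   `networks` snapshots, `clustering`, the workflow `trace`,
#'   `checkpoints` and the `decisions` log.
#' @export
kdss_init <- function(kb, net) {
  root <- names(Filter(function(m) is.null(m$parent), kb$modules))[1]
  list(memory = list(), fired = character(),
       focus = root, focus_stack = character(),
       net = net, networks = list(initial = net), clustering = NULL,
       trace = new_trace(), checkpoints = list(), decisions = list(),
       current_strategy = NA_character_)
}

#' Record a user decision on a suggestion
#'
#' Accepting a strategy marks it chosen (and hands focus to the module it
#' activates, when any); overriding first saves a checkpoint so the
#' abandoned advice can be returned to, then adopts the named alternative;
#' rejecting only logs the refusal in the trace.
#'
#' @param state Engine state.
#' @param sugg The [suggestion()] being decided.
#' @param choice `"accept"`, `"reject"`, or `"override:<alternative>"`
#'   where the alternative names another available strategy.
#' @param kb The knowledge base (used to validate override targets).
#' @return The updated state; `state$decisions` gains a record, and for
#'   overrides `state$checkpoints` gains a snapshot.
#' @export
decide <- function(state, sugg, choice, kb) {
  rec <- list(suggestion = sugg, choice = choice)
  if (identical(choice, "accept")) {
    state <- adopt_suggestion(state, sugg, sugg$subject)
  } else if (grepl("^override:", choice)) {
    alt <- sub("^override:", "", choice)
    known <- c(kb$strategies, vapply(kb$tools, `[[`, "", "name"))
    if (!alt %in% known) stop(sprintf("unknown alternative '%s'", alt))
    state <- checkpoint(state, label = sprintf("before override to %s", alt))
    rec$checkpoint <- names(state$checkpoints)[length(state$checkpoints)]
    state <- adopt_suggestion(state, sugg, alt)
  } else if (identical(choice, "reject")) {
    state$trace <- trace_add(state$trace, 1,
                             sprintf("rejected: %s", sugg$subject),
                             state$focus, status = "rejected")
  } else {
    stop(sprintf("unknown decision '%s'", choice))
  }
  state$decisions[[length(state$decisions) + 1L]] <- rec
  state
}

adopt_suggestion <- function(state, sugg, subject) {
  if (sugg$kind == "strategy") {
    state$memory <- assert_fact(state$memory,
                                fact("strategy_chosen", strategy = subject, source = "user"))
    if (!is.null(sugg$activates) && identical(subject, sugg$subject)) {
      state$focus_stack <- c(state$focus_stack, state$focus)
      state$focus <- sugg$activates
    }
    state$current_strategy <- subject
    state$trace <- trace_add(state$trace, 1, strategy_label(subject), state$focus)
  }
  state
}

strategy_label <- function(subject) {
  switch(subject,
         "add-fn-ppis" = "Add FN PPIs",
         "delete-fp-ppis" = "Delete FP PPIs",
         "preprocess-network" = "Preprocess PPIN",
         "cluster-network" = "Cluster PPIN",
         subject)
}

#' Save a checkpoint of the current state
#'
#' @param state Engine state.
#' @param label Free-text label.
#' @return The state with a new snapshot under `state$checkpoints`;
#'   checkpoint ids are `cp1`, `cp2`, ...
#' @export
checkpoint <- function(state, label = "") {
  id <- sprintf("cp%d", length(state$checkpoints) + 1L)
  snap <- state[c("memory", "fired", "focus", "focus_stack", "net",
                  "networks", "clustering", "current_strategy")]
  snap$trace_counter <- state$trace$counter
  snap$trace_cursor <- state$trace$cursor
  snap$label <- label
  state$checkpoints[[id]] <- snap
  state
}

#' Roll back to a checkpoint
#'
#' Restores working memory, refraction record, focus, networks and
#' clustering exactly as snapshotted. Trace nodes added after the
#' checkpoint are retained but marked `abandoned`, so the explored branch
#' stays visible in the exported workflow; the trace cursor returns to the
#' snapshot position. Rolling back twice to the same checkpoint is
#' idempotent.
#'
#' @param state Engine state.
#' @param id Checkpoint id (e.g. `"cp1"`).
#' @return The restored state.
#' @export
rollback <- function(state, id) {
  snap <- state$checkpoints[[id]]
  if (is.null(snap)) stop(sprintf("unknown checkpoint '%s'", id))
  for (fld in c("memory", "fired", "focus", "focus_stack", "net",
                "networks", "clustering", "current_strategy")) {
    state[[fld]] <- snap[[fld]]
  }
  for (nid in names(state$trace$nodes)) {
    if (as.integer(sub("^n", "", nid)) > snap$trace_counter) {
      state$trace$nodes[[nid]]$status <- "abandoned"
    }
  }
  state$trace$cursor <- snap$trace_cursor
  state
}

#' Execute a registered tool
#'
#' Validates the parameters against the tool's schema, invokes its runner
#' on the current state, asserts the runner's result facts into working
#' memory and appends a layer-2 trace node. A runner failure leaves the
#' state unchanged except for a `tool_failed` fact and a failed trace node.
#'
#' @param state Engine state.
#' @param spec A [tool_spec()].
#' @param params Named list of parameters; names outside the schema are a
#'   schema error (no state change).
#' @return The updated state; the runner's result is available under
#'   `state$last_result`.
#' @export
execute_tool <- function(state, spec, params = list()) {
  stopifnot(inherits(spec, "kdss_tool_spec"))
  bad <- setdiff(names(params), spec$param_schema)
  if (length(bad) > 0) {
    stop(sprintf("parameter '%s' not accepted by tool '%s'", bad[1], spec$name))
  }
  res <- tryCatch(spec$runner(state, params), error = function(e) e)
  if (inherits(res, "error")) {
    state$trace <- trace_add(state$trace, 2, sprintf("%s (failed)", spec$name),
                             state$focus, state$current_strategy, status = "failed")
    state$memory <- assert_fact(state$memory,
                                fact("tool_failed", tool = spec$name,
                                     message = conditionMessage(res),
                                     source = "tool-result"))
    return(state)
  }
  state <- res$state
  state$trace <- trace_add(state$trace, 2, res$label %||% spec$name,
                           state$focus, state$current_strategy)
  for (f in res$facts %||% list()) state$memory <- assert_fact(state$memory, f)
  state$last_result <- res$result
  state
}
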