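#' Parameters for defective-clique false-negative prediction
#'
#' @param min_common Minimum size of the clique that two non-adjacent
#'   proteins must share in their common neighbourhood for the missing pair
#'   to be predicted (the "number of common interactions between two
#'   defective cliques"). Must be >= 1.
#' @param max_predictions Optional cap: keep only the best-supported
#'   predictions (largest completed clique first, ties broken
#'   lexicographically).
#' @export
defective_clique_params <- function(min_common = DEFAULT_MIN_COMMON,
                                    max_predictions = NULL) {
  if (!is.numeric(min_common) || min_common < 1) {
    stop("min_common must be an integer >= 1")
  }
  structure(list(min_common = as.integer(min_common),
                 max_predictions = max_predictions),
            class = "defective_clique_params")
}

#' Predict false-negative interactions by defective-clique completion
#'
#' A defective clique is a near-clique missing exactly one edge. A
#' non-adjacent protein pair (u, v) is predicted as a missing interaction
#' when the common neighbourhood of u and v contains a clique of at least
#' `min_common` proteins, so that adding (u, v) completes a clique of size
#' `min_common + 2`. Self-loops are ignored. The search enumerates cliques
#' inside each common neighbourhood, which stays small at the scale of
#' curated PPI subnetworks.
#'
#' @param net A `ppin` object.
#' @param params A [defective_clique_params()].
#' @return Data frame of predicted pairs, columns `a`, `b`,
#'   `completed_clique` (size of the largest clique the pair completes),
#'   sorted by completed-clique size descending then lexicographically.
#' @export
predict_false_negatives <- function(net, params = defective_clique_params()) {
  stopifnot(inherits(params, "defective_clique_params"))
  g <- as_igraph(net, loops = FALSE)
  nodes <- net$nodes
  adj <- lapply(nodes, function(v) names(igraph::neighbors(g, v)))
  names(adj) <- nodes
  out <- list()
  n <- length(nodes)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      u <- nodes[j]; v <- nodes[i]  # u < v lexicographically
      if (v %in% adj[[u]]) next
      common <- intersect(adj[[u]], adj[[v]])
      if (length(common) < params$min_common) next
      k <- igraph::clique_num(igraph::induced_subgraph(g, common))
      if (k >= params$min_common) {
        out[[length(out) + 1L]] <- data.frame(
          a = u, b = v, completed_clique = k + 2L, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(a = character(), b = character(),
                      completed_clique = integer(), stringsAsFactors = FALSE))
  }
  pred <- do.call(rbind, out)
  pred <- pred[order(-pred$completed_clique, pred$a, pred$b), , drop = FALSE]
  rownames(pred) <- NULL
  if (!is.null(params$max_predictions)) {
    pred <- utils::head(pred, params$max_predictions)
  }
  pred
}

#' Suggested defective-clique parameter for a network
#'
#' Returns the knowledge base's frozen default for the minimum common-clique
#' size (see `scripts/calibration.R` for how it was fixed). Degenerate
#' networks fall back to the minimum legal value.
#'
#' @param net A `ppin` object.
#' @return An integer >= 1, deterministic for a given network.
#' @export
suggest_defective_clique_param <- function(net) {
  if (n_edges(net) == 0) return(1L)
  DEFAULT_MIN_COMMON
}

#' Add predicted interactions to a network
#'
#' New edges receive synthesised interaction identifiers `PRED-1`,
#' `PRED-2`, ... in order, are flagged non-core, and the operation is
#' recorded in the network's provenance.
#'
#' @param net A `ppin` object.
#' @param edges Data frame with columns `a`, `b`: non-adjacent pairs of
#'   existing nodes. Adding an already existing edge is an error.
#' @return The augmented network.
#' @export
apply_additions <- function(net, edges) {
  if (nrow(edges) == 0) return(net)
  stopifnot(all(c(edges$a, edges$b) %in% net$nodes))
  key_new <- edge_key(edges$a, edges$b)
  clash <- key_new %in% ppin_edge_keys(net)
  if (any(clash)) {
    stop(sprintf("edge %s-%s already exists in the network",
                 edges$a[which(clash)[1]], edges$b[which(clash)[1]]))
  }
  if (anyDuplicated(key_new)) stop("duplicate pairs in added edge list")
  start <- sum(grepl("^PRED-", unlist(net$edges$ids, use.names = FALSE)))
  add <- data.frame(a = pmin(edges$a, edges$b), b = pmax(edges$a, edges$b),
                    stringsAsFactors = FALSE)
  add$ids <- as.list(sprintf("PRED-%d", start + seq_len(nrow(add))))
  add$core <- if (anyNA(net$edges$core)) NA else FALSE
  out <- rbind(net$edges, add)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  net$edges <- out
  net$provenance <- c(net$provenance,
                      list(sprintf("apply_additions(%d predicted edges)", nrow(add))))
  net
}

#' False-positive filter policy
#'
#' Exactly one of `top_k` and `threshold` must be given. Under the
#' betweenness score high-scoring edges are suspect; under the combined
#' topological score low-scoring edges are.
#'
#' @param score_kind `"betweenness"`, `"combined"`, or
#'   `"clustering-coefficient"` (edge score = mean endpoint coefficient;
#'   low values are suspect, as for the combined score).
#' @param top_k Remove the k most extreme edges by rank.
#' @param threshold Score cutoff (exceeded for betweenness, undercut for
#'   the other kinds).
#' @param protect_core Exclude core-flagged edges from removal.
#' @export
fp_filter_policy <- function(score_kind = c("betweenness", "combined",
                                            "clustering-coefficient"),
                             top_k = NULL, threshold = NULL,
                             protect_core = FALSE) {
  score_kind <- match.arg(score_kind)
  if (is.null(top_k) == is.null(threshold)) {
    stop("exactly one of top_k and threshold must be set")
  }
  structure(list(score_kind = score_kind, top_k = top_k,
                 threshold = threshold, protect_core = protect_core),
            class = "fp_filter_policy")
}

default_bc_policy <- function() fp_filter_policy("betweenness", top_k = DEFAULT_BC_TOP_K)

#' Flag candidate false-positive interactions
#'
#' Scores every edge under the policy's metric and flags the most extreme
#' ones: highest betweenness or lowest combined score, either the `top_k`
#' most extreme or all beyond the threshold. Ties break lexicographically
#' on the edge's endpoints so the selection is deterministic.
#'
#' @param net A `ppin` object.
#' @param policy An [fp_filter_policy()]; the default is the knowledge
#'   base's frozen betweenness operating point (top 3 edges).
#' @return Data frame of flagged edges, columns `a`, `b`, `score`, most
#'   extreme first.
#' @export
flag_false_positives <- function(net, policy = default_bc_policy()) {
  stopifnot(inherits(policy, "fp_filter_policy"))
  scores <- switch(policy$score_kind,
                   betweenness = edge_betweenness_scores(net),
                   combined = combined_topological_score(net),
                   "clustering-coefficient" = {
                     cc <- clustering_coefficient(net)
                     e <- net$edges[, c("a", "b"), drop = FALSE]
                     data.frame(a = e$a, b = e$b,
                                score = unname((cc[e$a] + cc[e$b]) / 2),
                                stringsAsFactors = FALSE)
                   })
  # orient so that larger `extremity` = more suspect
  extremity <- if (policy$score_kind == "betweenness") scores$score else -scores$score
  ord <- order(-extremity, scores$a, scores$b)
  scores <- scores[ord, , drop = FALSE]
  extremity <- extremity[ord]
  if (policy$protect_core) {
    core <- vapply(ppin_edge_keys(net), identity, "")
    is_core <- net$edges$core[match(edge_key(scores$a, scores$b), core)] %in% TRUE
    scores <- scores[!is_core, , drop = FALSE]
    extremity <- extremity[!is_core]
  }
  keep <- if (!is.null(policy$top_k)) {
    seq_len(min(policy$top_k, nrow(scores)))
  } else if (policy$score_kind == "betweenness") {
    which(scores$score > policy$threshold)
  } else {
    which(scores$score < policy$threshold)
  }
  out <- scores[keep, c("a", "b", "score"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Remove edges from a network
#'
#' Isolated proteins are retained: purification changes the interaction set,
#' never the protein set.
#'
#' @param net A `ppin` object.
#' @param edges Data frame with columns `a`, `b`; every pair must be an
#'   existing edge.
#' @return The reduced network.
#' @export
remove_edges <- function(net, edges) {
  if (nrow(edges) == 0) return(net)
  keys <- ppin_edge_keys(net)
  target <- edge_key(edges$a, edges$b)
  missing <- !(target %in% keys)
  if (any(missing)) {
    stop(sprintf("edge %s-%s is not present in the network",
                 edges$a[which(missing)[1]], edges$b[which(missing)[1]]))
  }
  net$edges <- net$edges[!(keys %in% target), , drop = FALSE]
  rownames(net$edges) <- NULL
  net$provenance <- c(net$provenance,
                      list(sprintf("remove_edges(%d edges)", length(target))))
  net
}

#' Audit core-interaction preservation across a purification step
#'
#' Curated core interactions are treated as near-certain; deleting them is
#' considered harmful to the biological signal, so any removal of a core
#' edge yields a `warn` verdict that the decision engine surfaces as advice
#' to change strategy or parameters.
#'
#' @param before Network annotated with core flags, prior to the step.
#' @param after Network after the step.
#' @return An `audit_report`: `delta` ([diff_networks()] result),
#'   `core_removed`, `verdict` (`"ok"`, `"warn"`, or `"not assessable"`
#'   when `before` has unknown core flags) and a rationale `message`.
#' @export
core_preservation_audit <- function(before, after) {
  delta <- diff_networks(before, after)
  if (anyNA(before$edges$core)) {
    return(structure(list(delta = delta, core_removed = NA_integer_,
                          verdict = "not assessable",
                          message = "core flags unknown: supply a core interaction list"),
                     class = "audit_report"))
  }
  cr <- delta$removed_core_count
  verdict <- if (cr > 0) "warn" else "ok"
  message <- if (cr > 0) {
    sprintf(paste("%d core interaction(s) have been deleted;",
                  "consider changing strategy and/or modifying parameters"), cr)
  } else {
    "no core interactions were removed"
  }
  structure(list(delta = delta, core_removed = as.integer(cr),
                 verdict = verdict, message = message),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat(sprintf("core preservation audit: %s (%s)\n", x$verdict, x$message))
  invisible(x)
}
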