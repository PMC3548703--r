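# Synthetic fixtures: every generator is a pure function of its parameters
# and seed, so tests need no stored data beyond the packaged DIP table.

synthetic_ids <- function(n) sprintf("p%03d", seq_len(n))

ppin_from_pairs <- function(a, b, nodes, prefix = "SYN") {
  rec <- data.frame(protein_a = a, protein_b = b,
                    interaction_id = sprintf("%s-%d", prefix, seq_along(a)),
                    stringsAsFactors = FALSE)
  net <- build_network(rec, "keep")
  # retain isolated nodes
  net$nodes <- sort(unique(c(net$nodes, nodes)))
  net
}

#' Generate a preferential-attachment (scale-free) network
#'
#' Barabasi-Albert growth: each arriving node attaches to `m` existing
#' nodes with probability proportional to their degree. Degree
#' distributions of such graphs follow a power law, emulating the topology
#' expected of cellular interaction networks.
#'
#' @param n Number of nodes (> m).
#' @param m Edges per arriving node (>= 1).
#' @param seed RNG seed; the generator is deterministic per seed.
#' @return A `ppin` with synthetic protein identifiers.
#' @export
generate_ba_graph <- function(n, m, seed) {
  if (!(n > m && m >= 1)) stop("need n > m >= 1")
  g <- withr::with_seed(as.integer(seed), {
    igraph::sample_pa(n, m = m, directed = FALSE)
  })
  ids <- synthetic_ids(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  ppin_from_pairs(ids[el[, 1]], ids[el[, 2]], ids, prefix = "BA")
}

#' Generate a planted-complex benchmark network
#'
#' Disjoint protein groups of the given sizes; within-group pairs are
#' connected with probability `p_in`, between-group pairs with `p_out`.
#' The ground-truth clustering is returned for recovery scoring.
#'
#' @param sizes Integer vector of cluster sizes.
#' @param p_in,p_out Edge probabilities, `0 <= p_out < p_in <= 1`.
#' @param seed RNG seed.
#' @return List with `net` (a `ppin`) and `truth` (a `ppi_clustering`).
#' @export
generate_planted_complexes <- function(sizes, p_in, p_out, seed) {
  if (!(p_out >= 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 <= p_out < p_in <= 1")
  }
  n <- sum(sizes)
  ids <- synthetic_ids(n)
  member <- rep(seq_along(sizes), sizes)
  pairs <- utils::combn(n, 2)
  same <- member[pairs[1, ]] == member[pairs[2, ]]
  keep <- withr::with_seed(as.integer(seed), {
    stats::runif(ncol(pairs)) < ifelse(same, p_in, p_out)
  })
  net <- ppin_from_pairs(ids[pairs[1, keep]], ids[pairs[2, keep]], ids, prefix = "PL")
  truth <- new_clustering(split(ids, member))
  list(net = net, truth = truth)
}

#' Perturb a network with false-positive and false-negative noise
#'
#' Deletes each existing edge with probability `fn_rate` and adds
#' `round(fp_rate * |E|)` random non-edges, emulating the incompleteness
#' and spurious interactions of high-throughput screens. The exact delta is
#' returned as ground truth for recovery experiments and reconciles the
#' input and output networks through [diff_networks()].
#'
#' @param net A `ppin` object.
#' @param fp_rate,fn_rate Rates in \[0, 1).
#' @param seed RNG seed.
#' @return List with `net` (perturbed) and `delta` (a `network_delta`).
#' @export
perturb_network <- function(net, fp_rate, fn_rate, seed) {
  stopifnot(fp_rate >= 0, fp_rate < 1, fn_rate >= 0, fn_rate < 1)
  before <- net
  out <- withr::with_seed(as.integer(seed), {
    drop <- stats::runif(n_edges(net)) < fn_rate
    net2 <- net
    net2$edges <- net$edges[!drop, , drop = FALSE]
    rownames(net2$edges) <- NULL
    n_add <- round(fp_rate * n_edges(net))
    if (n_add > 0 && n_nodes(net) >= 2) {
      pairs <- utils::combn(net$nodes, 2)
      keys <- edge_key(pairs[1, ], pairs[2, ])
      free <- which(!(keys %in% ppin_edge_keys(net)))
      pick <- free[sample.int(length(free), min(n_add, length(free)))]
      add <- data.frame(a = pairs[1, pick], b = pairs[2, pick],
                        stringsAsFactors = FALSE)
      add$ids <- as.list(sprintf("FP-%d", seq_len(nrow(add))))
      add$core <- if (anyNA(net$edges$core)) NA else FALSE
      net2$edges <- rbind(net2$edges, add)
      net2$edges <- net2$edges[order(net2$edges$a, net2$edges$b), , drop = FALSE]
      rownames(net2$edges) <- NULL
    }
    net2
  })
  out$provenance <- c(out$provenance,
                      list(sprintf("perturb_network(fp=%g, fn=%g, seed=%d)",
                                   fp_rate, fn_rate, as.integer(seed))))
  list(net = out, delta = diff_networks(before, out))
}

#' Generate annotations aligned to a ground-truth clustering
#'
#' One synthetic term per true cluster, annotating a `coverage` fraction of
#' its members (at least one); the universe is the full node set. A local
#' stand-in for an ontology annotation database, constructed so each
#' cluster's best enrichment term is its own planted term.
#'
#' @param truth A `ppi_clustering` (its clusters and singletons form the
#'   universe).
#' @param coverage Fraction in (0, 1\] of each cluster to annotate.
#' @param seed RNG seed (selects which members are annotated).
#' @return An [annotation_map()].
#' @export
generate_annotations <- function(truth, coverage, seed) {
  stopifnot(coverage > 0, coverage <= 1)
  universe <- clustering_members(truth)
  terms <- withr::with_seed(as.integer(seed), {
    lapply(truth$clusters, function(members) {
      k <- max(1L, round(coverage * length(members)))
      sort(sample(members, k))
    })
  })
  names(terms) <- sprintf("planted_term_%s", names(truth$clusters))
  annotation_map(terms, universe)
}

#' Calibration sweep for the frozen knowledge-base defaults
#'
#' Evaluates a parameter grid on the packaged DIP yeast subnetwork and
#' reports which values reproduce a named reference outcome. Used once to
#' freeze the defaults in the knowledge base; kept as a first-class
#' operation so the freezing procedure is reproducible.
#'
#' @param target One of `"fn-edges=1"` (defective-clique completions),
#'   `"fp-removed=3"` (betweenness filter flags), `"mcl-reference-clusters"` (matched
#'   reference cluster sets), `"mcode-reference-complex"` (reference complex found).
#' @param grid Numeric vector of parameter values (min_common, top_k,
#'   inflation, or vwp respectively).
#' @return Data frame with the grid value, the measured outcome and
#'   whether it reproduces the reference.
#' @export
calibration_sweep <- function(target = c("fn-edges=1", "fp-removed=3",
                                         "mcl-reference-clusters", "mcode-reference-complex"),
                              grid) {
  target <- match.arg(target)
  if (length(grid) == 0) stop("empty calibration grid")
  net <- dip_yeast_subnet()
  aug <- apply_additions(net, predict_false_negatives(
    net, defective_clique_params(DEFAULT_MIN_COMMON, DEFAULT_MAX_PREDICTIONS)))
  ref_clusters <- reference_cluster_sets()
  rows <- lapply(grid, function(x) {
    switch(target,
      "fn-edges=1" = {
        np <- nrow(predict_false_negatives(net, defective_clique_params(x)))
        data.frame(value = x, outcome = np, reproduces = np == 1L)
      },
      "fp-removed=3" = {
        nf <- nrow(flag_false_positives(aug, fp_filter_policy("betweenness", top_k = x)))
        data.frame(value = x, outcome = nf, reproduces = nf == 3L)
      },
      "mcl-reference-clusters" = {
        cl <- mcl(aug, mcl_params(inflation = x))
        got <- vapply(cluster_sets(cl), function(s) paste(s, collapse = ","), "")
        want <- vapply(ref_clusters, function(s) paste(s, collapse = ","), "")
        hits <- sum(want %in% got)
        data.frame(value = x, outcome = hits, reproduces = hits == length(want))
      },
      "mcode-reference-complex" = {
        cx <- mcode_complexes(mcode(aug, mcode_params(vwp = x)))
        got <- vapply(cx, function(s) paste(s, collapse = ","), "")
        want <- paste(sort(c("abp1", "app1", "rvs167", "act1", "yor284w", "ysc84")),
                      collapse = ",")
        data.frame(value = x, outcome = as.integer(want %in% got),
                   reproduces = want %in% got)
      })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Reference multi-member cluster sets of the published system-output table
# for the Detect Defective Cliques + MCL workflow.
reference_cluster_sets <- function() {
  lapply(list(
    c("app1", "swe1", "hsl7"),
    c("act1", "srv2", "bnr1", "bni1", "cof1", "trm5", "aip1"),
    c("sla2", "abp1", "yor284w", "rvs167", "ysc84", "sla1", "ynl086w",
      "ypl246c", "rvs161", "acf2", "ybr108w", "yjr083c", "ygr268c",
      "ypr171w", "yhr133c"),
    c("cap2", "gic2"),
    c("crn1", "svl3")), sort)
}
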