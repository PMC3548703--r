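#' Degree distribution of a PPI network
#'
#' @param net A `ppin` object.
#' @param count_self_loops If `TRUE` a self-loop contributes 2 to its node's
#'   degree, the usual graph-theoretic convention; if `FALSE` (default)
#'   loops are ignored.
#' @return A `degree_distribution`: list with `counts` (named integer map,
#'   degree -> number of nodes), `n_nodes`, and `includes_self_loops`.
#' @export
degree_distribution <- function(net, count_self_loops = FALSE) {
  g <- as_igraph(net, loops = count_self_loops)
  d <- igraph::degree(g, loops = count_self_loops)
  counts <- table(d)
  structure(
    list(counts = stats::setNames(as.integer(counts), names(counts)),
         n_nodes = n_nodes(net),
         includes_self_loops = count_self_loops),
    class = "degree_distribution"
  )
}

#' Scale-free decision criterion
#'
#' The decision rule used by [is_scale_free()]: a network is called
#' scale-free when a least-squares fit of log(count) against log(degree)
#' over degrees >= `xmin` explains at least `r2_min` of the variance, the
#' fitted exponent lies in `gamma_range`, and the network has at least
#' `min_nodes` nodes. The object is pluggable so an alternative test (e.g.
#' a maximum-likelihood/KS variant) can be substituted.
#'
#' @param min_nodes Minimum network size for the decision to be assessable.
#' @param xmin Lower degree cutoff for the fit.
#' @param r2_min Minimum R-squared of the log-log fit.
#' @param gamma_range Admissible range for the fitted exponent.
#' @export
scale_free_criterion <- function(min_nodes = 20, xmin = 1, r2_min = 0.80,
                                 gamma_range = c(1.5, 3.5)) {
  structure(list(min_nodes = min_nodes, xmin = xmin, r2_min = r2_min,
                 gamma_range = gamma_range,
                 label = sprintf("log-log LS fit: R2>=%.2f, gamma in [%.1f,%.1f], n>=%d",
                                 r2_min, gamma_range[1], gamma_range[2], min_nodes)),
            class = "scale_free_criterion")
}

#' Test whether a network's degree distribution follows a power law
#'
#' Fits `log(count) ~ log(degree)` by least squares over degrees at or above
#' the criterion's cutoff and applies the criterion's decision rule. Biological
#' networks are expected to approximate a scale-free topology; a negative
#' verdict is what triggers the preprocessing advice in the decision engine.
#'
#' @param net A `ppin` object.
#' @param criterion A [scale_free_criterion()].
#' @return A `power_law_fit`: `gamma` (estimated exponent), `xmin`,
#'   `goodness` (R-squared in \[0,1\]), `decided_scale_free` (logical, `NA`
#'   when the network is below the criterion's minimum size), `criterion`,
#'   and a human-readable `rationale`.
#' @export
is_scale_free <- function(net, criterion = scale_free_criterion()) {
  dd <- degree_distribution(net, count_self_loops = FALSE)
  deg <- as.integer(names(dd$counts))
  cnt <- dd$counts
  keep <- deg >= criterion$xmin & cnt > 0
  deg <- deg[keep]; cnt <- cnt[keep]
  gamma <- NA_real_; r2 <- NA_real_
  if (length(deg) >= 3) {
    fit <- stats::lm(log(cnt) ~ log(deg))
    gamma <- -unname(stats::coef(fit)[2])
    r2 <- summary(fit)$r.squared
  }
  if (n_nodes(net) < criterion$min_nodes) {
    decided <- NA
    rationale <- sprintf("network too small for a scale-free assessment (%d < %d nodes)",
                         n_nodes(net), criterion$min_nodes)
  } else if (length(deg) < 3) {
    decided <- FALSE
    rationale <- "fewer than 3 distinct degrees: no power-law tail to fit"
  } else {
    decided <- r2 >= criterion$r2_min &&
      gamma >= criterion$gamma_range[1] && gamma <= criterion$gamma_range[2]
    rationale <- sprintf(
      "log-log fit: gamma=%.2f, R2=%.2f (%s) -> %sscale-free",
      gamma, r2, criterion$label, if (decided) "" else "not ")
  }
  structure(
    list(gamma = gamma, xmin = criterion$xmin, goodness = r2,
         decided_scale_free = decided, criterion = criterion,
         rationale = rationale),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(x$rationale, "\n")
  invisible(x)
}

#' Edge betweenness scores
#'
#' Raw (unnormalised) shortest-path betweenness of every edge, with
#' fractional credit when a node pair has several shortest paths. Self-loops
#' never lie on a shortest path and score 0. Interactions bridging otherwise
#' distant parts of the network score high and are candidate false positives.
#'
#' @param net A `ppin` object.
#' @return An `edge_score_map`: data.frame with columns `a`, `b`, `score`,
#'   plus a `score_kind` attribute.
#' @export
edge_betweenness_scores <- function(net) {
  e <- net$edges[, c("a", "b"), drop = FALSE]
  loops <- e$a == e$b
  score <- numeric(nrow(e))
  if (any(!loops)) {
    g <- as_igraph(net, loops = FALSE)
    eb <- igraph::edge_betweenness(g, directed = FALSE)
    ends <- igraph::as_edgelist(g)
    key <- edge_key(ends[, 1], ends[, 2])
    score[!loops] <- eb[match(edge_key(e$a[!loops], e$b[!loops]), key)]
  }
  out <- data.frame(a = e$a, b = e$b, score = score, stringsAsFactors = FALSE)
  attr(out, "score_kind") <- "betweenness"
  class(out) <- c("edge_score_map", class(out))
  out
}

#' Local clustering coefficient of every node
#'
#' For a node of degree k >= 2 (loops excluded): 2 * triangles / (k (k-1));
#' degree below 2 yields 0.
#'
#' @param net A `ppin` object.
#' @return Named numeric vector over all nodes, values in \[0, 1\].
#' @export
clustering_coefficient <- function(net) {
  g <- as_igraph(net, loops = FALSE)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  stats::setNames(cc, igraph::V(g)$name)[net$nodes]
}

#' Combined topological edge score
#'
#' Geometric mean of the two purification metrics after min-max
#' normalisation to \[0, 1\] over the network: edge betweenness, and an
#' edge-level clustering coefficient taken as the mean of the endpoint
#' coefficients. Edges of dense, mutually clustered neighbourhoods score
#' high; low combined scores mark suspect interactions.
#'
#' @param net A `ppin` object.
#' @return An `edge_score_map` with `score_kind = "combined"`.
#' @export
combined_topological_score <- function(net) {
  bt <- edge_betweenness_scores(net)
  cc <- clustering_coefficient(net)
  edge_cc <- (cc[bt$a] + cc[bt$b]) / 2
  norm01 <- function(x) {
    r <- range(x)
    if (diff(r) == 0) return(rep(0, length(x)))
    (x - r[1]) / diff(r)
  }
  out <- data.frame(a = bt$a, b = bt$b,
                    score = sqrt(norm01(bt$score) * norm01(unname(edge_cc))),
                    stringsAsFactors = FALSE)
  attr(out, "score_kind") <- "combined"
  class(out) <- c("edge_score_map", class(out))
  out
}

#' Maximum k-core of a network
#'
#' @param net A `ppin` object (self-loops ignored).
#' @return List with `k`, the largest k such that a subgraph with all
#'   degrees >= k exists, and `members`, the node set of that k-core.
#'   The empty graph yields `k = 0` and an empty member set.
#' @export
kcore_number <- function(net) {
  if (n_nodes(net) == 0) return(list(k = 0L, members = character()))
  g <- as_igraph(net, loops = FALSE)
  cores <- igraph::coreness(g)
  k <- max(cores)
  list(k = as.integer(k), members = sort(igraph::V(g)$name[cores == k]))
}
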