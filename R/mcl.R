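#' Parameters for Markov clustering
#'
#' @param inflation Entry-wise matrix power applied each iteration; larger
#'   values sharpen flow and yield finer clusters. Must be > 1.
#' @param expansion Matrix power simulating flow spreading (>= 2).
#' @param add_self_loops Add a unit loop to every node before normalising,
#'   the usual regularisation that guarantees convergence.
#' @param prune_threshold Entries below this value are dropped after each
#'   inflation to keep the matrix sparse.
#' @param max_iter Iteration cap.
#' @param convergence_tol Stop when the largest entry change falls below
#'   this tolerance.
#' @export
mcl_params <- function(inflation = 2.0, expansion = 2L, add_self_loops = TRUE,
                       prune_threshold = 1e-5, max_iter = 200L,
                       convergence_tol = 1e-6) {
  stopifnot(inflation > 1, expansion >= 2, convergence_tol > 0,
            prune_threshold >= 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 add_self_loops = add_self_loops,
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter),
                 convergence_tol = convergence_tol),
            class = "mcl_params")
}

#' @export
format.mcl_params <- function(x, ...) {
  sprintf("mcl(inflation=%g, expansion=%d, loops=%s, prune=%g)",
          x$inflation, x$expansion, x$add_self_loops, x$prune_threshold)
}

#' Markov clustering (MCL) of a PPI network
#'
#' Simulates random-walk flow on the network: the column-stochastic
#' transition matrix is alternately expanded (matrix power, letting flow
#' spread) and inflated (entry-wise power with column renormalisation,
#' strengthening strong currents), with small entries pruned, until the
#' matrix reaches its attractor structure. Clusters are read off as the
#' connected components of the limit matrix's support, which merges
#' overlapping attractor systems and so always yields a partition of the
#' node set. Nodes are indexed in sorted order, making the result
#' independent of input ordering.
#'
#' @param net A non-empty `ppin` object (self-loops in the data are ignored;
#'   regularising loops are controlled by the params).
#' @param params An [mcl_params()].
#' @return A `ppi_clustering`; its provenance records the parameters and a
#'   `converged` flag (best-effort clustering is returned if the iteration
#'   cap is hit).
#' @export
mcl <- function(net, params = mcl_params()) {
  stopifnot(inherits(params, "mcl_params"), n_nodes(net) > 0)
  nodes <- net$nodes
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  if (nrow(e) > 0) {
    ia <- match(e$a, nodes); ib <- match(e$b, nodes)
    A[cbind(ia, ib)] <- 1
    A[cbind(ib, ia)] <- 1
  }
  if (params$add_self_loops) diag(A) <- 1
  zero <- colSums(A) == 0
  if (any(zero)) diag(A)[zero] <- 1  # isolated node without loops: fix it on itself
  M <- sweep(A, 2, colSums(A), "/")
  converged <- FALSE
  for (it in seq_len(params$max_iter)) {
    Mx <- M
    for (p in seq_len(params$expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx ^ params$inflation
    Mx[Mx < params$prune_threshold] <- 0
    csx <- colSums(Mx)
    dead <- csx == 0
    if (any(dead)) {  # fully pruned column: park the node on itself
      Mx[cbind(which(dead), which(dead))] <- 1
      csx[dead] <- 1
    }
    Mx <- sweep(Mx, 2, csx, "/")
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < params$convergence_tol) { converged <- TRUE; break }
  }
  supp <- (M > 1e-9) | t(M > 1e-9)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(supp, mode = "undirected"))
  groups <- split(nodes, comp$membership)
  out <- new_clustering(groups, provenance = list(format(params)))
  out$provenance <- c(out$provenance, list(sprintf("converged=%s", converged)))
  out$converged <- converged
  out
}
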