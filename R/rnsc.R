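#' Parameters for restricted neighbourhood search clustering (RNSC)
#'
#' @param initial_clusters Number of clusters in the random initial
#'   partition, or `"random"` to pick `max(2, round(n/5))`.
#' @param tabu_length Number of steps a just-moved vertex may not move again.
#' @param diversification_period Every this many steps a random vertex is
#'   moved to a random cluster to escape local basins.
#' @param max_no_improve Stop a search phase after this many consecutive
#'   steps without improving the phase's best cost.
#' @param restarts Independent restarts; the lowest-cost clustering wins.
#' @param seed Mandatory RNG seed: there is no hidden global randomness.
#' @export
rnsc_params <- function(initial_clusters = "random", tabu_length = 3L,
                        diversification_period = 20L, max_no_improve = 30L,
                        restarts = 1L, seed) {
  if (missing(seed)) stop("rnsc_params requires an explicit seed")
  stopifnot(restarts >= 1, tabu_length >= 0)
  structure(list(initial_clusters = initial_clusters,
                 tabu_length = as.integer(tabu_length),
                 diversification_period = as.integer(diversification_period),
                 max_no_improve = as.integer(max_no_improve),
                 restarts = as.integer(restarts), seed = as.integer(seed)),
            class = "rnsc_params")
}

#' @export
format.rnsc_params <- function(x, ...) {
  sprintf("rnsc(restarts=%d, seed=%d, tabu=%d)", x$restarts, x$seed, x$tabu_length)
}

#' RNSC clustering cost
#'
#' The naive cost counts each "bad" relation once: non-adjacent pairs that
#' share a cluster plus adjacent pairs split across clusters, i.e. one half
#' of the per-vertex sum of alpha_v = (non-neighbours of v in v's cluster) +
#' (neighbours of v outside it). The scaled cost divides each alpha_v by the
#' size of v's closed neighbourhood united with its cluster, scaled by
#' (n-1)/3, de-emphasising high-degree vertices.
#'
#' @param net A `ppin` object (self-loops ignored).
#' @param clustering A `ppi_clustering` that partitions the network's nodes.
#' @param kind `"naive"` or `"scaled"`.
#' @return A non-negative number.
#' @export
rnsc_cost <- function(net, clustering, kind = c("naive", "scaled")) {
  kind <- match.arg(kind)
  nodes <- net$nodes
  groups <- c(cluster_sets(clustering), as.list(clustering$singletons))
  members <- unlist(groups, use.names = FALSE)
  if (length(members) != length(nodes) || !setequal(members, nodes) ||
      anyDuplicated(members) > 0) {
    stop("clustering is not a partition of the network's nodes")
  }
  m <- integer(length(nodes))
  names(m) <- nodes
  for (i in seq_along(groups)) m[groups[[i]]] <- i
  g <- as_igraph(net, loops = FALSE)
  adj <- lapply(nodes, function(v) names(igraph::neighbors(g, v)))
  names(adj) <- nodes
  sizes <- tabulate(m, nbins = length(groups))
  alpha <- vapply(nodes, function(v) {
    din <- sum(m[adj[[v]]] == m[v])
    (sizes[m[v]] - 1 - din) + (length(adj[[v]]) - din)
  }, numeric(1))
  if (kind == "naive") return(sum(alpha) / 2)
  n <- length(nodes)
  denom <- vapply(nodes, function(v) {
    din <- sum(m[adj[[v]]] == m[v])
    sizes[m[v]] + (length(adj[[v]]) - din)
  }, numeric(1))
  (n - 1) / 3 * sum(alpha / denom)
}

# One tabu-descent phase over vertex moves. cost_kind selects the objective.
# Returns list(m = best membership, cost = best cost).
rnsc_phase <- function(adj_idx, deg, n, m, params, cost_kind, nedges) {
  kmax <- max(m) + 1L
  sizes <- tabulate(m, nbins = kmax)
  din <- vapply(seq_len(n), function(v) sum(m[adj_idx[[v]]] == m[v]), integer(1))

  naive_cost <- function() {
    intra <- sum(din) / 2
    sum(choose(sizes, 2)) - intra + (nedges - intra)
  }
  scaled_cost <- function() {
    alpha <- (sizes[m] - 1 - din) + (deg - din)
    (n - 1) / 3 * sum(alpha / (sizes[m] + deg - din))
  }
  cost <- if (cost_kind == "naive") naive_cost() else scaled_cost()

  apply_move <- function(v, B) {
    A <- m[v]
    for (u in adj_idx[[v]]) {
      if (m[u] == A) din[u] <<- din[u] - 1L
      if (m[u] == B) din[u] <<- din[u] + 1L
    }
    din[v] <<- sum(m[adj_idx[[v]]] == B)
    sizes[A] <<- sizes[A] - 1L
    sizes[B] <<- sizes[B] + 1L
    m[v] <<- B
    if (B == kmax || sizes[A] == 0L) {   # renumber, keep one empty slot
      used <- which(sizes > 0L)
      remap <- integer(kmax)
      remap[used] <- seq_along(used)
      m <<- remap[m]
      sizes <<- tabulate(m, nbins = length(used) + 1L)
      kmax <<- length(used) + 1L
    }
  }

  move_delta <- function(v) {
    # delta of the objective for moving v to every cluster 1..kmax
    A <- m[v]
    dv <- tabulate(m[adj_idx[[v]]], nbins = kmax)
    if (cost_kind == "naive") {
      delta <- (sizes - dv) - (sizes[A] - 1L - dv[A]) + dv[A] - dv
      delta[A] <- Inf
      return(delta)
    }
    # scaled: recompute affected terms per target cluster
    base_v <- ((sizes[A] - 1 - dv[A]) + (deg[v] - dv[A])) /
      (sizes[A] + deg[v] - dv[A])
    nb <- adj_idx[[v]]
    delta <- rep(Inf, kmax)
    for (B in seq_len(kmax)) {
      if (B == A) next
      d <- 0
      # v's own term
      new_v <- ((sizes[B] + 1 - 1 - dv[B]) + (deg[v] - dv[B])) /
        (sizes[B] + 1 + deg[v] - dv[B])
      d <- d + new_v - base_v
      # members of A and B whose alpha/denominator change
      for (u in which(m == A | m == B)) {
        if (u == v) next
        is_nb <- u %in% nb
        a_old <- (sizes[m[u]] - 1 - din[u]) + (deg[u] - din[u])
        den_old <- sizes[m[u]] + deg[u] - din[u]
        if (m[u] == A) {
          s_new <- sizes[A] - 1L
          din_new <- din[u] - (if (is_nb) 1L else 0L)
        } else {
          s_new <- sizes[B] + 1L
          din_new <- din[u] + (if (is_nb) 1L else 0L)
        }
        a_new <- (s_new - 1 - din_new) + (deg[u] - din_new)
        den_new <- s_new + deg[u] - din_new
        d <- d + a_new / den_new - a_old / den_old
      }
      delta[B] <- (n - 1) / 3 * d
    }
    delta
  }

  best_m <- m
  best_cost <- cost
  tabu_until <- integer(n)
  step <- 0L
  no_improve <- 0L
  while (no_improve < params$max_no_improve) {
    step <- step + 1L
    if (params$diversification_period > 0 &&
        step %% params$diversification_period == 0L) {
      v <- sample.int(n, 1)
      B <- sample.int(kmax, 1)
      if (B != m[v]) apply_move(v, B)
      cost <- if (cost_kind == "naive") naive_cost() else scaled_cost()
    } else {
      movable <- which(tabu_until < step)
      if (length(movable) == 0) movable <- seq_len(n)
      best_d <- Inf; best_v <- 0L; best_B <- 0L
      for (v in movable) {
        delta <- move_delta(v)
        j <- which.min(delta)
        if (delta[j] < best_d) { best_d <- delta[j]; best_v <- v; best_B <- j }
      }
      if (best_v == 0L || !is.finite(best_d)) break
      apply_move(best_v, best_B)
      tabu_until[best_v] <- step + params$tabu_length
      cost <- cost + best_d
    }
    if (cost < best_cost - 1e-9) {
      best_cost <- cost
      best_m <- m
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
  }
  list(m = best_m, cost = best_cost)
}

#' RNSC: restricted neighbourhood search clustering
#'
#' Cost-based partitioning: starting from a seeded random partition, the
#' search repeatedly applies the best single-vertex move (steepest descent
#' over the move neighbourhood, a short tabu list preventing immediate
#' reversals, with periodic random diversification moves), first under the
#' integer-valued naive cost and then, from the naive optimum, under the
#' scaled cost. The best clustering over all restarts is returned.
#' Reproducible for a fixed seed; restart r uses seed + r - 1.
#'
#' @param net A non-empty `ppin` object (self-loops ignored).
#' @param params An [rnsc_params()].
#' @return A `ppi_clustering` with extra fields `naive_cost`, `scaled_cost`
#'   and `initial_cost` (naive cost of the random start of the winning
#'   restart).
#' @export
rnsc <- function(net, params) {
  stopifnot(inherits(params, "rnsc_params"), n_nodes(net) > 0)
  nodes <- net$nodes
  n <- length(nodes)
  g <- as_igraph(net, loops = FALSE)
  adj_idx <- lapply(nodes, function(v)
    match(names(igraph::neighbors(g, v)), nodes))
  deg <- lengths(adj_idx)
  nedges <- sum(deg) / 2
  k0 <- if (identical(params$initial_clusters, "random"))
    max(2L, as.integer(round(n / 5))) else as.integer(params$initial_clusters)
  k0 <- min(k0, n)

  best <- NULL
  for (r in seq_len(params$restarts)) {
    run <- withr::with_seed(params$seed + r - 1L, {
      m0 <- sample.int(k0, n, replace = TRUE)
      m0 <- match(m0, sort(unique(m0)))
      init <- rnsc_phase(adj_idx, deg, n, m0, params, "naive", nedges)
      scaled <- rnsc_phase(adj_idx, deg, n, init$m, params, "scaled", nedges)
      list(m0 = m0, naive = init, scaled = scaled)
    })
    if (is.null(best) || run$scaled$cost < best$scaled$cost - 1e-9) best <- run
  }
  groups <- split(nodes, best$scaled$m)
  out <- new_clustering(groups, provenance = list(format(params)))
  out$naive_cost <- {
    cl <- new_clustering(split(nodes, best$naive$m))
    rnsc_cost(net, cl, "naive")
  }
  out$scaled_cost <- best$scaled$cost
  out$initial_cost <- rnsc_cost(net, new_clustering(split(nodes, best$m0)), "naive")
  out
}
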