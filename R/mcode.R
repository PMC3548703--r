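#' Parameters for MCODE complex prediction
#'
#' @param vwp Vertex weight percentage in \[0, 1): how far below the seed's
#'   weight a neighbour's weight may fall and still be recruited.
#' @param haircut Iteratively remove complex members with fewer than two
#'   within-complex neighbours.
#' @param fluff Add boundary neighbours whose closed-neighbourhood density
#'   exceeds `fluff_density`.
#' @param fluff_density Density cutoff for fluffing, in \[0, 1\].
#' @export
mcode_params <- function(vwp = DEFAULT_MCODE_VWP, haircut = TRUE,
                         fluff = FALSE, fluff_density = 0.5) {
  stopifnot(vwp >= 0, vwp < 1, fluff_density >= 0, fluff_density <= 1)
  structure(list(vwp = vwp, haircut = haircut, fluff = fluff,
                 fluff_density = fluff_density),
            class = "mcode_params")
}

#' @export
format.mcode_params <- function(x, ...) {
  sprintf("mcode(vwp=%g, haircut=%s, fluff=%s)", x$vwp, x$haircut, x$fluff)
}

graph_density <- function(g) {
  nv <- igraph::vcount(g)
  if (nv < 2) return(0)
  2 * igraph::ecount(g) / (nv * (nv - 1))
}

#' MCODE: molecular complex detection
#'
#' Predicts dense complexes from local graph properties, in three stages.
#' Vertex weighting scores each protein by the highest k-core of its closed
#' neighbourhood times that core's density, so proteins embedded in dense
#' local cliques weigh most. Complex prediction then grows a complex from
#' the highest-weight unvisited seed, recruiting neighbours whose weight is
#' within `vwp` of the seed's; each protein joins at most one complex.
#' Post-processing optionally trims weakly attached members (haircut) and
#' absorbs dense boundary neighbours (fluff). Unassigned proteins are simply
#' not part of any complex: the result is a ranked complex list, not a
#' partition.
#'
#' @param net A `ppin` object; self-loops are ignored.
#' @param params An [mcode_params()].
#' @return An `mcode_result`: list of complexes ordered by non-increasing
#'   score, each with `members`, `seed` and `score` (density x size of the
#'   induced subgraph).
#' @export
mcode <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  g <- as_igraph(net, loops = FALSE)
  nodes <- net$nodes
  adj <- lapply(nodes, function(v) sort(names(igraph::neighbors(g, v))))
  names(adj) <- nodes

  weights <- vapply(nodes, function(v) {
    nb <- c(v, adj[[v]])
    sub <- igraph::induced_subgraph(g, nb)
    k <- igraph::coreness(sub)
    kmax <- max(k)
    if (kmax == 0) return(0)
    core <- igraph::induced_subgraph(sub, igraph::V(sub)[k >= kmax])
    kmax * graph_density(core)
  }, numeric(1))

  seen <- stats::setNames(rep(FALSE, length(nodes)), nodes)
  complexes <- list()
  for (seed in names(sort(weights, decreasing = TRUE))) {
    if (seen[seed]) next
    thr <- weights[seed] * (1 - params$vwp)
    members <- seed
    seen[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0) {
      nxt <- character()
      for (u in frontier) {
        for (x in adj[[u]]) {
          if (!seen[x] && weights[x] >= thr) {
            members <- c(members, x)
            seen[x] <- TRUE
            nxt <- c(nxt, x)
          }
        }
      }
      frontier <- nxt
    }
    if (params$haircut && length(members) > 2) {
      repeat {
        indeg <- vapply(members, function(v) sum(adj[[v]] %in% members), integer(1))
        if (all(indeg >= 2) || length(members) <= 2) break
        members <- members[indeg >= 2]
      }
    }
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)), members)
      for (b in boundary) {
        nb <- igraph::induced_subgraph(g, c(b, adj[[b]]))
        if (graph_density(nb) > params$fluff_density) members <- c(members, b)
      }
      members <- unique(members)
    }
    if (length(members) < 2) next
    # keep the connected component containing the seed
    sub <- igraph::induced_subgraph(g, members)
    comp <- igraph::components(sub)
    seed_comp <- comp$membership[match(seed, igraph::V(sub)$name)]
    if (is.na(seed_comp)) seed_comp <- which.max(comp$csize)
    members <- sort(igraph::V(sub)$name[comp$membership == seed_comp])
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(g, members)
    complexes[[length(complexes) + 1L]] <- list(
      members = members, seed = seed,
      score = graph_density(sub) * length(members))
  }
  ord <- order(-vapply(complexes, `[[`, numeric(1), "score"),
               vapply(complexes, function(x) x$members[1], ""))
  structure(list(complexes = complexes[ord], params = params),
            class = "mcode_result")
}

#' @export
print.mcode_result <- function(x, ...) {
  cat(sprintf("MCODE: %d complexes [%s]\n", length(x$complexes), format(x$params)))
  for (i in seq_along(x$complexes)) {
    cx <- x$complexes[[i]]
    cat(sprintf("  %d (score %.2f, seed %s): %s\n", i, cx$score, cx$seed,
                paste(cx$members, collapse = ", ")))
  }
  invisible(x)
}

#' Member sets of an MCODE result
#' @param result An `mcode_result`.
#' @return List of character vectors, ranked by score.
#' @export
mcode_complexes <- function(result) lapply(result$complexes, `[[`, "members")
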