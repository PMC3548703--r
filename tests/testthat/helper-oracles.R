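# Brute-force oracles, independent of the implementation paths they check.

oracle_adj <- function(net) {
  nodes <- net$nodes
  A <- matrix(FALSE, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  e <- net$edges[net$edges$a != net$edges$b, , drop = FALSE]
  for (i in seq_len(nrow(e))) {
    A[e$a[i], e$b[i]] <- TRUE
    A[e$b[i], e$a[i]] <- TRUE
  }
  A
}

# Edge betweenness by explicit enumeration of every shortest path.
oracle_edge_betweenness <- function(net) {
  A <- oracle_adj(net)
  nodes <- rownames(A)
  n <- length(nodes)
  score <- stats::setNames(numeric(nrow(net$edges)),
                           paste(net$edges$a, net$edges$b, sep = "\t"))
  all_shortest <- function(s, t) {
    # BFS distances from s, then DFS back from t along decreasing distance
    dist <- rep(Inf, n); dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in which(A[v, ])) if (dist[w] > dist[v] + 1) {
        dist[w] <- dist[v] + 1; q <- c(q, w)
      }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1L]] <<- rev(acc); return(invisible()) }
      for (w in which(A[v, ])) if (dist[w] == dist[v] - 1) walk(w, c(acc, w))
    }
    walk(t, t)
    paths
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_shortest(s, t)
    if (length(paths) == 0) next
    w <- 1 / length(paths)
    for (p in paths) {
      for (i in seq_len(length(p) - 1)) {
        u <- nodes[p[i]]; v <- nodes[p[i + 1]]
        key <- paste(min(u, v), max(u, v), sep = "\t")
        score[key] <- score[key] + w
      }
    }
  }
  score
}

# Clustering coefficient by exhaustive triple enumeration.
oracle_clustering_coefficient <- function(net) {
  A <- oracle_adj(net)
  nodes <- rownames(A)
  vapply(nodes, function(v) {
    nb <- which(A[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (A[nb[i], nb[j]]) tri <- tri + 1
    }
    2 * tri / (k * (k - 1))
  }, numeric(1))
}

# Max k-core by iterative peeling.
oracle_kcore <- function(net) {
  A <- oracle_adj(net)
  nodes <- rownames(A)
  best_k <- 0L; best_members <- character()
  for (k in seq_len(length(nodes))) {
    keep <- nodes
    repeat {
      deg <- vapply(keep, function(v) sum(A[v, keep]), numeric(1))
      drop <- keep[deg < k]
      if (length(drop) == 0) break
      keep <- setdiff(keep, drop)
    }
    if (length(keep) == 0) break
    best_k <- k; best_members <- sort(keep)
  }
  list(k = best_k, members = best_members)
}

# Does the common neighbourhood of (u, v) contain a clique of size >= m?
oracle_has_common_clique <- function(net, u, v, m) {
  A <- oracle_adj(net)
  common <- rownames(A)[A[u, ] & A[v, ]]
  if (length(common) < m) return(FALSE)
  combs <- utils::combn(common, m)
  for (j in seq_len(ncol(combs))) {
    s <- combs[, j]
    ok <- TRUE
    for (x in seq_len(m - 1)) for (y in (x + 1):m) {
      if (!A[s[x], s[y]]) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Naive and scaled RNSC costs by direct double loops over vertices/pairs.
oracle_rnsc_cost <- function(net, clustering, kind = "naive") {
  A <- oracle_adj(net)
  nodes <- rownames(A)
  groups <- c(unname(clustering$clusters), as.list(clustering$singletons))
  memb <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  for (i in seq_along(groups)) memb[groups[[i]]] <- i
  alpha <- vapply(nodes, function(v) {
    same <- nodes[memb == memb[v] & nodes != v]
    sum(!A[v, same]) + sum(A[v, nodes[memb != memb[v]]])
  }, numeric(1))
  if (kind == "naive") return(sum(alpha) / 2)
  n <- length(nodes)
  denom <- vapply(nodes, function(v) {
    cl <- nodes[memb == memb[v]]
    length(union(c(v, nodes[A[v, ]]), cl))
  }, numeric(1))
  (n - 1) / 3 * sum(alpha / denom)
}

# Upper-tail hypergeometric probability by complete enumeration of draws.
oracle_hypergeom_enum <- function(k, n, K, N) {
  pop <- c(rep(TRUE, K), rep(FALSE, N - K))
  draws <- utils::combn(N, n)
  hits <- vapply(seq_len(ncol(draws)), function(j) sum(pop[draws[, j]]) >= k,
                 logical(1))
  mean(hits)
}
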