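#' Upper-tail hypergeometric p-value
#'
#' Probability of observing at least `k` annotated proteins in a cluster of
#' size `n` drawn from a universe of `N` proteins of which `K` carry the
#' annotation: the chance the cluster's functional coherence arises by
#' random draw. Computed by direct summation of the hypergeometric mass in
#' log space for numerical stability.
#'
#' @param k Annotated proteins in the cluster.
#' @param n Cluster size.
#' @param K Annotated proteins in the universe.
#' @param N Universe size.
#' @return P(X >= k), in (0, 1].
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  if (k < 0 || k > n || n > N || K > N || k > K) {
    stop("hypergeometric bounds violated: need 0 <= k <= n <= N and k <= K <= N")
  }
  if (k == 0) return(1)
  upper <- min(n, K)
  i <- k:upper
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Build an annotation map
#'
#' @param terms Named list: term -> character vector of annotated proteins.
#' @param universe Protein universe; every annotated protein must belong to
#'   it. Defaults to the union of all annotated proteins.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(terms, universe = NULL) {
  terms <- lapply(terms, function(p) sort(unique(p)))
  if (is.null(universe)) universe <- sort(unique(unlist(terms, use.names = FALSE)))
  bad <- setdiff(unlist(terms, use.names = FALSE), universe)
  if (length(bad) > 0) {
    stop(sprintf("annotated protein '%s' is not in the universe", bad[1]))
  }
  structure(list(terms = terms, universe = sort(unique(universe))),
            class = "annotation_map")
}

#' Read a term-protein annotation table
#'
#' Two tab-separated columns: term, protein. A local stand-in for live
#' ontology term-finder services.
#'
#' @param path File path.
#' @param universe Optional protein universe (defaults to annotated proteins).
#' @return An `annotation_map`.
#' @export
read_annotation_map <- function(path, universe = NULL) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("term", "protein"))
  annotation_map(split(tolower(tab$protein), tab$term), universe)
}

#' Best enriched term per cluster
#'
#' For every cluster, scans all annotation terms and reports the one with
#' the smallest upper-tail hypergeometric p-value; ties break toward the
#' larger annotated-in-cluster count and then lexicographically. Clusters
#' whose best p-value exceeds `alpha` are reported with `p_label`
#' `"> alpha"` and no term, the usual suppression convention of published
#' enrichment tables. The universe defaults to the annotation map's.
#'
#' @param clustering A `ppi_clustering`.
#' @param ann An [annotation_map()]; its universe must contain all
#'   clustered proteins.
#' @param alpha Reporting cutoff (default 0.01).
#' @return Data frame, one row per cluster: `cluster`, `best_term`, `k`,
#'   `n`, `K`, `N`, `fraction` (the printed "k/n"), `p_value`, `p_label`.
#' @export
best_term_per_cluster <- function(clustering, ann, alpha = 0.01) {
  stopifnot(inherits(ann, "annotation_map"))
  N <- length(ann$universe)
  missing <- setdiff(unlist(clustering$clusters, use.names = FALSE), ann$universe)
  if (length(missing) > 0) {
    stop(sprintf("clustered protein '%s' is outside the annotation universe", missing[1]))
  }
  rows <- lapply(names(clustering$clusters), function(cid) {
    members <- clustering$clusters[[cid]]
    n <- length(members)
    best <- NULL
    for (term in sort(names(ann$terms))) {
      prots <- ann$terms[[term]]
      k <- length(intersect(members, prots))
      K <- length(prots)
      if (k == 0) next
      p <- hypergeometric_pvalue(k, n, K, N)
      if (is.null(best) || p < best$p - 1e-15 ||
          (abs(p - best$p) <= 1e-15 && k > best$k)) {
        best <- list(term = term, k = k, K = K, p = p)
      }
    }
    if (is.null(best) || best$p > alpha) {
      k <- if (is.null(best)) 0L else best$k
      data.frame(cluster = cid, best_term = NA_character_, k = k, n = n,
                 K = if (is.null(best)) 0L else best$K, N = N,
                 fraction = sprintf("%d/%d", k, n),
                 p_value = if (is.null(best)) NA_real_ else best$p,
                 p_label = sprintf("> %g", alpha),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(cluster = cid, best_term = best$term, k = best$k, n = n,
                 K = best$K, N = N, fraction = sprintf("%d/%d", best$k, n),
                 p_value = best$p, p_label = format(best$p, digits = 3),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cluster = character(), best_term = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), fraction = character(),
                      p_value = numeric(), p_label = character(),
                      stringsAsFactors = FALSE)
  }
  out
}

#' Write an enrichment table
#'
#' TSV with columns method, proteins, fraction, p-value, mirroring the
#' layout of published complex-validation tables.
#'
#' @param results Output of [best_term_per_cluster()].
#' @param clustering The clustering the results refer to.
#' @param method Label for the method column.
#' @param path Optional output file.
#' @export
format_enrichment_table <- function(results, clustering, method = "clustering",
                                    path = NULL) {
  rows <- c("method\tproteins\tfraction\tp_value",
            vapply(seq_len(nrow(results)), function(i) {
              members <- clustering$clusters[[results$cluster[i]]]
              sprintf("%s\t%s\t%s\t%s", method,
                      paste(members, collapse = ", "),
                      results$fraction[i], results$p_label[i])
            }, ""))
  content <- paste0(paste(rows, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(content, path, sep = "")
    return(invisible(content))
  }
  content
}
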