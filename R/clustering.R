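#' Construct a clustering of a PPI network
#'
#' Multi-member clusters are named `"1"`, `"2"`, ... in the given order;
#' size-1 groups are reported separately as `singletons` and suppressed from
#' the main cluster table, mirroring how published complex tables omit
#' unassigned proteins.
#'
#' @param groups List of character vectors (protein sets).
#' @param provenance List describing the producing algorithm and parameters.
#' @return A `ppi_clustering` with elements `clusters` (named list),
#'   `singletons` (character vector) and `provenance`.
#' @export
new_clustering <- function(groups, provenance = list()) {
  groups <- lapply(groups, function(g) sort(unique(g)))
  multi <- Filter(function(g) length(g) > 1, groups)
  single <- unlist(Filter(function(g) length(g) == 1, groups), use.names = FALSE)
  # deterministic order: by decreasing size then lexicographic first member
  ord <- order(-lengths(multi), vapply(multi, `[`, "", 1))
  multi <- multi[ord]
  names(multi) <- as.character(seq_along(multi))
  structure(list(clusters = multi,
                 singletons = sort(unique(single)),
                 provenance = provenance),
            class = "ppi_clustering")
}

#' @export
print.ppi_clustering <- function(x, ...) {
  cat(sprintf("clustering: %d clusters, %d singletons\n",
              length(x$clusters), length(x$singletons)))
  for (nm in names(x$clusters)) {
    cat(sprintf("  %s\t%s\n", nm, paste(x$clusters[[nm]], collapse = ", ")))
  }
  invisible(x)
}

#' All proteins covered by a clustering (clusters plus singletons)
#' @param clustering A `ppi_clustering`.
#' @export
clustering_members <- function(clustering) {
  sort(c(unlist(clustering$clusters, use.names = FALSE), clustering$singletons))
}

cluster_sets <- function(clustering) {
  unname(lapply(clustering$clusters, identity))
}

#' Mean best-match Jaccard agreement between two clusterings
#'
#' For each cluster of `truth`, the maximum Jaccard index against any
#' cluster of `pred` (singletons of `pred` count as size-1 clusters),
#' averaged over the clusters of `truth`. 1 means perfect recovery.
#'
#' @param pred,truth `ppi_clustering` objects.
#' @export
clustering_jaccard <- function(pred, truth) {
  pc <- c(cluster_sets(pred), as.list(pred$singletons))
  tc <- cluster_sets(truth)
  if (length(tc) == 0) return(NA_real_)
  jac <- vapply(tc, function(tt) {
    max(vapply(pc, function(pp) {
      length(intersect(pp, tt)) / length(union(pp, tt))
    }, numeric(1)), 0)
  }, numeric(1))
  mean(jac)
}

#' Knowledge-base default parameters for a clustering algorithm
#'
#' Returns the frozen defaults the decision engine proposes, optionally
#' specialised per species (the yeast MCL inflation differs from the
#' generic default; see `scripts/calibration.R`).
#'
#' @param net A `ppin` object (reserved for density-aware defaults).
#' @param algorithm `"mcl"`, `"mcode"` or `"rnsc"`.
#' @param species Optional species tag, e.g. `"S.cerevisiae"`.
#' @return A parameter object of the matching class.
#' @export
suggest_clustering_params <- function(net, algorithm, species = NULL) {
  switch(algorithm,
    mcl = {
      inflation <- if (identical(species, "S.cerevisiae"))
        DEFAULT_MCL_INFLATION_YEAST else 2.0
      mcl_params(inflation = inflation)
    },
    mcode = mcode_params(vwp = DEFAULT_MCODE_VWP, haircut = TRUE, fluff = FALSE),
    rnsc = rnsc_params(seed = 1L, restarts = DEFAULT_RNSC_RESTARTS),
    stop(sprintf("unknown clustering algorithm '%s'", algorithm))
  )
}

#' Write a clustering as a TSV table
#'
#' Two columns (`cluster`, `protein`), one row per assigned protein,
#' preceded by `#`-prefixed run-metadata header lines naming the producing
#' algorithm, in the layout of published system-output tables.
#'
#' @param clustering A `ppi_clustering`.
#' @param path Optional output file.
#' @return The table content, invisibly when written to `path`.
#' @export
format_clustering_table <- function(clustering, path = NULL) {
  meta <- vapply(clustering$provenance, function(p) paste0("# ", format(p)), "")
  rows <- c(meta, "cluster\tprotein",
            unlist(lapply(names(clustering$clusters), function(nm) {
              sprintf("%s\t%s", nm, clustering$clusters[[nm]])
            })))
  content <- paste0(paste(rows, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(content, path, sep = "")
    return(invisible(content))
  }
  content
}
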