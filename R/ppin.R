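# Canonical edge key: endpoints sorted, tab-joined.
edge_key <- function(a, b) {
  swap <- a > b
  key_a <- ifelse(swap, b, a)
  key_b <- ifelse(swap, a, b)
  paste(key_a, key_b, sep = "\t")
}

new_ppin <- function(nodes, edges, self_loop_policy = "keep", provenance = list()) {
  nodes <- sort(unique(nodes))
  stopifnot(is.data.frame(edges))
  structure(
    list(nodes = nodes, edges = edges,
         self_loop_policy = self_loop_policy, provenance = provenance),
    class = "ppin"
  )
}

#' Parse a DIP-style protein interaction table
#'
#' Reads tab-separated interaction records with three columns
#' (protein A, protein B, interaction identifier). A header line and an
#' optional leading row-number column are auto-detected and discarded,
#' mirroring the layout of DIP exports. Identifiers are lower-cased and
#' whitespace-stripped.
#'
#' @param x A file path, or a character scalar containing the table text,
#'   or a character vector of lines.
#' @return A data.frame with columns `protein_a`, `protein_b`,
#'   `interaction_id`, one row per interaction record.
#' @export
parse_interaction_table <- function(x) {
  lines <- interaction_table_lines(x)
  if (length(lines) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      interaction_id = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # header detection: any field mentioning 'protein' or 'ppi' on line 1
  first <- tolower(trimws(fields[[1]]))
  line_no <- seq_along(lines)
  if (any(grepl("protein|ppi_id|interaction", first))) {
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  if (length(fields) == 0) {
    return(data.frame(protein_a = character(), protein_b = character(),
                      interaction_id = character(), stringsAsFactors = FALSE))
  }
  fields <- lapply(fields, function(f) {
    f <- trimws(f)
    f[nzchar(f)]
  })
  nf <- lengths(fields)
  # leading row-number column: all rows have 4 fields and first is integer
  if (all(nf == 4) && all(vapply(fields, function(f) grepl("^[0-9]+$", f[1]), logical(1)))) {
    fields <- lapply(fields, `[`, -1)
    nf <- lengths(fields)
  }
  bad <- which(nf != 3)
  if (length(bad) > 0) {
    stop(sprintf("malformed interaction record on line %d: expected 3 columns, found %d",
                 line_no[bad[1]], nf[bad[1]]))
  }
  rec <- data.frame(
    protein_a = tolower(vapply(fields, `[`, "", 1)),
    protein_b = tolower(vapply(fields, `[`, "", 2)),
    interaction_id = vapply(fields, `[`, "", 3),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(rec$protein_a)) || any(!nzchar(rec$protein_b))) {
    stop("empty protein identifier in interaction table")
  }
  dup <- duplicated(rec$interaction_id)
  if (any(dup)) {
    stop(sprintf("duplicate interaction id '%s' in table", rec$interaction_id[which(dup)[1]]))
  }
  rec
}

interaction_table_lines <- function(x) {
  if (length(x) == 1 && !grepl("[\n\t]", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  } else if (length(x) == 1) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  x[nzchar(trimws(x))]
}

#' Build an undirected PPI network from interaction records
#'
#' Records with the same unordered protein pair merge into a single edge that
#' accumulates all interaction identifiers. Self-interactions are kept or
#' dropped according to the policy; either way every protein named in the
#' records becomes a node.
#'
#' @param records Data frame as returned by [parse_interaction_table()].
#' @param self_loop_policy `"keep"` (default) or `"drop"`.
#' @return A `ppin` object.
#' @export
build_network <- function(records, self_loop_policy = c("keep", "drop")) {
  self_loop_policy <- match.arg(self_loop_policy)
  nodes <- unique(c(records$protein_a, records$protein_b))
  if (nrow(records) == 0) {
    edges <- data.frame(a = character(), b = character(), stringsAsFactors = FALSE)
    edges$ids <- list()
    edges$core <- logical(0)
    return(new_ppin(character(), edges, self_loop_policy,
                    list(paste0("build_network(self_loop_policy=", self_loop_policy, ")"))))
  }
  a <- pmin(records$protein_a, records$protein_b)
  b <- pmax(records$protein_a, records$protein_b)
  keep <- rep(TRUE, length(a))
  if (self_loop_policy == "drop") keep <- a != b
  key <- paste(a, b, sep = "\t")[keep]
  ids <- split(records$interaction_id[keep], factor(key, levels = unique(key)))
  parts <- strsplit(names(ids), "\t", fixed = TRUE)
  edges <- data.frame(
    a = vapply(parts, `[`, "", 1),
    b = vapply(parts, `[`, "", 2),
    stringsAsFactors = FALSE
  )
  edges$ids <- unname(ids)
  edges$core <- rep(NA, nrow(edges))
  edges <- edges[order(edges$a, edges$b), , drop = FALSE]
  rownames(edges) <- NULL
  new_ppin(nodes, edges, self_loop_policy,
           list(paste0("build_network(self_loop_policy=", self_loop_policy, ")")))
}

#' @export
print.ppin <- function(x, ...) {
  cf <- core_fraction(x)
  cat(sprintf("PPI network: %d proteins, %d interactions", n_nodes(x), n_edges(x)))
  if (!is.na(cf)) cat(sprintf(", core fraction %.3f", cf))
  cat("\n")
  if (length(x$provenance)) {
    cat("provenance:\n")
    for (p in x$provenance) cat(" -", p, "\n")
  }
  invisible(x)
}

#' Number of nodes / edges of a PPI network
#' @param net A `ppin` object.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

ppin_edge_keys <- function(net) edge_key(net$edges$a, net$edges$b)

#' Flag core (manually curated) interactions
#'
#' Marks an edge as core when any of its interaction identifiers appears in
#' `core_ids`; all other edges are marked non-core. Identifiers in `core_ids`
#' that do not occur in the network are reported with a warning and ignored.
#'
#' @param net A `ppin` object.
#' @param core_ids Character vector of interaction identifiers.
#' @return The network with the `core` flag set on every edge.
#' @export
annotate_core <- function(net, core_ids) {
  all_ids <- unlist(net$edges$ids, use.names = FALSE)
  unknown <- setdiff(core_ids, all_ids)
  if (length(unknown) > 0) {
    warning(sprintf("%d core interaction id(s) not present in network (e.g. %s); ignored",
                    length(unknown), unknown[1]))
  }
  net$edges$core <- vapply(net$edges$ids, function(ids) any(ids %in% core_ids), logical(1))
  net$provenance <- c(net$provenance, list(sprintf("annotate_core(%d ids)", length(core_ids))))
  net
}

#' Fraction of core interactions
#'
#' @param net A `ppin` object.
#' @return `#core edges / #edges`, or `NA` if core flags are unknown
#'   (no core list was ever supplied) or the network has no edges.
#' @export
core_fraction <- function(net) {
  if (n_edges(net) == 0 || anyNA(net$edges$core)) return(NA_real_)
  mean(net$edges$core)
}

#' Exact difference between two networks
#'
#' @param before,after `ppin` objects over the same identifier space.
#' @return A `network_delta`: `added_edges` and `removed_edges` data frames
#'   (columns `a`, `b`) plus `removed_core_count`, the number of removed
#'   edges flagged core in `before`.
#' @export
diff_networks <- function(before, after) {
  kb <- ppin_edge_keys(before)
  ka <- ppin_edge_keys(after)
  added <- after$edges[!(ka %in% kb), c("a", "b"), drop = FALSE]
  removed_idx <- !(kb %in% ka)
  removed <- before$edges[removed_idx, c("a", "b"), drop = FALSE]
  core <- before$edges$core[removed_idx]
  rownames(added) <- rownames(removed) <- NULL
  structure(
    list(added_edges = added, removed_edges = removed,
         removed_core_count = sum(core %in% TRUE)),
    class = "network_delta"
  )
}

#' @export
print.network_delta <- function(x, ...) {
  cat(sprintf("network delta: +%d edges, -%d edges (%d core removed)\n",
              nrow(x$added_edges), nrow(x$removed_edges), x$removed_core_count))
  invisible(x)
}

#' Convert a PPI network to an igraph graph
#'
#' @param net A `ppin` object.
#' @param loops Keep self-loop edges (`FALSE` by default: most topology and
#'   clustering computations ignore them).
#' @return An undirected `igraph` graph whose vertices are the network's
#'   proteins in sorted order.
#' @export
as_igraph <- function(net, loops = FALSE) {
  e <- net$edges
  if (!loops) e <- e[e$a != e$b, , drop = FALSE]
  igraph::graph_from_data_frame(
    e[, c("a", "b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE)
  )
}

#' Export a network as SIF, GraphML or an edge-list TSV
#'
#' The TSV format is the same three-column dialect the parser reads (one row
#' per interaction identifier), so export followed by
#' [parse_interaction_table()] and [build_network()] round-trips the node and
#' edge sets. SIF lines use the `A pp B` convention understood by Cytoscape.
#' When a clustering is supplied, a companion node-attribute table mapping
#' each clustered protein to its cluster label is returned alongside.
#'
#' @param net A `ppin` object.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @param clustering Optional `ppi_clustering` (see [mcl()]).
#' @param path Optional file to write the network content to.
#' @return The exported content as a character scalar; when `clustering` is
#'   given, a list with elements `network` and `node_attributes` (a
#'   data.frame `protein`/`cluster`).
#' @export
export_network <- function(net, format = c("tsv", "sif", "graphml"),
                           clustering = NULL, path = NULL) {
  format <- match.arg(format)
  content <- switch(format,
    tsv = {
      rows <- c("protein_a\tprotein_b\tppi_id",
                unlist(lapply(seq_len(n_edges(net)), function(i) {
                  sprintf("%s\t%s\t%s", net$edges$a[i], net$edges$b[i], net$edges$ids[[i]])
                })))
      paste0(paste(rows, collapse = "\n"), "\n")
    },
    sif = {
      if (n_edges(net) == 0) "" else
        paste0(paste(sprintf("%s pp %s", net$edges$a, net$edges$b), collapse = "\n"), "\n")
    },
    graphml = {
      tf <- tempfile(fileext = ".graphml")
      on.exit(unlink(tf), add = TRUE)
      igraph::write_graph(as_igraph(net, loops = TRUE), tf, format = "graphml")
      paste0(paste(readLines(tf, warn = FALSE), collapse = "\n"), "\n")
    })
  if (!is.null(path)) writeLines(content, path, sep = "")
  if (is.null(clustering)) return(invisible(content))
  stopifnot(inherits(clustering, "ppi_clustering"))
  attrs <- data.frame(
    protein = unlist(clustering$clusters, use.names = FALSE),
    cluster = rep(names(clustering$clusters), lengths(clustering$clusters)),
    stringsAsFactors = FALSE
  )
  invisible(list(network = content, node_attributes = attrs))
}

#' The packaged yeast DIP subnetwork
#'
#' A 34-protein, 90-interaction subset of the *Saccharomyces cerevisiae*
#' protein-protein interaction network (DIP identifiers), centred on the
#' actin cytoskeleton machinery. Shipped as a plain TSV fixture so the whole
#' toolkit is exercisable offline.
#'
#' @param self_loop_policy Passed to [build_network()].
#' @return A `ppin` object with 34 nodes and 90 edges (default policy).
#' @export
dip_yeast_subnet <- function(self_loop_policy = "keep") {
  f <- system.file("extdata", "dip_yeast_subnet.tsv", package = "complexpert", mustWork = TRUE)
  build_network(parse_interaction_table(f), self_loop_policy)
}

#' Core interaction identifiers for the packaged subnetwork
#'
#' A synthetic stand-in for DIP's manually curated "core" labels, which are
#' not redistributable: 67 of the 90 interaction identifiers are flagged,
#' reproducing the reliable-interaction fraction of roughly 74% that drives
#' the preprocessing rules. The assignment is arbitrary but fixed.
#'
#' @return Character vector of 67 interaction identifiers.
#' @export
dip_core_ids <- function() {
  f <- system.file("extdata", "dip_core_ids_synthetic.txt", package = "complexpert", mustWork = TRUE)
  readLines(f, warn = FALSE)
}

#' Read a core-ID list file (one interaction identifier per line)
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_core_ids <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}
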