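# In-code fixtures: tiny graphs are built from flat endpoint vectors so no
# test depends on stored data beyond the packaged DIP table.

make_net <- function(pairs, policy = "keep") {
  a <- pairs[seq(1, length(pairs), 2)]
  b <- pairs[seq(2, length(pairs), 2)]
  rec <- data.frame(protein_a = a, protein_b = b,
                    interaction_id = sprintf("FX-%d", seq_along(a)),
                    stringsAsFactors = FALSE)
  build_network(rec, policy)
}

triangle_net <- function(labels = c("a", "b", "c")) {
  make_net(c(labels[1], labels[2], labels[2], labels[3], labels[3], labels[1]))
}

complete_net <- function(n, prefix = "v") {
  ids <- paste0(prefix, seq_len(n))
  pairs <- utils::combn(ids, 2)
  make_net(as.vector(pairs))
}

path_net <- function(labels) {
  make_net(as.vector(rbind(labels[-length(labels)], labels[-1])))
}

star_net <- function(n_leaves) {
  leaves <- paste0("leaf", seq_len(n_leaves))
  make_net(as.vector(rbind("hub", leaves)))
}

# Erdos-Renyi graph over n nodes; always includes all n nodes.
random_net <- function(n, p, seed) {
  ids <- sprintf("r%02d", seq_len(n))
  pairs <- utils::combn(ids, 2)
  keep <- withr::with_seed(seed, stats::runif(ncol(pairs)) < p)
  if (!any(keep)) keep[1] <- TRUE
  a <- pairs[1, keep]; b <- pairs[2, keep]
  rec <- data.frame(protein_a = a, protein_b = b,
                    interaction_id = sprintf("RN-%d", seq_along(a)),
                    stringsAsFactors = FALSE)
  net <- build_network(rec, "keep")
  net$nodes <- ids
  net
}

dip_net <- function(...) dip_yeast_subnet(...)

fn_completed_net <- function() {
  net <- dip_yeast_subnet()
  apply_additions(net, predict_false_negatives(
    net, defective_clique_params(max_predictions = 1)))
}
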