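test_that("hypergeometric p-value matches closed forms and enumeration", {
  expect_equal(hypergeometric_pvalue(0, 5, 10, 30), 1)
  # all draws annotated: P = 1 / C(N, n)
  expect_equal(hypergeometric_pvalue(3, 3, 3, 34), 1 / choose(34, 3),
               tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(2, 3, 5, 30),
               oracle_hypergeom_enum(2, 3, 5, 30), tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(1, 2, 4, 12),
               oracle_hypergeom_enum(1, 2, 4, 12), tolerance = 1e-12)
  expect_error(hypergeometric_pvalue(4, 3, 5, 30), "bounds")
  expect_error(hypergeometric_pvalue(2, 3, 1, 30), "bounds")
})

test_that("hypergeometric mass normalises and the tail is monotone in k", {
  n <- 6; K <- 8; N <- 20
  pmf <- vapply(0:n, function(i) {
    choose(K, i) * choose(N - K, n - i) / choose(N, n)
  }, numeric(1))
  expect_equal(sum(pmf), 1, tolerance = 1e-12)
  tails <- vapply(0:n, hypergeometric_pvalue, numeric(1), n = n, K = K, N = N)
  expect_true(all(diff(tails) < 0))
  # agreement with the distribution's standard implementation
  expect_equal(tails[-1], stats::phyper(0:(n - 1), K, N - K, n, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("best_term_per_cluster picks the minimal-p term with tie discipline", {
  cl <- new_clustering(list(c("a", "b", "c"), c("x", "y")))
  ann <- annotation_map(list(exact = c("a", "b", "c"),
                             broad = c("a", "b", "c", "x", "y", "q")),
                        universe = c(letters[1:6], "x", "y", "q", "z"))
  res <- best_term_per_cluster(cl, ann, alpha = 0.05)
  r1 <- res[res$n == 3, ]
  expect_equal(r1$best_term, "exact")
  expect_equal(r1$fraction, "3/3")
  expect_equal(r1$p_value, 1 / choose(10, 3), tolerance = 1e-12)
})

test_that("clusters without annotated members are reported above the cutoff", {
  cl <- new_clustering(list(c("crn1", "svl3")))
  net <- dip_net()
  ann <- annotation_map(list(some_term = c("act1", "cof1")), universe = net$nodes)
  res <- best_term_per_cluster(cl, ann, alpha = 0.01)
  expect_equal(res$fraction, "0/2")
  expect_equal(res$p_label, "> 0.01")
  expect_true(is.na(res$best_term))
})

test_that("planted annotations are recovered as each cluster's best term", {
  pl <- generate_planted_complexes(c(6, 7, 8), p_in = 0.9, p_out = 0.05, seed = 4)
  ann <- generate_annotations(pl$truth, coverage = 1, seed = 1)
  res <- best_term_per_cluster(pl$truth, ann, alpha = 0.01)
  expect_equal(res$best_term,
               sprintf("planted_term_%s", res$cluster))
  expect_equal(res$fraction, sprintf("%d/%d", res$n, res$n))
  # the fraction string always matches the stored integers
  expect_equal(res$fraction, sprintf("%d/%d", res$k, res$n))
  # half coverage annotates half the members
  ann5 <- generate_annotations(new_clustering(list(sprintf("p%03d", 1:10))),
                               coverage = 0.5, seed = 2)
  expect_length(ann5$terms[[1]], 5)
})

test_that("enrichment table mirrors the published layout", {
  cl <- new_clustering(list(c("a", "b"), c("x", "y")))
  ann <- annotation_map(list(t1 = c("a", "b")), universe = c("a", "b", "x", "y"))
  res <- best_term_per_cluster(cl, ann, alpha = 0.05)
  tab <- format_enrichment_table(res, cl, method = "MCL")
  lines <- strsplit(tab, "\n")[[1]]
  expect_equal(lines[1], "method\tproteins\tfraction\tp_value")
  expect_match(lines[2], "^MCL\ta, b\t2/2\t")
  expect_match(tab, "> 0.05", fixed = TRUE)
})
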