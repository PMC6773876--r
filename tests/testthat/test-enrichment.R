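# Subnetwork filtering, hypergeometric ORA, adjustment and aggregation.

test_that("filter_subnetworks applies the score-quantile criterion", {
  subs <- lapply(1:10, function(i)
    fake_subnetwork(sprintf("g%d_%d", i, 1:12), s_a = i))
  kept <- filter_subnetworks(subs, score_quantile = 0.80, min_sig_genes = 10)
  # quantile(1:10, .8) = 8.2 under linear interpolation; strictly above: 9, 10
  expect_setequal(vapply(kept, `[[`, numeric(1), "s_a"), c(9, 10))
})

test_that("filter_subnetworks enforces the significant-gene minimum", {
  good <- fake_subnetwork(sprintf("a%d", 1:12), s_a = 10, n_sig = 12)
  small <- fake_subnetwork(sprintf("b%d", 1:12), s_a = 100, n_sig = 9)
  # the top-score subnetwork is dropped for lacking input genes, and no
  # other clears the quantile it sets
  expect_length(filter_subnetworks(list(good, small), min_sig_genes = 10), 0L)
  # too few input genes loses even as the single (quantile-exempt) entry
  expect_length(filter_subnetworks(list(small), min_sig_genes = 10), 0L)
  # a single subnetwork is exempt from the (vacuous) quantile criterion
  expect_length(filter_subnetworks(list(good)), 1L)
  expect_warning(filter_subnetworks(list()), "no subnetworks")
})

test_that("hypergeometric_ora matches the combinatorial tail sum", {
  pool <- sprintf("g%02d", 1:20)
  pathway <- pool[1:5]
  query <- pool[c(1:3, 10:12)]  # x = 3, n = 6, K = 5, N = 20
  got <- hypergeometric_ora(query, pathway, pool)
  expect_equal(got$p, exact_hyper_tail(20, 5, 6, 3), tolerance = 1e-12)
  expect_equal(got$fold_enrichment, (3 / 6) / (5 / 20))
  expect_equal(got$overlap_genes, pool[1:3])
})

test_that("hypergeometric_ora handles the degenerate extremes", {
  pool <- letters[1:10]
  none <- hypergeometric_ora(pool[6:8], pool[1:3], pool)
  expect_equal(none$p, 1)  # x = 0: the upper tail is the whole mass
  sat <- hypergeometric_ora(pool, pool, pool)
  expect_equal(sat$p, 1)
  expect_equal(sat$fold_enrichment, 1)
  expect_error(hypergeometric_ora("a", "a", character()), "empty background")
  # genes outside the pool are dropped from the query
  out <- hypergeometric_ora(c(pool[1:2], "ZZZ"), pool[1:3], pool)
  expect_equal(out$p, exact_hyper_tail(10, 3, 2, 2))
})

test_that("ORA p is non-increasing in the overlap x", {
  pool <- sprintf("g%02d", 1:15)
  pathway <- pool[1:6]
  outside <- setdiff(pool, pathway)
  ps <- vapply(0:5, function(x) {
    query <- c(pathway[seq_len(x)], outside[seq_len(5 - x)])
    hypergeometric_ora(query, pathway, pool)$p
  }, numeric(1))
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("adjustment matches Bonferroni and the BH step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02), "bonferroni"), c(0.02, 0.04))
  expect_equal(adjust_pvalues(c(0.9, 0.01, 0.2, 0.3), "bonferroni")[1], 1)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  withr::local_seed(8)
  for (i in 1:20) {
    ps <- runif(sample(1:10, 1))
    expect_equal(adjust_pvalues(ps, "bh"), bh_oracle(ps))
    expect_equal(adjust_pvalues(ps, "bonferroni"), pmin(1, ps * length(ps)))
  }
})

test_that("aggregate_subnetworks keeps the lowest adjusted p per pathway", {
  recs <- data.frame(id = c("P1", "P1", "P2"),
                     p = c(0.001, 0.003, 0.2),
                     adj_p = c(0.01, 0.03, 0.5),
                     fold_enrichment = c(2, 3, 1))
  recs$overlap_genes <- list("a", "a", "b")
  out <- aggregate_subnetworks(recs, threshold = 0.05)
  expect_equal(out$id, "P1")
  expect_equal(out$adj_p, 0.01)

  none <- aggregate_subnetworks(recs[recs$adj_p > 0.05, ], 0.05)
  expect_equal(nrow(none), 0L)

  boundary <- data.frame(id = "P9", p = 0.01, adj_p = 0.05,
                         fold_enrichment = 1)
  boundary$overlap_genes <- list("x")
  expect_equal(nrow(aggregate_subnetworks(boundary, 0.05)), 1L)
})

test_that("removing a pathway never changes other pathways' raw ps", {
  pool <- sprintf("g%02d", 1:30)
  gsc <- gene_set_collection(list(A = pool[1:8], B = pool[5:14],
                                  C = pool[20:25]))
  query <- pool[c(1:6, 21, 22)]
  full <- enrich_subnetwork(query, gsc, pool)
  smaller <- enrich_subnetwork(query,
                               gene_set_collection(gsc$sets[c("A", "C")]),
                               pool)
  expect_equal(full$p[full$id == "A"], smaller$p[smaller$id == "A"])
  expect_equal(full$p[full$id == "C"], smaller$p[smaller$id == "C"])
  # only the adjusted values move with the family size m
  expect_equal(full$adj_p[full$id == "A"],
               min(1, full$p[full$id == "A"] * 3))
  expect_equal(smaller$adj_p[smaller$id == "A"],
               min(1, smaller$p[smaller$id == "A"] * 2))
})

make_enrichment_inputs <- function(seed = 1) {
  spec <- default_spec()
  pin <- generate_pin(spec, seed)
  deg <- generate_deg_table(spec, seed)
  list(spec = spec, pin = pin,
       proc = process_input(deg, pin),
       gsc = generate_gene_sets(spec, seed))
}

test_that("single-iteration results have lowest = highest, occurrence 1", {
  inp <- make_enrichment_inputs(6)
  res <- run_active_enrichment(inp$proc, inp$pin, inp$gsc,
                               search_config("greedy", seed = 6),
                               iterations = 1)
  expect_gt(nrow(res), 0)
  expect_equal(res$lowest_p, res$highest_p)
  expect_true(all(res$occurrence == 1L))
})

test_that("iterated runs track occurrence, bounds and orderings", {
  inp <- make_enrichment_inputs(7)
  res <- run_active_enrichment(inp$proc, inp$pin, inp$gsc,
                               search_config("greedy", seed = 7),
                               iterations = 3)
  expect_true(all(res$occurrence == 3L))  # deterministic greedy iterations
  expect_true(all(res$lowest_p <= res$highest_p))
  expect_true(all(res$occurrence <= 3L))
  expect_true(!is.unsorted(res$lowest_p))
  # up/down lists are disjoint per pathway
  up <- strsplit(res$Up_regulated, ";", fixed = TRUE)
  dn <- strsplit(res$Down_regulated, ";", fixed = TRUE)
  for (i in seq_len(nrow(res)))
    expect_length(intersect(up[[i]], dn[[i]]), 0L)
})

test_that("the planted target set attains the minimum lowest p", {
  inp <- make_enrichment_inputs(8)
  res <- run_active_enrichment(inp$proc, inp$pin, inp$gsc,
                               search_config("greedy", seed = 8))
  expect_equal(res$ID[which.min(res$lowest_p)], "TARGET")
  mod <- planted_module(inp$spec, 8)
  expect_gt(length(intersect(strsplit(res$Up_regulated[res$ID == "TARGET"],
                                      ";")[[1]], mod)), 10)
})

test_that("an all-insignificant input yields an empty table with warning", {
  inp <- make_enrichment_inputs(9)
  # permuted labels scatter the module, so no subnetwork passes the filter
  deg <- generate_deg_table(inp$spec, 9)
  perm <- permute_gene_labels(deg, inp$pin$nodes, seed = 909)
  proc <- process_input(perm, inp$pin)
  expect_warning(
    res <- run_active_enrichment(proc, inp$pin, inp$gsc,
                                 search_config("greedy", seed = 909),
                                 iterations = 2),
    "no pathway enriched")
  expect_equal(nrow(res), 0L)
})
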