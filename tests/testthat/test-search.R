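# The three active subnetwork search algorithms and their shared pieces.

test_that("connected_components partitions the on-set correctly", {
  pin <- path_pin(c("A", "B", "C"))
  expect_equal(connected_components(pin, c("A", "C")),
               list("A", "C"))
  tri <- interaction_network(cbind(c("A", "B", "A"), c("B", "C", "C")))
  expect_equal(connected_components(tri, c("A", "B", "C")),
               list(c("A", "B", "C")))
  expect_equal(connected_components(pin, character()), list())
  expect_error(connected_components(pin, "Z"), "not in the network")
})

test_that("connected_components agrees with the igraph traversal oracle", {
  skip_if_not_installed("igraph")
  withr::local_seed(21)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    syms <- sprintf("V%02d", 1:n)
    m <- sample(3:25, 1)
    pin <- interaction_network(cbind(sample(syms, m, TRUE),
                                     sample(syms, m, TRUE)),
                               nodes = syms)
    on <- sample(pin$nodes, sample(seq_len(n), 1))
    expect_equal(connected_components(pin, on), igraph_components(pin, on))
  }
})

test_that("sa_acceptance implements the annealing rule", {
  expect_equal(sa_acceptance(1.1, 1.0, 5), 1)        # any improvement
  expect_equal(sa_acceptance(0, 1, 1), exp(-1))      # delta = -T
  expect_lt(sa_acceptance(0, 1, 1e-6), 1e-100)       # frozen system
  expect_error(sa_acceptance(1, 2, 0), "temperature")
  expect_error(sa_acceptance(1, 2, -1), "temperature")
})

test_that("filter_overlapping keeps the boundary and discards duplicates", {
  a <- fake_subnetwork(c("1", "2", "3", "4"), s_a = 5)
  b <- fake_subnetwork(c("3", "4", "5", "6"), s_a = 4)  # overlap 2/4 = 0.5
  kept <- filter_overlapping(list(a, b), threshold = 0.5)
  expect_length(kept, 2L)

  dup <- filter_overlapping(list(a, fake_subnetwork(a$genes, s_a = 3)))
  expect_length(dup, 1L)
  expect_equal(dup[[1L]]$s_a, 5)

  disjoint <- filter_overlapping(list(a, fake_subnetwork(c("9", "10"), 1)))
  expect_length(disjoint, 2L)
})

test_that("greedy keeps a lone strong seed when neighbors only dilute", {
  # star: significant center, insignificant leaves; adding a z = 0 leaf
  # divides the raw score by sqrt(2) and cannot improve the calibrated one
  star <- interaction_network(cbind("hub", sprintf("leaf%d", 1:6)))
  zmap <- c(hub = 3)
  cal <- calibrate_background(star, zmap, draws = 500, seed = 1)
  subs <- greedy_search(star, zmap, "hub", search_config("greedy", seed = 1),
                        cal)
  expect_length(subs, 1L)
  expect_equal(subs[[1L]]$genes, "hub")
})

test_that("greedy joins adjacent significant genes", {
  pin <- path_pin(c("x1", "A", "B", "x2", "x3", "x4", "x5", "x6"))
  zmap <- c(A = 2, B = 2)
  cal <- calibrate_background(pin, zmap, draws = 1000, seed = 3)
  subs <- greedy_search(pin, zmap, c("A", "B"),
                        search_config("greedy", seed = 3), cal)
  expect_true(any(vapply(subs, function(s)
    setequal(s$genes, c("A", "B")), logical(1))))
})

test_that("depth-1 greedy candidates are exactly the seed's neighbors", {
  # path of three significant genes: from the middle seed both ends are
  # reachable, from an end seed only the middle (depth limit from seed)
  pin <- path_pin(c("L", "M", "R"))
  zmap <- c(L = 3, M = 3, R = 3)
  cal <- calibrate_background(pin, zmap, draws = 500, seed = 2)
  cfg <- search_config("greedy", search_depth = 1, max_depth = 1,
                       overlap_threshold = 1, seed = 2)
  subs <- greedy_search(pin, zmap, c("L", "M", "R"), cfg, cal)
  by_seed <- stats::setNames(lapply(subs, `[[`, "genes"),
                             vapply(subs, `[[`, character(1), "seed"))
  for (seed_gene in names(by_seed)) {
    nb <- pin$nodes[pin$adj[[match(seed_gene, pin$nodes)]]]
    expect_true(all(by_seed[[seed_gene]] %in% c(seed_gene, nb)))
  }
  expect_false("R" %in% by_seed[["L"]])  # distance 2 from the seed
})

test_that("greedy errors without any seed in the network", {
  pin <- path_pin(c("A", "B"))
  cal <- calibrate_background(pin, c(A = 1), draws = 50, seed = 1)
  expect_error(greedy_search(pin, c(Z = 1), "Z",
                             search_config("greedy"), cal), "no seeds")
})

test_that("all three algorithms return connected, reproducible subnetworks", {
  skip_if_not_installed("igraph")
  spec <- default_spec()
  pin <- generate_pin(spec, 5)
  deg <- generate_deg_table(spec, 5)
  proc <- process_input(deg, pin)
  zmap <- p_to_z(proc$p)
  cal <- calibrate_background(pin, zmap, draws = 500, seed = 5)
  configs <- list(
    greedy = search_config("greedy", seed = 5),
    sa = search_config("sa", sa_iters = 400, seed = 5),
    ga = search_config("ga", ga_pop = 12, ga_gens = 15, seed = 5))
  for (alg in names(configs)) {
    s1 <- active_search(pin, zmap, proc$genes, configs[[alg]], cal)
    s2 <- active_search(pin, zmap, proc$genes, configs[[alg]], cal)
    expect_gt(length(s1), 0)
    for (s in s1) expect_true(is_connected_in(pin, s$genes))
    expect_equal(lapply(s1, `[[`, "genes"), lapply(s2, `[[`, "genes"),
                 info = alg)
    for (s in s1)
      expect_equal(s$n_sig, length(intersect(s$genes, proc$genes)))
  }
  # greedy output obeys the pairwise overlap bound
  gs <- active_search(pin, zmap, proc$genes, configs$greedy, cal)
  for (i in seq_along(gs)) for (j in seq_len(i - 1L)) {
    ov <- length(intersect(gs[[i]]$genes, gs[[j]]$genes)) /
      min(length(gs[[i]]$genes), length(gs[[j]]$genes))
    expect_lte(ov, 0.5)
  }
})

test_that("zero annealing iterations return the initial assignment", {
  spec <- default_spec(n_genes = 40L, module_size = 5L)
  pin <- generate_pin(spec, 2)
  zmap <- p_to_z(stats::setNames(rep(0.01, 5), planted_module(spec, 2)))
  cal <- calibrate_background(pin, zmap, draws = 100, seed = 2)
  cfg <- search_config("sa", sa_iters = 0, sa_init_prob = 0.3, seed = 2)
  subs <- simulated_annealing_search(pin, zmap, names(zmap), cfg, cal)
  # reconstruct the seeded initial on-set independently
  init <- withr::with_seed(2L, stats::runif(length(pin$nodes)) < 0.3)
  expect_setequal(unlist(lapply(subs, `[[`, "genes")), pin$nodes[init])
})

test_that("genetic search satisfies elitism and the no-mutation contract", {
  spec <- default_spec(n_genes = 60L, module_size = 6L)
  pin <- generate_pin(spec, 4)
  deg <- generate_deg_table(spec, 4)
  proc <- process_input(deg, pin)
  zmap <- p_to_z(proc$p)
  cal <- calibrate_background(pin, zmap, draws = 300, seed = 4)
  cfg <- search_config("ga", ga_pop = 10, ga_gens = 25, seed = 4)
  out <- genetic_search(pin, zmap, proc$genes, cfg, cal)
  trace <- attr(out, "trace")
  expect_length(trace, 25L)
  expect_true(all(diff(trace) >= 0))  # elite preservation
  expect_gt(length(out), 0)
})
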