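# Kappa matrix, hierarchical clustering with silhouette selection, and
# fuzzy multi-membership clustering.

test_that("kappa matches the hand contingency computation", {
  universe <- sprintf("g%02d", 1:10)
  res <- fake_result(c("A", "B"),
                     list(universe[1:5], universe[4:8]))
  km <- kappa_matrix(res, universe)
  # a = 2, b = 3, c = 3, d = 2 -> Po = 0.4, Pe = 0.5, kappa = -0.2
  expect_equal(km["A", "B"], -0.2)
  expect_equal(diag(km), c(A = 1, B = 1))

  ident <- fake_result(c("A", "B"), list(universe[1:5], universe[1:5]))
  expect_equal(kappa_matrix(ident, universe)["A", "B"], 1)
})

test_that("kappa equals the direct 2x2 formula for random memberships", {
  withr::local_seed(12)
  universe <- sprintf("g%02d", 1:20)
  for (i in 1:15) {
    sets <- lapply(1:4, function(j) sample(universe, sample(3:15, 1)))
    res <- fake_result(sprintf("P%d", 1:4), sets)
    km <- kappa_matrix(res, universe)
    expect_equal(km, t(km))
    expect_true(all(km >= -1 & km <= 1 + 1e-12))
    for (i1 in 1:3) for (j1 in (i1 + 1):4) {
      v1 <- universe %in% sets[[i1]]
      v2 <- universe %in% sets[[j1]]
      a <- sum(v1 & v2); b <- sum(v1 & !v2)
      cc <- sum(!v1 & v2); d <- sum(!v1 & !v2)
      po <- (a + d) / 20
      pe <- ((a + b) * (a + cc) + (cc + d) * (b + d)) / 400
      expect_equal(km[i1, j1], (po - pe) / (1 - pe), tolerance = 1e-12)
    }
  }
})

test_that("degenerate constant membership pairs stay defined", {
  universe <- letters[1:6]
  res <- fake_result(c("full1", "full2", "other"),
                     list(universe, universe, universe[1:2]))
  km <- kappa_matrix(res, universe)
  expect_equal(km["full1", "full2"], 1)   # identical constant vectors
  expect_error(kappa_matrix(fake_result("solo", list(universe[1:2])),
                            universe), "nothing to cluster")
})

block_result <- function() {
  # three groups of three pathways; identical membership within a group,
  # disjoint gene blocks between groups -> within-kappa 1, between <= 0
  universe <- sprintf("g%02d", 1:30)
  blocks <- list(universe[1:10], universe[11:20], universe[21:30])
  ids <- sprintf("P%d", 1:9)
  sets <- rep(blocks, each = 3)
  fake_result(ids, sets, lowest_p = seq(0.001, 0.009, by = 0.001))
}

test_that("hierarchical clustering recovers a perfect block structure", {
  res <- block_result()
  km <- kappa_matrix(res, sprintf("g%02d", 1:30))
  expect_true(all(km[1:3, 1:3] == 1))
  expect_true(all(km[1:3, 4:9] <= 0))
  cl <- hierarchical_cluster(km, res)
  expect_equal(attr(cl, "k"), 3L)
  truth <- rep(1:3, each = 3)
  expect_equal(ari(cl$cluster, truth), 1)
  # representatives carry the cluster-minimum lowest_p
  for (g in unique(cl$cluster)) {
    in_g <- cl$ID[cl$cluster == g]
    rep_id <- cl$ID[cl$cluster == g & cl$is_representative]
    expect_length(rep_id, 1L)
    expect_equal(res$lowest_p[res$ID == rep_id],
                 min(res$lowest_p[res$ID %in% in_g]))
  }
})

test_that("the silhouette-selected cut maximizes the oracle silhouette", {
  res <- block_result()
  km <- kappa_matrix(res, sprintf("g%02d", 1:30))
  d <- stats::as.dist(1 - km)
  tree <- stats::hclust(d, method = "average")
  oracle <- vapply(2:8, function(k)
    silhouette_oracle(stats::cutree(tree, k), d), numeric(1))
  cl <- hierarchical_cluster(km, res)
  expect_equal(attr(cl, "k"), (2:8)[which.max(oracle)])
})

test_that("equal pairwise kappa breaks ties towards the smallest k", {
  ids <- sprintf("Q%d", 1:5)
  km <- matrix(0.4, 5, 5, dimnames = list(ids, ids)); diag(km) <- 1
  cl <- hierarchical_cluster(km, NULL)
  expect_equal(attr(cl, "k"), 2L)
  expect_true(all(table(cl$ID) == 1))  # a partition
})

test_that("two pathways fall back to one or two clusters by sign of kappa", {
  ids <- c("A", "B")
  near <- matrix(c(1, .8, .8, 1), 2, dimnames = list(ids, ids))
  far <- matrix(c(1, -.2, -.2, 1), 2, dimnames = list(ids, ids))
  expect_equal(attr(hierarchical_cluster(near, NULL), "k"), 1L)
  expect_equal(attr(hierarchical_cluster(far, NULL), "k"), 2L)
})

test_that("fuzzy clustering separates blocks and allows multi-membership", {
  # two pathway blocks plus a bridge pathway B whose kappa reaches the
  # 0.35 threshold with exactly one member of each block: B is absorbed
  # into both seeded groups but cannot seed (only 2 close neighbors) and
  # the groups share only B, so they never merge
  universe <- sprintf("g%02d", 1:60)
  sets <- list(P1 = universe[1:12],  P2 = universe[5:14],
               P3 = universe[7:16],
               Q1 = universe[31:42], Q2 = universe[35:44],
               Q3 = universe[37:46],
               B  = universe[c(1:6, 31:36)])
  res <- fake_result(names(sets), sets,
                     lowest_p = seq(0.001, 0.007, 0.001))
  km <- kappa_matrix(res, universe)
  expect_gte(km["B", "P1"], 0.35)
  expect_lt(km["B", "P2"], 0.35)
  fz <- fuzzy_cluster(km, res, kappa_threshold = 0.35)
  expect_equal(attr(fz, "k"), 2L)
  expect_equal(sum(fz$ID == "B"), 2L)  # the bridge joins both clusters
  p_cluster <- fz$cluster[fz$ID == "P1"]
  expect_setequal(fz$ID[fz$cluster == p_cluster], c("P1", "P2", "P3", "B"))
  expect_setequal(unique(fz$ID), res$ID)  # full coverage
})

test_that("disjoint kappa-1 blocks give two crisp fuzzy clusters", {
  universe <- sprintf("g%02d", 1:20)
  res <- fake_result(sprintf("P%d", 1:8),
                     c(rep(list(universe[1:10]), 4),
                       rep(list(universe[11:20]), 4)))
  km <- kappa_matrix(res, universe)
  fz <- fuzzy_cluster(km, res)
  expect_equal(attr(fz, "k"), 2L)
  expect_true(all(table(fz$ID) == 1))
})

test_that("an unreachable kappa threshold yields all singletons", {
  withr::local_seed(30)
  universe <- sprintf("g%02d", 1:20)
  sets <- lapply(1:5, function(i) sample(universe, 8))
  res <- fake_result(sprintf("P%d", 1:5), sets)
  km <- kappa_matrix(res, universe)
  diag_only <- fuzzy_cluster(km, res, kappa_threshold = 1.0)
  expect_equal(attr(diag_only, "k"), 5L)
  expect_true(all(table(diag_only$cluster) == 1))
})
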