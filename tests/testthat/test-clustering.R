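test_that("spectral clustering recovers well-separated similarity blocks", {
  inst <- make_block_instance(block_sizes = c(5, 5), intra_sim = 0.9,
                              inter_sim = 0.05)
  cs <- cluster_elements(inst, K = 2, seed = 7)[["1"]]
  expect_equal(cs$K_effective, 2)
  truth <- attr(inst, "truth")
  # labels equal up to renaming: within-block labels constant, across different
  lab <- cs$labels[names(truth)]
  expect_equal(length(unique(lab[truth == 1])), 1)
  expect_equal(length(unique(lab[truth == 2])), 1)
  expect_false(lab[truth == 1][1] == lab[truth == 2][1])
})

test_that("K caps at n (singletons) and K = 1 pools everything", {
  inst <- make_block_instance(block_sizes = c(3, 3))
  singletons <- cluster_elements(inst, K = 6, seed = 1)[["1"]]
  expect_equal(singletons$K_effective, 6)
  expect_true(all(lengths(singletons$clusters) == 1))
  pooled <- cluster_elements(inst, K = 1, seed = 1)[["1"]]
  expect_equal(pooled$K_effective, 1)
  expect_equal(lengths(pooled$clusters), c(t1_c001 = 6L))
  expect_error(cluster_elements(inst, K = 0), "at least 1")
})

test_that("distance matrices are clustered agglomeratively", {
  inst <- make_block_instance(block_sizes = c(4, 4), intra_sim = 0.9,
                              inter_sim = 0.05, matrix_kind = "distance")
  cs <- cluster_elements(inst, K = 2, seed = 3)[["1"]]
  truth <- attr(inst, "truth")
  lab <- cs$labels[names(truth)]
  expect_equal(length(unique(lab[truth == 1])), 1)
  expect_false(lab[truth == 1][1] == lab[truth == 2][1])
})

test_that("linkage orientation on similarities: single keeps the strongest link", {
  ids <- c("a", "b", "c")
  S <- matrix(c(1, 0.9, 0.2,
                0.9, 1, 0.4,
                0.2, 0.4, 1), 3, 3, dimnames = list(ids, ids))
  inst <- split_instance(tibble::tibble(id = ids), S)
  clusters <- list("1" = structure(
    list(clusters = list(t1_c001 = c("a", "b"), t1_c002 = "c"),
         labels = c(a = 1L, b = 1L, c = 2L), K_effective = 2L, entity_type = 1L),
    class = "cluster_set"))
  red_avg <- reduce_instance(inst, clusters, linkage = "average")
  expect_equal(red_avg$sim[["1"]]["t1_c001", "t1_c002"], 0.3)
  red_sgl <- reduce_instance(inst, clusters, linkage = "single")
  expect_equal(red_sgl$sim[["1"]]["t1_c001", "t1_c002"], 0.4)
  red_cpl <- reduce_instance(inst, clusters, linkage = "complete")
  expect_equal(red_cpl$sim[["1"]]["t1_c001", "t1_c002"], 0.2)
  # kappa_C sums member cardinalities
  expect_equal(red_avg$items$weight, c(2, 1))
})

test_that("reduction conserves cardinality mass and aggregates class mass", {
  inst <- make_block_instance(block_sizes = c(6, 4), classes = "block")
  clusters <- cluster_elements(inst, K = 3, seed = 2)
  red <- reduce_instance(inst, clusters)
  expect_equal(sum(red$items$weight), sum(inst$items$weight))
  expect_equal(sum(red$class_mass$mass), sum(inst$class_mass$mass))
  # per-class totals survive the aggregation
  tot <- function(x) dplyr::arrange(
    dplyr::summarise(dplyr::group_by(x, class), m = sum(mass)), class)
  expect_equal(tot(red$class_mass), tot(inst$class_mass))
})

test_that("singleton clusters reproduce the original instance", {
  inst <- random_instance(7, seed = 31)
  clusters <- cluster_elements(inst, K = 7, seed = 1)
  red <- reduce_instance(inst, clusters)
  # same similarities under the cluster relabeling
  members <- attr(red, "members")
  ord <- unlist(members)
  S0 <- inst$sim[["1"]][ord, ord]
  S1 <- red$sim[["1"]]
  dimnames(S0) <- dimnames(S1)
  expect_equal(S1, S0)
  expect_equal(unname(red$items$weight), rep(1, 7))
})

test_that("distance-kind cluster matrices are linked then complemented", {
  ids <- c("a", "b", "c")
  D <- matrix(c(0, 0.1, 0.8,
                0.1, 0, 0.6,
                0.8, 0.6, 0), 3, 3, dimnames = list(ids, ids))
  inst <- split_instance(tibble::tibble(id = ids), D, matrix_kind = "distance")
  clusters <- list("1" = structure(
    list(clusters = list(t1_c001 = c("a", "b"), t1_c002 = "c"),
         labels = c(a = 1L, b = 1L, c = 2L), K_effective = 2L, entity_type = 1L),
    class = "cluster_set"))
  red <- reduce_instance(inst, clusters, linkage = "average")
  expect_equal(red$sim[["1"]]["t1_c001", "t1_c002"], 1 - 0.7)  # 1 - mean(.8, .6)
  expect_equal(unname(red$matrix_kind["1"]), "similarity")
})

test_that("cluster-level objective equals unpacked element leakage under average linkage", {
  # unit cardinalities + average linkage: sim_C(A,B)*kappa_A*kappa_B equals the
  # sum of member-pair similarities, so the reduced objective is exact
  inst <- random_instance(9, seed = 77)
  clusters <- cluster_elements(inst, K = 3, seed = 5)
  red <- reduce_instance(inst, clusters, linkage = "average")
  cids <- red$items$id
  for (split_bits in list(c(1, 1, 2), c(1, 2, 2), c(2, 1, 2))) {
    cpart <- fold_partition(setNames(split_bits[seq_along(cids)], cids), "exact")
    epart <- unpack_partition(cpart, clusters)
    expect_equal(leakage(cpart, red), leakage(epart, inst), tolerance = 1e-10)
  }
})

test_that("elements missing from every cluster are reported", {
  inst <- tiny_instance()
  clusters <- list("1" = structure(
    list(clusters = list(t1_c001 = c("a", "b")),
         labels = c(a = 1L, b = 1L), K_effective = 1L, entity_type = 1L),
    class = "cluster_set"))
  expect_error(reduce_instance(inst, clusters), "missing from every cluster")
})

test_that("clustering is deterministic under a fixed seed", {
  inst <- make_block_instance(block_sizes = c(6, 6), jitter_sd = 0.05, seed = 4)
  a <- cluster_elements(inst, K = 3, seed = 11)[["1"]]$labels
  b <- cluster_elements(inst, K = 3, seed = 11)[["1"]]$labels
  expect_identical(a, b)
})
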