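test_that("the heuristic separates planted blocks", {
  inst <- make_block_instance(block_sizes = c(5, 5), intra_sim = 0.9,
                              inter_sim = 0.05)
  spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.2)
  part <- heuristic_split(inst, spec, K = 2)
  expect_equal(part$provenance, "heuristic")
  expect_equal(part$objective, 25 * 0.05)   # only inter-block pairs cut
  truth <- attr(inst, "truth")
  folds <- part$assignment[names(truth)]
  expect_equal(length(unique(folds[truth == 1])), 1)
  expect_false(folds[truth == 1][1] == folds[truth == 2][1])
  expect_true(is_feasible(check_constraints(part, inst, spec)))
})

test_that("with singleton clusters the heuristic matches the exact solver", {
  for (seed in c(13, 14)) {
    inst <- random_instance(8, seed = seed)
    spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.34)
    h <- heuristic_split(inst, spec, K = 8)
    exact <- solve_split(inst, spec)
    expect_equal(h$objective, exact$objective, tolerance = 1e-9)
  }
})

test_that("an infeasible reduced instance propagates advice", {
  inst <- make_block_instance(block_sizes = c(3, 3))
  expect_error(
    heuristic_split(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0), K = 1),
    "raising epsilon/delta or K")
})

test_that("unpacking maps every member to its cluster's fold", {
  clusters <- list("1" = structure(
    list(clusters = list(t1_c001 = c("x1", "x2"), t1_c002 = "x3"),
         labels = c(x1 = 1L, x2 = 1L, x3 = 2L), K_effective = 2L,
         entity_type = 1L),
    class = "cluster_set"))
  cpart <- fold_partition(c(t1_c001 = 1L, t1_c002 = 2L), "exact")
  part <- unpack_partition(cpart, clusters)
  expect_equal(part$assignment, c(x1 = 1L, x2 = 1L, x3 = 2L))
})

test_that("interaction records follow the both-endpoints rule", {
  part <- fold_partition(c(d1 = 1L, d2 = 2L, p1 = 1L, p2 = 2L), "exact")
  tbl <- tibble::tibble(row_id = c("d1", "d1", "d2"),
                        col_id = c("p1", "p2", "p2"))
  out <- assign_interactions(part, tbl)
  expect_equal(out$status, c("assigned", "discarded", "assigned"))
  expect_equal(out$fold, c(1L, NA, 2L))
  expect_equal(attr(out, "n_discarded"), 1L)
  expect_equal(attr(out, "discard_fraction"), 1 / 3)

  # co-assigned endpoints: no discards
  part2 <- fold_partition(c(d1 = 1L, d2 = 1L, p1 = 1L, p2 = 1L), "exact")
  expect_equal(attr(assign_interactions(part2, tbl), "n_discarded"), 0L)

  empty <- assign_interactions(part, tbl[0, ])
  expect_equal(nrow(empty), 0)

  expect_error(assign_interactions(part, tibble::tibble(row_id = "dX", col_id = "p1")),
               "missing from partition.*dX")
})

test_that("discards are exactly the cross-fold endpoint pairs on a 2D fixture", {
  td <- make_two_dim_instance(n_rows_blocks = c(4, 4), n_cols_blocks = c(3, 3),
                              interaction_density = 1, seed = 19)
  truth <- attr(td$instance, "truth")
  # block-aligned split: first blocks of both types to fold 1
  assign <- ifelse(truth == 1, 1L, 2L)
  part <- fold_partition(setNames(assign, names(truth)), "baseline")
  out <- assign_interactions(part, td$interactions)
  expected_disc <- truth[out$row_id] != truth[out$col_id]
  expect_equal(out$status == "discarded", unname(expected_disc))
  kept <- out[out$status == "assigned", ]
  expect_true(all(part$assignment[kept$row_id] == part$assignment[kept$col_id]))
})

test_that("random splits meet exact fractions with epsilon 0 and are seeded", {
  inst <- make_block_instance(block_sizes = c(5, 5))
  spec <- split_spec(fractions = c(0.8, 0.2), epsilon = 0)
  part <- random_split(inst, spec, seed = 99)
  expect_equal(as.integer(table(part$assignment)), c(8L, 2L))
  expect_identical(random_split(inst, spec, seed = 99)$assignment,
                   part$assignment)
  expect_false(identical(random_split(inst, spec, seed = 100)$assignment,
                         part$assignment))
})

test_that("stratified splits hit per-class targets with delta 0", {
  ids <- paste0("m", sprintf("%03d", 1:100))
  S <- diag(100); dimnames(S) <- list(ids, ids)
  items <- tibble::tibble(id = ids, classes = rep(c("A", "B"), c(80, 20)))
  inst <- split_instance(items, S)
  spec <- split_spec(fractions = c(0.8, 0.2), epsilon = 0, delta = 0)
  part <- stratified_random_split(inst, spec, seed = 7)
  tbl <- tidy(part, instance = inst) %>%
    dplyr::mutate(class = purrr::map_chr(classes, 1)) %>%
    dplyr::count(fold, class)
  test_fold <- dplyr::filter(tbl, fold == 2)
  expect_equal(test_fold$n[test_fold$class == "A"], 16L)
  expect_equal(test_fold$n[test_fold$class == "B"], 4L)
})

test_that("random interaction splitting assigns every record", {
  td <- make_two_dim_instance(interaction_density = 0.8, seed = 3)
  spec <- split_spec(fractions = c(0.75, 0.25))
  out <- random_interaction_split(td$interactions, spec, seed = 5)
  expect_true(all(out$status == "assigned"))
  counts <- table(out$fold)
  expect_equal(sum(counts), nrow(td$interactions))
  expect_lte(abs(counts[[1]] / nrow(out) - 0.75), 1 / nrow(out))
})

test_that("similarity-aware splits leak less than random ones on block data", {
  spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.2)
  inst <- make_block_instance(block_sizes = c(5, 5), intra_sim = 0.9,
                              inter_sim = 0.05, jitter_sd = 0.02, seed = 50)
  s1 <- scaled_leakage(heuristic_split(inst, spec, K = 2, seed = 1), inst)$scaled
  rnd <- mean(purrr::map_dbl(1:5, function(s) {
    scaled_leakage(random_split(inst, spec, seed = s), inst)$scaled
  }))
  expect_lt(s1, rnd)
})
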