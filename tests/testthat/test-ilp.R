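test_that("model dimensions follow the formulation", {
  inst <- tiny_instance()
  spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.34)
  m <- build_ilp(inst, spec)
  expect_equal(m$n_assign, 6)            # 3 elements x 2 folds
  expect_equal(m$n_cut, 3)               # all three pairs have positive weight
  expect_equal(sum(grepl("^assign:", m$row_label)), 3)
  expect_equal(sum(grepl("^fraction:", m$row_label)), 2)   # k x R = 2 x 1
  expect_equal(sum(grepl("^cut:", m$row_label)), 6)        # 3 pairs x 2 folds

  # single element: no pairs, no cut machinery
  ids <- "solo"
  S <- matrix(1, 1, 1, dimnames = list(ids, ids))
  m1 <- build_ilp(split_instance(tibble::tibble(id = ids), S), spec)
  expect_equal(m1$nvar, 2)
  expect_equal(m1$n_cut, 0)

  # 2D instance: fraction rows for each (fold, type)
  td <- make_two_dim_instance(n_rows_blocks = c(2, 2), n_cols_blocks = c(2, 2))
  m2 <- build_ilp(td$instance, spec)
  expect_equal(sum(grepl("^fraction:", m2$row_label)), 4)  # k x R = 2 x 2

  # zero-similarity pairs carry no cut variable
  idsz <- c("a", "b", "c")
  Sz <- matrix(0, 3, 3, dimnames = list(idsz, idsz)); diag(Sz) <- 1
  Sz["a", "b"] <- Sz["b", "a"] <- 0.4
  mz <- build_ilp(split_instance(tibble::tibble(id = idsz), Sz), spec)
  expect_equal(mz$n_cut, 1)
})

test_that("stratification rows appear only when class information exists", {
  inst <- random_instance(6, seed = 1, with_classes = TRUE)
  spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.34, delta = 0.34)
  expect_gt(sum(grepl("^class:", build_ilp(inst, spec)$row_label)), 0)
  inst0 <- random_instance(6, seed = 1, with_classes = FALSE)
  expect_equal(sum(grepl("^class:", build_ilp(inst0, spec)$row_label)), 0)
})

test_that("the solver reproduces the hand-enumerable optimum", {
  inst <- tiny_instance()
  sol <- solve_split(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0.34))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0.3)
  a <- sol$partition$assignment
  expect_true(a[["a"]] == a[["b"]] && a[["a"]] != a[["c"]])
})

test_that("infeasible bounds yield status infeasible with a named bound", {
  inst <- tiny_instance()
  sol <- solve_split(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0.1))
  expect_equal(sol$status, "infeasible")
  expect_match(sol$message, "exceed available mass")
  expect_null(sol$partition)
})

test_that("zero similarity gives a zero optimum", {
  ids <- paste0("x", 1:4)
  S <- diag(4); dimnames(S) <- list(ids, ids)
  inst <- split_instance(tibble::tibble(id = ids), S)
  sol <- solve_split(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0))
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective, 0)
})

test_that("brute force enumerates, filters and tie-breaks lexicographically", {
  inst <- tiny_instance()
  spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.34)
  bf <- brute_force_optimum(inst, spec)
  expect_equal(bf$objective, 0.3)
  expect_equal(unname(bf$partition$assignment), c(1L, 1L, 2L))

  # all-equal similarities on 4 elements, balanced: any 2+2 split cuts 4 pairs
  ids <- paste0("y", 1:4)
  S <- matrix(0.25, 4, 4, dimnames = list(ids, ids)); diag(S) <- 1
  inst4 <- split_instance(tibble::tibble(id = ids), S)
  bf4 <- brute_force_optimum(inst4, split_spec(fractions = c(0.5, 0.5), epsilon = 0))
  expect_equal(bf4$objective, 4 * 0.25)

  expect_equal(
    brute_force_optimum(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0.1))$status,
    "infeasible")
  expect_error(brute_force_optimum(random_instance(13, 1), spec, max_elements = 12),
               "capped")
})

test_that("cut variables equal the separation indicator at the optimum", {
  for (seed in 1:5) {
    inst <- random_instance(7, seed = 400 + seed)
    sol <- solve_split(inst, split_spec(fractions = c(0.5, 0.5), epsilon = 0.34))
    expect_equal(sol$status, "optimal")
    a <- sol$partition$assignment
    cv <- sol$cut_values
    expect_equal(cv$zeta, as.numeric(a[cv$x] != a[cv$xp]))
  }
})

test_that("solver and enumeration agree on objectives across a small sweep", {
  grid <- random_specs_grid(25, seed = 2024)
  instances <- purrr::pmap(grid, function(case, n, k, epsilon, with_classes) {
    random_instance(n, seed = 5000 + case, with_classes = with_classes)
  })
  specs <- purrr::pmap(grid, function(case, n, k, epsilon, with_classes) {
    spec_for_case(k, epsilon)
  })
  sols <- solve_split_batch(instances, specs)
  for (i in seq_len(nrow(grid))) {
    bf <- brute_force_optimum(instances[[i]], specs[[i]])
    expect_equal(sols[[i]]$status, bf$status, info = paste("case", i))
    if (bf$status == "optimal") {
      expect_equal(sols[[i]]$objective, bf$objective, tolerance = 1e-6,
                   info = paste("case", i))
    }
  }
})

test_that("the enumeration backend plugs into solve_split", {
  inst <- tiny_instance()
  spec <- split_spec(fractions = c(0.5, 0.5), epsilon = 0.34)
  sol <- solve_split(inst, spec, backend = "enumeration")
  expect_equal(sol$objective, 0.3)
  expect_error(solve_split(inst, spec, backend = "gurobi"), "available")
})

test_that("LP export writes a parseable model file", {
  path <- withr::local_tempfile(fileext = ".lp")
  write_lp(build_ilp(tiny_instance(), split_spec(fractions = c(.5, .5))), path)
  txt <- readLines(path)
  expect_equal(txt[1], "Minimize")
  expect_true(any(grepl("^Subject To", txt)))
  expect_true(any(grepl("Binary", txt)))
})
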