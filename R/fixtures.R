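#' Synthetic block-structured split instance
#'
#' Generates an instance whose similarity matrix has planted block structure:
#' off-diagonal similarity `intra_sim` within blocks and `inter_sim` across
#' blocks, optionally perturbed by symmetric Gaussian jitter clipped back to
#' `[0, 1]`. The planted block labels are attached as attribute `"truth"` so
#' clustering and splitting stages can be tested against ground truth: the
#' optimal balanced 2-fold split of two equal blocks separates them, with
#' leakage `inter_sim * n1 * n2`.
#'
#' @param block_sizes Integer vector of block sizes (default `c(5, 5)`).
#' @param intra_sim,inter_sim Within- and between-block similarity;
#'   `0 <= inter_sim < intra_sim <= 1`.
#' @param jitter_sd Standard deviation of the symmetric jitter (default 0).
#' @param classes `NULL` (no classes), `"block"` (class label = block), or a
#'   named numeric vector of class proportions, honored exactly via
#'   largest-remainder counts and assigned to shuffled elements.
#' @param entity_type Entity type of all elements (default 1).
#' @param matrix_kind `"similarity"` (default) or `"distance"` (the planted
#'   matrix is complemented before storing).
#' @param prefix Element-id prefix.
#' @param seed Seed controlling jitter and random class assignment.
#' @return A [split_instance()] with attribute `"truth"` (named integer
#'   block labels).
#' @export
#' @examples
#' inst <- make_block_instance(block_sizes = c(5, 5), intra_sim = 0.9,
#'                             inter_sim = 0.05)
#' attr(inst, "truth")
make_block_instance <- function(block_sizes = c(5, 5), intra_sim = 0.9,
                                inter_sim = 0.05, jitter_sd = 0,
                                classes = NULL, entity_type = 1L,
                                matrix_kind = "similarity",
                                prefix = "e", seed = 1L) {
  stopifnot(all(block_sizes >= 1), inter_sim >= 0, intra_sim <= 1,
            inter_sim < intra_sim)
  n <- sum(block_sizes)
  ids <- paste0(prefix, sprintf("%02d", seq_len(n)))
  labels <- setNames(rep(seq_along(block_sizes), block_sizes), ids)
  S <- ifelse(outer(labels, labels, `==`), intra_sim, inter_sim)
  if (jitter_sd > 0) {
    J <- withr::with_seed(seed, matrix(rnorm(n * n, sd = jitter_sd), n, n))
    J <- (J + t(J)) / 2
    S <- pmin(pmax(S + J, 0), 1)
  }
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)

  cls <- NULL
  if (identical(classes, "block")) {
    cls <- map(unname(labels), ~ paste0("B", .x))
  } else if (is.numeric(classes) && !is.null(names(classes))) {
    # exact largest-remainder class counts, shuffled across elements, so the
    # fixture's class sizes match the requested proportions exactly
    counts <- largest_remainder(n, classes / sum(classes))
    pool <- rep(names(classes), counts)
    cls <- map(withr::with_seed(seed + 1L, sample(pool)), identity)
  }
  items <- tibble(id = ids, entity_type = as.integer(entity_type), weight = 1L)
  if (!is.null(cls)) items$classes <- cls
  if (identical(matrix_kind, "distance")) {
    M <- 1 - S
    diag(M) <- 0
  } else {
    M <- S
  }
  inst <- split_instance(items, setNames(list(M), as.character(entity_type)),
                         matrix_kind = matrix_kind)
  attr(inst, "truth") <- labels
  inst
}

#' Random fingerprint set
#'
#' Independent Bernoulli bit vectors, for exercising the Tanimoto backend
#' without chemistry. Two independent fingerprints of bit density d have
#' expected Tanimoto similarity d / (2 - d).
#'
#' @param n Number of fingerprints.
#' @param n_bits Bits per fingerprint (default 1024).
#' @param bit_density Probability that any bit is set, in `(0, 1]`.
#' @param seed Seed.
#' @return List of [fingerprint()] objects.
#' @export
make_fingerprint_set <- function(n, n_bits = 1024L, bit_density = 0.1,
                                 seed = 1L) {
  if (bit_density <= 0 || bit_density > 1) {
    abort("`bit_density` must lie in (0, 1].")
  }
  withr::with_seed(seed, map(seq_len(n), function(i) {
    fingerprint(rbinom(n_bits, 1, bit_density) == 1, origin = "full-molecule")
  }))
}

#' Synthetic two-dimensional instance with interactions
#'
#' Builds a two-entity-type instance (e.g. drugs x targets) where each type
#' has its own planted block structure, plus an interaction table sampled at
#' the given density with labels drawn from a standard normal. Useful for
#' testing two-dimensional splitting and the interaction discard rule: a
#' block-aligned split discards exactly the interactions whose endpoints sit
#' in blocks assigned to different folds.
#'
#' @param n_rows_blocks,n_cols_blocks Block sizes for entity types 1 and 2.
#' @param intra_sim,inter_sim,jitter_sd Passed to [make_block_instance()]
#'   for both types.
#' @param interaction_density Probability that a (row, column) pair is
#'   observed, in `(0, 1]`.
#' @param seed Seed.
#' @return List with `instance` (a two-type [split_instance()], block truth
#'   in attribute `"truth"`) and `interactions` (tibble `row_id`, `col_id`,
#'   `label`).
#' @export
make_two_dim_instance <- function(n_rows_blocks = c(5, 5),
                                  n_cols_blocks = c(4, 4),
                                  intra_sim = 0.9, inter_sim = 0.05,
                                  jitter_sd = 0, interaction_density = 0.5,
                                  seed = 1L) {
  if (interaction_density <= 0 || interaction_density > 1) {
    abort("`interaction_density` must lie in (0, 1].")
  }
  rows <- make_block_instance(n_rows_blocks, intra_sim, inter_sim, jitter_sd,
                              entity_type = 1L, prefix = "d", seed = seed)
  cols <- make_block_instance(n_cols_blocks, intra_sim, inter_sim, jitter_sd,
                              entity_type = 2L, prefix = "p", seed = seed + 1L)
  items <- bind_rows(rows$items, cols$items)
  inst <- split_instance(
    items,
    list("1" = rows$sim[["1"]], "2" = cols$sim[["2"]]),
    matrix_kind = c("similarity", "similarity")
  )
  attr(inst, "truth") <- c(attr(rows, "truth"), attr(cols, "truth"))

  grid <- tidyr::expand_grid(row_id = rows$items$id, col_id = cols$items$id)
  interactions <- withr::with_seed(seed + 2L, {
    keep <- runif(nrow(grid)) <= interaction_density
    g <- grid[keep, , drop = FALSE]
    g$label <- rnorm(nrow(g))
    g
  })
  list(instance = inst, interactions = as_tibble(interactions))
}

#' Replicate a one-type instance into two copies
#'
#' Constructs the copy-replication instance used to relate one- and
#' two-dimensional splitting. Every element x gets two copies `x@1` and
#' `x@2`; copies of the same element are tied by a very large similarity `M`
#' (forcing any optimal split to co-assign them); each within-copy pair
#' inherits its base similarity, and each unordered pair of distinct
#' elements additionally receives its base similarity once across the
#' copies. Any cut pair of the base instance therefore appears exactly
#' three times in the replicated cut (two within-copy pairs plus one
#' cross-copy pair), so the replicated optimum is exactly `3` times the
#' base optimum.
#'
#' @param instance A single-entity-type [split_instance()]. Cardinality
#'   weights are copied.
#' @param big_m Tie weight between copies of the same element; defaults to
#'   `4 * sum(sim) + 1` over distinct base pairs, which provably dominates
#'   any cut. The matrix deliberately leaves `[0, 1]`; this is a test
#'   construction, not a user-facing instance.
#' @return A [split_instance()] (built without range validation) over `2n`
#'   elements.
#' @export
make_replicated_instance <- function(instance, big_m = NULL) {
  stopifnot(length(inst_types(instance)) == 1)
  ty <- inst_types(instance)
  ids <- inst_ids(instance, ty)
  n <- length(ids)
  S <- similarity_matrix(instance, ty)
  diag(S) <- 0
  if (is.null(big_m)) {
    big_m <- 4 * sum(S[upper.tri(S)]) + 1
  }
  new_ids <- c(paste0(ids, "@1"), paste0(ids, "@2"))
  B <- matrix(0, 2 * n, 2 * n, dimnames = list(new_ids, new_ids))
  B[seq_len(n), seq_len(n)] <- S
  B[n + seq_len(n), n + seq_len(n)] <- S
  # one cross-copy counterpart per unordered base pair
  cross <- S
  cross[lower.tri(cross)] <- 0
  B[seq_len(n), n + seq_len(n)] <- cross
  B[n + seq_len(n), seq_len(n)] <- t(cross)
  # copies of the same element are tied with weight M
  for (j in seq_len(n)) {
    B[j, n + j] <- B[n + j, j] <- big_m
  }
  diag(B) <- 1
  w <- inst_weights(instance)[ids]
  items <- tibble(id = new_ids, entity_type = 1L, weight = rep(unname(w), 2))
  split_instance(items, list("1" = B), validate = FALSE)
}

#' Graph instance for minimum k-section experiments
#'
#' Encodes an unweighted graph as a splitting instance: unit cardinalities
#' and `sim(x, x') = 1` exactly when the edge exists. With equal fold
#' fractions and `epsilon = 0`, minimizing leakage over this instance is the
#' minimum k-section problem and the optimal objective equals the minimum
#' balanced cut size.
#'
#' @param edges Two-column matrix or data frame of vertex ids (character).
#' @param vertices Optional vector of vertex ids (to include isolated ones).
#' @return A [split_instance()].
#' @export
make_graph_instance <- function(edges, vertices = NULL) {
  edges <- as.matrix(edges)
  ids <- unique(c(as.character(edges), as.character(vertices %||% character())))
  ids <- sort(ids)
  S <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (e in seq_len(nrow(edges))) {
    a <- as.character(edges[e, 1]); b <- as.character(edges[e, 2])
    S[a, b] <- S[b, a] <- 1
  }
  diag(S) <- 1
  split_instance(tibble(id = ids), list("1" = S))
}
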