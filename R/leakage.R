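#' Leakage of a partition
#'
#' The leakage `L(pi)` of a fold assignment is the total similarity across
#' fold boundaries: the sum, over unordered distinct pairs of elements
#' assigned to different folds, of `sim(x, x') * kappa(x) * kappa(x')`. The
#' cardinality factors weight similarities between larger clusters more
#' heavily. Pairs of elements of different entity types contribute zero
#' (cross-type similarities are not supported), diagonal entries are ignored,
#' and distance-kind matrices enter through their complement `1 - dist`.
#'
#' @param partition A [fold_partition()] total over the instance.
#' @param instance A [split_instance()].
#' @return Non-negative numeric scalar.
#' @export
#' @examples
#' items <- tibble::tibble(id = c("a", "b", "c"))
#' S <- matrix(c(1, .5, .2, .5, 1, .1, .2, .1, 1), 3, 3,
#'             dimnames = list(items$id, items$id))
#' inst <- split_instance(items, S)
#' part <- fold_partition(c(a = 1, b = 1, c = 2), "baseline")
#' leakage(part, inst)  # 0.2 + 0.1 = 0.3
leakage <- function(partition, instance) {
  assert_total_partition(partition, instance)
  total <- 0
  for (ty in inst_types(instance)) {
    ids <- inst_ids(instance, ty)
    if (length(ids) < 2) next
    S <- similarity_matrix(instance, ty)
    w <- inst_weights(instance)[ids]
    folds <- partition$assignment[ids]
    cross <- outer(folds, folds, `!=`)
    W <- outer(w, w)
    contrib <- S * W * cross
    total <- total + sum(contrib[upper.tri(contrib)])
  }
  total
}

#' Scaled leakage in [0, 1]
#'
#' Normalizes [leakage()] by the total pairwise similarity of the instance,
#' so that 0 means no similarity crosses a fold boundary and 1 means all of
#' it does. The denominator is the sum over unordered distinct pairs of
#' `sim(x, x')`, by default carrying the same cardinality weighting as the
#' numerator (so the ratio is guaranteed to stay within `[0, 1]`); set
#' `kappa_weighted = FALSE` to drop the cardinality factors from the
#' denominator only.
#'
#' @inheritParams leakage
#' @param kappa_weighted Include cardinality factors in the denominator
#'   (default `TRUE`).
#' @return A `leakage_result`: list with `raw`, `scaled` and `denominator`.
#'   `scaled` is 0 when the denominator is 0.
#' @export
scaled_leakage <- function(partition, instance, kappa_weighted = TRUE) {
  raw <- leakage(partition, instance)
  denom <- 0
  for (ty in inst_types(instance)) {
    ids <- inst_ids(instance, ty)
    if (length(ids) < 2) next
    S <- similarity_matrix(instance, ty)
    w <- inst_weights(instance)[ids]
    M <- if (kappa_weighted) S * outer(w, w) else S
    denom <- denom + sum(M[upper.tri(M)])
  }
  structure(
    list(raw = raw, scaled = if (denom > 0) raw / denom else 0,
         denominator = denom),
    class = "leakage_result"
  )
}

#' Per-test-sample worst-case leakage
#'
#' An earlier quantification of train/test leakage: for each element of the
#' test fold, only its single largest similarity to any training element is
#' counted, and the result is averaged over the test fold. Kept for
#' comparison with [leakage()], which instead sums every cross-fold
#' similarity and treats all folds symmetrically.
#'
#' @inheritParams leakage
#' @param train,test Fold indices to treat as training and test set.
#' @return Numeric scalar in `[0, 1]` for normalized similarities.
#' @export
elangovan_leakage <- function(partition, instance, train = 1L, test = 2L) {
  assert_total_partition(partition, instance)
  test_ids <- names(partition$assignment)[partition$assignment == test]
  train_ids <- names(partition$assignment)[partition$assignment == train]
  if (length(test_ids) == 0 || length(train_ids) == 0) abort("empty fold")
  per_elem <- map_dbl(test_ids, function(x) {
    ty <- instance$items$entity_type[match(x, instance$items$id)]
    peers <- intersect(train_ids, inst_ids(instance, ty))
    if (length(peers) == 0) return(0)
    S <- similarity_matrix(instance, ty)
    max(S[x, peers])
  })
  mean(per_elem)
}

#' @export
print.leakage_result <- function(x, ...) {
  cat("<leakage_result> raw L(pi) = ", signif(x$raw, 6),
      ", scaled = ", signif(x$scaled, 6),
      " (denominator ", signif(x$denominator, 6), ")\n", sep = "")
  invisible(x)
}
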