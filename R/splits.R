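#' Similarity-aware split via cluster-then-solve
#'
#' The scalable pipeline for similarity-based splitting (techniques S1/S2):
#' cluster each entity type into at most `K` groups
#' ([cluster_elements()]), build the reduced instance over clusters with the
#' chosen linkage ([reduce_instance()]), solve the reduced problem exactly
#' ([solve_split()]), and unpack the cluster assignment back to elements
#' ([unpack_partition()]). Because cluster cardinalities and class masses
#' aggregate their members exactly, a feasible cluster partition always
#' unpacks to a feasible element partition.
#'
#' @param instance A [split_instance()].
#' @param spec A [split_spec()].
#' @param K Clusters per entity type (default 50).
#' @param linkage Cluster-similarity linkage; see [reduce_instance()].
#' @param seed Seed for the clustering stage; defaults to `spec$seed`.
#' @param backend ILP backend, see [milp_backends()].
#' @return A [fold_partition()] with provenance `"heuristic"` and the
#'   element-level leakage as objective. The cluster partition and cluster
#'   sets are attached as attributes `"cluster_partition"` and `"clusters"`.
#' @export
#' @examples
#' \dontrun{
#' inst <- make_block_instance(block_sizes = c(5, 5))
#' part <- heuristic_split(inst, split_spec(fractions = c(.5, .5), epsilon = .2), K = 2)
#' leakage(part, inst)
#' }
heuristic_split <- function(instance, spec, K = 50L,
                            linkage = c("average", "single", "complete"),
                            seed = spec$seed, backend = "highs") {
  linkage <- match.arg(linkage)
  clusters <- cluster_elements(instance, K = K, seed = seed)
  reduced <- reduce_instance(instance, clusters, linkage = linkage)
  sol <- solve_split(reduced, spec, backend = backend)
  if (sol$status == "infeasible") {
    abort(paste0("reduced instance is infeasible (", sol$message,
                 "); consider raising epsilon/delta or K"))
  }
  part <- unpack_partition(sol$partition, clusters)
  part$provenance <- "heuristic"
  part$objective <- leakage(part, instance)
  attr(part, "cluster_partition") <- sol$partition
  attr(part, "clusters") <- clusters
  part
}

#' Unpack a cluster partition to the elements
#'
#' Assigns every element the fold of its cluster.
#'
#' @param cluster_partition A [fold_partition()] over cluster ids.
#' @param clusters Per-type cluster sets from [cluster_elements()].
#' @return A [fold_partition()] over element ids.
#' @export
unpack_partition <- function(cluster_partition, clusters) {
  members <- purrr::flatten(map(clusters, "clusters"))
  ids <- unlist(members, use.names = FALSE)
  folds <- rep(map_int(names(members), ~ cluster_partition$assignment[[.x]]),
               lengths(members))
  fold_partition(setNames(folds, ids),
                 provenance = cluster_partition$provenance)
}

#' Assign interaction records to folds, discarding cross-fold pairs
#'
#' For two-dimensional data each record links one element of entity type 1
#' (rows, e.g. drugs) to one of entity type 2 (columns, e.g. protein
#' targets). A record is assigned to fold i exactly when both endpoints are;
#' records whose endpoints fall into different folds cannot be kept without
#' leaking information across the boundary and are discarded.
#'
#' @param partition A [fold_partition()] covering both endpoint sets.
#' @param interactions Data frame with columns `row_id`, `col_id` and
#'   optionally `label`.
#' @return The interaction tibble with added columns `fold` (integer, `NA`
#'   when discarded) and `status` (`"assigned"`/`"discarded"`); attributes
#'   `n_discarded` and `discard_fraction`.
#' @export
assign_interactions <- function(partition, interactions) {
  interactions <- as_tibble(interactions)
  stopifnot(all(c("row_id", "col_id") %in% names(interactions)))
  a <- partition$assignment
  missing <- setdiff(unique(c(interactions$row_id, interactions$col_id)), names(a))
  if (length(missing) > 0) {
    bad <- interactions %>%
      filter(.data$row_id %in% missing | .data$col_id %in% missing)
    abort(paste0("interaction endpoint(s) missing from partition, e.g. record (",
                 bad$row_id[1], ", ", bad$col_id[1], ")"))
  }
  out <- interactions %>%
    mutate(
      fold = unname(ifelse(a[.data$row_id] == a[.data$col_id],
                           a[.data$row_id], NA_integer_)),
      status = ifelse(is.na(.data$fold), "discarded", "assigned")
    )
  n_disc <- sum(out$status == "discarded")
  structure(out, n_discarded = n_disc,
            discard_fraction = if (nrow(out) > 0) n_disc / nrow(out) else 0)
}

#' Random interaction-based split
#'
#' Technique R: shuffles the interaction records themselves into folds
#' according to the requested fractions, ignoring both element identity and
#' similarity. The leakiest baseline: the same molecule can appear in every
#' fold.
#'
#' @param interactions Data frame with `row_id`, `col_id` and optional
#'   `label` columns.
#' @param spec A [split_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return The interaction tibble with `fold` and `status` columns (no
#'   record is discarded).
#' @export
random_interaction_split <- function(interactions, spec, seed = spec$seed) {
  interactions <- as_tibble(interactions)
  n <- nrow(interactions)
  counts <- largest_remainder(n, spec$fractions)
  folds <- rep(seq_len(spec$k), counts)
  perm <- withr::with_seed(seed, sample.int(n))
  interactions$fold <- folds[order(perm)]
  interactions$status <- "assigned"
  interactions
}

largest_remainder <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(raw - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

#' Random identity-based split
#'
#' Technique I1/I2 baseline: a seeded shuffle followed by a greedy fill that
#' always hands the next element to the fold with the largest remaining
#' cardinality deficit relative to its target `s_i * n_r` (per entity type).
#' Similarity is ignored entirely. Errors when the resulting partition
#' cannot meet the fraction bounds.
#'
#' @param instance A [split_instance()].
#' @param spec A [split_spec()].
#' @param seed Seed; defaults to `spec$seed`.
#' @return A [fold_partition()] with provenance `"baseline"`.
#' @export
random_split <- function(instance, spec, seed = spec$seed) {
  greedy_fill(instance, spec, seed, stratified = FALSE)
}

#' Stratified random split
#'
#' Like [random_split()], but the greedy deficit is computed per class so
#' each fold preserves the class proportions within `delta`, as in classical
#' stratified sampling. Elements without classes fall back to the type-level
#' deficit.
#'
#' @inheritParams random_split
#' @return A [fold_partition()] with provenance `"baseline"`.
#' @export
stratified_random_split <- function(instance, spec, seed = spec$seed) {
  greedy_fill(instance, spec, seed, stratified = TRUE)
}

greedy_fill <- function(instance, spec, seed, stratified) {
  items <- instance$items
  k <- spec$k
  s <- unname(spec$fractions)
  tm <- type_mass(instance)
  # per-(type, fold) cardinality targets s_i * n_r; the next element goes to
  # the fold that is most underfilled RELATIVE to its target, so small folds
  # and small classes are not starved by large ones
  targets <- setNames(map(tm$n_r, ~ s * .x), tm$entity_type)
  deficit <- targets
  cls_targets <- NULL
  if (stratified) {
    totals <- class_mass_totals(instance)
    if (nrow(totals) > 0) {
      keys <- paste(totals$entity_type, totals$class, sep = "/")
      cls_targets <- setNames(map(totals$n_rc, ~ s * .x), keys)
    }
  }
  cls_deficit <- cls_targets
  cm <- instance$class_mass
  perm <- withr::with_seed(seed, sample.int(nrow(items)))
  assign <- integer(nrow(items))
  for (j in perm) {
    ty <- as.character(items$entity_type[j])
    w <- items$weight[j]
    score <- deficit[[ty]] / targets[[ty]]
    if (!is.null(cls_deficit)) {
      cls <- cm$class[cm$id == items$id[j]]
      if (length(cls) > 0) {
        keys <- paste(items$entity_type[j], cls, sep = "/")
        score <- Reduce(`+`, map(keys, ~ cls_deficit[[.x]] / cls_targets[[.x]]))
      }
    }
    i <- which.max(score)
    assign[j] <- i
    deficit[[ty]][i] <- deficit[[ty]][i] - w
    if (!is.null(cls_deficit)) {
      cls <- cm$class[cm$id == items$id[j]]
      for (cl in cls) {
        key <- paste(items$entity_type[j], cl, sep = "/")
        m <- cm$mass[cm$id == items$id[j] & cm$class == cl]
        cls_deficit[[key]][i] <- cls_deficit[[key]][i] - m
      }
    }
  }
  part <- fold_partition(setNames(assign, items$id), provenance = "baseline")
  rep <- check_constraints(part, instance, spec)
  if (!is_feasible(rep)) {
    bad <- dplyr::filter(rep, !.data$met)
    abort(paste0("random split infeasible: fold ", bad$fold[1], ", type ",
                 bad$entity_type[1],
                 if (!is.na(bad$class[1])) paste0(", class ", bad$class[1]) else "",
                 " achieved mass ", bad$mass[1], " < bound ", signif(bad$bound[1], 6)))
  }
  part$objective <- leakage(part, instance)
  part
}
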