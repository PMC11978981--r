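#' Cluster the elements of each entity type
#'
#' Groups the elements of every entity type into at most `K` clusters so that
#' the splitting problem can be solved on a constant-size reduced instance.
#' Similarity-kind matrices are clustered with spectral clustering (the
#' matrix is treated as a kernel matrix); distance-kind matrices with
#' agglomerative (average-linkage) hierarchical clustering. Clustering is
#' performed independently per entity type, so a two-dimensional instance
#' yields up to `2K` clusters in total. Deterministic given `seed`.
#'
#' @param instance A [split_instance()] with normalized matrices.
#' @param K Target number of clusters per entity type (default 50); capped at
#'   the number of elements of the type.
#' @param seed Integer seed for the spectral initialization.
#' @return Named list (by entity type) of `cluster_set` objects, each with
#'   `clusters` (named list: cluster id -> member ids), `labels` (named
#'   integer vector element -> cluster index) and `K_effective`.
#' @export
cluster_elements <- function(instance, K = 50L, seed = 42L) {
  if (K < 1) abort("`K` must be at least 1.")
  out <- list()
  for (ty in inst_types(instance)) {
    ids <- inst_ids(instance, ty)
    n <- length(ids)
    k_eff <- min(K, n)
    labels <- if (k_eff == 1) {
      setNames(rep(1L, n), ids)
    } else if (k_eff == n) {
      setNames(seq_len(n), ids)
    } else if (identical(unname(instance$matrix_kind[[as.character(ty)]]), "distance")) {
      d <- instance$sim[[as.character(ty)]]
      hc <- hclust(as.dist(d), method = "average")
      setNames(as.integer(cutree(hc, k = k_eff)), ids)
    } else {
      S <- similarity_matrix(instance, ty)
      spectral_labels(S, k_eff, seed)
    }
    labels <- setNames(as.integer(labels), ids)
    members <- split(ids, labels)
    cluster_ids <- paste0("t", ty, "_c", sprintf("%03d", seq_along(members)))
    names(members) <- cluster_ids
    out[[as.character(ty)]] <- structure(
      list(clusters = members, labels = labels,
           K_effective = length(members), entity_type = ty),
      class = "cluster_set"
    )
  }
  out
}

# spectral clustering of a similarity matrix treated as a kernel matrix;
# falls back to a spectral-embedding + kmeans path if specc's own
# initialization degenerates (it can on near-block-constant kernels)
spectral_labels <- function(S, k, seed) {
  ids <- rownames(S)
  S2 <- S
  diag(S2) <- 1
  res <- withr::with_seed(seed, tryCatch(
    as.integer(kernlab::specc(kernlab::as.kernelMatrix(S2), centers = k)@.Data),
    error = function(e) NULL
  ))
  if (is.null(res) || length(unique(res)) < k) {
    res <- withr::with_seed(seed, {
      d <- pmax(rowSums(S2), .Machine$double.eps)
      L <- diag(1 / sqrt(d)) %*% S2 %*% diag(1 / sqrt(d))
      ev <- eigen(L, symmetric = TRUE)
      emb <- ev$vectors[, seq_len(k), drop = FALSE]
      norms <- pmax(sqrt(rowSums(emb^2)), .Machine$double.eps)
      emb <- emb / norms
      as.integer(stats::kmeans(emb, centers = k, nstart = 10)$cluster)
    })
  }
  setNames(res, ids)
}

#' Build the reduced instance over clusters
#'
#' Replaces elements by clusters: the cardinality of a cluster is the summed
#' cardinality of its members; the similarity between two clusters is the
#' chosen linkage over all member pairs; the class mass of a cluster is the
#' summed member mass per class, so stratification bounds on the reduced
#' instance are evaluated on true member counts (a feasible cluster
#' partition therefore unpacks to a feasible element partition). For
#' distance-kind matrices the linkage is applied to distances and the result
#' complemented (`sim = 1 - dist`). Cross-type cluster similarity remains
#' zero.
#'
#' On similarity matrices, `"single"` linkage keeps the maximum member-pair
#' similarity (the strongest potential leak between the clusters),
#' `"complete"` the minimum, `"average"` the mean; on distances the
#' conventional orientation (min/max/mean of distances) applies.
#'
#' @param instance A [split_instance()].
#' @param clusters Per-type cluster sets from [cluster_elements()].
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @return A [split_instance()] whose elements are clusters, carrying the
#'   member map in attribute `"members"`.
#' @export
reduce_instance <- function(instance, clusters,
                            linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  all_clustered <- unlist(map(clusters, ~ unlist(.x$clusters)), use.names = FALSE)
  missing <- setdiff(instance$items$id, all_clustered)
  if (length(missing) > 0) {
    abort(paste0("element(s) missing from every cluster: ",
                 paste(head(missing, 5), collapse = ", ")))
  }

  w <- inst_weights(instance)
  item_rows <- list(); sim_list <- list(); members_all <- list()
  cm_rows <- list()
  for (ty in inst_types(instance)) {
    cs <- clusters[[as.character(ty)]]
    members <- cs$clusters
    cids <- names(members)
    kappa_C <- map_dbl(members, ~ sum(w[.x]))
    item_rows[[as.character(ty)]] <- tibble(
      id = cids, entity_type = ty, weight = unname(kappa_C),
      classes = map(members, function(ms) {
        sort(unique(instance$class_mass$class[instance$class_mass$id %in% ms]))
      })
    )
    raw <- instance$sim[[as.character(ty)]]  # linkage on the stored kind
    is_dist <- identical(unname(instance$matrix_kind[[as.character(ty)]]), "distance")
    linker <- linkage_fun(linkage, on_distance = is_dist)
    nc <- length(cids)
    M <- matrix(0, nc, nc, dimnames = list(cids, cids))
    if (nc > 1) {
      for (a in seq_len(nc - 1)) {
        for (b in (a + 1):nc) {
          vals <- raw[members[[a]], members[[b]], drop = FALSE]
          M[a, b] <- M[b, a] <- linker(vals)
        }
      }
    }
    if (is_dist) M <- 1 - M  # reduced instance is always similarity-kind
    diag(M) <- 1
    sim_list[[as.character(ty)]] <- M
    members_all <- c(members_all, members)

    if (nrow(instance$class_mass) > 0) {
      cm <- instance$class_mass %>% filter(.data$id %in% unlist(members))
      if (nrow(cm) > 0) {
        lab <- setNames(rep(cids, lengths(members)), unlist(members))
        cm_rows[[as.character(ty)]] <- cm %>%
          mutate(id = lab[.data$id]) %>%
          group_by(.data$id, .data$class) %>%
          summarise(mass = sum(.data$mass), .groups = "drop")
      }
    }
  }

  reduced <- split_instance(
    items = bind_rows(item_rows),
    sim = sim_list,
    matrix_kind = "similarity",
    class_mass = if (length(cm_rows) > 0) bind_rows(cm_rows) else NULL
  )
  attr(reduced, "members") <- members_all
  reduced
}

linkage_fun <- function(linkage, on_distance) {
  if (on_distance) {
    switch(linkage, average = function(v) mean(v),
           single = function(v) min(v), complete = function(v) max(v))
  } else {
    # orientation flipped on similarities: "single" keeps the strongest link
    switch(linkage, average = function(v) mean(v),
           single = function(v) max(v), complete = function(v) min(v))
  }
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set> type ", x$entity_type, ": ", length(x$labels),
      " elements in ", x$K_effective, " clusters\n", sep = "")
  invisible(x)
}
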