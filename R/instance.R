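#' Build a split instance
#'
#' A split instance bundles the elements to be partitioned into folds with
#' everything the optimizer needs to know about them: an entity type (1 for
#' one-dimensional data; 1 or 2 for two-dimensional data such as drugs vs.
#' protein targets), a positive integer cardinality weight (1 for elementary
#' data points, the member count for clusters), an optional set of class
#' labels used for stratification, and one square pairwise similarity (or
#' distance) matrix per entity type with entries in `[0, 1]`.
#'
#' Cross-type similarities are not supported and are treated as zero
#' throughout. Distance matrices are converted to similarities
#' (`1 - dist`) wherever a similarity is needed.
#'
#' @param items A data frame with one row per element. Columns: `id`
#'   (character, unique; required), `entity_type` (integer 1 or 2; default 1),
#'   `weight` (positive integer cardinality; default 1), `classes` (optional;
#'   either a list-column of character vectors or a character column with
#'   comma-separated labels; empty / `NA` means unclassified).
#' @param sim A square numeric matrix (single entity type) or a list of
#'   matrices indexed by entity type. Row/column names must match the element
#'   ids of that type; unnamed matrices are assumed to follow item order.
#' @param matrix_kind `"similarity"` or `"distance"`, recycled per type.
#' @param class_mass Optional data frame `(id, class, mass)` overriding the
#'   per-element class masses. Used by [reduce_instance()] so that a cluster
#'   mixing classes carries the true member mass per class rather than its
#'   whole cardinality. Defaults to `weight` for every class an element holds.
#' @param validate If `TRUE` (default), fail on any invariant violation;
#'   see [validate_instance()].
#'
#' @return An object of class `split_instance`.
#' @seealso [validate_instance()], [make_block_instance()], [split_spec()]
#' @export
#' @examples
#' items <- tibble::tibble(id = c("a", "b", "c"))
#' S <- matrix(c(1, .5, .2, .5, 1, .1, .2, .1, 1), 3, 3,
#'             dimnames = list(items$id, items$id))
#' inst <- split_instance(items, S)
split_instance <- function(items, sim, matrix_kind = "similarity",
                           class_mass = NULL, validate = TRUE) {
  items <- as_tibble(items)
  if (!"id" %in% names(items)) abort("`items` must have an `id` column.")
  items$id <- as.character(items$id)
  if (!"entity_type" %in% names(items)) items$entity_type <- 1L
  items$entity_type <- as.integer(items$entity_type)
  if (!"weight" %in% names(items)) items$weight <- 1L
  items$weight <- as.numeric(items$weight)
  items$classes <- parse_classes(items)

  types <- sort(unique(items$entity_type))
  if (is.matrix(sim)) sim <- setNames(list(sim), as.character(types[1]))
  if (is.null(names(sim))) names(sim) <- as.character(types[seq_along(sim)])
  matrix_kind <- setNames(rep(matrix_kind, length.out = length(sim)), names(sim))

  sim <- imap(sim, function(m, ty) {
    ids <- items$id[items$entity_type == as.integer(ty)]
    m <- as.matrix(m)
    if (is.null(dimnames(m)) && nrow(m) == length(ids)) {
      dimnames(m) <- list(ids, ids)
    }
    if (!is.null(rownames(m)) && setequal(rownames(m), ids)) {
      m <- m[ids, ids, drop = FALSE]
    }
    # symmetrize tiny asymmetries; larger ones are reported by validation
    if (is.numeric(m) && nrow(m) == ncol(m) &&
        max(abs(m - t(m)), na.rm = TRUE) <= 1e-9) {
      m <- (m + t(m)) / 2
    }
    m
  })

  if (is.null(class_mass)) {
    class_mass <- default_class_mass(items)
  } else {
    class_mass <- as_tibble(class_mass)
    stopifnot(all(c("id", "class", "mass") %in% names(class_mass)))
  }

  out <- structure(
    list(items = items, sim = sim, matrix_kind = matrix_kind,
         class_mass = class_mass),
    class = "split_instance"
  )
  if (validate) {
    bad <- validate_instance(out)
    if (length(bad) > 0) {
      abort(paste0("invalid split instance:\n", paste("-", bad, collapse = "\n")))
    }
  }
  out
}

parse_classes <- function(items) {
  if (!"classes" %in% names(items)) return(rep(list(character()), nrow(items)))
  cl <- items$classes
  if (is.list(cl)) {
    return(map(cl, function(x) if (length(x) == 0 || all(is.na(x))) character() else as.character(x)))
  }
  map(as.character(cl), function(x) {
    if (is.na(x) || !nzchar(x)) character() else trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  })
}

default_class_mass <- function(items) {
  rows <- purrr::pmap(list(items$id, items$classes, items$weight), function(id, cls, w) {
    if (length(cls) == 0) return(NULL)
    tibble(id = id, class = cls, mass = w)
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) tibble(id = character(), class = character(), mass = numeric()) else out
}

#' Validate a split instance
#'
#' Checks every structural invariant of a [split_instance()] and returns a
#' character vector describing each violation (empty when the instance is
#' well-formed): unique ids, entity types in \{1, 2\}, cardinalities at least
#' one, one square matrix per entity type with matching dimension and labels,
#' symmetry within `1e-9`, and all entries inside `[0, 1]`.
#'
#' @param instance A `split_instance`.
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_instance <- function(instance) {
  v <- character()
  items <- instance$items
  dup <- items$id[duplicated(items$id)]
  if (length(dup) > 0) v <- c(v, paste0("duplicate element id(s): ", paste(unique(dup), collapse = ", ")))
  if (!all(items$entity_type %in% c(1L, 2L))) {
    v <- c(v, "entity types other than 1 and 2 are not supported")
  }
  bad_w <- items$id[items$weight < 1 | items$weight != floor(items$weight)]
  if (length(bad_w) > 0) v <- c(v, paste0("cardinality must be a positive integer for: ", paste(bad_w, collapse = ", ")))

  for (ty in sort(unique(items$entity_type))) {
    ids <- items$id[items$entity_type == ty]
    m <- instance$sim[[as.character(ty)]]
    if (is.null(m)) {
      v <- c(v, paste0("no matrix supplied for entity type ", ty))
      next
    }
    if (nrow(m) != ncol(m)) {
      v <- c(v, paste0("matrix for type ", ty, " is not square (", nrow(m), "x", ncol(m), ")"))
      next
    }
    if (nrow(m) != length(ids)) {
      v <- c(v, paste0("matrix for type ", ty, " has dimension ", nrow(m),
                       " but the type has ", length(ids), " elements"))
      next
    }
    if (!identical(rownames(m), ids) || !identical(colnames(m), ids)) {
      v <- c(v, paste0("matrix labels for type ", ty, " do not match element ids/order"))
    }
    asym <- abs(m - t(m))
    if (any(asym > 1e-9, na.rm = TRUE)) {
      idx <- which(asym > 1e-9, arr.ind = TRUE)[1, ]
      v <- c(v, paste0("matrix for type ", ty, " is asymmetric at [",
                       rownames(m)[idx[1]], ", ", colnames(m)[idx[2]], "]: ",
                       signif(m[idx[1], idx[2]], 6), " vs ", signif(m[idx[2], idx[1]], 6)))
    }
    off <- m; diag(off) <- 0  # the diagonal is ignored everywhere
    bad <- which(off < 0 | off > 1 | !is.finite(off), arr.ind = TRUE)
    if (nrow(bad) > 0) {
      i <- bad[1, ]
      v <- c(v, paste0("matrix entry for type ", ty, " outside [0, 1] at [",
                       rownames(m)[i[1]], ", ", colnames(m)[i[2]], "]: ",
                       signif(m[i[1], i[2]], 6)))
    }
  }
  v
}

#' Specify the requested split
#'
#' Collects the user-facing parameters of the splitting problem: the number
#' of folds `k`, the requested fold fractions `s_i` (summing to one; names,
#' if given, become fold names such as `train`/`test`), and the relative
#' tolerances `epsilon` (fold-fraction constraints: each fold and entity type
#' must receive total cardinality at least `(1 - epsilon) * s_i * n_r`) and
#' `delta` (the same bound per class, enforcing stratification).
#'
#' @param k Number of folds (>= 2). Defaults to the length of `fractions`.
#' @param fractions Numeric vector of fold fractions in (0, 1) summing to 1.
#' @param epsilon Relative tolerance on fold fractions, in `[0, 1)`.
#' @param delta Relative tolerance on per-class fractions, in `[0, 1]`.
#'   `delta = 1` disables stratification.
#' @param technique One of `"I1"`, `"S1"`, `"I2"`, `"S2"`, `"R"` — identity- or
#'   similarity-based splitting of 1D/2D data, or random interaction-based
#'   splitting. Informational outside [run_cli()].
#' @param solver_time_limit_s Wall-clock limit passed to the ILP solver.
#' @param seed Integer seed governing every stochastic step.
#' @return An object of class `split_spec`.
#' @export
#' @examples
#' split_spec(fractions = c(train = 0.8, test = 0.2), epsilon = 0.1)
split_spec <- function(k = length(fractions), fractions = c(0.8, 0.2),
                       epsilon = 0.1, delta = 0.1, technique = "S1",
                       solver_time_limit_s = 1000, seed = 42L) {
  k <- as.integer(k)
  if (k < 2) abort("`k` must be at least 2.")
  if (length(fractions) != k) abort("`fractions` must have length `k`.")
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1.")
  if (any(fractions <= 0 | fractions >= 1)) abort("each fraction must lie in (0, 1).")
  if (epsilon < 0 || epsilon >= 1) abort("`epsilon` must lie in [0, 1).")
  if (delta < 0 || delta > 1) abort("`delta` must lie in [0, 1].")
  technique <- match.arg(technique, c("I1", "S1", "I2", "S2", "R"))
  if (is.null(names(fractions))) names(fractions) <- paste0("fold", seq_len(k))
  structure(
    list(k = k, fractions = fractions, epsilon = epsilon, delta = delta,
         technique = technique, solver_time_limit_s = solver_time_limit_s,
         seed = as.integer(seed)),
    class = "split_spec"
  )
}

#' Construct a fold partition
#'
#' A total mapping from element ids to fold indices in `1..k`, together with
#' provenance (`"exact"`, `"heuristic"` or `"baseline"`) and, when known, the
#' leakage objective value achieved.
#'
#' @param assignment Named integer vector: element id -> fold index.
#' @param provenance How the partition was produced.
#' @param objective Optional leakage value `L(pi)`.
#' @return An object of class `fold_partition`.
#' @export
fold_partition <- function(assignment,
                           provenance = c("exact", "heuristic", "baseline"),
                           objective = NULL) {
  provenance <- match.arg(provenance)
  if (is.null(names(assignment))) abort("`assignment` must be named by element id.")
  structure(
    list(assignment = setNames(as.integer(assignment), names(assignment)),
         provenance = provenance, objective = objective),
    class = "fold_partition"
  )
}

# -- internal accessors -------------------------------------------------------

inst_types <- function(instance) sort(unique(instance$items$entity_type))

inst_ids <- function(instance, type = NULL) {
  if (is.null(type)) return(instance$items$id)
  instance$items$id[instance$items$entity_type == type]
}

inst_weights <- function(instance) {
  setNames(instance$items$weight, instance$items$id)
}

# similarity matrix for one entity type, distances complemented
similarity_matrix <- function(instance, type) {
  m <- instance$sim[[as.character(type)]]
  if (identical(unname(instance$matrix_kind[[as.character(type)]]), "distance")) {
    m <- 1 - m
  }
  m
}

# total cardinality per entity type (n_r)
type_mass <- function(instance) {
  instance$items %>%
    group_by(.data$entity_type) %>%
    summarise(n_r = sum(.data$weight), .groups = "drop")
}

# total cardinality per (entity type, class) (n_r^c)
class_mass_totals <- function(instance) {
  cm <- instance$class_mass
  if (nrow(cm) == 0) return(tibble(entity_type = integer(), class = character(), n_rc = numeric()))
  cm %>%
    left_join(select(instance$items, "id", "entity_type"), by = "id") %>%
    group_by(.data$entity_type, .data$class) %>%
    summarise(n_rc = sum(.data$mass), .groups = "drop")
}

assert_total_partition <- function(partition, instance) {
  ids <- instance$items$id
  unknown <- setdiff(names(partition$assignment), ids)
  if (length(unknown) > 0) {
    abort(paste0("unknown element(s) in partition: ", paste(head(unknown, 5), collapse = ", ")))
  }
  missing <- setdiff(ids, names(partition$assignment))
  if (length(missing) > 0) {
    abort(paste0("partition is partial; unassigned element(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

#' @export
print.split_instance <- function(x, ...) {
  tm <- type_mass(x)
  cat("<split_instance> ", nrow(x$items), " elements, ",
      length(unique(x$items$entity_type)), " entity type(s)\n", sep = "")
  for (i in seq_len(nrow(tm))) {
    ty <- tm$entity_type[i]
    cat("  type ", ty, ": ", sum(x$items$entity_type == ty), " elements, mass ",
        tm$n_r[i], ", ", x$matrix_kind[[as.character(ty)]], " matrix\n", sep = "")
  }
  ncl <- length(unique(x$class_mass$class))
  if (ncl > 0) cat("  classes: ", ncl, "\n", sep = "")
  invisible(x)
}

#' @export
print.split_spec <- function(x, ...) {
  cat("<split_spec> k=", x$k, " technique=", x$technique,
      " epsilon=", x$epsilon, " delta=", x$delta, "\n  fractions: ",
      paste0(names(x$fractions), "=", x$fractions, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.fold_partition <- function(x, ...) {
  cat("<fold_partition> ", length(x$assignment), " elements in ",
      length(unique(x$assignment)), " folds (", x$provenance, ")\n", sep = "")
  if (!is.null(x$objective)) cat("  leakage objective: ", signif(x$objective, 6), "\n", sep = "")
  invisible(x)
}
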