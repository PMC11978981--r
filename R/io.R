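#' Read an item table
#'
#' Reads a TSV or CSV (by extension) with one row per element. Required
#' column: `id`. Recognized optional columns: `smiles`, `class`/`classes`
#' (comma-separated multi-labels), `weight`, `entity_type`. Duplicate ids
#' are rejected.
#'
#' @param path File path.
#' @return Tibble of element records in file order, with a `classes`
#'   list-column when class labels are present.
#' @export
read_items <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv
  } else {
    readr::read_tsv
  }
  tbl <- reader(path, show_col_types = FALSE, progress = FALSE)
  if (!"id" %in% names(tbl)) abort(paste0("missing `id` column in ", path))
  tbl$id <- as.character(tbl$id)
  dup <- unique(tbl$id[duplicated(tbl$id)])
  if (length(dup) > 0) {
    abort(paste0("duplicate id(s) in ", path, ": ", paste(head(dup, 5), collapse = ", ")))
  }
  if ("class" %in% names(tbl) && !"classes" %in% names(tbl)) {
    tbl <- rename(tbl, classes = "class")
  }
  if ("classes" %in% names(tbl)) tbl$classes <- parse_classes(tbl)
  as_tibble(tbl)
}

#' Read element records from a FASTA file
#'
#' Record ids are taken from the headers (up to the first whitespace);
#' sequences are retained as metadata only — pairwise similarity for
#' sequence data must be supplied as a user matrix ([read_matrix()]),
#' e.g. from an external identity/alignment tool. Duplicate headers and
#' empty files are rejected.
#'
#' @param path FASTA file path.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) abort(paste0("malformed FASTA ", path, ": ",
                                                    conditionMessage(e))))
  if (length(seqs) == 0) abort(paste0("empty FASTA file: ", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA header(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  tibble(id = ids, sequence = unname(as.character(seqs)))
}

#' Read a labeled square matrix
#'
#' Reads a TSV whose first row and first column hold element ids. The matrix
#' is aligned to `ids` when given; unmatched or missing labels are an error,
#' as is asymmetry beyond the `1e-9` tolerance (smaller asymmetries are
#' averaged away).
#'
#' @param path TSV file path.
#' @param ids Optional element ids to align (and restrict) the matrix to.
#' @return Square numeric matrix with dimnames.
#' @export
read_matrix <- function(path, ids = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  labels <- as.character(tbl[[1]])
  m <- as.matrix(tbl[, -1, drop = FALSE])
  if (!is.numeric(m)) abort(paste0("non-numeric cell(s) in matrix ", path))
  rownames(m) <- labels
  if (nrow(m) != ncol(m) || !setequal(labels, colnames(m))) {
    abort(paste0("matrix in ", path, " is not square or row/column labels differ"))
  }
  m <- m[, labels, drop = FALSE]
  if (!is.null(ids)) {
    missing <- setdiff(ids, labels)
    if (length(missing) > 0) {
      abort(paste0("matrix ", path, " lacks id(s): ", paste(head(missing, 5), collapse = ", ")))
    }
    m <- m[ids, ids, drop = FALSE]
  }
  if (max(abs(m - t(m))) > 1e-9) {
    idx <- which(abs(m - t(m)) > 1e-9, arr.ind = TRUE)[1, ]
    abort(paste0("matrix ", path, " asymmetric beyond tolerance at [",
                 rownames(m)[idx[1]], ", ", colnames(m)[idx[2]], "]"))
  }
  (m + t(m)) / 2
}

#' Write a labeled square matrix as TSV
#'
#' Inverse of [read_matrix()].
#'
#' @param m Square matrix with dimnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  tbl <- as_tibble(m, rownames = "id")
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

#' Write an item table as TSV
#'
#' Class list-columns are collapsed to comma-separated strings so the file
#' round-trips through [read_items()].
#'
#' @param items Item tibble (as in a [split_instance()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_items <- function(items, path) {
  out <- as_tibble(items)
  if ("classes" %in% names(out)) {
    out$classes <- map_chr(out$classes, ~ paste(.x, collapse = ","))
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Write a fold assignment table
#'
#' @param partition A [fold_partition()].
#' @param instance The matching [split_instance()].
#' @param path Output path.
#' @param fold_names Optional character vector naming folds 1..k.
#' @return The written tibble (`id`, `entity_type`, `fold_name`), invisibly.
#' @export
write_assignments <- function(partition, instance, path, fold_names = NULL) {
  tbl <- tidy(partition, instance = instance)
  if (!is.null(fold_names)) {
    tbl$fold_name <- fold_names[tbl$fold]
  } else {
    tbl$fold_name <- paste0("fold", tbl$fold)
  }
  out <- select(tbl, "id", "entity_type", "fold_name")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' Write an assigned interaction table
#'
#' @param interactions Output of [assign_interactions()] or
#'   [random_interaction_split()].
#' @param path Output path.
#' @param fold_names Optional character vector naming folds 1..k.
#' @return The written tibble, invisibly.
#' @export
write_interactions <- function(interactions, path, fold_names = NULL) {
  out <- as_tibble(interactions)
  named <- if (!is.null(fold_names)) fold_names[out$fold] else paste0("fold", out$fold)
  out$fold_name <- ifelse(out$status == "discarded", "discarded", named)
  out <- select(out, -"fold", -"status")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}
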