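#' Binary fingerprint
#'
#' @param bits Logical (or 0/1) vector of fixed length.
#' @param origin `"scaffold"` if computed from a Bemis-Murcko scaffold,
#'   `"full-molecule"` otherwise.
#' @return A `fingerprint`: logical vector with an `origin` attribute.
#' @export
fingerprint <- function(bits, origin = c("scaffold", "full-molecule")) {
  origin <- match.arg(origin)
  bits <- as.logical(bits)
  if (length(bits) < 1) abort("a fingerprint must have at least one bit.")
  structure(bits, origin = origin, class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' Intersection over union of the on-bit sets. Two all-zero fingerprints are
#' treated as identical objects and given similarity 1.
#'
#' @param fp1,fp2 Fingerprints (or plain logical/0-1 vectors) of equal length.
#' @return Numeric scalar in `[0, 1]`.
#' @export
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))  # 2 / 4
tanimoto <- function(fp1, fp2) {
  a <- as.logical(fp1); b <- as.logical(fp2)
  if (length(a) != length(b)) abort("fingerprint lengths differ.")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Tanimoto similarity matrix of a fingerprint set
#'
#' @param fps List of fingerprints of equal length.
#' @param ids Optional element ids for the dimnames.
#' @return Square symmetric matrix in `[0, 1]` with unit diagonal.
#' @export
tanimoto_matrix <- function(fps, ids = NULL) {
  n <- length(fps)
  B <- do.call(rbind, map(fps, as.logical)) * 1
  inter <- tcrossprod(B)
  ones <- rowSums(B)
  uni <- outer(ones, ones, `+`) - inter
  S <- ifelse(uni == 0, 1, inter / pmax(uni, 1))
  diag(S) <- 1
  if (!is.null(ids)) dimnames(S) <- list(ids, ids)
  S
}

#' Scaffold fingerprints from SMILES
#'
#' Computes, for each molecule, the Bemis-Murcko scaffold (ring systems plus
#' linkers, side chains stripped) and hashes its radius-2 circular (Morgan /
#' ECFP4) fingerprint to `n_bits` bits — the standard similarity
#' representation for scaffold-based cold splits of small-molecule data.
#' Acyclic molecules have an empty scaffold; for those the fingerprint of the
#' full molecule is used instead and marked `origin = "full-molecule"`, since
#' an empty scaffold would make all acyclic molecules mutually identical.
#' Set `use_scaffold = FALSE` to fingerprint the full molecules throughout.
#'
#' Chemistry is delegated to the RDKit toolkit through a bundled helper
#' executed with the system `python`.
#'
#' @param smiles Character vector of SMILES strings.
#' @param n_bits Fingerprint length (default 1024).
#' @param radius Circular fingerprint radius (default 2, i.e. ECFP4).
#' @param use_scaffold Fingerprint Bemis-Murcko scaffolds (default) or full
#'   molecules.
#' @return List of [fingerprint()] objects, one per input.
#' @export
scaffold_fingerprint <- function(smiles, n_bits = 1024L, radius = 2L,
                                 use_scaffold = TRUE) {
  stopifnot(n_bits >= 1, radius >= 0)
  res <- run_python_helper("scaffold_fp.py", list(
    smiles = as.list(as.character(smiles)),
    n_bits = as.integer(n_bits), radius = as.integer(radius),
    use_scaffold = isTRUE(use_scaffold)
  ))
  bad <- which(!map_lgl(res, "ok"))
  if (length(bad) > 0) {
    abort(paste0("unparseable SMILES at position(s) ",
                 paste(head(bad, 5), collapse = ", "), ": ",
                 paste(head(smiles[bad], 5), collapse = ", ")))
  }
  map(res, function(r) {
    bits <- rep(FALSE, n_bits)
    on <- unlist(r$on_bits)
    if (length(on) > 0) bits[on + 1L] <- TRUE
    fingerprint(bits, origin = r$origin)
  })
}

#' Tanimoto scaffold similarity matrix from SMILES
#'
#' Convenience composition of [scaffold_fingerprint()] and
#' [tanimoto_matrix()].
#'
#' @inheritParams scaffold_fingerprint
#' @param ids Optional element ids for the dimnames.
#' @return Square similarity matrix in `[0, 1]`.
#' @export
smiles_similarity <- function(smiles, ids = NULL, n_bits = 1024L,
                              radius = 2L, use_scaffold = TRUE) {
  fps <- scaffold_fingerprint(smiles, n_bits, radius, use_scaffold)
  tanimoto_matrix(fps, ids = ids)
}

#' Min-max normalize a matrix to [0, 1]
#'
#' Rescales the off-diagonal entries of a square matrix linearly so that the
#' smallest becomes 0 and the largest 1. The diagonal (ignored by every
#' downstream computation) is left untouched. A constant off-diagonal matrix
#' maps to all zeros. Idempotent.
#'
#' @param m Square numeric matrix with finite entries.
#' @return Matrix of the same shape with off-diagonal entries in `[0, 1]`.
#' @export
normalize_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) abort("matrix must be square.")
  off <- upper.tri(m) | lower.tri(m)
  vals <- m[off]
  if (any(!is.finite(vals))) abort("matrix contains non-finite entries.")
  if (length(vals) == 0) return(m)
  lo <- min(vals); hi <- max(vals)
  m[off] <- if (hi > lo) (vals - lo) / (hi - lo) else 0
  m
}

#' Convert a normalized distance matrix to a similarity matrix
#'
#' Elementwise complement `sim = 1 - dist`. Input entries must already lie in
#' `[0, 1]` (use [normalize_matrix()] first). Applying the conversion twice
#' recovers the input.
#'
#' @param m Square distance matrix with entries in `[0, 1]`.
#' @return Similarity matrix.
#' @export
distance_to_similarity <- function(m) {
  m <- as.matrix(m)
  off <- upper.tri(m) | lower.tri(m)
  if (any(m[off] < 0 | m[off] > 1, na.rm = TRUE)) {
    abort("entries outside [0, 1]; normalize the matrix first.")
  }
  1 - m
}

# -- python helper plumbing ---------------------------------------------------

find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) abort("no `python` interpreter found on PATH.")
  unname(p)
}

run_python_helper <- function(script, payload) {
  helper <- system.file("python", script, package = "coldsplit")
  if (!nzchar(helper)) abort(paste0("bundled helper ", script, " not found."))
  fin <- tempfile(fileext = ".json")
  fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA)
  status <- system2(find_python(), c(helper, fin, fout),
                    stdout = FALSE, stderr = "")
  if (status != 0 || !file.exists(fout)) {
    abort(paste0("helper ", script, " failed with status ", status))
  }
  jsonlite::read_json(fout)
}

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", length(x), " bits, ", sum(x), " set, origin: ",
      attr(x, "origin"), "\n", sep = "")
  invisible(x)
}
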