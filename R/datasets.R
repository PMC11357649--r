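#' Read a peptide list file
#'
#' One peptide per line; blank lines and `#` comments are ignored; sequences
#' are uppercased and whitespace-stripped with order preserved.
#'
#' @param path text file path.
#' @param label `"binder"` or `"non-binder"`, recorded as an attribute.
#' @return character vector of peptides with attributes `label` and
#'   `provenance` (the source path).
#' @export
read_peptide_list <- function(path, label = c("binder", "non-binder")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  peptides <- clean_seq(lines[nzchar(trimws(lines))])
  peptides <- peptides[nzchar(peptides)]
  bad <- invalid_residues(peptides)
  if (length(bad))
    stop("illegal characters in ", path, ", peptide ", bad[1], ": '",
         peptides[bad[1]], "'", call. = FALSE)
  if (length(peptides) == 0L)
    warning("empty peptide list: ", path, call. = FALSE)
  structure(peptides, label = label, provenance = path)
}

#' Expand variable-length peptides to a deduplicated nonamer pool
#'
#' Presents every peptide as its overlapping nonamers (under the presumption
#' that any nonamer of a non-binder is itself a non-binder), then removes
#' exact duplicates within the pool (first occurrence kept) and any nonamer
#' also present in the positive set.
#'
#' @param peptides character vector of peptides (length >= 9 contributes
#'   windows; shorter peptides contribute none).
#' @param positives character vector of nonamers to exclude (the binder
#'   training set); may be empty.
#' @return character vector of unique nonamers in first-occurrence order,
#'   with attribute `n_raw`: the raw window count before deduplication.
#' @export
#' @examples
#' expand_to_nonamer_pool(c("ACDEFGHIK", "ACDEFGHIKL"))
expand_to_nonamer_pool <- function(peptides, positives = character(0)) {
  raw <- unlist(lapply(peptides, function(p) nonamer_windows(p)$nonamer),
                use.names = FALSE)
  if (is.null(raw)) raw <- character(0)
  pool <- unique(raw)
  pool <- setdiff(pool, clean_seq(positives))
  structure(pool, n_raw = length(raw), label = "non-binder")
}

#' Random train/test splits of a nonamer pool
#'
#' Draws `n_splits` independent training sets of `n_train` nonamers without
#' replacement; the remainder of the pool is the matching test set. With the
#' published pool of 1123 non-binders and `n_train = 105` each split has
#' sizes (105, 1018). Splits are a pure function of (pool order, seed).
#'
#' @param pool character vector of nonamers.
#' @param n_train training-set size per split.
#' @param n_splits number of splits (default 10).
#' @param seed RNG seed (default 1).
#' @return list of length `n_splits`; each element is
#'   `list(train = ..., test = ...)`.
#' @export
split_pool <- function(pool, n_train = 105, n_splits = 10, seed = 1) {
  n <- length(pool)
  if (n_train >= n)
    stop("n_train (", n_train, ") must be smaller than the pool size (",
         n, ")", call. = FALSE)
  if (n_splits < 1L) stop("n_splits must be positive", call. = FALSE)
  with_seed(seed, lapply(seq_len(n_splits), function(i) {
    idx <- sample.int(n, n_train)
    list(train = pool[sort(idx)], test = pool[-sort(idx)])
  }))
}
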