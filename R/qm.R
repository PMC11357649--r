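#' Position-specific residue counts for a nonamer training set
#'
#' Tabulates, for each binding-core position p1..p9, how many training
#' nonamers carry each of the 20 amino acids there. Duplicated training
#' peptides are counted with multiplicity. The result is the raw material
#' for a quantitative matrix (see [mean_normalize()]).
#'
#' @param nonamers character vector of 9-residue peptides (one-letter codes,
#'   case-insensitive). Must be non-empty and contain standard residues only.
#' @return an object of class `"pfm"`: a 20 x 9 integer matrix of counts with
#'   rows in the fixed order A R N D C Q E G H I L K M F P S T W Y V and
#'   columns p1..p9, and attributes `n` (number of peptides) and
#'   `frequencies` (counts / n).
#' @export
#' @examples
#' pfm <- count_position_frequencies(c("AAAAAAAAA", "CCCCCCCCC"))
#' attr(pfm, "frequencies")["A", ]
count_position_frequencies <- function(nonamers) {
  nonamers <- assert_nonamers(nonamers, "training nonamer")
  n <- length(nonamers)
  counts <- matrix(0L, nrow = 20, ncol = 9, dimnames = list(AA20, POSITIONS))
  residues <- matrix(unlist(strsplit(nonamers, "")), nrow = 9)
  for (p in 1:9) {
    tab <- table(factor(residues[p, ], levels = AA20))
    counts[, p] <- as.integer(tab)
  }
  structure(counts,
            n = n,
            frequencies = counts / n,
            class = c("pfm", "matrix", "array"))
}

#' Construct a position-frequency object from a count matrix
#'
#' Lower-level companion to [count_position_frequencies()] for when the
#' per-cell counts are known directly (e.g. reconstructed from a published
#' matrix) rather than derived from an explicit peptide list.
#'
#' @param counts 20 x 9 non-negative integer matrix; every column must sum to
#'   the same total `n` (each position is observed once per peptide).
#' @return a `"pfm"` object as returned by [count_position_frequencies()].
#' @export
pfm_from_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(20, 9)))
    stop("counts must be 20 x 9", call. = FALSE)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  n <- unique(colSums(counts))
  if (length(n) != 1L)
    stop("every position must account for the same number of peptides; ",
         "column sums differ", call. = FALSE)
  if (n == 0L) stop("empty count matrix", call. = FALSE)
  dimnames(counts) <- list(AA20, POSITIONS)
  storage.mode(counts) <- "integer"
  structure(counts,
            n = as.integer(n),
            frequencies = counts / n,
            class = c("pfm", "matrix", "array"))
}

#' Mean-normalize position frequencies into a quantitative matrix
#'
#' Converts a position-frequency matrix into the quantitative matrix (QM) of
#' the logo model. Each cell's frequency X is rescaled as
#' \deqn{(X - X_{mean}) / (X_{max} - X_{min})}
#' where the mean, maximum and minimum are taken globally over all 180 cells
#' of the 20 x 9 frequency matrix. Because every column sums to 1, the global
#' mean frequency is always 1/20, so the coefficients are centred on the
#' composition a position-blind residue draw would give, and the global range
#' sets the scale. Values are constrained to [-1, 1] and sum to zero over the
#' whole matrix.
#'
#' @param pfm a `"pfm"` object from [count_position_frequencies()] or
#'   [pfm_from_counts()].
#' @param role `"binder"` or `"non-binder"`: what the training set represents.
#' @return an object of class `"qm"`: a 20 x 9 numeric matrix (full
#'   precision; rounding to the published 3 decimals happens at
#'   serialization) with attributes `role` and `n`.
#' @export
#' @examples
#' qm <- mean_normalize(count_position_frequencies(c("FFFFFFFFF")), "binder")
#' qm["F", "p1"]  # 0.95
mean_normalize <- function(pfm, role = c("binder", "non-binder")) {
  role <- match.arg(role)
  if (!inherits(pfm, "pfm")) stop("pfm must be a 'pfm' object", call. = FALSE)
  freq <- attr(pfm, "frequencies")
  f_mean <- mean(freq)
  f_max <- max(freq)
  f_min <- min(freq)
  if (f_max == f_min)
    stop("degenerate frequency matrix: all 180 cells equal (", f_max,
         "); mean normalization is undefined", call. = FALSE)
  values <- (freq - f_mean) / (f_max - f_min)
  new_qm(values, role = role, n = attr(pfm, "n"))
}

# Internal constructor + validator for the "qm" class.
new_qm <- function(values, role, n = NA_integer_) {
  values <- as.matrix(values)
  if (!all(dim(values) == c(20, 9)))
    stop("a quantitative matrix must be 20 x 9", call. = FALSE)
  if (any(values < -1 - 1e-9) || any(values > 1 + 1e-9))
    stop("quantitative-matrix values must lie in [-1, 1]; found ",
         signif(values[which.max(abs(values))], 4), call. = FALSE)
  dimnames(values) <- list(AA20, POSITIONS)
  structure(values,
            role = role,
            n = n,
            class = c("qm", "matrix", "array"))
}

#' Derive a quantitative matrix from a nonamer training set
#'
#' One-step composition of [count_position_frequencies()] and
#' [mean_normalize()].
#'
#' @inheritParams count_position_frequencies
#' @inheritParams mean_normalize
#' @return a `"qm"` object.
#' @export
#' @examples
#' qm <- derive_qm(c("FFFFFFFFF"), role = "binder")
derive_qm <- function(nonamers, role = c("binder", "non-binder")) {
  role <- match.arg(role)
  mean_normalize(count_position_frequencies(nonamers), role = role)
}

#' The published HLA-DRB1*03:01 quantitative matrices
#'
#' Returns the packaged binder QM (derived from 105 nonamer binders) or the
#' best-performing non-binder QM ("QM1", selected by Matthews' correlation
#' coefficient among ten random non-binder training splits), bit-exact to
#' their printed 3-decimal values.
#'
#' @param role `"binder"` or `"non-binder"`.
#' @return a `"qm"` object.
#' @export
#' @examples
#' published_qm("binder")["F", "p1"]  # 0.806
published_qm <- function(role = c("binder", "non-binder")) {
  role <- match.arg(role)
  file <- switch(role,
                 "binder" = "qm_drb1_0301_binder.tsv",
                 "non-binder" = "qm1_drb1_0301_nonbinder.tsv")
  path <- system.file("extdata", file, package = "logomhc", mustWork = TRUE)
  read_qm(path)
}

#' Read / write a quantitative matrix as TSV
#'
#' The on-disk format is a tab-separated table with an optional leading
#' comment line `# role: binder|non-binder`, a header `aa p1 ... p9`, and 20
#' data rows in the fixed order A R N D C Q E G H I L K M F P S T W Y V.
#' Values are written rounded half-up to 3 decimals, the precision of the
#' published tables; a load/save round trip therefore preserves a matrix at
#' 3 decimals exactly.
#'
#' @param path file path.
#' @param qm a `"qm"` object.
#' @return `read_qm` returns a `"qm"` object; `write_qm` returns `path`
#'   invisibly.
#' @export
read_qm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  role <- "binder"
  m <- grep("^#\\s*role:", lines, value = TRUE)
  if (length(m)) {
    role <- trimws(sub("^#\\s*role:\\s*", "", m[1]))
    if (!role %in% c("binder", "non-binder"))
      stop("unknown role in ", path, ": '", role, "'", call. = FALSE)
  }
  df <- utils::read.delim(text = lines, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!identical(names(df)[1], "aa") || ncol(df) != 10L)
    stop("expected header 'aa\\tp1...p9' in ", path, call. = FALSE)
  if (nrow(df) != 20L)
    stop("expected 20 amino-acid rows in ", path, ", found ", nrow(df),
         call. = FALSE)
  if (!setequal(df$aa, AA20))
    stop("unknown or missing amino-acid codes in ", path, ": ",
         paste(setdiff(df$aa, AA20), collapse = ", "), call. = FALSE)
  values <- as.matrix(df[match(AA20, df$aa), -1, drop = FALSE])
  if (any(!is.finite(values)))
    stop("non-numeric values in ", path, call. = FALSE)
  if (any(values < -1) || any(values > 1))
    stop("values outside [-1, 1] in ", path, call. = FALSE)
  new_qm(values, role = role)
}

#' @rdname read_qm
#' @export
write_qm <- function(qm, path) {
  if (!inherits(qm, "qm")) stop("qm must be a 'qm' object", call. = FALSE)
  vals <- round_half_up(unclass(qm), 3)
  df <- data.frame(aa = AA20, format(vals, nsmall = 3, trim = TRUE),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# role: ", attr(qm, "role")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reconstruct integer training counts from a quantitative matrix
#'
#' Inverts the mean normalization for a QM known to come from `n` training
#' nonamers with integer counts and a given global count range: the cell
#' value v maps back to `round(v * (c_max - c_min) + n/20)`. Useful for
#' auditing published matrices against their stated training compositions.
#'
#' @param qm a `"qm"` object.
#' @param n training-set size.
#' @param count_range `c(min, max)` of the per-cell counts across the matrix.
#' @return 20 x 9 integer matrix of reconstructed counts.
#' @export
#' @examples
#' counts <- qm_counts(published_qm("binder"), n = 105, count_range = c(0, 27))
#' counts[c("D", "N", "E", "A"), "p4"]  # 5 1 2 14
qm_counts <- function(qm, n, count_range) {
  if (!inherits(qm, "qm")) stop("qm must be a 'qm' object", call. = FALSE)
  scale <- diff(count_range)
  counts <- matrix(as.integer(round(unclass(qm) * scale + n / 20)),
                   nrow = 20, ncol = 9, dimnames = list(AA20, POSITIONS))
  counts
}

#' @export
print.qm <- function(x, ...) {
  cat(sprintf("Quantitative matrix (%s)%s\n", attr(x, "role"),
              if (!is.na(attr(x, "n")))
                sprintf(", derived from %d nonamers", attr(x, "n")) else ""))
  print(round_half_up(unclass(x), 3), ...)
  invisible(x)
}
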