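#' Generate a synthetic binder training set with planted anchors
#'
#' Emulates the anchor structure of an MHC class II binding core: at each
#' anchor position the planted residue is drawn with probability
#' `anchor_prob`, otherwise (and at all non-anchor positions) a residue is
#' drawn from the background distribution. Deterministic under `seed`.
#'
#' @param n number of nonamers.
#' @param anchors named character vector mapping positions to residues,
#'   e.g. `c(p1 = "F", p4 = "R", p6 = "F", p9 = "L")` (the canonical HLA-DR
#'   anchor layout).
#' @param anchor_prob probability in (0, 1] that an anchor position carries
#'   its planted residue.
#' @param background probability weights over the 20 residues in the fixed
#'   row order (default uniform).
#' @param seed RNG seed.
#' @return character vector of `n` nonamers with attribute
#'   `label = "binder"`.
#' @export
#' @examples
#' set <- generate_binder_set(10, c(p1 = "F"), seed = 7)
generate_binder_set <- function(n, anchors = c(p1 = "F", p4 = "R",
                                               p6 = "F", p9 = "L"),
                                anchor_prob = 0.8,
                                background = rep(1 / 20, 20),
                                seed = 1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (anchor_prob <= 0 || anchor_prob > 1)
    stop("anchor_prob must lie in (0, 1]", call. = FALSE)
  if (length(background) != 20 || any(background < 0) || sum(background) <= 0)
    stop("background must be 20 non-negative weights", call. = FALSE)
  if (length(anchors) && (!all(names(anchors) %in% POSITIONS) ||
                          !all(anchors %in% AA20)))
    stop("anchors must map p1..p9 to standard residues", call. = FALSE)
  background <- background / sum(background)
  with_seed(seed, {
    mat <- matrix(sample(AA20, n * 9, replace = TRUE, prob = background),
                  nrow = n, ncol = 9)
    for (p in names(anchors)) {
      col <- match(p, POSITIONS)
      hit <- stats::runif(n) < anchor_prob
      mat[hit, col] <- anchors[[p]]
    }
    structure(apply(mat, 1, paste, collapse = ""), label = "binder")
  })
}

#' Generate a synthetic non-binder peptide set
#'
#' Uniform-background peptides of variable length, emulating the shape of a
#' mixed-length non-binder collection before its expansion to a nonamer
#' pool. Deterministic under `seed`.
#'
#' @param n number of peptides.
#' @param length_range `c(min, max)` peptide lengths; minimum 9 so every
#'   peptide contributes at least one nonamer window.
#' @param background probability weights over the 20 residues (default
#'   uniform).
#' @param seed RNG seed.
#' @return character vector of `n` peptides with attribute
#'   `label = "non-binder"`.
#' @export
generate_nonbinder_set <- function(n, length_range = c(9, 25),
                                   background = rep(1 / 20, 20), seed = 1) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (length(length_range) != 2 || length_range[1] < 9 ||
      length_range[2] < length_range[1])
    stop("length_range must be c(min, max) with min >= 9", call. = FALSE)
  background <- background / sum(background)
  with_seed(seed, {
    choices <- seq(length_range[1], length_range[2])
    lens <- if (length(choices) == 1L) rep(choices, n)
    else sample(choices, n, replace = TRUE)
    peps <- vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = background), collapse = "")
    }, character(1))
    structure(peps, label = "non-binder")
  })
}

#' Implant a nonamer motif into a random host protein
#'
#' Builds a uniform-background host sequence of the given length and
#' substitutes the nonamer at a 1-based start position, so that a scan of
#' the host must recover the motif at exactly that position.
#'
#' @param host_length host protein length (>= 9).
#' @param nonamer the 9-residue motif to implant.
#' @param start 1-based start; must satisfy `1 <= start <= host_length - 8`.
#' @param seed RNG seed for the host background.
#' @return a single protein sequence string.
#' @export
#' @examples
#' implant_motif(19, "FLILSGLIL", start = 6, seed = 1)
implant_motif <- function(host_length, nonamer, start, seed = 1) {
  nonamer <- assert_nonamers(nonamer, "motif")
  if (host_length < 9) stop("host_length must be >= 9", call. = FALSE)
  if (start < 1 || start > host_length - 8)
    stop("start must lie in [1, ", host_length - 8, "] for a host of length ",
         host_length, call. = FALSE)
  with_seed(seed, {
    host <- sample(AA20, host_length, replace = TRUE)
    host[start:(start + 8)] <- strsplit(nonamer, "")[[1]]
    paste(host, collapse = "")
  })
}

#' Write a peptide set to a plain-text list or FASTA file
#'
#' @param peptides character vector of peptides.
#' @param path output path.
#' @param format `"list"` (one peptide per line) or `"fasta"`.
#' @return `path`, invisibly.
#' @export
write_peptide_set <- function(peptides, path, format = c("list", "fasta")) {
  format <- match.arg(format)
  if (format == "list") {
    writeLines(peptides, path)
  } else {
    ids <- names(peptides)
    if (is.null(ids) || any(!nzchar(ids)))
      ids <- sprintf("pep%0*d", nchar(length(peptides)), seq_along(peptides))
    writeLines(paste0(">", ids, "\n", peptides), path)
  }
  invisible(path)
}
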