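#' Decompose a peptide into overlapping nonamer windows
#'
#' MHC class II grooves accommodate a 9-residue binding core, so peptides of
#' any length are represented as every length-9 window at step 1. Peptides
#' shorter than 9 residues have no windows and yield a zero-row result.
#'
#' @param peptide a single peptide sequence (case-insensitive).
#' @return data.frame with columns `start` (1-based, inclusive) and
#'   `nonamer`.
#' @export
#' @examples
#' nonamer_windows("ARQQWELQGDRRCQS")  # 7 windows
nonamer_windows <- function(peptide) {
  stopifnot(length(peptide) == 1L)
  peptide <- clean_seq(peptide)
  len <- nchar(peptide)
  if (len < 9L)
    return(data.frame(start = integer(0), nonamer = character(0)))
  starts <- seq_len(len - 8L)
  data.frame(start = starts,
             nonamer = substring(peptide, starts, starts + 8L))
}

#' Score nonamers against a quantitative matrix
#'
#' The score of a nonamer is the sum of the matrix coefficients of its nine
#' residues at positions p1..p9: the binding score (BS) under a binder QM,
#' the non-binding score (NBS) under a non-binder QM. Vectorized over
#' nonamers; full precision is kept (round with [round_half_up()] for
#' table-style reporting).
#'
#' @param qm a `"qm"` object.
#' @param nonamers character vector of 9-residue peptides.
#' @return numeric vector of scores, one per nonamer.
#' @export
#' @examples
#' score_nonamers(published_qm("binder"), "MLLLGILVL")  # 2.102
score_nonamers <- function(qm, nonamers) {
  if (!inherits(qm, "qm")) stop("qm must be a 'qm' object", call. = FALSE)
  nonamers <- assert_nonamers(nonamers)
  residues <- matrix(unlist(strsplit(nonamers, "")), nrow = 9)
  vapply(seq_along(nonamers), function(i) {
    sum(unclass(qm)[cbind(residues[, i], POSITIONS)])
  }, numeric(1))
}

#' Binder / non-binder call from a score pair
#'
#' A nonamer is called a binder iff its binding score strictly exceeds its
#' non-binding score; ties go to non-binder.
#'
#' @param bs,nbs numeric vectors of binding and non-binding scores.
#' @return character vector, `"binder"` or `"non-binder"`.
#' @export
classify_call <- function(bs, nbs) {
  ifelse(bs > nbs, "binder", "non-binder")
}

# Score every standard-residue window of one sequence with both matrices.
# Windows containing non-standard residues (B J O U X Z *) are dropped with
# a warning when warn = TRUE; they can never support a binder call.
score_windows <- function(qm_b, qm_nb, sequence, strong_threshold = 2,
                          warn = TRUE) {
  win <- nonamer_windows(sequence)
  ok <- grepl(paste0("^[", paste(AA20, collapse = ""), "]{9}$"), win$nonamer)
  if (warn && any(!ok))
    warning(sum(!ok), " window(s) containing non-standard residues skipped",
            call. = FALSE)
  win <- win[ok, , drop = FALSE]
  if (nrow(win) == 0L) {
    return(data.frame(start = integer(0), nonamer = character(0),
                      bs = numeric(0), nbs = numeric(0),
                      call = character(0), strong = logical(0)))
  }
  bs <- score_nonamers(qm_b, win$nonamer)
  nbs <- score_nonamers(qm_nb, win$nonamer)
  data.frame(start = win$start, nonamer = win$nonamer, bs = bs, nbs = nbs,
             call = classify_call(bs, nbs), strong = bs > strong_threshold,
             row.names = NULL)
}

#' Classify a peptide of any length
#'
#' Every nonamer window is scored with both matrices; the parent peptide is
#' called a binder iff at least one window is called a binder.
#'
#' @param qm_b,qm_nb binder and non-binder `"qm"` objects.
#' @param peptide one peptide sequence, at least 9 residues in strict mode.
#' @param strict if `TRUE` (default) a peptide shorter than 9 residues is an
#'   error; if `FALSE` it is skipped: the call is `NA` with a warning.
#' @return a list of class `"peptide_call"` with elements `peptide`, `call`,
#'   `n_binding_windows` and `windows` (the scored-window data.frame of
#'   [scan_sequence()]).
#' @export
#' @examples
#' classify_peptide(published_qm("binder"), published_qm("non-binder"),
#'                  "ARQQWELQGDRRCQS")$call  # "binder"
classify_peptide <- function(qm_b, qm_nb, peptide, strict = TRUE) {
  peptide <- clean_seq(peptide)
  if (nchar(peptide) < 9L) {
    if (strict)
      stop("peptide '", peptide, "' is shorter than 9 residues; ",
           "no binding core can be placed (use strict = FALSE to skip)",
           call. = FALSE)
    warning("peptide '", peptide, "' shorter than 9 residues: skipped",
            call. = FALSE)
    return(structure(list(peptide = peptide, call = NA_character_,
                          n_binding_windows = NA_integer_,
                          windows = NULL),
                     class = "peptide_call"))
  }
  win <- score_windows(qm_b, qm_nb, peptide)
  n_bind <- sum(win$call == "binder")
  structure(list(peptide = peptide,
                 call = if (n_bind >= 1L) "binder" else "non-binder",
                 n_binding_windows = n_bind,
                 windows = win),
            class = "peptide_call")
}

#' @export
print.peptide_call <- function(x, ...) {
  cat(sprintf("%s: %s (%s of %s windows binding)\n", x$peptide, x$call,
              x$n_binding_windows,
              if (is.null(x$windows)) 0L else nrow(x$windows)))
  invisible(x)
}

#' Scan a protein sequence for strong binders
#'
#' Scores every nonamer window of a protein with the binder and non-binder
#' matrices and flags strong binders: windows with a binding score strictly
#' greater than the threshold (default 2), the candidates proposed for
#' epitope-based immunotherapy.
#'
#' @inheritParams classify_peptide
#' @param sequence protein sequence.
#' @param strong_threshold strong-binder cutoff on BS (strict inequality).
#' @return data.frame sorted by `start` with columns `start`, `nonamer`,
#'   `bs`, `nbs`, `call`, `strong`.
#' @export
#' @examples
#' scan <- scan_sequence(published_qm("binder"), published_qm("non-binder"),
#'                       "AAAAAFLILSGLILAAAAA")
#' scan[scan$strong, c("start", "nonamer", "bs")]
scan_sequence <- function(qm_b, qm_nb, sequence, strong_threshold = 2) {
  sequence <- clean_seq(sequence)
  if (nchar(sequence) < 9L && nchar(sequence) > 0L)
    warning("sequence shorter than 9 residues: no windows to score",
            call. = FALSE)
  score_windows(qm_b, qm_nb, sequence, strong_threshold = strong_threshold)
}

#' Scan a protein FASTA file for strong binders
#'
#' Applies [scan_sequence()] to every record of a protein FASTA file and
#' returns the strong binders. Within one record every occurrence is
#' reported (with its own start); the summary is one row per distinct
#' (record, nonamer) pair when `distinct = TRUE`.
#'
#' @inheritParams scan_sequence
#' @param fasta_path path to a protein FASTA file.
#' @param distinct collapse repeated identical nonamers within a record to
#'   one row (first occurrence)? Default `FALSE`: every occurrence reported.
#' @return data.frame with columns `record`, `start`, `nonamer`, `bs`,
#'   `nbs`, `call`, `strong`, restricted to strong binders.
#' @export
scan_fasta <- function(qm_b, qm_nb, fasta_path, strong_threshold = 2,
                       distinct = FALSE) {
  if (!file.exists(fasta_path))
    stop("no such file: ", fasta_path, call. = FALSE)
  seqs <- Biostrings::readAAStringSet(fasta_path)
  if (length(seqs) == 0L) stop("empty FASTA: ", fasta_path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  hits <- lapply(seq_along(seqs), function(i) {
    scan <- scan_sequence(qm_b, qm_nb, as.character(seqs[[i]]),
                          strong_threshold = strong_threshold)
    scan <- scan[scan$strong, , drop = FALSE]
    if (nrow(scan) == 0L) return(NULL)
    cbind(record = ids[i], scan)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(record = character(0), start = integer(0),
                      nonamer = character(0), bs = numeric(0),
                      nbs = numeric(0), call = character(0),
                      strong = logical(0))
  if (distinct && nrow(out))
    out <- out[!duplicated(out[, c("record", "nonamer")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}
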