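#' Fit (or assemble) a logo model for peptide binding prediction
#'
#' A logo model is a pair of quantitative matrices over the nonamer binding
#' core: a binder QM, whose coefficients sum to the binding score (BS), and
#' a non-binder QM giving the non-binding score (NBS). A nonamer is called a
#' binder iff BS > NBS; a longer peptide is a binder iff at least one of its
#' overlapping nonamer windows is. Matrices are derived from training sets
#' by global mean normalization of position-specific residue frequencies
#' (see [mean_normalize()]).
#'
#' Called with no training data, the published HLA-DRB1*03:01 matrices are
#' used (binder QM from 105 nonamer binders; non-binder QM1, the best of ten
#' random-split candidates by Matthews' correlation coefficient), so the
#' default model reproduces the published predictions.
#'
#' @param binders character vector of training nonamer binders, or `NULL` to
#'   use the published binder matrix.
#' @param nonbinders character vector of training nonamer non-binders, or
#'   `NULL` to use the published non-binder matrix.
#' @param qm_binder,qm_nonbinder pre-built `"qm"` objects; override the
#'   corresponding training set.
#' @param strong_threshold BS cutoff (strict) above which a nonamer is
#'   flagged a strong binder; default 2.
#' @return an object of class `"logo_model"` with elements `qm_binder`,
#'   `qm_nonbinder`, `strong_threshold`, and, when fitted from peptides, the
#'   training frequency matrices `pfm_binder` / `pfm_nonbinder`.
#' @seealso [predict.logo_model()], [scan_sequence()], [evaluate_qms()]
#' @export
#' @examples
#' model <- logo_model()  # the published model
#' predict(model, "ARQQWELQGDRRCQS")
logo_model <- function(binders = NULL, nonbinders = NULL,
                       qm_binder = NULL, qm_nonbinder = NULL,
                       strong_threshold = 2) {
  if (!is.finite(strong_threshold))
    stop("strong_threshold must be finite", call. = FALSE)
  pfm_b <- pfm_nb <- NULL
  if (is.null(qm_binder)) {
    if (is.null(binders)) {
      qm_binder <- published_qm("binder")
    } else {
      pfm_b <- count_position_frequencies(binders)
      qm_binder <- mean_normalize(pfm_b, "binder")
    }
  } else if (!inherits(qm_binder, "qm")) {
    stop("qm_binder must be a 'qm' object", call. = FALSE)
  }
  if (is.null(qm_nonbinder)) {
    if (is.null(nonbinders)) {
      qm_nonbinder <- published_qm("non-binder")
    } else {
      pfm_nb <- count_position_frequencies(nonbinders)
      qm_nonbinder <- mean_normalize(pfm_nb, "non-binder")
    }
  } else if (!inherits(qm_nonbinder, "qm")) {
    stop("qm_nonbinder must be a 'qm' object", call. = FALSE)
  }
  structure(list(qm_binder = qm_binder,
                 qm_nonbinder = qm_nonbinder,
                 strong_threshold = strong_threshold,
                 pfm_binder = pfm_b,
                 pfm_nonbinder = pfm_nb),
            class = "logo_model")
}

#' @export
print.logo_model <- function(x, ...) {
  src <- function(qm, pfm) {
    if (!is.null(pfm)) sprintf("fitted from %d nonamers", attr(pfm, "n"))
    else if (!is.na(attr(qm, "n")))
      sprintf("derived from %d nonamers", attr(qm, "n"))
    else "packaged published matrix"
  }
  cat("Logo model for MHC class II binding-core prediction\n")
  cat("  binder QM:     ", src(x$qm_binder, x$pfm_binder), "\n", sep = "")
  cat("  non-binder QM: ", src(x$qm_nonbinder, x$pfm_nonbinder), "\n",
      sep = "")
  cat("  call rule: binder iff BS > NBS; strong iff BS > ",
      x$strong_threshold, "\n", sep = "")
  invisible(x)
}

#' @method summary logo_model
#' @export
summary.logo_model <- function(object, n_top = 4, ...) {
  qm <- unclass(object$qm_binder)
  top <- sapply(POSITIONS, function(p) {
    ord <- order(qm[, p], decreasing = TRUE)[seq_len(n_top)]
    paste(AA20[ord], collapse = " ")
  })
  out <- list(model = object, top_residues = top)
  class(out) <- "summary.logo_model"
  out
}

#' @export
print.summary.logo_model <- function(x, ...) {
  print(x$model)
  cat("Preferred residues per core position (binder QM):\n")
  for (p in POSITIONS) cat("  ", p, ": ", x$top_residues[[p]], "\n", sep = "")
  invisible(x)
}

#' Extract a model's quantitative matrices
#'
#' @param object a `"logo_model"`.
#' @param role `"binder"`, `"non-binder"`, or `"both"` (a list of two).
#' @param ... unused.
#' @return a `"qm"` matrix, or a list of both.
#' @method coef logo_model
#' @export
coef.logo_model <- function(object, role = c("binder", "non-binder", "both"),
                            ...) {
  role <- match.arg(role)
  switch(role,
         "binder" = object$qm_binder,
         "non-binder" = object$qm_nonbinder,
         "both" = list(binder = object$qm_binder,
                       "non-binder" = object$qm_nonbinder))
}

#' Predict binder calls and scores for peptides
#'
#' Each peptide is decomposed into overlapping nonamer windows; each window
#' gets a binding score (BS, binder QM) and a non-binding score (NBS,
#' non-binder QM); the peptide is called a binder iff at least one window
#' has BS > NBS.
#'
#' @param object a `"logo_model"`.
#' @param peptides character vector of peptide sequences (length >= 9 each
#'   unless `strict = FALSE`).
#' @param type `"call"`: one row per peptide with the call, the number of
#'   binding windows, and the best window by BS; `"windows"`: one row per
#'   scored window across all peptides.
#' @param strict error on peptides shorter than 9 residues (default); if
#'   `FALSE` they are skipped with a warning and get an `NA` call.
#' @param ... unused.
#' @return a data.frame (see `type`).
#' @export
predict.logo_model <- function(object, peptides,
                               type = c("call", "windows"),
                               strict = TRUE, ...) {
  type <- match.arg(type)
  calls <- lapply(peptides, function(p)
    classify_peptide(object$qm_binder, object$qm_nonbinder, p,
                     strict = strict))
  if (type == "windows") {
    rows <- lapply(calls, function(pc) {
      if (is.null(pc$windows) || nrow(pc$windows) == 0L) return(NULL)
      cbind(peptide = pc$peptide, pc$windows)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(peptide = character(0), start = integer(0),
                        nonamer = character(0), bs = numeric(0),
                        nbs = numeric(0), call = character(0),
                        strong = logical(0))
    rownames(out) <- NULL
    return(out)
  }
  do.call(rbind, lapply(calls, function(pc) {
    if (is.null(pc$windows) || nrow(pc$windows) == 0L)
      return(data.frame(peptide = pc$peptide, call = NA_character_,
                        n_binding_windows = NA_integer_,
                        best_nonamer = NA_character_, best_bs = NA_real_))
    best <- which.max(pc$windows$bs)
    data.frame(peptide = pc$peptide, call = pc$call,
               n_binding_windows = pc$n_binding_windows,
               best_nonamer = pc$windows$nonamer[best],
               best_bs = pc$windows$bs[best])
  }))
}

#' Heatmap of the model coefficients
#'
#' Displays a quantitative matrix as a residue x position heatmap
#' (blue = disfavoured, red = favoured), the quantitative analogue of a
#' sequence logo.
#'
#' @param x a `"logo_model"`.
#' @param role which matrix to draw.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @method plot logo_model
#' @export
plot.logo_model <- function(x, role = c("binder", "non-binder"), ...) {
  role <- match.arg(role)
  qm <- unclass(coef(x, role))
  lim <- max(abs(qm))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(101)
  graphics::image(x = 1:9, y = 1:20, z = t(qm[20:1, ]),
                  zlim = c(-lim, lim), col = pal, axes = FALSE,
                  xlab = "binding-core position", ylab = "",
                  main = sprintf("%s quantitative matrix", role), ...)
  graphics::axis(1, at = 1:9, labels = POSITIONS)
  graphics::axis(2, at = 1:20, labels = rev(AA20), las = 2, cex.axis = 0.7)
  graphics::box()
  invisible(x)
}

#' Simulate nonamer sets from a fitted model
#'
#' Draws nonamers position-by-position from the training frequency matrix
#' of the binder side of a model fitted with [logo_model()] from explicit
#' training peptides. Models assembled from bare matrices (including the
#' default published model) carry no frequencies and cannot be simulated
#' from, because the normalization that produced a published matrix is not
#' invertible without its count range.
#'
#' @param object a `"logo_model"` fitted from training nonamers.
#' @param nsim number of replicate sets.
#' @param seed RNG seed (optional).
#' @param n nonamers per set; defaults to the training-set size.
#' @param ... unused.
#' @return a list of `nsim` character vectors of nonamers.
#' @export
simulate.logo_model <- function(object, nsim = 1, seed = NULL, n = NULL,
                                ...) {
  pfm <- object$pfm_binder
  if (is.null(pfm))
    stop("model carries no training frequencies; fit logo_model() from ",
         "training nonamers to simulate", call. = FALSE)
  freq <- attr(pfm, "frequencies")
  if (is.null(n)) n <- attr(pfm, "n")
  draw <- function() {
    mat <- vapply(1:9, function(p)
      sample(AA20, n, replace = TRUE, prob = freq[, p]), character(n))
    apply(matrix(mat, nrow = n), 1, paste, collapse = "")
  }
  if (is.null(seed)) replicate(nsim, draw(), simplify = FALSE)
  else with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
}
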