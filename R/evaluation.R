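#' Confusion matrix for binder prediction
#'
#' @param tp,fp,tn,fn non-negative integer counts. True positives are
#'   binders correctly called binders; true negatives non-binders correctly
#'   called non-binders.
#' @return an object of class `"confusion"` (a named integer vector).
#' @export
confusion <- function(tp, fp, tn, fn) {
  x <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(x < 0) || any(x != round(x)))
    stop("confusion-matrix counts must be non-negative integers",
         call. = FALSE)
  if (sum(x) == 0)
    stop("all-zero confusion matrix: no predictions to evaluate",
         call. = FALSE)
  structure(as.integer(x), names = names(x), class = "confusion")
}

#' The six classifier summary statistics
#'
#' Computes sensitivity (recall), specificity, accuracy, precision,
#' Matthews' correlation coefficient and F1 from a confusion matrix:
#' \deqn{MCC = (TN \cdot TP - FN \cdot FP) /
#'   \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' A metric whose denominator is zero is undefined and reported as `NaN`
#' with a warning rather than coerced to 0.
#'
#' @param cm a `"confusion"` object (or anything [confusion()] accepts as a
#'   named vector with elements tp, fp, tn, fn).
#' @return named numeric vector of class `"logo_metrics"` with elements
#'   `sensitivity`, `specificity`, `accuracy`, `precision`, `mcc`, `f1`
#'   (full precision; round for table-style reporting).
#' @export
#' @examples
#' round_half_up(classification_metrics(confusion(7658, 365, 653, 155)), 3)
classification_metrics <- function(cm) {
  if (!inherits(cm, "confusion")) cm <- confusion(cm["tp"], cm["fp"], cm["tn"], cm["fn"])
  tp <- as.numeric(cm["tp"]); fp <- as.numeric(cm["fp"])
  tn <- as.numeric(cm["tn"]); fn <- as.numeric(cm["fn"])
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  sens <- ratio(tp, tp + fn, "sensitivity")
  spec <- ratio(tn, tn + fp, "specificity")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  prec <- ratio(tp, tp + fp, "precision")
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (mcc_den == 0) {
    warning("mcc undefined: zero denominator", call. = FALSE)
    NaN
  } else (tn * tp - fn * fp) / mcc_den
  f1 <- if (is.nan(prec) || is.nan(sens) || (prec + sens) == 0) {
    warning("f1 undefined", call. = FALSE)
    NaN
  } else 2 * prec * sens / (prec + sens)
  structure(c(sensitivity = sens, specificity = spec, accuracy = acc,
              precision = prec, mcc = mcc, f1 = f1),
            class = "logo_metrics")
}

#' @export
print.logo_metrics <- function(x, ...) {
  print(round_half_up(unclass(x), 3), ...)
  invisible(x)
}

#' Evaluate a QM pair on labelled test sets
#'
#' Mirrors the published validation protocol, which is deliberately
#' asymmetric in granularity: positive test peptides may be of any length
#' and are classified at the peptide level (binder iff at least one window
#' is called a binder), while negative test peptides are nonamers classified
#' individually. TP/FN come from the positives, TN/FP from the negatives.
#' Positive peptides shorter than 9 residues cannot be classified and are
#' dropped with a warning.
#'
#' @param qm_b,qm_nb binder and non-binder `"qm"` objects.
#' @param binder_test character vector of known binders (any length >= 9).
#' @param nonbinder_test character vector of known non-binder nonamers.
#' @return list with elements `confusion` (a `"confusion"` object) and
#'   `metrics` (a `"logo_metrics"` vector).
#' @export
evaluate_qms <- function(qm_b, qm_nb, binder_test, nonbinder_test) {
  if (length(binder_test) == 0L) stop("empty binder test set", call. = FALSE)
  if (length(nonbinder_test) == 0L)
    stop("empty non-binder test set", call. = FALSE)
  binder_test <- clean_seq(binder_test)
  short <- nchar(binder_test) < 9L
  if (any(short)) {
    warning(sum(short), " binder test peptide(s) shorter than 9 residues ",
            "dropped", call. = FALSE)
    binder_test <- binder_test[!short]
    if (length(binder_test) == 0L)
      stop("no classifiable binder test peptides", call. = FALSE)
  }
  pos_calls <- vapply(binder_test, function(p) {
    classify_peptide(qm_b, qm_nb, p)$call
  }, character(1), USE.NAMES = FALSE)
  neg_bs <- score_nonamers(qm_b, nonbinder_test)
  neg_nbs <- score_nonamers(qm_nb, nonbinder_test)
  neg_calls <- classify_call(neg_bs, neg_nbs)
  cm <- confusion(tp = sum(pos_calls == "binder"),
                  fp = sum(neg_calls == "binder"),
                  tn = sum(neg_calls == "non-binder"),
                  fn = sum(pos_calls == "non-binder"))
  list(confusion = cm, metrics = classification_metrics(cm))
}

#' Select the best non-binder QM by Matthews' correlation coefficient
#'
#' Given evaluation reports for candidate non-binder matrices (one per
#' random training split), returns the index of the highest MCC; ties are
#' broken by the first occurrence.
#'
#' @param reports a list of `"logo_metrics"` vectors (or of the lists
#'   returned by [evaluate_qms()]), or a numeric vector of MCC values.
#' @return integer index of the selected report.
#' @export
select_best_qm <- function(reports) {
  if (length(reports) == 0L) stop("no reports to select from", call. = FALSE)
  mcc <- if (is.numeric(reports)) as.numeric(reports)
  else vapply(reports, function(r) {
    if (is.list(r) && !is.null(r$metrics)) r <- r$metrics
    as.numeric(r[["mcc"]])
  }, numeric(1))
  which.max(mcc)
}
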