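#' @title Evaluation: micro-averaged P/R/F1 and confusion matrices
#' @description Scoring follows the challenge protocol: relations are
#'   identified at abstract level by (pmid, CPR group, Arg1 term, Arg2
#'   term), and precision, recall and F1 are micro-averaged over the five
#'   evaluated CPR groups (3, 4, 5, 6, 9). A candidate-level 6x6 confusion
#'   matrix (gold class x predicted class, `other` pooling the
#'   non-evaluated groups) supports per-class precision/recall/F1; its
#'   (other, other) cell is undefined and ignored.
#' @name evaluation
NULL

#' Deduplicate relation records to abstract-level set semantics
#'
#' @param records data.frame with columns `pmid`, `cpr`, `arg1`, `arg2`
#'   (extra columns are preserved from the first occurrence).
#' @return The unique records.
#' @export
dedupe_relations <- function(records) {
  if (!nrow(records)) return(records)
  key <- paste(records$pmid, records$cpr, records$arg1, records$arg2,
               sep = "\r")
  out <- records[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Micro-averaged precision, recall and F1
#'
#' Both sets are deduplicated and restricted to the evaluated classes;
#' TP is the size of their intersection, P = TP / |pred|, R = TP / |gold|,
#' F1 their harmonic mean (0 when P + R = 0).
#'
#' @param gold,pred data.frames with columns `pmid`, `cpr`, `arg1`, `arg2`.
#' @param eval_classes Evaluated CPR groups (default 3/4/5/6/9).
#' @return List of class `prf_report`: `precision`, `recall`, `f1`, `tp`,
#'   `fp`, `fn`, `n_gold`, `n_pred`.
#' @export
micro_prf <- function(gold, pred, eval_classes = CPR_EVALUATED) {
  gold <- dedupe_relations(gold[gold$cpr %in% eval_classes, , drop = FALSE])
  pred <- dedupe_relations(pred[pred$cpr %in% eval_classes, , drop = FALSE])
  gk <- paste(gold$pmid, gold$cpr, gold$arg1, gold$arg2, sep = "\r")
  pk <- paste(pred$pmid, pred$cpr, pred$arg1, pred$arg2, sep = "\r")
  tp <- length(intersect(gk, pk))
  if (!length(gk)) warning("empty gold set: recall reported as 0")
  p <- if (length(pk)) tp / length(pk) else 0
  r <- if (length(gk)) tp / length(gk) else 0
  structure(list(precision = p, recall = r, f1 = f1_score(p, r),
                 tp = tp, fp = length(pk) - tp, fn = length(gk) - tp,
                 n_gold = length(gk), n_pred = length(pk)),
            class = "prf_report")
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Numeric in `[0, 1]`.
#' @return `2PR / (P + R)`, or 0 when `P + R == 0`.
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0,
         2 * precision * recall / (precision + recall), 0)
}

#' @export
print.prf_report <- function(x, ...) {
  cat(sprintf("P = %.4f  R = %.4f  F1 = %.4f  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f1, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Candidate-level confusion matrix over the six-class space
#'
#' @param gold_labels Gold CPR labels (1-10, or the class names
#'   "3"/"4"/"5"/"6"/"9"/"other") per candidate.
#' @param pred_labels Predicted labels, same conventions, aligned with
#'   `gold_labels`.
#' @return A `cpi_confusion` 6x6 integer matrix (rows = gold, columns =
#'   predicted); the (other, other) cell is `NA` by convention.
#' @export
cpi_confusion <- function(gold_labels, pred_labels) {
  to6 <- function(v) {
    v <- as.character(v)
    v[!v %in% CLASSES6] <- "other"
    factor(v, levels = CLASSES6)
  }
  g <- to6(gold_labels); p <- to6(pred_labels)
  stopifnot(length(g) == length(p))
  m <- table(gold = g, predicted = p)
  m <- matrix(as.integer(m), 6L, 6L, dimnames = dimnames(m))
  m["other", "other"] <- NA_integer_
  structure(m, class = c("cpi_confusion", class(m)))
}

#' Per-class precision, recall and F1 from a confusion matrix
#'
#' `recall(c)` is the diagonal over the gold row sum, `precision(c)` the
#' diagonal over the predicted column sum; a zero row or column yields 0
#' and is flagged.
#'
#' @param cm A 6x6 matrix as from [cpi_confusion()] (rows gold, columns
#'   predicted; an `NA` (other, other) cell is ignored).
#' @param eval_classes Classes reported (default "3","4","5","6","9").
#' @return data.frame: class, tp, gold, predicted, precision, recall, f1,
#'   degenerate (zero row/column flag).
#' @export
per_class_prf <- function(cm, eval_classes = as.character(CPR_EVALUATED)) {
  stopifnot(all(eval_classes %in% rownames(cm)))
  out <- lapply(eval_classes, function(cls) {
    tp <- cm[cls, cls]
    gold <- sum(cm[cls, ], na.rm = TRUE)
    pred <- sum(cm[, cls], na.rm = TRUE)
    p <- if (pred > 0) tp / pred else 0
    r <- if (gold > 0) tp / gold else 0
    data.frame(class = paste0("CPR:", cls), tp = tp, gold = gold,
               predicted = pred, precision = p, recall = r,
               f1 = f1_score(p, r), degenerate = gold == 0 || pred == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.cpi_confusion <- function(x, ...) {
  cat("Candidate-level confusion matrix (rows gold, columns predicted):\n")
  print(unclass(x))
  stats <- per_class_prf(x)
  cat("\n")
  print(format(stats, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report
#'
#' Emits a tab-separated report: the confusion matrix block followed by
#' per-class F1/precision/recall rows and the micro-averaged summary.
#'
#' @param prf A `prf_report` from [micro_prf()].
#' @param cm Optional `cpi_confusion`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_prf_report <- function(prf, cm = NULL, path) {
  lines <- character(0)
  if (!is.null(cm)) {
    lines <- c(lines, paste(c("gold\\pred", colnames(cm)), collapse = "\t"))
    for (r in rownames(cm)) {
      lines <- c(lines, paste(c(r, ifelse(is.na(cm[r, ]), "-", cm[r, ])),
                              collapse = "\t"))
    }
    st <- per_class_prf(cm)
    lines <- c(lines,
               paste(c("F1", sprintf("%.4f", st$f1), "-"), collapse = "\t"),
               paste(c("Precision", sprintf("%.4f", st$precision), "-"),
                     collapse = "\t"),
               paste(c("Recall", sprintf("%.4f", st$recall), "-"),
                     collapse = "\t"))
  }
  lines <- c(lines,
             sprintf("micro\tP=%.4f\tR=%.4f\tF1=%.4f", prf$precision,
                     prf$recall, prf$f1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
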