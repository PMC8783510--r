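#' Classification metrics for chalky/non-chalky predictions
#'
#' Accuracy plus per-class precision, recall and F1, all as percentages
#' rounded half-up to 2 decimals. Undefined ratios (0/0) are reported as
#' 0.00, so a degenerate classifier that never predicts a class gets
#' precision = recall = F1 = 0.00 for it. The raw confusion counts are
#' returned so every reported number can be recomputed from them.
#'
#' @param pred,truth equal-length character vectors of labels
#'   (`"chalky"` / `"non-chalky"`).
#' @return list of class `classification_report`: `accuracy`, `per_class`
#'   (data.frame with class, precision, recall, f1, tp, fp, fn, tn),
#'   `confusion` (2x2 truth x prediction count matrix), `n`.
#' @export
classification_metrics <- function(pred, truth) {
  assert_that(length(pred) == length(truth) && length(pred) > 0,
              "pred and truth must be non-empty and of equal length")
  classes <- c("non-chalky", "chalky")
  assert_that(all(pred %in% classes) && all(truth %in% classes),
              "labels must be 'chalky' or 'non-chalky'")
  pf <- factor(pred, levels = classes)
  tf <- factor(truth, levels = classes)
  confusion <- table(truth = tf, prediction = pf)
  safe_pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  per_class <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tn <- sum(pred != cl & truth != cl)
    prec <- safe_pct(tp, tp + fp)
    rec <- safe_pct(tp, tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    data.frame(class = cl,
               precision = round_half_up(prec),
               recall = round_half_up(rec),
               f1 = round_half_up(f1),
               tp = tp, fp = fp, fn = fn, tn = tn,
               stringsAsFactors = FALSE)
  }))
  structure(list(accuracy = round_half_up(100 * mean(pred == truth)),
                 per_class = per_class,
                 confusion = confusion,
                 n = length(pred)),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.2f%% (n = %d)\n", x$accuracy, x$n))
  df <- x$per_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-11s Pre %6.2f  Rec %6.2f  F1 %6.2f\n",
                df$class[i], df$precision[i], df$recall[i], df$f1[i]))
  invisible(x)
}
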