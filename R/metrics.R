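# Per-class sensitivity/precision scoring of multiclass predictions:
#   CSen = TP / (TP + FN),  CPre = TP / (TP + FP)
# reported as percentages, with unweighted macro averages across classes.

#' Assemble a per-class sensitivity/precision report
#'
#' The aggregation used for every classification report in the package:
#' per-class sensitivity and precision percentages plus their unweighted
#' macro means.  Classes whose precision is undefined (no predicted
#' positives) are excluded from the macro precision mean.
#'
#' @param class_names Character vector of class names.
#' @param sensitivity_pct Per-class sensitivities in percent.
#' @param precision_pct Per-class precisions in percent (`NA` if undefined).
#' @param counts Optional data frame of per-class `tp`, `fn`, `fp`, `support`.
#' @param classifier Optional classifier kind tag.
#' @return An object of class `class_report`.
#' @export
#' @examples
#' class_report(c("walking", "grazing"), c(95.7, 94.4), c(91.3, 89.2))
class_report <- function(class_names, sensitivity_pct, precision_pct,
                         counts = NULL, classifier = NA_character_) {
  stopifnot(
    length(class_names) == length(sensitivity_pct),
    length(class_names) == length(precision_pct)
  )
  per_class <- data.frame(
    class = class_names,
    sensitivity_pct = as.numeric(sensitivity_pct),
    precision_pct = as.numeric(precision_pct),
    stringsAsFactors = FALSE
  )
  if (!is.null(counts)) per_class <- cbind(per_class, counts)
  structure(
    list(
      per_class = per_class,
      macro_sensitivity_pct = mean(per_class$sensitivity_pct, na.rm = TRUE),
      macro_precision_pct = mean(per_class$precision_pct, na.rm = TRUE),
      classifier = classifier
    ),
    class = "class_report"
  )
}

#' Score predictions with per-class sensitivity and precision
#'
#' Computes one-vs-rest confusion counts per behaviour class and the derived
#' percentages: sensitivity `100 * TP / (TP + FN)` and precision
#' `100 * TP / (TP + FP)`.  A class that is never predicted has undefined
#' precision (`NA`), which is excluded from the macro precision mean.
#'
#' @param truth Character/factor vector of true labels.
#' @param predicted Vector of predicted labels, same length.
#' @param classes Classes to report on; defaults to all classes present in
#'   `truth` (canonical ethogram order when applicable).
#' @param classifier Optional classifier kind tag carried into the report.
#' @return A [class_report()].
#' @export
#' @examples
#' truth <- c("walking", "walking", "grazing", "grazing")
#' pred <- c("walking", "grazing", "grazing", "grazing")
#' evaluate(truth, pred)
evaluate <- function(truth, predicted, classes = NULL, classifier = NA_character_) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted)) {
    stopf("truth and predicted have different lengths")
  }
  if (length(truth) == 0L) stopf("no predictions to evaluate")
  if (is.null(classes)) {
    present <- unique(truth)
    classes <- if (all(present %in% behavior_levels())) {
      behavior_levels()[behavior_levels() %in% present]
    } else {
      sort(present)
    }
  }
  tp <- fn <- fp <- integer(length(classes))
  for (i in seq_along(classes)) {
    c_i <- classes[i]
    tp[i] <- sum(truth == c_i & predicted == c_i)
    fn[i] <- sum(truth == c_i & predicted != c_i)
    fp[i] <- sum(truth != c_i & predicted == c_i)
  }
  sens <- ifelse(tp + fn > 0, 100 * tp / (tp + fn), NA_real_)
  prec <- ifelse(tp + fp > 0, 100 * tp / (tp + fp), NA_real_)
  class_report(
    classes, sens, prec,
    counts = data.frame(tp = tp, fn = fn, fp = fp, support = tp + fn),
    classifier = classifier
  )
}

#' @export
print.class_report <- function(x, digits = 2, ...) {
  hdr <- if (is.na(x$classifier)) "Classification report" else {
    sprintf("Classification report [%s]", x$classifier)
  }
  cat(hdr, "\n")
  df <- x$per_class
  df$sensitivity_pct <- round(df$sensitivity_pct, digits)
  df$precision_pct <- round(df$precision_pct, digits)
  print.data.frame(df, row.names = FALSE)
  cat(sprintf(
    "Average: sensitivity %.2f%%, precision %.2f%%\n",
    x$macro_sensitivity_pct, x$macro_precision_pct
  ))
  invisible(x)
}
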