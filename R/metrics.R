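#' Multi-class confusion matrix
#'
#' Counts follow the convention: rows are the predicted class, columns the
#' actual class, so `counts[p, a]` is the number of items predicted `p`
#' whose true class is `a`.
#'
#' @param truth Vector of actual class labels.
#' @param estimate Vector of predicted class labels, same length.
#' @param class_order Optional ordered character vector of classes;
#'   defaults to the sorted union of the labels seen.
#'
#' @return An `ecg_confusion` object: a K x K integer matrix (rows
#'   predicted, columns actual) with a `class_order` attribute.
#' @examples
#' cm <- confusion_matrix(c("A", "B", "B"), c("A", "B", "A"))
#' cm
#' @export
confusion_matrix <- function(truth, estimate, class_order = NULL) {
  truth <- as.character(truth)
  estimate <- as.character(estimate)
  if (length(truth) == 0L) stop("empty inputs: no predictions to tabulate")
  if (length(truth) != length(estimate)) {
    stop("`truth` (", length(truth), ") and `estimate` (", length(estimate),
         ") differ in length")
  }
  classes <- class_order %||% sort(unique(c(truth, estimate)))
  bad <- setdiff(unique(c(truth, estimate)), classes)
  if (length(bad)) {
    stop("label(s) not in `class_order`: ", paste(bad, collapse = ", "))
  }
  counts <- table(factor(estimate, levels = classes),
                  factor(truth, levels = classes))
  m <- matrix(as.integer(counts), nrow = length(classes),
              dimnames = list(predicted = classes, actual = classes))
  structure(m, class = c("ecg_confusion", "matrix"), class_order = classes)
}

#' @export
print.ecg_confusion <- function(x, ...) {
  cat("Confusion matrix (rows = predicted, columns = actual)\n")
  print(unclass(x))
  cat(sprintf("Overall accuracy: %.1f%% (n = %d)\n",
              overall_accuracy(x), sum(x)))
  invisible(x)
}

#' Per-class one-vs-rest counts
#'
#' Treats each class in turn as positive and the rest as negative:
#' `tp = counts[c, c]`, `fn` the remainder of the actual-class column,
#' `fp` the remainder of the predicted-class row, `tn` everything else.
#'
#' @param cm An `ecg_confusion`.
#' @param class Optional single class; by default all classes are
#'   returned.
#' @return A tibble with columns `class`, `tp`, `tn`, `fp`, `fn` (one row
#'   per class).
#' @export
one_vs_rest <- function(cm, class = NULL) {
  stopifnot(inherits(cm, "ecg_confusion"))
  classes <- attr(cm, "class_order")
  if (!is.null(class)) {
    if (!class %in% classes) stop("unknown class: ", class)
    classes <- class
  }
  total <- sum(cm)
  purrr::map_dfr(classes, function(cl) {
    tp <- cm[cl, cl]
    fn <- sum(cm[, cl]) - tp   # actual-class support minus hits
    fp <- sum(cm[cl, ]) - tp   # predicted-class support minus hits
    tibble::tibble(class = cl, tp = as.integer(tp),
                   tn = as.integer(total - tp - fn - fp),
                   fp = as.integer(fp), fn = as.integer(fn))
  })
}

#' Per-class evaluation metrics from one-vs-rest counts
#'
#' Computes, in percent and from the raw counts:
#' sensitivity `tp/(tp+fn)`, recall (identical to sensitivity by
#' definition), precision `tp/(tp+fp)`, specificity `tn/(tn+fp)` and
#' F-measure `2*Pr*Re/(Pr+Re)`.  A zero denominator yields `NA` (an
#' explicit undefined marker) with a warning, never a silent zero.
#'
#' @param counts A tibble of one-vs-rest counts (from [one_vs_rest()]), or
#'   a single row's worth of `tp`, `tn`, `fp`, `fn` as named arguments via
#'   `tibble::tibble()`.
#' @return The input tibble with columns `sensitivity`, `specificity`,
#'   `precision`, `recall`, `f_measure` appended (percent, unrounded).
#' @export
class_metrics <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("tp", "tn", "fp", "fn") %in% names(counts)))
  if (any(unlist(counts[c("tp", "tn", "fp", "fn")]) < 0)) {
    stop("one-vs-rest counts must be nonnegative")
  }
  safe_ratio <- function(num, den, what) {
    out <- ifelse(den > 0, 100 * num / den, NA_real_)
    if (anyNA(out)) {
      warning(what, " undefined for ", sum(is.na(out)),
              " class(es) (zero denominator); reported as NA", call. = FALSE)
    }
    out
  }
  se <- safe_ratio(counts$tp, counts$tp + counts$fn, "sensitivity/recall")
  sp <- safe_ratio(counts$tn, counts$tn + counts$fp, "specificity")
  pr <- safe_ratio(counts$tp, counts$tp + counts$fp, "precision")
  f1 <- ifelse(!is.na(pr) & !is.na(se) & (pr + se) > 0,
               2 * pr * se / (pr + se), NA_real_)
  dplyr::mutate(counts, sensitivity = se, specificity = sp, precision = pr,
                recall = se, f_measure = f1)
}

#' Overall multi-class accuracy
#'
#' `100 * trace / total`: the fraction of items on the confusion-matrix
#' diagonal.  Invariant under permutation of the class order.
#'
#' @param cm An `ecg_confusion`.
#' @return Accuracy in percent.
#' @export
overall_accuracy <- function(cm) {
  stopifnot(inherits(cm, "ecg_confusion"))
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  100 * sum(diag(unclass(cm))) / total
}

#' Macro averages of per-class metrics
#'
#' Unweighted arithmetic means over classes of the unrounded per-class
#' values.  `NA` (undefined) entries are excluded with a warning.
#'
#' @param per_class A tibble from [class_metrics()].
#' @return A one-row tibble of macro-averaged metrics (percent).
#' @export
macro_average <- function(per_class) {
  stopifnot(is.data.frame(per_class), nrow(per_class) >= 1)
  cols <- c("sensitivity", "specificity", "precision", "recall", "f_measure")
  stopifnot(all(cols %in% names(per_class)))
  if (anyNA(per_class[cols])) {
    warning("undefined per-class metrics excluded from macro averages",
            call. = FALSE)
  }
  dplyr::summarise(per_class,
                   dplyr::across(dplyr::all_of(cols), ~mean(.x, na.rm = TRUE)))
}

#' Full evaluation report for a multi-class confusion matrix
#'
#' Combines one-vs-rest counts, per-class metrics, overall accuracy and
#' macro averages into one object.  All metrics are computed from raw
#' counts and kept unrounded; rounding to one decimal happens only at
#' print time.
#'
#' @param cm An `ecg_confusion`.
#' @return An `ecg_metrics_report`: a list with `per_class` (tibble),
#'   `macro` (one-row tibble), `overall_accuracy` (percent) and `n`.
#' @examples
#' cm <- confusion_matrix(rep(c("A", "B"), 5), rep(c("A", "B"), 5))
#' metrics_report(cm)
#' @export
metrics_report <- function(cm) {
  stopifnot(inherits(cm, "ecg_confusion"))
  per_class <- class_metrics(one_vs_rest(cm))
  structure(
    list(per_class = per_class, macro = macro_average(per_class),
         overall_accuracy = overall_accuracy(cm), n = sum(cm)),
    class = "ecg_metrics_report"
  )
}

#' @export
print.ecg_metrics_report <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "--", sprintf("%.1f%%", v))
  tab <- x$per_class
  cat("Per-class performance (one-vs-rest)\n")
  cat(sprintf("%-6s %5s %5s %4s %4s %8s %8s %8s %8s %8s\n",
              "Class", "TP", "TN", "FP", "FN", "Se", "Sp", "Pr", "Re", "F1"))
  for (i in seq_len(nrow(tab))) {
    cat(sprintf("%-6s %5d %5d %4d %4d %8s %8s %8s %8s %8s\n",
                tab$class[i], tab$tp[i], tab$tn[i], tab$fp[i], tab$fn[i],
                fmt(tab$sensitivity[i]), fmt(tab$specificity[i]),
                fmt(tab$precision[i]), fmt(tab$recall[i]),
                fmt(tab$f_measure[i])))
  }
  m <- x$macro
  cat(sprintf("%-6s %26s %8s %8s %8s %8s %8s\n", "Avg", "",
              fmt(m$sensitivity), fmt(m$specificity), fmt(m$precision),
              fmt(m$recall), fmt(m$f_measure)))
  cat(sprintf("Overall accuracy: %.1f%% (n = %d)\n", x$overall_accuracy, x$n))
  invisible(x)
}

#' Tidy an evaluation report
#'
#' @param x An `ecg_metrics_report`.
#' @param ... Unused.
#' @return The per-class tibble with counts and unrounded metrics.
#' @method tidy ecg_metrics_report
#' @export
tidy.ecg_metrics_report <- function(x, ...) x$per_class

#' One-row summary of an evaluation report
#'
#' @param x An `ecg_metrics_report`.
#' @param ... Unused.
#' @return One-row tibble: `n`, `overall_accuracy` and the macro-averaged
#'   metrics (percent, unrounded).
#' @method glance ecg_metrics_report
#' @export
glance.ecg_metrics_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(n = x$n, overall_accuracy = x$overall_accuracy),
    dplyr::rename_with(x$macro, ~paste0("macro_", .x)))
}

#' Serialize an evaluation report to JSON
#'
#' @param x An `ecg_metrics_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(x, path) {
  stopifnot(inherits(x, "ecg_metrics_report"))
  jsonlite::write_json(
    list(n = x$n, overall_accuracy = x$overall_accuracy,
         per_class = x$per_class, macro = x$macro),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
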