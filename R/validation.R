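# Validation metrics for the range classifier and the per-range regressions:
# per-node accuracy (each decision node binarises the BIS scale at one
# boundary and is scored on the samples that reach it), per-leaf positive
# predictive value, per-range median error and median absolute error, and
# the observed-vs-predicted 99 x 99 heat-map matrix.

range_to_upper <- function(labels) {
  up <- bis_range_upper()
  out <- up[as.character(labels)]
  if (any(is.na(out))) {
    abort_bisre("unknown range label", "bisre_argument_error")
  }
  unname(out)
}

#' Accuracy of one decision node
#'
#' Binarises both labelings at `boundary` (range upper bound <= boundary
#' versus above) and returns `(TP + TN) / total x 100`. Restriction to the
#' samples reaching the node is the caller's responsibility (see
#' [validate_classifier()]).
#'
#' @param truth,pred equal-length vectors of range labels.
#' @param boundary the BIS boundary the node decides (21, 41, 61 or 78).
#' @return accuracy in percent.
#' @export
node_accuracy <- function(truth, pred, boundary) {
  if (length(truth) != length(pred)) {
    abort_bisre("truth and pred lengths differ", "bisre_argument_error")
  }
  if (!length(truth)) return(NA_real_)
  t_low <- range_to_upper(truth) <= boundary
  p_low <- range_to_upper(pred) <= boundary
  100 * mean(t_low == p_low)
}

#' Positive predictive value of one leaf
#'
#' Fraction of samples predicted as `range_id` whose true label is
#' `range_id`, times 100. With no predictions of `range_id` the value is
#' undefined and `NA` is returned (never 0).
#'
#' @param truth,pred equal-length vectors of range labels.
#' @param range_id the leaf's range label.
#' @return PPV in percent, or `NA` if the range was never predicted.
#' @export
leaf_ppv <- function(truth, pred, range_id) {
  if (length(truth) != length(pred)) {
    abort_bisre("truth and pred lengths differ", "bisre_argument_error")
  }
  sel <- as.character(pred) == range_id
  if (!any(sel)) return(NA_real_)
  100 * mean(as.character(truth)[sel] == range_id)
}

#' Per-range median error and median absolute error
#'
#' Residuals are `predicted - observed`. Ranges with no samples get `NA`
#' markers rather than zeros.
#'
#' @param observed,predicted aligned numeric BIS vectors.
#' @param ranges range label per sample (defaults to the ranges of the
#'   observed values).
#' @return data.frame with one row per range plus a pooled `"all"` row,
#'   columns `range`, `n`, `median_error`, `median_abs_error`.
#' @export
error_summary <- function(observed, predicted,
                          ranges = bis_range_of(round(observed))) {
  if (length(observed) != length(predicted)) {
    abort_bisre("observed and predicted lengths differ",
                "bisre_argument_error")
  }
  res <- predicted - observed
  labels <- bis_range_labels()
  rows <- lapply(c(labels, "all"), function(lab) {
    sel <- if (lab == "all") rep(TRUE, length(res))
           else as.character(ranges) == lab
    data.frame(range = lab, n = sum(sel),
               median_error = if (any(sel)) stats::median(res[sel]) else NA_real_,
               median_abs_error = if (any(sel)) stats::median(abs(res[sel]))
                                  else NA_real_)
  })
  do.call(rbind, rows)
}

#' Observed-vs-predicted count matrix
#'
#' @param observed,predicted BIS values, rounded to integers in `[0, 98]`.
#' @return 99 x 99 integer matrix; cell `[i, j]` counts samples with
#'   observed BIS `i - 1` and predicted BIS `j - 1`.
#' @export
heatmap_matrix <- function(observed, predicted) {
  o <- round(observed)
  p <- round(predicted)
  bad <- which(!is.finite(o) | o < 0 | o > 98 | !is.finite(p) | p < 0 | p > 98)
  if (length(bad)) {
    abort_bisre(sprintf("BIS value out of [0, 98] at index %d", bad[1]),
                "bisre_validation_error")
  }
  m <- matrix(0L, 99, 99, dimnames = list(observed = 0:98, predicted = 0:98))
  tab <- table(factor(o, levels = 0:98), factor(p, levels = 0:98))
  m[] <- as.integer(tab)
  m
}

#' Full validation report for a BIS model
#'
#' Scores the range classifier with per-node accuracies (each node evaluated
#' on the samples that reach it along the predicted path) and per-leaf PPVs,
#' and the regressions with per-range error summaries and the heat-map
#' matrix. Overall accuracy and PPV are reported both sample-weighted and
#' macro-averaged.
#'
#' @param model a [bis_model()].
#' @param data data.frame with subparameter columns and observed `bis`.
#' @param truth optional true range labels; defaults to the ranges of the
#'   observed BIS values.
#' @return object of class `bis_validation_report`: list with
#'   `node_accuracy`, `leaf_ppv`, `errors`, `heatmap`, `n`.
#' @export
validate_classifier <- function(model, data,
                                truth = bis_range_of(round(data$bis))) {
  check_subparameters(data)
  tree <- model$tree
  pred <- predict_bis(data, model)
  reach2 <- data$bsr <= tree$bsr_threshold
  low <- reach2 & data$emg < tree$emg_threshold & data$sef < tree$sef_threshold_hi
  node_masks <- list(
    "21" = rep(TRUE, nrow(data)),
    "61" = reach2,
    "41" = low,
    "78" = reach2 & !low
  )
  acc <- vapply(names(node_masks), function(bd) {
    m <- node_masks[[bd]]
    node_accuracy(truth[m], pred$range[m], as.numeric(bd))
  }, numeric(1))
  acc_overall_sample <- sum(acc * vapply(node_masks, sum, numeric(1)),
                            na.rm = TRUE) /
    sum(vapply(node_masks, sum, numeric(1))[!is.na(acc)])
  labels <- bis_range_labels()
  ppv <- vapply(labels, function(lab) leaf_ppv(truth, pred$range, lab),
                numeric(1))
  pred_counts <- vapply(labels, function(lab) sum(pred$range == lab),
                        numeric(1))
  ppv_overall_sample <- sum(ppv * pred_counts, na.rm = TRUE) /
    sum(pred_counts[!is.na(ppv)])
  structure(
    list(
      node_accuracy = c(acc, overall_sample = acc_overall_sample,
                        overall_macro = mean(acc, na.rm = TRUE)),
      leaf_ppv = c(ppv, overall_sample = ppv_overall_sample,
                   overall_macro = mean(ppv, na.rm = TRUE)),
      errors = error_summary(data$bis, pred$bis, truth),
      heatmap = heatmap_matrix(pmin(pmax(data$bis, 0), 98), pred$bis),
      n = nrow(data)
    ),
    class = "bis_validation_report"
  )
}

#' Write a validation report to disk
#'
#' Emits a JSON summary (node accuracies, leaf PPVs, error table) and a
#' dense CSV heat-map matrix.
#'
#' @param report a `bis_validation_report`.
#' @param json_path path for the JSON summary.
#' @param heatmap_path optional path for the heat-map CSV.
#' @return `json_path`, invisibly.
#' @export
write_validation_report <- function(report, json_path, heatmap_path = NULL) {
  doc <- list(n = report$n,
              node_accuracy = as.list(report$node_accuracy),
              leaf_ppv = as.list(report$leaf_ppv),
              errors = report$errors)
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  if (!is.null(heatmap_path)) {
    utils::write.csv(report$heatmap, heatmap_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' @export
print.bis_validation_report <- function(x, ...) {
  cat(sprintf("BIS validation report (n = %d)\n", x$n))
  cat("Node accuracy (%):\n")
  print(round(x$node_accuracy, 1))
  cat("Leaf PPV (%):\n")
  print(round(x$leaf_ppv, 1))
  cat("Errors by range:\n")
  print(x$errors, row.names = FALSE)
  invisible(x)
}
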