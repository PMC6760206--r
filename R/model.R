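# The published BIS estimator: a four-node decision tree that assigns one of
# five BIS ranges from the subparameters, followed by a per-range multiple
# linear regression. The tree is evaluated sequentially:
#
#   node 1: BSR > 49.8 %                      -> range 0-21
#   node 2: EMG < 34.2 dB AND SEF < 20.2 Hz   -> node 3, else node 4
#   node 3: BSR > 2.1 % OR SEF < 14.8 Hz      -> range 21-41, else 41-61
#   node 4: RBR < -0.7                        -> range 61-78, else 78-98
#
# Comparisons are strict as printed; equality falls to the else branch.
# Regression outputs are not forced into their range's interval; only a
# global clip to [0, 98] is applied, matching the observed scatter of
# predictions across range boundaries.

#' Decision-tree threshold specification
#'
#' Holds the ordered node conditions of the four-level BIS range classifier.
#' Defaults are the published thresholds.
#'
#' @param bsr_threshold root-node BSR threshold (%); `BSR > bsr_threshold`
#'   assigns range 0-21.
#' @param emg_threshold second-node EMG threshold (dB).
#' @param sef_threshold_hi second-node SEF threshold (Hz); the low-BIS branch
#'   requires `EMG < emg_threshold` and `SEF < sef_threshold_hi` together.
#' @param bsr_low_threshold third-node BSR threshold (%).
#' @param sef_threshold_lo third-node SEF threshold (Hz); range 21-41 when
#'   `BSR > bsr_low_threshold` or `SEF < sef_threshold_lo`.
#' @param rbr_threshold fourth-node RBR threshold (log10 ratio); range 61-78
#'   when `RBR < rbr_threshold`, else 78-98.
#' @return object of class `bis_tree_spec`.
#' @export
bis_tree_spec <- function(bsr_threshold = 49.8,
                          emg_threshold = 34.2,
                          sef_threshold_hi = 20.2,
                          bsr_low_threshold = 2.1,
                          sef_threshold_lo = 14.8,
                          rbr_threshold = -0.7) {
  check_number(bsr_threshold, "bsr_threshold", 0, 100)
  check_number(emg_threshold, "emg_threshold")
  check_number(sef_threshold_hi, "sef_threshold_hi", 0.5, 30)
  check_number(bsr_low_threshold, "bsr_low_threshold", 0, 100)
  check_number(sef_threshold_lo, "sef_threshold_lo", 0.5, 30)
  check_number(rbr_threshold, "rbr_threshold")
  if (bsr_threshold <= bsr_low_threshold) {
    abort_bisre("bsr_threshold must exceed bsr_low_threshold",
                "bisre_config_error")
  }
  if (sef_threshold_hi <= sef_threshold_lo) {
    abort_bisre("sef_threshold_hi must exceed sef_threshold_lo",
                "bisre_config_error")
  }
  structure(
    list(bsr_threshold = bsr_threshold,
         emg_threshold = emg_threshold,
         sef_threshold_hi = sef_threshold_hi,
         bsr_low_threshold = bsr_low_threshold,
         sef_threshold_lo = sef_threshold_lo,
         rbr_threshold = rbr_threshold),
    class = "bis_tree_spec"
  )
}

#' Per-range regression coefficient table
#'
#' Validates and normalises a coefficient table with one row per BIS range
#' and columns `range`, `coef_bsr`, `coef_sef`, `coef_rbr`, `coef_emg`,
#' `intercept` (BIS units per subparameter unit; intercept in BIS units).
#'
#' @param df data.frame with the columns above.
#' @return the validated data.frame, rows ordered by increasing range.
#' @export
bis_range_regressions <- function(df) {
  needed <- c("range", "coef_bsr", "coef_sef", "coef_rbr", "coef_emg",
              "intercept")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    abort_bisre(paste0("regression table missing column(s): ",
                       paste(missing, collapse = ", ")),
                "bisre_schema_error")
  }
  labels <- bis_range_labels()
  absent <- setdiff(labels, df$range)
  if (length(absent)) {
    abort_bisre(paste0("regression missing for range(s): ",
                       paste(absent, collapse = ", ")),
                "bisre_schema_error")
  }
  df <- df[match(labels, df$range), needed]
  num <- as.matrix(df[, -1])
  if (any(!is.finite(num))) {
    abort_bisre("all regression coefficients must be finite",
                "bisre_schema_error")
  }
  rownames(df) <- NULL
  df
}

#' Assemble a BIS model
#'
#' A BIS model couples the range-classifying decision tree with the five
#' per-range regressions and a global output clip to `[0, 98]`.
#'
#' @param tree a [bis_tree_spec()].
#' @param regressions a coefficient table accepted by
#'   [bis_range_regressions()].
#' @return object of class `bis_model`.
#' @export
bis_model <- function(tree = bis_tree_spec(),
                      regressions = default_regression_table()) {
  if (!inherits(tree, "bis_tree_spec")) {
    abort_bisre("'tree' must be a bis_tree_spec", "bisre_config_error")
  }
  structure(
    list(tree = tree,
         regressions = bis_range_regressions(regressions),
         clip = c(0, 98)),
    class = "bis_model"
  )
}

#' The published regression coefficients
#'
#' One multiple linear regression per BIS range, in the field's usual
#' layout (range, BSR, SEF, RBR, EMG coefficients, intercept). For the
#' isoelectric range the model is essentially `42.1 - 0.42 x BSR`.
#'
#' @return data.frame accepted by [bis_range_regressions()].
#' @export
default_regression_table <- function() {
  data.frame(
    range = bis_range_labels(),
    coef_bsr = c(-0.42, -0.42, -3.01, -1.43, -1.97),
    coef_sef = c(0.00, 0.91, 3.84, 2.55, 0.88),
    coef_rbr = c(0.01, 3.06, -8.70, 4.26, 7.89),
    coef_emg = c(0.00, 0.04, 0.96, 0.41, -0.07),
    intercept = c(42.1, 29.9, -57.6, 5.3, 65.2),
    stringsAsFactors = FALSE
  )
}

#' The published BIS model
#'
#' The fixed estimator combining the default tree thresholds and the default
#' regression table.
#'
#' @return a `bis_model`.
#' @examples
#' m <- default_bis_model()
#' predict_bis(data.frame(bsr = 60, sef = 15, emg = 30, rbr = 0), m)
#' @export
default_bis_model <- function() {
  bis_model(bis_tree_spec(), default_regression_table())
}

check_subparameters <- function(x, cols = c("bsr", "sef", "emg", "rbr")) {
  if (!is.data.frame(x)) {
    abort_bisre("subparameter input must be a data.frame",
                "bisre_validation_error")
  }
  missing <- setdiff(cols, names(x))
  if (length(missing)) {
    abort_bisre(paste0("missing subparameter column(s): ",
                       paste(missing, collapse = ", ")),
                "bisre_validation_error")
  }
  for (cc in cols) {
    if (any(!is.finite(x[[cc]]))) {
      abort_bisre(sprintf("non-finite %s at row %d", cc,
                          which(!is.finite(x[[cc]]))[1]),
                  "bisre_validation_error")
    }
  }
  invisible(x)
}

#' Classify subparameter samples into BIS ranges
#'
#' Sequential evaluation of the four decision nodes. SFS is not a classifier
#' and never affects the result.
#'
#' @param x data.frame with numeric columns `bsr`, `sef`, `emg`, `rbr`.
#' @param tree a [bis_tree_spec()].
#' @return factor of range labels, one per row of `x`.
#' @examples
#' classify_range(data.frame(bsr = 0, sef = 15, emg = 30, rbr = 0))
#' @export
classify_range <- function(x, tree = bis_tree_spec()) {
  check_subparameters(x)
  n <- nrow(x)
  out <- character(n)
  suppressed <- x$bsr > tree$bsr_threshold
  low_bis <- !suppressed & x$emg < tree$emg_threshold &
    x$sef < tree$sef_threshold_hi
  high_bis <- !suppressed & !low_bis
  out[suppressed] <- "0-21"
  profound <- low_bis & (x$bsr > tree$bsr_low_threshold |
                           x$sef < tree$sef_threshold_lo)
  out[profound] <- "21-41"
  out[low_bis & !profound] <- "41-61"
  sedated <- high_bis & x$rbr < tree$rbr_threshold
  out[sedated] <- "61-78"
  out[high_bis & !sedated] <- "78-98"
  factor(out, levels = bis_range_labels())
}

#' Predict BIS from subparameters
#'
#' Classifies each sample with the model's tree, applies the matching
#' range regression, and clips the result to `[0, 98]`.
#'
#' @param x data.frame with numeric columns `bsr`, `sef`, `emg`, `rbr`.
#' @param model a [bis_model()]; default the published model.
#' @param round_output if `TRUE`, round to the nearest integer as a BIS
#'   monitor display would; the continuous value is the primary output.
#' @return data.frame with columns `bis` (predicted value) and `range`
#'   (factor of assigned range labels).
#' @examples
#' predict_bis(data.frame(bsr = 100, sef = 10, emg = 30, rbr = 0))
#' @export
predict_bis <- function(x, model = default_bis_model(),
                        round_output = FALSE) {
  rng <- classify_range(x, model$tree)
  reg <- model$regressions
  idx <- match(as.character(rng), reg$range)
  bis <- reg$intercept[idx] +
    reg$coef_bsr[idx] * x$bsr +
    reg$coef_sef[idx] * x$sef +
    reg$coef_rbr[idx] * x$rbr +
    reg$coef_emg[idx] * x$emg
  bis <- pmin(pmax(bis, model$clip[1]), model$clip[2])
  if (round_output) bis <- round(bis)
  data.frame(bis = bis, range = rng)
}

#' Serialise a BIS model to JSON / read one back
#'
#' The model document stores the six tree thresholds and the per-range
#' coefficient table. `read_bis_model(write_bis_model(m, f))` reproduces `m`
#' field by field.
#'
#' @param model a [bis_model()].
#' @param path file path of the JSON document.
#' @return `write_bis_model` returns `path` invisibly; `read_bis_model`
#'   returns a `bis_model`.
#' @export
write_bis_model <- function(model, path) {
  doc <- list(
    tree = model$tree[],
    regressions = model$regressions
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_bis_model
#' @export
read_bis_model <- function(path) {
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE),
    error = function(e) abort_bisre(
      paste0("cannot parse model document: ", conditionMessage(e)),
      "bisre_schema_error")
  )
  tree_fields <- c("bsr_threshold", "emg_threshold", "sef_threshold_hi",
                   "bsr_low_threshold", "sef_threshold_lo", "rbr_threshold")
  missing <- setdiff(tree_fields, names(doc$tree))
  if (is.null(doc$tree) || length(missing)) {
    abort_bisre(paste0("model document missing tree field(s): ",
                       paste(if (length(missing)) missing else tree_fields,
                             collapse = ", ")),
                "bisre_schema_error")
  }
  if (is.null(doc$regressions)) {
    abort_bisre("model document missing 'regressions'", "bisre_schema_error")
  }
  tree <- do.call(bis_tree_spec, doc$tree[tree_fields])
  bis_model(tree, as.data.frame(doc$regressions))
}

#' @export
print.bis_tree_spec <- function(x, ...) {
  cat("BIS range decision tree\n")
  cat(sprintf("  node 1: BSR > %.4g%% -> 0-21\n", x$bsr_threshold))
  cat(sprintf("  node 2: EMG < %.4g dB AND SEF < %.4g Hz -> node 3, else node 4\n",
              x$emg_threshold, x$sef_threshold_hi))
  cat(sprintf("  node 3: BSR > %.4g%% OR SEF < %.4g Hz -> 21-41, else 41-61\n",
              x$bsr_low_threshold, x$sef_threshold_lo))
  cat(sprintf("  node 4: RBR < %.4g -> 61-78, else 78-98\n", x$rbr_threshold))
  invisible(x)
}

#' @export
print.bis_model <- function(x, ...) {
  print(x$tree)
  cat("Per-range regressions (BIS = intercept + coef . subparameters):\n")
  print(x$regressions, row.names = FALSE)
  invisible(x)
}
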