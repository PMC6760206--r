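# Class-balanced sampling across BIS values.
#
# Intraoperative BIS concentrates at 40-60, so trees trained on raw pools
# would barely see the extreme ranges. The balanced sampler draws an (almost)
# equal number of samples for every integer BIS value represented in the
# pool: quota floor(total / k) per value with the remainder assigned to the
# lowest values, without replacement where the pool allows and with
# replacement (recorded) otherwise.

#' Draw a class-balanced dataset over BIS values
#'
#' @param pool data.frame containing a numeric BIS column; values are
#'   rounded to integers in `[0, 98]`.
#' @param total exact number of samples to return (default 100000).
#' @param seed integer seed.
#' @param bis_column name of the BIS column (default `"bis"`).
#' @return data.frame of exactly `total` rows whose per-BIS-value counts
#'   differ by at most one across the values present in the pool. The
#'   attribute `"with_replacement_values"` lists BIS values whose quota
#'   exceeded the pool and were drawn with replacement.
#' @export
balanced_sample <- function(pool, total = 100000, seed = 1L,
                            bis_column = "bis") {
  if (!is.data.frame(pool) || nrow(pool) == 0) {
    abort_bisre("pool must be a non-empty data.frame", "bisre_argument_error")
  }
  if (!bis_column %in% names(pool)) {
    abort_bisre(sprintf("pool has no '%s' column", bis_column),
                "bisre_argument_error")
  }
  b <- round(pool[[bis_column]])
  if (any(!is.finite(b) | b < 0 | b > 98)) {
    abort_bisre("pool BIS values must lie in [0, 98]",
                "bisre_validation_error")
  }
  values <- sort(unique(b))
  k <- length(values)
  if (total < k) {
    abort_bisre("total smaller than the number of represented BIS values",
                "bisre_argument_error")
  }
  quota <- rep(floor(total / k), k)
  rem <- total - sum(quota)
  if (rem > 0) quota[seq_len(rem)] <- quota[seq_len(rem)] + 1
  idx_by_value <- split(seq_along(b), b)
  with_seed(seed, {
    repl <- logical(k)
    picks <- lapply(seq_len(k), function(i) {
      rows <- idx_by_value[[as.character(values[i])]]
      q <- quota[i]
      if (length(rows) >= q) {
        rows[sample.int(length(rows), q)]
      } else {
        repl[i] <<- TRUE
        rows[sample.int(length(rows), q, replace = TRUE)]
      }
    })
    out <- pool[unlist(picks), , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "with_replacement_values") <- values[repl]
    out
  })
}
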