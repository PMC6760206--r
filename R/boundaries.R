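# BIS range boundaries as histogram discontinuities.
#
# If the index switches between regression equations at fixed BIS values,
# the pooled BIS histogram shows abrupt frequency changes at those values.
# Detection works on first differences of log counts: a boundary is declared
# at value b when |log c(b+1) - log c(b)| exceeds `sensitivity` times the
# median absolute deviation of all the log-count differences.

#' BIS histogram container
#'
#' @param counts non-negative integer counts indexed by BIS value 0..98
#'   (length 99).
#' @return object of class `bis_histogram` with fields `counts`, `values`,
#'   `total`.
#' @export
bis_histogram <- function(counts) {
  if (length(counts) != 99 || any(counts < 0) || any(!is.finite(counts))) {
    abort_bisre("counts must be 99 non-negative values (BIS 0..98)",
                "bisre_validation_error")
  }
  structure(list(counts = as.numeric(counts), values = 0:98,
                 total = sum(counts)),
            class = "bis_histogram")
}

#' Histogram of BIS values
#'
#' @param bis_values numeric vector; values are rounded to integers and must
#'   fall in `[0, 98]`.
#' @return a [bis_histogram()].
#' @export
build_histogram <- function(bis_values) {
  b <- round(bis_values)
  bad <- which(!is.finite(b) | b < 0 | b > 98)
  if (length(bad)) {
    abort_bisre(sprintf("BIS value out of [0, 98] at index %d: %s",
                        bad[1], format(bis_values[bad[1]])),
                "bisre_validation_error")
  }
  bis_histogram(tabulate(b + 1L, nbins = 99))
}

#' Detect range boundaries as log-count discontinuities
#'
#' Returns every BIS value `b` whose log-count jump to `b + 1` exceeds
#' `sensitivity` times the robust spread of all the jumps (median absolute
#' deviation scaled by 1.4826, so it estimates the standard deviation of the
#' within-range count noise and sensitivity 4 sits at roughly four sigmas).
#' Adjacent detections are merged to the larger-jump value so pile-up bins
#' at a boundary cannot produce a double detection. Counts are offset by
#' 0.5 before taking logs so empty bins stay finite; the statistic is
#' invariant under rescaling all counts.
#'
#' @param h a [bis_histogram()] with positive total.
#' @param sensitivity multiplier on the robust spread (default 4).
#' @return increasing integer vector of detected boundary values (possibly
#'   empty).
#' @export
detect_boundaries <- function(h, sensitivity = 4) {
  if (!inherits(h, "bis_histogram")) {
    abort_bisre("'h' must be a bis_histogram", "bisre_argument_error")
  }
  if (h$total <= 0) {
    abort_bisre("histogram is empty", "bisre_argument_error")
  }
  if (sum(h$counts > 0) <= 1) {
    warning("degenerate histogram (single occupied bin); no boundaries",
            call. = FALSE)
    return(integer(0))
  }
  d <- diff(log(h$counts + 0.5))        # d[i] is the jump between i-1 and i
  spread <- stats::mad(d)               # Gaussian-consistent MAD (x 1.4826)
  hits <- which(abs(d) > pmax(sensitivity * spread, 1e-12))
  if (!length(hits)) return(integer(0))
  # merge runs of adjacent detections, keeping the largest jump in each run
  runs <- split(hits, cumsum(c(1, diff(hits) != 1)))
  vals <- vapply(runs, function(r) r[which.max(abs(d[r]))], numeric(1))
  sort(as.integer(vals - 1))            # d index i corresponds to value i-1
}

#' Add the known boundary to a detected set
#'
#' BIS 21 separates isoelectricity from profound anaesthesia but is barely
#' populated in intraoperative data, so it is appended as a known boundary
#' rather than detected.
#'
#' @param detected integer vector from [detect_boundaries()].
#' @param known boundary value(s) always included (default 21).
#' @return increasing union of `detected` and `known`.
#' @export
finalize_boundaries <- function(detected, known = 21) {
  sort(unique(as.integer(c(known, detected))))
}

#' Read/write a histogram as two-column CSV
#'
#' @param h a [bis_histogram()].
#' @param path CSV path with columns `bis`, `count`.
#' @return `write_histogram` returns `path` invisibly; `read_histogram`
#'   returns a `bis_histogram`.
#' @export
write_histogram <- function(h, path) {
  utils::write.csv(data.frame(bis = h$values, count = h$counts), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_histogram
#' @export
read_histogram <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("bis", "count") %in% names(df))) {
    abort_bisre("histogram CSV needs columns 'bis' and 'count'",
                "bisre_schema_error")
  }
  counts <- numeric(99)
  counts[df$bis + 1] <- df$count
  bis_histogram(counts)
}
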