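# The five BIS ranges and their boundary conventions.
#
# The 0-98 BIS scale is partitioned by the boundary values 21, 41, 61 and 78
# into five anaesthetic-depth ranges: isoelectricity (0 <= BIS <= 21),
# profound anaesthesia (21 < BIS <= 41), adequate anaesthesia (41 < BIS <= 61),
# sedation (61 < BIS <= 78) and awake (78 < BIS <= 98). Every interval is
# lower-exclusive / upper-inclusive except the first, which includes 0.

#' BIS range labels
#'
#' @return Character vector of the five range labels, in increasing BIS
#'   order: `"0-21"`, `"21-41"`, `"41-61"`, `"61-78"`, `"78-98"`.
#' @export
bis_range_labels <- function() {
  c("0-21", "21-41", "41-61", "61-78", "78-98")
}

# Upper bound of each range, used when binarising labels at a boundary.
bis_range_upper <- function() {
  c("0-21" = 21, "21-41" = 41, "41-61" = 61, "61-78" = 78, "78-98" = 98)
}

#' Map BIS values to their range
#'
#' Ranges are lower-exclusive and upper-inclusive (`21 < BIS <= 41` etc.)
#' except the first, which is `0 <= BIS <= 21`.
#'
#' @param bis numeric vector of BIS values in `[0, 98]`.
#' @param boundaries increasing interior boundary values; default the
#'   published set `c(21, 41, 61, 78)`.
#' @return factor with levels [bis_range_labels()] (or constructed labels if
#'   non-default boundaries are supplied).
#' @examples
#' bis_range_of(c(0, 21, 21.5, 41, 77, 98))
#' @export
bis_range_of <- function(bis, boundaries = c(21, 41, 61, 78)) {
  if (any(!is.finite(bis)) || any(bis < 0) || any(bis > 98)) {
    bad <- which(!is.finite(bis) | bis < 0 | bis > 98)[1]
    abort_bisre(
      sprintf("BIS value out of [0, 98] at index %d: %s", bad,
              format(bis[bad])),
      "bisre_validation_error"
    )
  }
  boundaries <- sort(boundaries)
  edges <- c(0, boundaries, 98)
  labels <- paste0(edges[-length(edges)], "-", edges[-1])
  if (identical(boundaries, c(21, 41, 61, 78))) labels <- bis_range_labels()
  cut(bis, breaks = edges, labels = labels, include.lowest = TRUE,
      right = TRUE)
}
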