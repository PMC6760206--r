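# Per-range regression estimation with RANSAC.
#
# For each BIS range (as assigned by the decision tree, not by the observed
# BIS), repeatedly: draw a random subset, fit ordinary least squares on it,
# and count inliers (|residual| <= margin) over the whole range. The best
# iteration by inlier count (ties: smaller median absolute inlier residual)
# defines the consensus set, and the final coefficients are a least-squares
# refit on that set, which makes the refit idempotent on its own inliers.

#' RANSAC configuration
#'
#' @param sample_size rows per random subset (default 1000).
#' @param n_iterations number of random subsets (default 100).
#' @param inlier_margin absolute-residual inlier threshold in BIS units
#'   (default 5).
#' @param seed integer seed.
#' @return object of class `bis_ransac_config`.
#' @export
ransac_config <- function(sample_size = 1000, n_iterations = 100,
                          inlier_margin = 5, seed = 1L) {
  check_number(sample_size, "sample_size", 2)
  check_number(n_iterations, "n_iterations", 1)
  check_number(inlier_margin, "inlier_margin", 1e-12)
  structure(list(sample_size = as.integer(sample_size),
                 n_iterations = as.integer(n_iterations),
                 inlier_margin = inlier_margin,
                 seed = as.integer(seed)),
            class = "bis_ransac_config")
}

ols_coef <- function(X, y) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  if (fit$rank < ncol(X) + 1) return(NULL)
  fit$coefficients
}

#' RANSAC linear regression
#'
#' @param X numeric matrix of predictors (columns named by subparameter).
#' @param y numeric response (BIS values).
#' @param config a [ransac_config()].
#' @return list with `coefficients` (named vector, intercept first),
#'   `inliers` (logical mask over rows), `n_inliers`, and `iterations_used`.
#'   If `nrow(X) < sample_size` the whole-data least-squares fit is returned
#'   with a message and all rows marked inliers.
#' @export
ransac_fit <- function(X, y, config = ransac_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) {
    abort_bisre("X and y lengths differ", "bisre_argument_error")
  }
  if (config$sample_size < ncol(X) + 1) {
    abort_bisre("sample_size must exceed the number of coefficients",
                "bisre_config_error")
  }
  if (n < config$sample_size) {
    message(sprintf(
      "ransac_fit: %d rows < sample_size %d; falling back to least squares",
      n, config$sample_size))
    cf <- ols_coef(X, y)
    if (is.null(cf)) abort_bisre("rank-deficient design", "bisre_fitting_error")
    return(list(coefficients = cf, inliers = rep(TRUE, n), n_inliers = n,
                iterations_used = 0L))
  }
  with_seed(config$seed, {
    best <- list(count = -1L, med = Inf, inliers = NULL)
    used <- 0L
    for (it in seq_len(config$n_iterations)) {
      idx <- sample.int(n, config$sample_size)
      cf <- ols_coef(X[idx, , drop = FALSE], y[idx])
      if (is.null(cf)) next
      used <- used + 1L
      res <- abs(y - (cf[1] + X %*% cf[-1]))
      inl <- res <= config$inlier_margin
      cnt <- sum(inl)
      med <- if (cnt > 0) stats::median(res[inl]) else Inf
      if (cnt > best$count || (cnt == best$count && med < best$med)) {
        best <- list(count = cnt, med = med, inliers = inl)
      }
    }
    if (used == 0L) {
      abort_bisre("rank-deficient design in every RANSAC iteration",
                  "bisre_fitting_error")
    }
    inl <- as.vector(best$inliers)
    cf <- ols_coef(X[inl, , drop = FALSE], y[inl])
    if (is.null(cf)) {
      abort_bisre("rank-deficient design on the consensus set",
                  "bisre_fitting_error")
    }
    list(coefficients = cf, inliers = inl, n_inliers = sum(inl),
         iterations_used = used)
  })
}

#' Fit the five per-range regressions
#'
#' Partitions the data by the tree's predicted range (matching the estimator,
#' which applies a regression after the tree has chosen the range), runs
#' RANSAC within each partition with all four subparameters as regressors,
#' and assembles the fitted [bis_model()].
#'
#' @param data data.frame with columns `bsr`, `sef`, `rbr`, `emg` and `bis`.
#' @param tree the [bis_tree_spec()] used for partitioning.
#' @param config a [ransac_config()]; per-range seeds are derived from
#'   `config$seed`.
#' @param partition_by `"predicted"` (default: the tree's range) or
#'   `"observed"` (ranges of the observed BIS values).
#' @return list with `model` (the fitted `bis_model`), `fits` (per-range
#'   RANSAC details) and `coefficients` (the Table-style data.frame).
#' @export
fit_range_models <- function(data, tree = bis_tree_spec(),
                             config = ransac_config(),
                             partition_by = c("predicted", "observed")) {
  partition_by <- match.arg(partition_by)
  check_subparameters(data)
  if (!"bis" %in% names(data)) {
    abort_bisre("data has no 'bis' column", "bisre_argument_error")
  }
  rng <- if (partition_by == "predicted") {
    classify_range(data, tree)
  } else {
    bis_range_of(round(data$bis))
  }
  labels <- bis_range_labels()
  fits <- vector("list", length(labels))
  names(fits) <- labels
  rows <- lapply(labels, function(lab) {
    sel <- which(rng == lab)
    if (!length(sel)) {
      abort_bisre(sprintf("no samples in range %s; cannot fit its regression",
                          lab), "bisre_fitting_error")
    }
    sel
  })
  reg <- data.frame(range = labels, coef_bsr = NA_real_, coef_sef = NA_real_,
                    coef_rbr = NA_real_, coef_emg = NA_real_,
                    intercept = NA_real_)
  for (i in seq_along(labels)) {
    sel <- rows[[i]]
    X <- as.matrix(data[sel, c("bsr", "sef", "rbr", "emg")])
    cfg <- config
    cfg$seed <- derive_seed(config$seed, i)
    fits[[i]] <- ransac_fit(X, data$bis[sel], cfg)
    cf <- fits[[i]]$coefficients
    reg[i, c("coef_bsr", "coef_sef", "coef_rbr", "coef_emg")] <-
      cf[c("bsr", "sef", "rbr", "emg")]
    reg$intercept[i] <- cf[1]
  }
  list(model = bis_model(tree, reg), fits = fits, coefficients = reg)
}

#' Write a coefficient table as CSV
#'
#' Emits the per-range coefficient table in the conventional layout (range,
#' BSR, SEF, RBR, EMG coefficients, intercept).
#'
#' @param model a [bis_model()].
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_coefficients <- function(model, path) {
  utils::write.csv(model$regressions, path, row.names = FALSE)
  invisible(path)
}
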