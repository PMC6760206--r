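# Track I/O, case-level filters and the end-to-end pipeline driver.
#
# The interchange format is the per-second CSV track a BIS monitor exports:
# columns time_s, bis, sqi, bsr, sef, emg, rbr, sfs (sqi and sfs optional,
# unknown columns preserved). The pipeline mirrors the study design: case
# generation/ingestion, duration and signal-quality filters, a case-level
# 80/20 split, histogram boundary detection, tree discovery on balanced
# datasets, per-range RANSAC regressions, and validation.

track_mandatory <- c("time_s", "bis", "bsr", "sef", "emg", "rbr")

#' Read / write a per-second subparameter track
#'
#' @param path CSV path. The header must contain `time_s`, `bis`, `bsr`,
#'   `sef`, `emg`, `rbr` (case-insensitive); `sqi` and `sfs` are optional
#'   and unknown columns are preserved as-is.
#' @return `read_track` returns a data.frame with lower-case known column
#'   names; `write_track` returns `path` invisibly.
#' @export
read_track <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  known <- c(track_mandatory, "sqi", "sfs")
  lower <- tolower(names(df))
  names(df)[lower %in% known] <- lower[lower %in% known]
  missing <- setdiff(track_mandatory, names(df))
  if (length(missing)) {
    abort_bisre(paste0("track is missing mandatory column(s): ",
                       paste(missing, collapse = ", ")),
                "bisre_schema_error")
  }
  for (cc in intersect(known, names(df))) {
    if (!is.numeric(df[[cc]])) {
      num <- suppressWarnings(as.numeric(df[[cc]]))
      bad <- which(is.na(num) & !is.na(df[[cc]]))
      if (length(bad)) {
        abort_bisre(sprintf("non-numeric value in column '%s' at row %d: %s",
                            cc, bad[1], df[[cc]][bad[1]]),
                    "bisre_parse_error")
      }
      df[[cc]] <- num
    }
  }
  df
}

#' @rdname read_track
#' @param samples data.frame of per-second samples.
#' @export
write_track <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE)
  invisible(path)
}

#' Keep only samples with adequate signal quality
#'
#' @param samples data.frame; if it has an `sqi` column, rows with
#'   `sqi > threshold` are kept (strictly greater); without the column the
#'   input is returned unchanged.
#' @param threshold SQI threshold in percent (default 90).
#' @return the filtered data.frame.
#' @export
filter_sqi <- function(samples, threshold = 90) {
  if (!"sqi" %in% names(samples)) return(samples)
  samples[samples$sqi > threshold, , drop = FALSE]
}

#' Keep only cases with sufficiently long recordings
#'
#' @param cases list of `bis_synthetic_case` objects or per-second sample
#'   data.frames.
#' @param min_duration_s minimum recording duration; cases strictly longer
#'   are kept (default 30 minutes).
#' @return the retained sublist, with attribute `"n_dropped"`.
#' @export
filter_cases <- function(cases, min_duration_s = 1800) {
  dur <- vapply(cases, function(cs) {
    if (inherits(cs, "bis_synthetic_case")) nrow(cs$samples) else nrow(cs)
  }, numeric(1))
  keep <- dur > min_duration_s
  out <- cases[keep]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Pipeline configuration
#'
#' @param n_cases number of synthetic cases to generate (ignored when
#'   `cases` is supplied).
#' @param cases optional pre-built list of cases (bypasses generation).
#' @param case_template [case_spec()] template for generation.
#' @param generator_model [bis_model()] used by the generator.
#' @param seed master seed driving every stage.
#' @param sqi_threshold keep samples with SQI strictly above this value.
#' @param min_duration_s keep cases strictly longer than this.
#' @param train_fraction case-level fraction assigned to training.
#' @param boundaries interior BIS boundaries used for range labelling;
#'   `NULL` means use the detected boundaries united with the known 21.
#' @param fit_tree,fit_regressions disable a stage by setting it `FALSE`;
#'   with both disabled the supplied `published_model` is validated as-is.
#' @param published_model model used when fitting stages are disabled.
#' @param tree_config [tree_fit_config()] for the discovery stage.
#' @param ransac [ransac_config()] for the regression stage.
#' @param balanced_total balanced-dataset size per tree fit and for the
#'   balanced test dataset.
#' @param out_dir optional directory for artifacts (model.json,
#'   coefficients.csv, boundaries.csv, validation.json, heatmap.csv,
#'   log.txt).
#' @return object of class `bis_pipeline_config`.
#' @export
pipeline_config <- function(n_cases = 40,
                            cases = NULL,
                            case_template = case_spec(),
                            generator_model = default_bis_model(),
                            seed = 1L,
                            sqi_threshold = 90,
                            min_duration_s = 1800,
                            train_fraction = 0.8,
                            boundaries = c(21, 41, 61, 78),
                            fit_tree = TRUE,
                            fit_regressions = TRUE,
                            published_model = default_bis_model(),
                            tree_config = tree_fit_config(),
                            ransac = ransac_config(),
                            balanced_total = 100000,
                            out_dir = NULL) {
  check_number(n_cases, "n_cases", 1)
  check_number(sqi_threshold, "sqi_threshold", 0, 100)
  check_number(min_duration_s, "min_duration_s", 0)
  check_number(train_fraction, "train_fraction", 1e-9, 1 - 1e-9)
  structure(as.list(environment()), class = "bis_pipeline_config")
}

#' Run the discovery pipeline end to end
#'
#' Stages, in order: case generation (or ingestion), duration filter,
#' case-level train/test split, SQI filter, histogram boundary detection,
#' balanced sampling + tree ensemble + bagging, per-range RANSAC
#' regressions, and validation (classifier metrics on a balanced test
#' dataset, regression errors on the full test pool). Every stage's seed is
#' derived from the master seed, so a rerun with the same configuration is
#' byte-identical. A stage failure aborts with the stage name; artifacts
#' produced so far are kept if `out_dir` is set.
#'
#' @param config a [pipeline_config()].
#' @return list with `model`, `tree_spec`, `boundaries` (used for
#'   labelling), `detected_boundaries`, `classifier_report`,
#'   `regression_errors`, `log` (character vector of stage messages), and
#'   counts of cases and samples.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  out <- new.env(parent = emptyenv())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(config$out_dir)) {
        dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
        writeLines(c(log_lines, paste0("FAILED at stage: ", name)),
                   file.path(config$out_dir, "log.txt"))
      }
      abort_bisre(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e)),
                  "bisre_pipeline_error", stage = name)
    })
  }

  cases <- stage("generate", {
    if (!is.null(config$cases)) config$cases
    else generate_dataset(config$n_cases, config$case_template,
                          config$generator_model,
                          seed = derive_seed(config$seed, 1))
  })
  note("generated/ingested %d cases (seed %d)", length(cases), config$seed)

  cases <- stage("filter_cases", filter_cases(cases, config$min_duration_s))
  note("duration filter: kept %d cases, dropped %d", length(cases),
       attr(cases, "n_dropped"))
  if (!length(cases)) {
    stage("filter_cases", stop("no cases left after the duration filter"))
  }

  split <- stage("split", with_seed(derive_seed(config$seed, 2), {
    n <- length(cases)
    train_ids <- sort(sample.int(n, max(1, round(config$train_fraction * n))))
    list(train = train_ids, test = setdiff(seq_len(n), train_ids))
  }))
  note("case split: %d train / %d test", length(split$train),
       length(split$test))

  pool_of <- function(ids) {
    pool <- pool_samples(cases[ids])
    n0 <- nrow(pool)
    pool <- filter_sqi(pool, config$sqi_threshold)
    note("SQI filter: kept %d of %d samples", nrow(pool), n0)
    pool
  }
  train_pool <- stage("pool_train", pool_of(split$train))

  detected <- stage("boundaries", {
    h <- build_histogram(train_pool$bis)
    detect_boundaries(h)
  })
  note("detected histogram boundaries: %s",
       paste(detected, collapse = ", "))
  boundaries <- config$boundaries %||% finalize_boundaries(detected)
  note("labelling boundaries in use: %s", paste(boundaries, collapse = ", "))

  tree_spec <- config$published_model$tree
  discovery <- NULL
  if (isTRUE(config$fit_tree)) {
    discovery <- stage("fit_tree", {
      cfg <- config$tree_config
      cfg$seed <- derive_seed(config$seed, 3)
      discover_tree(train_pool, cfg, total = config$balanced_total,
                    boundaries = boundaries)
    })
    tree_spec <- discovery$tree_spec
    note("tree discovery: modal structure supported by %d/%d trees",
         attr(discovery$bagged, "n_modal"), config$tree_config$n_trees)
  }

  model <- config$published_model
  if (isTRUE(config$fit_regressions)) {
    model <- stage("fit_regressions", {
      cfg <- config$ransac
      cfg$seed <- derive_seed(config$seed, 4)
      fit_range_models(train_pool, tree_spec, cfg)$model
    })
    note("fitted per-range regressions by RANSAC (%d/%d/%g)",
         config$ransac$sample_size, config$ransac$n_iterations,
         config$ransac$inlier_margin)
  } else if (isTRUE(config$fit_tree)) {
    model <- bis_model(tree_spec, config$published_model$regressions)
  }

  validation <- stage("validate", {
    if (length(split$test)) {
      test_pool <- pool_of(split$test)
      bal <- balanced_sample(label_samples(test_pool, boundaries),
                             total = min(config$balanced_total,
                                         max(nrow(test_pool), 99)),
                             seed = derive_seed(config$seed, 5))
      list(classifier = validate_classifier(model, bal,
             truth = bis_range_of(round(bal$bis), boundaries)),
           errors = error_summary(test_pool$bis,
                                  predict_bis(test_pool, model)$bis))
    } else {
      note("no test cases; skipping validation")
      NULL
    }
  })

  if (!is.null(config$out_dir)) {
    stage("write_artifacts", {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      write_bis_model(model, file.path(config$out_dir, "model.json"))
      write_coefficients(model, file.path(config$out_dir, "coefficients.csv"))
      utils::write.csv(data.frame(boundary = boundaries),
                       file.path(config$out_dir, "boundaries.csv"),
                       row.names = FALSE)
      if (!is.null(validation)) {
        write_validation_report(validation$classifier,
                                file.path(config$out_dir, "validation.json"),
                                file.path(config$out_dir, "heatmap.csv"))
      }
      writeLines(log_lines, file.path(config$out_dir, "log.txt"))
    })
  }

  list(model = model, tree_spec = tree_spec,
       boundaries = boundaries, detected_boundaries = detected,
       discovery = discovery,
       classifier_report = validation$classifier,
       regression_errors = validation$errors,
       n_cases = length(cases), n_train_samples = nrow(train_pool),
       log = log_lines)
}
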