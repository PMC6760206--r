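# Discovery of the range-classifying decision tree.
#
# Ten CART fits on freshly drawn balanced datasets, a majority vote on the
# threshold-independent tree structure, per-node median thresholds across
# the trees sharing the modal structure, and a final consolidation of the
# univariate tree into the published compound-node template:
#
#   BSR / (EMG AND SEF) / (BSR OR SEF) / RBR.
#
# A single CART split is univariate, so the compound second and third nodes
# can only arise from consecutive univariate splits whose off-branches lead
# to the same range outcomes; `to_treespec()` performs that reduction and
# fails loudly (keeping the raw tree) when the learned structure does not
# reduce to the template.
#
# Raw trees are stored in canonical form: every split node has a `lo` child
# (feature < threshold) and a `hi` child (feature >= threshold), which makes
# the structure signature independent of rpart's internal split direction.

#' Configuration of the tree-fitting ensemble
#'
#' @param n_trees number of CART fits, each on a fresh balanced dataset.
#' @param max_depth maximum number of split levels.
#' @param min_node_fraction a node holding less than this fraction of the
#'   training samples is not split further (the stopping rule is on the node
#'   being considered for splitting).
#' @param split_criterion `"information"` (entropy gain, default) or
#'   `"gini"`.
#' @param cp complexity floor passed to the CART fit: a split must improve
#'   the overall impurity by this relative amount, which suppresses
#'   noise-chasing splits inside otherwise pure template leaves.
#' @param features classifier inputs; SFS is excluded by default, matching
#'   the final published model, and can be re-admitted for exploration.
#' @param seed master seed; per-tree sampling seeds are derived from it.
#' @return object of class `bis_tree_fit_config`.
#' @export
tree_fit_config <- function(n_trees = 10, max_depth = 5,
                            min_node_fraction = 0.10,
                            split_criterion = c("information", "gini"),
                            cp = 0.01,
                            features = c("bsr", "sef", "rbr", "emg"),
                            seed = 1L) {
  check_number(n_trees, "n_trees", 1)
  check_number(max_depth, "max_depth", 1)
  check_number(min_node_fraction, "min_node_fraction", 1e-12, 1 - 1e-12)
  check_number(cp, "cp", 0, 1)
  structure(list(n_trees = as.integer(n_trees),
                 max_depth = as.integer(max_depth),
                 min_node_fraction = min_node_fraction,
                 split_criterion = match.arg(split_criterion),
                 cp = cp, features = features, seed = as.integer(seed)),
            class = "bis_tree_fit_config")
}

#' Attach integer BIS and range labels to a sample pool
#'
#' @param pool data.frame with a `bis` column.
#' @param boundaries interior range boundaries (default `c(21, 41, 61, 78)`).
#' @return `pool` with added `bis_int` (rounded BIS) and `range_label`
#'   (factor) columns.
#' @export
label_samples <- function(pool, boundaries = c(21, 41, 61, 78)) {
  if (!"bis" %in% names(pool)) {
    abort_bisre("pool has no 'bis' column", "bisre_argument_error")
  }
  pool$bis_int <- round(pool$bis)
  pool$range_label <- bis_range_of(pool$bis_int, boundaries)
  pool
}

is_leaf <- function(node) identical(node$type, "leaf")

raw_leaf <- function(label, n = 0L) {
  list(type = "leaf", label = as.character(label), n = n)
}

raw_split <- function(feature, threshold, lo, hi, n = 0L) {
  list(type = "split", feature = feature, threshold = threshold,
       lo = lo, hi = hi, n = n)
}

#' Fit a single CART range classifier
#'
#' Greedy binary splitting maximising the configured impurity gain, with
#' the depth and minimum-node-size stopping rules. Single-class data yields
#' a single leaf rather than an error.
#'
#' @param data data.frame with the feature columns of `config$features` and
#'   a `range_label` factor (see [label_samples()]).
#' @param config a [tree_fit_config()].
#' @return object of class `bis_raw_tree` (nested `lo`/`hi` split nodes with
#'   range-labelled leaves).
#' @export
fit_cart <- function(data, config = tree_fit_config()) {
  miss <- setdiff(c(config$features, "range_label"), names(data))
  if (length(miss)) {
    abort_bisre(paste0("data missing column(s): ", paste(miss, collapse = ", ")),
                "bisre_argument_error")
  }
  labs <- droplevels(factor(data$range_label))
  if (nlevels(labs) < 2) {
    return(structure(raw_leaf(levels(labs)[1], nrow(data)),
                     class = "bis_raw_tree"))
  }
  n <- nrow(data)
  ctrl <- rpart::rpart.control(
    minsplit = max(2, ceiling(config$min_node_fraction * n)),
    minbucket = 1, cp = config$cp, maxdepth = config$max_depth,
    maxcompete = 0, maxsurrogate = 0, usesurrogate = 0, xval = 0
  )
  fml <- stats::as.formula(paste("range_label ~",
                                 paste(config$features, collapse = " + ")))
  fit <- rpart::rpart(fml, data = data, method = "class",
                      parms = list(split = config$split_criterion),
                      control = ctrl)
  rpart_to_raw(fit)
}

# Convert an rpart object (fitted with maxcompete = maxsurrogate = 0) to the
# canonical lo/hi raw-tree form.
rpart_to_raw <- function(fit) {
  frame <- fit$frame
  node_ids <- as.integer(rownames(frame))
  ylevels <- attr(fit, "ylevels")
  internal <- which(frame$var != "<leaf>")
  split_row <- integer(nrow(frame))
  split_row[internal] <- seq_along(internal)
  build <- function(id) {
    row <- match(id, node_ids)
    if (frame$var[row] == "<leaf>") {
      return(raw_leaf(ylevels[frame$yval[row]], frame$n[row]))
    }
    s <- fit$splits[split_row[row], , drop = FALSE]
    left <- build(2L * id)
    right <- build(2L * id + 1L)
    if (s[, "ncat"] < 0) {          # left child takes x < threshold
      lo <- left; hi <- right
    } else {                        # left child takes x >= threshold
      lo <- right; hi <- left
    }
    raw_split(as.character(frame$var[row]), unname(s[, "index"]),
              lo, hi, frame$n[row])
  }
  structure(build(1L), class = "bis_raw_tree")
}

#' Threshold-independent structure signature of a raw tree
#'
#' Preorder encoding of split features and leaf labels; two trees with the
#' same splits and leaf labels share a signature regardless of their
#' threshold values.
#'
#' @param tree a `bis_raw_tree`.
#' @return single character string.
#' @export
tree_signature <- function(tree) {
  walk <- function(node) {
    if (is_leaf(node)) return(paste0("[", node$label, "]"))
    paste0("(", node$feature, " ", walk(node$lo), " ", walk(node$hi), ")")
  }
  walk(tree)
}

#' Depth (number of split levels) of a raw tree
#'
#' @param tree a `bis_raw_tree`.
#' @return integer depth; a single leaf has depth 0.
#' @export
tree_depth <- function(tree) {
  if (is_leaf(tree)) return(0L)
  1L + max(tree_depth(tree$lo), tree_depth(tree$hi))
}

# All thresholds of a raw tree in preorder.
tree_thresholds <- function(tree) {
  if (is_leaf(tree)) return(numeric(0))
  c(tree$threshold, tree_thresholds(tree$lo), tree_thresholds(tree$hi))
}

#' Consolidate an ensemble of raw trees by structure vote
#'
#' Selects the modal structure signature by majority vote (ties resolved to
#' the first-occurring signature, recorded in the `"vote"` attribute) and
#' sets every node threshold to the median of the corresponding thresholds
#' across the trees sharing the modal structure.
#'
#' @param trees list of `bis_raw_tree` objects.
#' @return consolidated `bis_raw_tree` with attributes `"vote"` (table of
#'   signature counts) and `"n_modal"` (number of trees merged).
#' @export
bag_trees <- function(trees) {
  if (!length(trees)) abort_bisre("no trees to bag", "bisre_argument_error")
  sigs <- vapply(trees, tree_signature, character(1))
  counts <- table(factor(sigs, levels = unique(sigs)))  # first-occurrence tiebreak
  modal_sig <- names(counts)[which.max(counts)]
  modal <- trees[sigs == modal_sig]
  merge_nodes <- function(nodes) {
    if (is_leaf(nodes[[1]])) {
      return(raw_leaf(nodes[[1]]$label,
                      stats::median(vapply(nodes, function(x) x$n, numeric(1)))))
    }
    raw_split(
      nodes[[1]]$feature,
      stats::median(vapply(nodes, function(x) x$threshold, numeric(1))),
      merge_nodes(lapply(nodes, `[[`, "lo")),
      merge_nodes(lapply(nodes, `[[`, "hi")),
      stats::median(vapply(nodes, function(x) x$n, numeric(1)))
    )
  }
  out <- structure(merge_nodes(modal), class = "bis_raw_tree")
  attr(out, "vote") <- counts
  attr(out, "n_modal") <- length(modal)
  out
}

#' Reduce a univariate raw tree to the compound-node tree specification
#'
#' Matches the learned tree against the published template: a BSR root
#' splitting off the isoelectric leaf; a chain of one EMG and one SEF guard
#' (either order) whose high sides lead to sedation/awake outcomes (an RBR
#' split or, where the stopping rules prevented further splitting, a single
#' leaf); and a lower pair of BSR / SEF splits (either order) peeling off
#' the profound-anaesthesia leaves before the adequate-anaesthesia leaf.
#' The EMG and SEF guards merge into the compound AND condition of the
#' second node, and the lower BSR / SEF pair into the OR condition of the
#' third. When both guard branches carry an RBR split, the fourth-node
#' threshold is their median.
#'
#' @param tree a `bis_raw_tree` whose leaves carry the five range labels.
#' @return a [bis_tree_spec()].
#' @export
to_treespec <- function(tree) {
  fail <- function(msg) {
    abort_bisre(paste0("tree does not reduce to the published template: ",
                       msg), "bisre_structural_mismatch", tree = tree)
  }
  leaf_labelled <- function(node, label) {
    is_leaf(node) && identical(node$label, label)
  }
  # high-side outcome of a guard: an RBR split over 61-78 / 78-98, or a
  # single leaf in one of those ranges; returns the RBR threshold(s).
  parse_upper <- function(node) {
    if (is_leaf(node)) {
      if (!node$label %in% c("61-78", "78-98")) {
        fail(sprintf("guard high side is a '%s' leaf", node$label))
      }
      return(numeric(0))
    }
    if (node$feature != "rbr") fail("guard high side does not split on RBR")
    if (!leaf_labelled(node$lo, "61-78") || !leaf_labelled(node$hi, "78-98")) {
      fail("RBR split does not separate 61-78 from 78-98")
    }
    node$threshold
  }
  if (is_leaf(tree) || tree$feature != "bsr") fail("root is not a BSR split")
  if (!leaf_labelled(tree$hi, "0-21")) {
    fail("high-BSR side of the root is not the 0-21 leaf")
  }
  bsr_thr <- tree$threshold
  emg_thr <- NULL; sef_hi <- NULL; rbr_thrs <- numeric(0)
  node <- tree$lo
  for (step in 1:2) {
    if (is_leaf(node)) fail("guard chain ends early in a leaf")
    if (node$feature == "emg") {
      if (!is.null(emg_thr)) fail("two EMG guards")
      emg_thr <- node$threshold
    } else if (node$feature == "sef") {
      if (!is.null(sef_hi)) fail("two SEF guards")
      sef_hi <- node$threshold
    } else {
      fail(sprintf("unexpected '%s' split in the guard chain", node$feature))
    }
    rbr_thrs <- c(rbr_thrs, parse_upper(node$hi))
    node <- node$lo
  }
  if (!length(rbr_thrs)) fail("no RBR split under either guard")
  bsr_low <- NULL; sef_lo <- NULL
  for (step in 1:2) {
    if (is_leaf(node)) fail("lower subtree ends early in a leaf")
    if (node$feature == "bsr") {
      if (!is.null(bsr_low)) fail("two lower BSR splits")
      if (!leaf_labelled(node$hi, "21-41")) {
        fail("high side of the lower BSR split is not a 21-41 leaf")
      }
      bsr_low <- node$threshold
      node <- node$lo
    } else if (node$feature == "sef") {
      if (!is.null(sef_lo)) fail("two lower SEF splits")
      if (!leaf_labelled(node$lo, "21-41")) {
        fail("low side of the lower SEF split is not a 21-41 leaf")
      }
      sef_lo <- node$threshold
      node <- node$hi
    } else {
      fail(sprintf("unexpected '%s' split in the lower subtree", node$feature))
    }
  }
  if (!leaf_labelled(node, "41-61")) {
    fail("lower subtree does not terminate in the 41-61 leaf")
  }
  bis_tree_spec(bsr_threshold = bsr_thr,
                emg_threshold = emg_thr,
                sef_threshold_hi = sef_hi,
                bsr_low_threshold = bsr_low,
                sef_threshold_lo = sef_lo,
                rbr_threshold = stats::median(rbr_thrs))
}

#' Expand a tree specification to its canonical univariate raw tree
#'
#' Inverse of [to_treespec()]: the compound second node becomes an EMG guard
#' followed by an SEF guard (each high side carrying a copy of the RBR
#' split), and the compound third node a BSR split followed by an SEF split.
#' `to_treespec(expand_treespec(spec))` reproduces `spec` exactly.
#'
#' @param spec a [bis_tree_spec()].
#' @return a `bis_raw_tree`.
#' @export
expand_treespec <- function(spec) {
  rbr_node <- function() raw_split("rbr", spec$rbr_threshold,
                                   raw_leaf("61-78"), raw_leaf("78-98"))
  lower <- raw_split(
    "bsr", spec$bsr_low_threshold,
    raw_split("sef", spec$sef_threshold_lo,
              raw_leaf("21-41"), raw_leaf("41-61")),
    raw_leaf("21-41")
  )
  structure(
    raw_split("bsr", spec$bsr_threshold,
              raw_split("emg", spec$emg_threshold,
                        raw_split("sef", spec$sef_threshold_hi,
                                  lower, rbr_node()),
                        rbr_node()),
              raw_leaf("0-21")),
    class = "bis_raw_tree"
  )
}

#' Run the full tree-discovery stage on a sample pool
#'
#' Labels the pool by BIS range, draws a fresh balanced dataset for each of
#' the ensemble's fits, fits the CART ensemble, consolidates by structure
#' vote with median thresholds, and reduces the result to the compound-node
#' tree specification.
#'
#' @param pool data.frame of subparameter samples with a `bis` column.
#' @param config a [tree_fit_config()].
#' @param total balanced-dataset size per fit (default 100000).
#' @param boundaries interior BIS range boundaries used for labelling.
#' @return list with `trees` (the raw ensemble), `bagged` (consolidated raw
#'   tree) and `tree_spec` (the reduced [bis_tree_spec()]).
#' @export
discover_tree <- function(pool, config = tree_fit_config(), total = 100000,
                          boundaries = c(21, 41, 61, 78)) {
  labelled <- label_samples(pool, boundaries)
  trees <- lapply(seq_len(config$n_trees), function(i) {
    samp <- balanced_sample(labelled, total = total,
                            seed = derive_seed(config$seed, i))
    fit_cart(samp, config)
  })
  bagged <- bag_trees(trees)
  list(trees = trees, bagged = bagged, tree_spec = to_treespec(bagged))
}
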