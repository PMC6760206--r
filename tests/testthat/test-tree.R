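# CART fitting, structure signatures, bagging and template consolidation.

test_that("a perfectly separable BSR cut is found inside the separating gap", {
  set.seed(1)
  n <- 800
  d <- data.frame(bsr = c(runif(n / 2, 60, 100), runif(n / 2, 0, 40)),
                  sef = runif(n, 8, 26), rbr = runif(n, -2, 1),
                  emg = runif(n, 25, 45))
  d$range_label <- factor(ifelse(d$bsr > 50, "0-21", "41-61"))
  tr <- fit_cart(d, tree_fit_config(min_node_fraction = 0.2))
  expect_equal(tr$feature, "bsr")
  expect_true(tr$threshold > 40 && tr$threshold < 60)
  expect_equal(tree_depth(tr), 1L)
  # independent exhaustive entropy search agrees on feature and cut region
  oracle <- entropy_split_oracle(d, c("bsr", "sef", "rbr", "emg"),
                                 d$range_label)
  expect_equal(oracle$feature, "bsr")
  expect_equal(oracle$cut, tr$threshold, tolerance = 1)
})

test_that("single-class data yields a single leaf", {
  d <- data.frame(bsr = runif(50), sef = 10, rbr = 0, emg = 30,
                  range_label = factor(rep("41-61", 50)))
  tr <- fit_cart(d, tree_fit_config())
  expect_true(identical(tr$type, "leaf"))
  expect_equal(tr$label, "41-61")
})

test_that("fitted trees respect depth and minimum-node stopping rules", {
  pool <- label_samples(quick_pool(20000, seed = 3, bis_noise = 2))
  cfg <- tree_fit_config(max_depth = 5, min_node_fraction = 0.10)
  tr <- fit_cart(pool, cfg)
  expect_lte(tree_depth(tr), 5L)
  min_split_n <- function(node) {
    if (identical(node$type, "leaf")) return(Inf)
    min(node$n, min_split_n(node$lo), min_split_n(node$hi))
  }
  expect_gte(min_split_n(tr), ceiling(0.10 * nrow(pool)))
})

test_that("signatures ignore thresholds but distinguish structures", {
  t1 <- expand_treespec(bis_tree_spec())
  t2 <- expand_treespec(bis_tree_spec(bsr_threshold = 48, emg_threshold = 35,
                                      sef_threshold_hi = 21,
                                      bsr_low_threshold = 3,
                                      sef_threshold_lo = 14,
                                      rbr_threshold = -0.5))
  expect_identical(tree_signature(t1), tree_signature(t2))
  t3 <- t1
  t3$feature <- "sef"
  expect_false(identical(tree_signature(t1), tree_signature(t3)))
})

test_that("bagging takes the modal structure with per-node median thresholds", {
  mk <- function(root_thr) {
    tr <- expand_treespec(bis_tree_spec(bsr_threshold = root_thr))
    tr
  }
  trees <- lapply(c(49.0, 49.4, 49.8, 50.2, 50.6), mk)
  bagged <- bag_trees(trees)
  expect_equal(bagged$threshold, 49.8)
  expect_equal(attr(bagged, "n_modal"), 5L)
  # thresholds stay inside the min-max envelope of the inputs
  thr <- sapply(trees, function(t) t$threshold)
  expect_true(bagged$threshold >= min(thr) && bagged$threshold <= max(thr))
  # 3-vs-2 structure vote
  other <- expand_treespec(bis_tree_spec())
  other$feature <- "sef"
  mixed <- c(trees[1:3], list(other, other))
  expect_equal(tree_signature(bag_trees(mixed)), tree_signature(trees[[1]]))
  # identical trees consolidate to themselves
  same <- bag_trees(list(mk(49.8), mk(49.8)))
  expect_equal(unlist(to_treespec(same)), unlist(bis_tree_spec()))
})

test_that("template expansion and consolidation are mutually inverse", {
  spec <- bis_tree_spec(bsr_threshold = 51, emg_threshold = 33,
                        sef_threshold_hi = 21, bsr_low_threshold = 2.5,
                        sef_threshold_lo = 15, rbr_threshold = -0.65)
  expect_equal(unlist(to_treespec(expand_treespec(spec))), unlist(spec))
})

test_that("non-template structures raise a structural mismatch with the tree", {
  stub <- structure(
    list(type = "split", feature = "bsr", threshold = 50,
         lo = list(type = "leaf", label = "21-41", n = 10),
         hi = list(type = "leaf", label = "0-21", n = 10), n = 20),
    class = "bis_raw_tree")
  err <- tryCatch(to_treespec(stub), bisre_structural_mismatch = function(e) e)
  expect_s3_class(err, "bisre_structural_mismatch")
  expect_identical(err$tree, stub)
})

test_that("the root split on balanced model-generated data is BSR", {
  hits <- vapply(1:3, function(ms) {
    pool <- filter_sqi(pool_samples(generate_dataset(
      15, case_spec(), seed = 900 + ms)))
    samp <- balanced_sample(label_samples(pool), 30000, seed = ms)
    tr <- fit_cart(samp, tree_fit_config())
    identical(tr$feature, "bsr")
  }, logical(1))
  expect_gte(mean(hits), 2 / 3)
})
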