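# A small planted-signal world used across these tests: 3 informative
# features (2-sigma class shift) + noise, split by target.
planted_world <- function(seed, n_per_class = 300, n_noise = 5,
                          n_informative = 3) {
  spec <- synthetic_spec(
    seed = seed,
    features = default_feature_spec(n_informative = n_informative,
                                    n_noise = n_noise, missing_rate = 0))
  labels_tr <- rep(c(0L, 1L), each = n_per_class)
  labels_va <- rep(c(0L, 1L), each = n_per_class)
  list(train = make_feature_table(labels_tr, spec, target_id = "TR"),
       train_labels = labels_tr,
       val = make_feature_table(labels_va, spec, target_id = "VA"),
       val_labels = labels_va)
}

test_that("training is deterministic and rejects degenerate labels", {
  w <- planted_world(71, n_per_class = 120)
  m1 <- train_forest(w$train, w$train_labels, hyperparameters(seed = 4))
  m2 <- train_forest(w$train, w$train_labels, hyperparameters(seed = 4))
  expect_identical(m1$importances, m2$importances)
  expect_identical(predict(m1, w$val)$score, predict(m2, w$val)$score)
  expect_equal(sum(m1$importances), 1, tolerance = 1e-8)
  expect_error(train_forest(w$train, rep(1L, nrow(w$train))),
               "degenerate-label")
})

test_that("planted signal is learned; permuted labels are not", {
  w <- planted_world(72, n_per_class = 400)
  m <- train_forest(w$train, w$train_labels)
  v <- metrics(confusion(w$val_labels, predict(m, w$val)$label))
  # 3 independent 2-sigma features: Bayes MCC ~ 0.92; forest gets close
  expect_gt(v$MCC, 0.8)

  # single informative feature: the simulation oracle puts held-out MCC
  # near the Bayes limit 2*pnorm(1)-1 ~ 0.68, clearly inside (0.5, 0.8)
  w1 <- planted_world(73, n_per_class = 400, n_informative = 1)
  m1 <- train_forest(w1$train, w1$train_labels)
  v1 <- metrics(confusion(w1$val_labels, predict(m1, w1$val)$label))
  expect_gt(v1$MCC, 0.5)
  expect_lt(v1$MCC, 0.8)

  # permutation null
  set.seed(72)
  mp <- train_forest(w$train, sample(w$train_labels))
  vp <- metrics(confusion(w$val_labels, predict(mp, w$val)$label))
  expect_lt(abs(vp$MCC), 0.1)
})

test_that("forward selection ranks informative features above noise", {
  w <- planted_world(74, n_per_class = 150, n_noise = 50)
  sel <- forward_select(w$train, w$train_labels, w$val, w$val_labels,
                        importance_threshold = 0.01)
  ranked <- names(sort(sel$importances, decreasing = TRUE))
  expect_setequal(ranked[1:3], sprintf("informative_%d", 1:3))
  expect_true(all(sprintf("informative_%d", 1:3) %in% sel$selected))
  expect_equal(nrow(sel$trace), length(sel$importances))
  expect_equal(sel$trace$feature, ranked)

  # threshold 0 keeps everything
  sel0 <- forward_select(w$train, w$train_labels, w$val, w$val_labels,
                         importance_threshold = 0)
  expect_length(sel0$selected, length(registry_names(w$train)))

  # impossible threshold falls back to top-1
  expect_warning(
    sel1 <- forward_select(w$train, w$train_labels, w$val, w$val_labels,
                           importance_threshold = 2),
    "top-1")
  expect_length(sel1$selected, 1L)
})

test_that("select_common_features intersects and falls back on disjoint sets", {
  expect_setequal(select_common_features(list(c("a", "b", "c"),
                                              c("b", "c", "d"))),
                  c("b", "c"))
  expect_setequal(select_common_features(list(c("a", "b"), c("a", "b"))),
                  c("a", "b"))
  expect_warning(u <- select_common_features(list(c("a"), c("b"))), "union")
  expect_setequal(u, c("a", "b"))
  # ordering by mean importance
  imp <- list(c(a = 0.1, b = 0.5), c(a = 0.2, b = 0.6))
  expect_equal(select_common_features(list(c("a", "b"), c("a", "b")), imp),
               c("b", "a"))
})

test_that("tune_forest optimizes coordinate-wise with the stated tie rule", {
  w <- planted_world(75, n_per_class = 120)
  # single-value grids return those values
  hp <- tune_forest(w$train, w$train_labels, w$val, w$val_labels,
                    grid = list(n_trees = 25, min_samples_split = 4,
                                class_weights = list(c(1, 1))))
  expect_equal(hp$n_trees, 25L)
  expect_equal(hp$min_samples_split, 4L)
  expect_equal(hp$class_weight_incorrect, 1)

  # tuned MCC is >= the default's on the grid that contains the default
  defaults <- hyperparameters()
  hp2 <- tune_forest(w$train, w$train_labels, w$val, w$val_labels,
                     grid = list(min_samples_split = c(2, 10, 50)),
                     defaults = defaults)
  trace <- attr(hp2, "tuning_trace")$min_samples_split
  best_mcc <- max(trace$mcc)
  default_mcc <- trace$mcc[trace$value == 10]
  expect_gte(best_mcc, default_mcc)
  expect_equal(trace$mcc[trace$value == hp2$min_samples_split], best_mcc)
})

test_that("prediction contracts and persistence round trip", {
  w <- planted_world(76, n_per_class = 100)
  m <- train_forest(w$train, w$train_labels)
  p <- predict(m, w$val)
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_identical(p$label, as.integer(p$score >= 0.5))

  # schema error on missing selected feature
  broken <- as.data.frame(w$val)
  broken$informative_1 <- NULL
  expect_error(predict(m, feature_table(broken)), "schema")

  path <- withr::local_tempfile(fileext = ".json")
  save_classifier(m, path)
  m2 <- load_classifier(path)
  expect_identical(predict(m2, w$val)$score, p$score)
  expect_equal(m2$importances, m$importances, tolerance = 1e-12)
})

test_that("raising the correct-class weight does not lower correct recall", {
  w <- planted_world(77, n_per_class = 200, n_informative = 1)
  rec <- vapply(c(0.05, 2), function(cw) {
    m <- train_forest(w$train, w$train_labels,
                      hyperparameters(class_weight_correct = cw, seed = 3))
    metrics(confusion(w$val_labels, predict(m, w$val)$label))$R_corr
  }, numeric(1))
  expect_gte(rec[2], rec[1] - 0.05)   # monotone within seed noise
})

test_that("rank_decoys orders by score with CONSRANK then id tie-breaks", {
  df <- data.frame(target_id = "T1", model_id = c("m1", "m2", "m3", "m4"),
                   CONSRANK_score = c(0.2, 0.9, 0.5, 0.9),
                   other = c(1, 1, 1, 1))
  ft <- feature_table(df)
  fake <- structure(list(
    forest = list(matrix(c(0, 0, 0, 0, 1, 1), 1, 6)),  # single-leaf tree
    selected_features = "other",
    importances = c(other = 1),
    normalization = list(mu = c(other = 0), sigma = c(other = 1),
                         features = "other"),
    hp = hyperparameters()), class = "trained_classifier")
  # all scores equal (single leaf): CONSRANK decides, then model id
  expect_equal(rank_decoys(fake, ft), c("m2", "m4", "m3", "m1"))
})

test_that("impurity and permutation views agree on the top feature", {
  w <- planted_world(78, n_per_class = 200, n_informative = 1, n_noise = 6)
  m <- train_forest(w$train, w$train_labels)
  expect_equal(names(which.max(m$importances)), "informative_1")
  # crude permutation check: shuffling the top feature hurts accuracy more
  # than shuffling a noise feature
  set.seed(78)
  drop_in_acc <- function(feat) {
    v <- as.data.frame(w$val)
    v[[feat]] <- sample(v[[feat]])
    mean(predict(m, feature_table(v))$label == w$val_labels)
  }
  base <- mean(predict(m, w$val)$label == w$val_labels)
  expect_gt(base - drop_in_acc("informative_1"),
            base - drop_in_acc("noise_1") + 0.02)
})
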