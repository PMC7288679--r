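test_that("dataset construction enforces labels, fingerprints, unique ids", {
  data <- separable_dataset(6L, 12L)
  expect_equal(levels(data$label), c("negative", "positive"))
  expect_equal(sum(data$label == "positive"), 6L)
  expect_equal(nrow(data), 18L)

  dup_pos <- add_fingerprints(tibble::tibble(compound_id = "X",
                                             smiles = "CC"))
  expect_error(build_dataset(dup_pos, dup_pos), "duplicate")
})

test_that("the split honours the fraction, the seed, and class guards", {
  data <- separable_dataset(6L, 14L) # 20 rows
  sp <- split_dataset(data, test_fraction = 0.3, seed = 9)
  expect_equal(nrow(sp$test), 6L)    # round(0.3 * 20)
  expect_equal(nrow(sp$train), 14L)
  expect_length(intersect(sp$train$compound_id, sp$test$compound_id), 0L)
  expect_setequal(c(sp$train$compound_id, sp$test$compound_id),
                  data$compound_id)

  sp2 <- split_dataset(data, test_fraction = 0.3, seed = 9)
  expect_identical(sp$test$compound_id, sp2$test$compound_id)
  sp3 <- split_dataset(data, test_fraction = 0.3, seed = 10)
  expect_false(identical(sp$test$compound_id, sp3$test$compound_id))

  # 10 rows, fraction 0.3 -> 3 test / 7 train
  small <- data[c(1:3, 7:13), ]
  sps <- split_dataset(small, 0.3, seed = 1)
  expect_equal(nrow(sps$test), 3L)
  expect_equal(nrow(sps$train), 7L)

  expect_warning(split_dataset(data, test_fraction = 0, seed = 1), "empty")
  single <- data[data$label == "negative", ]
  expect_error(split_dataset(single, 0.3, seed = 1), "single-class")
  expect_error(split_dataset(data[1:3, ], 0.3, seed = 1), "at least 4")
})

test_that("the forest separates a planted single-bit signal", {
  data <- separable_dataset()
  # the fixture really is separable: some bit is present in every positive
  # and no negative (checked pre-model, so failures implicate the forest)
  m <- fp_matrix(data$fp)
  pos <- data$label == "positive"
  perfect_bits <- which(colSums(m[pos, ]) == sum(pos) &
                          colSums(m[!pos, ]) == 0)
  expect_gt(length(perfect_bits), 0L)

  model <- train_forest(data, n_trees = 100L, seed = 4)
  train_scores <- predict_proba(model, data$fp)
  expect_true(all(train_scores[pos] > 0.9))
  expect_true(all(train_scores[!pos] < 0.5))
  acc <- mean((train_scores > 0.5) == pos)
  expect_equal(acc, 1.0)
})

test_that("training and prediction are deterministic and well-guarded", {
  data <- separable_dataset()
  m1 <- train_forest(data, n_trees = 50L, seed = 7)
  m2 <- train_forest(data, n_trees = 50L, seed = 7)
  expect_identical(predict_proba(m1, data$fp), predict_proba(m2, data$fp))

  one_tree <- train_forest(data, n_trees = 1L, seed = 7)
  s <- predict_proba(one_tree, data$fp)
  expect_true(all(s %in% c(0, 1)))

  expect_equal(predict_proba(m1, list()), numeric(0))
  expect_true(all(predict_proba(m1, data$fp) >= 0 &
                    predict_proba(m1, data$fp) <= 1))

  expect_error(train_forest(data[0, ], seed = 1), "empty")
  expect_error(train_forest(data[data$label == "positive", ], seed = 1),
               "single-class")
  fake <- structure(list(forest = NULL), class = "bioactivity_model")
  expect_error(predict_proba(fake, data$fp), "trained")
  expect_error(predict_proba(m1, list(logical(512))), "length")
})

test_that("metric identities hold on closed-form and random confusion counts", {
  m <- classification_metrics(tp = 1, fp = 1, fn = 1, tn = 0)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)

  m2 <- classification_metrics(tp = 8, fp = 2, fn = 4, tn = 86)
  expect_equal(m2$precision, 0.8)
  expect_equal(m2$recall, 8 / 12, tolerance = 1e-12)
  expect_equal(m2$f1, 2 * 0.8 * (8 / 12) / (0.8 + 8 / 12), tolerance = 1e-12)

  # degenerate denominators yield 0 by convention
  expect_equal(classification_metrics(0, 0, 5, 10)$precision, 0)
  expect_equal(classification_metrics(0, 3, 0, 10)$recall, 0)
  expect_equal(classification_metrics(0, 0, 0, 10)$f1, 0)

  set.seed(41)
  for (i in 1:200) {
    tp <- sample(0:30, 1); fp <- sample(0:30, 1)
    fn <- sample(0:30, 1); tn <- sample(0:30, 1)
    got <- classification_metrics(tp, fp, fn, tn)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    expect_equal(got$precision, p)
    expect_equal(got$recall, r)
    expect_equal(got$f1, f)
    expect_true(got$f1 >= 0 && got$f1 <= 1)
  }
})

test_that("held-out evaluation reproduces the confusion matrix at the threshold", {
  data <- separable_dataset()
  sp <- split_dataset(data, 0.3, seed = 2)
  model <- train_forest(sp$train, n_trees = 100L, seed = 3)
  met <- evaluate_model(model, sp$test)
  expect_equal(met$tp + met$fp + met$fn + met$tn, nrow(sp$test))
  # recompute independently from raw scores
  sc <- predict_proba(model, sp$test$fp)
  act <- sp$test$label == "positive"
  expect_equal(met$tp, sum(sc > 0.5 & act))
  expect_equal(met$fn, sum(sc <= 0.5 & act))
  # separable fixture: perfect held-out classification
  expect_equal(met$f1, 1.0)
  # identical pipeline reruns give identical metrics
  met2 <- evaluate_model(train_forest(split_dataset(data, 0.3, seed = 2)$train,
                                      n_trees = 100L, seed = 3),
                         split_dataset(data, 0.3, seed = 2)$test)
  expect_identical(tibble::as_tibble(met), tibble::as_tibble(met2))
})

test_that("a trivial always-negative classifier has F1 = 0 under imbalance", {
  expect_equal(classification_metrics(tp = 0, fp = 0, fn = 10, tn = 100)$f1,
               0)
})

test_that("the full-data refit still ranks motif carriers highly", {
  data <- separable_dataset()
  sp <- split_dataset(data, 0.3, seed = 2)
  eval_model <- train_forest(sp$train, n_trees = 100L, seed = 3)
  metrics_before <- evaluate_model(eval_model, sp$test)
  final <- retrain_full(data, n_trees = 100L, seed = 5)
  scores <- predict_proba(final, data$fp)
  expect_true(all(scores[data$label == "positive"] > 0.9))
  # metrics computed before the refit are untouched by it
  expect_identical(tibble::as_tibble(metrics_before),
                   tibble::as_tibble(evaluate_model(eval_model, sp$test)))
  expect_identical(predict_proba(retrain_full(data, 100L, seed = 5),
                                 data$fp),
                   scores)
})

test_that("label shuffling preserves counts but breaks the structure link", {
  data <- separable_dataset()
  shuffled <- shuffle_dataset_labels(data, seed = 8)
  expect_equal(table(shuffled$label), table(data$label))
  expect_identical(shuffled$fp, data$fp)
  expect_false(identical(shuffled$label, data$label))
  expect_identical(shuffle_dataset_labels(data, seed = 8)$label,
                   shuffled$label)
})

test_that("tidy and glance expose model structure and metrics", {
  data <- separable_dataset()
  model <- train_forest(data, n_trees = 25L, seed = 1)
  td <- generics::tidy(model)
  expect_true(all(c("bit", "importance") %in% names(td)))
  expect_equal(nrow(td), 1024L)
  expect_true(all(diff(td$importance) <= 0))

  gl <- generics::glance(model)
  expect_equal(gl$n_trees, 25L)
  expect_equal(gl$n_positive, 12L)

  met <- classification_metrics(3, 1, 2, 10)
  expect_equal(nrow(generics::tidy(met)), 7L)
  expect_equal(generics::glance(met)$n_test, 16L)
})
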