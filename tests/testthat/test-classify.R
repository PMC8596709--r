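test_that("the train/validation split is reproducible and sized correctly", {
  df <- gaussian_features(50, c("A", "B"))
  s1 <- split_train_validation(df, 0.7, seed = 42)
  s2 <- split_train_validation(df, 0.7, seed = 42)
  expect_equal(nrow(s1$train), 70)
  expect_equal(nrow(s1$validation), 30)
  expect_identical(s1$train$id, s2$train$id)
  expect_length(intersect(s1$train$id, s1$validation$id), 0)
  expect_warning(s3 <- split_train_validation(df, 1.0, seed = 1), "empty")
  expect_equal(nrow(s3$validation), 0)
  expect_error(split_train_validation(df[0, ]), "empty")
})

test_that("median imputation uses training medians only", {
  key1 <- feature_schema()$feature[1]
  key2 <- feature_schema()$feature[2]
  train <- tibble::tibble(species = "A", !!key1 := c(1, 2, NA, 3), !!key2 := c(1, 1, 1, 1))
  validation <- tibble::tibble(species = "A", !!key1 := c(NA, 9, 9, 9), !!key2 := c(NA, 2, 2, 2))
  out <- impute_median(train, validation)
  expect_equal(out$train[[key1]], c(1, 2, 2, 3))
  expect_equal(out$validation[[key1]][1], 2) # train median, not validation's 9
  expect_equal(out$validation[[key2]][1], 1)
  # no missing anywhere: identity
  clean <- impute_median(out$train, out$validation)
  expect_identical(clean$train, out$train)
  # entirely-missing training feature is dropped with a warning
  train2 <- train
  train2[[key2]] <- NA_real_
  expect_warning(out2 <- impute_median(train2, validation), "dropping")
  expect_false(key2 %in% names(out2$train))
})

test_that("every tree's bootstrap holds exactly the configured class counts", {
  df <- gaussian_features(c(60, 25, 40), c("A", "B", "C"), shift = 1)
  sizes <- c(A = 20L, B = 10L, C = 15L)
  model <- train_balanced_rf(df, class_sizes = sizes, n_trees = 60, seed = 3)
  counts <- inbag_class_counts(model)
  expect_equal(dim(counts), c(3L, 60L))
  for (cl in names(sizes)) {
    expect_true(all(counts[cl, ] == sizes[[cl]]))
  }
})

test_that("well-separated classes are nearly perfectly classified out of bag", {
  df <- gaussian_features(200, c("A", "B"), shift = 6) # d' > 6 per feature
  model <- train_balanced_rf(df,
    class_sizes = c(A = 50L, B = 50L),
    n_trees = 300, seed = 4
  )
  expect_lt(model$oob_error, 0.05)
})

test_that("permuted labels classify at chance", {
  df <- gaussian_features(120, c("A", "B", "C"), shift = 4)
  set.seed(5)
  df$species <- sample(df$species)
  model <- train_balanced_rf(df, n_trees = 400, seed = 5)
  expect_lt(abs(model$oob_error - 2 / 3), 0.05)
})

test_that("single-class and misconfigured training are refused", {
  df <- gaussian_features(30, "A")
  expect_error(train_balanced_rf(df), "2 classes")
  df2 <- gaussian_features(30, c("A", "B"))
  expect_error(
    train_balanced_rf(df2, class_sizes = c(A = 10L)),
    "missing classes"
  )
})

test_that("metrics match hand-computed confusion matrices", {
  df <- gaussian_features(40, c("A", "B"), shift = 8)
  model <- train_balanced_rf(df, n_trees = 200, seed = 6)
  # near-perfect separation: every class metric at its ideal value
  rep_perfect <- evaluate(model, df)
  expect_equal(rep_perfect$accuracy, 1)
  expect_true(all(rep_perfect$metrics$TPR == 1))
  expect_true(all(rep_perfect$metrics$TNR == 1))
  expect_true(all(rep_perfect$metrics$wAcc == 1))
  expect_true(all(rep_perfect$metrics$clErr == 0))
  # confusion rows sum to validation class counts
  expect_equal(
    as.numeric(rowSums(rep_perfect$confusion)[c("A", "B")]),
    as.numeric(table(df$species))
  )
  # probabilities: winning vote fractions sum with the rest to 1
  expect_equal(unname(rowSums(rep_perfect$votes)), rep(1, nrow(df)))
})

test_that("metric identities hold for an arbitrary confusion matrix", {
  confusion <- matrix(c(30, 5, 10, 55), 2, 2,
    dimnames = list(c("A", "B"), c("A", "B"))
  )
  m <- wingbeat:::confusion_metrics(confusion)
  # hand-computed from rows (A: 30 correct, 10 missed; B: 55 correct, 5 missed)
  expect_equal(m$TPR, c(30 / 40, 55 / 60))
  expect_equal(m$TNR, c(55 / 60, 30 / 40))
  expect_equal(m$wAcc, 0.5 * m$TNR + 0.5 * m$TPR)
  expect_equal(m$clErr, 1 - m$TPR)
})

test_that("a constant predictor earns wAcc one half", {
  # degenerate confusion: everything predicted as class A
  confusion <- matrix(c(20, 30, 0, 0), 2, 2,
    dimnames = list(c("A", "B"), c("A", "B"))
  )
  m <- wingbeat:::confusion_metrics(confusion)
  expect_equal(m$TPR[1], 1)
  expect_equal(m$TNR[1], 0)
  expect_equal(m$wAcc[1], 0.5)
})

test_that("importance ranks a decisive feature first by both measures", {
  set.seed(7)
  keys <- feature_schema()$feature
  df <- gaussian_features(100, c("A", "B"), shift = 0, n_informative = 0, n_noise = 6)
  decisive <- keys[10]
  df[[decisive]] <- ifelse(df$species == "A", 0, 4) + rnorm(nrow(df), 0, 0.1)
  model <- train_balanced_rf(df, n_trees = 300, seed = 7)
  imp <- importance_table(model)
  expect_equal(imp$feature[1], decisive)
  expect_equal(imp$feature[which.max(imp$gini)], decisive)
  # overall MDA is the unweighted mean of the per-class columns
  expect_equal(imp$mda_overall, rowMeans(cbind(imp$mda_A, imp$mda_B)))
  # pure-noise features have importance within permutation noise of zero
  raw <- randomForest::importance(model$fit, scale = FALSE)
  sds <- model$fit$importanceSD
  noise_keys <- setdiff(model$features, decisive)
  z <- raw[noise_keys, "MeanDecreaseAccuracy"] / pmax(sds[noise_keys, "MeanDecreaseAccuracy"], 1e-12)
  expect_true(all(abs(z) < 3.5))
})

test_that("out-of-bag and validation errors agree on large synthetic data", {
  df <- gaussian_features(500, c("A", "B"), shift = 1.5)
  parts <- split_train_validation(df, 0.7, seed = 8)
  model <- train_balanced_rf(parts$train, n_trees = 400, seed = 8)
  validation_error <- 1 - evaluate(model, parts$validation)$accuracy
  expect_lt(abs(model$oob_error - validation_error), 0.05)
})

test_that("a withheld clone class is allocated to its source class", {
  set.seed(9)
  df_ab <- gaussian_features(60, c("A", "B"), shift = 5)
  clone <- gaussian_features(40, "A", shift = 5, seed = 99)
  clone$species <- "C" # same distribution as A, new label
  df <- dplyr::bind_rows(df_ab, clone)
  loso <- leave_one_species_out(df, "C", n_trees = 300, seed = 9)
  expect_equal(sum(loso$allocation$proportion), 1)
  expect_gt(loso$allocation$proportion[loso$allocation$class == "A"], 0.8)
  expect_length(loso$max_class_probability, 40)
  expect_error(leave_one_species_out(df, "Z"), "not present")
})

test_that("misclassified observations carry lower classification certainty", {
  df <- gaussian_features(300, c("A", "B"), shift = 2, seed = 31)
  parts <- split_train_validation(df, 0.7, seed = 10)
  model <- train_balanced_rf(parts$train, n_trees = 400, seed = 10)
  rep <- evaluate(model, parts$validation)
  obs <- rep$observations
  expect_gt(
    stats::median(obs$max_class_probability[obs$correct]),
    stats::median(obs$max_class_probability[!obs$correct])
  )
})

test_that("sub-classification tasks relabel and refuse degenerate splits", {
  df <- dplyr::bind_rows(
    gaussian_features(40, c("A_fabae", "S_avenae"), shift = 3, seed = 21),
    gaussian_features(40, c("B_aeneus", "P_chrysocephala"), shift = 3, seed = 22)
  )
  order_task <- subtask_classify(df, "aphid-vs-beetle", n_trees = 150, seed = 11)
  expect_setequal(rownames(order_task$report$confusion), c("Hemiptera", "Coleoptera"))
  beetles <- subtask_classify(df, "within-beetles", n_trees = 150, seed = 11)
  expect_setequal(rownames(beetles$report$confusion), c("B_aeneus", "P_chrysocephala"))
  aphids_only <- df[df$species %in% c("A_fabae", "S_avenae"), ]
  expect_error(subtask_classify(aphids_only, "within-beetles"), "fewer than 2")
})
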