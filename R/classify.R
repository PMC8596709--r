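#' Tuned per-class bootstrap sizes for the study species
#'
#' The class-specific per-tree sample sizes tuned to balance class error
#' rates on the real corpus: one preset for feature tables where missing
#' values are imputed, one for tables restricted to complete observations.
#'
#' @param impute Use the with-imputation sizes (`TRUE`) or the
#'   complete-observation sizes (`FALSE`).
#' @return Named integer vector of per-tree bootstrap counts.
#' @export
class_size_preset <- function(impute = TRUE) {
  if (impute) {
    c(
      A_fabae = 75L, P_chrysocephala = 75L, S_avenae = 120L,
      P_testudinaceus = 50L, B_aeneus = 120L, D_platanoidis = 300L
    )
  } else {
    c(
      A_fabae = 60L, P_chrysocephala = 60L, S_avenae = 96L,
      P_testudinaceus = 40L, B_aeneus = 96L, D_platanoidis = 240L
    )
  }
}

feature_cols <- function(df) {
  intersect(feature_schema()$feature, names(df))
}

#' Split a feature table into training and validation sets
#'
#' Plain random allocation of recordings (no stratification), reproducible
#' under the seed.
#'
#' @param features Feature tibble (one row per recording).
#' @param fraction Training fraction.
#' @param seed Integer seed.
#' @return List with `train` and `validation` tibbles.
#' @export
split_train_validation <- function(features, fraction = 0.7, seed = 1) {
  if (nrow(features) == 0) stop("empty feature table", call. = FALSE)
  if (fraction >= 1) {
    warning("training fraction >= 1: validation set is empty", call. = FALSE)
  }
  set.seed(seed)
  n_train <- round(fraction * nrow(features))
  idx <- sample.int(nrow(features), min(n_train, nrow(features)))
  list(train = features[idx, ], validation = features[-idx, ])
}

#' Impute missing feature values by training-set medians
#'
#' Missing values in both the training and the validation table are replaced
#' by the per-feature median computed from the training data only, so no
#' information leaks from validation to training. Features entirely missing
#' in training are dropped from both tables with a warning.
#'
#' @param train,validation Feature tibbles (`validation` may be `NULL`).
#' @return List with `train`, `validation` and the named `medians` used.
#' @export
impute_median <- function(train, validation = NULL) {
  cols <- feature_cols(train)
  medians <- vapply(train[cols], function(v) stats::median(v, na.rm = TRUE), numeric(1))
  dead <- names(medians)[is.na(medians)]
  if (length(dead)) {
    warning(
      "dropping features entirely missing in training: ",
      paste(dead, collapse = ", "),
      call. = FALSE
    )
    train <- train[setdiff(names(train), dead)]
    if (!is.null(validation)) validation <- validation[setdiff(names(validation), dead)]
    medians <- medians[!is.na(medians)]
  }
  fill <- function(df) {
    for (f in names(medians)) {
      df[[f]][is.na(df[[f]])] <- medians[[f]]
    }
    df
  }
  list(train = fill(train), validation = if (!is.null(validation)) fill(validation), medians = medians)
}

#' Train a balanced random forest
#'
#' Grows a random forest in which every tree's bootstrap contains exactly a
#' configured number of observations per class, drawn with replacement —
#' the balanced-bootstrap counter to class imbalance. By default each class
#' is resampled at the smallest class count; the tuned study-species sizes
#' are available via [class_size_preset()].
#'
#' @param train Feature tibble with a `species` column.
#' @param class_sizes Named per-class per-tree bootstrap counts, or `NULL`
#'   for the smallest-class default.
#' @param n_trees Number of trees.
#' @param vars_per_split Variables tried at each split (capped at the number
#'   of features).
#' @param impute Impute missing values by training medians before fitting;
#'   when `FALSE`, rows with any missing feature are dropped.
#' @param seed Integer seed (mandatory: all stochastic results reproducible).
#' @return A `wb_brf` object wrapping the forest with its out-of-bag votes,
#'   error, confusion and the configuration used.
#' @export
train_balanced_rf <- function(train, class_sizes = NULL, n_trees = 1000,
                              vars_per_split = 10, impute = TRUE, seed = 1) {
  cols <- feature_cols(train)
  if (length(cols) == 0) stop("no schema features found in `train`", call. = FALSE)
  y <- factor(train$species)
  if (nlevels(y) < 2) stop("need at least 2 classes to classify", call. = FALSE)
  medians <- NULL
  if (impute) {
    imp <- impute_median(train)
    train <- imp$train
    medians <- imp$medians
    cols <- feature_cols(train)
  } else {
    keep <- stats::complete.cases(train[cols])
    train <- train[keep, ]
    y <- factor(train$species)
  }
  y <- factor(train$species)
  tab <- table(y)
  if (is.null(class_sizes)) {
    class_sizes <- stats::setNames(rep(min(tab), nlevels(y)), levels(y))
  }
  if (!all(levels(y) %in% names(class_sizes))) {
    stop(
      "class_sizes missing classes: ",
      paste(setdiff(levels(y), names(class_sizes)), collapse = ", "),
      call. = FALSE
    )
  }
  # with-replacement draws may exceed a class's n, so configured sizes are
  # honoured exactly (the in-bag audit depends on this)
  class_sizes <- stats::setNames(as.integer(class_sizes[levels(y)]), levels(y))
  if (any(class_sizes <= 0)) stop("class sample sizes must be positive", call. = FALSE)
  mtry <- min(vars_per_split, length(cols))
  set.seed(seed)
  fit <- randomForest::randomForest(
    x = as.data.frame(train[cols]), y = y,
    ntree = n_trees, mtry = mtry,
    sampsize = class_sizes, strata = y, replace = TRUE,
    importance = TRUE, keep.inbag = TRUE, norm.votes = TRUE
  )
  structure(
    list(
      fit = fit, features = cols, class_sizes = class_sizes,
      n_trees = n_trees, vars_per_split = mtry, impute = impute,
      medians = medians, seed = seed,
      oob_error = mean(fit$predicted != y),
      train_y = y
    ),
    class = "wb_brf"
  )
}

#' @export
print.wb_brf <- function(x, ...) {
  cat(sprintf(
    "<wb_brf> %d trees, mtry %d, %d features, %d classes; OOB error %.2f%%\n",
    x$n_trees, x$vars_per_split, length(x$features),
    nlevels(x$train_y), 100 * x$oob_error
  ))
  cat(
    "per-tree class sizes:",
    paste(names(x$class_sizes), x$class_sizes, sep = "=", collapse = ", "), "\n"
  )
  invisible(x)
}

#' Audit the balanced bootstrap
#'
#' Counts, for every tree, how many in-bag draws came from each class.
#' For a balanced forest every column equals the configured class sizes.
#'
#' @param model A `wb_brf`.
#' @return Matrix (class x tree) of in-bag draw counts.
#' @export
inbag_class_counts <- function(model) {
  stopifnot(inherits(model, "wb_brf"))
  ib <- model$fit$inbag
  t(vapply(
    levels(model$train_y),
    function(cl) colSums(ib[model$train_y == cl, , drop = FALSE]),
    numeric(ncol(ib))
  ))
}

# per-class one-vs-rest metrics from a (true x predicted) confusion matrix
confusion_metrics <- function(confusion) {
  classes <- rownames(confusion)
  total <- sum(confusion)
  purrr::map_dfr(classes, function(cl) {
    tp <- confusion[cl, cl]
    fn <- sum(confusion[cl, ]) - tp
    fp <- sum(confusion[, cl]) - tp
    tn <- total - tp - fn - fp
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    tnr <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    tibble::tibble(
      class = cl, n = tp + fn,
      TPR = tpr, TNR = tnr,
      wAcc = 0.5 * tnr + 0.5 * tpr, clErr = 1 - tpr
    )
  })
}

#' Evaluate a classifier on a validation set
#'
#' Predicts the validation observations (imputing missing features with the
#' training medians when the model was trained with imputation), and reports
#' the confusion matrix, per-class one-vs-rest TPR / TNR, weighted accuracy
#' `wAcc = 0.5 TNR + 0.5 TPR`, class error `clErr = 1 - TPR`, overall
#' accuracy, and each observation's class-probability profile (fraction of
#' trees voting for each class).
#'
#' @param model A `wb_brf`.
#' @param validation Feature tibble with a `species` column.
#' @return A `wb_report` object: `confusion`, `metrics` (tibble),
#'   `accuracy`, `observations` (id, truth, prediction, correct,
#'   max_class_probability), `votes` matrix.
#' @export
evaluate <- function(model, validation) {
  stopifnot(inherits(model, "wb_brf"))
  if (nrow(validation) == 0) stop("empty validation set", call. = FALSE)
  v <- validation
  if (model$impute && !is.null(model$medians)) {
    for (f in intersect(names(model$medians), names(v))) {
      v[[f]][is.na(v[[f]])] <- model$medians[[f]]
    }
  }
  votes <- stats::predict(model$fit, as.data.frame(v[model$features]), type = "prob")
  pred <- factor(colnames(votes)[max.col(votes, ties.method = "first")],
    levels = colnames(votes)
  )
  truth_chr <- as.character(v$species)
  unknown <- setdiff(unique(truth_chr), colnames(votes))
  if (length(unknown)) {
    warning(
      "classes absent from the model are counted as always wrong: ",
      paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  truth <- factor(truth_chr, levels = union(colnames(votes), unknown))
  confusion <- table(
    truth = truth,
    predicted = factor(pred, levels = levels(truth))
  )
  obs <- tibble::tibble(
    id = if ("id" %in% names(v)) v$id else as.character(seq_len(nrow(v))),
    truth = truth_chr,
    prediction = as.character(pred),
    correct = truth_chr == as.character(pred),
    max_class_probability = apply(votes, 1, max)
  )
  structure(
    list(
      confusion = unclass(confusion),
      metrics = confusion_metrics(unclass(confusion)),
      accuracy = mean(obs$correct),
      observations = obs,
      votes = votes
    ),
    class = "wb_report"
  )
}

#' @export
print.wb_report <- function(x, ...) {
  cat(sprintf("<wb_report> overall accuracy %.1f%% (n = %d)\n", 100 * x$accuracy, nrow(x$observations)))
  print(x$metrics)
  invisible(x)
}

#' Out-of-bag classification report
#'
#' The same report as [evaluate()], computed from the out-of-bag
#' predictions of the training data.
#'
#' @param model A `wb_brf`.
#' @return A `wb_report`.
#' @export
oob_report <- function(model) {
  stopifnot(inherits(model, "wb_brf"))
  votes <- model$fit$votes
  pred <- model$fit$predicted
  truth <- model$train_y
  confusion <- table(truth = truth, predicted = pred)
  obs <- tibble::tibble(
    id = as.character(seq_along(truth)),
    truth = as.character(truth),
    prediction = as.character(pred),
    correct = truth == pred,
    max_class_probability = apply(votes, 1, max)
  )
  structure(
    list(
      confusion = unclass(confusion),
      metrics = confusion_metrics(unclass(confusion)),
      accuracy = mean(obs$correct),
      observations = obs,
      votes = votes
    ),
    class = "wb_report"
  )
}

#' Feature importance
#'
#' Permutation importance (mean decrease in accuracy, overall and per class)
#' and mean decrease in Gini impurity. The overall mean decrease in accuracy
#' is the unweighted mean of the per-class values.
#'
#' @param model A `wb_brf`.
#' @param scale Divide raw importances by their permutation SE (passed to
#'   `randomForest::importance`).
#' @return A `wb_importance` tibble: `feature`, one `mda_<class>` column per
#'   class, `mda_overall`, `gini`, sorted by `mda_overall` descending.
#' @export
importance_table <- function(model, scale = FALSE) {
  stopifnot(inherits(model, "wb_brf"))
  imp <- randomForest::importance(model$fit, scale = scale)
  classes <- levels(model$train_y)
  per_class <- imp[, classes, drop = FALSE]
  out <- tibble::as_tibble(per_class, .name_repair = ~ paste0("mda_", .x))
  out <- dplyr::bind_cols(tibble::tibble(feature = rownames(imp)), out)
  out$mda_overall <- unname(rowMeans(per_class))
  out$gini <- imp[, "MeanDecreaseGini"]
  out <- dplyr::arrange(out, dplyr::desc(.data$mda_overall))
  class(out) <- c("wb_importance", class(out))
  out
}

#' Leave-one-species-out open-set evaluation
#'
#' Retrains the forest with every observation of one species withheld, then
#' predicts the withheld observations, characterizing how an unknown species
#' is absorbed into the known classes: the proportion allocated to each
#' remaining class and the distribution of the maximal class probability.
#'
#' @param features Labelled feature tibble.
#' @param excluded Species to withhold.
#' @param ... Passed to [train_balanced_rf()] (class sizes, trees, seed...).
#' @return A `wb_loso` object: `excluded`, `allocation` (tibble class /
#'   proportion), `max_class_probability` (numeric per withheld
#'   observation), `model`.
#' @export
leave_one_species_out <- function(features, excluded, ...) {
  if (!excluded %in% features$species) {
    stop("species not present: ", excluded, call. = FALSE)
  }
  train <- features[features$species != excluded, ]
  held <- features[features$species == excluded, ]
  model <- train_balanced_rf(train, ...)
  if (model$impute && !is.null(model$medians)) {
    for (f in intersect(names(model$medians), names(held))) {
      held[[f]][is.na(held[[f]])] <- model$medians[[f]]
    }
  }
  votes <- stats::predict(model$fit, as.data.frame(held[model$features]), type = "prob")
  pred <- colnames(votes)[max.col(votes, ties.method = "first")]
  allocation <- tibble::tibble(class = colnames(votes)) |>
    dplyr::mutate(proportion = vapply(
      .data$class,
      function(cl) mean(pred == cl), numeric(1)
    ))
  structure(
    list(
      excluded = excluded, allocation = allocation,
      max_class_probability = apply(votes, 1, max),
      n_held_out = nrow(held), model = model
    ),
    class = "wb_loso"
  )
}

#' @export
print.wb_loso <- function(x, ...) {
  cat(sprintf(
    "<wb_loso> excluded %s (%d observations); allocation:\n",
    x$excluded, x$n_held_out
  ))
  print(x$allocation)
  invisible(x)
}

#' Sub-classification tasks
#'
#' Re-labels the feature table for one of the study's classification tasks —
#' all species, aphids (Hemiptera) vs beetles (Coleoptera), within-aphid
#' species, or within-beetle species — draws a fresh 70:30 split, trains a
#' balanced forest and evaluates it.
#'
#' @param features Labelled feature tibble.
#' @param task One of `"all-species"`, `"aphid-vs-beetle"`,
#'   `"within-aphids"`, `"within-beetles"`.
#' @param order_map Named character vector mapping species to insect order;
#'   defaults to the study-species mapping from [species_presets()].
#' @param fraction,seed Split parameters.
#' @param ... Passed to [train_balanced_rf()].
#' @return List with `task`, `model`, `report` (validation [evaluate()]
#'   report) and `importance`.
#' @export
subtask_classify <- function(features,
                             task = c(
                               "all-species", "aphid-vs-beetle",
                               "within-aphids", "within-beetles"
                             ),
                             order_map = NULL, fraction = 0.7, seed = 1, ...) {
  task <- match.arg(task)
  if (is.null(order_map)) {
    order_map <- vapply(species_presets(), function(t) t$order, character(1))
  }
  df <- features
  if (task != "all-species") {
    ord <- unname(order_map[df$species])
    if (anyNA(ord)) {
      stop(
        "species without an order mapping: ",
        paste(unique(df$species[is.na(ord)]), collapse = ", "),
        call. = FALSE
      )
    }
    if (task == "aphid-vs-beetle") {
      df$species <- ord
    } else {
      want <- if (task == "within-aphids") "Hemiptera" else "Coleoptera"
      df <- df[ord == want, ]
    }
  }
  if (length(unique(df$species)) < 2) {
    stop("task ", task, " has fewer than 2 classes", call. = FALSE)
  }
  parts <- split_train_validation(df, fraction = fraction, seed = seed)
  model <- train_balanced_rf(parts$train, seed = seed, ...)
  list(
    task = task, model = model,
    report = evaluate(model, parts$validation),
    importance = importance_table(model)
  )
}
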