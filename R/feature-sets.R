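#' Representative features by correlation clustering
#'
#' Features are standardized (zero mean, unit variance), their pairwise
#' Pearson correlation matrix `r` computed (pairwise-complete observations),
#' and complete-linkage hierarchical clustering run on the distance `1 - r`.
#' Cutting the dendrogram into `k` groups, each group's representative is the
#' member feature closest (squared Euclidean distance in standardized
#' observation space) to the group centroid; ties break alphabetically.
#' Constant features are excluded with a warning.
#'
#' @param features Feature tibble.
#' @param k Number of clusters.
#' @return Character vector of `k` representative feature keys. The full
#'   cluster assignment is attached as attribute `"clusters"`.
#' @export
cluster_representatives <- function(features, k) {
  cols <- feature_cols(features)
  X <- as.matrix(features[cols])
  sds <- apply(X, 2, stats::sd, na.rm = TRUE)
  constant <- is.na(sds) | sds == 0
  if (any(constant)) {
    warning(
      "excluding constant features from clustering: ",
      paste(cols[constant], collapse = ", "),
      call. = FALSE
    )
    X <- X[, !constant, drop = FALSE]
    cols <- cols[!constant]
  }
  if (length(cols) < k) stop("fewer than k features with finite variance", call. = FALSE)
  Xs <- scale(X)
  r <- stats::cor(Xs, use = "pairwise.complete.obs")
  r[is.na(r)] <- 0 # pairs with no overlapping observations: uncorrelated
  hc <- stats::hclust(stats::as.dist(1 - r), method = "complete")
  grp <- stats::cutree(hc, k = k)
  reps <- vapply(sort(unique(grp)), function(g) {
    members <- sort(cols[grp == g]) # alphabetical: deterministic tie-break
    centroid <- rowMeans(Xs[, members, drop = FALSE], na.rm = TRUE)
    d <- vapply(
      members,
      function(f) sum((Xs[, f] - centroid)^2, na.rm = TRUE), numeric(1)
    )
    members[which.min(d)]
  }, character(1))
  attr(reps, "clusters") <- grp
  reps
}

#' The eight feature-set definitions
#'
#' Sets 1-5 are derived from the [feature_schema()] (so schema changes cannot
#' desynchronize them): all 52 features; the 25 computed without detrending;
#' the 27 computed after detrending; the 20 harmonic-peak frequencies (raw
#' and detrended); and the harmonic peaks supplemented with the frequency
#' indices (bioacoustic indices, spectral entropies, dominant and fundamental
#' frequencies). Sets 6-8 are the representatives of a complete-linkage
#' correlation clustering with 3, 5 and 14 clusters, computed from the
#' supplied feature table.
#'
#' @param features Feature tibble used for the clustered sets 6-8; when
#'   `NULL` only sets 1-5 are returned.
#' @return Named list of character vectors of feature keys.
#' @export
feature_sets <- function(features = NULL) {
  sch <- feature_schema()
  harm <- sch$feature[grepl("^harmonic_", sch$feature)]
  freq_idx <- sch$feature[grepl("^(bioacoustic_index|spectral_entropy|dominant_frequency|fundamental_frequency)", sch$feature)]
  sets <- list(
    set1_all = sch$feature,
    set2_raw = sch$feature[!sch$detrended],
    set3_detrended = sch$feature[sch$detrended],
    set4_harmonics = harm,
    set5_harmonics_freq = union(harm, freq_idx)
  )
  if (!is.null(features)) {
    sets$set6_cluster3 <- as.character(cluster_representatives(features, 3))
    sets$set7_cluster5 <- as.character(cluster_representatives(features, 5))
    sets$set8_cluster14 <- as.character(cluster_representatives(features, 14))
  }
  sets
}

#' Compare classification accuracy across feature sets
#'
#' Trains one balanced random forest per feature set per missing-value
#' policy (median imputation vs omitting incomplete observations) on a
#' common training/validation split, and reports out-of-bag and validation
#' accuracy for each.
#'
#' @param features Labelled feature tibble.
#' @param sets Named list of feature-key vectors (default: all eight from
#'   [feature_sets()] computed on `features`).
#' @param fraction,seed Split parameters.
#' @param ... Passed to [train_balanced_rf()] (e.g. `n_trees`).
#' @return Tibble with one row per set x policy: `set`, `n_features`,
#'   `impute`, `oob_accuracy`, `validation_accuracy`.
#' @export
compare_feature_sets <- function(features, sets = NULL, fraction = 0.7,
                                 seed = 1, ...) {
  sets <- sets %||% feature_sets(features)
  missing_feats <- setdiff(unique(unlist(sets)), names(features))
  if (length(missing_feats)) {
    stop(
      "feature sets reference absent features: ",
      paste(missing_feats, collapse = ", "),
      call. = FALSE
    )
  }
  parts <- split_train_validation(features, fraction = fraction, seed = seed)
  meta <- setdiff(names(features), feature_schema()$feature)
  purrr::map_dfr(names(sets), function(nm) {
    purrr::map_dfr(c(TRUE, FALSE), function(imp) {
      train <- parts$train[c(meta, sets[[nm]])]
      validation <- parts$validation[c(meta, sets[[nm]])]
      model <- train_balanced_rf(train, impute = imp, seed = seed, ...)
      rep_v <- evaluate(model, validation)
      tibble::tibble(
        set = nm, n_features = length(sets[[nm]]), impute = imp,
        oob_accuracy = 1 - model$oob_error,
        validation_accuracy = rep_v$accuracy
      )
    })
  })
}
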