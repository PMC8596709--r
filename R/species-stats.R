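#' Per-feature linear models with Type II ANOVA
#'
#' Fits `feature ~ temperature + humidity + species` to each feature on its
#' stored (transformed) scale and produces a Type II ANOVA table: the F test
#' for each term measures the effect of dropping it while retaining all
#' others, so the species test is adjusted for the environmental covariates
#' (and is invariant to the order the covariates are written). Rows with a
#' missing feature value or missing covariates are dropped per feature.
#'
#' @param features Labelled feature tibble with `temperature` and `humidity`.
#' @param keys Feature keys to analyse (default: all schema features present).
#' @param p_adjust Optional multiplicity correction applied to the species
#'   p-values across features (`"none"` or `"holm"`).
#' @return A tibble with one row per feature: F statistics, degrees of
#'   freedom and p-values for species, temperature and humidity, plus `n`
#'   (rows analysed) and the storage transformation.
#' @export
feature_anova <- function(features, keys = NULL, p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  sch <- feature_schema()
  keys <- keys %||% intersect(sch$feature, names(features))
  if (length(unique(stats::na.omit(features$species))) < 2) {
    stop("need at least 2 species", call. = FALSE)
  }
  rows <- purrr::map_dfr(keys, function(key) {
    d <- tibble::tibble(
      value = features[[key]],
      temperature = features$temperature,
      humidity = features$humidity,
      species = factor(features$species)
    )
    d <- d[stats::complete.cases(d), ]
    base <- tibble::tibble(
      feature = key,
      transform = sch$transform[sch$feature == key],
      n = nrow(d),
      F_species = NA_real_, df_species = NA_integer_, p_species = NA_real_,
      F_temperature = NA_real_, p_temperature = NA_real_,
      F_humidity = NA_real_, p_humidity = NA_real_,
      flagged = TRUE
    )
    n_par <- 2 + nlevels(droplevels(d$species))
    if (nrow(d) <= n_par || length(unique(d$value)) < 2 ||
      length(unique(as.character(d$species))) < 2) {
      return(base)
    }
    fit <- stats::lm(value ~ temperature + humidity + species, data = d)
    if (fit$df.residual < 1) {
      return(base)
    }
    an <- car::Anova(fit, type = 2)
    get <- function(term, col) an[term, col]
    base$F_species <- get("species", "F value")
    base$df_species <- as.integer(get("species", "Df"))
    base$p_species <- get("species", "Pr(>F)")
    base$F_temperature <- get("temperature", "F value")
    base$p_temperature <- get("temperature", "Pr(>F)")
    base$F_humidity <- get("humidity", "F value")
    base$p_humidity <- get("humidity", "Pr(>F)")
    base$flagged <- FALSE
    base
  })
  if (p_adjust == "holm") {
    rows$p_species_adjusted <- stats::p.adjust(rows$p_species, method = "holm")
  }
  dplyr::arrange(rows, dplyr::desc(.data$F_species))
}

#' Covariate-adjusted species means
#'
#' Predicts each species' mean feature value at the sample-average
#' temperature and humidity from the [feature_anova()] linear model, then
#' back-transforms to the original scale (exponentiating log features — the
#' geometric mean — and squaring square-root features). Species medians are
#' computed directly from the back-transformed per-species observations.
#'
#' @param features Labelled feature tibble.
#' @param key Feature key, e.g. `"fundamental_frequency_g"`.
#' @return Tibble with one row per species: `adjusted_mean` and `median` on
#'   the original scale, and `n`.
#' @export
adjusted_species_means <- function(features, key) {
  sch <- feature_schema()
  if (!key %in% sch$feature) stop("unknown feature key: ", key, call. = FALSE)
  if (!key %in% names(features)) stop("feature not present in table: ", key, call. = FALSE)
  tf <- sch$transform[sch$feature == key]
  d <- tibble::tibble(
    value = features[[key]],
    temperature = features$temperature,
    humidity = features$humidity,
    species = factor(features$species)
  )
  d <- d[stats::complete.cases(d), ]
  d$species <- droplevels(d$species)
  fit <- stats::lm(value ~ temperature + humidity + species, data = d)
  newdata <- tibble::tibble(
    species = factor(levels(d$species), levels = levels(d$species)),
    temperature = mean(d$temperature),
    humidity = mean(d$humidity)
  )
  pred <- stats::predict(fit, newdata)
  meds <- tapply(back_transform(d$value, tf), d$species, stats::median)
  tibble::tibble(
    species = levels(d$species),
    adjusted_mean = back_transform(as.numeric(pred), tf),
    median = as.numeric(meds[levels(d$species)]),
    n = as.integer(table(d$species)[levels(d$species)])
  )
}
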