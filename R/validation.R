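#' Normal-theory confidence band of replicate values
#'
#' The 95% band used for cross-validation predictions: mean +/- 1.96
#' sample standard deviations of the replicate predictions (normal
#' distribution statistics, not a standard error of the mean — the band
#' describes the spread of replicate fits).
#'
#' @param x Numeric vector of replicate values (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `mean`, `lower`, `upper`.
#' @export
confidence_band <- function(x, level = 0.95) {
  if (length(x) < 2) abort("Need >= 2 replicate values for a band.")
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(x); s <- stats::sd(x)
  tibble(mean = m, lower = m - z * s, upper = m + z * s)
}

## Fit on a training set `replicates` times with fresh seeds, then
## predict the requested (condition, observable, time) cells per fit.
replicate_fit_predictions <- function(train, cells, config, replicates, seeds,
                                      params, polish) {
  preds <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    cfg <- config
    cfg$seed <- seeds[r]
    fit <- ga_fit(train, cfg, params = params, polish = polish)
    mt <- model_observable_table(fit$params,
                                 conditions = unique(cells$condition),
                                 times = sort(unique(cells$time_weeks)))
    preds[[r]] <- semi_join(mt, cells,
                            by = c("condition", "observable", "time_weeks")) |>
      mutate(replicate_fit = r)
  }
  list_rbind(preds)
}

cv_fold_report <- function(fold_id, held_label, train, test, config,
                           replicates, seeds, params, polish, level) {
  cells <- distinct(test, .data$condition, .data$observable, .data$time_weeks)
  preds <- replicate_fit_predictions(train, cells, config, replicates, seeds,
                                     params, polish)
  obs <- test |>
    group_by(.data$condition, .data$observable, .data$time_weeks) |>
    summarise(observed = mean(.data$value), .groups = "drop")
  bands <- preds |>
    group_by(.data$condition, .data$observable, .data$time_weeks) |>
    summarise(confidence_band(.data$value, level), .groups = "drop")
  bands |>
    left_join(obs, by = c("condition", "observable", "time_weeks")) |>
    mutate(fold = fold_id, held_out = held_label, .before = 1) |>
    rename(lo95 = "lower", hi95 = "upper")
}

#' Leave-one-condition-out cross-validation
#'
#' For each treatment condition in the dataset: drop all of its data,
#' refit the model `replicates` times on the remaining conditions with
#' fresh GA seeds, simulate the held-out regimen under every replicate
#' fit, and summarize the predictions for each held-out data box with a
#' mean and a 95% normal band. Held-out data never enter the training
#' objective (the objective is additive over boxes).
#'
#' @param ds A dataset with >= 2 conditions.
#' @param config GA configuration per training run.
#' @param replicates Replicate fits per fold (default 20; the full-scale
#'   analysis uses 100).
#' @param seed Master seed; per-fold, per-replicate seeds derive from it.
#' @param params Parameter template with bounds.
#' @param polish Polish each training fit. Defaults to `FALSE` here: the
#'   band is meant to express training stochasticity, which a fully
#'   converged local refinement would collapse.
#' @param level Band confidence level.
#' @return A tibble with one row per held-out data box: `fold`,
#'   `held_out`, `condition`, `observable`, `time_weeks`, `mean`, `lo95`,
#'   `hi95`, `observed` (mean of the held-out replicate measurements).
#' @export
leave_one_condition_out <- function(ds, config = ga_config(), replicates = 20,
                                    seed = 1L, params = parameter_table(),
                                    polish = FALSE, level = 0.95) {
  validate_dataset(ds)
  conds <- sort(unique(ds$condition))
  if (length(conds) < 2) abort("Need >= 2 conditions for condition-wise CV.")
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L,
                                       length(conds) * replicates))
  out <- vector("list", length(conds))
  for (k in seq_along(conds)) {
    train <- new_dataset(ds[ds$condition != conds[k], ])
    test <- ds[ds$condition == conds[k], ]
    if (nrow(train) == 0) abort("A fold has an empty training set.")
    fold_seeds <- seeds[(k - 1) * replicates + seq_len(replicates)]
    out[[k]] <- cv_fold_report(k, conds[k], train, test, config, replicates,
                               fold_seeds, params, polish, level)
  }
  list_rbind(out)
}

#' Leave-one-data-box-out cross-validation
#'
#' As [leave_one_condition_out()], but the holdout unit is a single data
#' box (one condition, one observable, one time point); all other boxes
#' of the same condition stay in training. The fold count equals the box
#' count.
#'
#' @inheritParams leave_one_condition_out
#' @return A tibble with one row per fold (= per box), same columns as
#'   [leave_one_condition_out()].
#' @export
leave_one_box_out <- function(ds, config = ga_config(), replicates = 20,
                              seed = 1L, params = parameter_table(),
                              polish = FALSE, level = 0.95) {
  validate_dataset(ds)
  boxes <- dataset_boxes(ds)
  if (nrow(boxes) < 2) abort("Need >= 2 data boxes for box-wise CV.")
  seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L,
                                       nrow(boxes) * replicates))
  key <- paste(ds$condition, ds$observable, ds$time_weeks)
  out <- vector("list", nrow(boxes))
  for (k in seq_len(nrow(boxes))) {
    bkey <- paste(boxes$condition[k], boxes$observable[k], boxes$time_weeks[k])
    train <- new_dataset(ds[key != bkey, ])
    test <- ds[key == bkey, ]
    if (nrow(train) == 0) abort("A fold has an empty training set.")
    fold_seeds <- seeds[(k - 1) * replicates + seq_len(replicates)]
    out[[k]] <- cv_fold_report(k, bkey, train, test, config, replicates,
                               fold_seeds, params, polish, level)
  }
  list_rbind(out)
}

#' Band coverage against a reference table
#'
#' Fraction of held-out boxes whose reference (e.g. noise-free truth)
#' value falls inside the fold's 95% band — the calibration summary of a
#' cross-validation run.
#'
#' @param folds Output of [leave_one_condition_out()] or
#'   [leave_one_box_out()].
#' @param reference A tibble `condition`, `observable`, `time_weeks`,
#'   `value` (e.g. from [model_observable_table()]); if `NULL`, the
#'   observed replicate means in `folds` are used.
#' @return A list with `coverage` (fraction in `[0, 1]`) and the joined
#'   per-box table.
#' @export
band_coverage <- function(folds, reference = NULL) {
  tbl <- if (is.null(reference)) {
    mutate(folds, target = .data$observed)
  } else {
    folds |>
      left_join(rename(reference, target = "value"),
                by = c("condition", "observable", "time_weeks"))
  }
  tbl <- mutate(tbl, covered = .data$target >= .data$lo95 & .data$target <= .data$hi95)
  list(coverage = mean(tbl$covered, na.rm = TRUE), table = tbl)
}
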