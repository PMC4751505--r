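#' Measurement-noise model for synthetic datasets
#'
#' Replicate measurements are the noise-free model observable multiplied
#' by lognormal noise with median 1 (`meanlog = 0`), which preserves
#' positivity and makes the noise-free value the median (not the mean) of
#' the replicate distribution. The missingness pattern lists
#' (condition, observable) pairs that were not measured; by default the
#' lymphoid observables are absent for the CX + AI and CX + AR groups,
#' mimicking the incomplete lymphoid sampling of the experiments.
#'
#' @param sigma Lognormal sdlog (default 0.15).
#' @param replicates Replicates per data box (default 5, a typical mouse
#'   group size).
#' @param missing A tibble with columns `condition`, `observable` of boxes
#'   to drop, or `NULL` for none.
#' @return A `prostimm_noise` list.
#' @export
noise_model <- function(sigma = 0.15, replicates = 5,
                        missing = default_missingness()) {
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (replicates < 1) abort("`replicates` must be >= 1.")
  structure(list(sigma = sigma, replicates = as.integer(replicates),
                 missing = missing), class = "prostimm_noise")
}

#' @rdname noise_model
#' @export
default_missingness <- function() {
  tidyr::expand_grid(condition = c("CX + AI", "CX + AR"),
                     observable = c("CTL-L", "Treg-L"))
}

#' Noise-free model observables at the measurement design points
#'
#' @param params A parameter tibble.
#' @param conditions Condition labels (default the 7 experimental ones).
#' @param times Measurement times in weeks (default 2.5 and 5; time 0 is
#'   never emitted as data).
#' @param ... Passed to [simulate_model()].
#' @return A tibble `condition`, `observable`, `time_weeks`, `value`.
#' @export
model_observable_table <- function(params, conditions = experimental_conditions(),
                                   times = c(2.5, 5), ...) {
  purrr::map(conditions, function(cond) {
    tr <- simulate_model(params, cond, ...)
    if (!is_valid_trajectory(tr)) {
      abort(paste0("Invalid trajectory under condition ", cond, "."))
    }
    obs <- observe(tr)
    obs <- obs[obs$time %in% times, ]
    tibble(condition = cond, observable = obs$observable,
           time_weeks = obs$time, value = obs$value)
  }) |> list_rbind()
}

#' Generate a synthetic mouse-experiment-like dataset
#'
#' Simulates every condition under the ground-truth parameters, evaluates
#' the five observables at the measurement times, draws replicate values
#' with multiplicative lognormal noise and drops the boxes listed in the
#' missingness pattern. Fully reproducible from `seed`.
#'
#' @param truth Ground-truth parameter tibble (default [default_truth()]).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param conditions Condition labels to include.
#' @param times Measurement times (weeks).
#' @return A `prostimm_dataset`: a tibble with columns `condition`,
#'   `observable`, `time_weeks`, `replicate_id`, `value` and provenance
#'   (truth hash, sigma, seed) in attributes. A data box is one
#'   (condition, observable, time) cell.
#' @examples
#' ds <- generate_dataset(seed = 1)
#' dplyr::n_distinct(ds$condition)
#' @export
generate_dataset <- function(truth = default_truth(), noise = noise_model(),
                             seed = 1L, conditions = experimental_conditions(),
                             times = c(2.5, 5)) {
  base <- model_observable_table(truth, conditions, times)
  if (!is.null(noise$missing) && nrow(noise$missing) > 0) {
    base <- anti_join(base, noise$missing, by = c("condition", "observable"))
  }
  withr_seed(seed, {
    ds <- tidyr::expand_grid(base, replicate_id = seq_len(noise$replicates))
    ds$value <- ds$value * stats::rlnorm(nrow(ds), meanlog = 0, sdlog = noise$sigma)
  })
  ds <- ds[, c("condition", "observable", "time_weeks", "replicate_id", "value")]
  new_dataset(ds, provenance = list(
    truth_hash = rlang::hash(param_vector(truth)),
    sigma = noise$sigma, replicates = noise$replicates, seed = as.integer(seed)
  ))
}

## evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

new_dataset <- function(tbl, provenance = NULL) {
  structure(as_tibble(tbl), provenance = provenance,
            class = c("prostimm_dataset", class(as_tibble(tbl))))
}

#' Validate a dataset table
#'
#' @param ds A data frame with the dataset schema.
#' @return The validated `prostimm_dataset` (invisibly its input), or an
#'   error naming offending rows.
#' @export
validate_dataset <- function(ds) {
  req <- c("condition", "observable", "time_weeks", "replicate_id", "value")
  miss <- setdiff(req, names(ds))
  if (length(miss) > 0) {
    abort(paste0("Dataset is missing column(s): ", paste(miss, collapse = ", ")))
  }
  known <- vapply(experimental_conditions(), function(x) x, character(1))
  norm <- gsub(" ", "", ds$condition)
  bad <- which(!norm %in% gsub(" ", "", known))
  if (length(bad) > 0) {
    abort(paste0("Unknown condition label at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!ds$observable %in% observable_names)
  if (length(bad) > 0) {
    abort(paste0("Unknown observable at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad <- which(!is.finite(ds$value) | ds$value <= 0)
  if (length(bad) > 0) {
    abort(paste0("Non-positive or non-finite value at row(s): ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  key <- paste(ds$condition, ds$observable, ds$time_weeks, ds$replicate_id)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (condition, observable, time, replicate) at row(s): ",
                 paste(utils::head(which(duplicated(key)), 5), collapse = ", ")))
  }
  invisible(new_dataset(ds, provenance = attr(ds, "provenance")))
}

#' Data boxes of a dataset
#'
#' A data box is the set of replicate values for one (condition,
#' observable, time) cell — the unit of bootstrap resampling and of the
#' box-wise cross-validation holdout.
#'
#' @param ds A dataset.
#' @return A tibble keyed by `condition`, `observable`, `time_weeks` with
#'   the replicate count `n` per box.
#' @export
dataset_boxes <- function(ds) {
  ds |>
    group_by(.data$condition, .data$observable, .data$time_weeks) |>
    summarise(n = dplyr::n(), .groups = "drop")
}

#' Write / read dataset TSV files
#'
#' Plain tab-separated files with columns `condition`, `observable`,
#' `time_weeks`, `replicate_id`, `value`. `write_dataset()` also writes a
#' provenance sidecar (`<path>.json`) when the dataset carries synthetic
#' provenance.
#'
#' @param ds A dataset.
#' @param path TSV file path.
#' @return `read_dataset()` returns a validated `prostimm_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  readr::write_tsv(as_tibble(ds), path)
  prov <- attr(ds, "provenance")
  if (!is.null(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           condition = readr::col_character(),
                           observable = readr::col_character(),
                           time_weeks = readr::col_double(),
                           replicate_id = readr::col_integer(),
                           value = readr::col_double()))
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else NULL
  out <- new_dataset(tbl, provenance = prov)
  validate_dataset(out)
  out
}
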