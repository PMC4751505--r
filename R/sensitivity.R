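#' Local parameter sensitivity of the tumor-size outcomes
#'
#' Increases each estimated parameter in turn by a fixed fraction
#' (default 5%), re-simulates every treatment condition, and reports the
#' percent change of each tumor-size outcome:
#' `S = 100 * (Y_perturbed - Y) / Y`. A perturbed simulation that fails
#' is flagged (`valid = FALSE`, sensitivity `NA`).
#'
#' @param params A parameter tibble (typically a fit's estimates).
#' @param perturbation Positive fraction (default 0.05).
#' @param conditions Condition labels (default the 7 experimental ones).
#' @return A tibble: `name`, `index`, `condition`, `outcome_type`
#'   (`"I"`/`"II"`), `baseline`, `perturbed`, `sensitivity` (percent),
#'   `valid`.
#' @export
local_sensitivity <- function(params, perturbation = 0.05,
                              conditions = experimental_conditions()) {
  if (!is.numeric(perturbation) || perturbation <= 0) {
    abort("`perturbation` must be a positive fraction.")
  }
  check_parameter_table(params)
  base <- purrr::map(conditions, function(cond) {
    tr <- simulate_model(params, cond)
    bind_cols(tibble(condition = cond), outcomes(tr))
  }) |> list_rbind()

  est <- params[params$estimated, ]
  est <- est[order(est$index), ]
  rows <- purrr::map(seq_len(nrow(est)), function(j) {
    pj <- params
    i <- match(est$name[j], pj$name)
    pj$value[i] <- pj$value[i] * (1 + perturbation)
    purrr::map(conditions, function(cond) {
      tr <- simulate_model(pj, cond)
      ok <- is_valid_trajectory(tr)
      oc <- if (ok) outcomes(tr) else tibble(type_I = NA_real_, type_II = NA_real_)
      b <- base[base$condition == cond, ]
      tibble(
        name = est$name[j], index = est$index[j], condition = cond,
        outcome_type = c("I", "II"),
        baseline = c(b$type_I, b$type_II),
        perturbed = c(oc$type_I, oc$type_II),
        valid = ok
      )
    }) |> list_rbind()
  }) |> list_rbind()
  mutate(rows, sensitivity = 100 * (.data$perturbed - .data$baseline) / .data$baseline)
}
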