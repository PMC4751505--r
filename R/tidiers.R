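#' Tidy a model fit
#'
#' @param x A `prostimm_fit`.
#' @param ... Unused.
#' @return A tibble with one row per estimated parameter: `name`,
#'   `index`, `estimate`, `lower`, `upper`.
#' @method tidy prostimm_fit
#' @export
tidy.prostimm_fit <- function(x, ...) {
  est <- x$params[x$params$estimated, ]
  est <- est[order(est$index), ]
  tibble(name = est$name, index = est$index, estimate = est$value,
         lower = est$lower, upper = est$upper)
}

#' One-row fit summary
#'
#' @param x A `prostimm_fit`.
#' @param ... Unused.
#' @return A one-row tibble: objective value, GA settings, seed, polish
#'   flag and replicate count.
#' @method glance prostimm_fit
#' @export
glance.prostimm_fit <- function(x, ...) {
  tibble(objective = x$objective,
         generations = x$config$generations,
         population = x$config$population,
         p_crossover = x$config$p_crossover,
         p_mutation = x$config$p_mutation,
         eta_crossover = x$config$eta_crossover,
         eta_mutation = x$config$eta_mutation,
         seed = x$seed,
         polished = x$polished,
         n_replicates = length(x$replicate_objectives %||% integer(0)))
}

#' @importFrom rlang %||%
NULL

#' Tidy a Bliss CI matrix
#'
#' @param x A `prostimm_ci_matrix`.
#' @param ... Unused.
#' @return The long pair table: `group_a`, `group_b`, `e_a`, `e_b`,
#'   `e_ab`, `ci`, plus the outcome `type`.
#' @method tidy prostimm_ci_matrix
#' @export
tidy.prostimm_ci_matrix <- function(x, ...) {
  mutate(x$pairs, type = x$type)
}

#' Tidy a trajectory into long format
#'
#' @param x A `prostimm_trajectory`.
#' @param ... Unused.
#' @return A long tibble: `time`, `state`, `value`, `regimen`.
#' @method tidy prostimm_trajectory
#' @export
tidy.prostimm_trajectory <- function(x, ...) {
  out <- tidyr::pivot_longer(as_tibble(x), -"time",
                             names_to = "state", values_to = "value")
  out$regimen <- attr(x, "regimen")$label
  out
}
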