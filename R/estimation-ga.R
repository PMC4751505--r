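#' Genetic-algorithm configuration
#'
#' Settings of the real-coded single-objective GA: generation count,
#' population size, crossover and mutation probabilities, and the
#' distribution indices of simulated-binary crossover (SBX) and
#' polynomial mutation. Larger distribution indices produce children
#' closer to their parents.
#'
#' @param generations,population Positive integer counts.
#' @param p_crossover,p_mutation Probabilities in `[0, 1]`; `p_mutation`
#'   is applied per gene (default 1/25, one expected mutation per
#'   25-parameter individual).
#' @param eta_crossover,eta_mutation Positive distribution indices.
#' @param seed Integer RNG seed; the GA is deterministic given seed and
#'   configuration.
#' @return A `prostimm_ga_config` list.
#' @export
ga_config <- function(generations = 100, population = 100,
                      p_crossover = 0.9, p_mutation = 1 / 25,
                      eta_crossover = 20, eta_mutation = 20, seed = 1L) {
  stopifnot(generations >= 1, population >= 2,
            p_crossover >= 0, p_crossover <= 1,
            p_mutation >= 0, p_mutation <= 1,
            eta_crossover > 0, eta_mutation > 0)
  structure(list(generations = as.integer(generations),
                 population = as.integer(population),
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 eta_crossover = eta_crossover, eta_mutation = eta_mutation,
                 seed = as.integer(seed)),
            class = "prostimm_ga_config")
}

hyper_fields <- c("generations", "population", "p_crossover",
                  "p_mutation", "eta_crossover", "eta_mutation")

#' Hyperparameter candidate grid for GA parameter selection
#'
#' Candidate levels for each GA setting; their Cartesian product is the
#' candidate set searched during GA parameter selection. The default grid
#' varies five of the six settings over three levels each and fixes the
#' per-gene mutation probability at 1/25, giving 3^5 = 243 candidate
#' configurations.
#'
#' @param generations,population,p_crossover,p_mutation,eta_crossover,eta_mutation
#'   Numeric vectors of candidate levels.
#' @return A `prostimm_hyper_grid` list of candidate levels.
#' @examples
#' nrow(hypergrid_enumerate(hyper_grid()))  # 243
#' @export
hyper_grid <- function(generations = c(50, 100, 200),
                       population = c(50, 100, 200),
                       p_crossover = c(0.7, 0.8, 0.9),
                       p_mutation = 1 / 25,
                       eta_crossover = c(2, 10, 20),
                       eta_mutation = c(10, 20, 50)) {
  structure(list(generations = generations, population = population,
                 p_crossover = p_crossover, p_mutation = p_mutation,
                 eta_crossover = eta_crossover, eta_mutation = eta_mutation),
            class = "prostimm_hyper_grid")
}

#' Enumerate a hyperparameter grid
#'
#' @param grid A [hyper_grid()].
#' @return A tibble with one row per candidate configuration (`config_id`
#'   plus the six GA settings), in a deterministic order (the last-listed
#'   field varies fastest).
#' @export
hypergrid_enumerate <- function(grid) {
  if (!inherits(grid, "prostimm_hyper_grid")) abort("`grid` must be a hyper_grid().")
  levels <- grid[hyper_fields]
  tbl <- rev(expand.grid(rev(levels), KEEP.OUT.ATTRS = FALSE))
  tbl <- as_tibble(tbl)
  bind_cols(tibble(config_id = seq_len(nrow(tbl))), tbl)
}

#' Coordinate-wise GA hyperparameter selection
#'
#' Implements the one-by-one selection of individual GA settings: for
#' each setting in a fixed order, runs are grouped by that setting's
#' level and the level with the smallest median fitting error wins (the
#' median is robust to occasional GA failures); ties go to the
#' first-listed level. The winning levels are assembled into the selected
#' configuration.
#'
#' @param errors A tibble as returned by [hypergrid_enumerate()] with an
#'   additional `error` column, one row per candidate configuration.
#' @param grid The [hyper_grid()] that generated the candidates.
#' @return A [ga_config()] with the selected levels (seed unset, 0).
#' @export
select_hyperparameters <- function(errors, grid) {
  enum <- hypergrid_enumerate(grid)
  if (!"error" %in% names(errors)) abort("`errors` must contain an `error` column.")
  if (nrow(errors) != nrow(enum)) {
    abort(sprintf("Expected one error per candidate config (%d), got %d rows.",
                  nrow(enum), nrow(errors)))
  }
  chosen <- list()
  for (f in hyper_fields) {
    lv <- grid[[f]]
    med <- vapply(lv, function(l) {
      stats::median(errors$error[errors[[f]] == l])
    }, numeric(1))
    chosen[[f]] <- lv[which.min(med)]  # which.min takes the first on ties
  }
  ga_config(generations = chosen$generations, population = chosen$population,
            p_crossover = chosen$p_crossover, p_mutation = chosen$p_mutation,
            eta_crossover = chosen$eta_crossover,
            eta_mutation = chosen$eta_mutation, seed = 0L)
}

#' Real-coded genetic algorithm minimizer
#'
#' Single-objective box-bounded GA with binary tournament selection,
#' simulated-binary crossover, polynomial mutation and one-elite
#' preservation. Deterministic given seed and configuration.
#'
#' @param objective Function mapping a numeric vector to a scalar to be
#'   minimized; non-finite returns are treated as `+Inf`.
#' @param lower,upper Numeric bound vectors of equal length (the search
#'   dimension).
#' @param cfg A [ga_config()].
#' @return A `prostimm_ga_fit` list: `par` (best vector), `value` (best
#'   objective), `trace` (per-generation best objective, non-increasing
#'   by elitism), `config`, `seed`, `n_evaluations`.
#' @examples
#' f <- function(x) sum(x^2)
#' fit <- ga_minimize(f, rep(-1, 5), rep(1, 5), ga_config(seed = 7))
#' fit$value
#' @export
ga_minimize <- function(objective, lower, upper, cfg = ga_config()) {
  d <- length(lower)
  if (length(upper) != d) abort("`lower` and `upper` must have equal length.")
  if (any(!is.finite(lower)) || any(!is.finite(upper)) || any(upper <= lower)) {
    abort("Bounds must be finite with upper > lower in every dimension.")
  }
  eval_one <- function(x) {
    v <- objective(x)
    if (!is.finite(v)) Inf else v
  }
  n_eval <- 0L
  withr_seed(cfg$seed, {
    pop <- matrix(runif(cfg$population * d, rep(lower, each = cfg$population),
                        rep(upper, each = cfg$population)),
                  nrow = cfg$population, ncol = d)
    fit <- apply(pop, 1, eval_one)
    n_eval <- n_eval + cfg$population
    trace <- numeric(cfg$generations + 1)
    trace[1] <- min(fit)
    for (g in seq_len(cfg$generations)) {
      elite_i <- which.min(fit)
      elite <- pop[elite_i, ]
      elite_fit <- fit[elite_i]
      parents <- tournament_select(fit, cfg$population)
      children <- sbx_crossover(pop[parents, , drop = FALSE], lower, upper,
                                cfg$p_crossover, cfg$eta_crossover)
      children <- poly_mutate(children, lower, upper,
                              cfg$p_mutation, cfg$eta_mutation)
      cfit <- apply(children, 1, eval_one)
      n_eval <- n_eval + nrow(children)
      worst <- which.max(cfit)
      children[worst, ] <- elite
      cfit[worst] <- elite_fit
      pop <- children
      fit <- cfit
      trace[g + 1] <- min(fit)
    }
    best <- which.min(fit)
    structure(list(par = pop[best, ], value = fit[best], trace = trace,
                   config = cfg, seed = cfg$seed, n_evaluations = n_eval),
              class = "prostimm_ga_fit")
  })
}

tournament_select <- function(fit, n) {
  a <- sample.int(length(fit), n, replace = TRUE)
  b <- sample.int(length(fit), n, replace = TRUE)
  ifelse(fit[a] <= fit[b], a, b)
}

sbx_crossover <- function(parents, lower, upper, p_c, eta) {
  n <- nrow(parents); d <- ncol(parents)
  children <- parents
  for (i in seq(1, n - 1, by = 2)) {
    if (runif(1) > p_c) next
    p1 <- parents[i, ]; p2 <- parents[i + 1, ]
    u <- runif(d)
    beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                   (1 / (2 * (1 - u)))^(1 / (eta + 1)))
    do_x <- runif(d) <= 0.5  # per-gene exchange
    c1 <- ifelse(do_x, 0.5 * ((1 + beta) * p1 + (1 - beta) * p2), p1)
    c2 <- ifelse(do_x, 0.5 * ((1 - beta) * p1 + (1 + beta) * p2), p2)
    children[i, ] <- pmin(pmax(c1, lower), upper)
    children[i + 1, ] <- pmin(pmax(c2, lower), upper)
  }
  children
}

poly_mutate <- function(pop, lower, upper, p_m, eta) {
  n <- nrow(pop); d <- ncol(pop)
  span <- upper - lower
  for (i in seq_len(n)) {
    hit <- which(runif(d) <= p_m)
    for (j in hit) {
      x <- pop[i, j]
      d1 <- (x - lower[j]) / span[j]
      d2 <- (upper[j] - x) / span[j]
      u <- runif(1)
      if (u <= 0.5) {
        dq <- (2 * u + (1 - 2 * u) * (1 - d1)^(eta + 1))^(1 / (eta + 1)) - 1
      } else {
        dq <- 1 - (2 * (1 - u) + 2 * (u - 0.5) * (1 - d2)^(eta + 1))^(1 / (eta + 1))
      }
      pop[i, j] <- min(max(x + dq * span[j], lower[j]), upper[j])
    }
  }
  pop
}
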