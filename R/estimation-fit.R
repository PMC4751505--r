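## Precompute everything the objective needs. All conditions present in
## the dataset are stacked into one compiled ODE system (independent
## 15-state copies), so each objective evaluation is a single solver
## call plus an indexed lookup. This sits inside the GA's inner loop.
make_fit_context <- function(ds, template) {
  validate_dataset(ds)
  check_bounds(template)
  conds <- sort(unique(ds$condition))
  times <- sort(unique(ds$time_weeks))
  sim_times <- sort(unique(c(0, times)))
  regs <- lapply(conds, as_regimen)
  n <- length(conds)
  obs_i <- match(ds$observable, observable_names)
  time_i <- match(ds$time_weeks, times)
  cond_i <- match(ds$condition, conds)
  est <- template[template$estimated, ]
  est <- est[order(est$index), ]
  fix <- template[!template$estimated, ]
  list(
    conds = conds, n_cond = n,
    times = times, sim_times = sim_times,
    t_idx = match(times, sim_times),
    y0 = unlist(lapply(regs, initial_state)),
    chis = vapply(regs, function(r) as.numeric(r$cx), numeric(1)),
    # row slot in the stacked (observable x time x condition) value array
    slot = obs_i + 5 * (time_i - 1) + 5 * length(times) * (cond_i - 1),
    value = ds$value,
    fixed = setNames(fix$value, fix$name)[names(fixed_param_defaults)],
    lower = est$lower, upper = est$upper,
    template = template, n_rows = nrow(ds)
  )
}

## residuals (model - data) for the 25 estimated values in canonical order
ctx_residuals <- function(ctx, est_values) {
  pv <- c(unname(est_values), unname(ctx$fixed), ctx$n_cond, ctx$chis)
  pv <- c(pv, numeric(50 - length(pv)))  # pad to the compiled parms length
  sol <- try(suppressWarnings(
    deSolve::lsoda(ctx$y0, ctx$sim_times,
                   func = "prostimm_derivs_multi", parms = pv,
                   dllname = "prostimm",
                   initfunc = "prostimm_initmod_multi",
                   rtol = 1e-6, atol = 1e-8, maxsteps = 10000, verbose = FALSE)),
    silent = TRUE)
  if (inherits(sol, "try-error") || nrow(sol) != length(ctx$sim_times) ||
      !all(is.finite(sol)) || max(abs(sol)) >= 1e8) {
    return(NULL)
  }
  sol[sol < 0] <- 0
  idx <- ctx$t_idx
  vals <- vapply(seq_len(ctx$n_cond), function(k) {
    off <- 1 + 15 * (k - 1)  # column offset: state j of copy k is off + j
    tum <- (sol[idx, off + 5] + sol[idx, off + 6]) /
      (sol[1, off + 5] + sol[1, off + 6])
    rbind(tum, sol[idx, off + 13], sol[idx, off + 14],
          sol[idx, off + 10], sol[idx, off + 11])
  }, matrix(0, 5, length(idx)))
  vals[ctx$slot] - ctx$value
}

#' Sum-of-squared-errors objective
#'
#' The calibration objective: the sum over all data boxes and replicates
#' of the squared difference between the model observable and the
#' measured value. Initial (time 0) values never contribute; invalid
#' trajectories give `+Inf`.
#'
#' @param params A parameter tibble with the candidate values.
#' @param ds A dataset.
#' @return A non-negative scalar (or `Inf` for a failed simulation).
#' @examples
#' ds <- generate_dataset(noise = noise_model(sigma = 0), seed = 1)
#' sse_objective(default_truth(), ds)  # ~ 0 at the generating truth
#' @export
sse_objective <- function(params, ds) {
  if (nrow(ds) == 0) abort("Dataset is empty.")
  check_parameter_table(params)
  ctx <- make_fit_context(ds, params)
  est <- params[params$estimated, ]
  est <- est[order(est$index), ]
  res <- ctx_residuals(ctx, est$value)
  if (is.null(res)) return(Inf)
  sum(res^2)
}

check_bounds <- function(template) {
  est <- template[template$estimated, ]
  if (any(!is.finite(est$lower)) || any(!is.finite(est$upper)) ||
      any(est$upper <= est$lower) || any(est$lower <= 0)) {
    abort("Estimated parameters need finite positive bounds with upper > lower.")
  }
  invisible(template)
}

## The GA searches log10-transformed parameters: rates span several
## orders of magnitude, and SBX/polynomial-mutation steps are better
## behaved on the log scale. Initialization is therefore log-uniform
## within bounds.
ctx_objective_log <- function(ctx) {
  function(z) {
    res <- ctx_residuals(ctx, 10^z)
    if (is.null(res)) Inf else sum(res^2)
  }
}

polish_fit <- function(ctx, z_start) {
  lo <- log10(ctx$lower); hi <- log10(ctx$upper)
  out <- try(suppressWarnings(minpack.lm::nls.lm(
    par = z_start,
    lower = lo, upper = hi,
    fn = function(z) {
      r <- ctx_residuals(ctx, 10^z)
      if (is.null(r)) rep(1e6, ctx$n_rows) else r
    },
    control = minpack.lm::nls.lm.control(maxiter = 100))), silent = TRUE)
  if (inherits(out, "try-error")) return(NULL)
  list(par = pmin(pmax(unname(out$par), lo), hi), value = sum(out$fvec^2))
}

new_fit_result <- function(params, objective, config, seed, trace,
                           replicate_objectives = NULL, stage1 = NULL,
                           polished = FALSE) {
  structure(list(params = params, objective = objective, config = config,
                 seed = seed, trace = trace,
                 replicate_objectives = replicate_objectives,
                 stage1 = stage1, polished = polished),
            class = "prostimm_fit")
}

#' @export
print.prostimm_fit <- function(x, ...) {
  cat("<prostimm_fit>  SSE =", format(x$objective, digits = 6),
      " (", x$config$generations, "generations x", x$config$population,
      "population", if (x$polished) ", polished" else "", ")\n")
  invisible(x)
}

#' Single-configuration GA calibration of the model
#'
#' Fits the 25 estimated parameters to a dataset by minimizing
#' [sse_objective()] with [ga_minimize()] under one GA configuration,
#' optionally followed by a bounded Levenberg-Marquardt polish of the
#' best individual (the GA locates the basin; the local step sharpens the
#' optimum).
#'
#' @param ds A dataset.
#' @param config A [ga_config()].
#' @param params Parameter template carrying the search bounds (default
#'   [parameter_table()] with bounds `[1e-3, 1e2]`).
#' @param polish Apply the local refinement step (default `TRUE`).
#' @return A `prostimm_fit` (see [mga_fit()] for fields).
#' @export
ga_fit <- function(ds, config = ga_config(), params = parameter_table(),
                   polish = TRUE) {
  ctx <- make_fit_context(ds, params)
  obj <- ctx_objective_log(ctx)
  ga <- ga_minimize(obj, log10(ctx$lower), log10(ctx$upper), config)
  par <- ga$par; val <- ga$value
  polished <- FALSE
  if (polish) {
    pol <- polish_fit(ctx, par)
    if (!is.null(pol) && is.finite(pol$value) && pol$value < val) {
      par <- pol$par; val <- pol$value; polished <- TRUE
    }
  }
  est <- set_estimated(params, 10^par)
  new_fit_result(est, val, config, config$seed, ga$trace, polished = polished)
}

#' Modified genetic algorithm calibration (GA with hyperparameter selection)
#'
#' The full calibration procedure: (1) run the GA once for every
#' candidate configuration of the hyperparameter grid; (2) select the GA
#' settings coordinate-wise by median fitting error
#' ([select_hyperparameters()]); (3) re-run the GA `replicates` times
#' under the selected settings with fresh random seeds; (4) return the
#' best fit (optionally polished, see [ga_fit()]).
#'
#' @param ds A dataset.
#' @param grid A [hyper_grid()] of candidate GA settings (default: the
#'   243-configuration grid).
#' @param replicates Replicate fits under the selected settings
#'   (default 20; large-scale studies would use hundreds).
#' @param seed Master seed; all stage seeds derive from it.
#' @param params Parameter template carrying the search bounds.
#' @param polish Apply the final local refinement (default `TRUE`).
#' @return A `prostimm_fit` with fields `params` (estimates), `objective`
#'   (SSE), `config` (selected GA settings), `seed`, `trace`
#'   (per-generation best objective of the winning run),
#'   `replicate_objectives`, and `stage1` (the per-candidate errors).
#' @examples
#' \donttest{
#' ds <- generate_dataset(noise = noise_model(sigma = 0, replicates = 1), seed = 1)
#' small <- hyper_grid(generations = 30, population = c(20, 30),
#'                     p_crossover = 0.9, eta_crossover = 15, eta_mutation = 20)
#' fit <- mga_fit(ds, small, replicates = 3, seed = 1)
#' }
#' @export
mga_fit <- function(ds, grid = hyper_grid(), replicates = 20, seed = 1L,
                    params = parameter_table(), polish = TRUE) {
  if (replicates < 1) abort("`replicates` must be >= 1.")
  ctx <- make_fit_context(ds, params)
  obj <- ctx_objective_log(ctx)
  lo <- log10(ctx$lower); hi <- log10(ctx$upper)

  enum <- hypergrid_enumerate(grid)
  stage_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L,
                                             nrow(enum) + replicates))
  runs <- vector("list", nrow(enum))
  errs <- numeric(nrow(enum))
  for (i in seq_len(nrow(enum))) {
    cfg <- ga_config(generations = enum$generations[i],
                     population = enum$population[i],
                     p_crossover = enum$p_crossover[i],
                     p_mutation = enum$p_mutation[i],
                     eta_crossover = enum$eta_crossover[i],
                     eta_mutation = enum$eta_mutation[i],
                     seed = stage_seeds[i])
    runs[[i]] <- ga_minimize(obj, lo, hi, cfg)
    errs[i] <- runs[[i]]$value
  }
  stage1 <- bind_cols(enum, tibble(error = errs))
  selected <- select_hyperparameters(stage1, grid)

  # Each replicate is optionally polished before comparison: different GA
  # runs land in different basins, and the basin depth after local
  # refinement — not the raw GA value — is what ranks them.
  rep_seeds <- stage_seeds[nrow(enum) + seq_len(replicates)]
  # the stage-1 run under the selected settings competes too, so the
  # final objective can never be worse than the selected candidate's error
  sel_i <- which(enum$generations == selected$generations &
                 enum$population == selected$population &
                 enum$p_crossover == selected$p_crossover &
                 enum$p_mutation == selected$p_mutation &
                 enum$eta_crossover == selected$eta_crossover &
                 enum$eta_mutation == selected$eta_mutation)
  best <- NULL
  best_polished <- FALSE
  rep_obj <- numeric(replicates)
  for (r in c(if (length(sel_i) == 1) 0L, seq_len(replicates))) {
    if (r == 0L) {
      run <- runs[[sel_i]]
    } else {
      cfg <- selected
      cfg$seed <- rep_seeds[r]
      run <- ga_minimize(obj, lo, hi, cfg)
    }
    run_polished <- FALSE
    if (polish) {
      pol <- polish_fit(ctx, run$par)
      if (!is.null(pol) && is.finite(pol$value) && pol$value < run$value) {
        run$par <- pol$par
        run$value <- pol$value
        run_polished <- TRUE
      }
    }
    if (r > 0L) rep_obj[r] <- run$value
    if (is.null(best) || run$value < best$value) {
      best <- run
      best_polished <- run_polished
    }
  }
  est <- set_estimated(params, 10^best$par)
  new_fit_result(est, best$value, best$config, seed, best$trace,
                 replicate_objectives = rep_obj, stage1 = stage1,
                 polished = best_polished)
}

#' Bootstrap identifiability analysis
#'
#' Resamples replicate measurements within each data box (nonparametric
#' bootstrap, with replacement, preserving box sizes), refits the model
#' to each resample, and summarizes each parameter's bootstrap estimate
#' distribution by its coefficient of variation CV = sd / mean (sample
#' standard deviation). A parameter is flagged non-identifiable when its
#' CV exceeds 1.
#'
#' @param ds A dataset (boxes need >= 1 replicate; resampling preserves
#'   box sizes so no resample can empty a box).
#' @param config GA configuration used for each refit.
#' @param n_boot Number of bootstrap resamples (>= 2; the full-scale
#'   analysis uses 100).
#' @param seed Master seed.
#' @param params Parameter template with bounds.
#' @param polish Polish each refit (default `TRUE`).
#' @param cv_threshold Identifiability threshold on the CV (default 1).
#' @return A tibble: `name`, `index`, `mean`, `sd`, `cv`, `identifiable`,
#'   with the bootstrap estimates matrix in attribute `"estimates"`.
#' @export
bootstrap_identifiability <- function(ds, config = ga_config(), n_boot = 100,
                                      seed = 1L, params = parameter_table(),
                                      polish = TRUE, cv_threshold = 1) {
  if (n_boot < 2) abort("`n_boot` must be >= 2.")
  validate_dataset(ds)
  boot_seeds <- withr_seed(seed, sample.int(.Machine$integer.max - 1L, 2 * n_boot))
  est_names <- estimated_param_names
  estimates <- matrix(NA_real_, nrow = n_boot, ncol = length(est_names),
                      dimnames = list(NULL, est_names))
  for (b in seq_len(n_boot)) {
    res <- withr_seed(boot_seeds[b], resample_within_boxes(ds))
    cfg <- config
    cfg$seed <- boot_seeds[n_boot + b]
    fit <- ga_fit(res, cfg, params = params, polish = polish)
    ev <- fit$params[fit$params$estimated, ]
    estimates[b, ] <- ev$value[order(ev$index)]
  }
  out <- tibble(
    name = est_names,
    index = seq_along(est_names),
    mean = colMeans(estimates),
    sd = apply(estimates, 2, stats::sd)
  )
  out$cv <- out$sd / out$mean
  out$identifiable <- out$cv <= cv_threshold
  attr(out, "estimates") <- estimates
  out
}

resample_within_boxes <- function(ds) {
  resampled <- ds |>
    group_by(.data$condition, .data$observable, .data$time_weeks) |>
    group_modify(function(g, key) {
      if (nrow(g) == 0) abort("Empty data box encountered during resampling.")
      picked <- g[sample.int(nrow(g), nrow(g), replace = TRUE), ]
      picked$replicate_id <- seq_len(nrow(picked))
      picked
    }) |>
    ungroup()
  new_dataset(resampled)
}

#' Delta-method identifiability screen
#'
#' A fast, deterministic complement to [bootstrap_identifiability()]: the
#' Jacobian of the residual vector with respect to the log-parameters is
#' evaluated at a reference parameter set, and the Gauss-Newton
#' covariance under a nominal measurement noise is propagated to a
#' predicted coefficient of variation per parameter. Parameters whose
#' predicted CV exceeds the threshold are sloppy directions of the
#' design: the data constrain them weakly (for this model, notably the
#' antigen-scale parameters, since the antigen pool itself is never
#' measured).
#'
#' @param ds A dataset (defines the measurement design; its values are
#'   not used beyond the design).
#' @param params Reference parameter tibble (values and bounds).
#' @param sigma Nominal relative measurement noise (default 0.05).
#' @param cv_threshold Identifiability threshold on the predicted CV
#'   (default 1, the same cut used for the bootstrap CV).
#' @return A tibble: `name`, `index`, `cv`, `identifiable`.
#' @export
identifiability_screen <- function(ds, params, sigma = 0.05, cv_threshold = 1) {
  ctx <- make_fit_context(ds, params)
  est <- params[params$estimated, ]
  est <- est[order(est$index), ]
  z0 <- log10(est$value)
  r0 <- ctx_residuals(ctx, 10^z0)
  if (is.null(r0)) abort("Reference simulation failed in identifiability screen.")
  h <- 1e-5
  J <- vapply(seq_along(z0), function(j) {
    z <- z0
    z[j] <- z[j] + h
    (ctx_residuals(ctx, 10^z) - r0) / h
  }, numeric(length(r0)))
  # pseudo-inverse of J'J via SVD (the information matrix is near-singular
  # along sloppy directions by construction)
  sv <- svd(crossprod(J))
  keep <- sv$d > max(sv$d) * 1e-12
  Cinv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  cv <- log(10) * sigma * sqrt(pmax(diag(Cinv), 0))
  tibble(name = est$name, index = est$index, cv = cv,
         identifiable = cv <= cv_threshold)
}
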